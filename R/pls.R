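# Partial least squares regression (single response), spatial spin
# permutation inference, bootstrap gene Z-scores, and the subject-level
# clinical PLS.

# Fast internal first-component fit on pre-standardized inputs: weights are
# the normalized cross-covariance direction, sign-aligned so that the
# component scores correlate positively with the response.
.pls1_core <- function(Xs, ys) {
  w <- as.numeric(crossprod(Xs, ys))
  nrm <- sqrt(sum(w^2))
  if (nrm == 0) stop("response is uncorrelated with every predictor column")
  w <- w / nrm
  s <- as.numeric(Xs %*% w)
  r <- stats::cor(s, ys)
  if (is.finite(r) && r < 0) {
    w <- -w
    s <- -s
    r <- -r
  }
  list(weights = w, scores = s, evy = if (is.finite(r)) r^2 else 0)
}

#' Partial least squares regression of a map on gene expression
#'
#' Fits PLS with a single response. Predictor columns and the response are
#' z-scored first; the first component is extracted as the dominant singular
#' direction of the predictor-response cross-covariance (for a single
#' response this is the normalized `t(X) %*% y` direction), and further
#' components, if requested, follow by deflation. The first-component weight
#' vector has unit norm and its sign is fixed so that the component scores
#' correlate positively with the response. Explained variance in the
#' response is the squared Pearson correlation between the first-component
#' scores and the response.
#'
#' @param X Observations x predictors numeric matrix (e.g. regions x genes).
#' @param y Numeric response vector aligned with the rows of `X`.
#' @param n_components Number of components to extract (inference downstream
#'   uses only the first).
#' @return List of class `pls_fit`: `weights` (named, first component, unit
#'   norm), `scores` (named by observations), `explained_variance_y`,
#'   `weight_matrix` (predictors x components), `score_matrix`,
#'   `dropped_columns` (zero-variance predictors removed with a warning).
#' @export
pls_fit <- function(X, y, n_components = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows of X must align with y")
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (stats::sd(y) == 0) stop("response has zero variance")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0]
  if (length(dropped)) {
    warning("dropping ", length(dropped), " zero-variance column(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  Xs <- scale(X)
  ys <- as.numeric(scale(y))
  n_components <- min(n_components, ncol(Xs), nrow(Xs) - 1L)

  W <- matrix(0, ncol(Xs), n_components,
              dimnames = list(colnames(Xs), NULL))
  S <- matrix(0, nrow(Xs), n_components,
              dimnames = list(rownames(X), NULL))
  Xd <- Xs
  yd <- ys
  for (k in seq_len(n_components)) {
    # dominant singular direction of the cross-covariance t(Xd) %*% yd
    sv <- svd(crossprod(Xd, matrix(yd)), nu = 1, nv = 0)
    w <- as.numeric(sv$u)
    s <- as.numeric(Xd %*% w)
    if (sum(s * yd) < 0) {
      w <- -w
      s <- -s
    }
    W[, k] <- w
    S[, k] <- s
    p <- as.numeric(crossprod(Xd, s)) / sum(s^2)
    Xd <- Xd - tcrossprod(s, p)
    yd <- yd - s * sum(s * yd) / sum(s^2)
  }
  scores1 <- S[, 1]
  r <- stats::cor(scores1, ys)
  structure(list(weights = stats::setNames(W[, 1], colnames(Xs)),
                 scores = stats::setNames(scores1, rownames(X)),
                 explained_variance_y = r^2,
                 weight_matrix = W,
                 score_matrix = S,
                 dropped_columns = dropped),
            class = "pls_fit")
}

#' Spherical-rotation (spin) permutation null for parcellated maps
#'
#' Draws rotations uniformly from SO(3), applies each to the parcel
#' centroids, and relabels every region to the region whose original
#' centroid is nearest to its rotated position (duplicates permitted). An
#' exactly-identity relabeling is rejected and redrawn. Because rotations
#' are isometries of the sphere, the relabeled maps preserve the spatial
#' autocorrelation structure of the original map.
#'
#' @param atlas A `parcel_atlas`; only left-hemisphere parcels are used.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param regions Optional subset of left-hemisphere parcel ids (in analysis
#'   order); defaults to all left parcels.
#' @param off_sphere What to do when centroids are not on a common sphere
#'   (relative radius spread > 1e-6): `"error"` (default) or `"project"`
#'   onto the mean-radius sphere with a warning.
#' @return Integer matrix of class `spin_perms`, `n_perm` x n_regions; row
#'   `p` maps analysis position `i` to source position `perm[p, i]`.
#' @export
spin_rotation_null <- function(atlas, n_perm = 1000L, seed = 1L,
                               regions = NULL,
                               off_sphere = c("error", "project")) {
  off_sphere <- match.arg(off_sphere)
  left <- atlas[atlas$hemisphere == "left", , drop = FALSE]
  if (is.null(regions)) regions <- left$parcel_id
  if (!all(regions %in% left$parcel_id))
    stop("'regions' must be left-hemisphere parcel ids")
  C <- .atlas_coords(atlas, "left", regions)
  radii <- sqrt(rowSums(C^2))
  rbar <- mean(radii)
  if (max(abs(radii - rbar)) / rbar > 1e-6) {
    if (off_sphere == "error")
      stop("centroids are not on a common sphere; use off_sphere = 'project'")
    warning("projecting centroids onto the mean-radius sphere")
    C <- C * (rbar / radii)
  }
  n <- nrow(C)
  set.seed(seed)
  perms <- matrix(0L, n_perm, n)
  colnames(perms) <- regions
  for (p in seq_len(n_perm)) {
    repeat {
      R <- .random_rotation()
      rotated <- C %*% t(R)
      d <- .cross_dist(rotated, C)
      perm <- max.col(-d, ties.method = "first")
      if (!all(perm == seq_len(n))) break
    }
    perms[p, ] <- perm
  }
  structure(perms, class = c("spin_perms", class(perms)), seed = seed)
}

# Haar-uniform rotation: QR of a Gaussian matrix with sign correction, then
# a column flip if the determinant is -1 (maps O(3) \ SO(3) onto SO(3)).
.random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Columns retained by pls_fit (robust to missing dimnames: when X has no
# column names, zero-variance columns can only be identified positionally).
.kept_columns <- function(X, fit) {
  if (!length(fit$dropped_columns)) return(rep(TRUE, ncol(X)))
  if (is.null(colnames(X))) return(apply(X, 2, stats::sd) > 0)
  !(colnames(X) %in% fit$dropped_columns)
}

# Explained variance of the first PLS component for many response vectors at
# once (columns of Y), on a pre-standardized predictor matrix.
.pls1_evy_batch <- function(Xs, Y) {
  Ys <- .zscore_cols(Y)
  W <- crossprod(Xs, Ys)                       # p x m
  nrm <- sqrt(colSums(W^2))
  nrm[nrm == 0] <- 1
  S <- Xs %*% sweep(W, 2, nrm, "/")            # n x m scores
  Ss <- .zscore_cols(S)
  (colSums(Ss * Ys) / (nrow(Xs) - 1))^2
}

#' Spin-permutation p-value for the PLS explained variance
#'
#' The observed statistic is the variance in the response explained by the
#' first PLS component; the null distribution refits the PLS with the
#' response relabeled by each spatial permutation. The p-value uses the
#' add-one rule `(1 + #{null >= observed}) / (n_perm + 1)` and is therefore
#' never zero.
#'
#' @param X Regions x genes predictor matrix (rownames are parcel ids).
#' @param y Response map aligned with the rows of `X`.
#' @param atlas A `parcel_atlas` (ignored when `perms` is supplied).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param perms Optional precomputed permutation matrix (`spin_perms` or any
#'   n_perm x n_regions index matrix), e.g. to share spins across analyses
#'   or to substitute a naive permutation null.
#' @param null `"spin"` (default) or `"naive"` (unrestricted shuffling of
#'   the response across regions, provided for comparison; it destroys
#'   spatial autocorrelation and over-rejects on smooth maps).
#' @return List: `p_spin`, `observed` (explained variance), `null`
#'   (permutation statistics), `fit` (the observed [pls_fit()]), `n_perm`.
#' @export
pls_spin_pvalue <- function(X, y, atlas = NULL, n_perm = 1000L, seed = 1L,
                            perms = NULL, null = c("spin", "naive")) {
  null <- match.arg(null)
  fit <- pls_fit(X, y)
  if (is.null(perms)) {
    if (null == "spin") {
      if (is.null(atlas)) stop("'atlas' is required for the spin null")
      perms <- spin_rotation_null(atlas, n_perm, seed, regions = rownames(X))
    } else {
      set.seed(seed)
      n <- length(y)
      perms <- t(replicate(n_perm, sample.int(n)))
    }
  }
  n_perm <- nrow(perms)
  keep <- .kept_columns(X, fit)
  Xs <- .zscore_cols(as.matrix(X)[, keep, drop = FALSE])
  Y <- matrix(y[t(perms)], nrow = ncol(perms))  # regions x n_perm
  null_evy <- .pls1_evy_batch(Xs, Y)
  obs <- fit$explained_variance_y
  list(p_spin = (1 + sum(null_evy >= obs)) / (n_perm + 1),
       observed = obs, null = null_evy, fit = fit, n_perm = n_perm)
}

#' Bootstrap Z-scores, FDR and signed gene lists for PLS1 weights
#'
#' Resamples observations (regions) with replacement, refits the
#' first-component weights, aligns each bootstrap replicate's sign to the
#' original weight vector (dot product), and defines the Z-score of each
#' gene as its original weight divided by the bootstrap standard error.
#' Two-sided normal p-values are corrected with Benjamini-Hochberg FDR; the
#' positive and negative gene lists collect genes with `q < fdr_threshold`
#' and the matching weight sign. Genes with zero bootstrap SE are flagged
#' and excluded from the lists.
#'
#' @param X Regions x genes predictor matrix.
#' @param y Response map aligned with rows of `X`.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param fdr_threshold FDR threshold for list membership (default 0.001).
#' @return List of class `pls_bootstrap`: `weights`, `bootstrap_se`,
#'   `z_score`, `p`, `q_fdr`, `pls1_plus`, `pls1_minus`, `flagged` (zero-SE
#'   genes), `n_boot`, `gene_table` (a tidy `data.frame`).
#' @export
bootstrap_gene_z <- function(X, y, n_boot = 1000L, seed = 1L,
                             fdr_threshold = 0.001) {
  fit <- pls_fit(X, y)
  keep <- .kept_columns(X, fit)
  X <- as.matrix(X)[, keep, drop = FALSE]
  w0 <- fit$weights
  n <- nrow(X)
  set.seed(seed)
  boots <- matrix(NA_real_, length(w0), n_boot,
                  dimnames = list(names(w0), NULL))
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(y[idx]) > 0) break
    }
    Xs <- .zscore_cols(X[idx, , drop = FALSE])
    ys <- as.numeric(scale(y[idx]))
    wb <- .pls1_core(Xs, ys)$weights
    if (sum(wb * w0) < 0) wb <- -wb
    boots[, b] <- wb
  }
  se <- apply(boots, 1, stats::sd)
  flagged <- names(w0)[se == 0]
  if (length(flagged))
    warning(length(flagged), " gene(s) with zero bootstrap SE excluded from lists")
  z <- ifelse(se > 0, w0 / se, NA_real_)
  p <- 2 * stats::pnorm(-abs(z))
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  names(z) <- names(p) <- names(q) <- names(w0)
  plus <- names(w0)[ok & z > 0 & q < fdr_threshold]
  minus <- names(w0)[ok & z < 0 & q < fdr_threshold]
  gene_table <- data.frame(gene_id = names(w0), weight = w0, se = se,
                           z = z, p = p, q = q,
                           list = ifelse(names(w0) %in% plus, "+",
                                         ifelse(names(w0) %in% minus, "-",
                                                "none")),
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(list(weights = w0, bootstrap_se = se, z_score = z, p = p,
                 q_fdr = q, pls1_plus = plus, pls1_minus = minus,
                 flagged = flagged, n_boot = n_boot,
                 fdr_threshold = fdr_threshold, gene_table = gene_table),
            class = "pls_bootstrap")
}

#' Subject-level PLS predicting symptom improvement from GMV change
#'
#' Fits a single-component PLS of the symptom improvement
#' (`hamd_pre - hamd_post`) on the subject x region GMV-change matrix. The
#' association strength is the Pearson correlation between subject scores
#' and the outcome; its significance comes from shuffling the outcome across
#' subjects with the add-one rule. Regional contributions are summarized by
#' `z = weight / bootstrap SE` over subject resamples (sign-aligned as in
#' [bootstrap_gene_z()]).
#'
#' @param delta_gmv Subject x region matrix of GMV change (mm3).
#' @param outcome Named numeric vector of symptom improvement per subject.
#' @param n_perm Outcome permutations.
#' @param n_boot Subject bootstrap resamples.
#' @param seed Integer seed.
#' @return List of class `clinical_pls`: `score_per_subject`,
#'   `r_with_outcome`, `p_perm`, `region_weight`, `region_se`, `region_z`,
#'   `n_perm`, `n_boot`.
#' @export
clinical_pls <- function(delta_gmv, outcome, n_perm = 1000L, n_boot = 1000L,
                         seed = 1L) {
  delta_gmv <- as.matrix(delta_gmv)
  if (nrow(delta_gmv) < 3L) stop("need at least 3 subjects")
  if (!is.null(names(outcome)) && !is.null(rownames(delta_gmv))) {
    if (!setequal(names(outcome), rownames(delta_gmv)))
      stop("subjects in predictor and outcome do not match")
    outcome <- outcome[rownames(delta_gmv)]
  } else if (length(outcome) != nrow(delta_gmv)) {
    stop("subjects in predictor and outcome do not match")
  }
  fit <- pls_fit(delta_gmv, outcome)
  r_obs <- suppressWarnings(stats::cor(fit$scores, outcome))

  keep <- .kept_columns(delta_gmv, fit)
  Xk <- delta_gmv[, keep, drop = FALSE]
  Xs <- .zscore_cols(Xk)
  set.seed(child_seed(seed, "clinical"))
  null_r <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    yp <- sample(outcome)
    null_r[p] <- sqrt(.pls1_evy_batch(Xs, matrix(yp))[1])
  }
  p_perm <- (1 + sum(null_r >= r_obs)) / (n_perm + 1)

  w0 <- fit$weights
  n <- nrow(Xk)
  boots <- matrix(NA_real_, length(w0), n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, replace = TRUE)
      if (stats::sd(outcome[idx]) > 0) break
    }
    wb <- .pls1_core(.zscore_cols(Xk[idx, , drop = FALSE]),
                     as.numeric(scale(outcome[idx])))$weights
    if (sum(wb * w0) < 0) wb <- -wb
    boots[, b] <- wb
  }
  se <- apply(boots, 1, stats::sd)
  z <- ifelse(se > 0, w0 / se, NA_real_)
  structure(list(score_per_subject = fit$scores,
                 r_with_outcome = r_obs,
                 p_perm = p_perm,
                 region_weight = w0,
                 region_se = stats::setNames(se, names(w0)),
                 region_z = stats::setNames(z, names(w0)),
                 explained_variance_y = fit$explained_variance_y,
                 n_perm = n_perm, n_boot = n_boot),
            class = "clinical_pls")
}
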