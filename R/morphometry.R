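# Regional gray-matter-volume change statistics.

# Reshape the long study table to region x subject matrices, validating
# completeness (every subject must have both timepoints for every parcel).
.study_matrices <- function(table) {
  req <- c("subject_id", "parcel_id", "gmv_pre", "gmv_post", "tiv",
           "hamd_pre", "hamd_post")
  miss <- setdiff(req, names(table))
  if (length(miss)) stop("study table is missing columns: ",
                         paste(miss, collapse = ", "))
  subjects <- unique(table$subject_id)
  regions <- unique(table$parcel_id)
  key <- paste(table$parcel_id, table$subject_id)
  full <- as.vector(outer(regions, subjects, paste))
  if (anyDuplicated(key) || !setequal(key, full))
    stop("study table must contain exactly one row per subject x parcel")
  idx <- match(full, key)
  pre <- matrix(table$gmv_pre[idx], length(regions), length(subjects),
                dimnames = list(regions, subjects))
  post <- matrix(table$gmv_post[idx], length(regions), length(subjects),
                 dimnames = list(regions, subjects))
  per_sub <- table[match(subjects, table$subject_id), , drop = FALSE]
  if (any(per_sub$tiv <= 0)) stop("tiv must be positive for every subject")
  list(pre = pre, post = post, subjects = subjects, regions = regions,
       tiv = stats::setNames(per_sub$tiv, subjects),
       hamd_pre = stats::setNames(per_sub$hamd_pre, subjects),
       hamd_post = stats::setNames(per_sub$hamd_post, subjects))
}

#' Regional GMV-change t-map with TIV adjustment
#'
#' Per region, fits the difference-score model
#' `delta_s = b0 + b1 * (TIV_s - mean(TIV))` over subjects, where
#' `delta_s = gmv_post - gmv_pre`. The reported t statistic is that of the
#' intercept `b0` (the TIV-adjusted mean change) on `n - 2` degrees of
#' freedom, with a two-sided Student-t p-value. A positive t means a
#' regional volume increase after treatment.
#'
#' @param table A `gmv_study` long table (one row per subject x parcel).
#' @return `data.frame` of class `gmv_tmap` with columns `parcel_id`,
#'   `t_value`, `p_value`, `mean_delta`, `df`.
#' @export
regional_change_tmap <- function(table) {
  m <- .study_matrices(table)
  n <- length(m$subjects)
  if (n < 3L) stop("need at least 3 subjects")
  delta <- m$post - m$pre                  # region x subject
  tc <- m$tiv - mean(m$tiv)
  # centered covariate: the intercept is the plain mean change, its SE uses
  # the residual variance after removing the TIV slope (df = n - 2)
  mean_delta <- rowMeans(delta)
  ss_t <- sum(tc^2)
  if (ss_t > 0) {
    b1 <- as.numeric(delta %*% tc) / ss_t
    resid <- delta - mean_delta - outer(b1, tc)
  } else {
    resid <- delta - mean_delta
  }
  s2 <- rowSums(resid^2) / (n - 2)
  se <- sqrt(s2 / n)
  t_value <- ifelse(se > 0, mean_delta / se,
                    ifelse(mean_delta == 0, 0, sign(mean_delta) * Inf))
  p_value <- ifelse(is.finite(t_value),
                    2 * stats::pt(-abs(t_value), df = n - 2), 0)
  p_value[t_value == 0] <- 1
  out <- data.frame(parcel_id = m$regions, t_value = t_value,
                    p_value = p_value, mean_delta = mean_delta,
                    df = n - 2L, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gmv_tmap", "data.frame")
  out
}

#' Paired t-test of symptom change
#'
#' Paired Student t-test of post- versus pre-treatment HAMD scores
#' (differences `post - pre`, so improvement gives a negative t), on
#' `n - 1` degrees of freedom.
#'
#' @param table A `gmv_study` long table.
#' @return List with `t`, `df`, `p`, `mean_diff` and a `degenerate` flag
#'   (TRUE when the differences have zero variance and nonzero mean, in
#'   which case `t` is infinite).
#' @export
hamd_change_test <- function(table) {
  m <- .study_matrices(table)
  n <- length(m$subjects)
  if (n < 2L) stop("need at least 2 subjects")
  d <- m$hamd_post - m$hamd_pre
  s <- stats::sd(d)
  degenerate <- FALSE
  if (s == 0) {
    if (mean(d) == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- 0
      degenerate <- TRUE
      warning("zero variance of HAMD differences; t is infinite")
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(t = t, df = n - 1L, p = p, mean_diff = mean(d),
       degenerate = degenerate)
}

#' Subject x region GMV-change matrix
#'
#' Convenience accessor used by the clinical PLS: the matrix of
#' `gmv_post - gmv_pre` with subjects as rows, plus the symptom
#' improvement (`hamd_pre - hamd_post`, positive = improvement).
#'
#' @param table A `gmv_study` long table.
#' @return List with `delta_gmv` (subject x region matrix) and
#'   `improvement` (named subject vector).
#' @export
study_change_matrix <- function(table) {
  m <- .study_matrices(table)
  list(delta_gmv = t(m$post - m$pre),
       improvement = m$hamd_pre - m$hamd_post)
}
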