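# Gene set enrichment: hypergeometric over-representation of signed PLS
# gene lists, and running-sum GSEA over the ranked bootstrap Z statistic
# with a gene-label permutation null and set-size-normalized NES.

#' Gene set collection constructor
#'
#' @param sets Named list of character vectors of gene ids.
#' @param background Character vector: the gene universe. Members outside
#'   the background are dropped (harmonization) and counted.
#' @param descriptions Optional named character vector of set descriptions.
#' @return A list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, background,
                                descriptions = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  background <- unique(background)
  dropped <- lapply(sets, function(s) setdiff(s, background))
  sets <- lapply(sets, function(s) intersect(unique(s), background))
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets,
                 descriptions = descriptions[names(sets)],
                 background = background),
            class = "gene_set_collection",
            dropped_members = dropped)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, with universe size `N`, set size `K`, list size `n` and
#' overlap `k`, computes the upper-tail hypergeometric probability
#' `P(X >= k)`, then Benjamini-Hochberg FDR across sets. A set is called
#' significant when `q < alpha`.
#'
#' @param gene_list Character vector of genes (e.g. a PLS1+ list); must be
#'   contained in the collection background.
#' @param collection A `gene_set_collection`.
#' @param alpha FDR significance threshold (default 0.05).
#' @return `data.frame`: `set_id`, `set_size`, `overlap`, `p`, `q`,
#'   `significant`.
#' @export
ora_hypergeometric <- function(gene_list, collection, alpha = 0.05) {
  bg <- collection$background
  if (!length(bg)) stop("empty background")
  if (!length(gene_list)) stop("empty gene list")
  gene_list <- unique(gene_list)
  if (!all(gene_list %in% bg))
    stop("gene list contains genes outside the background")
  N <- length(bg)
  n <- length(gene_list)
  res <- lapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    K <- length(s)
    k <- length(intersect(gene_list, s))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set_id = id, set_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out
}

#' GSEA running-sum enrichment score
#'
#' Genes are sorted by statistic, descending (ties broken by gene id for
#' determinism). Walking down the ranking, set members ("hits") increment
#' the running sum by their `|statistic|^exponent`, normalized so the hit
#' increments total 1; non-members decrement by `1/(N - K)`. The enrichment
#' score is the maximum-magnitude deviation of the running sum, and the
#' leading edge collects the hits at or before the extremum (positive ES)
#' or at or after it (negative ES).
#'
#' @param ranked Named numeric vector: gene -> statistic (finite).
#' @param set Character vector of gene ids (nonempty intersection with
#'   `names(ranked)` required).
#' @param exponent Weighting exponent on `|statistic|` (default 1; 0 gives
#'   the classic unweighted Kolmogorov-Smirnov walk).
#' @return List: `es`, `running_sum` (in ranking order, named), `leading_edge`.
#' @export
gsea_es <- function(ranked, set, exponent = 1) {
  if (!all(is.finite(ranked))) stop("ranked statistics must be finite")
  ord <- order(-ranked, names(ranked))
  stats_sorted <- ranked[ord]
  hits <- names(stats_sorted) %in% set
  if (!any(hits)) stop("set has no genes in the ranked list")
  .gsea_walk(stats_sorted, hits, exponent)
}

# Core running-sum computation on a pre-sorted statistic vector.
.gsea_walk <- function(stats_sorted, hits, exponent) {
  N <- length(stats_sorted)
  K <- sum(hits)
  if (K == N) {
    steps <- abs(stats_sorted)^exponent
    tot <- sum(steps)
    steps <- if (tot > 0) steps / tot else rep(1 / N, N)
  } else {
    w <- abs(stats_sorted[hits])^exponent
    tot <- sum(w)
    w <- if (tot > 0) w / tot else rep(1 / K, K)
    steps <- rep(-1 / (N - K), N)
    steps[hits] <- w
  }
  rs <- cumsum(steps)
  i_star <- which.max(abs(rs))
  es <- rs[[i_star]]
  leading <- if (es >= 0) which(hits & seq_len(N) <= i_star)
             else which(hits & seq_len(N) >= i_star)
  list(es = es, running_sum = rs,
       leading_edge = names(stats_sorted)[leading])
}

#' Permutation GSEA with normalized enrichment scores
#'
#' For each set, the observed enrichment score is compared with a null
#' distribution obtained by permuting gene labels (equivalently, redrawing
#' the hit positions uniformly) `n_perm` times. The normalized enrichment
#' score is `NES = ES / mean(|null ES| of the same sign)`, and the p-value
#' is the add-one tail frequency among same-sign nulls. P-values are
#' corrected across sets with Benjamini-Hochberg FDR.
#'
#' @param ranked Named numeric vector: gene -> statistic.
#' @param collection A `gene_set_collection`; sets are harmonized to the
#'   genes present in `ranked`.
#' @param n_perm Number of label permutations (default 10000).
#' @param exponent Hit-weighting exponent (default 1).
#' @param seed Integer seed.
#' @param alpha FDR significance threshold (default 0.05).
#' @return `data.frame` of class `gsea_result`: `set_id`, `set_size`,
#'   `es`, `nes`, `p`, `q`, `significant`, `leading_edge_size`,
#'   `nes_reliable` (FALSE when no same-sign null existed), plus the
#'   leading-edge genes in `attr(, "leading_edge")`.
#' @export
gsea_permutation <- function(ranked, collection, n_perm = 10000L,
                             exponent = 1, seed = 1L, alpha = 0.05) {
  if (!all(is.finite(ranked))) stop("ranked statistics must be finite")
  universe <- names(ranked)
  coll <- gene_set_collection(collection$sets, intersect(collection$background,
                                                         universe),
                              collection$descriptions)
  ord <- order(-ranked, names(ranked))
  stats_sorted <- ranked[ord]
  N <- length(stats_sorted)
  set.seed(seed)
  leading <- list()
  rows <- list()
  for (id in names(coll$sets)) {
    s <- coll$sets[[id]]
    if (!length(s)) stop("set '", id, "' has no genes in the ranked list")
    hits <- names(stats_sorted) %in% s
    obs <- .gsea_walk(stats_sorted, hits, exponent)
    K <- sum(hits)
    null_es <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      h <- logical(N)
      h[sample.int(N, K)] <- TRUE
      null_es[p] <- .gsea_walk(stats_sorted, h, exponent)$es
    }
    same <- if (obs$es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    if (length(same)) {
      nes <- obs$es / mean(abs(same))
      pval <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      reliable <- TRUE
    } else {
      nes <- NA_real_
      pval <- 1 / (n_perm + 1)
      reliable <- FALSE
    }
    leading[[id]] <- obs$leading_edge
    rows[[id]] <- data.frame(set_id = id, set_size = K, es = obs$es,
                             nes = nes, p = pval,
                             leading_edge_size = length(obs$leading_edge),
                             nes_reliable = reliable,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < alpha
  out <- out[, c("set_id", "set_size", "es", "nes", "p", "q", "significant",
                 "leading_edge_size", "nes_reliable")]
  attr(out, "leading_edge") <- leading
  class(out) <- c("gsea_result", "data.frame")
  out
}

#' Overlap counts between signed PLS gene lists and gene sets
#'
#' Exact intersection sizes per (list, set) pair after harmonization to the
#' collection background.
#'
#' @param pls_lists List with elements `plus` and `minus` (character
#'   vectors of gene ids).
#' @param collection A `gene_set_collection`.
#' @return `data.frame`: `list`, `set_id`, `overlap`, `list_size`,
#'   `set_size`.
#' @export
celltype_overlap_counts <- function(pls_lists, collection) {
  stopifnot(all(c("plus", "minus") %in% names(pls_lists)))
  bg <- collection$background
  rows <- list()
  for (side in c("plus", "minus")) {
    gl <- intersect(pls_lists[[side]], bg)
    for (id in names(collection$sets)) {
      s <- collection$sets[[id]]
      rows[[paste(side, id)]] <-
        data.frame(list = side, set_id = id,
                   overlap = length(intersect(gl, s)),
                   list_size = length(gl), set_size = length(s),
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
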