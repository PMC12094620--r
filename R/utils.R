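# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stage-specific child seed from the run seed
#'
#' A single run seed fans out to one child seed per pipeline stage so that a
#' stage can be rerun in isolation and reproduce its random stream. The
#' derivation is a fixed affine map modulo 2^31 - 1 and involves no global
#' state.
#'
#' @param seed Integer run seed.
#' @param stage Character stage name (one of the names in
#'   `.pipeline_stages`).
#' @return An integer seed in `[1, 2^31 - 1]`.
#' @export
child_seed <- function(seed, stage) {
  stages <- .pipeline_stages
  idx <- match(stage, stages)
  if (is.na(idx)) stop("unknown stage: ", stage)
  s <- (as.numeric(seed) %% 2147483647) * 48271 + idx * 1000003
  as.integer(s %% 2147483647 + 1)
}

.pipeline_stages <- c("simulate", "expression", "tmap", "pls_spin",
                      "pls_boot", "clinical", "enrich")

# Format doubles so that read.delim round-trips them bit-exactly.
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# Euclidean distance matrix between the rows of two coordinate matrices.
.cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Column z-scores; columns with zero variance become all-zero instead of NaN
# so that downstream linear algebra stays finite (their weight is then 0).
.zscore_cols <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  Xs <- sweep(X, 2, mu, "-")
  ok <- sd > 0
  Xs[, ok] <- sweep(Xs[, ok, drop = FALSE], 2, sd[ok], "/")
  Xs[, !ok] <- 0
  attr(Xs, "zero_var") <- !ok
  Xs
}
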