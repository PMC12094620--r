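# Shared fixtures: all test data is built in code at run time.

# Small-but-complete synthetic configuration for fast end-to-end tests.
tiny_config <- function(seed = 1L, ...) {
  args <- list(n_parcels_left = 40L, n_donors = 4L, n_samples_per_donor = 50L,
               n_genes = 60L, probes_per_gene = 2L, n_subjects = 12L,
               n_causal_genes = 10L, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(synthetic_config, args)
}

# Hand-built donor with explicit probe x sample expression and coordinates.
# `parcels` gives the true parcel per sample; coordinates sit exactly on the
# centroids unless `offset` shifts them.
make_donor <- function(id, atlas, parcels, expression, probe_gene_map,
                       above = NULL, offset = 0) {
  coords <- as.matrix(atlas[match(parcels, atlas$parcel_id),
                            c("x", "y", "z")]) + offset
  sample_ids <- sprintf("%s_s%02d", id, seq_along(parcels))
  rownames(coords) <- sample_ids
  colnames(expression) <- sample_ids
  if (is.null(above)) {
    above <- matrix(TRUE, nrow(expression), ncol(expression))
    dimnames(above) <- dimnames(expression)
  } else {
    dimnames(above) <- dimnames(expression)
  }
  structure(list(donor_id = id, sample_coords = coords,
                 expression = expression, above_background = above,
                 probe_gene_map = probe_gene_map),
            class = "donor_expression")
}

# Independent Spearman rank-correlation oracle (explicit ranks + Pearson
# formula), used to check differential stability on tiny profiles.
spearman_oracle <- function(a, b) {
  ra <- rank(a)
  rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# Brute-force Benjamini-Hochberg step-up oracle.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}
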