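# Synthetic study generator: every pipeline input with planted ground truth.
#
# The generator emulates (i) a two-hemisphere spherical parcel atlas, (ii)
# multi-donor microarray tables with probe-level structure, (iii) a
# longitudinal gray-matter-volume (GMV) study whose regional change map is an
# expression-weighted combination of a sparse set of causal genes, and (iv)
# cell-type style gene sets enriched for those causal genes. All downstream
# recovery and calibration tests are phrased against the returned ground
# truth, so nothing external is ever downloaded.

#' Configuration for the synthetic study generator
#'
#' Collects every knob of the synthetic data model with defaults that mirror
#' a small bitemporal-ECT style longitudinal study (24 subjects) read out on
#' a 360-parcel cortical atlas (180 per hemisphere), paired with a
#' six-donor microarray resource in which only two donors sample both
#' hemispheres.
#'
#' @param n_parcels_left Number of left-hemisphere parcels (>= 4).
#' @param n_parcels_total Total parcels over both hemispheres; must equal
#'   `2 * n_parcels_left`.
#' @param n_donors Number of expression donors.
#' @param n_samples_per_donor Tissue samples per donor (left hemisphere).
#' @param n_genes Number of genes in the synthetic transcriptome.
#' @param probes_per_gene Microarray probes per gene (>= 1).
#' @param n_subjects Number of longitudinal imaging subjects.
#' @param n_causal_genes Number of genes with nonzero planted weight on the
#'   GMV-change map (half positive, half negative).
#' @param n_clinical_regions Number of regions with nonzero planted loading
#'   on the symptom-change outcome.
#' @param effect_scale Multiplier on the planted regional GMV-change map
#'   (mm3 per unit of summed z-scored expression); 0 gives a planted null.
#' @param spatial_smoothing_kernel_mm Gaussian kernel bandwidth (mm) used to
#'   smooth the regional expression signal and the planted change map over
#'   parcel centroids; 0 disables smoothing (spatially unstructured maps).
#' @param noise_sd_gmv Subject-level SD (mm3) of the post-scan GMV noise.
#' @param noise_sd_hamd SD (score units) of the symptom-change noise.
#' @param noise_sd_expr Probe-level expression noise SD (log2 intensity).
#' @param background_fail_rate Per-sample probability that a well-behaved
#'   probe falls below microarray background; in `[0, 1]`.
#' @param invalid_probe_rate Fraction (of `n_genes * probes_per_gene`) of
#'   additional probes planted without a valid gene annotation.
#' @param planted_fail_fraction Fraction of valid probes planted to fail the
#'   >= 50 percent above-background rule.
#' @param seed Integer seed; generators are pure functions of
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_parcels_left = 180L,
                             n_parcels_total = 2L * n_parcels_left,
                             n_donors = 6L,
                             n_samples_per_donor = 120L,
                             n_genes = 500L,
                             probes_per_gene = 2L,
                             n_subjects = 24L,
                             n_causal_genes = 20L,
                             n_clinical_regions = 10L,
                             effect_scale = 3.5,
                             spatial_smoothing_kernel_mm = 0,
                             noise_sd_gmv = 30,
                             noise_sd_hamd = 2,
                             noise_sd_expr = 0.2,
                             background_fail_rate = 0.05,
                             invalid_probe_rate = 0.05,
                             planted_fail_fraction = 0.05,
                             seed = 1L) {
  cfg <- list(n_parcels_left = as.integer(n_parcels_left),
              n_parcels_total = as.integer(n_parcels_total),
              n_donors = as.integer(n_donors),
              n_samples_per_donor = as.integer(n_samples_per_donor),
              n_genes = as.integer(n_genes),
              probes_per_gene = as.integer(probes_per_gene),
              n_subjects = as.integer(n_subjects),
              n_causal_genes = as.integer(n_causal_genes),
              n_clinical_regions = as.integer(n_clinical_regions),
              effect_scale = effect_scale,
              spatial_smoothing_kernel_mm = spatial_smoothing_kernel_mm,
              noise_sd_gmv = noise_sd_gmv,
              noise_sd_hamd = noise_sd_hamd,
              noise_sd_expr = noise_sd_expr,
              background_fail_rate = background_fail_rate,
              invalid_probe_rate = invalid_probe_rate,
              planted_fail_fraction = planted_fail_fraction,
              seed = as.integer(seed))
  counts <- c("n_parcels_left", "n_parcels_total", "n_donors",
              "n_samples_per_donor", "n_genes", "probes_per_gene",
              "n_subjects")
  for (nm in counts) {
    if (cfg[[nm]] <= 0L) stop("'", nm, "' must be a positive count")
  }
  if (cfg$n_parcels_left < 4L) stop("'n_parcels_left' must be >= 4")
  if (cfg$n_parcels_total != 2L * cfg$n_parcels_left)
    stop("'n_parcels_total' must equal 2 * n_parcels_left")
  if (cfg$probes_per_gene < 1L) stop("'probes_per_gene' must be >= 1")
  for (nm in c("background_fail_rate", "invalid_probe_rate",
               "planted_fail_fraction")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop("'", nm, "' must lie in [0, 1]")
  }
  for (nm in c("noise_sd_gmv", "noise_sd_hamd", "noise_sd_expr",
               "spatial_smoothing_kernel_mm")) {
    if (cfg[[nm]] < 0) stop("'", nm, "' must be non-negative")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# Radius (mm) of the sphere carrying parcel centroids; on the order of a
# human cortical hemisphere.
.atlas_radius <- 100

#' Generate a two-hemisphere spherical parcel atlas
#'
#' Left-hemisphere centroids are a Fibonacci lattice on a sphere of radius
#' 100 mm, so spherical rotations of the centroid frame are exact isometries
#' (a prerequisite of the spin permutation null). Right-hemisphere centroids
#' are the mirror image across the x = 0 plane.
#'
#' @param config A [synthetic_config()].
#' @return A `data.frame` of class `parcel_atlas` with columns `parcel_id`,
#'   `hemisphere`, `x`, `y`, `z`; the sphere radius is kept in
#'   `attr(, "radius")`.
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_parcels_left
  i <- seq_len(n) - 1
  zf <- 1 - 2 * (i + 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - zf^2))
  left <- cbind(x = rho * cos(phi), y = rho * sin(phi), z = zf) *
    .atlas_radius
  right <- left
  right[, "x"] <- -right[, "x"]
  width <- max(4L, nchar(as.character(n)))
  ids_l <- sprintf("L%0*d", width, seq_len(n))
  ids_r <- sprintf("R%0*d", width, seq_len(n))
  atlas <- data.frame(parcel_id = c(ids_l, ids_r),
                      hemisphere = rep(c("left", "right"), each = n),
                      x = c(left[, 1], right[, 1]),
                      y = c(left[, 2], right[, 2]),
                      z = c(left[, 3], right[, 3]),
                      stringsAsFactors = FALSE)
  attr(atlas, "radius") <- .atlas_radius
  class(atlas) <- c("parcel_atlas", "data.frame")
  atlas
}

# Gaussian-kernel smoother over parcel centroids. Rows of `values` are
# parcels in the order of `coords`; bandwidth 0 is the identity.
.smooth_over_parcels <- function(values, coords, bandwidth_mm) {
  if (bandwidth_mm <= 0) return(values)
  d <- .cross_dist(coords, coords)
  w <- exp(-d^2 / (2 * bandwidth_mm^2))
  w <- w / rowSums(w)
  w %*% values
}

.atlas_coords <- function(atlas, hemisphere = NULL, ids = NULL) {
  a <- atlas
  if (!is.null(hemisphere)) a <- a[a$hemisphere == hemisphere, , drop = FALSE]
  if (!is.null(ids)) a <- a[match(ids, a$parcel_id), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$parcel_id
  m
}

#' Generate multi-donor microarray expression tables
#'
#' Draws a shared regional gene signal over the left-hemisphere parcels
#' (optionally smoothed over centroids to inject spatial autocorrelation),
#' then scatters per-donor tissue samples near random parcel centroids and
#' reads each sample out through `probes_per_gene` probes per gene with a
#' fixed per-probe offset plus noise. Exactly two donors also receive
#' right-hemisphere samples, mirroring the hemispheric coverage pattern of
#' public donor brain resources. A planted subset of probes fails the
#' above-background intensity rule, and a planted set of additional probes
#' carries no valid gene annotation.
#'
#' @param atlas A `parcel_atlas`.
#' @param config A [synthetic_config()].
#' @return A list of class `donor_expression_set`: one element per donor,
#'   each of class `donor_expression` with fields `donor_id`,
#'   `sample_coords` (sample x 3 matrix, mm), `expression` (probe x sample,
#'   log2 scale), `above_background` (probe x sample logical) and
#'   `probe_gene_map` (`data.frame` probe_id, gene_id with `NA` for
#'   unannotated probes). The ground truth (regional signal matrix, planted
#'   failing/unannotated probes, probe offsets) is in `attr(, "truth")`.
#' @export
generate_donor_expression <- function(atlas, config) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(config, "synthetic_config"))
  if (config$probes_per_gene < 1L) stop("'probes_per_gene' must be >= 1")
  set.seed(config$seed)

  left <- atlas[atlas$hemisphere == "left", , drop = FALSE]
  right <- atlas[atlas$hemisphere == "right", , drop = FALSE]
  coords_l <- .atlas_coords(atlas, "left")
  n_reg <- nrow(left)
  genes <- sprintf("g%04d", seq_len(config$n_genes))

  # Shared regional gene signal on a log2-intensity scale; smoothing over
  # centroids (bandwidth > 0) makes the expression maps spatially
  # autocorrelated, which is what makes the spin null necessary.
  signal <- matrix(stats::rnorm(n_reg * config$n_genes, mean = 7, sd = 1),
                   n_reg, config$n_genes,
                   dimnames = list(left$parcel_id, genes))
  signal <- .smooth_over_parcels(signal, coords_l,
                                 config$spatial_smoothing_kernel_mm)
  # the right hemisphere carries its own regional signal (hemispheric
  # asymmetry); downstream analysis is restricted to the left anyway
  signal_r <- matrix(stats::rnorm(nrow(right) * config$n_genes, mean = 7,
                                  sd = 1),
                     nrow(right), config$n_genes,
                     dimnames = list(right$parcel_id, genes))
  signal_r <- .smooth_over_parcels(signal_r, .atlas_coords(atlas, "right"),
                                   config$spatial_smoothing_kernel_mm)

  n_valid <- config$n_genes * config$probes_per_gene
  n_invalid <- round(config$invalid_probe_rate * n_valid)
  probe_ids <- sprintf("p%05d", seq_len(n_valid + n_invalid))
  gene_of_probe <- c(rep(genes, each = config$probes_per_gene),
                     rep(NA_character_, n_invalid))
  probe_gene_map <- data.frame(probe_id = probe_ids, gene_id = gene_of_probe,
                               stringsAsFactors = FALSE)
  probe_offset <- stats::rnorm(length(probe_ids), sd = 0.25)
  names(probe_offset) <- probe_ids

  # Planted intensity failures: these probes fall below background in ~70%
  # of samples, so pooled across donors they fail the >= 50% rule almost
  # surely; all other probes fail at `background_fail_rate`.
  n_fail <- round(config$planted_fail_fraction * n_valid)
  failing_probes <- if (n_fail > 0) sort(sample(probe_ids[seq_len(n_valid)], n_fail)) else character(0)
  fail_prob <- stats::setNames(rep(config$background_fail_rate, length(probe_ids)),
                               probe_ids)
  fail_prob[failing_probes] <- 0.7

  bilateral <- seq_len(min(2L, config$n_donors))
  donors <- vector("list", config$n_donors)
  for (d in seq_len(config$n_donors)) {
    donor_id <- sprintf("donor%02d", d)
    reg_idx <- sample.int(n_reg, config$n_samples_per_donor, replace = TRUE)
    parcels <- left$parcel_id[reg_idx]
    coords <- coords_l[reg_idx, , drop = FALSE]
    gene_sig <- signal[reg_idx, , drop = FALSE]   # sample x gene
    if (d %in% bilateral) {
      n_r <- max(1L, config$n_samples_per_donor %/% 4L)
      ridx <- sample.int(nrow(right), n_r, replace = TRUE)
      parcels <- c(parcels, right$parcel_id[ridx])
      coords <- rbind(coords, .atlas_coords(atlas, "right")[ridx, , drop = FALSE])
      gene_sig <- rbind(gene_sig, signal_r[ridx, , drop = FALSE])
    }
    n_smp <- length(parcels)
    jitter <- matrix(stats::runif(n_smp * 3, -0.5, 0.5), n_smp, 3)
    sample_ids <- sprintf("%s_s%03d", donor_id, seq_len(n_smp))
    sample_coords <- coords + jitter
    rownames(sample_coords) <- sample_ids
    colnames(sample_coords) <- c("x", "y", "z")

    valid <- !is.na(gene_of_probe)
    expr <- matrix(stats::rnorm(length(probe_ids) * n_smp,
                                sd = config$noise_sd_expr),
                   length(probe_ids), n_smp,
                   dimnames = list(probe_ids, sample_ids))
    expr[valid, ] <- expr[valid, ] +
      t(gene_sig)[match(gene_of_probe[valid], genes), , drop = FALSE]
    expr[!valid, ] <- expr[!valid, ] + 7  # unannotated probes: flat signal
    expr <- expr + probe_offset

    above <- matrix(stats::runif(length(probe_ids) * n_smp), length(probe_ids),
                    n_smp) >= fail_prob
    dimnames(above) <- dimnames(expr)

    donors[[d]] <- structure(list(donor_id = donor_id,
                                  sample_coords = sample_coords,
                                  sample_parcel_truth = stats::setNames(parcels, sample_ids),
                                  expression = expr,
                                  above_background = above,
                                  probe_gene_map = probe_gene_map),
                             class = "donor_expression")
  }
  names(donors) <- vapply(donors, `[[`, "", "donor_id")
  structure(donors,
            class = "donor_expression_set",
            truth = list(signal = signal,
                         probe_offset = probe_offset,
                         failing_probes = failing_probes,
                         invalid_probes = probe_ids[is.na(gene_of_probe)],
                         gene_of_probe = stats::setNames(gene_of_probe, probe_ids)))
}

#' Generate a longitudinal GMV study with a planted transcriptomic effect
#'
#' The planted regional change map is
#' `delta_r = effect_scale * sum_g beta_g * z(signal)_rg`, where `beta` is a
#' sparse gene weight vector (half positive, half negative causal genes) and
#' `z()` standardizes each gene's regional signal across parcels; the map is
#' optionally smoothed over centroids. Per subject, pre-treatment GMV is a
#' regional baseline plus a subject offset plus a small TIV association, the
#' post scan adds `delta_r` and Gaussian noise, and the symptom improvement
#' (`hamd_pre - hamd_post`) is a sparse linear readout of regional GMV
#' change plus noise.
#'
#' @param atlas A `parcel_atlas`.
#' @param expr_truth Regions x genes matrix of the true regional signal
#'   (e.g. `attr(donors, "truth")$signal`); must cover all left parcels.
#' @param config A [synthetic_config()].
#' @return A list with `study` (long `data.frame` of class `gmv_study`:
#'   subject_id, parcel_id, gmv_pre, gmv_post, tiv, hamd_pre, hamd_post) and
#'   `truth` (class `ground_truth`: `causal_gene_weights`, `region_effect`,
#'   `clinical_loading`, `enriched_set_ids`, `seed`).
#' @export
generate_study <- function(atlas, expr_truth, config) {
  stopifnot(inherits(atlas, "parcel_atlas"), inherits(config, "synthetic_config"))
  if (config$noise_sd_gmv < 0 || config$noise_sd_hamd < 0)
    stop("noise SDs must be non-negative")
  left <- atlas[atlas$hemisphere == "left", , drop = FALSE]
  if (!all(left$parcel_id %in% rownames(expr_truth)))
    stop("'expr_truth' must cover all left-hemisphere parcels")
  expr_truth <- expr_truth[left$parcel_id, , drop = FALSE]
  set.seed(config$seed + 1L)

  genes <- colnames(expr_truth)
  n_reg <- nrow(expr_truth)
  n_sub <- config$n_subjects

  beta <- stats::setNames(numeric(length(genes)), genes)
  n_causal <- min(config$n_causal_genes, length(genes))
  if (config$effect_scale > 0 && n_causal < 1L)
    stop("need at least one causal gene when effect_scale > 0")
  causal <- sample(genes, n_causal)
  half <- ceiling(n_causal / 2)
  beta[causal[seq_len(half)]] <- 1
  beta[causal[setdiff(seq_len(n_causal), seq_len(half))]] <- -1

  Z <- .zscore_cols(expr_truth)
  delta <- as.numeric(config$effect_scale * (Z %*% beta))
  delta <- as.numeric(.smooth_over_parcels(matrix(delta), .atlas_coords(atlas, "left"),
                                           config$spatial_smoothing_kernel_mm))
  names(delta) <- left$parcel_id

  baseline <- 4000 + 800 * stats::runif(n_reg)
  subj_off <- stats::rnorm(n_sub, sd = 200)
  tiv <- stats::rnorm(n_sub, mean = 1.5e6, sd = 1.3e5)
  tiv_slope <- 0.002  # mm3 of regional GMV per mm3 of TIV

  gmv_pre <- outer(baseline, rep(1, n_sub)) +
    outer(rep(1, n_reg), subj_off + tiv_slope * (tiv - mean(tiv)))
  gmv_post <- gmv_pre + delta +
    matrix(stats::rnorm(n_reg * n_sub, sd = config$noise_sd_gmv), n_reg, n_sub)

  # Clinical loading: the regions with the largest planted |delta| drive the
  # symptom improvement, signed so that each loaded region's expected change
  # contributes positively to improvement.
  cload <- stats::setNames(numeric(n_reg), left$parcel_id)
  n_clin <- min(config$n_clinical_regions, n_reg)
  top <- order(-abs(delta))[seq_len(n_clin)]
  cload[top] <- 0.05 * sign(delta[top])
  cload[top][cload[top] == 0] <- 0.05

  dgmv <- gmv_post - gmv_pre               # region x subject
  improvement <- as.numeric(crossprod(dgmv, cload)) +
    stats::rnorm(n_sub, sd = config$noise_sd_hamd)
  hamd_pre <- sample(22:30, n_sub, replace = TRUE)
  hamd_post <- hamd_pre - improvement

  subjects <- sprintf("sub%03d", seq_len(n_sub))
  study <- data.frame(subject_id = rep(subjects, each = n_reg),
                      parcel_id = rep(left$parcel_id, n_sub),
                      gmv_pre = as.numeric(gmv_pre),
                      gmv_post = as.numeric(gmv_post),
                      tiv = rep(tiv, each = n_reg),
                      hamd_pre = rep(hamd_pre, each = n_reg),
                      hamd_post = rep(hamd_post, each = n_reg),
                      stringsAsFactors = FALSE)
  class(study) <- c("gmv_study", "data.frame")

  truth <- structure(list(causal_gene_weights = beta,
                          region_effect = delta,
                          clinical_loading = cload,
                          enriched_set_ids = character(0),
                          seed = config$seed),
                     class = "ground_truth")
  list(study = study, truth = truth)
}

#' Generate cell-type style gene sets with planted enrichment
#'
#' Emits seven named gene sets patterned on canonical cortical cell classes.
#' The excitatory- and inhibitory-neuron-like sets draw `enrichment_fraction`
#' of their members from the positive-weight causal genes, the astrocyte- and
#' microglia-like sets from the negative-weight causal genes; the remaining
#' members (and the other three sets entirely) are drawn uniformly from
#' non-causal genes.
#'
#' @param truth A `ground_truth` from [generate_study()].
#' @param config A [synthetic_config()].
#' @param set_size Members per set.
#' @param enrichment_fraction Fraction of each enriched set drawn from the
#'   matching causal-gene pool; in `[0, 1]`.
#' @return A list of class `gene_set_collection` with fields `sets` (named
#'   list of gene-id vectors), `descriptions`, and `background` (the gene
#'   universe). The planted-enriched set ids are in
#'   `attr(, "enriched_set_ids")`.
#' @export
generate_gene_sets <- function(truth, config, set_size = 40L,
                               enrichment_fraction = 0.5) {
  stopifnot(inherits(truth, "ground_truth"))
  if (enrichment_fraction < 0 || enrichment_fraction > 1)
    stop("'enrichment_fraction' must lie in [0, 1]")
  beta <- truth$causal_gene_weights
  if (!any(beta != 0)) stop("ground truth has no causal genes")
  set.seed(config$seed + 2L)

  universe <- names(beta)
  pos <- names(beta)[beta > 0]
  neg <- names(beta)[beta < 0]
  noncausal <- names(beta)[beta == 0]

  cell_types <- c("Astro", "Endo", "Micro", "Neuro-Ex", "Neuro-In",
                  "Oligo", "OPC")
  pools <- list(Astro = neg, Endo = NULL, Micro = neg, `Neuro-Ex` = pos,
                `Neuro-In` = pos, Oligo = NULL, OPC = NULL)
  sets <- vector("list", length(cell_types))
  names(sets) <- cell_types
  for (ct in cell_types) {
    pool <- pools[[ct]]
    if (is.null(pool)) {
      sets[[ct]] <- sort(sample(noncausal, min(set_size, length(noncausal))))
      next
    }
    n_enr <- min(round(enrichment_fraction * set_size), length(pool))
    enr <- if (n_enr > 0) sample(pool, n_enr) else character(0)
    rest <- sample(noncausal, min(set_size - n_enr, length(noncausal)))
    sets[[ct]] <- sort(c(enr, rest))
  }
  enriched <- names(pools)[!vapply(pools, is.null, TRUE)]
  structure(list(sets = sets,
                 descriptions = stats::setNames(
                   sprintf("synthetic %s marker set", cell_types), cell_types),
                 background = universe),
            class = "gene_set_collection",
            enriched_set_ids = enriched)
}
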