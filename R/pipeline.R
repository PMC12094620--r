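# End-to-end orchestration: configuration, input validation, and the staged
# pipeline run (expression matrix -> t-map -> PLS inference -> clinical PLS
# -> enrichment), with every intermediate written to the run directory and
# a JSON manifest sufficient to reproduce the run.

#' Pipeline run configuration
#'
#' Collects input locations (or a synthetic-data configuration), analysis
#' parameters and the run seed. A single seed fans out to per-stage child
#' seeds (see [child_seed()]) so stages can be rerun independently.
#'
#' @param atlas_path,donor_dir,gmv_path,gmt_path Input file locations;
#'   leave `NULL` and supply `synthetic` to generate inputs.
#' @param synthetic Optional [synthetic_config()]; when given, stage 0
#'   generates all inputs into the run directory.
#' @param tolerance_mm Sample-to-parcel assignment tolerance (mm).
#' @param n_perm_spin Spin permutations for the PLS significance test.
#' @param n_boot Bootstrap resamples for gene / region Z-scores.
#' @param n_perm_clinical Outcome permutations for the clinical PLS.
#' @param n_perm_gsea Label permutations for GSEA.
#' @param fdr_gene_threshold FDR threshold defining the signed gene lists.
#' @param ora_threshold FDR threshold for ORA significance.
#' @param gsea_exponent GSEA hit-weighting exponent.
#' @param seed Integer run seed.
#' @param out_dir Output directory for the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(atlas_path = NULL, donor_dir = NULL,
                            gmv_path = NULL, gmt_path = NULL,
                            synthetic = NULL,
                            tolerance_mm = 2,
                            n_perm_spin = 1000L,
                            n_boot = 1000L,
                            n_perm_clinical = 1000L,
                            n_perm_gsea = 10000L,
                            fdr_gene_threshold = 0.001,
                            ora_threshold = 0.05,
                            gsea_exponent = 1,
                            seed = 1L,
                            out_dir = "brainpls_run") {
  cfg <- list(atlas_path = atlas_path, donor_dir = donor_dir,
              gmv_path = gmv_path, gmt_path = gmt_path,
              synthetic = synthetic,
              tolerance_mm = tolerance_mm,
              n_perm_spin = as.integer(n_perm_spin),
              n_boot = as.integer(n_boot),
              n_perm_clinical = as.integer(n_perm_clinical),
              n_perm_gsea = as.integer(n_perm_gsea),
              fdr_gene_threshold = fdr_gene_threshold,
              ora_threshold = ora_threshold,
              gsea_exponent = gsea_exponent,
              seed = as.integer(seed),
              out_dir = out_dir)
  for (nm in c("fdr_gene_threshold", "ora_threshold")) {
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop("'", nm, "' must lie in (0, 1)")
  }
  for (nm in c("n_perm_spin", "n_boot", "n_perm_clinical", "n_perm_gsea")) {
    if (cfg[[nm]] <= 0L) stop("'", nm, "' must be a positive count")
  }
  if (is.null(synthetic) &&
      (is.null(atlas_path) || is.null(donor_dir) || is.null(gmv_path) ||
       is.null(gmt_path)))
    stop("supply either all four input paths or a synthetic config")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate pipeline inputs
#'
#' Checks id consistency across files, hemisphere labels, coordinate
#' finiteness and GMT parseability without mutating anything.
#'
#' @param config A `pipeline_config` whose input paths exist (for synthetic
#'   configs, run [run_pipeline()] first or point at a generated inputs
#'   directory).
#' @return A list with `issues` (character vector, empty when clean) and
#'   `counts` (parcels, donors, subjects, sets).
#' @export
validate_inputs <- function(config) {
  issues <- character(0)
  counts <- list()
  atlas <- tryCatch(read_atlas(config$atlas_path), error = function(e) {
    issues <<- c(issues, paste("atlas:", conditionMessage(e)))
    NULL
  })
  if (!is.null(atlas)) {
    counts$parcels <- nrow(atlas)
    bad <- !is.finite(atlas$x) | !is.finite(atlas$y) | !is.finite(atlas$z)
    if (any(bad))
      issues <- c(issues, paste0("atlas: non-finite centroid for parcel ",
                                 atlas$parcel_id[which(bad)[1]]))
    if (anyDuplicated(atlas$parcel_id))
      issues <- c(issues, "atlas: duplicate parcel ids")
    if (!all(atlas$hemisphere %in% c("left", "right")))
      issues <- c(issues, "atlas: hemisphere labels must be left/right")
  }
  donors <- tryCatch(read_donor_expression(config$donor_dir),
                     error = function(e) {
                       issues <<- c(issues, paste("donors:", conditionMessage(e)))
                       NULL
                     })
  if (!is.null(donors)) {
    counts$donors <- length(donors)
    for (d in donors) {
      if (!all(dim(d$expression) == dim(d$above_background)))
        issues <- c(issues, paste0("donors: expression/background shape ",
                                   "mismatch for ", d$donor_id))
      if (!all(is.finite(d$sample_coords)))
        issues <- c(issues, paste0("donors: non-finite sample coordinate ",
                                   "for ", d$donor_id))
    }
  }
  study <- tryCatch(read_gmv_study(config$gmv_path), error = function(e) {
    issues <<- c(issues, paste("gmv:", conditionMessage(e)))
    NULL
  })
  if (!is.null(study)) {
    counts$subjects <- length(unique(study$subject_id))
    chk <- tryCatch({
      .study_matrices(study)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(chk)) issues <- c(issues, paste("gmv:", chk))
    if (!is.null(atlas) && !all(study$parcel_id %in% atlas$parcel_id))
      issues <- c(issues, "gmv: unknown parcel id in study table")
  }
  sets <- tryCatch(read_gmt(config$gmt_path), error = function(e) {
    issues <<- c(issues, paste("gene sets:", conditionMessage(e)))
    NULL
  })
  if (!is.null(sets)) counts$sets <- length(sets$sets)
  list(issues = issues, counts = counts)
}

#' Run the full pipeline
#'
#' Stages: (0) optional synthetic-input generation; (1) expression matrix
#' construction; (2) regional change t-map and HAMD paired test; (3) PLS of
#' the t-map on regional expression with spin significance, bootstrap gene
#' Z-scores and signed gene lists; (4) subject-level clinical PLS; (5) ORA
#' and permutation GSEA of the gene lists / ranked Z statistic. Every
#' intermediate is written as TSV/JSON under `config$out_dir` together with
#' a manifest (package version, config, child seeds, input checksums).
#' Identical config and seed reproduce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all in-memory stage results and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$synthetic)) {
    scfg <- config$synthetic
    inputs <- file.path(out, "inputs")
    dir.create(inputs, showWarnings = FALSE)
    atlas <- generate_atlas(scfg)
    donors <- generate_donor_expression(atlas, scfg)
    truth_sig <- attr(donors, "truth")$signal
    st <- generate_study(atlas, truth_sig, scfg)
    sets <- generate_gene_sets(st$truth, scfg)
    write_atlas(atlas, file.path(inputs, "atlas.tsv"))
    write_donor_expression(donors, file.path(inputs, "donors"))
    write_gmv_study(st$study, file.path(inputs, "gmv_study.tsv"))
    write_gmt(sets, file.path(inputs, "gene_sets.gmt"))
    config$atlas_path <- file.path(inputs, "atlas.tsv")
    config$donor_dir <- file.path(inputs, "donors")
    config$gmv_path <- file.path(inputs, "gmv_study.tsv")
    config$gmt_path <- file.path(inputs, "gene_sets.gmt")
  }

  val <- validate_inputs(config)
  if (length(val$issues))
    stop("input validation failed:\n  ", paste(val$issues, collapse = "\n  "))

  atlas <- read_atlas(config$atlas_path)
  donors <- read_donor_expression(config$donor_dir)
  study <- read_gmv_study(config$gmv_path)
  sets <- read_gmt(config$gmt_path)

  # stage 1: expression matrix
  message("stage expression: building region x gene matrix")
  rgm <- build_region_gene_matrix(donors, atlas,
                                  tolerance_mm = config$tolerance_mm)
  write_region_gene_matrix(rgm, file.path(out, "region_gene_matrix.tsv"))
  write_json_summary(rgm$provenance[c("filter_counts", "dropped_regions",
                                      "n_regions", "n_genes")],
                     file.path(out, "expression_provenance.json"))

  # stage 2: morphometry
  message("stage tmap: regional change statistics")
  tmap <- regional_change_tmap(study)
  hamd <- hamd_change_test(study)
  write_tmap(tmap, file.path(out, "tmap.tsv"))
  write_json_summary(hamd[c("t", "df", "p", "mean_diff")],
                     file.path(out, "hamd_test.json"))

  # stage 3: transcriptomic PLS, restricted to regions present in both
  regions <- intersect(rgm$regions, tmap$parcel_id)
  if (!length(regions)) stop("stage pls: no shared regions between ",
                             "expression matrix and t-map")
  X <- rgm$values[regions, , drop = FALSE]
  y <- tmap$t_value[match(regions, tmap$parcel_id)]
  message("stage pls: spin permutation test (n_perm = ",
          config$n_perm_spin, ")")
  spin <- pls_spin_pvalue(X, y, atlas, n_perm = config$n_perm_spin,
                          seed = child_seed(config$seed, "pls_spin"))
  message("stage pls: bootstrap gene Z (n_boot = ", config$n_boot, ")")
  boot <- bootstrap_gene_z(X, y, n_boot = config$n_boot,
                           seed = child_seed(config$seed, "pls_boot"),
                           fdr_threshold = config$fdr_gene_threshold)
  .write_tsv(boot$gene_table, file.path(out, "pls1_genes.tsv"))
  .write_tsv(data.frame(parcel_id = names(spin$fit$scores),
                        score = spin$fit$scores, stringsAsFactors = FALSE),
             file.path(out, "pls1_region_scores.tsv"))
  write_json_summary(list(explained_variance_y = spin$observed,
                          p_spin = spin$p_spin,
                          n_perm = spin$n_perm,
                          n_boot = boot$n_boot,
                          n_pls1_plus = length(boot$pls1_plus),
                          n_pls1_minus = length(boot$pls1_minus),
                          seed = config$seed),
                     file.path(out, "pls_summary.json"))

  # stage 4: clinical PLS
  message("stage clinical: subject-level PLS")
  chg <- study_change_matrix(study)
  clin <- clinical_pls(chg$delta_gmv, chg$improvement,
                       n_perm = config$n_perm_clinical,
                       n_boot = config$n_boot,
                       seed = config$seed)
  .write_tsv(data.frame(parcel_id = names(clin$region_weight),
                        weight = clin$region_weight,
                        se = clin$region_se, z = clin$region_z,
                        stringsAsFactors = FALSE),
             file.path(out, "clinical_regions.tsv"))
  write_json_summary(list(r_with_outcome = clin$r_with_outcome,
                          p_perm = clin$p_perm,
                          n_perm = clin$n_perm, n_boot = clin$n_boot),
                     file.path(out, "clinical_summary.json"))

  # stage 5: enrichment against the measured-gene universe
  message("stage enrich: ORA and GSEA (n_perm = ", config$n_perm_gsea, ")")
  universe <- names(boot$z_score)[!is.na(boot$z_score)]
  coll <- gene_set_collection(sets$sets, universe, sets$descriptions)
  ranked <- boot$z_score[universe]
  ora_plus <- if (length(boot$pls1_plus))
    ora_hypergeometric(intersect(boot$pls1_plus, universe), coll,
                       alpha = config$ora_threshold) else NULL
  ora_minus <- if (length(boot$pls1_minus))
    ora_hypergeometric(intersect(boot$pls1_minus, universe), coll,
                       alpha = config$ora_threshold) else NULL
  gsea <- gsea_permutation(ranked, coll, n_perm = config$n_perm_gsea,
                           exponent = config$gsea_exponent,
                           seed = child_seed(config$seed, "enrich"))
  overlaps <- celltype_overlap_counts(list(plus = boot$pls1_plus,
                                           minus = boot$pls1_minus), coll)
  if (!is.null(ora_plus))
    .write_tsv(ora_plus, file.path(out, "ora_pls1_plus.tsv"))
  if (!is.null(ora_minus))
    .write_tsv(ora_minus, file.path(out, "ora_pls1_minus.tsv"))
  gsea_out <- as.data.frame(gsea)
  gsea_out$leading_edge <- vapply(attr(gsea, "leading_edge"),
                                  paste, "", collapse = ";")[gsea_out$set_id]
  .write_tsv(gsea_out, file.path(out, "gsea.tsv"))
  .write_tsv(overlaps, file.path(out, "celltype_overlaps.tsv"))

  manifest <- list(
    package = "brainpls",
    version = as.character(utils::packageVersion("brainpls")),
    seed = config$seed,
    child_seeds = stats::setNames(
      lapply(.pipeline_stages, child_seed, seed = config$seed),
      .pipeline_stages),
    parameters = config[c("tolerance_mm", "n_perm_spin", "n_boot",
                          "n_perm_clinical", "n_perm_gsea",
                          "fdr_gene_threshold", "ora_threshold",
                          "gsea_exponent")],
    input_checksums = list(
      atlas = unname(tools::md5sum(config$atlas_path)),
      gmv = unname(tools::md5sum(config$gmv_path)),
      gene_sets = unname(tools::md5sum(config$gmt_path))),
    validation_counts = val$counts)
  write_json_summary(manifest, file.path(out, "manifest.json"))

  invisible(list(out_dir = out, atlas = atlas, expression = rgm,
                 tmap = tmap, hamd = hamd, spin = spin, boot = boot,
                 clinical = clin, ora_plus = ora_plus,
                 ora_minus = ora_minus, gsea = gsea, overlaps = overlaps,
                 manifest = manifest))
}
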