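# Construction of the regions x genes expression matrix from donor
# microarray tables: probe annotation and intensity filtering,
# differential-stability probe selection, nearest-centroid sample
# assignment, per-donor scaled-robust-sigmoid normalization, and two-stage
# (within-donor, then across-donor) regional averaging restricted to the
# left hemisphere.

.check_donors <- function(donors) {
  if (!length(donors)) stop("empty donor list")
  for (d in donors) {
    if (!all(dim(d$expression) == dim(d$above_background)))
      stop("expression and above_background dimensions differ for ",
           d$donor_id)
  }
  invisible(donors)
}

#' Drop probes without a valid gene annotation
#'
#' Probes whose `probe_gene_map` entry is missing are removed from every
#' donor's expression and above-background tables.
#'
#' @param donors List of `donor_expression` objects.
#' @return The filtered donor list; dropped/kept probe counts are in
#'   `attr(, "filter_counts")`.
#' @export
filter_probes_by_annotation <- function(donors) {
  .check_donors(donors)
  map <- donors[[1]]$probe_gene_map
  keep <- map$probe_id[!is.na(map$gene_id) & map$gene_id != ""]
  if (!length(keep)) stop("no probes with a valid gene annotation remain")
  out <- lapply(donors, function(d) {
    d$expression <- d$expression[keep, , drop = FALSE]
    d$above_background <- d$above_background[keep, , drop = FALSE]
    d$probe_gene_map <- d$probe_gene_map[match(keep, d$probe_gene_map$probe_id), ,
                                         drop = FALSE]
    d
  })
  names(out) <- names(donors)
  attr(out, "filter_counts") <- list(
    annotation = c(kept = length(keep), dropped = nrow(map) - length(keep)))
  class(out) <- class(donors)
  out
}

#' Drop probes at or below microarray background in too many samples
#'
#' Samples are pooled across all donors; a probe is dropped when it is at or
#' below background in at least `min_fraction` of the pooled samples
#' (equivalently, kept only when above background in more than
#' `1 - min_fraction`). Set `pool_donors = FALSE` to require the criterion
#' within every donor separately.
#'
#' @param donors List of `donor_expression` objects.
#' @param min_fraction Below-background fraction at which a probe is
#'   dropped; default 0.5.
#' @param pool_donors Pool samples across donors (default) or apply the rule
#'   per donor.
#' @return The filtered donor list with `attr(, "filter_counts")`.
#' @export
filter_probes_by_intensity <- function(donors, min_fraction = 0.5,
                                       pool_donors = TRUE) {
  .check_donors(donors)
  below <- lapply(donors, function(d) !d$above_background)
  if (pool_donors) {
    tot_below <- Reduce(`+`, lapply(below, rowSums))
    tot_n <- sum(vapply(below, ncol, 0L))
    drop <- (tot_below / tot_n) >= min_fraction
  } else {
    per_donor <- vapply(below, function(b) rowMeans(b) >= min_fraction,
                        logical(nrow(below[[1]])))
    drop <- apply(per_donor, 1, any)
  }
  keep <- rownames(donors[[1]]$expression)[!drop]
  if (!length(keep)) stop("no probes pass the intensity filter")
  prev <- attr(donors, "filter_counts") %||% list()
  out <- lapply(donors, function(d) {
    d$expression <- d$expression[keep, , drop = FALSE]
    d$above_background <- d$above_background[keep, , drop = FALSE]
    d$probe_gene_map <- d$probe_gene_map[match(keep, d$probe_gene_map$probe_id), ,
                                         drop = FALSE]
    d
  })
  names(out) <- names(donors)
  attr(out, "filter_counts") <- c(prev, list(
    intensity = c(kept = length(keep), dropped = sum(drop))))
  class(out) <- class(donors)
  out
}

#' Assign tissue samples to atlas parcels by nearest centroid
#'
#' Each sample is assigned to the parcel with the nearest centroid provided
#' that distance is at most `tolerance_mm`; otherwise it is left
#' unassigned. Exact distance ties (within 1e-12 mm) go to the
#' lexicographically smallest parcel id.
#'
#' @param donor A `donor_expression` object.
#' @param atlas A `parcel_atlas`.
#' @param tolerance_mm Maximum assignment distance in mm (default 2).
#' @return Named character vector sample -> parcel id, `NA` for unassigned
#'   samples; assignment counts in `attr(, "counts")`.
#' @export
assign_samples_to_parcels <- function(donor, atlas, tolerance_mm = 2) {
  centroids <- .atlas_coords(atlas)
  ord <- order(rownames(centroids))
  centroids <- centroids[ord, , drop = FALSE]
  d <- .cross_dist(donor$sample_coords, centroids)
  assigned <- apply(d, 1, function(row) {
    m <- min(row)
    if (m > tolerance_mm) return(NA_character_)
    # first match in parcel-id order resolves ties to the smallest id
    colnames(d)[which(row <= m + 1e-12)[1]]
  })
  names(assigned) <- rownames(donor$sample_coords)
  attr(assigned, "counts") <- c(assigned = sum(!is.na(assigned)),
                                unassigned = sum(is.na(assigned)))
  assigned
}

# Per-donor probe x region matrix of mean expression over assigned samples.
.donor_region_means <- function(donor, atlas, tolerance_mm) {
  assigned <- assign_samples_to_parcels(donor, atlas, tolerance_mm)
  ok <- !is.na(assigned)
  if (!any(ok)) return(NULL)
  f <- factor(assigned[ok])
  expr <- donor$expression[, ok, drop = FALSE]
  # rowsum over samples within parcel, transposed to probe x region
  sums <- t(rowsum(t(expr), f))
  sweep(sums, 2, as.numeric(table(f)), "/")
}

# Row-wise Spearman correlation between two matrices with matching rows.
.row_spearman <- function(a, b) {
  ra <- t(apply(a, 1, rank))
  rb <- t(apply(b, 1, rank))
  n <- ncol(ra)
  ra <- ra - rowMeans(ra)
  rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Differential stability and per-gene probe selection
#'
#' For every probe, builds per-donor regional mean profiles (via
#' [assign_samples_to_parcels()]) and computes differential stability (DS):
#' the mean over donor pairs of the Spearman correlation between the two
#' donors' profiles, restricted to regions both donors cover. For each gene
#' the probe with maximal DS is selected; ties break to the
#' lexicographically smallest probe id. Genes whose probes have no DS value
#' in any donor pair (fewer than two shared regions, or constant profiles)
#' are dropped and reported.
#'
#' @param donors List of `donor_expression` objects (>= 2 donors).
#' @param atlas A `parcel_atlas`.
#' @param tolerance_mm Assignment tolerance in mm.
#' @return `data.frame` with columns `gene_id`, `probe_id`, `ds`; dropped
#'   genes in `attr(, "dropped_genes")`, per-probe DS in
#'   `attr(, "probe_ds")`.
#' @export
differential_stability <- function(donors, atlas, tolerance_mm = 2) {
  .check_donors(donors)
  if (length(donors) < 2L) stop("differential stability requires >= 2 donors")
  profiles <- lapply(donors, .donor_region_means, atlas = atlas,
                     tolerance_mm = tolerance_mm)
  profiles <- profiles[!vapply(profiles, is.null, TRUE)]
  if (length(profiles) < 2L) stop("fewer than 2 donors have assigned samples")
  probes <- rownames(donors[[1]]$expression)
  pair_cors <- list()
  for (i in seq_len(length(profiles) - 1L)) {
    for (j in seq(i + 1L, length(profiles))) {
      shared <- intersect(colnames(profiles[[i]]), colnames(profiles[[j]]))
      if (length(shared) < 2L) next
      pair_cors[[length(pair_cors) + 1L]] <-
        .row_spearman(profiles[[i]][, shared, drop = FALSE],
                      profiles[[j]][, shared, drop = FALSE])
    }
  }
  if (!length(pair_cors)) stop("no donor pair shares two or more regions")
  cor_mat <- do.call(cbind, pair_cors)
  ds <- rowMeans(cor_mat, na.rm = TRUE)
  ds[!is.finite(ds)] <- NA_real_
  names(ds) <- probes

  map <- donors[[1]]$probe_gene_map
  sel <- lapply(split(map$probe_id, map$gene_id), function(pr) {
    pr <- sort(pr)
    v <- ds[pr]
    if (all(is.na(v))) return(NULL)
    best <- pr[which(v == max(v, na.rm = TRUE))][1]
    data.frame(probe_id = best, ds = ds[[best]], stringsAsFactors = FALSE)
  })
  dropped <- names(sel)[vapply(sel, is.null, TRUE)]
  sel <- sel[!vapply(sel, is.null, TRUE)]
  out <- data.frame(gene_id = names(sel),
                    probe_id = vapply(sel, `[[`, "", "probe_id"),
                    ds = vapply(sel, `[[`, 0, "ds"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), , drop = FALSE]
  attr(out, "dropped_genes") <- dropped
  attr(out, "probe_ds") <- ds
  out
}

#' Scaled robust sigmoid normalization
#'
#' Outlier-robust sigmoid transform
#' `y = 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))`, followed by
#' min-max rescaling to `[0, 1]`. The factor 1.35 converts the IQR to a
#' normal-equivalent SD. A degenerate spread (IQR = 0) returns 0.5 for all
#' entries.
#'
#' @param values Numeric vector (length >= 2, all finite).
#' @return Numeric vector in `[0, 1]`.
#' @export
scaled_robust_sigmoid <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (!all(is.finite(values))) stop("non-finite values are not allowed")
  iqr <- stats::IQR(values)
  if (iqr == 0) return(rep(0.5, length(values)))
  y <- 1 / (1 + exp(-(values - stats::median(values)) / (iqr / 1.35)))
  (y - min(y)) / (max(y) - min(y))
}

#' Build the left-hemisphere regions x genes expression matrix
#'
#' Full processing pipeline: annotation filter, pooled intensity filter,
#' differential-stability probe selection, then per donor: assign samples to
#' parcels, normalize each selected gene across that donor's assigned
#' samples with the scaled robust sigmoid, and average samples within each
#' region; finally average regional values across the donors that cover each
#' region (no imputation) and restrict to left-hemisphere parcels. Regions
#' covered by no donor are dropped and reported.
#'
#' @param donors List of `donor_expression` objects.
#' @param atlas A `parcel_atlas`.
#' @param tolerance_mm Sample-to-parcel assignment tolerance in mm.
#' @param min_fraction Intensity-filter threshold (see
#'   [filter_probes_by_intensity()]).
#' @param pool_donors Pool samples across donors for the intensity filter.
#' @return A list of class `region_gene_matrix`: `values` (region x gene
#'   matrix, no missing entries), `regions`, `genes`, and `provenance`
#'   (probe counts per filter, assignment counts per donor, dropped genes
#'   and regions).
#' @export
build_region_gene_matrix <- function(donors, atlas, tolerance_mm = 2,
                                     min_fraction = 0.5, pool_donors = TRUE) {
  donors <- filter_probes_by_annotation(donors)
  donors <- filter_probes_by_intensity(donors, min_fraction, pool_donors)
  if (length(donors) >= 2L) {
    selection <- differential_stability(donors, atlas, tolerance_mm)
  } else {
    # DS is undefined for a single donor: fall back to the tie-break rule
    # (lexicographically smallest probe id per gene)
    map <- donors[[1]]$probe_gene_map
    picks <- vapply(split(map$probe_id, map$gene_id), function(p) sort(p)[1], "")
    selection <- data.frame(gene_id = names(picks), probe_id = unname(picks),
                            ds = NA_real_, stringsAsFactors = FALSE)
    selection <- selection[order(selection$gene_id), , drop = FALSE]
  }

  left_ids <- atlas$parcel_id[atlas$hemisphere == "left"]
  donor_mats <- list()
  assign_counts <- list()
  for (d in donors) {
    assigned <- assign_samples_to_parcels(d, atlas, tolerance_mm)
    assign_counts[[d$donor_id]] <- attr(assigned, "counts")
    ok <- !is.na(assigned)
    if (!any(ok)) next
    expr <- d$expression[selection$probe_id, ok, drop = FALSE]
    rownames(expr) <- selection$gene_id
    # per-donor, per-gene normalization across that donor's assigned samples
    norm <- t(apply(expr, 1, scaled_robust_sigmoid))
    dimnames(norm) <- dimnames(expr)
    f <- factor(assigned[ok])
    region_means <- t(rowsum(t(norm), f)) /
      rep(as.numeric(table(f)), each = nrow(norm))
    donor_mats[[d$donor_id]] <- region_means
  }
  if (!length(donor_mats)) stop("no donor has any assigned sample")

  genes <- selection$gene_id
  sum_mat <- matrix(0, length(left_ids), length(genes),
                    dimnames = list(left_ids, genes))
  cnt <- stats::setNames(numeric(length(left_ids)), left_ids)
  for (m in donor_mats) {
    reg <- intersect(colnames(m), left_ids)
    if (!length(reg)) next
    sum_mat[reg, ] <- sum_mat[reg, ] + t(m[, reg, drop = FALSE])
    cnt[reg] <- cnt[reg] + 1
  }
  covered <- names(cnt)[cnt > 0]
  dropped_regions <- setdiff(left_ids, covered)
  values <- sum_mat[covered, , drop = FALSE] / cnt[covered]

  structure(list(values = values,
                 regions = covered,
                 genes = genes,
                 provenance = list(
                   filter_counts = attr(donors, "filter_counts"),
                   probe_selection = selection,
                   dropped_genes = attr(selection, "dropped_genes"),
                   assignment = assign_counts,
                   dropped_regions = dropped_regions,
                   n_regions = length(covered),
                   n_genes = length(genes))),
            class = "region_gene_matrix")
}
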