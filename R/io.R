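# Readers and writers for the interchange formats: TSV with header rows for
# tabular data, GMT for gene sets, JSON for run summaries. Doubles are
# serialized with 17 significant digits so every writer/reader pair
# round-trips values bit-exactly.

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  out <- df
  out[num] <- lapply(df[num], .fmt_num)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

#' Write / read a parcel atlas table
#'
#' TSV columns: `parcel_id`, `hemisphere`, `x`, `y`, `z` (mm).
#' @param atlas A `parcel_atlas`.
#' @param path File path.
#' @return `read_atlas` returns a `parcel_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  .write_tsv(as.data.frame(atlas), path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  df <- .read_tsv(path)
  req <- c("parcel_id", "hemisphere", "x", "y", "z")
  if (!all(req %in% names(df)))
    stop("atlas file must have columns: ", paste(req, collapse = ", "))
  radii <- sqrt(df$x^2 + df$y^2 + df$z^2)
  attr(df, "radius") <- mean(radii)
  class(df) <- c("parcel_atlas", "data.frame")
  df
}

#' Write / read a GMV study table
#'
#' TSV columns: `subject_id`, `parcel_id`, `gmv_pre`, `gmv_post`, `tiv`,
#' `hamd_pre`, `hamd_post`.
#' @param study A `gmv_study` table.
#' @param path File path.
#' @export
write_gmv_study <- function(study, path) {
  .write_tsv(as.data.frame(study), path)
}

#' @rdname write_gmv_study
#' @export
read_gmv_study <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("gmv_study", "data.frame")
  df
}

#' Write / read a regions x genes expression matrix
#'
#' TSV with the region id in the first column (`region_id`) and one column
#' per gene.
#' @param mat A `region_gene_matrix` (or plain matrix with dimnames).
#' @param path File path.
#' @export
write_region_gene_matrix <- function(mat, path) {
  values <- if (inherits(mat, "region_gene_matrix")) mat$values else mat
  df <- data.frame(region_id = rownames(values),
                   as.data.frame(values, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' @rdname write_region_gene_matrix
#' @export
read_region_gene_matrix <- function(path) {
  df <- .read_tsv(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  structure(list(values = values, regions = rownames(values),
                 genes = colnames(values), provenance = list()),
            class = "region_gene_matrix")
}

#' Write / read a regional t-map
#'
#' TSV columns: `parcel_id`, `t_value`, `p_value`, `mean_delta`, `df`.
#' @param tmap A `gmv_tmap` table.
#' @param path File path.
#' @export
write_tmap <- function(tmap, path) {
  .write_tsv(as.data.frame(tmap), path)
}

#' @rdname write_tmap
#' @export
read_tmap <- function(path) {
  df <- .read_tsv(path)
  class(df) <- c("gmv_tmap", "data.frame")
  df
}

#' Write / read gene sets in GMT format
#'
#' One set per line: set name, description, then tab-separated member gene
#' ids. Lines with fewer than three fields are a parse error (reported with
#' their line number).
#'
#' @param collection A `gene_set_collection`.
#' @param path File path.
#' @param background Optional universe for the read collection; defaults to
#'   the union of all members.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$descriptions[[id]], collection$sets[[id]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 3L)
  if (length(bad))
    stop("GMT parse error: fewer than 3 fields on line ", bad[1])
  ids <- vapply(parts, `[[`, "", 1)
  if (anyDuplicated(ids)) stop("duplicate set ids in GMT file")
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- ids
  desc <- stats::setNames(vapply(parts, `[[`, "", 2), ids)
  if (is.null(background)) background <- unique(unlist(sets))
  gene_set_collection(sets, background, desc)
}

#' Write / read donor microarray tables
#'
#' Each donor is written as four TSVs under `dir`:
#' `<donor>_samples.tsv` (sample_id, x, y, z),
#' `<donor>_expression.tsv` (probe_id x sample log2 intensities),
#' `<donor>_background.tsv` (probe_id x sample 0/1 above-background flags),
#' and a shared `probe_gene_map.tsv` (probe_id, gene_id; empty = no valid
#' annotation).
#'
#' @param donors A `donor_expression_set` (list of `donor_expression`).
#' @param dir Output directory (created if needed).
#' @export
write_donor_expression <- function(donors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  map <- donors[[1]]$probe_gene_map
  map_out <- map
  map_out$gene_id[is.na(map_out$gene_id)] <- ""
  .write_tsv(map_out, file.path(dir, "probe_gene_map.tsv"))
  for (d in donors) {
    base <- file.path(dir, d$donor_id)
    .write_tsv(data.frame(sample_id = rownames(d$sample_coords),
                          d$sample_coords, stringsAsFactors = FALSE),
               paste0(base, "_samples.tsv"))
    .write_tsv(data.frame(probe_id = rownames(d$expression),
                          as.data.frame(d$expression, check.names = FALSE),
                          check.names = FALSE),
               paste0(base, "_expression.tsv"))
    .write_tsv(data.frame(probe_id = rownames(d$above_background),
                          as.data.frame(d$above_background + 0L,
                                        check.names = FALSE),
                          check.names = FALSE),
               paste0(base, "_background.tsv"))
  }
  invisible(dir)
}

#' @rdname write_donor_expression
#' @export
read_donor_expression <- function(dir) {
  map <- .read_tsv(file.path(dir, "probe_gene_map.tsv"),
                   colClasses = "character")
  map$gene_id[map$gene_id == ""] <- NA_character_
  files <- list.files(dir, pattern = "_samples\\.tsv$")
  donor_ids <- sort(sub("_samples\\.tsv$", "", files))
  donors <- lapply(donor_ids, function(id) {
    base <- file.path(dir, id)
    smp <- .read_tsv(paste0(base, "_samples.tsv"))
    coords <- as.matrix(smp[, c("x", "y", "z")])
    rownames(coords) <- smp$sample_id
    edf <- .read_tsv(paste0(base, "_expression.tsv"), check.names = FALSE)
    expr <- as.matrix(edf[, -1, drop = FALSE])
    rownames(expr) <- edf[[1]]
    bdf <- .read_tsv(paste0(base, "_background.tsv"), check.names = FALSE)
    above <- as.matrix(bdf[, -1, drop = FALSE]) > 0
    rownames(above) <- bdf[[1]]
    structure(list(donor_id = id, sample_coords = coords,
                   expression = expr, above_background = above,
                   probe_gene_map = map),
              class = "donor_expression")
  })
  names(donors) <- donor_ids
  class(donors) <- "donor_expression_set"
  donors
}

#' Write a JSON summary file
#'
#' Scalars are written unboxed and doubles at full precision.
#' @param x A list.
#' @param path File path.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
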