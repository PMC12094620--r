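# Expression-matrix construction: probe filters, sample assignment,
# differential stability, SRS normalization, and the assembled matrix.

small_atlas <- function(n = 6L) generate_atlas(tiny_config(n_parcels_left = n))

test_that("annotation filter drops exactly the unannotated probes", {
  atlas <- small_atlas()
  map <- data.frame(probe_id = sprintf("p%02d", 1:10),
                    gene_id = c(sprintf("g%d", 1:8), NA, NA),
                    stringsAsFactors = FALSE)
  expr <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(map$probe_id, NULL))
  d <- make_donor("d1", atlas, rep(atlas$parcel_id[1], 4), expr, map)
  out <- filter_probes_by_annotation(list(d))
  expect_equal(nrow(out[[1]]$expression), 8L)
  expect_identical(rownames(out[[1]]$expression), map$probe_id[1:8])

  all_mapped <- map
  all_mapped$gene_id <- sprintf("g%d", 1:10)
  d2 <- make_donor("d1", atlas, rep(atlas$parcel_id[1], 4), expr, all_mapped)
  out2 <- filter_probes_by_annotation(list(d2))
  expect_identical(out2[[1]]$expression, d2$expression)

  none <- map
  none$gene_id <- NA_character_
  d3 <- make_donor("d1", atlas, rep(atlas$parcel_id[1], 4), expr, none)
  expect_error(filter_probes_by_annotation(list(d3)), "no probes")
})

test_that("intensity filter applies the pooled >= 50% boundary rule", {
  atlas <- small_atlas()
  map <- data.frame(probe_id = c("p49", "p50", "p51"),
                    gene_id = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  n_smp <- 100L
  expr <- matrix(rnorm(3 * n_smp), 3, n_smp, dimnames = list(map$probe_id, NULL))
  above <- rbind(p49 = seq_len(n_smp) <= 49,   # above in 49% -> dropped
                 p50 = seq_len(n_smp) <= 50,   # exactly 50%  -> dropped
                 p51 = seq_len(n_smp) <= 51)   # 51%          -> kept
  d <- make_donor("d1", atlas, rep(atlas$parcel_id[1], n_smp), expr, map,
                  above = above)
  out <- filter_probes_by_intensity(list(d))
  expect_identical(rownames(out[[1]]$expression), "p51")
})

test_that("filters are idempotent", {
  cfg <- tiny_config(seed = 2L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  once <- filter_probes_by_intensity(filter_probes_by_annotation(donors))
  twice <- filter_probes_by_intensity(filter_probes_by_annotation(once))
  expect_identical(rownames(once[[1]]$expression),
                   rownames(twice[[1]]$expression))
})

test_that("sample assignment honors tolerance and the tie-break rule", {
  # hand-built atlas so the two nearest parcels of the midpoint are known
  atlas <- data.frame(parcel_id = c("L0001", "L0002", "R0001", "R0002"),
                      hemisphere = c("left", "left", "right", "right"),
                      x = c(100, 70.7, -100, -70.7),
                      y = c(0, 70.7, 0, 70.7),
                      z = c(0, 0, 0, 0), stringsAsFactors = FALSE)
  class(atlas) <- c("parcel_atlas", "data.frame")
  map <- data.frame(probe_id = "p1", gene_id = "g1", stringsAsFactors = FALSE)
  c1 <- c(100, 0, 0)
  c2 <- c(70.7, 70.7, 0)
  mid <- (c1 + c2) / 2
  coords <- rbind(c1, c1 + c(2.6, 0, 0), mid)
  rownames(coords) <- paste0("s", 1:3)
  expr <- matrix(0, 1, 3, dimnames = list("p1", rownames(coords)))
  d <- structure(list(donor_id = "d1", sample_coords = coords,
                      expression = expr,
                      above_background = expr > -1,
                      probe_gene_map = map),
                 class = "donor_expression")
  # the midpoint is genuinely equidistant from its two nearest centroids
  expect_lt(abs(sqrt(sum((mid - c1)^2)) - sqrt(sum((mid - c2)^2))), 1e-12)
  tol <- sqrt(sum((mid - c1)^2)) + 1
  a <- assign_samples_to_parcels(d, atlas, tolerance_mm = tol)
  expect_identical(unname(a[1]), "L0001")
  expect_identical(unname(a[3]), "L0001")   # tie goes to the smaller id
  a2 <- assign_samples_to_parcels(d, atlas, tolerance_mm = 2)
  expect_true(is.na(a2[2]))
})

test_that("differential stability matches a brute-force Spearman oracle", {
  atlas <- small_atlas(6L)
  ids <- atlas$parcel_id[atlas$hemisphere == "left"][1:5]
  map <- data.frame(probe_id = c("p1", "p2"), gene_id = c("g1", "g2"),
                    stringsAsFactors = FALSE)
  # three donors, 5 regions each, hand-built profiles
  prof <- list(d1 = rbind(p1 = c(1, 2, 3, 4, 5), p2 = c(2, 1, 5, 3, 4)),
               d2 = rbind(p1 = c(1, 3, 2, 5, 4), p2 = c(5, 4, 3, 2, 1)),
               d3 = rbind(p1 = c(2, 1, 4, 3, 5), p2 = c(1, 2, 4, 5, 3)))
  donors <- lapply(names(prof), function(nm)
    make_donor(nm, atlas, ids, prof[[nm]], map))
  sel <- differential_stability(donors, atlas)
  for (pr in c("p1", "p2")) {
    expected <- mean(c(spearman_oracle(prof$d1[pr, ], prof$d2[pr, ]),
                       spearman_oracle(prof$d1[pr, ], prof$d3[pr, ]),
                       spearman_oracle(prof$d2[pr, ], prof$d3[pr, ])))
    expect_equal(attr(sel, "probe_ds")[[pr]], expected, tolerance = 1e-12)
  }
  expect_error(differential_stability(donors[1], atlas), ">= 2 donors")
})

test_that("identical and rank-reversed donor profiles give DS of 1 and -1", {
  atlas <- small_atlas(6L)
  ids <- atlas$parcel_id[atlas$hemisphere == "left"][1:4]
  map <- data.frame(probe_id = c("pA", "pB"), gene_id = c("g1", "g2"),
                    stringsAsFactors = FALSE)
  base <- c(1, 2, 3, 4)
  d1 <- make_donor("d1", atlas, ids, rbind(pA = base, pB = base), map)
  d2 <- make_donor("d2", atlas, ids, rbind(pA = base, pB = rev(base)), map)
  sel <- differential_stability(list(d1, d2), atlas)
  ds <- attr(sel, "probe_ds")
  expect_equal(ds[["pA"]], 1, tolerance = 1e-12)
  expect_equal(ds[["pB"]], -1, tolerance = 1e-12)
})

test_that("scaled robust sigmoid matches its closed form and edge cases", {
  x <- c(0, 1, 2, 100)
  y <- scaled_robust_sigmoid(x)
  sig <- 1 / (1 + exp(-(x - median(x)) / (IQR(x) / 1.35)))
  expected <- (sig - min(sig)) / (max(sig) - min(sig))
  expect_equal(y, expected, tolerance = 1e-12)
  expect_true(all(diff(scaled_robust_sigmoid(1:5)) > 0))
  expect_equal(scaled_robust_sigmoid(rep(3, 4)), rep(0.5, 4))
  expect_error(scaled_robust_sigmoid(c(1, NA)), "non-finite")
  expect_error(scaled_robust_sigmoid(1), "at least 2")
})

test_that("region-gene matrix has full coverage and no missing values", {
  cfg <- tiny_config(seed = 3L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  rgm <- build_region_gene_matrix(donors, atlas)
  expect_false(anyNA(rgm$values))
  expect_lte(nrow(rgm$values), cfg$n_parcels_left)
  expect_true(all(rgm$values >= 0 & rgm$values <= 1))
  expect_true(all(rownames(rgm$values) %in%
                    atlas$parcel_id[atlas$hemisphere == "left"]))
})

test_that("single noiseless donor recovers the SRS of the planted signal", {
  cfg <- tiny_config(probes_per_gene = 1L, noise_sd_expr = 0,
                     invalid_probe_rate = 0, planted_fail_fraction = 0,
                     background_fail_rate = 0, n_donors = 2L, seed = 7L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  sig <- attr(donors, "truth")$signal
  rgm1 <- build_region_gene_matrix(donors[1], atlas)
  # oracle: SRS applied to the planted per-sample signal, then averaged per
  # region (probe offsets are constant per probe, and SRS min-max rescaling
  # makes the result invariant to them up to the monotone sigmoid; with one
  # probe and zero noise the sample values are signal + offset exactly)
  donor <- donors[[1]]
  assigned <- assign_samples_to_parcels(donor, atlas)
  ok <- !is.na(assigned)
  sel_genes <- colnames(sig)
  for (g in sample(sel_genes, 5)) {
    vals <- donor$expression[paste0(donor$probe_gene_map$probe_id[
      match(g, donor$probe_gene_map$gene_id)]), ok]
    srs <- scaled_robust_sigmoid(vals)
    orac <- tapply(srs, assigned[ok], mean)
    orac <- orac[names(orac) %in% rownames(rgm1$values)]  # left hemisphere
    expect_equal(rgm1$values[names(orac), g], orac[names(orac)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # two identical donors give the same matrix as one
  dup <- donors[c(1, 1)]
  dup[[2]]$donor_id <- "copy"
  class(dup) <- "donor_expression_set"
  rgm2 <- build_region_gene_matrix(dup, atlas)
  expect_equal(rgm2$values, rgm1$values, tolerance = 1e-12)
})

test_that("matrix construction is invariant to donor and sample order", {
  cfg <- tiny_config(seed = 5L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  rgm <- build_region_gene_matrix(donors, atlas)
  shuffled <- donors[rev(seq_along(donors))]
  set.seed(1)
  shuffled <- lapply(shuffled, function(d) {
    perm <- sample(ncol(d$expression))
    d$sample_coords <- d$sample_coords[perm, , drop = FALSE]
    d$expression <- d$expression[, perm, drop = FALSE]
    d$above_background <- d$above_background[, perm, drop = FALSE]
    d
  })
  class(shuffled) <- "donor_expression_set"
  rgm2 <- build_region_gene_matrix(shuffled, atlas)
  expect_equal(rgm2$values, rgm$values, tolerance = 1e-12)
})

test_that("low-noise recovery: emitted columns track the planted signal", {
  cfg <- tiny_config(noise_sd_expr = 0.05, seed = 6L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  sig <- attr(donors, "truth")$signal
  rgm <- build_region_gene_matrix(donors, atlas)
  rho <- vapply(colnames(rgm$values), function(g)
    cor(rgm$values[, g], sig[rownames(rgm$values), g], method = "spearman"),
    0)
  expect_gte(mean(rho > 0.95), 0.95)
})
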