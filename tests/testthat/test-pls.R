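# PLS fitting, spin permutation inference, bootstrap Z-scores, and the
# clinical PLS.

test_that("response equal to an orthogonal standardized column is fully
           explained by a unit weight vector", {
  n <- 12
  H <- contr.helmert(n)[, 1:5]           # orthogonal, mean-zero columns
  X <- scale(H)
  colnames(X) <- paste0("g", 1:5)
  y <- X[, 3]
  fit <- pls_fit(X, y)
  e3 <- c(0, 0, 1, 0, 0)
  expect_equal(unname(fit$weights), e3, tolerance = 1e-10)
  expect_equal(fit$explained_variance_y, 1, tolerance = 1e-10)
})

test_that("first-component weights equal the normalized standardized
           cross-covariance on random toys", {
  set.seed(10)
  for (rep in 1:20) {
    X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("g", 1:5)))
    y <- rnorm(12)
    fit <- pls_fit(X, y)
    w <- as.numeric(crossprod(scale(X), scale(y)))
    w <- w / sqrt(sum(w^2))
    if (cor(as.numeric(scale(X) %*% w), y) < 0) w <- -w
    expect_lt(max(abs(fit$weights - w)), 1e-10)
    expect_gte(cor(fit$scores, y), 0)    # sign convention
  }
})

test_that("explained variance under an independent response matches the
           permutation-null mean", {
  set.seed(11)
  n <- 30
  X <- matrix(rnorm(n * 8), n, 8)
  evy <- replicate(200, pls_fit(X, rnorm(n))$explained_variance_y)
  null_evy <- pls_spin_pvalue(X, rnorm(n), n_perm = 200, seed = 1,
                              null = "naive")$null
  # both are draws from the same null; compare means within MC error
  se <- sqrt(var(evy) / 200 + var(null_evy) / 200)
  expect_lt(abs(mean(evy) - mean(null_evy)), 4 * se)
})

test_that("pls_fit rejects degenerate inputs and drops constant columns", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(pls_fit(X, rep(1, 10)), "zero variance")
  X2 <- cbind(X, c = rep(2, 10))
  expect_warning(fit <- pls_fit(X2, rnorm(10)), "zero-variance")
  expect_identical(fit$dropped_columns, "c")
  expect_length(fit$weights, 2L)
})

test_that("spin relabelings are valid maps and identity is excluded", {
  atlas <- generate_atlas(tiny_config(n_parcels_left = 30L))
  perms <- spin_rotation_null(atlas, n_perm = 50, seed = 4)
  expect_equal(dim(perms), c(50L, 30L))
  expect_true(all(perms >= 1 & perms <= 30))
  expect_false(any(apply(perms, 1, function(p) all(p == 1:30))))
  expect_identical(spin_rotation_null(atlas, n_perm = 50, seed = 4)[, ],
                   perms[, ])
})

test_that("a sub-gap rotation relabels every region to itself", {
  atlas <- generate_atlas(tiny_config(n_parcels_left = 30L))
  C <- as.matrix(atlas[atlas$hemisphere == "left", c("x", "y", "z")])
  gap <- min(dist(C))
  # rotation about z by an angle small enough that every centroid moves
  # less than half the minimum inter-centroid gap
  theta <- 0.4 * gap / attr(atlas, "radius")
  R <- rbind(c(cos(theta), -sin(theta), 0),
             c(sin(theta), cos(theta), 0),
             c(0, 0, 1))
  rotated <- C %*% t(R)
  expect_true(max(sqrt(rowSums((rotated - C)^2))) < gap / 2)
  d <- brainpls:::.cross_dist(rotated, C)
  expect_identical(max.col(-d, ties.method = "first"), 1:30)
})

test_that("spin p-value hits the add-one floor for a planted map and the
           batch null equals looped refits", {
  set.seed(12)
  atlas <- generate_atlas(tiny_config(n_parcels_left = 30L))
  ids <- atlas$parcel_id[atlas$hemisphere == "left"]
  X <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(ids, paste0("g", 1:10)))
  beta <- c(3, -3, rep(0, 8))
  y <- as.numeric(scale(X) %*% beta)   # strong planted coupling, no noise
  sp <- pls_spin_pvalue(X, y, atlas, n_perm = 99, seed = 5)
  expect_equal(sp$p_spin, 1 / 100)
  # the vectorized null path must agree with refitting pls_fit per spin
  perms <- spin_rotation_null(atlas, n_perm = 10, seed = 6, regions = ids)
  sp2 <- pls_spin_pvalue(X, y, perms = perms)
  looped <- apply(perms, 1, function(p)
    pls_fit(X, y[p])$explained_variance_y)
  expect_equal(unname(sp2$null), unname(looped), tolerance = 1e-12)
})

test_that("bootstrap Z recovers the signs of a sparse planted model", {
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 20), n, 20, dimnames = list(NULL, paste0("g", 1:20)))
  beta <- c(2, 2, -2, -2, rep(0, 16))
  y <- as.numeric(scale(X) %*% beta)   # noiseless exact linear relation
  bz <- bootstrap_gene_z(X, y, n_boot = 300, seed = 7)
  expect_true(all(sign(bz$z_score[beta != 0]) == sign(beta[beta != 0])))
  expect_true(all(abs(bz$z_score[beta != 0]) >
                    median(abs(bz$z_score[beta == 0]))))
  expect_true(all(bz$q_fdr > 0 & bz$q_fdr <= 1, na.rm = TRUE))
  expect_length(intersect(bz$pls1_plus, bz$pls1_minus), 0L)
})

test_that("null gene Z-scores are approximately standard normal", {
  set.seed(14)
  n <- 80
  X <- matrix(rnorm(n * 40), n, 40, dimnames = list(NULL, paste0("g", 1:40)))
  y <- rnorm(n)                         # independent of every column
  bz <- bootstrap_gene_z(X, y, n_boot = 400, seed = 8)
  ks <- suppressWarnings(ks.test(bz$z_score, "pnorm"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(bz$z_score)), 0.5)
})

test_that("degenerate resamples give zero SE and the flagged exclusion path", {
  X <- matrix(c(0, 1, 0, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  y <- c(0, 1)
  # with 2 rows, every variance-positive resample is a permutation of the
  # two rows, so all aligned bootstrap weight vectors are identical
  expect_warning(bz <- bootstrap_gene_z(X, y, n_boot = 10, seed = 1),
                 "zero bootstrap SE")
  expect_true(all(bz$bootstrap_se == 0))
  expect_length(bz$pls1_plus, 0L)
  expect_true(all(is.na(bz$z_score)))
})

test_that("clinical PLS identifies a single driving region", {
  # orthogonal regional changes: the component then isolates the driver
  d <- scale(contr.helmert(10)[, 1:6])
  dimnames(d) <- list(sprintf("s%02d", 1:10), paste0("L", 1:6))
  outcome <- d[, 4]
  cl <- clinical_pls(d, outcome, n_perm = 99, n_boot = 49, seed = 2)
  expect_equal(cl$r_with_outcome, 1, tolerance = 1e-8)
  expect_identical(names(which.max(abs(cl$region_weight))), "L4")
  # correlated regions: the driver still carries the largest weight
  set.seed(15)
  d2 <- matrix(rnorm(10 * 6), 10, 6, dimnames = dimnames(d))
  cl2 <- clinical_pls(d2, d2[, 4], n_perm = 99, n_boot = 49, seed = 2)
  expect_identical(names(which.max(abs(cl2$region_weight))), "L4")
  expect_error(clinical_pls(d2, d2[-1, 4]), "do not match")
  expect_error(clinical_pls(d2[1:2, ], d2[1:2, 4]), "at least 3")
})

test_that("clinical permutation test is calibrated under a shuffled outcome", {
  set.seed(16)
  n <- 20
  d <- matrix(rnorm(n * 15), n, 15,
              dimnames = list(sprintf("s%02d", 1:n), paste0("L", 1:15)))
  rej <- 0
  reps <- 150
  for (r in seq_len(reps)) {
    y <- rnorm(n)                      # outcome independent of predictors
    cl <- clinical_pls(d, setNames(y, rownames(d)), n_perm = 99,
                       n_boot = 5, seed = r)
    if (cl$p_perm <= 0.05) rej <- rej + 1
  }
  ci <- qbinom(c(0.005, 0.995), reps, 0.05)
  expect_gte(rej, ci[1])
  expect_lte(rej, ci[2])
})

test_that("clinical region_z ranks planted regions above unloaded ones", {
  cfg <- tiny_config(seed = 21L)
  atlas <- generate_atlas(cfg)
  donors <- generate_donor_expression(atlas, cfg)
  st <- generate_study(atlas, attr(donors, "truth")$signal, cfg)
  chg <- study_change_matrix(st$study)
  cl <- clinical_pls(chg$delta_gmv, chg$improvement, n_perm = 99,
                     n_boot = 300, seed = 3)
  loading <- st$truth$clinical_loading
  loaded <- names(loading)[loading != 0]
  unloaded <- setdiff(names(cl$region_z), loaded)
  expect_gt(median(abs(cl$region_z[loaded])),
            median(abs(cl$region_z[unloaded])))
})

test_that("permutation p-values are reproducible and never zero", {
  set.seed(17)
  atlas <- generate_atlas(tiny_config(n_parcels_left = 20L))
  ids <- atlas$parcel_id[atlas$hemisphere == "left"]
  X <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(ids, paste0("g", 1:6)))
  y <- rnorm(20)
  p1 <- pls_spin_pvalue(X, y, atlas, n_perm = 49, seed = 9)$p_spin
  p2 <- pls_spin_pvalue(X, y, atlas, n_perm = 49, seed = 9)$p_spin
  expect_identical(p1, p2)
  expect_gt(p1, 0)
})
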