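test_that("noise-free layers are a pure monotone gradient", {
  cfg <- landscape_config(grid_rows = 16, grid_cols = 20, noise_sd = 0,
                          gradient_direction = 0, seed = 1)
  stk <- generate_climate_rasters(cfg, 1)
  v <- layer_values(stk, 1)
  expect_true(all(diff(t(v)[, 1]) > 0))          # increases west -> east
  expect_true(all(apply(v, 1, function(r) all(diff(r) > 0))))
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
})

test_that("generators are bit-identical for a fixed seed", {
  cfg <- landscape_config(seed = 42)
  expect_identical(generate_climate_rasters(cfg, 2),
                   generate_climate_rasters(cfg, 2))
  cfg2 <- landscape_config(seed = 43)
  expect_false(identical(generate_climate_rasters(cfg, 2),
                         generate_climate_rasters(cfg2, 2)))
  occ <- simulate_occurrences(generate_climate_rasters(cfg, 1),
                              c(bio1 = 1), 20, seed = 7)
  occ2 <- simulate_occurrences(generate_climate_rasters(cfg, 1),
                               c(bio1 = 1), 20, seed = 7)
  expect_identical(occ$points, occ2$points)
})

test_that("smoothed fields are spatially autocorrelated (Moran's I)", {
  cfg <- landscape_config(grid_rows = 64, grid_cols = 64,
                          autocorrelation_range = 8, noise_sd = 5,
                          seed = 5)
  v <- layer_values(generate_climate_rasters(cfg, 1), 1)
  i_obs <- moran_i_rook(v)
  set.seed(11)
  i_shuf <- moran_i_rook(matrix(sample(v), nrow(v), ncol(v)))
  expect_gt(i_obs, 0.5)
  expect_gt(i_obs, i_shuf)
})

test_that("future rasters are deterministic shifts of the present", {
  stk <- generate_climate_rasters(landscape_config(seed = 3), 2)
  expect_equal(generate_future_rasters(stk, 0), stk)
  fut <- generate_future_rasters(stk, c(2, -1))
  expect_equal(mean(layer_values(fut, 1)), 2, tolerance = 1e-9)
  expect_equal(mean(layer_values(fut, 2)), -1, tolerance = 1e-9)
  ## three pseudo-GCMs: per-cell mean equals present + mean(deltas)
  deltas <- c(1, 2, 3)
  futs <- lapply(deltas, function(d) generate_future_rasters(stk, c(d, 0)))
  avg <- Reduce(`+`, lapply(futs, layer_values, 1)) / 3
  expect_equal(avg, layer_values(stk, 1) + mean(deltas), tolerance = 1e-9)
})

test_that("neutral loci hit the target differentiation", {
  pm <- population_model(n_populations = 10, inds_per_population = 20,
                         n_neutral_loci = 1000, n_adaptive_loci = 10,
                         fst_target = 0.3, adaptive_slope = 0, seed = 5)
  set.seed(1)
  clim <- matrix(scale(rnorm(200)), ncol = 1)
  gm <- simulate_genotypes(pm, clim)
  fst <- pairwise_fst(gm)
  expect_lt(abs(fst$overall - 0.3), 0.05)
  expect_error(population_model(fst_target = 1.2), "fst_target")
})

test_that("zero-slope adaptive loci are indistinguishable from neutral", {
  pm <- population_model(n_populations = 10, inds_per_population = 20,
                         n_neutral_loci = 1500, n_adaptive_loci = 500,
                         fst_target = 0.1, adaptive_slope = 0, seed = 8)
  set.seed(2)
  clim <- matrix(scale(rnorm(200)), ncol = 1)
  gm <- simulate_genotypes(pm, clim)
  truth <- attr(gm, "truth")
  r <- abs(as.numeric(cor(gm$values, clim)))
  ks <- suppressWarnings(ks.test(r[truth$adaptive], r[!truth$adaptive]))
  expect_gt(ks$p.value, 0.01)
})

test_that("strong clines separate allele frequencies at climate extremes", {
  pm <- population_model(n_populations = 2, inds_per_population = 100,
                         n_neutral_loci = 50, n_adaptive_loci = 40,
                         fst_target = 0.05, adaptive_slope = 2, seed = 9)
  clim <- matrix(rep(c(-2, 2), each = 100), ncol = 1)  # +/- 2 SD extremes
  gm <- simulate_genotypes(pm, clim)
  truth <- attr(gm, "truth")
  ad <- gm$values[, truth$adaptive]
  af_cold <- colMeans(ad[1:100, ]) / 2
  af_hot <- colMeans(ad[101:200, ]) / 2
  expect_gt(mean(abs(af_hot - af_cold)), 0.4)
})

test_that("occurrences follow the true suitability surface", {
  stk <- generate_climate_rasters(landscape_config(grid_rows = 20,
                                                   grid_cols = 20,
                                                   noise_sd = 0), 1)
  ## step suitability: only the north (top) half is habitable
  north <- stk
  north$layers$bio1 <- rbind(matrix(50, 10, 20), matrix(-50, 10, 20))
  occ <- simulate_occurrences(north, c(bio1 = 1), 200, seed = 3)
  expect_true(all(occ$points$row <= 10))
  ## uniform suitability: quadrant counts consistent with uniformity
  flat <- stk
  flat$layers$bio1 <- matrix(0, 20, 20)
  occ_u <- simulate_occurrences(flat, c(bio1 = 1), 1000, seed = 4)
  quad <- table(factor(occ_u$points$row <= 10, c(TRUE, FALSE)),
                factor(occ_u$points$col <= 10, c(TRUE, FALSE)))
  expect_gt(chisq.test(as.vector(quad))$p.value, 0.01)
  ## degenerate surface rejected
  dead <- stk
  dead$layers$bio1 <- matrix(-Inf, 20, 20)
  expect_error(simulate_occurrences(dead, c(bio1 = 1), 10, seed = 1),
               "zero")
})

test_that("simulated IBR distances obey the linear model", {
  set.seed(6)
  n <- 12
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  g0 <- simulate_ibr_distances(D, beta = 2, noise_sd = 0, seed = 1)
  expect_equal(cor(g0[upper.tri(g0)], D[upper.tri(D)]), 1,
               tolerance = 1e-12)
  g <- simulate_ibr_distances(D, beta = 2, noise_sd = 0.3, seed = 2)
  expect_equal(g, t(g), ignore_attr = TRUE)
  expect_true(all(diag(g) == 0))
  ## subtracting the seeded noise back recovers beta * input exactly
  ## (on pairs that were not clipped at zero)
  E <- attr(g, "noise")
  expect_lt(max(abs((g - E)[g > 0] - (2 * D)[g > 0])), 1e-12)
  asym <- D; asym[1, 2] <- asym[1, 2] + 1
  expect_error(simulate_ibr_distances(asym, 1, 0), "symmetric")
})

test_that("zero-slope IBR gives a near-zero regression R-squared", {
  set.seed(10)
  n <- 20
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  r2 <- vapply(1:100, function(i) {
    g <- simulate_ibr_distances(D, beta = 0, noise_sd = 1, seed = i)
    gv <- g[upper.tri(g)]; dv <- D[upper.tri(D)]
    summary(lm(gv ~ dv))$r.squared
  }, numeric(1))
  expect_lt(mean(r2), 0.05)
})
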