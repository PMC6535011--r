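make_stack <- function(nr = 20, nc = 20, seed = 1, n_layers = 2) {
  generate_climate_rasters(
    landscape_config(grid_rows = nr, grid_cols = nc, noise_sd = 0.5,
                     autocorrelation_range = 3, seed = seed), n_layers)
}

test_that("greedy decorrelation drops the right layers", {
  stk <- make_stack()
  ## duplicate layer: one of the pair is dropped
  dup <- stk
  dup$layers$bio3 <- dup$layers$bio1
  out <- remove_correlated_variables(dup, 0.75)
  expect_equal(length(out$layers), 2)
  expect_length(attr(out, "dropped"), 1)
  ## independent layers survive
  expect_equal(names(remove_correlated_variables(stk, 0.75)$layers),
               names(stk$layers))
  ## r(A,B) = 0.9, C almost independent: the member of (A,B) with the
  ## larger mean |r| to the others goes
  set.seed(2)
  a <- matrix(rnorm(400), 20)
  b <- 0.95 * a + 0.2 * matrix(rnorm(400), 20)
  cc <- matrix(rnorm(400), 20)
  tri <- raster_stack(list(A = a, B = b, C = cc))
  C <- abs(cor(cbind(as.vector(a), as.vector(b), as.vector(cc))))
  diag(C) <- 0
  victim <- c("A", "B")[which.max(rowMeans(C)[1:2])]
  out3 <- remove_correlated_variables(tri, 0.75)
  expect_equal(attr(out3, "dropped"), victim)
  expect_equal(length(out3$layers), 2)
})

test_that("background sampling avoids presences and is seeded", {
  stk <- make_stack(10, 10)
  occ <- data.frame(x = c(0.5, 1.5), y = c(0.5, 1.5))
  bg1 <- sample_background(stk, 50, seed = 3, exclusion = occ)
  bg2 <- sample_background(stk, 50, seed = 3, exclusion = occ)
  expect_identical(bg1, bg2)
  expect_false(any(paste(bg1$row, bg1$col) %in%
                   paste(clean_occurrences(stk, occ)$row,
                         clean_occurrences(stk, occ)$col)))
  expect_error(sample_background(stk, 1e5, seed = 1), "free cells")
})

test_that("the percentile envelope behaves at its landmarks", {
  set.seed(4)
  env <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_envelope(env, percentile = 0.05)
  med <- matrix(apply(env, 2, median), 1)
  expect_equal(predict(fit, med), 1)
  expect_equal(predict(fit, matrix(c(99, 99), 1)), 0)
  ## one variable inside, one outside -> 0.5
  half <- matrix(c(median(env[, 1]), 99), 1)
  expect_equal(predict(fit, half), 0.5)
})

test_that("logistic member separates a separable toy exactly", {
  env_p <- matrix(rnorm(40, 3), 20, 2)
  env_b <- matrix(rnorm(40, -3), 20, 2)
  fit <- fit_logistic(env_p, env_b)
  expect_equal(auc_rank(predict(fit, env_p), predict(fit, env_b)), 1)
  expect_error(fit_logistic(env_p, env_p[0, ]), "background")
})

test_that("the L1 member collapses to uniform and to the MLE limit", {
  set.seed(5)
  env_p <- matrix(rnorm(120, 1), 60, 2, dimnames = list(NULL, c("a", "b")))
  env_b <- matrix(rnorm(400, 0), 200, 2, dimnames = list(NULL, c("a", "b")))
  ## infinite penalty: fully shrunk, uniform suitability
  flat <- fit_maxent_like(env_p, env_b, l1_penalty = 1e6)
  s <- predict(flat, rbind(env_p, env_b))
  expect_equal(diff(range(s)), 0)
  ## zero penalty: coefficients match the unpenalized logistic fit on
  ## the same feature set
  mx <- fit_maxent_like(env_p, env_b, l1_penalty = 0, thresh = 1e-13)
  gl <- fit_logistic(env_p, env_b, interactions = TRUE)
  expect_lt(max(abs(mx$coef - gl$coef)), 1e-4)
  ## presences clustered at the hot end give monotone suitability
  stk <- make_stack(20, 20, seed = 6, n_layers = 1)
  v <- layer_values(stk, 1)
  hot_cells <- which(v > quantile(v, 0.85), arr.ind = TRUE)
  xy <- adaptscape:::cell_to_xy(stk, hot_cells[, 1], hot_cells[, 2])
  envp <- extract_env(stk, xy[, "x"], xy[, "y"])
  bg <- sample_background(stk, 200, seed = 7)
  envb <- extract_env(stk, bg$x, bg$y)
  fit <- fit_maxent_like(envp, envb, l1_penalty = 0.001)
  grid <- matrix(seq(min(v), max(v), length.out = 20), ncol = 1,
                 dimnames = list(NULL, "bio1"))
  s_grid <- predict(fit, grid)
  expect_gt(cor(s_grid, grid[, 1], method = "spearman"), 0.9)
  expect_gt(s_grid[20], s_grid[1])
  expect_error(fit_maxent_like(envp[1, , drop = FALSE], envb), "two")
})

test_that("cross-validation scores perfect and random models correctly", {
  set.seed(8)
  env_p <- matrix(rnorm(200, 4), 100, 2)
  env_b <- matrix(rnorm(600, -4), 300, 2)
  cv <- cross_validate(function(p, b) fit_logistic(p, b), env_p, env_b,
                       seed = 9)
  expect_length(cv, 10)
  expect_true(all(vapply(cv, `[[`, numeric(1), "auc") == 1))
  expect_true(all(vapply(cv, `[[`, numeric(1), "tss") == 1))
  ## presences indistinguishable from background -> AUC about 0.5
  env_p0 <- matrix(rnorm(200), 100, 2)
  env_b0 <- matrix(rnorm(600), 300, 2)
  cv0 <- cross_validate(function(p, b) fit_logistic(p, b), env_p0,
                        env_b0, seed = 10)
  expect_lt(abs(mean(vapply(cv0, `[[`, numeric(1), "auc")) - 0.5), 0.05)
  ## fewer than 50 presences -> 5 replicates
  cv5 <- cross_validate(function(p, b) fit_envelope(p),
                        env_p[1:40, ], env_b, seed = 11)
  expect_length(cv5, 5)
})

test_that("ensemble weighting is proportional to TSS above the cutoff", {
  set.seed(12)
  env <- matrix(rnorm(40), 20, 2)
  dummy <- function(tss) list(fit = fit_envelope(env), replicate = 1,
                              auc = 0.9, tss = tss, threshold = 0.5,
                              eval_pres = env[1:10, ],
                              eval_bg = env[11:20, ])
  ens <- build_ensemble(list(dummy(0.8), dummy(0.4)), tss_cutoff = 0.4)
  expect_equal(ens$weights, c(2 / 3, 1 / 3))
  ## adding a sub-cutoff member changes nothing
  ens2 <- build_ensemble(list(dummy(0.8), dummy(0.4), dummy(0.2)),
                         tss_cutoff = 0.4)
  expect_equal(ens2$weights, ens$weights)
  expect_length(build_ensemble(list(dummy(0.9)))$weights, 1)
  expect_error(build_ensemble(list(dummy(0.1))), "best member TSS")
})

test_that("projection merges pseudo-GCMs by the per-cell mean", {
  stk <- make_stack(16, 16, seed = 13)
  occ <- simulate_occurrences(stk, c(`(Intercept)` = -1, bio1 = 2), 80,
                              seed = 14)
  ens <- fit_enm(stk, occ, n_background = 150, seed = 15)
  ## future identical to present: projection equals the present range
  same <- project_ensemble(ens, list(stk, stk, stk))
  pres <- predict_raster(ens, stk)
  expect_equal(same$binary$layers$range, pres$binary$layers$range)
  expect_equal(same$continuous$layers$suitability,
               pres$continuous$layers$suitability, tolerance = 1e-12)
  ## three shifted stacks: per-cell mean equals the hand average
  futs <- lapply(c(0.5, 1, 1.5), function(d)
    generate_future_rasters(stk, c(d, 0)))
  pr <- project_ensemble(ens, futs)
  hand <- Reduce(`+`, lapply(futs, function(f)
    predict_raster(ens, f)$continuous$layers$suitability)) / 3
  expect_equal(pr$continuous$layers$suitability, hand, tolerance = 1e-12)
})

test_that("range-change arithmetic reproduces consistent printed rows", {
  mk <- function(pct) {
    n <- round(pct * 100)
    matrix(c(rep(1, n), rep(0, 10000 - n)), 100, 100)
  }
  ## rows whose printed change agrees with the printed inputs
  rows <- list(c(46.82, 49.50, 5.72), c(29.27, 12.08, -58.73),
               c(14.34, 7.54, -47.42))
  for (r in rows) {
    rc <- range_change(mk(r[1]), mk(r[2]))
    expect_equal(rc$percent_present, r[1])
    expect_equal(rc$percent_future, r[2])
    expect_equal(round(rc$percent_change, 2), r[3])
  }
  idem <- mk(30)
  expect_equal(range_change(idem, idem)$percent_change, 0)
})

test_that("union, overlap and Schoener's D identities hold", {
  a <- matrix(c(1, 1, 0, 0), 2)
  b <- matrix(c(0, 0, 1, 0), 2)
  u <- combine_ranges(a, b)
  expect_equal(sum(u), sum(a) + sum(b))           # disjoint areas add
  expect_equal(combine_ranges(a, a), a)           # idempotent
  expect_gte(sum(u), max(sum(a), sum(b)))
  expect_equal(range_overlap(a, b), 0)
  nested <- matrix(c(1, 0, 0, 0), 2)
  expect_equal(range_overlap(a, nested), 25)      # = smaller range %
  ## Schoener's D
  expect_equal(schoener_d(a, a), 1)
  expect_equal(schoener_d(a, b), 0)
  expect_equal(schoener_d(matrix(c(1, 0), 1), matrix(c(0.5, 0.5), 1)),
               0.5)
  ## invariant to positive rescaling
  set.seed(16)
  s1 <- matrix(runif(100), 10); s2 <- matrix(runif(100), 10)
  expect_equal(schoener_d(s1, s2), schoener_d(3 * s1, s2))
  ## printed overlap arithmetic: 10.5% -> 1.7% is an 84% reduction
  expect_equal(round(percent_reduction(10.5, 1.7)), 84)
})

test_that("AUC is invariant to monotone transforms of suitability", {
  set.seed(17)
  pos <- runif(50); neg <- runif(80) * 0.8
  expect_equal(auc_rank(pos, neg), auc_rank(pos^3, neg^3))
  expect_equal(auc_rank(plogis(pos), plogis(neg)), auc_rank(pos, neg))
})

test_that("null models bracket an informative observed model", {
  stk <- make_stack(16, 16, seed = 18)
  nm <- null_model_test(stk, n_presences = 30, observed_auc = 0.93,
                        n_null = 19, seed = 19, n_background = 120)
  expect_length(nm$null_aucs, 19)
  expect_true(nm$significant)
  expect_equal(nm$p, 1 / 20)
  expect_error(null_model_test(stk, 30, n_null = 0), "n_null")
})

test_that("the niche-identity test tells apart identical and opposite groups", {
  stk <- make_stack(24, 24, seed = 20)
  hot <- simulate_occurrences(stk, c(`(Intercept)` = -1, bio1 = 3), 60,
                              seed = 21)
  cold <- simulate_occurrences(stk, c(`(Intercept)` = -1, bio1 = -3), 60,
                               seed = 22)
  opp <- niche_similarity_test(hot, cold, stk, n_perm = 99, seed = 23,
                               n_background = 200)
  expect_lte(opp$p_lower, 0.05)
  same <- niche_similarity_test(hot, hot, stk, n_perm = 99, seed = 24,
                                n_background = 200)
  expect_gte(same$p_lower, 0.95)
  expect_error(niche_similarity_test(hot, cold, stk, n_perm = 0), "n_perm")
})
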