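test_that("reclassification maps values to costs in [1, 100]", {
  m <- matrix(c(0, 25, 50, 75, 100, NA), 2, 3)
  ## single class -> uniform surface
  uni <- reclassify_to_resistance(m, data.frame(value = 0, cost = 1))
  expect_true(all(uni[!is.na(uni)] == 1))
  expect_true(is.na(uni[2, 3]))
  ## forest 100% -> cost 1, 0% -> cost 100, linear: 50% -> 50.5
  tab <- data.frame(value = c(0, 100), cost = c(100, 1))
  lin <- reclassify_to_resistance(m, tab, interpolate = TRUE)
  expect_equal(lin[1, 2], 50.5)
  expect_equal(lin[1, 1], 100)
  expect_equal(lin[1, 3], 1)
  expect_error(reclassify_to_resistance(
    m, data.frame(value = 0, cost = 200)), "100")
})

test_that("surface combination respects the documented operators", {
  a <- matrix(10, 3, 3); b <- matrix(30, 3, 3)
  expect_equal(combine_surfaces(list(a, a)), a)          # mean identity
  expect_equal(combine_surfaces(list(matrix(1, 2, 2),
                                     matrix(100, 2, 2)))[1, 1], 50.5)
  ## product_rescaled spans [1, 100] for a non-constant product
  set.seed(1)
  s1 <- matrix(runif(9, 1, 100), 3); s2 <- matrix(runif(9, 1, 100), 3)
  pr <- combine_surfaces(list(s1, s2), "product_rescaled")
  expect_equal(range(pr), c(1, 100))
})

test_that("graph conductances follow the Circuitscape convention", {
  g <- build_graph(matrix(4, 3, 3), connectivity = 8)
  e <- g$edges
  horiz <- e[abs(g$nodes[e$from, 1] - g$nodes[e$to, 1]) +
             abs(g$nodes[e$from, 2] - g$nodes[e$to, 2]) == 1, ]
  diag_e <- e[abs(g$nodes[e$from, 1] - g$nodes[e$to, 1]) == 1 &
              abs(g$nodes[e$from, 2] - g$nodes[e$to, 2]) == 1, ]
  expect_true(all(abs(horiz$conductance - 1 / 4) < 1e-12))
  expect_true(all(abs(diag_e$conductance - 1 / (4 * sqrt(2))) < 1e-12))
  ## nodata cells are isolated
  m <- matrix(1, 3, 3); m[2, 2] <- NA
  g2 <- build_graph(m)
  expect_equal(nrow(g2$nodes), 8)
  ## 4-neighbourhood has no diagonals
  g4 <- build_graph(matrix(1, 3, 3), connectivity = 4)
  expect_equal(nrow(g4$edges), 12)
})

test_that("series and parallel closed forms are exact", {
  ## chain of 5 unit-resistance edges -> R = 5
  chain <- toy_graph(6, from = 1:5, to = 2:6, conductance = rep(1, 5))
  R <- effective_resistance(chain, c(1L, 6L))
  expect_equal(R[1, 2], 5, tolerance = 1e-12)
  ## single edge of resistance r -> R = r
  one <- toy_graph(2, 1, 2, 1 / 3.7)
  expect_equal(effective_resistance(one, c(1L, 2L))[1, 2], 3.7,
               tolerance = 1e-12)
  ## two parallel unit edges -> R = 0.5
  par <- toy_graph(2, c(1, 1), c(2, 2), c(1, 1))
  expect_equal(effective_resistance(par, c(1L, 2L))[1, 2], 0.5,
               tolerance = 1e-12)
})

test_that("sparse solves agree with the dense pseudoinverse oracle", {
  for (s in 1:10) {
    n <- sample(10:100, 1)
    g <- random_graph(n, seed = 300 + s)
    focal <- sample.int(n, min(5, n))
    R <- effective_resistance(g, as.integer(focal))
    R_oracle <- dense_resistance_oracle(n, g$edges, focal)
    expect_lt(max(abs(R - R_oracle)), 1e-8)
    ## metric properties: symmetry and triangle inequality
    expect_equal(R, t(R), tolerance = 1e-10)
    k <- nrow(R)
    for (a in 1:k) for (b in 1:k) for (cc in 1:k)
      expect_lte(R[a, b], R[a, cc] + R[cc, b] + 1e-9)
  }
})

test_that("disconnected focal pairs are flagged infinite", {
  m <- matrix(1, 3, 3); m[, 2] <- NA  # two disconnected columns
  g <- build_graph(m)
  expect_warning(R <- effective_resistance(
    g, rbind(c(1, 1), c(1, 3))), "different components")
  expect_true(is.infinite(R[1, 2]))
})

test_that("current is conserved and splits by conductance", {
  ## chain: every interior node carries current 1, ends carry 0.5
  chain <- toy_graph(5, 1:4, 2:5, rep(1, 4))
  cd <- current_density(chain, 1L, 5L)
  expect_equal(as.numeric(cd$map[2:4, 1]), rep(1, 3), tolerance = 1e-10)
  expect_equal(as.numeric(cd$map[c(1, 5), 1]), rep(0.5, 2),
               tolerance = 1e-10)
  ## two-path network: source 1, sink 4; upper path conductance 2,
  ## lower path 1 -> currents split 2/3 vs 1/3 (hand Kirchhoff solve)
  two <- toy_graph(4, from = c(1, 2, 1, 3), to = c(2, 4, 3, 4),
                   conductance = c(2, 2, 1, 1))
  cd2 <- current_density(two, 1L, 4L)
  expect_equal(cd2$map[2, 1], 2 / 3, tolerance = 1e-10)
  expect_equal(cd2$map[3, 1], 1 / 3, tolerance = 1e-10)
  ## injection balance at the terminals
  expect_equal(cd2$map[1, 1], 0.5, tolerance = 1e-10)
  expect_equal(cd2$map[4, 1], 0.5, tolerance = 1e-10)
})

test_that("raising any cell's cost never lowers a resistance (Rayleigh)", {
  for (s in 1:3) {
    set.seed(400 + s)
    m <- matrix(runif(64, 1, 50), 8, 8)
    g <- build_graph(m)
    focal <- rbind(c(1, 1), c(8, 8), c(1, 8))
    R0 <- effective_resistance(g, focal)
    bump <- m
    cell <- c(sample(8, 1), sample(8, 1))
    bump[cell[1], cell[2]] <- min(bump[cell[1], cell[2]] * 10, 100)
    R1 <- effective_resistance(build_graph(bump), focal)
    expect_true(all(R1 - R0 >= -1e-9))
  }
})

test_that("IBR regression is exact on noise-free data and ranks surfaces", {
  set.seed(5)
  n <- 15
  D <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  g <- simulate_ibr_distances(D, beta = 2, noise_sd = 0, seed = 1)
  out <- ibr_regression(g, D, n_perm = 99, seed = 2)
  expect_equal(out$mantel_r, 1, tolerance = 1e-10)
  expect_equal(out$r_squared, 1, tolerance = 1e-10)
  expect_lte(out$mantel_p, 0.05)
  ## the generating surface wins the R-squared ranking
  alt1 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  alt2 <- as.matrix(dist(matrix(rnorm(n * 2), n)))
  noisy <- simulate_ibr_distances(D, beta = 1, noise_sd = 0.3, seed = 3)
  rank <- ibr_regression(noisy, list(true = D, alt1 = alt1, alt2 = alt2),
                         n_perm = 99, seed = 4)
  expect_equal(rank$surface[1], "true")
  expect_error(ibr_regression(g, D[-1, -1]), "focal sets")
})

test_that("rescue potential finds reachable targets and respects walls", {
  flat <- matrix(1, 10, 10)
  locs <- rbind(c(5, 2), c(5, 4), c(5, 9))
  labs <- c("hot_dry", "cold_wet", "cold_wet")
  r <- rescue_potential(flat, locs, labs)
  ## the adjacent target has the lowest summary resistance
  expect_lt(r$target_summary$mean_resistance[1],
            r$target_summary$mean_resistance[2])
  expect_equal(r$current$n_pairs, 2)
  ## a 100-cost wall between source and target raises the resistance
  wall <- flat; wall[, 6] <- 100
  rw <- rescue_potential(wall, locs, labs)
  expect_gt(rw$target_summary$mean_resistance[2],
            r$target_summary$mean_resistance[2])
  expect_error(rescue_potential(flat, locs, rep("cold_wet", 3)),
               "hot_dry")
})
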