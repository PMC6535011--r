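# Independent oracles and fixture builders shared across tests.

## Moran's I with rook weights, computed straight from the definition
## (independent of any package code; no spatial helper is used).
moran_i_rook <- function(m) {
  n <- length(m)
  xbar <- mean(m)
  dev <- m - xbar
  num <- 0; W <- 0
  nr <- nrow(m); nc <- ncol(m)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (j < nc) { num <- num + 2 * dev[i, j] * dev[i, j + 1]; W <- W + 2 }
    if (i < nr) { num <- num + 2 * dev[i, j] * dev[i + 1, j]; W <- W + 2 }
  }
  (n / W) * num / sum(dev^2)
}

## dense Moore-Penrose pseudoinverse effective resistance oracle
dense_resistance_oracle <- function(n, edges, focal) {
  L <- matrix(0, n, n)
  for (k in seq_len(nrow(edges))) {
    i <- edges$from[k]; j <- edges$to[k]; g <- edges$conductance[k]
    L[i, j] <- L[i, j] - g; L[j, i] <- L[j, i] - g
    L[i, i] <- L[i, i] + g; L[j, j] <- L[j, j] + g
  }
  s <- svd(L)
  pos <- s$d > max(s$d) * 1e-10
  Lp <- s$v[, pos, drop = FALSE] %*% diag(1 / s$d[pos], sum(pos)) %*%
    t(s$u[, pos, drop = FALSE])
  k <- length(focal)
  R <- matrix(0, k, k)
  for (a in seq_len(k)) for (b in seq_len(k))
    R[a, b] <- Lp[focal[a], focal[a]] + Lp[focal[b], focal[b]] -
      2 * Lp[focal[a], focal[b]]
  R
}

## hand-built graph in the raster_graph layout (n nodes on a 1-column grid)
toy_graph <- function(n, from, to, conductance) {
  structure(list(nodes = cbind(row = seq_len(n), col = rep(1L, n)),
                 edges = data.frame(from = from, to = to,
                                    conductance = conductance),
                 index = matrix(seq_len(n), n, 1),
                 dims = c(n, 1L),
                 geometry = list(xll = 0, yll = 0, cellsize = 1)),
            class = "raster_graph")
}

## connected random graph with random conductances
random_graph <- function(n, seed) {
  set.seed(seed)
  from <- integer(0); to <- integer(0)
  ## spanning chain guarantees connectivity, plus random extra edges
  from <- c(from, seq_len(n - 1)); to <- c(to, seq(2, n))
  extra <- matrix(sample.int(n, 2 * n, replace = TRUE), ncol = 2)
  extra <- extra[extra[, 1] != extra[, 2], , drop = FALSE]
  from <- c(from, pmin(extra[, 1], extra[, 2]))
  to <- c(to, pmax(extra[, 1], extra[, 2]))
  dup <- duplicated(cbind(from, to))
  from <- from[!dup]; to <- to[!dup]
  toy_graph(n, from, to, stats::runif(length(from), 0.2, 3))
}

## Genepop toy file text
toy_genepop_lines <- function() {
  c("toy dataset",
    "loc1", "loc2",
    "Pop",
    "a1 , 0101 0102",
    "a2 , 0102 0202",
    "Pop",
    "b1 , 0202 0101",
    "b2 , 0101 0000")
}

## synthetic study at the generator defaults: landscape, roost-structured
## climate, genotypes with truth labels
synth_study <- function(seed, n_populations = 15, inds_per_population = 20,
                        n_neutral = 2000, n_adaptive = 20,
                        fst_target = 0.1, slope = 2) {
  lc <- landscape_config(grid_rows = 48, grid_cols = 48,
                         autocorrelation_range = 6, noise_sd = 0.5,
                         seed = seed)
  stk <- generate_climate_rasters(lc, 2)
  ok <- which(valid_mask(stk), arr.ind = TRUE)
  set.seed(seed + 1)
  cells <- ok[sample.int(nrow(ok), n_populations), , drop = FALSE]
  xy <- cbind(x = cells[, 2] - 0.5, y = nrow(valid_mask(stk)) - cells[, 1] + 0.5)
  env <- extract_env(stk, xy[, "x"], xy[, "y"])
  ind_pop <- rep(seq_len(n_populations), each = inds_per_population)
  clim <- apply(env[ind_pop, , drop = FALSE], 2, scale)
  colnames(clim) <- colnames(env)
  pm <- population_model(n_populations, inds_per_population,
                         n_neutral, n_adaptive, fst_target, slope,
                         seed = seed + 2)
  gm <- simulate_genotypes(pm, clim)
  list(gm = gm, clim = clim, truth = attr(gm, "truth"), stack = stk,
       cells = cells)
}

## candidate_set wrapper for truth loci
truth_candidates <- function(truth) {
  tr <- truth[truth$adaptive, ]
  out <- data.frame(locus_id = tr$locus_id, method = "truth",
                    variable = tr$layer, direction = 1,
                    statistic = NA_real_, stringsAsFactors = FALSE)
  class(out) <- c("candidate_set", "data.frame")
  out
}
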