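#' Configuration for a synthetic landscape
#'
#' Describes the geometry and spatial structure of simulated climate or
#' landscape layers: a deterministic linear gradient plus a spatially
#' autocorrelated Gaussian random field (white noise smoothed with a
#' Gaussian kernel).
#'
#' @param grid_rows,grid_cols grid dimensions, at least 8 each.
#' @param cell_size cell edge length in map units.
#' @param gradient_direction angle of the gradient in radians; 0 points
#'   east (values increase with x), `pi/2` points north.
#' @param autocorrelation_range Gaussian smoothing kernel SD, in cells;
#'   controls the spatial autocorrelation of the noise field.
#' @param noise_sd standard deviation of the smoothed noise field, in
#'   layer units relative to a unit-SD gradient. 0 gives a pure gradient.
#' @param seed integer seed; identical seed and config give bit-identical
#'   layers.
#' @return an object of class `landscape_config`.
#' @export
landscape_config <- function(grid_rows = 64, grid_cols = 64, cell_size = 1,
                             gradient_direction = 0,
                             autocorrelation_range = 8,
                             noise_sd = 0.5, seed = 1) {
  if (grid_rows < 8 || grid_cols < 8)
    stop("grid must be at least 8 x 8")
  if (autocorrelation_range <= 0)
    stop("'autocorrelation_range' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 cell_size = cell_size,
                 gradient_direction = gradient_direction,
                 autocorrelation_range = autocorrelation_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "landscape_config")
}

## row-normalized Gaussian smoothing matrix for one axis
gaussian_smoother <- function(n, sd) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) stats::dnorm(j - i, sd = sd))
  K / rowSums(K)
}

#' Generate standardized synthetic climate layers
#'
#' Each layer is a unit-SD linear gradient along `gradient_direction` plus
#' an independent Gaussian random field (white noise smoothed to
#' `autocorrelation_range`, rescaled to SD `noise_sd`), standardized to
#' mean 0 and SD 1 over the grid. Successive layers rotate the gradient by
#' 90 degrees so that, e.g., a temperature-like and a rainfall-like layer
#' are decorrelated by construction.
#'
#' @param config a [landscape_config()].
#' @param n_layers number of layers; named bio1, bio2, ...
#' @return a raster_stack of standardized layers.
#' @export
generate_climate_rasters <- function(config, n_layers = 2) {
  stopifnot(inherits(config, "landscape_config"))
  nr <- config$grid_rows; nc <- config$grid_cols
  xc <- (seq_len(nc) - 0.5) * config$cell_size
  yc <- ((nr - seq_len(nr)) + 0.5) * config$cell_size  # row 1 = top
  with_seed(config$seed, {
    Kr <- gaussian_smoother(nr, config$autocorrelation_range)
    Kc <- gaussian_smoother(nc, config$autocorrelation_range)
    layers <- list()
    for (l in seq_len(n_layers)) {
      ang <- config$gradient_direction + (l - 1) * pi / 2
      g <- outer(yc, xc, function(y, x) cos(ang) * x + sin(ang) * y)
      if (stats::sd(g) > 0) g <- (g - mean(g)) / stats::sd(g)
      if (config$noise_sd > 0) {
        field <- Kr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% t(Kc)
        field <- field / stats::sd(field) * config$noise_sd
        g <- g + field
      }
      layers[[sprintf("bio%d", l)]] <- (g - mean(g)) / stats::sd(g)
    }
    raster_stack(layers, cellsize = config$cell_size)
  })
}

#' Shift present layers into pseudo-future layers
#'
#' Emulates a general-circulation-model projection by adding a
#' deterministic per-layer shift (optionally with spatially uncorrelated
#' jitter) to each standardized present-day layer, preserving geometry.
#'
#' @param present a raster_stack.
#' @param delta_mean numeric shift per layer, recycled across layers.
#' @param delta_sd optional SD of cellwise Gaussian jitter (default 0).
#' @param seed seed for the jitter, ignored when `delta_sd = 0`.
#' @return a raster_stack with the same geometry.
#' @export
generate_future_rasters <- function(present, delta_mean, delta_sd = 0,
                                    seed = 1) {
  stopifnot(inherits(present, "raster_stack"))
  if (delta_sd < 0) stop("'delta_sd' must be non-negative")
  delta <- rep_len(delta_mean, n_layers(present))
  out <- present
  with_seed(seed, {
    for (i in seq_along(out$layers)) {
      m <- out$layers[[i]] + delta[i]
      if (delta_sd > 0)
        m <- m + matrix(stats::rnorm(length(m), sd = delta_sd),
                        nrow(m), ncol(m))
      out$layers[[i]] <- m
    }
  })
  out
}

#' Demographic and selection model for synthetic genotypes
#'
#' Parameters of the hierarchical island model used by
#' [simulate_genotypes()]. Defaults emulate a ddRAD-style dataset of a
#' cave-roosting bat: a few hundred individuals from discrete roosts,
#' moderate differentiation, and a small panel of climate-adaptive loci
#' riding on top of the neutral structure.
#'
#' @param n_populations,inds_per_population sampling design (roosts and
#'   individuals per roost).
#' @param n_neutral_loci,n_adaptive_loci locus counts; adaptive must be
#'   fewer than neutral.
#' @param fst_target expected Weir–Cockerham differentiation among
#'   populations, in (0, 1).
#' @param adaptive_slope log-odds change in allele frequency per SD of
#'   the associated climate variable at adaptive loci.
#' @param missing_rate proportion of genotype calls dropped at random
#'   (default 0 = complete matrix).
#' @param seed integer seed.
#' @return an object of class `population_model`.
#' @export
population_model <- function(n_populations = 15, inds_per_population = 20,
                             n_neutral_loci = 2000, n_adaptive_loci = 20,
                             fst_target = 0.1, adaptive_slope = 2,
                             missing_rate = 0, seed = 1) {
  if (fst_target <= 0 || fst_target >= 1)
    stop("'fst_target' must lie in (0, 1)")
  if (n_adaptive_loci >= n_neutral_loci)
    stop("'n_adaptive_loci' must be smaller than 'n_neutral_loci'")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("'missing_rate' must lie in [0, 1)")
  structure(list(n_populations = as.integer(n_populations),
                 inds_per_population = as.integer(inds_per_population),
                 n_neutral_loci = as.integer(n_neutral_loci),
                 n_adaptive_loci = as.integer(n_adaptive_loci),
                 fst_target = fst_target,
                 adaptive_slope = adaptive_slope,
                 missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_model")
}

#' Simulate structured genotypes with climate-adaptive loci
#'
#' Neutral loci follow a Balding–Nichols island model: ancestral frequency
#' p ~ Uniform(0.05, 0.95); population frequency ~ Beta with mean p and
#' variance p(1-p) * fst_target; genotypes ~ Binomial(2, population
#' frequency). Adaptive loci are drawn the same way but with an
#' individual-level frequency logistic(logit(p_pop) + slope * climate),
#' so selection is layered on top of drift and `adaptive_slope = 0`
#' reduces exactly to the neutral model. Ground-truth locus labels are
#' attached so recovery tests are self-contained.
#'
#' @param model a [population_model()].
#' @param climate_at_samples numeric matrix, one row per individual and
#'   one column per climate variable (standardized); adaptive loci are
#'   assigned to columns in rotation. A vector is treated as one column.
#' @return a [genotype_matrix()] whose `truth` attribute is a data.frame
#'   with columns locus_id, adaptive, layer (assigned column name or NA)
#'   and ancestral_p.
#' @export
simulate_genotypes <- function(model, climate_at_samples) {
  stopifnot(inherits(model, "population_model"))
  if (is.null(dim(climate_at_samples)))
    climate_at_samples <- matrix(climate_at_samples, ncol = 1,
                                 dimnames = list(NULL, "bio1"))
  n <- model$n_populations * model$inds_per_population
  if (nrow(climate_at_samples) != n)
    stop("need one climate row per simulated individual (", n, ")")
  if (is.null(colnames(climate_at_samples)))
    colnames(climate_at_samples) <-
      sprintf("bio%d", seq_len(ncol(climate_at_samples)))
  F <- model$fst_target
  L <- model$n_neutral_loci + model$n_adaptive_loci
  pop <- rep(sprintf("pop%02d", seq_len(model$n_populations)),
             each = model$inds_per_population)
  with_seed(model$seed, {
    p_anc <- stats::runif(L, 0.05, 0.95)
    ## Balding-Nichols population frequencies, loci x populations
    a <- p_anc * (1 - F) / F
    b <- (1 - p_anc) * (1 - F) / F
    pfreq <- matrix(stats::rbeta(L * model$n_populations,
                                 shape1 = rep(a, model$n_populations),
                                 shape2 = rep(b, model$n_populations)),
                    nrow = L)
    pfreq <- pmin(pmax(pfreq, 1e-4), 1 - 1e-4)
    adaptive <- c(rep(FALSE, model$n_neutral_loci),
                  rep(TRUE, model$n_adaptive_loci))
    layer_idx <- rep(NA_integer_, L)
    if (model$n_adaptive_loci > 0)
      layer_idx[adaptive] <- rep_len(seq_len(ncol(climate_at_samples)),
                                     model$n_adaptive_loci)
    pop_idx <- rep(seq_len(model$n_populations),
                   each = model$inds_per_population)
    G <- matrix(0L, nrow = n, ncol = L)
    for (l in seq_len(L)) {
      f <- pfreq[l, pop_idx]
      if (adaptive[l])
        f <- stats::plogis(stats::qlogis(f) +
                           model$adaptive_slope *
                           climate_at_samples[, layer_idx[l]])
      G[, l] <- stats::rbinom(n, 2L, f)
    }
    if (model$missing_rate > 0) {
      drop <- stats::runif(length(G)) < model$missing_rate
      G[drop] <- NA_integer_
    }
    locus_ids <- sprintf("locus%05d", seq_len(L))
    truth <- data.frame(
      locus_id = locus_ids, adaptive = adaptive,
      layer = ifelse(is.na(layer_idx), NA_character_,
                     colnames(climate_at_samples)[layer_idx]),
      ancestral_p = p_anc, stringsAsFactors = FALSE)
    gm <- genotype_matrix(G, sample_ids = sprintf("ind%03d", seq_len(n)),
                          locus_ids = locus_ids, populations = pop)
    attr(gm, "truth") <- truth
    gm
  })
}

#' Sample occurrence points from a logistic suitability surface
#'
#' True suitability is `plogis(intercept + sum(coef * layer))` over the
#' stack; cells are then sampled (with replacement) with probability
#' proportional to suitability and reported at their centres.
#'
#' @param stack a raster_stack of (standardized) climate layers.
#' @param coef named coefficients for layers of `stack`; an `(Intercept)`
#'   entry is optional (default 0).
#' @param n_points number of points, at least 5.
#' @param seed integer seed.
#' @return an object of class `occurrence_set`: data.frame `points`
#'   (id, x, y, row, col), plus the true `suitability` raster_stack.
#' @export
simulate_occurrences <- function(stack, coef, n_points, seed = 1) {
  stopifnot(inherits(stack, "raster_stack"))
  if (n_points < 5) stop("'n_points' must be at least 5")
  b0 <- if ("(Intercept)" %in% names(coef)) coef[["(Intercept)"]] else 0
  lin <- matrix(b0, stack$nrow, stack$ncol)
  for (nm in setdiff(names(coef), "(Intercept)")) {
    if (!nm %in% names(stack$layers))
      stop("coefficient for unknown layer: ", nm)
    lin <- lin + coef[[nm]] * stack$layers[[nm]]
  }
  suit <- stats::plogis(lin)
  suit[!valid_mask(stack)] <- NA_real_
  w <- as.vector(t(suit))  # cell index in row-major order
  w[is.na(w)] <- 0
  if (sum(w) <= 0) stop("suitability surface is zero everywhere")
  with_seed(seed, {
    cells <- sample.int(length(w), n_points, replace = TRUE, prob = w)
    row <- (cells - 1L) %/% stack$ncol + 1L
    col <- (cells - 1L) %% stack$ncol + 1L
    xy <- cell_to_xy(stack, row, col)
    pts <- data.frame(id = sprintf("occ%04d", seq_len(n_points)),
                      x = xy[, "x"], y = xy[, "y"],
                      row = row, col = col, stringsAsFactors = FALSE)
    structure(list(points = pts,
                   suitability = raster_stack(
                     list(suitability = suit), xll = stack$xll,
                     yll = stack$yll, cellsize = stack$cellsize,
                     nodata = stack$nodata),
                   coef = coef, seed = seed),
              class = "occurrence_set")
  })
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set: %d points over a %d x %d suitability grid\n",
              nrow(x$points), x$suitability$nrow, x$suitability$ncol))
  invisible(x)
}

#' Simulate genetic distances under isolation by resistance
#'
#' Linearized genetic distance = beta * resistance distance + symmetric
#' Gaussian noise, clipped at zero, with a zero diagonal.
#'
#' @param resistance_distances symmetric matrix with zero diagonal.
#' @param beta slope of the isolation-by-resistance relationship.
#' @param noise_sd SD of the symmetric Gaussian noise.
#' @param seed integer seed.
#' @return symmetric genetic-distance matrix; the pre-clip noise matrix is
#'   attached as attribute `noise`.
#' @export
simulate_ibr_distances <- function(resistance_distances, beta,
                                   noise_sd = 0, seed = 1) {
  check_square_symmetric(resistance_distances, "'resistance_distances'")
  if (any(diag(resistance_distances) != 0))
    stop("'resistance_distances' must have a zero diagonal")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  n <- nrow(resistance_distances)
  with_seed(seed, {
    E <- matrix(0, n, n)
    if (noise_sd > 0) {
      vals <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
      E[upper.tri(E)] <- vals
      E <- E + t(E)
    }
    g <- pmax(beta * resistance_distances + E, 0)
    diag(g) <- 0
    dimnames(g) <- dimnames(resistance_distances)
    attr(g, "noise") <- E
    g
  })
}
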