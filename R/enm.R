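#' Drop highly correlated raster layers
#'
#' Greedy decorrelation: while any pair of layers has Pearson |r| above
#' `r_threshold` over shared valid cells, the member of the worst pair
#' with the larger mean |r| to all remaining layers is dropped. The
#' procedure is deterministic.
#'
#' @param stack a raster_stack.
#' @param r_threshold absolute-correlation cutoff (default 0.75).
#' @return raster_stack with the surviving layers; dropped names in
#'   attribute `dropped`.
#' @export
remove_correlated_variables <- function(stack, r_threshold = 0.75) {
  keep <- names(stack$layers)
  dropped <- character(0)
  repeat {
    if (length(keep) < 2) break
    vals <- sapply(keep, function(nm) as.vector(stack$layers[[nm]]))
    C <- abs(stats::cor(vals, use = "pairwise.complete.obs"))
    diag(C) <- 0
    if (max(C) <= r_threshold) break
    worst <- which(C == max(C), arr.ind = TRUE)[1, ]
    mean_r <- rowMeans(C[worst, , drop = FALSE])
    victim <- keep[worst[which.max(mean_r)]]
    dropped <- c(dropped, victim)
    keep <- setdiff(keep, victim)
  }
  out <- stack
  out$layers <- stack$layers[keep]
  attr(out, "dropped") <- dropped
  out
}

#' Snap occurrence points to cells and drop per-cell duplicates
#'
#' @param stack a raster_stack.
#' @param points data.frame with columns x, y (or an occurrence_set).
#' @return data.frame (x, y, row, col) of cell centres of occupied valid
#'   cells, one row per cell.
#' @export
clean_occurrences <- function(stack, points) {
  if (inherits(points, "occurrence_set")) points <- points$points
  inx <- in_extent(stack, points$x, points$y)
  points <- points[inx, , drop = FALSE]
  rc <- xy_to_cell(stack, points$x, points$y)
  ok <- valid_mask(stack)[rc]
  rc <- rc[ok, , drop = FALSE]
  rc <- unique(as.data.frame(rc))
  xy <- cell_to_xy(stack, rc$row, rc$col)
  data.frame(x = xy[, "x"], y = xy[, "y"], row = rc$row, col = rc$col)
}

#' Sample background (pseudo-absence) cells
#'
#' Uniform random sample of valid cells, excluding cells occupied by the
#' given presences; deterministic per seed.
#'
#' @param stack a raster_stack.
#' @param n number of background points.
#' @param seed integer seed.
#' @param exclusion optional presence points (data.frame x, y or
#'   occurrence_set) whose cells are excluded.
#' @return data.frame (x, y, row, col).
#' @export
sample_background <- function(stack, n, seed = 1, exclusion = NULL) {
  ok <- valid_mask(stack)
  if (!is.null(exclusion)) {
    occ <- clean_occurrences(stack, exclusion)
    ok[cbind(occ$row, occ$col)] <- FALSE
  }
  free <- which(ok, arr.ind = TRUE)
  if (n > nrow(free))
    stop("requested ", n, " background points but only ", nrow(free),
         " free cells")
  with_seed(seed, {
    idx <- sample.int(nrow(free), n)
    xy <- cell_to_xy(stack, free[idx, 1], free[idx, 2])
    data.frame(x = xy[, "x"], y = xy[, "y"],
               row = free[idx, 1], col = free[idx, 2])
  })
}

## polynomial feature expansion used by the parametric members
enm_features <- function(env, interactions = FALSE) {
  env <- as.matrix(env)
  if (is.null(colnames(env)))
    colnames(env) <- paste0("v", seq_len(ncol(env)))
  nm <- colnames(env)
  out <- cbind(env, env^2)
  colnames(out) <- c(nm, paste0(nm, "_sq"))
  if (interactions && ncol(env) > 1) {
    cmb <- utils::combn(seq_len(ncol(env)), 2)
    prods <- env[, cmb[1, ], drop = FALSE] * env[, cmb[2, ], drop = FALSE]
    colnames(prods) <- paste0(nm[cmb[1, ]], "_x_", nm[cmb[2, ]])
    out <- cbind(out, prods)
  }
  out
}

#' Percentile climatic envelope (BIOCLIM-style) member
#'
#' Suitability of a cell = fraction of variables whose value lies inside
#' the presence envelope, the [percentile, 1 - percentile] quantile range
#' of presence values for that variable.
#'
#' @param env_pres matrix of environmental values at presences.
#' @param env_bg ignored (kept for the common fitter signature).
#' @param percentile tail fraction trimmed per side (default 0.05).
#' @return object of class `enm_fit`.
#' @export
fit_envelope <- function(env_pres, env_bg = NULL, percentile = 0.05) {
  env_pres <- as.matrix(env_pres)
  lo <- apply(env_pres, 2, stats::quantile, probs = percentile,
              names = FALSE)
  hi <- apply(env_pres, 2, stats::quantile, probs = 1 - percentile,
              names = FALSE)
  structure(list(algorithm = "envelope", lo = lo, hi = hi),
            class = "enm_fit")
}

#' Quadratic logistic regression member
#'
#' Maximum-likelihood logistic regression of presence (1) versus
#' background (0) on linear and quadratic features; suitability is the
#' fitted probability.
#'
#' @param env_pres,env_bg environmental matrices for presences and
#'   background points.
#' @param interactions also include pairwise products (default FALSE).
#' @return object of class `enm_fit`.
#' @export
fit_logistic <- function(env_pres, env_bg, interactions = FALSE) {
  if (is.null(env_bg) || nrow(as.matrix(env_bg)) == 0)
    stop("background points are required (all-presence labels)")
  X <- enm_features(rbind(as.matrix(env_pres), as.matrix(env_bg)),
                    interactions = interactions)
  y <- c(rep(1, nrow(as.matrix(env_pres))), rep(0, nrow(as.matrix(env_bg))))
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  env_all <- rbind(as.matrix(env_pres), as.matrix(env_bg))
  structure(list(algorithm = "logistic", coef = fit$coefficients,
                 interactions = interactions,
                 clamp = apply(env_all, 2, range)),
            class = "enm_fit")
}

#' L1-regularized exponential-family member (Maxent-like)
#'
#' Lasso-penalized logistic regression of presence versus background on
#' linear, quadratic and pairwise-product features, in the spirit of
#' Maxent's regularized exponential model. The raw linear score is
#' affinely rescaled to [0, 1] over the training region (presence plus
#' background environments, a sample of the study area).
#'
#' @param env_pres,env_bg environmental matrices.
#' @param l1_penalty non-negative lasso penalty (glmnet lambda).
#' @param thresh glmnet convergence threshold.
#' @return object of class `enm_fit`.
#' @export
fit_maxent_like <- function(env_pres, env_bg, l1_penalty = 0.001,
                            thresh = 1e-9) {
  env_pres <- as.matrix(env_pres)
  if (nrow(env_pres) < 2)
    stop("need at least two presence points")
  if (l1_penalty < 0) stop("'l1_penalty' must be non-negative")
  X <- enm_features(rbind(env_pres, as.matrix(env_bg)),
                    interactions = TRUE)
  y <- c(rep(1, nrow(env_pres)), rep(0, nrow(as.matrix(env_bg))))
  ## warm-start path down to the requested penalty: a cold single-lambda
  ## fit often fails to converge
  path <- sort(unique(c(exp(seq(log(0.5), log(max(l1_penalty, 1e-5)),
                                length.out = 25)), l1_penalty)),
               decreasing = TRUE)
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = TRUE,
                        thresh = thresh, maxit = 1e6)
  at <- which.min(abs(fit$lambda - l1_penalty))
  beta <- as.numeric(fit$beta[, at])
  a0 <- as.numeric(fit$a0[at])
  score <- a0 + X %*% beta
  env_all <- rbind(env_pres, as.matrix(env_bg))
  structure(list(algorithm = "maxent_like", coef = c(a0, beta),
                 score_range = range(score),
                 clamp = apply(env_all, 2, range)),
            class = "enm_fit")
}

#' Predict suitability from a fitted member
#'
#' Predictors are clamped to the range seen during training before the
#' feature expansion (Maxent-style clamping), so quadratic responses do
#' not extrapolate when projecting onto novel (e.g. future) climates.
#'
#' @param object an `enm_fit`.
#' @param env matrix of environmental values (raw layer scale).
#' @param ... unused.
#' @return numeric suitability in [0, 1].
#' @export
predict.enm_fit <- function(object, env, ...) {
  env <- as.matrix(env)
  if (!is.null(object$clamp))
    for (j in seq_len(ncol(env)))
      env[, j] <- pmin(pmax(env[, j], object$clamp[1, j]),
                       object$clamp[2, j])
  switch(object$algorithm,
    envelope = {
      inside <- sweep(env, 2, object$lo, `>=`) &
        sweep(env, 2, object$hi, `<=`)
      rowMeans(inside)
    },
    logistic = {
      X <- cbind(1, enm_features(env, interactions = object$interactions))
      as.numeric(stats::plogis(X %*% object$coef))
    },
    maxent_like = {
      X <- cbind(1, enm_features(env, interactions = TRUE))
      s <- as.numeric(X %*% object$coef)
      rng <- object$score_range
      if (diff(rng) < 1e-12) rep(0.5, length(s))
      else pmin(pmax((s - rng[1]) / diff(rng), 0), 1)
    },
    stop("unknown algorithm"))
}

#' Rank-based AUC
#' @param pos,neg suitability scores of presences and background.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(pos, neg) {
  np <- length(pos); nb <- length(neg)
  if (np == 0 || nb == 0) stop("need both positive and negative scores")
  r <- rank(c(pos, neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' Maximized true skill statistic
#'
#' Scans 101 evenly spaced thresholds on [0, 1] and returns the maximum
#' of sensitivity + specificity - 1 and the threshold achieving it (the
#' lowest such threshold on ties).
#'
#' @param pos,neg suitability scores of presences and background.
#' @return list(tss, threshold, sensitivity, specificity).
#' @export
tss_max <- function(pos, neg) {
  thr <- seq(0, 1, length.out = 101)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  tss <- sens + spec - 1
  i <- which.max(tss)
  list(tss = tss[i], threshold = thr[i], sensitivity = sens[i],
       specificity = spec[i])
}

#' Cross-validate an ENM member algorithm
#'
#' Random presence/background splits (default 70/30); the member is
#' fitted on the training portion and evaluated (rank AUC, maximized
#' TSS) on the held-out portion. Replicates default to 10, or 5 when
#' there are fewer than 50 presences.
#'
#' @param fitter function(env_pres, env_bg) returning an `enm_fit`.
#' @param env_pres,env_bg environmental matrices.
#' @param n_replicates number of replicates; default NULL = 10 (5 when
#'   presences < 50).
#' @param train_fraction training share (default 0.7).
#' @param seed integer seed.
#' @return list of replicates, each with elements fit, auc, tss,
#'   threshold, and the held-out environments (eval_pres, eval_bg).
#' @export
cross_validate <- function(fitter, env_pres, env_bg, n_replicates = NULL,
                           train_fraction = 0.7, seed = 1) {
  env_pres <- as.matrix(env_pres); env_bg <- as.matrix(env_bg)
  np <- nrow(env_pres); nb <- nrow(env_bg)
  if (is.null(n_replicates)) n_replicates <- if (np < 50) 5L else 10L
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      tr_p <- sample.int(np, max(2, floor(train_fraction * np)))
      tr_b <- sample.int(nb, max(2, floor(train_fraction * nb)))
      te_p <- setdiff(seq_len(np), tr_p)
      te_b <- setdiff(seq_len(nb), tr_b)
      fit <- fitter(env_pres[tr_p, , drop = FALSE],
                    env_bg[tr_b, , drop = FALSE])
      sp <- predict(fit, env_pres[te_p, , drop = FALSE])
      sb <- predict(fit, env_bg[te_b, , drop = FALSE])
      ev <- tss_max(sp, sb)
      list(fit = fit, replicate = rep_i, auc = auc_rank(sp, sb),
           tss = ev$tss, threshold = ev$threshold,
           eval_pres = env_pres[te_p, , drop = FALSE],
           eval_bg = env_bg[te_b, , drop = FALSE])
    })
  })
}

#' Build a TSS-weighted ensemble from cross-validated members
#'
#' Members with held-out TSS at or above `tss_cutoff` are included with
#' weights proportional to TSS. Ensemble suitability is the weighted mean
#' of member predictions, affinely rescaled to [0, 1] using the range
#' observed on the pooled held-out evaluation data; the binarization
#' threshold is the TSS-maximizing threshold of that rescaled ensemble
#' suitability on the pooled evaluation data.
#'
#' @param members flat list of cross-validation replicates, possibly
#'   concatenated across algorithms (see [cross_validate()]).
#' @param tss_cutoff inclusion cutoff (default 0.4).
#' @return object of class `ensemble_model` with elements fits, weights,
#'   tss, threshold, rescale, evaluation (pooled AUC/TSS).
#' @export
build_ensemble <- function(members, tss_cutoff = 0.4) {
  tss <- vapply(members, `[[`, numeric(1), "tss")
  keep <- which(tss >= tss_cutoff)
  if (length(keep) == 0)
    stop(sprintf("no member reaches TSS >= %.2f (best member TSS = %.3f)",
                 tss_cutoff, max(tss)))
  w <- tss[keep] / sum(tss[keep])
  fits <- lapply(members[keep], `[[`, "fit")
  ens <- structure(list(fits = fits, weights = w, tss = tss[keep],
                        threshold = NA_real_, rescale = NULL),
                   class = "ensemble_model")
  ## pooled held-out evaluation of the ensemble itself
  ep <- do.call(rbind, lapply(members[keep], `[[`, "eval_pres"))
  eb <- do.call(rbind, lapply(members[keep], `[[`, "eval_bg"))
  raw_p <- ensemble_raw(ens, ep)
  raw_b <- ensemble_raw(ens, eb)
  rng <- range(c(raw_p, raw_b))
  if (diff(rng) < 1e-12) rng <- c(rng[1] - 0.5, rng[1] + 0.5)
  ens$rescale <- rng
  sp <- (raw_p - rng[1]) / diff(rng)
  sb <- (raw_b - rng[1]) / diff(rng)
  ev <- tss_max(sp, sb)
  ens$threshold <- ev$threshold
  ens$evaluation <- list(auc = auc_rank(sp, sb), tss = ev$tss)
  ens
}

## weighted-mean member suitability, before rescaling
ensemble_raw <- function(ens, env) {
  s <- 0
  for (i in seq_along(ens$fits))
    s <- s + ens$weights[i] * predict(ens$fits[[i]], env)
  s
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("ensemble_model: %d members, TSS %.3f-%.3f, threshold %.2f\n",
              length(x$fits), min(x$tss), max(x$tss), x$threshold))
  cat(sprintf("  pooled evaluation: AUC %.3f, TSS %.3f\n",
              x$evaluation$auc, x$evaluation$tss))
  invisible(x)
}

#' Ensemble suitability at arbitrary environments
#' @param object an ensemble_model.
#' @param env environmental matrix.
#' @param ... unused.
#' @return suitability in [0, 1].
#' @export
predict.ensemble_model <- function(object, env, ...) {
  raw <- ensemble_raw(object, env)
  pmin(pmax((raw - object$rescale[1]) / diff(object$rescale), 0), 1)
}

#' Predict an ensemble over a raster stack
#' @param ens ensemble_model.
#' @param stack raster_stack of the layers the members were fitted on.
#' @return list(continuous, binary): single-layer raster_stacks; binary
#'   = suitability >= the ensemble threshold.
#' @export
predict_raster <- function(ens, stack) {
  ok <- valid_mask(stack)
  env <- sapply(names(stack$layers),
                function(nm) stack$layers[[nm]][ok])
  suit <- matrix(NA_real_, stack$nrow, stack$ncol)
  suit[ok] <- predict(ens, env)
  cont <- raster_stack(list(suitability = suit), xll = stack$xll,
                       yll = stack$yll, cellsize = stack$cellsize,
                       nodata = stack$nodata)
  bin <- suit
  bin[ok] <- as.numeric(suit[ok] >= ens$threshold)
  binary <- raster_stack(list(range = bin), xll = stack$xll,
                         yll = stack$yll, cellsize = stack$cellsize,
                         nodata = stack$nodata)
  list(continuous = cont, binary = binary)
}

#' Project an ensemble onto future climate scenarios
#'
#' Predicts continuous suitability on each pseudo-GCM future stack,
#' averages per cell (unweighted mean across stacks), and binarizes with
#' the present-day ensemble threshold.
#'
#' @param ens ensemble_model.
#' @param future_stacks a raster_stack or list of co-registered
#'   raster_stacks (one per GCM).
#' @return list(continuous, binary) raster_stacks.
#' @export
project_ensemble <- function(ens, future_stacks) {
  if (inherits(future_stacks, "raster_stack"))
    future_stacks <- list(future_stacks)
  base <- future_stacks[[1]]
  acc <- matrix(0, base$nrow, base$ncol)
  for (s in future_stacks) {
    stopifnot_same_geometry(base, s)
    acc <- acc + predict_raster(ens, s)$continuous$layers$suitability
  }
  suit <- acc / length(future_stacks)
  ok <- !is.na(suit)
  bin <- suit
  bin[ok] <- as.numeric(suit[ok] >= ens$threshold)
  geom <- function(m, nm) raster_stack(stats::setNames(list(m), nm),
                                       xll = base$xll, yll = base$yll,
                                       cellsize = base$cellsize,
                                       nodata = base$nodata)
  list(continuous = geom(suit, "suitability"), binary = geom(bin, "range"))
}

## coerce a binary range argument (raster_stack or matrix) to a 0/1 matrix
as_binary_matrix <- function(x) {
  if (inherits(x, "raster_stack")) x <- x$layers[[1]]
  if (is.list(x) && !is.null(x$binary)) x <- x$binary$layers[[1]]
  x
}

#' Percent suitable area and range change
#'
#' Percent suitable = 100 x suitable cells / mask cells, for present and
#' future binary ranges; percent range change = 100 x (future% -
#' present%) / present%.
#'
#' @param present_binary,future_binary binary rasters (raster_stack,
#'   matrix, or a [predict_raster()] result).
#' @param mask optional 0/1 raster or logical matrix restricting the
#'   reporting region (e.g. a peninsula); default: all cells with data.
#' @return list(percent_present, percent_future, percent_change).
#' @export
range_change <- function(present_binary, future_binary, mask = NULL) {
  p <- as_binary_matrix(present_binary)
  f <- as_binary_matrix(future_binary)
  if (!all(dim(p) == dim(f))) stop("binary rasters are not co-registered")
  m <- if (is.null(mask)) !is.na(p) else {
    mm <- as_binary_matrix(mask)
    !is.na(mm) & mm > 0
  }
  if (!any(m)) stop("empty mask")
  pct_p <- 100 * sum(p[m] > 0, na.rm = TRUE) / sum(m)
  pct_f <- 100 * sum(f[m] > 0, na.rm = TRUE) / sum(m)
  chg <- if (pct_p > 0) 100 * (pct_f - pct_p) / pct_p else NA_real_
  list(percent_present = pct_p, percent_future = pct_f,
       percent_change = chg)
}

#' Cellwise union of two binary ranges
#' @param binary_a,binary_b binary rasters (raster_stack or matrix).
#' @return matrix 0/1 (NA preserved where both NA).
#' @export
combine_ranges <- function(binary_a, binary_b) {
  a <- as_binary_matrix(binary_a); b <- as_binary_matrix(binary_b)
  if (!all(dim(a) == dim(b))) stop("binary rasters are not co-registered")
  out <- pmax(a, b, na.rm = TRUE)
  out[is.na(a) & is.na(b)] <- NA_real_
  out
}

#' Percent of the mask where two ranges overlap
#' @param binary_a,binary_b binary rasters.
#' @param mask optional mask (default all data cells).
#' @return percent of mask cells suitable in both.
#' @export
range_overlap <- function(binary_a, binary_b, mask = NULL) {
  a <- as_binary_matrix(binary_a); b <- as_binary_matrix(binary_b)
  m <- if (is.null(mask)) !is.na(a) else {
    mm <- as_binary_matrix(mask); !is.na(mm) & mm > 0
  }
  100 * sum(a[m] > 0 & b[m] > 0, na.rm = TRUE) / sum(m)
}

#' Percent reduction of a projected loss (or overlap)
#'
#' `100 * (1 - adaptive / full)`: how much smaller a quantity (projected
#' range loss, overlap area) becomes when adaptive groups are modelled
#' separately.
#'
#' @param full,adaptive the two non-negative quantities.
#' @return percent reduction.
#' @export
percent_reduction <- function(full, adaptive) 100 * (1 - adaptive / full)

#' Schoener's D niche overlap between two suitability surfaces
#'
#' Each surface is normalized to sum to one over the shared valid cells;
#' D = 1 - 0.5 * sum |p_a - p_b|, ranging from 0 (disjoint) to 1
#' (identical).
#'
#' @param suit_a,suit_b non-negative suitability rasters (raster_stack
#'   or matrix) on a common grid.
#' @return D in [0, 1].
#' @export
schoener_d <- function(suit_a, suit_b) {
  a <- as_binary_matrix(suit_a); b <- as_binary_matrix(suit_b)
  if (!all(dim(a) == dim(b))) stop("surfaces are not co-registered")
  ok <- !is.na(a) & !is.na(b)
  av <- a[ok]; bv <- b[ok]
  if (any(av < 0) || any(bv < 0)) stop("suitabilities must be non-negative")
  if (sum(av) <= 0 || sum(bv) <= 0) stop("all-zero suitability surface")
  1 - 0.5 * sum(abs(av / sum(av) - bv / sum(bv)))
}

#' Null-model test of ENM discrimination
#'
#' Repeatedly samples random presence sets of the observed size from the
#' valid cells, runs the same fit/evaluate pipeline (single 70/30
#' split), and records held-out AUC. The observed model performs better
#' than random when its AUC exceeds the null maximum (rank test,
#' p = 1 / (n_null + 1)).
#'
#' @param stack raster_stack of predictors.
#' @param n_presences size of the random presence sets.
#' @param observed_auc AUC of the observed model (optional; verdict is NA
#'   without it).
#' @param n_null number of null datasets (default 99).
#' @param seed integer seed.
#' @param fitter member fitting function (default [fit_envelope()]).
#' @param n_background background size for the null fits.
#' @return list(null_aucs, null_range, observed_auc, significant, p).
#' @export
null_model_test <- function(stack, n_presences, observed_auc = NA,
                            n_null = 99, seed = 1, fitter = fit_envelope,
                            n_background = 1000) {
  if (n_null < 1) stop("'n_null' must be at least 1")
  ok <- valid_mask(stack)
  cells <- which(ok, arr.ind = TRUE)
  n_background <- min(n_background, nrow(cells) - n_presences)
  aucs <- with_seed(seed, vapply(seq_len(n_null), function(i) {
    idx <- sample.int(nrow(cells), n_presences)
    xy <- cell_to_xy(stack, cells[idx, 1], cells[idx, 2])
    envp <- extract_env(stack, xy[, "x"], xy[, "y"])
    bg <- sample_background(stack, n_background,
                            seed = sample.int(2^30, 1),
                            exclusion = data.frame(x = xy[, "x"],
                                                   y = xy[, "y"]))
    envb <- extract_env(stack, bg$x, bg$y)
    cv <- cross_validate(fitter, envp, envb, n_replicates = 1,
                         seed = sample.int(2^30, 1))
    cv[[1]]$auc
  }, numeric(1)))
  list(null_aucs = aucs, null_range = range(aucs),
       observed_auc = observed_auc,
       significant = if (is.na(observed_auc)) NA
                     else observed_auc > max(aucs),
       p = 1 / (n_null + 1))
}

#' Niche-identity permutation test on Schoener's D
#'
#' Pools the two occurrence sets, repeatedly reassigns labels at random
#' (preserving group sizes), refits both suitability surfaces with the
#' same fitter, and recomputes D. The one-sided p-value is the
#' probability of a null D at or below the observed D (lower overlap
#' than random).
#'
#' @param occ_a,occ_b occurrence points of the two groups (data.frame
#'   x, y or occurrence_set).
#' @param stack raster_stack of predictors.
#' @param n_perm number of permutations (default 99).
#' @param seed integer seed.
#' @param fitter member fitting function (default [fit_envelope()]).
#' @param n_background shared background size.
#' @return list(d_observed, d_null, p_lower).
#' @export
niche_similarity_test <- function(occ_a, occ_b, stack, n_perm = 99,
                                  seed = 1, fitter = fit_envelope,
                                  n_background = 1000) {
  if (n_perm < 1) stop("'n_perm' must be at least 1")
  a <- clean_occurrences(stack, occ_a)
  b <- clean_occurrences(stack, occ_b)
  pooled <- rbind(a, b)
  na <- nrow(a)
  bg <- sample_background(stack, min(n_background,
                                     sum(valid_mask(stack)) - nrow(pooled)),
                          seed = seed, exclusion = pooled)
  env_bg <- extract_env(stack, bg$x, bg$y)
  surf <- function(pts) {
    envp <- extract_env(stack, pts$x, pts$y)
    fit <- fitter(envp, env_bg)
    predict_raster_fit(fit, stack)
  }
  d_obs <- schoener_d(surf(a), surf(b))
  d_null <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(nrow(pooled), na)
    schoener_d(surf(pooled[idx, , drop = FALSE]),
               surf(pooled[-idx, , drop = FALSE]))
  }, numeric(1)))
  list(d_observed = d_obs, d_null = d_null,
       p_lower = (1 + sum(d_null <= d_obs)) / (n_perm + 1))
}

## predict a single member fit over a stack (continuous suitability)
predict_raster_fit <- function(fit, stack) {
  ok <- valid_mask(stack)
  env <- sapply(names(stack$layers), function(nm) stack$layers[[nm]][ok])
  suit <- matrix(NA_real_, stack$nrow, stack$ncol)
  suit[ok] <- predict(fit, env)
  suit
}

#' Fit a cross-validated ensemble niche model from occurrences
#'
#' Convenience wrapper: cleans occurrences, samples background,
#' cross-validates each requested member algorithm, and builds the
#' TSS-weighted ensemble.
#'
#' @param stack raster_stack of (decorrelated) predictors.
#' @param occurrences presence points (data.frame x, y or
#'   occurrence_set).
#' @param algorithms subset of c("envelope", "logistic", "maxent").
#' @param n_background background size (default min(10000, free cells)).
#' @param tss_cutoff ensemble inclusion cutoff.
#' @param n_replicates cross-validation replicates per algorithm
#'   (default: 10, or 5 when presences < 50).
#' @param seed integer seed.
#' @return ensemble_model; the cleaned presences are attached as
#'   attribute `presences` and member replicates as attribute `members`.
#' @export
fit_enm <- function(stack, occurrences,
                    algorithms = c("envelope", "logistic", "maxent"),
                    n_background = NULL, tss_cutoff = 0.4,
                    n_replicates = NULL, seed = 1) {
  occ <- clean_occurrences(stack, occurrences)
  if (nrow(occ) < 5) stop("fewer than 5 usable presence cells")
  free <- sum(valid_mask(stack)) - nrow(occ)
  if (is.null(n_background)) n_background <- min(10000, free)
  bg <- sample_background(stack, n_background, seed = seed,
                          exclusion = occ)
  envp <- extract_env(stack, occ$x, occ$y)
  envb <- extract_env(stack, bg$x, bg$y)
  fitters <- list(
    envelope = function(p, b) fit_envelope(p, b),
    logistic = function(p, b) fit_logistic(p, b),
    maxent = function(p, b) fit_maxent_like(p, b))
  members <- list()
  for (i in seq_along(algorithms)) {
    alg <- algorithms[i]
    members <- c(members,
                 cross_validate(fitters[[alg]], envp, envb,
                                n_replicates = n_replicates,
                                seed = seed + i))
  }
  ens <- build_ensemble(members, tss_cutoff = tss_cutoff)
  attr(ens, "presences") <- occ
  attr(ens, "members") <- members
  ens
}
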