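#' Redundancy analysis of genotypes on climate predictors
#'
#' Constrained ordination: the centered genotype matrix Y is projected
#' onto the column space of the standardized climate predictors X, and
#' the fitted matrix is decomposed by SVD. SNP loadings are the right
#' singular vectors scaled by singular value / sqrt(n - 1); site scores
#' are the projections of Y (weighted-average scores) and of the fitted
#' matrix (linear-combination scores) onto the constrained axes;
#' predictor biplot scores are correlations between predictors and the
#' linear-combination site scores.
#'
#' @param gm a complete (imputed) [genotype_matrix()].
#' @param X data.frame or matrix of climate predictors, one row per
#'   individual; standardized internally.
#' @param scale_genotypes scale loci to unit variance before the fit
#'   (default FALSE: centered only, so loadings stay comparable across
#'   loci of similar frequency).
#' @return object of class `rda_gea` with elements loadings, site_lc,
#'   site_wa, biplot, singular_values, prop_constrained, prop_per_axis.
#' @export
fit_rda <- function(gm, X, scale_genotypes = FALSE) {
  Y <- gm$values
  if (anyNA(Y)) stop("genotype matrix must be complete; run impute_missing()")
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(Y)
  if (nrow(X) != n) stop("X must have one row per individual")
  if (n <= ncol(X)) stop("need more individuals than predictors")
  Xs <- scale(X)
  qrX <- qr(Xs)
  if (qrX$rank < ncol(Xs)) {
    bad <- colnames(Xs)[-seq_len(qrX$rank)]
    stop("collinear predictors: ", paste(bad, collapse = ", "))
  }
  Yc <- scale(Y, center = TRUE, scale = scale_genotypes)
  Yc[is.nan(Yc)] <- 0  # zero-variance loci when scaling
  Yhat <- qr.fitted(qrX, Yc)
  k <- min(qrX$rank, n - 1, ncol(Yc))
  sv <- svd(Yhat, nu = k, nv = k)
  d <- sv$d[seq_len(k)]
  pos <- d > max(d[1], 0) * 1e-10
  k <- max(sum(pos), 1L)
  u <- sv$u[, seq_len(k), drop = FALSE]
  v <- sv$v[, seq_len(k), drop = FALSE]
  d <- d[seq_len(k)]
  axis_names <- paste0("RDA", seq_len(k))
  loadings <- sweep(v, 2, d / sqrt(n - 1), `*`)
  dimnames(loadings) <- list(gm$locus_ids, axis_names)
  site_lc <- u %*% diag(d, k)
  site_wa <- Yc %*% v
  dimnames(site_lc) <- dimnames(site_wa) <-
    list(gm$sample_ids, axis_names)
  biplot <- stats::cor(Xs, site_lc)
  total_ss <- sum(Yc^2)
  structure(list(loadings = loadings, site_lc = site_lc,
                 site_wa = site_wa, biplot = biplot,
                 singular_values = d,
                 prop_constrained = sum(d^2) / total_ss,
                 prop_per_axis = d^2 / total_ss,
                 n = n, predictors = colnames(Xs)),
            class = "rda_gea")
}

#' @export
print.rda_gea <- function(x, ...) {
  cat(sprintf("rda_gea: %d constrained axes over %d loci, %d sites\n",
              length(x$singular_values), nrow(x$loadings), x$n))
  cat(sprintf("  constrained variance fraction: %.3f\n",
              x$prop_constrained))
  invisible(x)
}

#' Flag loci with extreme ordination loadings
#'
#' A locus is an outlier on an axis when its loading lies more than
#' `sd_threshold` standard deviations from the mean loading of that axis.
#'
#' @param loadings numeric vector of loadings for one axis.
#' @param sd_threshold positive threshold in SD units (default 3).
#' @return logical vector.
#' @export
flag_loading_outliers <- function(loadings, sd_threshold = 3) {
  if (sd_threshold <= 0) stop("'sd_threshold' must be positive")
  abs(loadings - mean(loadings)) > sd_threshold * stats::sd(loadings)
}

#' Candidate adaptive loci from RDA loadings
#'
#' Flags loci whose loading on any retained constrained axis exceeds
#' `sd_threshold` SDs from the axis mean, then assigns each candidate to
#' the climate variable with the largest absolute genotype-variable
#' correlation; the direction of association is the sign of that
#' correlation.
#'
#' @param model an [fit_rda()] result.
#' @param gm the (complete) genotype matrix the model was fitted to.
#' @param X the climate predictors used in the fit.
#' @param n_axes number of leading axes to scan (default: all).
#' @param sd_threshold outlier threshold in SD units (default 3).
#' @return a `candidate_set`: data.frame with columns locus_id, method,
#'   variable, direction, statistic (max |loading| in SD units).
#' @export
rda_outliers <- function(model, gm, X, n_axes = NULL, sd_threshold = 3) {
  stopifnot(inherits(model, "rda_gea"))
  k <- ncol(model$loadings)
  if (is.null(n_axes)) n_axes <- k
  if (n_axes > k) stop("'n_axes' exceeds available constrained axes")
  flagged <- rep(FALSE, nrow(model$loadings))
  zmax <- rep(0, nrow(model$loadings))
  for (a in seq_len(n_axes)) {
    l <- model$loadings[, a]
    z <- abs(l - mean(l)) / stats::sd(l)
    flagged <- flagged | flag_loading_outliers(l, sd_threshold)
    zmax <- pmax(zmax, z)
  }
  candidate_set(assign_variable(gm, X, which(flagged)),
                method = "rda", statistic = zmax[flagged])
}

## per-candidate climate-variable assignment by largest |correlation|
assign_variable <- function(gm, X, idx) {
  X <- as.matrix(X)
  if (length(idx) == 0)
    return(data.frame(locus_id = character(0), variable = character(0),
                      direction = numeric(0), stringsAsFactors = FALSE))
  r <- stats::cor(gm$values[, idx, drop = FALSE], X)
  r[is.na(r)] <- 0
  best <- apply(abs(r), 1, which.max)
  data.frame(locus_id = gm$locus_ids[idx],
             variable = colnames(X)[best],
             direction = sign(r[cbind(seq_along(idx), best)]),
             stringsAsFactors = FALSE)
}

candidate_set <- function(df, method, statistic = NA_real_) {
  if (nrow(df) == 0) {
    statistic <- numeric(0)
    method <- character(0)
  }
  out <- data.frame(locus_id = df$locus_id, method = method,
                    variable = df$variable, direction = df$direction,
                    statistic = statistic, stringsAsFactors = FALSE)
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d loci (method: %s)\n", nrow(x),
              paste(unique(x$method), collapse = "+")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  invisible(x)
}

#' Latent-factor association scan of genotypes on climate
#'
#' A transparent latent-factor mixed-model analogue: unobserved structure
#' is estimated as the first K principal components of the centered
#' genotype matrix after regressing out the climate predictors; each
#' locus is then regressed on each climate variable plus the K factors.
#' Z-scores are calibrated by genomic control (lambda = median(z^2) /
#' 0.4549) and calibrated p-values converted to q-values by
#' Benjamini-Hochberg within each climate variable.
#'
#' @param gm a complete genotype_matrix.
#' @param X climate predictors (data.frame or matrix), one row per
#'   individual.
#' @param K number of latent factors, `0 <= K < n - p - 2`.
#' @return object of class `latent_assoc`: list with per-variable
#'   data.frames (locus_id, effect, se, z, p_raw, p_calibrated, q),
#'   lambda per variable, K, and the factor matrix.
#' @export
fit_latent_association <- function(gm, X, K) {
  Y <- gm$values
  if (anyNA(Y)) stop("genotype matrix must be complete; run impute_missing()")
  X <- as.matrix(X); storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(Y); p <- ncol(X)
  if (K < 0 || K >= n - p - 2) stop("'K' out of range")
  Xs <- scale(X)
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  U <- NULL
  if (K > 0) {
    R <- Yc - qr.fitted(qr(Xs), Yc)
    sv <- svd(R, nu = K, nv = 0)
    U <- sv$u
  }
  res <- list(); lambda <- numeric(p)
  zero_var <- apply(Y, 2, stats::var) == 0
  for (j in seq_len(p)) {
    M <- cbind(1, Xs[, j], U)
    H <- chol2inv(chol(crossprod(M)))
    B <- H %*% crossprod(M, Yc)
    rss <- colSums((Yc - M %*% B)^2)
    df <- n - ncol(M)
    se <- sqrt(pmax(rss / df, 0) * H[2, 2])
    z <- as.numeric(B[2, ]) / se
    z[!is.finite(z)] <- 0
    z[zero_var] <- 0
    lam <- stats::median(z^2) / stats::qchisq(0.5, df = 1)
    lam <- max(lam, 1e-8)
    p_raw <- stats::pchisq(z^2, df = 1, lower.tail = FALSE)
    p_cal <- stats::pchisq(z^2 / lam, df = 1, lower.tail = FALSE)
    p_raw[zero_var] <- 1; p_cal[zero_var] <- 1
    q <- stats::p.adjust(p_cal, method = "BH")
    lambda[j] <- lam
    res[[colnames(Xs)[j]]] <- data.frame(
      locus_id = gm$locus_ids, effect = as.numeric(B[2, ]), se = se,
      z = z, p_raw = p_raw, p_calibrated = p_cal, q = q,
      zero_variance = zero_var, stringsAsFactors = FALSE)
  }
  names(lambda) <- colnames(Xs)
  structure(list(tests = res, lambda = lambda, K = K, factors = U),
            class = "latent_assoc")
}

#' @export
print.latent_assoc <- function(x, ...) {
  cat(sprintf("latent_assoc: K = %d factors, %d loci\n", x$K,
              nrow(x$tests[[1]])))
  cat("  genomic inflation lambda:",
      paste(sprintf("%s = %.3f", names(x$lambda), x$lambda),
            collapse = ", "), "\n")
  invisible(x)
}

#' Candidate loci from the latent-factor scan
#'
#' A locus is a candidate when its q-value falls below `q_threshold` for
#' any climate variable; it is assigned to the variable with the smallest
#' q, with direction = sign of the effect there.
#'
#' @param result a [fit_latent_association()] result.
#' @param q_threshold false-discovery-rate level (default 0.05).
#' @return a `candidate_set`.
#' @export
latent_candidates <- function(result, q_threshold = 0.05) {
  stopifnot(inherits(result, "latent_assoc"))
  qs <- sapply(result$tests, function(d) d$q)
  if (is.null(dim(qs))) qs <- matrix(qs, nrow = 1)
  sig <- which(apply(qs, 1, min) < q_threshold)
  if (length(sig) == 0)
    return(candidate_set(data.frame(locus_id = character(0),
                                    variable = character(0),
                                    direction = numeric(0)),
                         method = "latent"))
  best <- apply(qs[sig, , drop = FALSE], 1, which.min)
  vars <- names(result$tests)[best]
  eff <- mapply(function(i, v) result$tests[[v]]$effect[i], sig, vars)
  zst <- mapply(function(i, v) abs(result$tests[[v]]$z[i]), sig, vars)
  candidate_set(data.frame(
    locus_id = result$tests[[1]]$locus_id[sig], variable = vars,
    direction = sign(eff), stringsAsFactors = FALSE),
    method = "latent", statistic = zst)
}

#' Choose the number of latent factors from the eigenvalue scree
#'
#' Takes the principal-component eigenvalues of the centered genotype
#' matrix and returns the position of the largest consecutive drop ratio
#' (the scree elbow), capped at `k_max`. When no ratio exceeds
#' `ratio_min` the matrix is treated as unstructured and 0 is returned.
#'
#' @param gm a complete genotype_matrix.
#' @param k_max upper bound on K.
#' @param ratio_min minimum eigenvalue drop ratio regarded as structure
#'   (default 1.3).
#' @return integer K, `0 <= K <= k_max`; deterministic.
#' @export
select_K <- function(gm, k_max = 10, ratio_min = 1.3) {
  Y <- gm$values
  if (anyNA(Y)) stop("genotype matrix must be complete")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  d <- svd(Yc, nu = 0, nv = 0)$d
  kk <- min(k_max, length(d) - 1)
  if (kk < 1) return(0L)
  ratios <- d[seq_len(kk)]^2 / d[seq_len(kk) + 1]^2
  if (max(ratios) < ratio_min) return(0L)
  as.integer(which.max(ratios))
}

#' Conservative intersection of two candidate sets
#'
#' Keeps only loci flagged by both methods (each method's set having
#' already been unioned over the climate variables); the assigned
#' variable and direction are taken from the first set and the evidence
#' of both methods is recorded.
#'
#' @param rda_set,latent_set `candidate_set` objects.
#' @return a `candidate_set` with method `"rda+latent"`.
#' @export
intersect_candidates <- function(rda_set, latent_set) {
  common <- intersect(rda_set$locus_id, latent_set$locus_id)
  a <- rda_set[match(common, rda_set$locus_id), , drop = FALSE]
  out <- candidate_set(data.frame(locus_id = common,
                                  variable = a$variable,
                                  direction = a$direction,
                                  stringsAsFactors = FALSE),
                       method = "rda+latent", statistic = a$statistic)
  out
}

#' Write a candidate set as CSV
#' @param cs candidate_set.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_candidates <- function(cs, path) {
  utils::write.csv(as.data.frame(cs), path, row.names = FALSE)
  invisible(path)
}
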