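#' Reclassify a landscape layer to a resistance cost surface
#'
#' Maps layer values to movement costs in [1, 100] (1 = no resistance,
#' 100 = strong barrier) using a breakpoint table, either piecewise
#' constant (cost of the interval's lower breakpoint) or linearly
#' interpolated between breakpoints. Nodata propagates.
#'
#' @param layer numeric matrix or single-layer raster_stack.
#' @param table data.frame with columns `value` (breakpoints, increasing)
#'   and `cost` (each in [1, 100]).
#' @param interpolate linear interpolation between breakpoints (default
#'   FALSE = piecewise constant).
#' @return cost surface of the same form as `layer` (matrix in, matrix
#'   out; stack in, single-layer stack named "cost" out).
#' @export
reclassify_to_resistance <- function(layer, table, interpolate = FALSE) {
  stk <- NULL
  if (inherits(layer, "raster_stack")) {
    stk <- layer; layer <- layer$layers[[1]]
  }
  if (!all(c("value", "cost") %in% names(table)))
    stop("'table' needs columns value and cost")
  if (is.unsorted(table$value, strictly = TRUE))
    stop("breakpoints must be strictly increasing")
  if (any(table$cost < 1 | table$cost > 100))
    stop("costs must lie in [1, 100]")
  v <- as.vector(layer)
  out <- rep(NA_real_, length(v))
  ok <- !is.na(v)
  if (interpolate) {
    out[ok] <- stats::approx(table$value, table$cost, xout = v[ok],
                             rule = 2)$y
  } else {
    idx <- pmax(findInterval(v[ok], table$value), 1L)
    out[ok] <- table$cost[idx]
  }
  m <- matrix(out, nrow(layer), ncol(layer))
  if (is.null(stk)) return(m)
  raster_stack(list(cost = m), xll = stk$xll, yll = stk$yll,
               cellsize = stk$cellsize, nodata = stk$nodata)
}

#' Combine resistance surfaces
#'
#' Cellwise combination of several cost surfaces. The mean of surfaces
#' already in [1, 100] needs no rescaling; `sum_rescaled` and
#' `product_rescaled` affinely rescale the result back to [1, 100]
#' (a constant result maps to the midpoint 50.5).
#'
#' @param surfaces list of cost matrices (or single-layer stacks) on one
#'   grid.
#' @param method one of "mean", "sum_rescaled", "product_rescaled".
#' @return cost matrix in [1, 100].
#' @export
combine_surfaces <- function(surfaces,
                             method = c("mean", "sum_rescaled",
                                        "product_rescaled")) {
  method <- match.arg(method)
  mats <- lapply(surfaces, function(s)
    if (inherits(s, "raster_stack")) s$layers[[1]] else s)
  d <- dim(mats[[1]])
  if (any(!vapply(mats, function(m) all(dim(m) == d), logical(1))))
    stop("surfaces are not co-registered")
  acc <- switch(method,
    mean = Reduce(`+`, mats) / length(mats),
    sum_rescaled = Reduce(`+`, mats),
    product_rescaled = Reduce(`*`, mats))
  if (method != "mean") {
    ok <- !is.na(acc)
    rng <- range(acc[ok])
    acc[ok] <- if (diff(rng) < 1e-12) 50.5
               else 1 + 99 * (acc[ok] - rng[1]) / diff(rng)
  }
  acc
}

#' Build a conductance graph from a resistance surface
#'
#' One node per valid (non-nodata) cell; edges connect 4- or
#' 8-neighbours with conductance equal to the mean of the two cells'
#' conductances (1 / cost), diagonal edges divided by sqrt(2) to correct
#' for length.
#'
#' @param surface cost matrix or single-layer raster_stack, costs >= 1
#'   on valid cells.
#' @param connectivity 8 (default) or 4.
#' @return object of class `raster_graph`: list with nodes (row, col),
#'   edges (from, to, conductance), node index matrix, and dims.
#' @export
build_graph <- function(surface, connectivity = 8) {
  if (inherits(surface, "raster_stack")) {
    geom <- surface[c("xll", "yll", "cellsize")]
    surface <- surface$layers[[1]]
  } else geom <- list(xll = 0, yll = 0, cellsize = 1)
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  ok <- !is.na(surface)
  if (any(surface[ok] <= 0)) stop("costs must be positive")
  idx <- matrix(NA_integer_, nrow(surface), ncol(surface))
  idx[ok] <- seq_len(sum(ok))
  nodes <- which(ok, arr.ind = TRUE)
  cond <- matrix(NA_real_, nrow(surface), ncol(surface))
  cond[ok] <- 1 / surface[ok]
  nr <- nrow(surface); nc <- ncol(surface)
  offs <- list(c(0, 1), c(1, 0))
  if (connectivity == 8) offs <- c(offs, list(c(1, 1), c(1, -1)))
  from <- integer(0); to <- integer(0); g <- numeric(0)
  for (o in offs) {
    r1 <- seq_len(nr - abs(o[1]) * (o[1] != 0)) ; # rows with neighbour
    rows <- if (o[1] == 0) seq_len(nr) else seq_len(nr - 1)
    cols <- if (o[2] == 1) seq_len(nc - 1)
            else if (o[2] == -1) seq(2, nc) else seq_len(nc)
    A <- as.matrix(expand.grid(row = rows, col = cols))
    B <- cbind(A[, 1] + o[1], A[, 2] + o[2])
    ia <- idx[A]; ib <- idx[B]
    good <- !is.na(ia) & !is.na(ib)
    if (!any(good)) next
    cc <- (cond[A][good] + cond[B][good]) / 2
    if (all(o != 0)) cc <- cc / sqrt(2)  # diagonal length correction
    from <- c(from, ia[good]); to <- c(to, ib[good]); g <- c(g, cc)
  }
  structure(list(nodes = nodes, edges = data.frame(from = from, to = to,
                                                   conductance = g),
                 index = idx, dims = c(nr, nc), geometry = geom),
            class = "raster_graph")
}

#' @export
print.raster_graph <- function(x, ...) {
  cat(sprintf("raster_graph: %d nodes, %d edges on a %d x %d grid\n",
              nrow(x$nodes), nrow(x$edges), x$dims[1], x$dims[2]))
  invisible(x)
}

## sparse graph Laplacian
graph_laplacian <- function(graph) {
  n <- nrow(graph$nodes)
  e <- graph$edges
  W <- Matrix::sparseMatrix(i = c(e$from, e$to), j = c(e$to, e$from),
                            x = c(e$conductance, e$conductance),
                            dims = c(n, n))
  Matrix::Diagonal(n, Matrix::rowSums(W)) - W
}

## connected component id per node
graph_components <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = seq_len(nrow(graph$nodes))))
  comp <- igraph::components(g)$membership
  comp[order(as.integer(names(comp)))]
}

## map focal specifications (node ids, or row/col matrix) to node ids
focal_node_ids <- function(graph, focal) {
  if (is.matrix(focal) || is.data.frame(focal)) {
    focal <- as.matrix(focal)[, 1:2, drop = FALSE]
    ids <- graph$index[focal]
  } else ids <- as.integer(focal)
  if (anyNA(ids)) stop("some focal locations fall on nodata cells")
  ids
}

#' Effective resistance between focal nodes
#'
#' Circuit-theory resistance distance: for each pair, the voltage
#' difference under unit current injection/extraction, computed from
#' sparse grounded-Laplacian solves (one Cholesky factorization and one
#' solve per focal node per connected component). Pairs in different
#' components get `Inf` with a warning.
#'
#' @param graph a [build_graph()] result.
#' @param focal node ids, or a two-column matrix/data.frame of (row,
#'   col) cells.
#' @return symmetric matrix of effective resistances, zero diagonal.
#' @export
effective_resistance <- function(graph, focal) {
  ids <- focal_node_ids(graph, focal)
  k <- length(ids)
  R <- matrix(Inf, k, k); diag(R) <- 0
  comp <- graph_components(graph)
  L <- graph_laplacian(graph)
  for (cid in unique(comp[ids])) {
    in_comp <- which(comp[ids] == cid)
    if (length(in_comp) < 2) next
    nodes_c <- which(comp == cid)
    ground <- nodes_c[length(nodes_c)]
    keep <- setdiff(nodes_c, ground)
    Lg <- L[keep, keep, drop = FALSE]
    pos <- match(ids[in_comp], keep)  # NA if a focal IS the ground
    ch <- Matrix::Cholesky(methods::as(Lg, "symmetricMatrix"), LDL = FALSE)
    ## G columns for each focal node (zero column for the ground)
    G <- matrix(0, length(keep), length(in_comp))
    for (m in seq_along(in_comp)) {
      if (is.na(pos[m])) next
      rhs <- numeric(length(keep)); rhs[pos[m]] <- 1
      G[, m] <- as.numeric(Matrix::solve(ch, rhs))
    }
    gii <- vapply(seq_along(in_comp), function(m)
      if (is.na(pos[m])) 0 else G[pos[m], m], numeric(1))
    for (a in seq_len(length(in_comp) - 1)) for (b in seq(a + 1, length(in_comp))) {
      gij <- if (is.na(pos[a])) 0 else G[pos[a], b]
      R[in_comp[a], in_comp[b]] <- R[in_comp[b], in_comp[a]] <-
        gii[a] + gii[b] - 2 * gij
    }
  }
  if (any(!is.finite(R[upper.tri(R)])))
    warning("some focal pairs are in different components; ",
            "infinite resistance recorded")
  dimnames(R) <- list(names(focal), names(focal))
  R
}

#' Cumulative current density between source and target nodes
#'
#' For every (source, target) pair a unit current is injected at the
#' source and extracted at the target; the per-cell current is half the
#' sum of absolute currents on incident edges, accumulated over all
#' pairs with equal weight (pairwise-mode analogue of Circuitscape).
#'
#' @param graph a [build_graph()] result.
#' @param sources,targets node ids or (row, col) matrices.
#' @return object of class `current_density_map`: list with `map`
#'   (matrix of accumulated current) and `n_pairs`.
#' @export
current_density <- function(graph, sources, targets) {
  src <- focal_node_ids(graph, sources)
  tgt <- focal_node_ids(graph, targets)
  n <- nrow(graph$nodes)
  comp <- graph_components(graph)
  L <- graph_laplacian(graph)
  e <- graph$edges
  node_cur <- numeric(n)
  n_pairs <- 0L
  ## factor each needed component once
  for (cid in unique(comp[src])) {
    s_c <- src[comp[src] == cid]
    t_c <- tgt[comp[tgt] == cid]
    t_c <- setdiff(t_c, NA)
    if (length(s_c) == 0 || length(t_c) == 0) next
    nodes_c <- which(comp == cid)
    ground <- nodes_c[length(nodes_c)]
    keep <- setdiff(nodes_c, ground)
    ch <- Matrix::Cholesky(methods::as(L[keep, keep, drop = FALSE],
                                       "symmetricMatrix"), LDL = FALSE)
    loc <- rep(NA_integer_, n); loc[keep] <- seq_along(keep)
    for (s in s_c) for (t in t_c) {
      if (s == t) next
      rhs <- numeric(length(keep))
      if (!is.na(loc[s])) rhs[loc[s]] <- rhs[loc[s]] + 1
      if (!is.na(loc[t])) rhs[loc[t]] <- rhs[loc[t]] - 1
      v <- numeric(n)
      v[keep] <- as.numeric(Matrix::solve(ch, rhs))
      ib <- abs(e$conductance * (v[e$from] - v[e$to]))
      inc <- numeric(n)
      inc_from <- tapply(ib, e$from, sum)
      inc_to <- tapply(ib, e$to, sum)
      inc[as.integer(names(inc_from))] <- inc_from
      inc[as.integer(names(inc_to))] <-
        inc[as.integer(names(inc_to))] + inc_to
      node_cur <- node_cur + inc / 2
      n_pairs <- n_pairs + 1L
    }
  }
  m <- matrix(NA_real_, graph$dims[1], graph$dims[2])
  m[graph$nodes] <- node_cur
  structure(list(map = m, n_pairs = n_pairs,
                 sources = src, targets = tgt, geometry = graph$geometry),
            class = "current_density_map")
}

#' @export
print.current_density_map <- function(x, ...) {
  cat(sprintf("current_density_map: %d source-target pairs, max current %.3g\n",
              x$n_pairs, max(x$map, na.rm = TRUE)))
  invisible(x)
}

#' Isolation-by-resistance regression
#'
#' Relates linearized genetic differentiation to resistance distance for
#' one or several candidate resistance surfaces: Mantel r (Pearson, with
#' simultaneous row/column permutations via vegan) and ordinary
#' least-squares R-squared over the off-diagonal pairs. Surfaces are
#' ranked by R-squared.
#'
#' @param genetic symmetric matrix of linearized FST (theta / (1 -
#'   theta)), or an `fst_matrix`.
#' @param resistance symmetric resistance-distance matrix, or a named
#'   list of them (one per candidate surface).
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed for the permutation test.
#' @return data.frame (surface, mantel_r, mantel_p, r_squared, slope)
#'   sorted by decreasing R-squared, class `ibr_result`.
#' @export
ibr_regression <- function(genetic, resistance, n_perm = 999, seed = 1) {
  if (inherits(genetic, "fst_matrix")) genetic <- genetic$linearized
  check_square_symmetric(genetic, "'genetic'")
  if (!is.list(resistance)) resistance <- list(surface1 = resistance)
  if (is.null(names(resistance)))
    names(resistance) <- sprintf("surface%d", seq_along(resistance))
  gv <- upper_vals(genetic)
  rows <- lapply(names(resistance), function(nm) {
    rm <- resistance[[nm]]
    check_square_symmetric(rm, paste0("resistance '", nm, "'"))
    if (nrow(rm) != nrow(genetic))
      stop("focal sets differ between genetic and resistance matrices")
    rv <- upper_vals(rm)
    fin <- is.finite(rv)
    fit <- stats::lm(gv[fin] ~ rv[fin])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn
    mt <- with_seed(seed, suppressMessages(
      vegan::mantel(stats::as.dist(rm), stats::as.dist(genetic),
                    permutations = n_perm)))
    data.frame(surface = nm, mantel_r = unname(mt$statistic),
               mantel_p = mt$signif,
               r_squared = r2,
               slope = unname(stats::coef(fit)[2]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$r_squared), ]
  rownames(out) <- NULL
  class(out) <- c("ibr_result", "data.frame")
  out
}

#' Evolutionary-rescue connectivity from hot-dry to cold-wet locations
#'
#' Maps the potential for adaptive gene flow: current density from all
#' hot-dry-adapted locations (sources) to all cold-wet-adapted locations
#' (targets) across the best-supported resistance surface, plus a
#' per-target summary (mean effective resistance from all sources; low
#' values = rescue plausible).
#'
#' @param surface cost matrix or single-layer raster_stack (the
#'   top-ranked surface from [ibr_regression()]).
#' @param locations two-column matrix/data.frame of (row, col) cells,
#'   one per location.
#' @param labels character vector per location, containing at least one
#'   "hot_dry" and one "cold_wet"; other labels are ignored.
#' @param connectivity neighbourhood for the graph (default 8).
#' @return list(current, target_summary, resistance): the accumulated
#'   `current_density_map`, a data.frame (target, row, col,
#'   mean_resistance), and the full source x target resistance matrix.
#' @export
rescue_potential <- function(surface, locations, labels,
                             connectivity = 8) {
  locations <- as.matrix(locations)[, 1:2, drop = FALSE]
  if (nrow(locations) != length(labels))
    stop("one label per location required")
  src <- locations[labels == "hot_dry", , drop = FALSE]
  tgt <- locations[labels == "cold_wet", , drop = FALSE]
  if (nrow(src) == 0) stop("no hot_dry source locations")
  if (nrow(tgt) == 0) stop("no cold_wet target locations")
  graph <- build_graph(surface, connectivity = connectivity)
  cur <- current_density(graph, src, tgt)
  all_focal <- rbind(src, tgt)
  R <- effective_resistance(graph, all_focal)
  ns <- nrow(src)
  Rst <- R[seq_len(ns), ns + seq_len(nrow(tgt)), drop = FALSE]
  summary_df <- data.frame(target = seq_len(nrow(tgt)),
                           row = tgt[, 1], col = tgt[, 2],
                           mean_resistance = colMeans(Rst))
  list(current = cur, target_summary = summary_df, resistance = Rst)
}

#' Write a square distance matrix as CSV with focal ids
#' @param m square matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_distance_matrix <- function(m, path) {
  df <- as.data.frame(m)
  if (is.null(rownames(m))) rownames(df) <- sprintf("f%d", seq_len(nrow(m)))
  utils::write.csv(df, path, row.names = TRUE)
  invisible(path)
}
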