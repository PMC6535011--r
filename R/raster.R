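#' Raster stack of co-registered grids
#'
#' A lightweight container for named, co-registered raster layers such as
#' bioclimatic grids, slope or forest cover. Values are stored as numeric
#' matrices with row 1 at the top (north) edge; cell centres sit at
#' half-cell offsets from the lower-left corner, matching the ESRI ASCII
#' grid convention. Missing cells are `NA` internally and written out as
#' the `nodata` marker.
#'
#' @param layers named list of numeric matrices, all with identical
#'   dimensions. `NA` marks nodata cells; the nodata footprint must agree
#'   across layers.
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param cellsize positive cell edge length, in map units.
#' @param nodata value used for missing cells on disk.
#' @return an object of class `raster_stack`.
#' @export
raster_stack <- function(layers, xll = 0, yll = 0, cellsize = 1,
                         nodata = -9999) {
  if (!is.list(layers) || length(layers) == 0L)
    stop("'layers' must be a non-empty named list of matrices")
  if (is.null(names(layers)) || anyDuplicated(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("'layers' must have unique non-empty names")
  dims <- vapply(layers, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all layers must share the same dimensions")
  if (cellsize <= 0) stop("'cellsize' must be positive")
  structure(
    list(layers = lapply(layers, function(m) {
           storage.mode(m) <- "double"; m
         }),
         nrow = dims[1, 1], ncol = dims[2, 1],
         xll = xll, yll = yll, cellsize = cellsize, nodata = nodata),
    class = "raster_stack")
}

#' @export
print.raster_stack <- function(x, ...) {
  cat(sprintf("raster_stack: %d layer(s), %d x %d cells (cellsize %g)\n",
              length(x$layers), x$nrow, x$ncol, x$cellsize))
  for (nm in names(x$layers)) {
    v <- x$layers[[nm]]
    cat(sprintf("  %-16s [%.3g, %.3g], %d nodata\n", nm,
                suppressWarnings(min(v, na.rm = TRUE)),
                suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  }
  invisible(x)
}

#' @export
names.raster_stack <- function(x) names(x$layers)

n_layers <- function(stack) length(stack$layers)

#' Test two stacks for identical grid geometry
#' @param a,b raster_stack objects.
#' @return logical.
#' @export
same_geometry <- function(a, b) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    isTRUE(all.equal(a$cellsize, b$cellsize)) &&
    isTRUE(all.equal(c(a$xll, a$yll), c(b$xll, b$yll)))
}

stopifnot_same_geometry <- function(a, b) {
  if (!same_geometry(a, b))
    stop("raster grids are not co-registered (geometry mismatch)")
}

#' Extract a single layer matrix
#' @param stack a raster_stack.
#' @param name layer name or index.
#' @return numeric matrix.
#' @export
layer_values <- function(stack, name) stack$layers[[name]]

#' Logical mask of valid (non-nodata) cells
#' @param stack a raster_stack.
#' @return logical matrix, TRUE where every layer has data.
#' @export
valid_mask <- function(stack) {
  ok <- !is.na(stack$layers[[1]])
  for (m in stack$layers[-1]) ok <- ok & !is.na(m)
  ok
}

## row/col (1-based, row 1 = top) <-> map coordinates of cell centres
cell_to_xy <- function(stack, row, col) {
  cbind(x = stack$xll + (col - 0.5) * stack$cellsize,
        y = stack$yll + (stack$nrow - row + 0.5) * stack$cellsize)
}

xy_to_cell <- function(stack, x, y) {
  col <- floor((x - stack$xll) / stack$cellsize) + 1L
  row <- stack$nrow - floor((y - stack$yll) / stack$cellsize)
  cbind(row = as.integer(row), col = as.integer(col))
}

in_extent <- function(stack, x, y) {
  x >= stack$xll & x <= stack$xll + stack$ncol * stack$cellsize &
    y >= stack$yll & y <= stack$yll + stack$nrow * stack$cellsize
}

#' Per-sample environmental values at point locations
#'
#' Looks up every layer of the stack at the cells containing the given
#' coordinates.
#'
#' @param stack a raster_stack.
#' @param x,y point coordinates in map units.
#' @return matrix with one row per point and one column per layer.
#' @export
extract_env <- function(stack, x, y) {
  if (any(!in_extent(stack, x, y)))
    stop("some points fall outside the raster extent")
  rc <- xy_to_cell(stack, x, y)
  out <- vapply(stack$layers,
                function(m) m[cbind(rc[, "row"], rc[, "col"])],
                numeric(nrow(rc)))
  if (length(x) == 1L) out <- matrix(out, nrow = 1,
                                     dimnames = list(NULL, names(stack$layers)))
  out
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header followed by whitespace-separated values, top row first.
#'
#' @param path file path.
#' @param name layer name for the resulting single-layer stack.
#' @return a raster_stack with one layer.
#' @export
read_ascii_grid <- function(path, name = "layer") {
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ESRI ASCII header in ", path)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  stk <- raster_stack(stats::setNames(list(m), name),
                      xll = hdr$xllcorner, yll = hdr$yllcorner,
                      cellsize = hdr$cellsize, nodata = nodata)
  stk
}

#' Write raster layers as ESRI ASCII grids
#'
#' Writes one `.asc` file per layer with the standard six-line header.
#'
#' @param stack a raster_stack.
#' @param dir output directory (created if absent).
#' @param layers layer names to write; default all.
#' @return invisibly, the written file paths.
#' @export
write_ascii_grid <- function(stack, dir, layers = names(stack$layers)) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in layers) {
    m <- stack$layers[[nm]]
    m[is.na(m)] <- stack$nodata
    path <- file.path(dir, paste0(nm, ".asc"))
    hdr <- c(sprintf("ncols %d", stack$ncol),
             sprintf("nrows %d", stack$nrow),
             sprintf("xllcorner %.10g", stack$xll),
             sprintf("yllcorner %.10g", stack$yll),
             sprintf("cellsize %.10g", stack$cellsize),
             sprintf("NODATA_value %.10g", stack$nodata))
    body <- apply(m, 1, function(r) paste(format(r, trim = TRUE,
                                                 digits = 10),
                                          collapse = " "))
    writeLines(c(hdr, body), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read several ASCII grids into one stack
#' @param paths named character vector of .asc paths; names become layers.
#' @return raster_stack.
#' @export
read_raster_stack <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.asc$", "", basename(paths))
  stks <- mapply(read_ascii_grid, paths, names(paths), SIMPLIFY = FALSE)
  base <- stks[[1]]
  for (s in stks[-1]) {
    stopifnot_same_geometry(base, s)
    base$layers <- c(base$layers, s$layers)
  }
  base
}
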