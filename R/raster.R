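#' Georeferenced raster grid
#'
#' A minimal in-memory raster: a numeric matrix on a uniform square lattice
#' plus a geotransform (lower-left corner, cell size). Row 1 of the matrix is
#' the northernmost row, matching the on-disk order of ESRI ASCII grids.
#' The package uses a projected, equal-area convention throughout: the area of
#' one cell is \code{cell_size^2} (km^2), with no latitude correction, so that
#' area-to-distance rate statistics are exact.
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param cell_size cell edge length in km (> 0).
#' @param xll,yll coordinates of the lower-left corner of the grid.
#' @param nodata value standing for missing cells on disk.
#' @return an object of class \code{raster_grid}.
#' @export
raster_grid <- function(values, cell_size = 10, xll = 0, yll = 0,
                        nodata = -9999) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be a single positive number", call. = FALSE)
  structure(
    list(values = values, cell_size = cell_size,
         xll = xll, yll = yll, nodata = nodata),
    class = "raster_grid"
  )
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll))
  cat(sprintf("  values: min %.4g, max %.4g\n",
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Cell-center coordinates
#'
#' Centers follow the convention (col - 0.5, row-from-bottom - 0.5) * cell_size
#' offset from the lower-left corner.
#'
#' @param grid a \code{raster_grid}.
#' @param rows,cols 1-based matrix indices (row 1 = top).
#' @return data.frame with columns \code{lon}, \code{lat}.
#' @export
cell_centers <- function(grid, rows, cols) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid$values)
  data.frame(
    lon = grid$xll + (cols - 0.5) * grid$cell_size,
    lat = grid$yll + (nr - rows + 0.5) * grid$cell_size
  )
}

#' Map coordinates to cell indices
#'
#' @param grid a \code{raster_grid}.
#' @param lon,lat coordinates in the grid's projected units.
#' @return data.frame with columns \code{row}, \code{col}; coordinates falling
#'   outside the grid give NA.
#' @export
cells_from_coords <- function(grid, lon, lat) {
  stopifnot(inherits(grid, "raster_grid"))
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$xll) / grid$cell_size) + 1L
  row <- nr - floor((lat - grid$yll) / grid$cell_size)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Read an ESRI ASCII grid
#'
#' Parses the standard six-line header (ncols, nrows, xllcorner/xllcenter,
#' yllcorner/yllcenter, cellsize, NODATA_value) followed by rows of values in
#' north-to-south order. Cells equal to the NODATA value become NA.
#'
#' @param path file path.
#' @return a \code{raster_grid}. Cell size is interpreted in km.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list(); i <- 1L
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("not an ESRI ASCII grid (missing header): ", path, call. = FALSE)
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - hdr$cellsize / 2
         else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - hdr$cellsize / 2
         else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, found %d in %s", nr * nc,
                 length(vals), path), call. = FALSE)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  raster_grid(m, cell_size = hdr$cellsize, xll = xll, yll = yll,
              nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param grid a \code{raster_grid}.
#' @param path output file path.
#' @param digits significant digits for floating-point layers; integer-valued
#'   layers are written exactly.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(grid, path, digits = 8) {
  stopifnot(inherits(grid, "raster_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  intlike <- all(m == round(m))
  fmt <- function(v) {
    if (intlike) format(v, scientific = FALSE, trim = TRUE)
    else formatC(v, digits = digits, format = "g")
  }
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", grid$xll),
    sprintf("yllcorner %.10g", grid$yll),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %.10g", grid$nodata)
  )
  body <- apply(m, 1L, function(r) paste(fmt(r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Bundle bioclimatic layers for one time slice
#'
#' @param layers named list of \code{raster_grid} objects sharing dimensions,
#'   cell size and origin.
#' @return an object of class \code{climate_stack}.
#' @export
climate_stack <- function(layers) {
  if (length(layers) == 0 || is.null(names(layers)) ||
      any(!nzchar(names(layers))))
    stop("`layers` must be a non-empty named list", call. = FALSE)
  if (!all(vapply(layers, inherits, logical(1), "raster_grid")))
    stop("all layers must be raster_grid objects", call. = FALSE)
  d <- dim(layers[[1]]$values)
  cs <- layers[[1]]$cell_size
  for (nm in names(layers)) {
    g <- layers[[nm]]
    if (!identical(dim(g$values), d))
      stop("layer dimensions differ: ", nm, call. = FALSE)
    if (!isTRUE(all.equal(g$cell_size, cs)))
      stop("layer cell sizes differ: ", nm, call. = FALSE)
  }
  structure(list(layers = layers), class = "climate_stack")
}

#' @export
names.climate_stack <- function(x) names(x$layers)

#' @export
dim.climate_stack <- function(x) dim(x$layers[[1]]$values)

#' @export
`[[.climate_stack` <- function(x, i) x$layers[[i]]

#' @export
print.climate_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<climate_stack> %d variables on %d x %d grid: %s\n",
              length(x$layers), d[1], d[2],
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Extract per-cell variable values from a stack
#'
#' @param stack a \code{climate_stack}.
#' @param rows,cols cell indices; if omitted, all cells in column-major order.
#' @return numeric matrix with one column per variable.
#' @export
stack_values <- function(stack, rows = NULL, cols = NULL) {
  stopifnot(inherits(stack, "climate_stack"))
  if (is.null(rows)) {
    out <- vapply(stack$layers, function(g) as.vector(g$values),
                  numeric(prod(dim(stack))))
  } else {
    idx <- cbind(rows, cols)
    out <- vapply(stack$layers, function(g) g$values[idx],
                  numeric(length(rows)))
  }
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(stack)))
  out
}
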