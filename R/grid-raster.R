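#' Regular raster grid definition
#'
#' A lightweight grid description shared by all rasters in an analysis: a
#' rectangular extent in a projected, metre-based coordinate system divided
#' into square cells. All covariate rasters in a study must share one grid so
#' that cell indices line up.
#'
#' @param xmin,ymin Coordinates (m) of the lower-left corner of the extent.
#' @param extent_m Numeric length-2: width and height of the extent in metres.
#'   Must be divisible into whole cells of `resolution_m`.
#' @param resolution_m Cell edge length in metres (default 30).
#' @return An object of class `fp_grid` with fields `xmin`, `ymin`, `res`,
#'   `ncol`, `nrow`, `xmax`, `ymax`.
#' @export
fp_grid <- function(xmin = 0, ymin = 0, extent_m = c(3000, 3000),
                    resolution_m = 30) {
  if (resolution_m <= 0) stop("resolution_m must be > 0")
  if (length(extent_m) != 2 || any(extent_m <= 0))
    stop("extent_m must be two positive lengths")
  nc <- extent_m[1] / resolution_m
  nr <- extent_m[2] / resolution_m
  if (abs(nc - round(nc)) > 1e-9 || abs(nr - round(nr)) > 1e-9)
    stop("extent_m must divide into whole cells of resolution_m")
  structure(
    list(xmin = xmin, ymin = ymin, res = resolution_m,
         ncol = as.integer(round(nc)), nrow = as.integer(round(nr)),
         xmax = xmin + extent_m[1], ymax = ymin + extent_m[2]),
    class = "fp_grid")
}

#' @export
print.fp_grid <- function(x, ...) {
  cat(sprintf("<fp_grid> %d x %d cells @ %g m, x [%g, %g], y [%g, %g]\n",
              x$nrow, x$ncol, x$res, x$xmin, x$xmax, x$ymin, x$ymax))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid An [fp_grid()].
#' @return List with `x` (ncol values, ascending) and `y` (nrow values,
#'   ascending) cell-centre coordinates.
#' @export
grid_centers <- function(grid) {
  list(x = grid$xmin + (seq_len(grid$ncol) - 0.5) * grid$res,
       y = grid$ymin + (seq_len(grid$nrow) - 0.5) * grid$res)
}

#' Construct a raster on a grid
#'
#' Values are stored as an `nrow x ncol` matrix; row `i` is the i-th row of
#' cells from the *bottom* (ascending y), column `j` the j-th column from the
#' left (ascending x).
#'
#' @param grid An [fp_grid()].
#' @param values Matrix of dimension `grid$nrow x grid$ncol`, or a single
#'   number recycled to all cells.
#' @return An object of class `fp_raster`.
#' @export
fp_raster <- function(grid, values = 0) {
  if (length(values) == 1)
    values <- matrix(values, grid$nrow, grid$ncol)
  values <- as.matrix(values)
  if (!all(dim(values) == c(grid$nrow, grid$ncol)))
    stop("values must be nrow x ncol for this grid")
  structure(list(grid = grid, values = values), class = "fp_raster")
}

#' @export
print.fp_raster <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<fp_raster> %d x %d @ %g m; range [%g, %g]\n",
              x$grid$nrow, x$grid$ncol, x$grid$res,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Row/column index of the cells containing points
#'
#' Points on an interior cell edge belong to the cell above/right of the edge;
#' points on the top/right boundary of the extent are assigned to the last
#' cell so the closed extent is fully covered.
#'
#' @param grid An [fp_grid()].
#' @param xy Two-column matrix (x, y) of point coordinates.
#' @return Integer matrix with columns `row`, `col`; NA for points outside
#'   the extent.
#' @export
cell_index <- function(grid, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  col <- floor((xy[, 1] - grid$xmin) / grid$res) + 1L
  row <- floor((xy[, 2] - grid$ymin) / grid$res) + 1L
  col[xy[, 1] == grid$xmax] <- grid$ncol
  row[xy[, 2] == grid$ymax] <- grid$nrow
  out <- xy[, 1] < grid$xmin | xy[, 1] > grid$xmax |
    xy[, 2] < grid$ymin | xy[, 2] > grid$ymax
  col[out] <- NA_integer_; row[out] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Extract raster values at point locations
#'
#' @param raster An [fp_raster()].
#' @param xy Two-column matrix of coordinates.
#' @param ids Optional identifiers used in the error message for points
#'   falling outside the raster extent.
#' @return Numeric vector of cell values (value of the cell containing each
#'   point).
#' @export
raster_extract <- function(raster, xy, ids = NULL) {
  idx <- cell_index(raster$grid, xy)
  bad <- is.na(idx[, 1])
  if (any(bad)) {
    lab <- if (is.null(ids)) which(bad) else ids[bad]
    stop("points outside raster extent: ",
         paste(utils::head(lab, 10), collapse = ", "))
  }
  raster$values[cbind(idx[, 1], idx[, 2])]
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format (`ncols/nrows/xllcorner/yllcorner/cellsize`
#' header followed by rows of values from the top row down). Non-finite cells
#' are written as the NODATA value.
#'
#' @param raster An [fp_raster()].
#' @param path Output file path.
#' @param nodata NODATA sentinel written for non-finite cells.
#' @export
write_ascii_raster <- function(raster, path, nodata = -9999) {
  g <- raster$grid
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write raster to ", path))
  on.exit(close(con))
  writeLines(c(paste("ncols", g$ncol), paste("nrows", g$nrow),
               paste("xllcorner", format(g$xmin, digits = 15)),
               paste("yllcorner", format(g$ymin, digits = 15)),
               paste("cellsize", format(g$res, digits = 15)),
               paste("NODATA_value", nodata)), con)
  v <- raster$values
  v[!is.finite(v)] <- nodata
  for (i in rev(seq_len(g$nrow)))  # ascii grids run top row first
    writeLines(paste(format(v[i, ], digits = 15, trim = TRUE),
                     collapse = " "), con)
  invisible(path)
}

#' Read an ESRI ASCII grid raster
#'
#' @param path File written by [write_ascii_raster()] (or any conforming
#'   ASCII grid).
#' @param nodata_to Value given to NODATA cells on read (default `Inf`, the
#'   sentinel used by distance rasters for "no feature anywhere").
#' @return An [fp_raster()].
#' @export
read_ascii_raster <- function(path, nodata_to = Inf) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  nc <- hdr$ncols; nr <- hdr$nrows
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr) stop("corrupt ascii raster: ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[rev(seq_len(nr)), , drop = FALSE]  # back to ascending-y rows
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- nodata_to
  grid <- fp_grid(hdr$xllcorner, hdr$yllcorner,
                  extent_m = c(nc, nr) * hdr$cellsize,
                  resolution_m = hdr$cellsize)
  fp_raster(grid, m)
}
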