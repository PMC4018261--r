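#' Gridded raster layers
#'
#' `sdmbias` represents every gridded surface (environmental predictors,
#' retention-probability surfaces, suitability maps, binary maps) as a plain
#' in-memory grid following the ESRI ASCII convention: the extent is anchored
#' at the lower-left *corner* (`xll`, `yll`), cells are square with side
#' `cellsize` in decimal degrees, and the value matrix is stored with row 1 as
#' the northernmost row.
#'
#' A point maps to the cell whose half-open interval contains it: cells are
#' closed on their southern and western edges and open on the north/east, so a
#' point lying exactly on an internal boundary belongs to the cell to the
#' north (or east). Extraction is nearest-cell; no interpolation is ever done.
#'
#' @param values numeric matrix, row 1 = northernmost row.
#' @param xll,yll coordinates of the lower-left corner of the grid (degrees).
#' @param cellsize cell side length in degrees, > 0.
#' @param nodata sentinel value marking missing cells (stored as `NA`
#'   internally; the sentinel is used on write).
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, xll = 0, yll = 0, cellsize = 1,
                        nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cellsize) || length(cellsize) != 1L || cellsize <= 0) {
    stop("'cellsize' must be a single positive number", call. = FALSE)
  }
  values[!is.na(values) & values == nodata] <- NA_real_
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("all non-nodata raster values must be finite", call. = FALSE)
  }
  structure(
    list(nrows = nrow(values), ncols = ncol(values),
         xll = as.numeric(xll), yll = as.numeric(yll),
         cellsize = as.numeric(cellsize), nodata = nodata,
         values = values),
    class = "grid_raster")
}

#' @method print grid_raster
#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d x %d cells, cellsize %g deg\n",
              x$nrows, x$ncols, x$cellsize))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]\n",
              x$xll, x$xll + x$ncols * x$cellsize,
              x$yll, x$yll + x$nrows * x$cellsize))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

raster_same_grid <- function(a, b) {
  isTRUE(all.equal(c(a$nrows, a$ncols, a$xll, a$yll, a$cellsize),
                   c(b$nrows, b$ncols, b$xll, b$yll, b$cellsize)))
}

#' Cell indices for points
#'
#' Maps longitude/latitude pairs to (row, col) indices of the containing
#' cell. Cells are half-open: a point on an internal boundary belongs to the
#' north/east neighbour. Points outside the extent get `NA` indices.
#'
#' @param r a [grid_raster()].
#' @param lon,lat numeric vectors of point coordinates (degrees).
#' @return a data.frame with integer columns `row` and `col`.
#' @export
cell_index <- function(r, lon, lat) {
  col <- floor((lon - r$xll) / r$cellsize) + 1L
  row_from_bottom <- floor((lat - r$yll) / r$cellsize)
  row <- r$nrows - as.integer(row_from_bottom)
  bad <- col < 1L | col > r$ncols | row < 1L | row > r$nrows
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates
#'
#' @param r a [grid_raster()].
#' @param row,col integer cell indices (row 1 = northernmost).
#' @return data.frame with columns `lon` and `lat` of cell centers.
#' @export
cell_center <- function(r, row, col) {
  data.frame(lon = r$xll + (col - 0.5) * r$cellsize,
             lat = r$yll + (r$nrows - row + 0.5) * r$cellsize)
}

#' Raster values at points (nearest cell)
#' @param r a [grid_raster()].
#' @param lon,lat point coordinates.
#' @return numeric vector; `NA` for nodata cells, error if any point falls
#'   outside the extent.
#' @export
raster_value_at <- function(r, lon, lat) {
  idx <- cell_index(r, lon, lat)
  if (anyNA(idx$row)) {
    first <- which(is.na(idx$row))[1]
    stop(sprintf("point %d (%.6g, %.6g) falls outside the raster extent",
                 first, lon[first], lat[first]), call. = FALSE)
  }
  r$values[cbind(idx$row, idx$col)]
}

# lon (by col) and lat (by row) of all cell centers
cell_center_lons <- function(r) r$xll + (seq_len(r$ncols) - 0.5) * r$cellsize
cell_center_lats <- function(r) {
  r$yll + (r$nrows - seq_len(r$nrows) + 0.5) * r$cellsize
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`,
#' `cellsize`, optional `NODATA_value`) followed by `nrows * ncols` values in
#' north-to-south row order. A write-then-read round trip preserves header
#' fields and values exactly.
#'
#' @param path path to the `.asc` file.
#' @return a [grid_raster()].
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  n_hdr <- 0L
  for (ln in lines) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(toks[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner",
                   "cellsize", "nodata_value")) {
      val <- suppressWarnings(as.numeric(toks[2]))
      if (length(toks) < 2L || is.na(val)) {
        stop(sprintf("malformed ESRI ASCII header: bad value for key '%s'",
                     toks[1]), call. = FALSE)
      }
      hdr[[key]] <- val
      n_hdr <- n_hdr + 1L
    } else break
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]])) {
      stop(sprintf("malformed ESRI ASCII header: missing key '%s'", key),
           call. = FALSE)
    }
  }
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  body <- paste(lines[-seq_len(n_hdr)], collapse = " ")
  vals <- suppressWarnings(as.numeric(strsplit(trimws(body), "\\s+")[[1]]))
  if (anyNA(vals)) stop("non-numeric value in ESRI ASCII grid body",
                        call. = FALSE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop(sprintf(
      "dimension error: header declares %d x %d = %d values but %d found",
      nr, nc, nr * nc, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  grid_raster(m, xll = hdr$xllcorner, yll = hdr$yllcorner,
              cellsize = hdr$cellsize, nodata = nodata)
}

#' Write an ESRI ASCII grid
#'
#' @param r a [grid_raster()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_asc <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", r$ncols),
    sprintf("nrows %d", r$nrows),
    sprintf("xllcorner %s", format(r$xll, digits = 17)),
    sprintf("yllcorner %s", format(r$yll, digits = 17)),
    sprintf("cellsize %s", format(r$cellsize, digits = 17)),
    sprintf("NODATA_value %s", format(r$nodata, digits = 17))), con)
  v <- r$values
  v[is.na(v)] <- r$nodata
  for (i in seq_len(r$nrows)) {
    writeLines(paste(format(v[i, ], digits = 17, trim = TRUE,
                            scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}
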