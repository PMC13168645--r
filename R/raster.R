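#' Grid geometry for in-memory rasters
#'
#' A minimal georeferencing record (rows, columns, pixel size, lower-left
#' corner, CRS label). All rasters in a pipeline share one grid; operations
#' that combine rasters check grid equality.
#'
#' @param nrow,ncol grid dimensions in pixels.
#' @param pixel_size_m pixel edge length in metres (default 30, Landsat-like).
#' @param xll,yll coordinates of the lower-left corner.
#' @param crs free-form CRS identifier carried through I/O.
#' @return an object of class `pw_grid`.
#' @export
pw_grid <- function(nrow, ncol, pixel_size_m = 30, xll = 0, yll = 0,
                    crs = "local") {
  stopifnot(nrow >= 1, ncol >= 1, pixel_size_m > 0)
  structure(list(nrow = as.integer(nrow), ncol = as.integer(ncol),
                 pixel_size_m = pixel_size_m, xll = xll, yll = yll,
                 crs = crs),
            class = "pw_grid")
}

#' @export
format.pw_grid <- function(x, ...) {
  sprintf("<pw_grid %d x %d @ %gm (%s)>", x$nrow, x$ncol, x$pixel_size_m,
          x$crs)
}

#' @export
print.pw_grid <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$nrow == b$nrow && a$ncol == b$ncol &&
    abs(a$pixel_size_m - b$pixel_size_m) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

check_same_grid <- function(a, b, what = "rasters") {
  if (!grids_equal(a, b)) stop(what, " are not on the same grid", call. = FALSE)
  invisible(TRUE)
}

#' Pixel area in hectares for a grid
#' @param grid a [pw_grid()].
#' @return hectares per pixel.
#' @export
pixel_area_ha <- function(grid) grid$pixel_size_m^2 / 1e4

#' Write a raster matrix as an Esri ASCII grid
#'
#' Plain-text raster interchange used throughout the package (the environment
#' provides no GeoTIFF driver). Values are written at full double precision
#' (`%.17g`) so a write/read round trip is exact; `NA` maps to the nodata
#' value.
#'
#' @param values numeric or integer matrix (row 1 = top of the map).
#' @param path output file path.
#' @param grid a [pw_grid()] describing geometry.
#' @param nodata nodata sentinel written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(values, path, grid, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$nrow,
            ncol(values) == grid$ncol)
  hdr <- c(sprintf("NCOLS %d", grid$ncol),
           sprintf("NROWS %d", grid$nrow),
           sprintf("XLLCORNER %.10g", grid$xll),
           sprintf("YLLCORNER %.10g", grid$yll),
           sprintf("CELLSIZE %.10g", grid$pixel_size_m),
           sprintf("NODATA_VALUE %.10g", nodata),
           sprintf("CRS %s", grid$crs))
  v <- values
  v[is.na(v)] <- nodata
  body <- apply(v, 1L, function(r) paste(sprintf("%.17g", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an Esri ASCII grid written by [write_asc()]
#'
#' @param path file path.
#' @return list with `values` (matrix, nodata as `NA`) and `grid`.
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:7]
  gv <- function(i) strsplit(trimws(hdr[i]), "\\s+")[[1]][2]
  ncol <- as.integer(gv(1)); nrow <- as.integer(gv(2))
  xll <- as.numeric(gv(3)); yll <- as.numeric(gv(4))
  cell <- as.numeric(gv(5)); nodata <- as.numeric(gv(6))
  crs <- sub("^CRS ", "", hdr[7])
  vals <- matrix(NA_real_, nrow, ncol)
  for (r in seq_len(nrow)) {
    vals[r, ] <- as.numeric(strsplit(trimws(lines[7 + r]), "\\s+")[[1]])
  }
  vals[vals == nodata] <- NA_real_
  list(values = vals,
       grid = pw_grid(nrow, ncol, pixel_size_m = cell, xll = xll, yll = yll,
                      crs = crs))
}

#' Round-trip a raster through disk
#'
#' Contract check used by the pipeline: writing then reading must preserve
#' grid, geometry, nodata pattern and values exactly.
#'
#' @param values raster matrix.
#' @param path file path to use.
#' @param grid a [pw_grid()].
#' @return the re-read raster list (as [read_asc()]).
#' @export
raster_round_trip <- function(values, path, grid) {
  write_asc(values, path, grid)
  back <- read_asc(path)
  if (!grids_equal(grid, back$grid)) {
    stop("grid metadata lost in raster round trip", call. = FALSE)
  }
  back
}
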