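#' Multi-band georeferenced raster held in memory
#'
#' `scene_raster` is the package's lightweight container for a co-registered
#' multi-band grid: a rows x cols x bands numeric array plus the minimal
#' georeferencing metadata needed by the pipeline (pixel size, six-element
#' geotransform with a top-left, pixel-is-area origin, CRS identifier, and an
#' optional nodata sentinel). Label rasters use the same container with a
#' single integer band.
#'
#' @param grid numeric array, rows x cols x bands (a matrix is promoted to a
#'   single band).
#' @param band_names character vector, one name per band.
#' @param pixel_size_m positive pixel edge length in metres.
#' @param geotransform numeric length-6 vector
#'   `(origin_x, px_w, 0, origin_y, 0, -px_h)`; defaults to an origin at (0,0).
#' @param crs coordinate reference system identifier (free-form string).
#' @param nodata optional nodata sentinel; `NA` values in `grid` are always
#'   treated as missing.
#' @return an object of class `scene_raster`.
#' @export
scene_raster <- function(grid, band_names = NULL, pixel_size_m = 1,
                         geotransform = NULL, crs = "local", nodata = NULL) {
  if (is.matrix(grid)) grid <- array(grid, dim = c(dim(grid), 1L))
  stopifnot(is.array(grid), length(dim(grid)) == 3L)
  if (!is.numeric(pixel_size_m) || length(pixel_size_m) != 1L || pixel_size_m <= 0)
    stop("pixel_size_m must be a single positive number")
  nb <- dim(grid)[3L]
  if (is.null(band_names)) band_names <- paste0("band", seq_len(nb))
  if (length(band_names) != nb)
    stop("band_names length (", length(band_names), ") != band count (", nb, ")")
  if (is.null(geotransform))
    geotransform <- c(0, pixel_size_m, 0, 0, 0, -pixel_size_m)
  stopifnot(length(geotransform) == 6L)
  structure(
    list(grid = grid, band_names = band_names, pixel_size_m = pixel_size_m,
         geotransform = geotransform, crs = crs, nodata = nodata),
    class = "scene_raster")
}

#' @export
print.scene_raster <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<scene_raster> %d x %d px, %d band(s) [%s], %g m/px\n",
              d[1L], d[2L], d[3L], paste(x$band_names, collapse = ", "),
              x$pixel_size_m))
  invisible(x)
}

#' @export
dim.scene_raster <- function(x) dim(x$grid)

#' Extract one band of a scene raster as a matrix
#'
#' @param x a `scene_raster`.
#' @param band band name or index.
#' @return numeric matrix (rows x cols).
#' @export
scene_band <- function(x, band) {
  stopifnot(inherits(x, "scene_raster"))
  if (is.character(band)) {
    i <- match(band, x$band_names)
    if (is.na(i)) stop("missing band: '", band, "'")
  } else i <- as.integer(band)
  m <- x$grid[, , i, drop = FALSE]
  dim(m) <- dim(x$grid)[1:2]
  m
}

# Logical matrix of pixels that carry data (all bands non-missing).
scene_valid_mask <- function(x) {
  ok <- !apply(is.na(x$grid), c(1L, 2L), any)
  if (!is.null(x$nodata))
    ok <- ok & !apply(x$grid == x$nodata, c(1L, 2L), any)
  ok
}

#' Write / read a single-band raster as an ESRI ASCII grid
#'
#' Plain-text interchange for label maps and masks. Values are written
#' row-major from the top-left corner, matching the pixel-is-area convention
#' used throughout the package.
#'
#' @param x single-band `scene_raster`.
#' @param path output file path.
#' @param digits significant digits for numeric grids.
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a `scene_raster`.
#' @export
write_ascii_grid <- function(x, path, digits = 6L) {
  stopifnot(inherits(x, "scene_raster"), dim(x$grid)[3L] == 1L)
  m <- x$grid[, , 1L]
  nodata_val <- if (is.null(x$nodata)) -9999 else x$nodata
  m[is.na(m)] <- nodata_val
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(m)), paste("nrows", nrow(m)),
    paste("xllcorner", format(x$geotransform[1L], digits = 12)),
    paste("yllcorner", format(x$geotransform[4L] + x$geotransform[6L] * nrow(m),
                              digits = 12)),
    paste("cellsize", format(x$pixel_size_m, digits = 12)),
    paste("NODATA_value", format(nodata_val, digits = 12))), con)
  write.table(signif(m, digits), con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6L)
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- as.numeric(kv[, 2L])
  names(vals) <- tolower(kv[, 1L])
  m <- as.matrix(read.table(path, skip = 6L))
  dimnames(m) <- NULL
  m[m == vals[["nodata_value"]]] <- NA
  scene_raster(m, pixel_size_m = vals[["cellsize"]],
               geotransform = c(vals[["xllcorner"]], vals[["cellsize"]], 0,
                                vals[["yllcorner"]] - vals[["cellsize"]] * nrow(m) * -1,
                                0, -vals[["cellsize"]]),
               nodata = NULL)
}
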