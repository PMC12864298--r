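#' Aggregate a binary change mask onto an analysis grid
#'
#' Changed pixels are treated as points and binned into a regular grid of
#' `cell_size_px` x `cell_size_px` pixel cells; the cell value x_j is the
#' count of changed pixels it contains. Gi* on raw binary pixels is
#' degenerate, so counts-per-cell is the standard operationalization for
#' hotspot analysis of change rasters. Partial edge cells are kept (they
#' simply cover fewer pixels).
#'
#' @param mask logical change matrix.
#' @param cell_size_px cell side in mask pixels.
#' @return object of class `hotspot_grid`: list with `counts` (cell matrix),
#'   `cell_size_px` and `n_changed`.
#' @export
aggregate_changes_to_grid <- function(mask, cell_size_px) {
  stopifnot(is.matrix(mask))
  cell_size_px <- as.integer(cell_size_px)
  if (cell_size_px < 1L) stop("cell_size_px must be >= 1")
  if (!any(mask %in% TRUE)) warning("empty change mask; grid of zeros")
  h <- ceiling(nrow(mask) / cell_size_px)
  w <- ceiling(ncol(mask) / cell_size_px)
  counts <- matrix(0, h, w)
  m <- mask; m[is.na(m)] <- FALSE
  idx <- which(m, arr.ind = TRUE)
  if (nrow(idx)) {
    ci <- (idx[, 1L] - 1L) %/% cell_size_px + 1L
    cj <- (idx[, 2L] - 1L) %/% cell_size_px + 1L
    for (p in seq_len(nrow(idx)))
      counts[ci[p], cj[p]] <- counts[ci[p], cj[p]] + 1
  }
  structure(list(counts = counts, cell_size_px = cell_size_px,
                 n_changed = nrow(idx)), class = "hotspot_grid")
}

#' Getis-Ord Gi* z-scores on a value grid
#'
#' The self-inclusive local statistic
#' `Gi* = (sum_j w_ij x_j - Xbar W_i) / (S sqrt((n sum_j w_ij^2 - W_i^2)/(n-1)))`
#' with binary fixed-distance-band weights: `w_ij = 1` when the cell-centre
#' distance is at most `band_radius` (in cell units), which always includes
#' the cell itself. `Xbar` and `S` are the global mean and (population)
#' standard deviation over all n cells. A constant field (S = 0) is defined
#' to give z = 0 everywhere. The default radius of 1.5 cells yields the
#' 8-neighbour (queen) plus self neighbourhood, since the diagonal
#' centre-to-centre distance is sqrt(2); a radius in [1, sqrt(2)) gives
#' rook plus self.
#'
#' @param grid a `hotspot_grid` or numeric matrix of cell values.
#' @param band_radius weight-band radius in cell units (> 0).
#' @return numeric matrix of z-scores, one per cell.
#' @export
gi_star <- function(grid, band_radius = 1.5) {
  x <- if (inherits(grid, "hotspot_grid")) grid$counts else grid
  stopifnot(is.matrix(x))
  if (band_radius <= 0) stop("band_radius must be > 0")
  n <- length(x)
  if (n < 2L) stop("need at least 2 cells")
  xbar <- mean(x)
  s <- sqrt(mean(x^2) - xbar^2)
  if (s == 0) return(matrix(0, nrow(x), ncol(x)))
  # neighbourhood offsets within the band (includes (0,0): self)
  r <- floor(band_radius)
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= band_radius^2, , drop = FALSE]
  h <- nrow(x); w <- ncol(x)
  wsum <- matrix(0, h, w)   # sum_j w_ij x_j
  wi <- matrix(0, h, w)     # W_i = sum_j w_ij (edge cells have fewer)
  for (q in seq_len(nrow(off))) {
    dr <- off$dr[q]; dc <- off$dc[q]
    sr <- max(1L, 1L - dr):min(h, h - dr)
    sc <- max(1L, 1L - dc):min(w, w - dc)
    wsum[sr, sc] <- wsum[sr, sc] + x[sr + dr, sc + dc, drop = FALSE]
    wi[sr, sc] <- wi[sr, sc] + 1
  }
  denom <- s * sqrt(pmax(n * wi - wi^2, 0) / (n - 1))  # binary weights: sum w^2 = W_i
  z <- (wsum - xbar * wi) / denom
  z[denom == 0] <- 0  # W_i = n: every cell is a neighbour, no local contrast
  z
}

#' Classify Gi* z-scores into significance bins
#'
#' Two-sided normal thresholds: |z| >= 2.576 (99%), 1.96 (95%), 1.645 (90%);
#' the sign separates hotspots (clusters of high values) from coldspots.
#'
#' @param z numeric matrix/vector of z-scores.
#' @return character object of the same shape with levels `cold99`,
#'   `cold95`, `cold90`, `ns`, `hot90`, `hot95`, `hot99`.
#' @export
classify_significance <- function(z) {
  out <- ifelse(z >= 2.576, "hot99",
         ifelse(z >= 1.96, "hot95",
         ifelse(z >= 1.645, "hot90",
         ifelse(z <= -2.576, "cold99",
         ifelse(z <= -1.96, "cold95",
         ifelse(z <= -1.645, "cold90", "ns"))))))
  if (!is.null(dim(z))) dim(out) <- dim(z)
  out
}
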