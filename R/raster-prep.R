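#' Temporal median composite of co-registered rasters
#'
#' Reduces a within-year stack of acquisitions to a single analysis-ready
#' composite: per pixel and band, the median of the observations flagged
#' valid. This is the standard cloud/speckle-suppressing reducer for both
#' optical mosaics and pseudo-quad-pol SAR composites. A pixel with no valid
#' observation in any raster becomes `NA` (nodata). The median of an
#' even-count stack is the mean of the two middle values.
#'
#' @param stack list of `scene_raster`s sharing shape, bands and geotransform.
#' @param validity_masks optional list of logical matrices (TRUE = valid),
#'   one per raster; `NULL` treats every non-`NA` pixel as valid.
#' @return a `scene_raster` composite.
#' @export
temporal_median_composite <- function(stack, validity_masks = NULL) {
  if (length(stack) == 0L) stop("empty stack")
  d <- dim(stack[[1L]]$grid)
  for (r in stack) {
    if (!inherits(r, "scene_raster")) stop("stack must contain scene_raster objects")
    if (!identical(dim(r$grid), d)) stop("shape mismatch in stack")
    if (!isTRUE(all.equal(r$geotransform, stack[[1L]]$geotransform)))
      stop("geotransform mismatch in stack")
  }
  if (!is.null(validity_masks) && length(validity_masks) != length(stack))
    stop("validity_masks must match stack length")
  n <- length(stack)
  out <- array(NA_real_, d)
  for (b in seq_len(d[3L])) {
    obs <- matrix(NA_real_, d[1L] * d[2L], n)
    for (i in seq_len(n)) {
      v <- stack[[i]]$grid[, , b]
      if (!is.null(validity_masks)) v[!validity_masks[[i]]] <- NA
      obs[, i] <- v
    }
    out[, , b] <- matrix(apply(obs, 1L, median, na.rm = TRUE), d[1L], d[2L])
  }
  out[is.nan(out)] <- NA
  tmpl <- stack[[1L]]
  scene_raster(out, tmpl$band_names, tmpl$pixel_size_m, tmpl$geotransform,
               tmpl$crs, nodata = NULL)
}

#' Append NDVI and GNDVI bands to an optical raster
#'
#' NDVI = (NIR - Red)/(NIR + Red); GNDVI = (NIR - Green)/(NIR + Green).
#' Zero-denominator pixels are defined as 0. Both indices lie in [-1, 1] for
#' non-negative reflectances; NDVI tracks greenness, GNDVI chlorophyll, which
#' together help separate seasonally deciduous dry forest from open fields.
#'
#' @param optical a `scene_raster` with bands named Red, Green and NIR.
#' @return the input raster with `NDVI` and `GNDVI` bands appended.
#' @export
compute_indices <- function(optical) {
  stopifnot(inherits(optical, "scene_raster"))
  for (b in c("Red", "Green", "NIR"))
    if (!b %in% optical$band_names) stop("missing band: '", b, "'")
  nir <- scene_band(optical, "NIR")
  red <- scene_band(optical, "Red")
  green <- scene_band(optical, "Green")
  nd <- function(a, b) {
    den <- a + b
    out <- ifelse(den == 0, 0, (a - b) / den)
    out[is.na(den)] <- NA
    out
  }
  grid <- array(c(optical$grid, nd(nir, red), nd(nir, green)),
                c(dim(optical$grid)[1:2], dim(optical$grid)[3L] + 2L))
  scene_raster(grid, c(optical$band_names, "NDVI", "GNDVI"),
               optical$pixel_size_m, optical$geotransform, optical$crs,
               optical$nodata)
}

#' Fit global min-max normalization statistics on training data only
#'
#' Scans every training patch (or raster) and records the per-band minimum
#' and maximum. These frozen statistics define the global scaling to [0,1]
#' that is later applied unchanged to validation, test and inference-year
#' imagery, so no information from held-out data leaks into the scaling.
#'
#' @param train_patches list of `scene_raster`s (or numeric arrays) drawn
#'   from the training split only; all must share the band count.
#' @return object of class `norm_stats`: list with `min` and `max` vectors
#'   (one entry per band) and `band_names`.
#' @export
fit_normalization <- function(train_patches) {
  if (length(train_patches) == 0L) stop("need at least one training patch")
  as_arr <- function(p) if (inherits(p, "scene_raster")) p$grid else p
  nb <- dim(as_arr(train_patches[[1L]]))[3L]
  mn <- rep(Inf, nb); mx <- rep(-Inf, nb)
  for (p in train_patches) {
    a <- as_arr(p)
    if (dim(a)[3L] != nb) stop("band count mismatch across patches")
    for (b in seq_len(nb)) {
      v <- a[, , b]
      v <- v[!is.na(v)]
      if (length(v)) {
        mn[b] <- min(mn[b], min(v))
        mx[b] <- max(mx[b], max(v))
      }
    }
  }
  if (any(!is.finite(mn)))
    stop("band ", which(!is.finite(mn))[1L], " is all-nodata in training data")
  bn <- if (inherits(train_patches[[1L]], "scene_raster"))
    train_patches[[1L]]$band_names else paste0("band", seq_len(nb))
  structure(list(min = mn, max = mx, band_names = bn), class = "norm_stats")
}

#' Apply frozen normalization statistics, clipping to [0,1]
#'
#' `x -> (x - min)/(max - min)`, clipped to [0,1] so out-of-range values in
#' held-out data keep the documented range contract. A degenerate band
#' (max = min) maps to 0 everywhere.
#'
#' @param raster a `scene_raster` (or numeric array) to normalize.
#' @param stats a `norm_stats` from [`fit_normalization()`].
#' @return object of the same type, values in [0,1].
#' @export
apply_normalization <- function(raster, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  is_sr <- inherits(raster, "scene_raster")
  a <- if (is_sr) raster$grid else raster
  if (dim(a)[3L] != length(stats$min))
    stop("band mismatch: raster has ", dim(a)[3L], " bands, stats have ",
         length(stats$min))
  for (b in seq_len(dim(a)[3L])) {
    rng <- stats$max[b] - stats$min[b]
    a[, , b] <- if (rng == 0) 0 * a[, , b]
      else pmin(pmax((a[, , b] - stats$min[b]) / rng, 0), 1)
  }
  if (is_sr) { raster$grid <- a; raster } else a
}

#' Chunk a paired scene into co-indexed optical/SAR patch windows
#'
#' Lays a regular, non-overlapping grid of `optical_patch`-pixel windows over
#' the fine grid with matching half-size windows on the coarse SAR grid
#' (constant ground footprint across sensors). Incomplete edge windows are
#' dropped, and the drop count is recorded. Patches are grouped into square
#' tiles of `tile_patches` x `tile_patches` adjacent patches; whole tiles are
#' later allocated to a single split to limit spatial-autocorrelation leakage.
#'
#' @param optical fine-grid `scene_raster`.
#' @param sar coarse-grid `scene_raster`, exactly half the optical resolution.
#' @param labels optional fine-grid label raster (same extent as `optical`).
#' @param optical_patch fine-grid patch side in pixels (even; default 576,
#'   i.e. 288 SAR pixels — a ~2.88 km ground footprint at 5 m).
#' @param tile_patches tile side, in patches (default 2).
#' @return object of class `patch_set`: a data.frame with one row per patch
#'   (`patch_id`, `tile_id`, 0-based half-open window origins `opt_row`,
#'   `opt_col`, `sar_row`, `sar_col`, sizes, and `split = NA`), with the
#'   source rasters and drop count in attributes.
#' @export
chunk_scene <- function(optical, sar, labels = NULL, optical_patch = 576L,
                        tile_patches = 2L) {
  stopifnot(inherits(optical, "scene_raster"), inherits(sar, "scene_raster"))
  do <- dim(optical$grid); ds <- dim(sar$grid)
  if (do[1L] %/% 2L != ds[1L] || do[2L] %/% 2L != ds[2L] ||
      do[1L] %% 2L != 0L || do[2L] %% 2L != 0L)
    stop("misaligned extents: optical must be exactly 2x the SAR grid")
  if (!is.null(labels) && !identical(dim(labels$grid)[1:2], do[1:2]))
    stop("misaligned extents: labels must match the optical grid")
  optical_patch <- as.integer(optical_patch)
  if (optical_patch %% 2L != 0L) stop("optical_patch must be even")
  sar_patch <- optical_patch %/% 2L
  n_r <- do[1L] %/% optical_patch
  n_c <- do[2L] %/% optical_patch
  if (n_r < 1L || n_c < 1L) stop("scene smaller than one patch")
  pr <- rep(seq_len(n_r) - 1L, times = n_c)
  pc <- rep(seq_len(n_c) - 1L, each = n_r)
  tiles <- (pr %/% tile_patches) + (pc %/% tile_patches) *
    ((n_r + tile_patches - 1L) %/% tile_patches)
  ps <- data.frame(
    patch_id = seq_along(pr),
    tile_id = tiles,
    opt_row = pr * optical_patch, opt_col = pc * optical_patch,
    sar_row = pr * sar_patch, sar_col = pc * sar_patch,
    opt_size = optical_patch, sar_size = sar_patch,
    split = NA_character_)
  attr(ps, "dropped_edge") <- as.integer(
    ceiling(do[1L] / optical_patch) * ceiling(do[2L] / optical_patch) - n_r * n_c)
  attr(ps, "optical") <- optical
  attr(ps, "sar") <- sar
  attr(ps, "labels") <- labels
  class(ps) <- c("patch_set", "data.frame")
  ps
}

# Largest-remainder apportionment of n items to the given shares.
largest_remainder <- function(n, shares) {
  quota <- n * shares
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    order_frac <- order(quota - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1L
  }
  as.integer(base)
}

#' Assign tile-grouped train/validation/test splits
#'
#' Two-stage split at whole-tile granularity: 30% of tiles are held out as an
#' untouched test set; of the remaining pool, 85% go to training and 15% to
#' validation (largest-remainder rounding at each stage), yielding overall
#' shares near 59.5% / 10.5% / 30%. Every patch in a tile shares the tile's
#' split, limiting leakage between spatially adjacent patches.
#'
#' @param patchset a `patch_set` from [`chunk_scene()`] (or any data.frame
#'   with `patch_id` and `tile_id` columns).
#' @param seed RNG seed for the tile shuffle.
#' @param test_share,train_share_of_pool stage proportions (defaults 0.30
#'   and 0.85).
#' @return the `patch_set` with `split` filled in (`train`/`val`/`test`).
#' @export
split_patches <- function(patchset, seed = 1L, test_share = 0.30,
                          train_share_of_pool = 0.85) {
  tiles <- unique(patchset$tile_id)
  if (length(tiles) < 3L) stop("need at least 3 tiles to form three splits")
  set.seed(seed)
  tiles <- sample(tiles)
  n <- length(tiles)
  n_test <- largest_remainder(n, c(test_share, 1 - test_share))[1L]
  pool <- n - n_test
  n_train <- largest_remainder(pool, c(train_share_of_pool,
                                       1 - train_share_of_pool))[1L]
  split_of_tile <- setNames(
    rep(c("test", "train", "val"), c(n_test, n_train, pool - n_train)), tiles)
  patchset$split <- unname(split_of_tile[as.character(patchset$tile_id)])
  patchset
}

#' Resample a raster by an integer factor
#'
#' Three modes: `maxpool_down` (blockwise maximum), `meanpool_down`
#' (blockwise mean), and `bilinear_up` (bilinear interpolation with pixel
#' centres aligned under the pixel-is-area convention, edge-clamped). Down
#' modes require dimensions divisible by the factor.
#'
#' @param raster a `scene_raster` or numeric matrix/array.
#' @param factor integer >= 1.
#' @param mode one of `"maxpool_down"`, `"meanpool_down"`, `"bilinear_up"`.
#' @return resampled object of the same type.
#' @export
resample_raster <- function(raster, factor,
                            mode = c("maxpool_down", "bilinear_up",
                                     "meanpool_down")) {
  mode <- match.arg(mode)
  factor <- as.integer(factor)
  if (factor < 1L) stop("factor must be a positive integer")
  is_sr <- inherits(raster, "scene_raster")
  a <- if (is_sr) raster$grid else raster
  was_mat <- is.matrix(a)
  if (was_mat) a <- array(a, c(dim(a), 1L))
  if (factor == 1L) {
    out <- a
  } else if (mode %in% c("maxpool_down", "meanpool_down")) {
    d <- dim(a)
    if (d[1L] %% factor != 0L || d[2L] %% factor != 0L)
      stop("dimensions not divisible by factor for pooling")
    h <- d[1L] %/% factor; w <- d[2L] %/% factor
    fun <- if (mode == "maxpool_down") max else mean
    out <- array(0, c(h, w, d[3L]))
    for (b in seq_len(d[3L])) {
      m <- a[, , b]
      # reshape blocks: factor x h x factor x w
      blk <- array(m, c(factor, h, factor, w))
      out[, , b] <- apply(blk, c(2L, 4L), fun)
    }
  } else {  # bilinear_up
    d <- dim(a)
    h <- d[1L] * factor; w <- d[2L] * factor
    # output pixel centre in input pixel coordinates (pixel-is-area)
    src_r <- ((seq_len(h) - 0.5) / factor) + 0.5
    src_c <- ((seq_len(w) - 0.5) / factor) + 0.5
    r0 <- pmin(pmax(floor(src_r), 1L), d[1L]); r1 <- pmin(r0 + 1L, d[1L])
    c0 <- pmin(pmax(floor(src_c), 1L), d[2L]); c1 <- pmin(c0 + 1L, d[2L])
    fr <- pmin(pmax(src_r - r0, 0), 1); fc <- pmin(pmax(src_c - c0, 0), 1)
    out <- array(0, c(h, w, d[3L]))
    for (b in seq_len(d[3L])) {
      m <- a[, , b]
      top <- m[r0, c0, drop = FALSE] * outer(1 - fr, 1 - fc) +
             m[r0, c1, drop = FALSE] * outer(1 - fr, fc)
      bot <- m[r1, c0, drop = FALSE] * outer(fr, 1 - fc) +
             m[r1, c1, drop = FALSE] * outer(fr, fc)
      out[, , b] <- top + bot
    }
  }
  if (was_mat) out <- out[, , 1L]
  if (is_sr) {
    s <- if (mode == "bilinear_up") 1 / factor else factor
    raster$grid <- if (is.matrix(out)) array(out, c(dim(out), 1L)) else out
    raster$pixel_size_m <- raster$pixel_size_m * s
    raster$geotransform[c(2L, 6L)] <- raster$geotransform[c(2L, 6L)] * s
    raster
  } else out
}

#' Extract the pixel arrays for one patch of a patch set
#'
#' @param patchset a `patch_set` carrying its source rasters.
#' @param patch_id patch id to extract.
#' @return list with `optical`, `sar` (arrays) and `labels` (matrix or NULL).
#' @export
get_patch <- function(patchset, patch_id) {
  row <- patchset[patchset$patch_id == patch_id, ]
  if (nrow(row) != 1L) stop("unknown patch_id ", patch_id)
  opt <- attr(patchset, "optical"); sar <- attr(patchset, "sar")
  lab <- attr(patchset, "labels")
  oi <- row$opt_row + seq_len(row$opt_size)
  oj <- row$opt_col + seq_len(row$opt_size)
  si <- row$sar_row + seq_len(row$sar_size)
  sj <- row$sar_col + seq_len(row$sar_size)
  list(optical = opt$grid[oi, oj, , drop = FALSE],
       sar = sar$grid[si, sj, , drop = FALSE],
       labels = if (is.null(lab)) NULL else lab$grid[oi, oj, 1L])
}

#' Write a patch-set manifest as CSV
#'
#' @param patchset a `patch_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_patchset_csv <- function(patchset, path) {
  write.csv(as.data.frame(patchset), path, row.names = FALSE)
  invisible(path)
}
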