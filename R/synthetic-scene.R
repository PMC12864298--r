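#' Configuration for the paired-scene simulator
#'
#' Describes a synthetic landscape with `n_classes` land-cover classes
#' (default roster: 0 = other, 1 = urban, 2 = agriculture, 3 = forest,
#' 4 = water, 5 = tropical dry forest) observed by two sensors: a 4-band
#' optical instrument (Red, Green, Blue, NIR reflectance in [0,1]) on the fine
#' grid and a 4-band SAR backscatter composite (VV, HH, VV+VH, HH+HV, linear
#' power > 0) on a grid of exactly half the resolution. Optical noise is
#' additive Gaussian; SAR noise is multiplicative gamma speckle with
#' `speckle_looks` looks (mean 1, variance 1/L). The label field is a smoothed
#' Gaussian random field quantile-thresholded into classes, which produces the
#' fragmented patch mosaic typical of dry-forest landscapes.
#'
#' @param height_px,width_px fine-grid dimensions; both must be even so the
#'   SAR grid is exactly half resolution.
#' @param n_classes number of classes (>= 2), ids `0:(n_classes-1)`.
#' @param class_spectra numeric matrix `n_classes x 8`: per-class means for
#'   the 4 optical bands (reflectance) followed by the 4 SAR bands (linear
#'   backscatter, all > 0). Rows in class-id order. `NULL` uses a built-in
#'   separable roster for 6 classes.
#' @param optical_noise_sd standard deviation of additive optical noise.
#' @param speckle_looks number of looks L >= 1 for gamma speckle; `Inf`
#'   disables speckle.
#' @param smoothness correlation length (Gaussian kernel sd, fine pixels) of
#'   the label random field; 0 gives per-pixel independent labels.
#' @param change_fraction default fraction of a source class converted per
#'   epoch transition in [`generate_series()`].
#' @param pixel_size_m fine-grid pixel size in metres (SAR = 2x this).
#' @param seed default RNG seed for the generator functions.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(height_px = 128L, width_px = 128L, n_classes = 6L,
                         class_spectra = NULL, optical_noise_sd = 0.02,
                         speckle_looks = 4, smoothness = 6,
                         change_fraction = 0.1, pixel_size_m = 5,
                         seed = 1L) {
  height_px <- as.integer(height_px); width_px <- as.integer(width_px)
  n_classes <- as.integer(n_classes)
  if (n_classes < 2L) stop("n_classes must be >= 2")
  if (height_px %% 2L != 0L || width_px %% 2L != 0L)
    stop("height_px and width_px must be even (SAR grid is half resolution)")
  if (is.null(class_spectra)) class_spectra <- default_class_spectra(n_classes)
  class_spectra <- as.matrix(class_spectra)
  if (nrow(class_spectra) != n_classes || ncol(class_spectra) != 8L)
    stop("class_spectra must be n_classes x 8 (4 optical + 4 SAR means)")
  if (any(class_spectra[, 5:8] <= 0))
    stop("all SAR class means must be > 0 (linear backscatter)")
  if (change_fraction < 0 || change_fraction > 1)
    stop("change_fraction must lie in [0, 1]")
  if (!is.infinite(speckle_looks) && speckle_looks < 1)
    stop("speckle_looks must be >= 1 (or Inf to disable speckle)")
  structure(
    list(height_px = height_px, width_px = width_px, n_classes = n_classes,
         class_spectra = class_spectra, optical_noise_sd = optical_noise_sd,
         speckle_looks = speckle_looks, smoothness = smoothness,
         change_fraction = change_fraction, pixel_size_m = pixel_size_m,
         seed = as.integer(seed)),
    class = "scene_config")
}

# Built-in class roster: {0 other, 1 urban, 2 agriculture, 3 forest, 4 water,
# 5 TDF}. Means are chosen for separability (the point of the simulator is a
# known answer, not radiometric realism): optical reflectances are ordered as
# a field scientist would expect (water dark, urban bright, vegetation
# NIR-high) and SAR backscatter separates smooth (water), volume-scattering
# (forest/TDF) and double-bounce (urban) surfaces.
default_class_spectra <- function(n_classes = 6L) {
  base <- rbind(
    other       = c(0.30, 0.28, 0.26, 0.35, 0.30, 0.28, 0.58, 0.56),
    urban       = c(0.55, 0.52, 0.50, 0.45, 0.80, 0.85, 1.60, 1.70),
    agriculture = c(0.20, 0.30, 0.12, 0.55, 0.20, 0.18, 0.40, 0.36),
    forest      = c(0.06, 0.12, 0.05, 0.70, 0.45, 0.42, 0.90, 0.84),
    water       = c(0.04, 0.06, 0.08, 0.03, 0.04, 0.05, 0.09, 0.10),
    tdf         = c(0.12, 0.18, 0.08, 0.48, 0.32, 0.30, 0.66, 0.60))
  if (n_classes <= 6L) return(base[seq_len(n_classes), , drop = FALSE])
  extra <- t(vapply(seq_len(n_classes - 6L), function(i) {
    f <- 0.5 + 0.5 * i / (n_classes - 5L)
    c(pmin(base[1L, 1:4] * f + 0.1 * i / n_classes, 1), base[1L, 5:8] * f)
  }, numeric(8L)))
  rbind(base, extra)
}

optical_band_names <- c("Red", "Green", "Blue", "NIR")
sar_band_names <- c("VV", "HH", "VV+VH", "HH+HV")

# Separable Gaussian smoothing of a matrix with edge-renormalized weights.
smooth_field <- function(m, sd) {
  if (sd <= 0) return(m)
  half <- max(1L, ceiling(3 * sd))
  k <- dnorm(seq(-half, half), sd = sd)
  kernel_matrix <- function(n) {
    idx <- outer(seq_len(n), seq(-half, half), `+`)
    km <- matrix(0, n, n)
    for (j in seq_along(k)) {
      ok <- idx[, j] >= 1L & idx[, j] <= n
      km[cbind(which(ok), idx[ok, j])] <- km[cbind(which(ok), idx[ok, j])] + k[j]
    }
    km / rowSums(km)
  }
  kernel_matrix(nrow(m)) %*% m %*% t(kernel_matrix(ncol(m)))
}

#' Generate a categorical label map as a thresholded random field
#'
#' White noise on the fine grid is smoothed with a separable Gaussian kernel
#' of sd `config$smoothness` pixels and cut at empirical quantiles into
#' `n_classes` contiguous-blob classes with (near-)equal area shares, so every
#' class holds at least 1% of pixels for any usable class count.
#'
#' @param config a [`scene_config()`].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return single-band integer `scene_raster` of class ids in
#'   `0:(n_classes-1)`.
#' @export
generate_label_map <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  set.seed(seed)
  z <- matrix(rnorm(config$height_px * config$width_px),
              config$height_px, config$width_px)
  z <- smooth_field(z, config$smoothness)
  qs <- quantile(z, probs = seq_len(config$n_classes - 1L) / config$n_classes,
                 names = FALSE)
  lab <- matrix(findInterval(z, qs), nrow(z), ncol(z))
  scene_raster(lab, band_names = "class", pixel_size_m = config$pixel_size_m,
               crs = "synthetic")
}

# 2x2 block mean of a matrix (pixel-is-area, top-left aligned).
block_mean2 <- function(m) {
  h <- nrow(m) %/% 2L; w <- ncol(m) %/% 2L
  0.25 * (m[2 * seq_len(h) - 1L, 2 * seq_len(w) - 1L, drop = FALSE] +
          m[2 * seq_len(h),      2 * seq_len(w) - 1L, drop = FALSE] +
          m[2 * seq_len(h) - 1L, 2 * seq_len(w),      drop = FALSE] +
          m[2 * seq_len(h),      2 * seq_len(w),      drop = FALSE])
}

#' Render optical and SAR observations of a label map
#'
#' Optical: per-pixel class mean reflectance plus additive Gaussian noise,
#' clipped to [0,1], on the fine grid. SAR: the per-class backscatter field is
#' block-averaged 2x2 to the coarse grid (the 5 m to 10 m correspondence is a
#' pixel-is-area block mean) and multiplied by unit-mean gamma speckle with
#' `speckle_looks` looks; `speckle_looks = Inf` renders a speckle-free scene.
#'
#' @param labels label raster from [`generate_label_map()`].
#' @param config the matching [`scene_config()`].
#' @param seed RNG seed.
#' @return list with `optical` (H x W x 4 `scene_raster`) and `sar`
#'   (H/2 x W/2 x 4 `scene_raster`).
#' @export
render_scene <- function(labels, config, seed = config$seed) {
  stopifnot(inherits(labels, "scene_raster"), inherits(config, "scene_config"))
  lab <- labels$grid[, , 1L]
  if (any(lab < 0 | lab >= config$n_classes))
    stop("label id without spectra: labels must lie in [0, n_classes)")
  set.seed(seed)
  h <- nrow(lab); w <- ncol(lab)
  cls <- lab + 1L  # 1-based row into class_spectra

  opt <- array(0, c(h, w, 4L))
  for (b in 1:4) {
    mu <- matrix(config$class_spectra[cls, b], h, w)
    opt[, , b] <- pmin(pmax(mu + rnorm(h * w, sd = config$optical_noise_sd), 0), 1)
  }

  sar <- array(0, c(h %/% 2L, w %/% 2L, 4L))
  for (b in 1:4) {
    mu_fine <- matrix(config$class_spectra[cls, b + 4L], h, w)
    mu_coarse <- block_mean2(mu_fine)
    if (is.infinite(config$speckle_looks)) {
      sar[, , b] <- mu_coarse
    } else {
      L <- config$speckle_looks
      speckle <- matrix(rgamma(length(mu_coarse), shape = L, rate = L),
                        nrow(mu_coarse), ncol(mu_coarse))
      sar[, , b] <- mu_coarse * speckle
    }
  }

  gt <- labels$geotransform
  list(
    optical = scene_raster(opt, optical_band_names,
                           pixel_size_m = config$pixel_size_m,
                           geotransform = gt, crs = "synthetic"),
    sar = scene_raster(sar, sar_band_names,
                       pixel_size_m = 2 * config$pixel_size_m,
                       geotransform = c(gt[1L], 2 * gt[2L], 0, gt[4L], 0, 2 * gt[6L]),
                       crs = "synthetic"))
}

#' Inject a contiguous class transition between two epochs
#'
#' Flips a spatially contiguous subset of `from_class` pixels to `to_class`,
#' totalling `change_fraction` of the source class (within one pixel of
#' rounding). The patch is grown by breadth-first search over 4-neighbour
#' adjacency from a random source-class seed pixel; if a connected component
#' is exhausted, growth restarts from a new random component, so highly
#' fragmented sources yield several compact change patches.
#'
#' @param labels_t1 label raster at epoch 1.
#' @param from_class,to_class class ids.
#' @param change_fraction fraction of `from_class` pixels to convert, in [0,1].
#' @param seed RNG seed.
#' @return list with `labels` (epoch-2 label raster) and `truth_mask`
#'   (logical matrix marking exactly the changed pixels).
#' @export
inject_change <- function(labels_t1, from_class, to_class, change_fraction,
                          seed = 1L) {
  stopifnot(inherits(labels_t1, "scene_raster"))
  if (change_fraction < 0 || change_fraction > 1)
    stop("change_fraction must lie in [0, 1]")
  lab <- labels_t1$grid[, , 1L]
  src <- which(lab == from_class)
  if (length(src) == 0L) stop("from_class ", from_class, " absent from labels")
  n_target <- round(change_fraction * length(src))
  h <- nrow(lab); w <- ncol(lab)
  chosen <- logical(length(lab))
  if (n_target > 0L) {
    set.seed(seed)
    is_src <- logical(length(lab)); is_src[src] <- TRUE
    visited <- logical(length(lab))
    n_chosen <- 0L
    while (n_chosen < n_target) {
      pool <- src[!visited[src]]
      queue <- integer(2L * n_target); qh <- 1L; qt <- 1L
      queue[qt] <- if (length(pool) > 1L) sample(pool, 1L) else pool
      visited[queue[qt]] <- TRUE; qt <- qt + 1L
      while (qh < qt && n_chosen < n_target) {
        p <- queue[qh]; qh <- qh + 1L
        chosen[p] <- TRUE; n_chosen <- n_chosen + 1L
        r <- (p - 1L) %% h + 1L; cc <- (p - 1L) %/% h + 1L
        for (nb in c(if (r > 1L) p - 1L, if (r < h) p + 1L,
                     if (cc > 1L) p - h, if (cc < w) p + h)) {
          if (is_src[nb] && !visited[nb]) {
            visited[nb] <- TRUE
            if (qt > length(queue)) queue <- c(queue, integer(length(queue)))
            queue[qt] <- nb; qt <- qt + 1L
          }
        }
      }
    }
  }
  lab2 <- lab
  lab2[chosen] <- as.integer(to_class)
  out <- labels_t1
  out$grid <- array(lab2, c(h, w, 1L))
  list(labels = out, truth_mask = matrix(chosen, h, w))
}

#' Generate a multi-epoch scene series with known transitions
#'
#' Epoch 1 is a fresh label map rendered to optical/SAR; each later epoch
#' applies its change specification to the previous labels and re-renders
#' both sensors with fresh observation noise (labels persist, radiometry does
#' not), mirroring a multi-year image time series over a changing landscape.
#'
#' @param config a [`scene_config()`].
#' @param epochs integer number of epochs, or a list of change specs of
#'   length `epochs - 1`, each `list(from = id, to = id, fraction = f)`
#'   (fraction defaults to `config$change_fraction`). An entry of `NULL`
#'   means no change that step.
#' @param seed RNG seed.
#' @return list of epochs, each `list(optical, sar, labels, truth_mask)`;
#'   `truth_mask` is `NULL` for the first epoch.
#' @export
generate_series <- function(config, epochs, seed = config$seed) {
  stopifnot(inherits(config, "scene_config"))
  if (is.numeric(epochs)) {
    n_ep <- as.integer(epochs)
    specs <- vector("list", max(n_ep - 1L, 0L))
  } else {
    specs <- epochs
    n_ep <- length(specs) + 1L
  }
  if (n_ep < 1L) stop("need at least one epoch")
  labels <- generate_label_map(config, seed = seed)
  out <- vector("list", n_ep)
  out[[1L]] <- c(render_scene(labels, config, seed = seed + 1000L),
                 list(labels = labels, truth_mask = NULL))
  if (n_ep > 1L) for (e in 2:n_ep) {
    sp <- specs[[e - 1L]]
    if (is.null(sp)) {
      truth <- matrix(FALSE, config$height_px, config$width_px)
    } else {
      frac <- if (is.null(sp$fraction)) config$change_fraction else sp$fraction
      ch <- inject_change(labels, sp$from, sp$to, frac, seed = seed + 2000L + e)
      labels <- ch$labels
      truth <- ch$truth_mask
    }
    out[[e]] <- c(render_scene(labels, config, seed = seed + 1000L + e),
                  list(labels = labels, truth_mask = truth))
  }
  out
}
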