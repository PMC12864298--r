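# Shared fixtures and independent oracles for the test suite.

# Small rendered scene with indices appended; returns config, labels, rasters.
make_scene <- function(height = 64, width = 64, noise = 0.02, looks = 4,
                       smoothness = 5, seed = 11) {
  cfg <- scene_config(height_px = height, width_px = width,
                      optical_noise_sd = noise, speckle_looks = looks,
                      smoothness = smoothness, seed = seed)
  lab <- generate_label_map(cfg)
  sc <- render_scene(lab, cfg)
  list(config = cfg, labels = lab, optical = compute_indices(sc$optical),
       sar = sc$sar)
}

# Normalized train/val/test sample lists from one scene.
make_patch_samples <- function(scene, optical_patch = 16L, split_seed = 4) {
  ps <- chunk_scene(scene$optical, scene$sar, scene$labels,
                    optical_patch = optical_patch, tile_patches = 2L)
  ps <- split_patches(ps, seed = split_seed)
  ids <- function(s) ps$patch_id[ps$split == s]
  ostats <- fit_normalization(lapply(ids("train"),
    function(id) get_patch(ps, id)$optical))
  sstats <- fit_normalization(lapply(ids("train"),
    function(id) get_patch(ps, id)$sar))
  mk <- function(id) {
    p <- get_patch(ps, id)
    list(optical = apply_normalization(p$optical, ostats),
         sar = apply_normalization(p$sar, sstats), labels = p$labels)
  }
  list(train = lapply(ids("train"), mk), val = lapply(ids("val"), mk),
       test = lapply(ids("test"), mk), patchset = ps,
       ostats = ostats, sstats = sstats)
}

# Brute-force median of a vector with NAs: sort and take the middle
# (mean of the two middles for even counts). Independent of stats::median.
oracle_median <- function(v) {
  v <- sort(v[!is.na(v)])
  n <- length(v)
  if (n == 0L) return(NA_real_)
  if (n %% 2L == 1L) v[(n + 1L) %/% 2L] else (v[n %/% 2L] + v[n %/% 2L + 1L]) / 2
}

# Direct per-cell evaluation of the Gi* formula with an explicit double loop.
oracle_gi_star <- function(x, band_radius) {
  n <- length(x)
  xbar <- mean(x); s <- sqrt(mean(x^2) - xbar^2)
  h <- nrow(x); w <- ncol(x)
  z <- matrix(0, h, w)
  if (s == 0) return(z)
  for (i1 in seq_len(h)) for (j1 in seq_len(w)) {
    wsum <- 0; wi <- 0
    for (i2 in seq_len(h)) for (j2 in seq_len(w)) {
      if ((i1 - i2)^2 + (j1 - j2)^2 <= band_radius^2) {
        wsum <- wsum + x[i2, j2]; wi <- wi + 1
      }
    }
    den <- s * sqrt((n * wi - wi^2) / (n - 1))
    z[i1, j1] <- if (den == 0) 0 else (wsum - xbar * wi) / den
  }
  z
}

# Blockwise maximum by explicit loops.
oracle_maxpool <- function(m, f) {
  h <- nrow(m) %/% f; w <- ncol(m) %/% f
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    out[i, j] <- max(m[((i - 1) * f + 1):(i * f), ((j - 1) * f + 1):(j * f)])
  out
}

# Tiny deterministic "model stub": the truth map with a stated fraction of
# pixels flipped to a random other class.
noisy_map_stub <- function(truth, flip_rate, n_classes, seed) {
  set.seed(seed)
  out <- truth
  n <- length(out)
  flip <- sample(n, round(flip_rate * n))
  out[flip] <- (out[flip] + sample(n_classes - 1L, length(flip),
                                   replace = TRUE)) %% n_classes
  out
}
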