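test_that("temporal median composite matches the brute-force oracle", {
  # identity on a single raster
  r <- scene_raster(array(runif(24), c(4, 3, 2)))
  expect_equal(temporal_median_composite(list(r))$grid, r$grid)
  # odd-count median: {1,2,3} -> 2
  st <- lapply(1:3, function(v) scene_raster(array(v, c(2, 2, 1))))
  expect_true(all(temporal_median_composite(st)$grid == 2))
  # randomized stacks with random validity masks vs sorted-middle oracle
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(1:5, 1)
    stack <- lapply(seq_len(n), function(i) scene_raster(array(rnorm(12), c(2, 3, 2))))
    masks <- lapply(seq_len(n), function(i) matrix(runif(6) > 0.3, 2, 3))
    out <- temporal_median_composite(stack, masks)$grid
    for (i in 1:2) for (j in 1:3) for (b in 1:2) {
      vals <- vapply(seq_len(n), function(q)
        if (masks[[q]][i, j]) stack[[q]]$grid[i, j, b] else NA_real_, numeric(1))
      expect_equal(out[i, j, b], oracle_median(vals))
    }
  }
  expect_error(temporal_median_composite(list()), "empty")
  expect_error(temporal_median_composite(list(
    scene_raster(array(0, c(2, 2, 1))), scene_raster(array(0, c(3, 2, 1))))),
    "shape")
})

test_that("NDVI and GNDVI follow the normalized-difference formula", {
  g <- array(0, c(1, 3, 4))
  #              Red  Green Blue NIR
  g[1, 1, ] <- c(0.2, 0.3, 0.1, 0.6)
  g[1, 2, ] <- c(0.5, 0.2, 0.1, 0.5)  # NIR = Red -> NDVI 0
  g[1, 3, ] <- c(0.0, 0.0, 0.1, 0.4)  # Red = 0  -> NDVI 1, GNDVI 1
  r <- scene_raster(g, c("Red", "Green", "Blue", "NIR"))
  out <- compute_indices(r)
  ndvi <- scene_band(out, "NDVI"); gndvi <- scene_band(out, "GNDVI")
  expect_equal(ndvi[1, 1], 0.5)
  expect_equal(gndvi[1, 1], 1 / 3)
  expect_equal(ndvi[1, 2], 0)
  expect_equal(ndvi[1, 3], 1)
  expect_true(all(ndvi >= -1 & ndvi <= 1))
  # zero denominator -> 0 by convention
  z <- scene_raster(array(0, c(1, 1, 4)), c("Red", "Green", "Blue", "NIR"))
  expect_equal(as.vector(scene_band(compute_indices(z), "NDVI")), 0)
  expect_error(compute_indices(scene_raster(array(0, c(1, 1, 2)), c("a", "b"))),
               "Red")
})

test_that("normalization stats come from training data only and clip", {
  tr <- list(array(c(0, 50, 200, 100), c(2, 2, 1)))
  st <- fit_normalization(tr)
  expect_equal(st$min, 0); expect_equal(st$max, 200)
  # constant band
  stc <- fit_normalization(list(array(7, c(2, 2, 1))))
  expect_equal(stc$min, stc$max)
  expect_true(all(apply_normalization(array(7, c(2, 2, 1)), stc) == 0))
  # formula, boundaries, clipping of out-of-range held-out values
  x <- array(c(0, 100, 200, 250), c(2, 2, 1))
  y <- apply_normalization(x, st)
  expect_equal(as.vector(y), c(0, 0.5, 1, 1))
  # training data attains both 0 and 1 after normalization
  ytr <- apply_normalization(tr[[1]], st)
  expect_equal(range(ytr), c(0, 1))
  expect_error(apply_normalization(array(0, c(2, 2, 2)), st), "mismatch")
})

test_that("chunk_scene lays a 2:1 co-indexed grid and drops edges", {
  opt <- scene_raster(array(0, c(1152, 1152, 1)), pixel_size_m = 5)
  sar <- scene_raster(array(0, c(576, 576, 1)), pixel_size_m = 10)
  ps <- chunk_scene(opt, sar)
  expect_equal(nrow(ps), 4)
  expect_true(all(ps$opt_row == 2 * ps$sar_row & ps$opt_col == 2 * ps$sar_col))
  expect_true(all(ps$opt_size == 2 * ps$sar_size))
  # exactly one patch extent
  one <- chunk_scene(scene_raster(array(0, c(576, 576, 1))),
                     scene_raster(array(0, c(288, 288, 1))))
  expect_equal(nrow(one), 1)
  # 600x600: one patch, edge remnants dropped
  part <- chunk_scene(scene_raster(array(0, c(600, 600, 1))),
                      scene_raster(array(0, c(300, 300, 1))))
  expect_equal(nrow(part), 1)
  expect_gt(attr(part, "dropped_edge"), 0)
  # windows tile the cropped extent exactly, non-overlapping
  sc <- make_scene(64, 96, seed = 2)
  ps2 <- chunk_scene(sc$optical, sc$sar, sc$labels, optical_patch = 32)
  cover <- matrix(0L, 64, 96)
  for (i in seq_len(nrow(ps2)))
    cover[ps2$opt_row[i] + 1:32, ps2$opt_col[i] + 1:32] <-
      cover[ps2$opt_row[i] + 1:32, ps2$opt_col[i] + 1:32] + 1L
  expect_true(all(cover == 1L))
  expect_error(chunk_scene(opt, scene_raster(array(0, c(575, 576, 1)))),
               "misaligned")
})

test_that("tile-grouped splits hit the two-stage shares exactly", {
  # 1000 single-patch tiles -> 595 / 105 / 300
  fake <- data.frame(patch_id = 1:1000, tile_id = 1:1000)
  sp <- split_patches(fake, seed = 1)
  expect_equal(as.vector(table(sp$split)[c("train", "val", "test")]),
               c(595, 105, 300))
  # determinism
  sp2 <- split_patches(fake, seed = 1)
  expect_identical(sp$split, sp2$split)
  # partition + tile exclusivity over several seeds on a multi-patch tiling
  sc <- make_scene(96, 96, seed = 3)
  ps <- chunk_scene(sc$optical, sc$sar, sc$labels, optical_patch = 16)
  for (seed in 1:5) {
    s <- split_patches(ps, seed = seed)
    expect_false(any(is.na(s$split)))
    per_tile <- tapply(s$split, s$tile_id, function(x) length(unique(x)))
    expect_true(all(per_tile == 1))
  }
  expect_error(split_patches(data.frame(patch_id = 1:2, tile_id = 1:2)),
               "tiles")
})

test_that("resampling modes follow their block and interpolation rules", {
  m <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]]
  expect_equal(resample_raster(m, 2, "maxpool_down"), matrix(4, 1, 1)[1, 1],
               ignore_attr = TRUE)
  expect_equal(as.vector(resample_raster(m, 2, "meanpool_down")), 2.5)
  # constant rasters map to constants in all modes
  cst <- matrix(3.3, 4, 4)
  for (mode in c("maxpool_down", "meanpool_down", "bilinear_up"))
    expect_true(all(resample_raster(cst, 2, mode) == 3.3))
  # factor 1 identity
  expect_equal(resample_raster(m, 1, "bilinear_up"), m)
  # maxpool equals the explicit block-max oracle on random instances
  set.seed(7)
  for (rep in 1:50) {
    f <- sample(2:3, 1)
    mm <- matrix(rnorm(12 * f * f), 4 * f, 3 * f)[1:(4 * f), 1:(3 * f)]
    mm <- matrix(rnorm((4 * f) * (3 * f)), 4 * f, 3 * f)
    expect_equal(resample_raster(mm, f, "maxpool_down"), oracle_maxpool(mm, f))
  }
  # bilinear up-sampling is exact for an affine field (away from clamped edges)
  aff <- outer(1:8, 1:6, function(i, j) 2 * i + 3 * j)
  up <- resample_raster(aff, 2, "bilinear_up")
  exp_val <- function(i, j) 2 * ((i - 0.5) / 2 + 0.5) + 3 * ((j - 0.5) / 2 + 0.5)
  for (i in 3:14) for (j in 3:10) expect_equal(up[i, j], exp_val(i, j))
  expect_error(resample_raster(matrix(0, 3, 3), 2, "maxpool_down"),
               "divisible")
  # scene_raster metadata updated
  r <- scene_raster(array(0, c(4, 4, 1)), pixel_size_m = 10)
  expect_equal(resample_raster(r, 2, "bilinear_up")$pixel_size_m, 5)
})
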