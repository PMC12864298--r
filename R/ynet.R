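#' Configuration of the dual-encoder segmentation network
#'
#' The Y-Net consumes a fine-resolution optical patch (6 channels: Red,
#' Green, Blue, NIR plus NDVI and GNDVI) and a coarse SAR patch (4 channels)
#' whose side is exactly half the optical side. Each sensor has its own input
#' stem; the optical stem is max-pooled once so both feature maps share the
#' coarse grid, where they are fused early by channel concatenation. A shared
#' U-Net-style encoder-decoder follows, with skip connections from the shared
#' encoder and from both stems, and a final 2x up-sampling so logits land on
#' the fine (optical) grid.
#'
#' @param optical_channels fine-grid input channels (default 6).
#' @param sar_channels coarse-grid input channels (default 4).
#' @param n_classes output classes (default 6).
#' @param base_width stem width; channel counts double per encoder level
#'   (default 16, a desk-scale setting; 64 for full scale).
#' @param depth number of scales in the shared encoder (>= 2, default 4).
#'   Optical patch sides must be divisible by `2^depth`.
#' @return an object of class `ynet_config`.
#' @export
ynet_config <- function(optical_channels = 6L, sar_channels = 4L,
                        n_classes = 6L, base_width = 16L, depth = 4L) {
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be >= 2")
  if (n_classes < 2L) stop("n_classes must be >= 2")
  structure(list(optical_channels = as.integer(optical_channels),
                 sar_channels = as.integer(sar_channels),
                 n_classes = as.integer(n_classes),
                 base_width = as.integer(base_width), depth = depth),
            class = "ynet_config")
}

# Shared-encoder channel width at scale l (1 = coarse/fusion scale).
shared_width <- function(config, l, fused_width) fused_width * 2^(l - 1L)

#' Build the dual-encoder Y-Net
#'
#' @param config a [`ynet_config()`].
#' @param seed RNG seed for weight initialization (He-normal).
#' @return object of class `seg_model` with `arch = "ynet"`. Its
#'   `n_parameters` field reports the trainable parameter count.
#' @export
build_ynet <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ynet_config"))
  set.seed(seed)
  w <- config$base_width
  fw <- 2L * w  # channels after stem fusion
  enc <- vector("list", config$depth)
  enc[[1L]] <- new_block(fw, fw)
  if (config$depth > 1L) for (l in 2:config$depth)
    enc[[l]] <- new_block(shared_width(config, l - 1L, fw),
                          shared_width(config, l, fw))
  dec <- vector("list", config$depth - 1L)
  for (l in seq_len(config$depth - 1L)) {
    skip_ch <- shared_width(config, l, fw) + if (l == 1L) w else 0L
    dec[[l]] <- new_block(shared_width(config, l + 1L, fw) + skip_ch,
                          shared_width(config, l, fw))
  }
  m <- structure(list(
    arch = "ynet", config = config,
    opt_stem = new_block(config$optical_channels, w),
    sar_stem = new_block(config$sar_channels, w),
    enc = enc, dec = dec,
    fine_block = new_block(fw + w, w),
    head = new_conv(w, config$n_classes, k = 1L)), class = "seg_model")
  m$n_parameters <- sum(vapply(collect_layers(m[c(
    "opt_stem", "sar_stem", "enc", "dec", "fine_block", "head")]),
    count_layer_params, numeric(1)))
  m
}

#' Build the single-stream concatenation baseline (U-Net)
#'
#' The optical patch is max-pooled 2x onto the coarse SAR grid and the two
#' stacks are concatenated into one 10-channel input to a standard U-Net; the
#' decoder finishes with a 2x up-sampling stage so outputs are at the fine
#' resolution, making the baseline directly comparable to the Y-Net.
#'
#' @inheritParams build_ynet
#' @return object of class `seg_model` with `arch = "unet_concat"`.
#' @export
build_unet_concat <- function(config, seed = 1L) {
  stopifnot(inherits(config, "ynet_config"))
  set.seed(seed)
  w <- config$base_width
  width <- function(l) w * 2^(l - 1L)
  enc <- vector("list", config$depth)
  enc[[1L]] <- new_block(config$optical_channels + config$sar_channels, w)
  if (config$depth > 1L) for (l in 2:config$depth)
    enc[[l]] <- new_block(width(l - 1L), width(l))
  dec <- vector("list", config$depth - 1L)
  for (l in seq_len(config$depth - 1L))
    dec[[l]] <- new_block(width(l + 1L) + width(l), width(l))
  m <- structure(list(
    arch = "unet_concat", config = config,
    enc = enc, dec = dec,
    fine_block = new_block(w, w),
    head = new_conv(w, config$n_classes, k = 1L)), class = "seg_model")
  m$n_parameters <- sum(vapply(collect_layers(m[c(
    "enc", "dec", "fine_block", "head")]), count_layer_params, numeric(1)))
  m
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> arch=%s, base_width=%d, depth=%d, %s parameters\n",
              x$arch, x$config$base_width, x$config$depth,
              format(x$n_parameters, big.mark = ",")))
  invisible(x)
}

model_layers <- function(model) {
  keep <- setdiff(names(model), c("arch", "config", "n_parameters"))
  collect_layers(model[keep])
}

check_patch_shapes <- function(model, d_opt, d_sar) {
  cfg <- model$config
  if (d_opt[3L] != cfg$optical_channels || d_sar[3L] != cfg$sar_channels)
    stop(sprintf("channel mismatch: expected %d optical / %d SAR, got %d / %d",
                 cfg$optical_channels, cfg$sar_channels, d_opt[3L], d_sar[3L]))
  if (any(d_opt[1:2] != 2L * d_sar[1:2]))
    stop(sprintf(
      "shape mismatch at fusion: optical %dx%d must be 2x SAR %dx%d",
      d_opt[1L], d_opt[2L], d_sar[1L], d_sar[2L]))
  if (any(d_opt[1:2] %% 2L^cfg$depth != 0L))
    stop("optical patch sides must be divisible by 2^depth = ", 2L^cfg$depth)
}

# Stack a list of H x W x C arrays into the C x (H*W*B) activation layout.
stack_batch <- function(patches) {
  d <- dim(patches[[1L]])
  do.call(cbind, lapply(patches, function(a) t(matrix(a, d[1L] * d[2L], d[3L]))))
}

# Full forward pass; returns logits plus (optionally) every cache needed for
# backprop. Shapes: optical Hf x Wf, SAR Hs = Hf/2.
seg_forward <- function(model, opt_x, sar_x, Hf, Wf, B, training = FALSE,
                        keep_cache = FALSE) {
  cfg <- model$config
  Hs <- Hf %/% 2L; Ws <- Wf %/% 2L
  cache <- list()
  if (model$arch == "ynet") {
    cache$opt_stem <- block_fwd(model$opt_stem, opt_x, Hf, Wf, B, training)
    pool0 <- nn_maxpool2(cache$opt_stem$y, Hf, Wf, B)
    cache$pool0_idx <- pool0$idx
    cache$sar_stem <- block_fwd(model$sar_stem, sar_x, Hs, Ws, B, training)
    x <- rbind(pool0$y, cache$sar_stem$y)
  } else {
    pool0 <- nn_maxpool2(opt_x, Hf, Wf, B)
    cache$pool0_idx <- pool0$idx
    x <- rbind(pool0$y, sar_x)
  }
  # shared encoder at scales 1..depth (scale l grid = coarse / 2^(l-1))
  Hl <- Hs; Wl <- Ws
  enc_caches <- vector("list", cfg$depth)
  enc_dims <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    if (l > 1L) {
      p <- nn_maxpool2(x, Hl, Wl, B)
      enc_caches[[l - 1L]]$pool_idx <- p$idx
      x <- p$y; Hl <- Hl %/% 2L; Wl <- Wl %/% 2L
    }
    enc_caches[[l]] <- c(enc_caches[[l]],
                         block_fwd(model$enc[[l]], x, Hl, Wl, B, training))
    enc_dims[[l]] <- c(Hl, Wl)
    x <- enc_caches[[l]]$y
  }
  # decoder back to the coarse scale
  dec_caches <- vector("list", cfg$depth - 1L)
  for (l in rev(seq_len(cfg$depth - 1L))) {
    x <- nn_upsample2(x, Hl, Wl, B)
    Hl <- Hl * 2L; Wl <- Wl * 2L
    skip <- enc_caches[[l]]$y
    if (model$arch == "ynet" && l == 1L)
      skip <- rbind(skip, cache$sar_stem$y)
    dec_in <- rbind(x, skip)
    dec_caches[[l]] <- block_fwd(model$dec[[l]], dec_in, Hl, Wl, B, training)
    dec_caches[[l]]$in_ch_up <- nrow(x)
    x <- dec_caches[[l]]$y
  }
  # up to the fine grid
  x <- nn_upsample2(x, Hs, Ws, B)
  if (model$arch == "ynet") {
    fine_in <- rbind(x, cache$opt_stem$y)
  } else fine_in <- x
  cache$fine_up_ch <- nrow(x)
  cache$fine <- block_fwd(model$fine_block, fine_in, Hf, Wf, B, training)
  head <- conv_fwd(model$head, cache$fine$y, Hf, Wf, B)
  out <- list(logits = head$y)
  if (keep_cache) {
    cache$enc <- enc_caches; cache$dec <- dec_caches; cache$head <- head
    out$cache <- cache
  }
  out
}

seg_backward <- function(model, cache, dlogits, Hf, Wf, B) {
  cfg <- model$config
  Hs <- Hf %/% 2L; Ws <- Wf %/% 2L
  dy <- conv_bwd(model$head, cache$head, dlogits, Hf, Wf, B)
  dy <- block_bwd(model$fine_block, cache$fine, dy, Hf, Wf, B)
  up_ch <- cache$fine_up_ch
  d_up <- dy[seq_len(up_ch), , drop = FALSE]
  d_opt_skip <- if (model$arch == "ynet")
    dy[up_ch + seq_len(nrow(dy) - up_ch), , drop = FALSE] else NULL
  dy <- nn_upsample2_bwd(d_up, Hs, Ws, B)

  d_sar_skip <- NULL
  enc_extra <- vector("list", cfg$depth)  # gradient into enc outputs via skips
  Hl <- Hs; Wl <- Ws
  dims <- list(c(Hs, Ws))
  for (l in 2:cfg$depth) dims[[l]] <- dims[[l - 1L]] %/% 2L
  for (l in seq_len(cfg$depth - 1L)) {
    dd <- block_bwd(model$dec[[l]], cache$dec[[l]], dy,
                    dims[[l]][1L], dims[[l]][2L], B)
    up_ch <- cache$dec[[l]]$in_ch_up
    d_up <- dd[seq_len(up_ch), , drop = FALSE]
    d_skip <- dd[up_ch + seq_len(nrow(dd) - up_ch), , drop = FALSE]
    if (model$arch == "ynet" && l == 1L) {
      enc_ch <- nrow(cache$enc[[1L]]$y)
      d_sar_skip <- d_skip[enc_ch + seq_len(nrow(d_skip) - enc_ch), ,
                           drop = FALSE]
      d_skip <- d_skip[seq_len(enc_ch), , drop = FALSE]
    }
    enc_extra[[l]] <- d_skip
    dy <- nn_upsample2_bwd(d_up, dims[[l + 1L]][1L], dims[[l + 1L]][2L], B)
  }
  # encoder, deepest first
  for (l in rev(seq_len(cfg$depth))) {
    if (!is.null(enc_extra[[l]])) dy <- dy + enc_extra[[l]]
    dy <- block_bwd(model$enc[[l]], cache$enc[[l]], dy,
                    dims[[l]][1L], dims[[l]][2L], B)
    if (l > 1L) {
      dy <- nn_maxpool2_bwd(dy, cache$enc[[l - 1L]]$pool_idx,
                            dims[[l - 1L]][1L], dims[[l - 1L]][2L], B)
    }
  }
  # split fused input gradient between the two stems
  if (model$arch == "ynet") {
    w <- model$config$base_width
    d_pool0 <- dy[seq_len(w), , drop = FALSE]
    d_sar <- dy[w + seq_len(nrow(dy) - w), , drop = FALSE]
    if (!is.null(d_sar_skip)) d_sar <- d_sar + d_sar_skip
    block_bwd(model$sar_stem, cache$sar_stem, d_sar, Hs, Ws, B)
    d_opt <- nn_maxpool2_bwd(d_pool0, cache$pool0_idx, Hf, Wf, B)
    if (!is.null(d_opt_skip)) d_opt <- d_opt + d_opt_skip
    block_bwd(model$opt_stem, cache$opt_stem, d_opt, Hf, Wf, B)
  }
  invisible(NULL)
}

softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

#' Forward pass: per-pixel class probabilities
#'
#' Runs the network in inference mode (batch-norm running statistics) and
#' applies a per-pixel softmax, so each pixel's probabilities sum to one.
#'
#' @param model a `seg_model`.
#' @param optical_patch H x W x C fine-grid array (normalized to [0,1]).
#' @param sar_patch H/2 x W/2 x C coarse-grid array.
#' @return H x W x n_classes array of class probabilities.
#' @export
seg_predict <- function(model, optical_patch, sar_patch) {
  d_opt <- dim(optical_patch); d_sar <- dim(sar_patch)
  check_patch_shapes(model, d_opt, d_sar)
  fw <- seg_forward(model, stack_batch(list(optical_patch)),
                    stack_batch(list(sar_patch)),
                    d_opt[1L], d_opt[2L], 1L, training = FALSE)
  p <- softmax_cols(fw$logits)
  array(t(p), c(d_opt[1L], d_opt[2L], model$config$n_classes))
}

#' Loss specification for training
#'
#' @param epsilon smoothing constant of the soft Jaccard loss.
#' @param ignore_class class id excluded from the loss and metrics (default
#'   0, the catch-all "other" class); `NULL` keeps every class.
#' @return object of class `loss_spec`.
#' @export
loss_spec <- function(epsilon = 1e-6, ignore_class = 0L) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  structure(list(epsilon = epsilon, ignore_class = ignore_class),
            class = "loss_spec")
}

# Soft Jaccard pieces shared by loss value and gradient. probs and the
# one-hot matrix are n_classes x n_pixels; `keep` flags non-ignored pixels.
jaccard_terms <- function(probs, onehot, keep, spec) {
  p <- probs[, keep, drop = FALSE]
  y <- onehot[, keep, drop = FALSE]
  inter <- rowSums(p * y)
  union <- rowSums(p + y - p * y)
  list(p = p, y = y, inter = inter, union = union)
}

#' Soft Jaccard (IoU) loss
#'
#' `L = 1 - mean_c (sum p*y + eps) / (sum (p + y - p*y) + eps)`, the mean
#' taken over non-ignored classes and the sums over non-ignored pixels.
#' Bounded in [0, 1]; 0 for a perfect one-hot prediction.
#'
#' @param probs H x W x n_classes probability array (or n_classes x n_pixels
#'   matrix).
#' @param labels integer matrix (or vector) of class ids.
#' @param spec a [`loss_spec()`].
#' @return scalar loss.
#' @export
jaccard_loss <- function(probs, labels, spec = loss_spec()) {
  if (is.array(probs) && length(dim(probs)) == 3L) {
    nc <- dim(probs)[3L]
    probs <- t(matrix(probs, prod(dim(probs)[1:2]), nc))
  }
  nc <- nrow(probs)
  lab <- as.integer(labels)
  if (any(lab < 0L | lab >= nc, na.rm = TRUE)) {
    bad <- setdiff(unique(lab), c(spec$ignore_class, 0:(nc - 1L)))
    if (length(bad)) stop("label out of range: ", paste(bad, collapse = ", "))
  }
  keep <- !is.na(lab)
  if (!is.null(spec$ignore_class)) keep <- keep & lab != spec$ignore_class
  if (!any(keep)) stop("no non-ignored labeled pixels")
  onehot <- matrix(0, nc, length(lab))
  onehot[cbind(lab[keep] + 1L, which(keep))] <- 1
  cls <- setdiff(seq_len(nc), spec$ignore_class + 1L)
  tr <- jaccard_terms(probs, onehot, keep, spec)
  j <- (tr$inter[cls] + spec$epsilon) / (tr$union[cls] + spec$epsilon)
  1 - mean(j)
}

# Loss + gradient wrt logits for a batch in activation layout.
jaccard_loss_grad <- function(logits, lab_vec, spec) {
  nc <- nrow(logits)
  probs <- softmax_cols(logits)
  keep <- !is.na(lab_vec)
  if (!is.null(spec$ignore_class)) keep <- keep & lab_vec != spec$ignore_class
  if (!any(keep)) return(list(loss = NA_real_, grad = 0 * logits))
  onehot <- matrix(0, nc, length(lab_vec))
  onehot[cbind(lab_vec[keep] + 1L, which(keep))] <- 1
  cls <- setdiff(seq_len(nc), spec$ignore_class + 1L)
  p <- probs; y <- onehot
  inter <- rowSums(p[, keep, drop = FALSE] * y[, keep, drop = FALSE])
  union <- rowSums(p[, keep, drop = FALSE] + y[, keep, drop = FALSE] -
                   p[, keep, drop = FALSE] * y[, keep, drop = FALSE])
  j <- (inter + spec$epsilon) / (union + spec$epsilon)
  loss <- 1 - mean(j[cls])
  # dL/dp_c(i) for kept pixels; zero elsewhere and for the ignored class
  dP <- matrix(0, nc, ncol(p))
  denom <- (union + spec$epsilon)^2
  for (c in cls) {
    yc <- y[c, ]; scale <- 1 / length(cls)
    d <- -scale * (yc * (union[c] + spec$epsilon) -
                   (1 - yc) * (inter[c] + spec$epsilon)) / denom[c]
    d[!keep] <- 0
    dP[c, ] <- d
  }
  # chain through softmax
  s <- colSums(dP * probs)
  grad <- probs * sweep(dP, 2L, s)
  list(loss = loss, grad = grad)
}
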