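# Minimal layer toolkit for the segmentation networks.
#
# Each layer is an environment holding parameters, gradients and AdamW state;
# forward passes return caches consumed by the matching backward pass.
# Activations are C x (H*W*B) matrices (see src/nn_ops.cpp for the layout).

new_conv <- function(in_ch, out_ch, k = 3L) {
  e <- new.env(parent = emptyenv())
  e$k <- as.integer(k)
  e$in_ch <- as.integer(in_ch); e$out_ch <- as.integer(out_ch)
  fan_in <- in_ch * k * k
  e$W <- matrix(rnorm(out_ch * fan_in, sd = sqrt(2 / fan_in)), out_ch, fan_in)
  e$b <- numeric(out_ch)
  e$type <- "conv"
  e
}

conv_fwd <- function(e, x, H, W, B) {
  cols <- if (e$k == 1L) x else nn_im2col(x, H, W, B, e$k)
  y <- e$W %*% cols + e$b
  list(y = y, cols = cols)
}

conv_bwd <- function(e, cache, dy, H, W, B) {
  e$dW <- dy %*% t(cache$cols)
  e$db <- rowSums(dy)
  dcols <- t(e$W) %*% dy
  if (e$k == 1L) dcols else nn_col2im(dcols, e$in_ch, H, W, B, e$k)
}

new_bn <- function(ch, momentum = 0.1, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$gamma <- rep(1, ch); e$beta <- numeric(ch)
  e$run_mean <- numeric(ch); e$run_var <- rep(1, ch)
  e$momentum <- momentum; e$eps <- eps
  e$type <- "bn"
  e
}

bn_fwd <- function(e, x, training) {
  if (training) {
    mu <- rowMeans(x)
    v <- rowMeans(x * x) - mu^2
    e$run_mean <- (1 - e$momentum) * e$run_mean + e$momentum * mu
    e$run_var <- (1 - e$momentum) * e$run_var + e$momentum * v
  } else {
    mu <- e$run_mean; v <- e$run_var
  }
  inv_sd <- 1 / sqrt(v + e$eps)
  xhat <- (x - mu) * inv_sd
  list(y = xhat * e$gamma + e$beta, xhat = xhat, inv_sd = inv_sd,
       training = training)
}

bn_bwd <- function(e, cache, dy) {
  e$dgamma <- rowSums(dy * cache$xhat)
  e$dbeta <- rowSums(dy)
  if (!cache$training)
    return(dy * e$gamma * cache$inv_sd)
  n <- ncol(dy)
  dxhat <- dy * e$gamma
  (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat)) *
    cache$inv_sd
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(y = x * mask, mask = mask)
}

# Conv block: 2 x (3x3 conv -> batch norm -> ReLU), widths set by caller.
new_block <- function(in_ch, out_ch) {
  list(conv1 = new_conv(in_ch, out_ch), bn1 = new_bn(out_ch),
       conv2 = new_conv(out_ch, out_ch), bn2 = new_bn(out_ch))
}

block_fwd <- function(blk, x, H, W, B, training) {
  c1 <- conv_fwd(blk$conv1, x, H, W, B)
  b1 <- bn_fwd(blk$bn1, c1$y, training)
  r1 <- relu_fwd(b1$y)
  c2 <- conv_fwd(blk$conv2, r1$y, H, W, B)
  b2 <- bn_fwd(blk$bn2, c2$y, training)
  r2 <- relu_fwd(b2$y)
  list(y = r2$y, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, r2 = r2)
}

block_bwd <- function(blk, cache, dy, H, W, B) {
  dy <- dy * cache$r2$mask
  dy <- bn_bwd(blk$bn2, cache$b2, dy)
  dy <- conv_bwd(blk$conv2, cache$c2, dy, H, W, B)
  dy <- dy * cache$r1$mask
  dy <- bn_bwd(blk$bn1, cache$b1, dy)
  conv_bwd(blk$conv1, cache$c1, dy, H, W, B)
}

# Flatten a model's nested blocks into a list of parameter layers.
collect_layers <- function(x) {
  if (is.environment(x)) return(list(x))
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

layer_param_names <- function(e) {
  if (e$type == "conv") c("W", "b") else c("gamma", "beta")
}

count_layer_params <- function(e) {
  sum(vapply(layer_param_names(e), function(p) length(e[[p]]), numeric(1)))
}

# One AdamW step over every layer. Decoupled weight decay is applied to conv
# kernels only (not to biases or batch-norm affine parameters).
adamw_step <- function(layers, lr, weight_decay, step,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (e in layers) {
    for (p in layer_param_names(e)) {
      g <- switch(p, W = e$dW, b = e$db, gamma = e$dgamma, beta = e$dbeta)
      if (is.null(g)) next
      ms <- paste0("m_", p); vs <- paste0("v_", p)
      if (is.null(e[[ms]])) { e[[ms]] <- 0 * g; e[[vs]] <- 0 * g }
      e[[ms]] <- beta1 * e[[ms]] + (1 - beta1) * g
      e[[vs]] <- beta2 * e[[vs]] + (1 - beta2) * g * g
      mhat <- e[[ms]] / (1 - beta1^step)
      vhat <- e[[vs]] / (1 - beta2^step)
      upd <- mhat / (sqrt(vhat) + eps)
      if (p == "W" && e$type == "conv") upd <- upd + weight_decay * e[[p]]
      e[[p]] <- e[[p]] - lr * upd
    }
  }
  invisible(NULL)
}

# Deep-copy / restore parameter values (for best-checkpoint restoration).
snapshot_params <- function(layers) {
  lapply(layers, function(e) {
    nm <- c(layer_param_names(e),
            if (e$type == "bn") c("run_mean", "run_var"))
    setNames(lapply(nm, function(p) e[[p]]), nm)
  })
}

restore_params <- function(layers, snap) {
  for (i in seq_along(layers))
    for (p in names(snap[[i]])) layers[[i]][[p]] <- snap[[i]][[p]]
  invisible(NULL)
}

# One-cycle learning-rate schedule, stepped once per optimizer step: cosine
# warm-up from peak/div_factor to the peak over pct_start of the budget, then
# cosine annealing down to peak/final_div_factor.
onecycle_lr <- function(step, total_steps, peak_lr, pct_start = 0.3,
                        div_factor = 25, final_div_factor = 1e4) {
  warm <- max(1, round(pct_start * total_steps))
  lo <- peak_lr / div_factor
  end <- peak_lr / final_div_factor
  if (step <= warm) {
    t <- (step - 1) / max(warm - 1, 1)
    lo + (peak_lr - lo) * (1 - cos(pi * t)) / 2
  } else {
    t <- (step - warm) / max(total_steps - warm, 1)
    end + (peak_lr - end) * (1 + cos(pi * min(t, 1))) / 2
  }
}
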