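#' Training configuration
#'
#' Defaults follow the study design for the full-scale experiments: up to 300
#' epochs, batches of 10 patch pairs, AdamW with weight decay 5e-4, a
#' one-cycle learning-rate schedule stepped per batch around a peak rate of
#' 1.58e-4, and early stopping after 10 consecutive epochs without validation
#' Jaccard-loss improvement (the best-validation weights are restored).
#'
#' @param max_epochs maximum training epochs.
#' @param batch_size patches per optimizer step.
#' @param peak_lr one-cycle peak learning rate.
#' @param weight_decay decoupled weight decay on convolution kernels.
#' @param patience early-stopping patience in epochs.
#' @param seed RNG seed for shuffling and initialization.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 300L, batch_size = 10L,
                         peak_lr = 1.58e-4, weight_decay = 5e-4,
                         patience = 10L, seed = 1L) {
  stopifnot(max_epochs > 0, batch_size > 0, peak_lr > 0, weight_decay >= 0,
            patience > 0, patience < max_epochs)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size), peak_lr = peak_lr,
                 weight_decay = weight_decay, patience = as.integer(patience),
                 seed = as.integer(seed)), class = "train_config")
}

#' Assemble a semi-supervised training set
#'
#' Two compositions are supported. `ratio` mode builds a training set of
#' fixed size N (the labeled patch count) in which `round(r * N)` patches
#' carry pseudo-labels and the rest carry ground truth, so the label budget
#' shrinks as r grows while the data volume stays constant. `augment` mode
#' keeps every labeled patch and appends `extra_count` pseudo-labeled
#' patches, growing the training set. Pseudo-labels enter the loss exactly
#' like ground truth.
#'
#' @param labeled list of training samples, each
#'   `list(optical=, sar=, labels=)` with ground-truth labels.
#' @param pseudo list of samples whose `labels` are pseudo-labels.
#' @param mode `"ratio"` or `"augment"`.
#' @param unlabeled_fraction r in [0, 0.9] (ratio mode).
#' @param extra_count pseudo patches to append (augment mode; default all).
#' @param seed RNG seed for the subsampling.
#' @return list of training samples; each element has a logical
#'   `is_pseudo` field.
#' @export
assemble_ssl_dataset <- function(labeled, pseudo, mode = c("ratio", "augment"),
                                 unlabeled_fraction = 0,
                                 extra_count = length(pseudo), seed = 1L) {
  mode <- match.arg(mode)
  tag <- function(s, p) { s$is_pseudo <- p; s }
  if (mode == "ratio") {
    r <- unlabeled_fraction
    if (r < 0 || r > 0.9) stop("unlabeled_fraction must lie in [0, 0.9]")
    n <- length(labeled)
    n_pseudo <- round(r * n)
    if (n_pseudo > length(pseudo)) stop("not enough pseudo-labeled patches")
    set.seed(seed)
    keep_lab <- sample(n, n - n_pseudo)
    take_pse <- if (n_pseudo > 0) sample(length(pseudo), n_pseudo) else integer()
    c(lapply(labeled[keep_lab], tag, p = FALSE),
      lapply(pseudo[take_pse], tag, p = TRUE))
  } else {
    if (extra_count > length(pseudo)) stop("not enough pseudo-labeled patches")
    set.seed(seed)
    take <- if (extra_count > 0) sample(length(pseudo), extra_count) else integer()
    c(lapply(labeled, tag, p = FALSE), lapply(pseudo[take], tag, p = TRUE))
  }
}

# Evaluate mean Jaccard loss (and optionally OA/mIoU) over a sample list.
eval_loss <- function(model, samples, spec) {
  losses <- vapply(samples, function(s) {
    d <- dim(s$optical)
    fw <- seg_forward(model, stack_batch(list(s$optical)),
                      stack_batch(list(s$sar)), d[1L], d[2L], 1L,
                      training = FALSE)
    jaccard_loss(softmax_cols(fw$logits), as.integer(s$labels), spec)
  }, numeric(1))
  mean(losses)
}

predict_labels_sample <- function(model, s) {
  p <- seg_predict(model, s$optical, s$sar)
  apply(p, c(1L, 2L), which.max) - 1L
}

#' Train a segmentation model
#'
#' Optimizes the soft Jaccard loss with AdamW under a per-step one-cycle
#' learning-rate schedule. After each epoch the validation Jaccard loss is
#' measured; training stops once it has failed to improve for
#' `config$patience` consecutive epochs, and the best-validation weights are
#' restored before returning.
#'
#' @param model a `seg_model` from [`build_ynet()`] or
#'   [`build_unet_concat()`].
#' @param dataset list of training samples (`optical`, `sar`, `labels`).
#' @param val_set list of validation samples.
#' @param config a [`train_config()`].
#' @param spec a [`loss_spec()`].
#' @param verbose print one line per epoch.
#' @return list with the trained `model`, `history` data.frame (epoch,
#'   train_loss, val_loss, lr), `best_epoch` and `stopped_epoch`.
#' @export
train_model <- function(model, dataset, val_set, config = train_config(),
                        spec = loss_spec(), verbose = FALSE) {
  if (length(dataset) == 0L || length(val_set) == 0L)
    stop("train and validation sets must be non-empty")
  layers <- model_layers(model)
  steps_per_epoch <- max(1L, ceiling(length(dataset) / config$batch_size))
  total_steps <- config$max_epochs * steps_per_epoch
  set.seed(config$seed)
  best_val <- Inf; best_snap <- NULL; best_epoch <- 0L
  since_best <- 0L; step <- 0L
  hist <- list()
  for (epoch in seq_len(config$max_epochs)) {
    order_idx <- sample(length(dataset))
    ep_losses <- numeric()
    for (s0 in seq_len(steps_per_epoch)) {
      idx <- order_idx[((s0 - 1L) * config$batch_size + 1L):
                       min(s0 * config$batch_size, length(dataset))]
      idx <- idx[!is.na(idx)]
      batch <- dataset[idx]
      d <- dim(batch[[1L]]$optical)
      B <- length(batch)
      opt_x <- stack_batch(lapply(batch, `[[`, "optical"))
      sar_x <- stack_batch(lapply(batch, `[[`, "sar"))
      lab <- unlist(lapply(batch, function(s) as.integer(s$labels)))
      fw <- seg_forward(model, opt_x, sar_x, d[1L], d[2L], B,
                        training = TRUE, keep_cache = TRUE)
      lg <- jaccard_loss_grad(fw$logits, lab, spec)
      if (!is.finite(lg$loss))
        stop("divergent loss (NaN) at epoch ", epoch, ", step ", s0)
      seg_backward(model, fw$cache, lg$grad, d[1L], d[2L], B)
      step <- step + 1L
      lr <- onecycle_lr(step, total_steps, config$peak_lr)
      adamw_step(layers, lr, config$weight_decay, step)
      ep_losses <- c(ep_losses, lg$loss)
    }
    val_loss <- eval_loss(model, val_set, spec)
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = mean(ep_losses),
                                val_loss = val_loss, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      mean(ep_losses), val_loss))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss; best_epoch <- epoch
      best_snap <- snapshot_params(layers)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  if (!is.null(best_snap)) restore_params(layers, best_snap)
  list(model = model, history = do.call(rbind, hist),
       best_epoch = best_epoch, stopped_epoch = epoch)
}

#' Predict a full-scene class map by patchwise inference
#'
#' Chunks the scene into the model's non-overlapping patch grid, runs each
#' optical/SAR patch pair through the network in inference mode, and
#' stitches the argmax class maps back into a seamless full-scene label
#' raster (plus the class-probability raster).
#'
#' @param model a trained `seg_model`.
#' @param optical,sar normalized scene rasters (fine and coarse grids).
#' @param patch_size optical patch side (must divide the scene dimensions).
#' @return list with `labels` (integer class matrix) and `probs`
#'   (H x W x n_classes array).
#' @export
predict_map <- function(model, optical, sar, patch_size = 64L) {
  do <- dim(optical$grid)
  if (do[1L] < patch_size || do[2L] < patch_size)
    stop("scene smaller than one patch")
  if (do[1L] %% patch_size != 0L || do[2L] %% patch_size != 0L)
    stop("scene dimensions must be multiples of patch_size for seamless tiling")
  half <- patch_size %/% 2L
  nc <- model$config$n_classes
  out_lab <- matrix(NA_integer_, do[1L], do[2L])
  out_prob <- array(NA_real_, c(do[1L], do[2L], nc))
  for (pr in seq_len(do[1L] %/% patch_size) - 1L) {
    for (pc in seq_len(do[2L] %/% patch_size) - 1L) {
      oi <- pr * patch_size + seq_len(patch_size)
      oj <- pc * patch_size + seq_len(patch_size)
      si <- pr * half + seq_len(half)
      sj <- pc * half + seq_len(half)
      p <- seg_predict(model, optical$grid[oi, oj, , drop = FALSE],
                       sar$grid[si, sj, , drop = FALSE])
      out_prob[oi, oj, ] <- p
      out_lab[oi, oj] <- apply(p, c(1L, 2L), which.max) - 1L
    }
  }
  list(labels = out_lab, probs = out_prob)
}

#' Segmentation metrics report
#'
#' Computes overall accuracy, per-class intersection-over-union and F1,
#' their unweighted class means, and the row-normalized confusion matrix
#' (rows are ground-truth classes, in percent). The ignored class and any
#' class absent from both maps are excluded from the means (with a warning
#' for the latter).
#'
#' @param predicted integer class matrix/vector.
#' @param truth aligned ground-truth classes (NA = unlabeled).
#' @param ignore_class class id excluded from all metrics (default 0);
#'   `NULL` keeps all.
#' @param classes optional full class roster; classes absent from both maps
#'   are then excluded from the means with a warning. Default: the classes
#'   present in either map.
#' @return object of class `metrics_report`: list with `overall_accuracy`,
#'   `miou`, `per_class` data.frame (class, iou, f1), `confusion_pct`, and
#'   `n_pixels`.
#' @export
evaluate_map <- function(predicted, truth, ignore_class = 0L, classes = NULL) {
  p <- as.integer(predicted); t <- as.integer(truth)
  keep <- !is.na(p) & !is.na(t)
  if (!is.null(ignore_class)) keep <- keep & t != ignore_class
  if (!any(keep)) stop("no valid pixels to evaluate")
  p <- p[keep]; t <- t[keep]
  oa <- mean(p == t)
  if (is.null(classes)) classes <- unique(c(p, t))
  classes <- sort(setdiff(classes, ignore_class))
  iou <- f1 <- numeric(length(classes))
  for (i in seq_along(classes)) {
    cl <- classes[i]
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    if (tp + fp + fn == 0) {
      warning("class ", cl, " absent from both maps; excluded from mIoU")
      iou[i] <- NA_real_; f1[i] <- NA_real_
    } else {
      iou[i] <- tp / (tp + fp + fn)
      f1[i] <- 2 * tp / (2 * tp + fp + fn)
    }
  }
  tcl <- sort(unique(t))
  pcl <- sort(unique(c(p, t)))
  conf <- matrix(0, length(tcl), length(pcl),
                 dimnames = list(truth = tcl, predicted = pcl))
  for (i in seq_along(tcl))
    conf[i, ] <- 100 * tabulate(match(p[t == tcl[i]], pcl),
                                length(pcl)) / sum(t == tcl[i])
  structure(list(
    overall_accuracy = oa,
    miou = mean(iou, na.rm = TRUE),
    per_class = data.frame(class = classes, iou = iou, f1 = f1),
    confusion_pct = conf,
    n_pixels = length(p)), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Overall accuracy: %.3f   mIoU: %.3f   (%d pixels)\n",
              x$overall_accuracy, x$miou, x$n_pixels))
  print(transform(x$per_class, iou = round(iou, 3), f1 = round(f1, 3)),
        row.names = FALSE)
  cat("Row-normalized confusion matrix (%):\n")
  print(round(x$confusion_pct, 1))
  invisible(x)
}

#' F1 score implied by an intersection-over-union value
#'
#' The Dice/Jaccard identity `F1 = 2 IoU / (1 + IoU)`, which links every
#' printed per-class IoU/F1 pair.
#'
#' @param iou IoU value(s) in [0, 1].
#' @return F1 value(s).
#' @export
f1_from_iou <- function(iou) 2 * iou / (1 + iou)
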