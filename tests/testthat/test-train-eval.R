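make_dummy_sample <- function(seed, side = 16L) {
  set.seed(seed)
  list(optical = array(runif(side * side * 6), c(side, side, 6)),
       sar = array(runif((side / 2)^2 * 4), c(side / 2, side / 2, 4)),
       labels = matrix(sample(1:5, side * side, TRUE), side, side))
}

test_that("SSL dataset assembly follows ratio and augment compositions", {
  labeled <- lapply(1:100, make_dummy_sample, side = 4L)
  pseudo <- lapply(101:260, make_dummy_sample, side = 4L)
  # r = 0: fully supervised
  d0 <- assemble_ssl_dataset(labeled, pseudo, "ratio", 0)
  expect_length(d0, 100)
  expect_false(any(vapply(d0, `[[`, logical(1), "is_pseudo")))
  # r = 0.3, N = 100 -> 30 pseudo + 70 labeled, size constant in r
  d3 <- assemble_ssl_dataset(labeled, pseudo, "ratio", 0.3, seed = 2)
  expect_length(d3, 100)
  expect_equal(sum(vapply(d3, `[[`, logical(1), "is_pseudo")), 30)
  for (r in c(0.1, 0.5, 0.9))
    expect_length(assemble_ssl_dataset(labeled, pseudo, "ratio", r), 100)
  # augment mode grows the set: 561 labeled + 4470 pseudo -> 5031 (scaled
  # here to 100 labeled + 150 pseudo -> 250)
  da <- assemble_ssl_dataset(labeled, pseudo, "augment", extra_count = 150)
  expect_length(da, 250)
  expect_equal(sum(vapply(da, `[[`, logical(1), "is_pseudo")), 150)
  expect_error(assemble_ssl_dataset(labeled, pseudo, "ratio", 0.95), "0.9")
})

test_that("training overfits one batch and stops on patience", {
  # one structured batch (a real synthetic patch) memorized in 200 steps
  sc <- make_scene(16, 16, noise = 0.01, smoothness = 3, seed = 12)
  ost <- fit_normalization(list(sc$optical)); sst <- fit_normalization(list(sc$sar))
  s <- list(optical = apply_normalization(sc$optical, ost)$grid,
            sar = apply_normalization(sc$sar, sst)$grid,
            labels = sc$labels$grid[, , 1])
  m <- build_ynet(ynet_config(base_width = 16, depth = 2), seed = 2)
  fit <- train_model(m, list(s), list(s),
                     train_config(max_epochs = 200, batch_size = 1,
                                  peak_lr = 5e-3, patience = 199, seed = 1))
  expect_lt(min(fit$history$train_loss), 0.05)
  # patience contract: training stops exactly `patience` epochs after the
  # last validation improvement (a vanishing learning rate guarantees an
  # early plateau; batch-norm running statistics still drift, so the plateau
  # onset is data-dependent but the stop offset is exact)
  m2 <- build_ynet(ynet_config(base_width = 4, depth = 2), seed = 2)
  fit2 <- train_model(m2, list(s), list(s),
                      train_config(max_epochs = 50, batch_size = 1,
                                   peak_lr = 1e-12, patience = 3, seed = 1))
  expect_lt(fit2$stopped_epoch, 50)
  expect_equal(fit2$stopped_epoch, fit2$best_epoch + 3)
  expect_equal(nrow(fit2$history), fit2$stopped_epoch)
  expect_error(train_model(m, list(), list(s)), "non-empty")
})

test_that("training history is reproducible under a fixed seed", {
  s1 <- make_dummy_sample(5); s2 <- make_dummy_sample(6)
  run <- function() {
    m <- build_ynet(ynet_config(base_width = 4, depth = 2), seed = 7)
    train_model(m, list(s1, s2), list(s1),
                train_config(max_epochs = 3, batch_size = 2,
                             peak_lr = 1e-3, patience = 2, seed = 3))$history
  }
  expect_equal(run(), run(), tolerance = 1e-12)
})

test_that("full-scene prediction stitches patches without seams", {
  sc <- make_scene(32, 48, seed = 8)
  m <- build_ynet(ynet_config(base_width = 4, depth = 2), seed = 4)
  ost <- fit_normalization(list(sc$optical))
  sst <- fit_normalization(list(sc$sar))
  opt_n <- apply_normalization(sc$optical, ost)
  sar_n <- apply_normalization(sc$sar, sst)
  pm <- predict_map(m, opt_n, sar_n, patch_size = 16)
  expect_identical(dim(pm$labels), c(32L, 48L))
  expect_false(any(is.na(pm$labels)))
  # oracle: direct per-patch prediction rearranged
  for (pr in 0:1) for (pc in 0:2) {
    oi <- pr * 16 + 1:16; oj <- pc * 16 + 1:16
    si <- pr * 8 + 1:8; sj <- pc * 8 + 1:8
    p <- seg_predict(m, opt_n$grid[oi, oj, , drop = FALSE],
                     sar_n$grid[si, sj, , drop = FALSE])
    expect_equal(pm$probs[oi, oj, ], p)
    expect_identical(pm$labels[oi, oj],
                     apply(p, c(1, 2), which.max) - 1L)
  }
  expect_error(predict_map(m, opt_n, sar_n, patch_size = 64), "smaller")
})

test_that("evaluation metrics match hand computations and the F1 identity", {
  # perfect map
  lab <- matrix(sample(1:5, 100, TRUE), 10, 10)
  mr <- evaluate_map(lab, lab)
  expect_equal(mr$overall_accuracy, 1)
  expect_equal(mr$miou, 1)
  # 2-class counts TP=30 FP=10 FN=10 TN=50 -> IoU 0.6, F1 0.75 for class 1
  p <- rep(c(1, 1, 2, 2), c(30, 10, 10, 50))
  t <- rep(c(1, 2, 1, 2), c(30, 10, 10, 50))
  mr2 <- evaluate_map(p, t, ignore_class = NULL)
  cl1 <- mr2$per_class[mr2$per_class$class == 1, ]
  expect_equal(cl1$iou, 0.6)
  expect_equal(cl1$f1, 0.75)
  # rows of the confusion matrix sum to 100
  expect_true(all(abs(rowSums(mr2$confusion_pct) - 100) < 0.1))
  # F1 = 2 IoU / (1 + IoU) for every class on a random evaluation
  set.seed(2)
  pr <- sample(0:4, 500, TRUE); tr <- sample(0:4, 500, TRUE)
  mr3 <- evaluate_map(pr, tr, ignore_class = 0)
  expect_equal(mr3$per_class$f1, f1_from_iou(mr3$per_class$iou),
               tolerance = 5e-4)
  # class absent from both maps is excluded from mIoU with a warning
  expect_warning(
    mr4 <- evaluate_map(c(1, 1, 2), c(1, 1, 2), ignore_class = NULL,
                        classes = 1:3),
    "absent")
  expect_equal(mr4$miou, 1)
  expect_true(is.na(mr4$per_class$iou[mr4$per_class$class == 3]))
  expect_error(evaluate_map(0, 0, ignore_class = 0), "valid")
})
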