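# Desk-scale recovery experiments shared by the acceptance tests.
# The generator settings are the package's stated desk-scale world: a
# 192 x 192 px fine grid (96 px SAR), 6 separable classes, additive optical
# noise sd 0.02, 4-look speckle, 32-px optical patches in 2x2-patch tiles.

ynet_recovery_experiment <- function(seed = 11, epochs = 40) {
  sc <- make_scene(192, 192, noise = 0.02, looks = 4, smoothness = 5,
                   seed = seed)
  sp <- make_patch_samples(sc, optical_patch = 32L, split_seed = seed + 1)
  m <- build_ynet(ynet_config(base_width = 16, depth = 3), seed = seed + 2)
  fit <- train_model(m, sp$train, sp$val,
                     train_config(max_epochs = epochs, batch_size = 10,
                                  peak_lr = 3e-3, patience = 10,
                                  seed = seed + 3))
  preds <- unlist(lapply(sp$test, function(s)
    as.integer(dryshift:::predict_labels_sample(fit$model, s))))
  truth <- unlist(lapply(sp$test, function(s) as.integer(s$labels)))
  list(metrics = evaluate_map(preds, truth), fit = fit, samples = sp)
}

pseudolabel_recovery_experiment <- function(seed = 3) {
  sc <- make_scene(96, 96, noise = 0, looks = Inf, smoothness = 5, seed = seed)
  ft <- build_feature_table(sc$optical, sc$sar)
  ens <- fit_cluster_ensemble(ft, k = 6, seed = seed + 1)
  truth <- as.integer(sc$labels$grid)
  ens <- suppressWarnings(map_clusters_to_classes(ens, truth))
  pl <- vote_pseudolabels(predict_class_maps(ens, ft))
  evaluate_clustering(pl, truth)
}

change_recovery_experiment <- function(seed = 37, flip_rate = 0.02) {
  cfg <- scene_config(height_px = 64, width_px = 64, seed = seed)
  series <- generate_series(cfg, list(list(from = 5, to = 2, fraction = 0.1)),
                            seed = seed)
  truth_maps <- lapply(series, function(e) e$labels$grid[, , 1])
  n_src <- sum(truth_maps[[1]] == 5)
  maps_by_model <- lapply(1:5, function(m)
    lapply(1:2, function(e)
      noisy_map_stub(truth_maps[[e]], flip_rate, 6, seed = seed + 10 * m + e)))
  res <- change_summary(maps_by_model, target_class = 5, pixel_size_m = 5)
  list(recovered_fraction = sum(res$masks[[1]]) / n_src,
       injected_fraction = sum(series[[2]]$truth_mask) / n_src)
}
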