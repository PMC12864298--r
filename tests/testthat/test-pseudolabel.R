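test_that("feature table stacks 10 normalized features on the fine grid", {
  sc <- make_scene(32, 32, seed = 5)
  ft <- build_feature_table(sc$optical, sc$sar)
  expect_identical(colnames(ft), c("Red", "Green", "Blue", "NIR", "GNDVI",
                                   "NDVI", "VV", "HH", "VV+VH", "HH+HV"))
  expect_equal(nrow(ft), 32 * 32)
  expect_true(all(is.finite(ft)))
  # every non-constant feature spans [0, 1] after per-feature normalization
  rng <- apply(ft, 2, range)
  expect_true(all(abs(rng[1, ]) < 1e-12))
  expect_true(all(abs(rng[2, ] - 1) < 1e-12))
  # constant SAR band -> constant (zero) feature column
  sar_c <- sc$sar; sar_c$grid[, , 1] <- 2.5
  ftc <- build_feature_table(sc$optical, sar_c)
  expect_true(all(ftc[, "VV"] == 0))
  expect_error(build_feature_table(sc$optical, sc$optical), "half")
})

test_that("three k-means variants recover separated blobs and are seeded", {
  set.seed(10)
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30))  # 10+ sigma separation
  x <- do.call(rbind, lapply(1:3, function(i)
    cbind(rnorm(80, centers[i, 1], 1.5), rnorm(80, centers[i, 2], 1.5))))
  truth <- rep(0:2, each = 80)
  ens <- fit_cluster_ensemble(x, k = 3, seed = 4)
  for (v in c("kmeans", "kmeans_pp", "pca_kmeans")) {
    # each cluster is pure: adjusted agreement with the partition is 1
    tab <- table(ens[[v]]$cluster, truth)
    expect_true(all(rowSums(tab > 0) == 1))
  }
  ens2 <- fit_cluster_ensemble(x, k = 3, seed = 4)
  for (v in c("kmeans", "kmeans_pp", "pca_kmeans"))
    expect_identical(ens[[v]]$centers, ens2[[v]]$centers)
  # PCA variant works in a (k-1)-dimensional subspace
  expect_identical(ncol(ens$pca_rotation), 2L)
  expect_error(fit_cluster_ensemble(x, k = 1), "k must be")
  expect_error(fit_cluster_ensemble(x[1:2, ], k = 3), "at least")
})

test_that("cluster-to-class mapping is argmax overlap with stated tie rules", {
  ens <- structure(list(k = 2L,
    kmeans = list(cluster = NULL), kmeans_pp = list(cluster = NULL),
    pca_kmeans = list(cluster = NULL), mapping = NULL),
    class = "cluster_ensemble")
  # contingency [[10,0],[0,10]] -> diagonal map; [[6,4],[1,9]] -> same;
  # tie row [[5,5]] -> lowest class id
  cases <- list(
    list(a = rep(1:2, c(10, 10)), lab = rep(c(0, 1), c(10, 10)), exp = c(0, 1)),
    list(a = rep(1:2, c(10, 10)), lab = c(rep(0, 6), rep(1, 4), rep(0, 1), rep(1, 9)),
         exp = c(0, 1)),
    list(a = rep(1, 10), lab = rep(c(0, 1), each = 5), exp = c(0, 0)))
  for (cs in cases) {
    asn <- list(kmeans = cs$a, kmeans_pp = cs$a, pca_kmeans = cs$a)
    m <- suppressWarnings(map_clusters_to_classes(ens, cs$lab, asn))
    expect_identical(m$mapping$kmeans, as.integer(cs$exp))
  }
  # empty cluster -> class 0 with a warning (one per affected variant)
  asn <- list(kmeans = rep(1, 4), kmeans_pp = rep(1, 4), pca_kmeans = rep(1, 4))
  w <- capture_warnings(m <- map_clusters_to_classes(ens, rep(3, 4), asn))
  expect_true(any(grepl("no labeled", w)))
  expect_identical(m$mapping$kmeans[2], 0L)
})

test_that("pseudo-label vote follows 2-of-3 with k-means++ tiebreak", {
  a <- c(1, 1, 1, 2)  # kmeans
  b <- c(1, 2, 3, 3)  # kmeans_pp (preferred on 3-way disagreement)
  c_ <- c(2, 2, 2, 1)  # pca_kmeans
  # pixel 1: (1,1,2) -> 1; pixel 2: (1,2,2) -> 2; pixel 3: (1,3,2) -> 3 (km++);
  # pixel 4: (2,3,1) -> 3 (km++)
  expect_identical(vote_pseudolabels(list(a, b, c_)), c(1L, 2L, 3L, 3L))
  # idempotent on three identical maps
  expect_identical(vote_pseudolabels(list(a, a, a)), as.integer(a))
  # symmetric in the two non-preferred variants
  expect_identical(vote_pseudolabels(list(c_, b, a)),
                   vote_pseudolabels(list(a, b, c_)))
  # shape preserved
  am <- matrix(a, 2, 2)
  expect_identical(dim(vote_pseudolabels(list(am, matrix(b, 2, 2),
                                              matrix(c_, 2, 2)))), c(2L, 2L))
  expect_error(vote_pseudolabels(list(a, b)), "three")
  expect_error(vote_pseudolabels(list(a, b, c_[1:2])), "misaligned")
})

test_that("clustering evaluation metrics match hand computations", {
  expect_equal(evaluate_clustering(1:4, 1:4)$accuracy, 1)
  expect_equal(evaluate_clustering(1:4, 1:4)$macro_f1, 1)
  # binary confusion TP=40 FP=10 FN=10 TN=40 -> acc 0.8, F1 0.8 for each class
  p <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
  t <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
  ev <- evaluate_clustering(p, t)
  expect_equal(ev$accuracy, 0.8)
  expect_equal(unname(ev$per_class_f1["1"]), 0.8)
  expect_equal(ev$macro_f1, 0.8)
  expect_error(evaluate_clustering(NA, NA), "valid")
})

test_that("mapping is frozen after fitting and reused on new scenes", {
  sc <- make_scene(32, 32, noise = 0, looks = Inf, seed = 6)
  ft <- build_feature_table(sc$optical, sc$sar)
  ens <- fit_cluster_ensemble(ft, k = 6, seed = 2)
  ens <- suppressWarnings(map_clusters_to_classes(ens, as.integer(sc$labels$grid)))
  frozen <- ens$mapping
  sc2 <- make_scene(32, 32, noise = 0, looks = Inf, seed = 99)
  maps <- predict_class_maps(ens, build_feature_table(sc2$optical, sc2$sar))
  expect_identical(ens$mapping, frozen)
  expect_length(maps, 3)
  unmapped <- fit_cluster_ensemble(ft, k = 6, seed = 2)
  expect_error(predict_class_maps(unmapped, ft), "frozen mapping")
})

test_that("pseudo-label accuracy does not increase with optical noise", {
  accs <- vapply(c(0, 0.06, 0.2), function(noise) {
    sc <- make_scene(48, 48, noise = noise, looks = if (noise == 0) Inf else 4,
                     seed = 17)
    ft <- build_feature_table(sc$optical, sc$sar)
    ens <- fit_cluster_ensemble(ft, k = 6, seed = 3)
    ens <- suppressWarnings(map_clusters_to_classes(ens,
                                                    as.integer(sc$labels$grid)))
    pl <- vote_pseudolabels(predict_class_maps(ens, ft))
    evaluate_clustering(pl, as.integer(sc$labels$grid))$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_equal(accs[1], 1, tolerance = 1e-6)
})
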