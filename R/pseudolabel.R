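#' Build the 10-feature pixel table for unsupervised clustering
#'
#' Stacks, per fine-grid pixel, the six optical features (Red, Green, Blue,
#' NIR, GNDVI, NDVI) with the four SAR composite bands bilinearly up-sampled
#' 2x onto the fine grid. Each feature column is min-max normalized to [0,1]
#' per scene before stacking, so no single sensor dominates the Euclidean
#' metric.
#'
#' @param optical fine-grid `scene_raster` with Red, Green, Blue, NIR bands;
#'   NDVI/GNDVI are computed on the fly when absent.
#' @param sar coarse-grid 4-band `scene_raster` at half the optical
#'   resolution.
#' @return object of class `feature_table`: numeric matrix (pixels x 10,
#'   pixels in column-major scene order) with feature names, plus the scene
#'   dimensions in attributes.
#' @export
build_feature_table <- function(optical, sar) {
  stopifnot(inherits(optical, "scene_raster"), inherits(sar, "scene_raster"))
  if (!all(c("NDVI", "GNDVI") %in% optical$band_names))
    optical <- compute_indices(optical)
  do <- dim(optical$grid); ds <- dim(sar$grid)
  if (do[1L] != 2L * ds[1L] || do[2L] != 2L * ds[2L])
    stop("sar grid must be exactly half the optical resolution")
  if (ds[3L] != 4L) stop("missing band: expected 4 SAR bands")
  sar_up <- resample_raster(sar, 2L, mode = "bilinear_up")
  feat_names <- c("Red", "Green", "Blue", "NIR", "GNDVI", "NDVI",
                  "VV", "HH", "VV+VH", "HH+HV")
  cols <- vector("list", 10L)
  for (i in 1:6) cols[[i]] <- as.vector(scene_band(optical, feat_names[i]))
  for (i in 1:4) cols[[6L + i]] <- as.vector(sar_up$grid[, , i])
  x <- do.call(cbind, cols)
  colnames(x) <- feat_names
  # per-feature min-max normalization to [0,1]
  for (j in seq_len(ncol(x))) {
    rng <- range(x[, j], na.rm = TRUE)
    x[, j] <- if (diff(rng) == 0) 0 else (x[, j] - rng[1L]) / diff(rng)
  }
  structure(x, class = c("feature_table", class(x)),
            scene_dim = do[1:2])
}

# k-means++ seeding: D^2-weighted sequential centre choice.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  i <- sample.int(n, 1L)
  centers[1L, ] <- x[i, ]
  d2 <- rowSums(sweep(x, 2L, centers[1L, ])^2)
  if (k > 1L) for (j in 2:k) {
    probs <- d2 / sum(d2)
    i <- sample.int(n, 1L, prob = probs)
    centers[j, ] <- x[i, ]
    d2 <- pmin(d2, rowSums(sweep(x, 2L, centers[j, ])^2))
  }
  centers
}

run_kmeans <- function(x, centers_or_k, nstart = 1L) {
  stats::kmeans(x, centers = centers_or_k, iter.max = 300L,
                nstart = nstart, algorithm = "Lloyd")
}

# Best-of-n k-means++ runs (fresh D^2 seeding each restart, lowest total
# within-cluster sum of squares kept) — the standard guard against local
# optima that a single seeding draw can still hit.
run_kmeanspp <- function(x, k, nstart = 10L) {
  best <- NULL
  for (i in seq_len(nstart)) {
    fit <- run_kmeans(x, kmeanspp_centers(x, k))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Fit the three-variant k-means ensemble
#'
#' Fits (a) traditional k-means with uniform-random initialization, (b)
#' k-means with k-means++ seeding, and (c) k-means++ run in the subspace of
#' the first k-1 principal components (the PCA k-means variant), all with the
#' same k and a shared seed. Lloyd iterations, at most 300 per fit, 10
#' restarts per variant (best total within-cluster sum of squares kept).
#'
#' @param features a [`build_feature_table()`] matrix (or any numeric
#'   matrix, pixels x features).
#' @param k number of clusters (default 6, matching the LULC class count).
#' @param seed RNG seed.
#' @return object of class `cluster_ensemble` with elements `kmeans`,
#'   `kmeans_pp`, `pca_kmeans` (each holding `centers` and `cluster`
#'   assignments in fit order), the PCA rotation, `k`, and (after
#'   [`map_clusters_to_classes()`]) frozen cluster-to-class mappings.
#' @export
fit_cluster_ensemble <- function(features, k = 6L, seed = 1L) {
  x <- unclass(features)
  if (!is.matrix(x) || nrow(x) < k) stop("need at least k pixel rows")
  if (k < 2L) stop("k must be >= 2")
  set.seed(seed)
  f1 <- run_kmeans(x, k, nstart = 10L)
  f2 <- run_kmeanspp(x, k)
  pca <- prcomp(x, center = TRUE, scale. = FALSE)
  npc <- min(k - 1L, ncol(pca$rotation))
  xp <- pca$x[, seq_len(npc), drop = FALSE]
  f3 <- run_kmeanspp(xp, k)
  structure(list(
    kmeans = list(centers = f1$centers, cluster = f1$cluster),
    kmeans_pp = list(centers = f2$centers, cluster = f2$cluster),
    pca_kmeans = list(centers = f3$centers, cluster = f3$cluster),
    pca_center = pca$center, pca_rotation = pca$rotation[, seq_len(npc),
                                                         drop = FALSE],
    k = as.integer(k), seed = as.integer(seed), mapping = NULL),
    class = "cluster_ensemble")
}

variant_names <- c("kmeans", "kmeans_pp", "pca_kmeans")

# Nearest-centroid assignment of new pixels for one fitted variant.
assign_clusters <- function(ensemble, variant, features) {
  x <- unclass(features)
  if (variant == "pca_kmeans")
    x <- sweep(x, 2L, ensemble$pca_center) %*% ensemble$pca_rotation
  cen <- ensemble[[variant]]$centers
  d <- outer(rowSums(x^2), rep(1, nrow(cen))) - 2 * x %*% t(cen)
  d <- sweep(d, 2L, rowSums(cen^2), "+")
  max.col(-d, ties.method = "first")
}

#' Freeze the cluster-to-class mapping from labeled training pixels
#'
#' For each variant, builds the cluster x class contingency table on the
#' labeled training subset and maps every cluster to its argmax-overlap
#' class (ties broken toward the lowest class id). A cluster that captured
#' no labeled pixel maps to class 0 ("other") with a warning. The mapping is
#' stored in the ensemble and never re-estimated.
#'
#' @param ensemble a `cluster_ensemble`.
#' @param assignments list with one integer cluster-assignment vector per
#'   variant (names `kmeans`, `kmeans_pp`, `pca_kmeans`), or `NULL` to use
#'   the assignments stored at fit time.
#' @param reference_labels integer class ids aligned with the assignments.
#' @return the ensemble with `$mapping`, a list of per-variant integer
#'   vectors (`mapping[[v]][cluster]` = class id).
#' @export
map_clusters_to_classes <- function(ensemble, reference_labels,
                                    assignments = NULL) {
  stopifnot(inherits(ensemble, "cluster_ensemble"))
  lab <- as.integer(reference_labels)
  mapping <- list()
  for (v in variant_names) {
    a <- if (is.null(assignments)) ensemble[[v]]$cluster else assignments[[v]]
    if (length(a) != length(lab)) stop("assignments and labels misaligned")
    map_v <- integer(ensemble$k)
    for (cl in seq_len(ensemble$k)) {
      sel <- a == cl & !is.na(lab)
      if (!any(sel)) {
        warning("cluster ", cl, " (", v, ") has no labeled pixels; mapped to class 0")
        map_v[cl] <- 0L
      } else {
        tab <- table(lab[sel])
        classes <- as.integer(names(tab))
        map_v[cl] <- min(classes[tab == max(tab)])  # tie -> lowest class id
      }
    }
    mapping[[v]] <- map_v
  }
  ensemble$mapping <- mapping
  ensemble
}

#' Predict per-variant class maps for a scene
#'
#' @param ensemble a mapped `cluster_ensemble`.
#' @param features a `feature_table` for the scene.
#' @return list of three integer class vectors (one per variant), each in
#'   scene pixel order.
#' @export
predict_class_maps <- function(ensemble, features) {
  if (is.null(ensemble$mapping))
    stop("ensemble has no frozen mapping; call map_clusters_to_classes() first")
  setNames(lapply(variant_names, function(v)
    ensemble$mapping[[v]][assign_clusters(ensemble, v, features)]),
    variant_names)
}

#' Majority-vote pseudo-labels from the three mapped class maps
#'
#' Per pixel, the class chosen by at least two of the three variants wins; on
#' a three-way disagreement the k-means++ vote is kept (the variant with the
#' most reliable clustering accuracy). Pseudo-labels are produced once and
#' frozen — there is no iterative refinement.
#'
#' @param maps list of three aligned integer class vectors/matrices, in the
#'   order `kmeans`, `kmeans_pp`, `pca_kmeans`.
#' @return integer pseudo-label vector (or matrix, matching the input shape).
#' @export
vote_pseudolabels <- function(maps) {
  if (length(maps) != 3L) stop("need exactly three class maps")
  d <- dim(maps[[1L]])
  a <- as.integer(maps[[1L]]); b <- as.integer(maps[[2L]]); c <- as.integer(maps[[3L]])
  if (length(a) != length(b) || length(b) != length(c))
    stop("misaligned class maps")
  out <- b  # default: k-means++ (three-way disagreement rule)
  out[a == c] <- a[a == c]      # two non-preferred variants agree
  out[a == b] <- a[a == b]      # any pair involving km++ agrees with it
  out[b == c] <- b[b == c]
  if (!is.null(d)) dim(out) <- d
  out
}

#' Accuracy and macro-F1 of a mapped clustering
#'
#' @param predicted integer class predictions.
#' @param truth aligned integer reference classes (NA = unlabeled).
#' @return list with `accuracy`, `macro_f1` and `per_class_f1`.
#' @export
evaluate_clustering <- function(predicted, truth) {
  p <- as.integer(predicted); t <- as.integer(truth)
  keep <- !is.na(p) & !is.na(t)
  if (!any(keep)) stop("no jointly valid pixels to evaluate")
  p <- p[keep]; t <- t[keep]
  acc <- mean(p == t)
  classes <- sort(unique(c(p, t)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  names(f1) <- classes
  list(accuracy = acc, macro_f1 = mean(f1, na.rm = TRUE), per_class_f1 = f1)
}
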