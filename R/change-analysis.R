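#' Pixel-wise difference of two class maps
#'
#' Produces a transition-code raster (`code = from * n_classes + to`) plus
#' binary loss and gain masks for a target class: loss pixels carried the
#' target class at t1 but not at t2, gain pixels the reverse.
#'
#' @param map_t1,map_t2 aligned integer class matrices.
#' @param target_class class id tracked by the loss/gain masks.
#' @param n_classes class count used for the transition encoding (default:
#'   one more than the largest id present).
#' @return list with `transition` (integer matrix), `loss` and `gain`
#'   (logical matrices).
#' @export
diff_maps <- function(map_t1, map_t2, target_class,
                      n_classes = max(map_t1, map_t2, na.rm = TRUE) + 1L) {
  if (!identical(dim(map_t1), dim(map_t2)))
    stop("misaligned class maps")
  transition <- map_t1 * n_classes + map_t2
  list(transition = transition,
       loss = !is.na(map_t1) & map_t1 == target_class & map_t2 != target_class,
       gain = !is.na(map_t1) & map_t1 != target_class & map_t2 == target_class)
}

#' k-of-n majority vote over binary change masks
#'
#' A pixel is flagged as changed iff at least `k` of the `n` model-specific
#' masks flag it. With the default five-model ensemble and `k = 3`, a change
#' must be supported by a majority of independently trained models, which
#' suppresses single-run artefacts.
#'
#' @param masks list of aligned logical matrices.
#' @param k agreement threshold, `1 <= k <= length(masks)`.
#' @return list with `mask` (logical majority mask) and `votes` (integer
#'   matrix of per-pixel agreement counts).
#' @export
ensemble_change_vote <- function(masks, k = 3L) {
  n <- length(masks)
  if (n < 1L) stop("need at least one mask")
  if (k < 1L || k > n) stop("k must lie in [1, n]")
  d <- dim(masks[[1L]])
  votes <- matrix(0L, d[1L], d[2L])
  for (m in masks) {
    if (!identical(dim(m), d)) stop("mixed mask shapes")
    votes <- votes + (m %in% TRUE)
  }
  list(mask = votes >= k, votes = votes)
}

#' Class areas in hectares
#'
#' `area = pixel count * pixel_size_m^2 / 10000`.
#'
#' @param label_map integer class matrix.
#' @param pixel_size_m pixel edge length in metres.
#' @param classes class ids to report (default: all present).
#' @return named numeric vector of hectares per class.
#' @export
class_areas <- function(label_map, pixel_size_m, classes = NULL) {
  if (pixel_size_m <= 0) stop("pixel_size_m must be > 0")
  lab <- as.integer(label_map)
  if (is.null(classes)) classes <- sort(unique(lab[!is.na(lab)]))
  areas <- vapply(classes, function(cl) sum(lab == cl, na.rm = TRUE),
                  numeric(1)) * pixel_size_m^2 / 1e4
  names(areas) <- classes
  areas
}

#' Signed percent change between two areas
#'
#' `100 * (t2 - t1) / t1`, rounded half-even to one decimal (so 21,307 ->
#' 19,645 ha prints as -7.8).
#'
#' @param area_t1,area_t2 areas in the same unit; `area_t1` must be > 0.
#' @return signed percent, one decimal.
#' @export
percent_change <- function(area_t1, area_t2) {
  if (area_t1 <= 0) stop("percent change undefined for area_t1 <= 0")
  round(100 * (area_t2 - area_t1) / area_t1, 1)
}

#' Error margin on an area from a misclassification rate
#'
#' `margin = trunc(area * rate)` in whole hectares, truncated toward zero.
#' The rate is conventionally `1 -` the target class's diagonal entry of the
#' row-normalized confusion matrix (e.g. 1.2% for a 98.8% diagonal).
#'
#' @param area_ha area in hectares.
#' @param misclassification_rate rate in [0, 1].
#' @return integer hectares.
#' @export
error_margin <- function(area_ha, misclassification_rate) {
  if (misclassification_rate < 0 || misclassification_rate > 1)
    stop("misclassification_rate must lie in [0, 1]")
  as.integer(trunc(area_ha * misclassification_rate))
}

#' Ensemble change summary over a map series
#'
#' For each pair of consecutive epochs, computes the per-model target-class
#' loss masks, the k-of-n majority change mask, the per-epoch class areas
#' (from the pixel-wise plurality consensus of the model maps, ties toward
#' the lowest class id), and the percent change and error margin of the
#' target class.
#'
#' @param maps_by_model list (one entry per model) of lists of aligned
#'   integer class matrices (one per epoch).
#' @param target_class class id whose loss is tracked.
#' @param pixel_size_m pixel size of the maps in metres.
#' @param misclassification_rate rate used for [`error_margin()`].
#' @param k majority threshold (default 3 of the 5-model ensemble).
#' @param baseline_area_ha optional externally supplied epoch-1 area of the
#'   target class (hectares); defaults to the consensus-map area.
#' @return object of class `change_result`: list with `ledger` (data.frame:
#'   epoch, area_ha, pct_change, error_margin_ha), `masks` (majority loss
#'   mask per epoch pair), `votes`, and `consensus` label maps.
#' @export
change_summary <- function(maps_by_model, target_class, pixel_size_m,
                           misclassification_rate = 0, k = 3L,
                           baseline_area_ha = NULL) {
  n_models <- length(maps_by_model)
  if (n_models < 1L) stop("need at least one model")
  n_ep <- length(maps_by_model[[1L]])
  if (n_ep < 2L) stop("need at least two epochs")
  consensus <- lapply(seq_len(n_ep), function(e) {
    stack <- lapply(maps_by_model, `[[`, e)
    plurality_map(stack)
  })
  areas <- vapply(consensus, function(m)
    sum(m == target_class, na.rm = TRUE) * pixel_size_m^2 / 1e4, numeric(1))
  if (!is.null(baseline_area_ha)) areas[1L] <- baseline_area_ha
  masks <- votes <- vector("list", n_ep - 1L)
  for (e in seq_len(n_ep - 1L)) {
    per_model <- lapply(maps_by_model, function(mm)
      diff_maps(mm[[e]], mm[[e + 1L]], target_class)$loss)
    v <- ensemble_change_vote(per_model, k = k)
    masks[[e]] <- v$mask; votes[[e]] <- v$votes
  }
  ledger <- data.frame(
    epoch = seq_len(n_ep),
    area_ha = areas,
    pct_change = c(NA, vapply(seq_len(n_ep - 1L), function(e)
      percent_change(areas[e], areas[e + 1L]), numeric(1))),
    error_margin_ha = c(NA, vapply(areas[-1L], function(a)
      as.numeric(error_margin(a, misclassification_rate)), numeric(1))))
  structure(list(ledger = ledger, masks = masks, votes = votes,
                 consensus = consensus, target_class = target_class,
                 k = k, n_models = n_models), class = "change_result")
}

# Per-pixel plurality over a list of class maps; ties -> lowest class id.
plurality_map <- function(stack) {
  if (length(stack) == 1L) return(stack[[1L]])
  d <- dim(stack[[1L]])
  classes <- sort(unique(unlist(lapply(stack, function(m)
    unique(as.integer(m[!is.na(m)]))))))
  counts <- array(0L, c(length(classes), length(stack[[1L]])))
  for (m in stack)
    for (i in seq_along(classes))
      counts[i, ] <- counts[i, ] + (as.integer(m) == classes[i])
  out <- classes[apply(counts, 2L, which.max)]  # which.max: first max = lowest id
  matrix(out, d[1L], d[2L])
}

#' Write a change ledger as CSV
#'
#' @param result a `change_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_change_ledger <- function(result, path) {
  write.csv(result$ledger, path, row.names = FALSE)
  invisible(path)
}
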