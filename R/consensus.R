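## GLM-MKL consensus: combine a significant MKL model's voxel weight map
## with a significant group-ANCOVA F-map.  Weight z-scores (mean / SE over
## cross-validation folds) and F-values are each min-max rescaled to [0, 1],
## thresholded at their own 95th percentile over the analysis mask, and
## intersected.  The z-map keeps its sign before rescaling, so only voxels
## pushing the decision in one direction can survive a high percentile.

#' Weight z-score map from cross-validated weights
#'
#' `z = mean / max(SE, eps)` with `eps = 1e-12`; the sign of the mean is
#' preserved.  An all-zero SE map (identical folds) is degenerate.
#'
#' @param weight_mean,weight_se aligned voxel vectors (from
#'   [compute_weight_maps()]).
#' @return voxel vector of z-scores.
#' @export
weight_zmap <- function(weight_mean, weight_se) {
  cc_assert(length(weight_mean) == length(weight_se), "consistency",
            "mean and SE maps must be aligned")
  cc_assert(all(weight_se >= 0), "validation", "SE must be nonnegative")
  if (all(weight_se == 0))
    cc_stop("degenerate", "all-fold-identical weights: SE map is all zero")
  z <- weight_mean / pmax(weight_se, 1e-12)
  z[weight_mean == 0] <- 0
  z
}

#' Min-max rescale a map to [0, 1]
#'
#' `(x - min) / (max - min)` over the analysis mask.
#'
#' @param map numeric voxel vector.
#' @return rescaled vector with min 0 and max 1.
#' @export
minmax_rescale <- function(map) {
  lo <- min(map); hi <- max(map)
  if (hi <= lo)
    cc_stop("rescale", "constant map cannot be min-max rescaled")
  (map - lo) / (hi - lo)
}

#' Percentile-threshold two maps and intersect
#'
#' Each map is thresholded at its own `percentile` (linear-interpolation
#' definition, over the shared analysis mask); the intersection of the two
#' surviving voxel sets is returned.
#'
#' @param map_a,map_b aligned voxel vectors.
#' @param percentile threshold percentile in (0, 100).
#' @return logical voxel vector of the intersection.
#' @export
percentile_threshold_intersect <- function(map_a, map_b, percentile = 95) {
  cc_assert(length(map_a) == length(map_b), "consistency",
            "maps must share the mask")
  cc_assert(percentile > 0 && percentile < 100, "validation",
            "percentile must lie in (0, 100)")
  ta <- quantile(map_a, percentile / 100, names = FALSE)  # type 7 (linear)
  tb <- quantile(map_b, percentile / 100, names = FALSE)
  (map_a > ta) & (map_b > tb)
}

#' GLM-MKL consensus map
#'
#' Full consensus for one (MKL model, seed map) pair: weight z-scores,
#' min-max rescaling of both the z-map and the F-map, 95th-percentile
#' thresholding and intersection.  Intended for pairs where the MKL model
#' performed above chance (`perm_p < 0.05`) and the GLM map carries at
#' least one FDR-significant cluster; the caller gates on those conditions
#' (as [run_full_pipeline()] does).
#'
#' @param weight_map one kernel's entry from [compute_weight_maps()]
#'   (list with `mean` and `se`).
#' @param f_map a `voxel_stat_map` from [fit_voxelwise_ancova()], on the
#'   same mask.
#' @param percentile threshold percentile.
#' @param provenance optional identifier list (model id, seed map id).
#' @return an object of class `consensus_map`: `zmap`, `rescaled_z`,
#'   `rescaled_f`, logical `intersection`, `threshold_percentile`,
#'   `provenance` and the voxel geometry.
#' @export
consensus_map <- function(weight_map, f_map, percentile = 95,
                          provenance = NULL) {
  z <- weight_zmap(weight_map$mean, weight_map$se)
  cc_assert(length(z) == length(f_map$stat), "consistency",
            "weight map and F-map must share the analysis mask")
  rz <- minmax_rescale(z)
  rf <- minmax_rescale(f_map$stat)
  inter <- percentile_threshold_intersect(rz, rf, percentile)
  structure(list(zmap = z, rescaled_z = rz, rescaled_f = rf,
                 intersection = inter,
                 threshold_percentile = percentile,
                 provenance = provenance,
                 mask_index = f_map$mask_index, dim3 = f_map$dim3),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat("<consensus_map> ", sum(x$intersection), "/", length(x$intersection),
      " voxels in the consensus set (", x$threshold_percentile,
      "th percentile)\n", sep = "")
  invisible(x)
}

#' Dice overlap between a consensus set and a reference voxel set
#'
#' @param consensus a `consensus_map` (or logical voxel vector over the
#'   mask).
#' @param reference_index linear grid voxel indices of the reference set
#'   (e.g. a planted target block).
#' @param mask_index linear indices of the analysis mask (taken from the
#'   consensus map if available).
#' @return Dice coefficient `2|A n B| / (|A| + |B|)`.
#' @export
dice_overlap <- function(consensus, reference_index, mask_index = NULL) {
  if (inherits(consensus, "consensus_map")) {
    mask_index <- consensus$mask_index
    consensus <- consensus$intersection
  }
  cc_assert(!is.null(mask_index), "validation", "mask_index required")
  a <- mask_index[consensus]
  inter <- length(intersect(a, reference_index))
  denom <- length(a) + length(reference_index)
  if (denom == 0) return(0)
  2 * inter / denom
}
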