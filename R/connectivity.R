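## Seed-to-voxel functional connectivity: per-subject, per-seed Pearson
## correlation of the seed's mean denoised time series with every
## gray-matter voxel, Fisher z-transformed; plus the per-subject global
## correlation (GCOR) used downstream as a group-level covariate.
##
## All correlations use the valid frames only (identical valid set for seed
## and voxel by construction).  Flattened maps use column-major voxel order
## (x fastest).

#' Fisher z-transform of a correlation coefficient
#'
#' `z = atanh(r)` with `|r|` clipped to `1 - 1e-7` so that maps stay finite
#' in the presence of self-seeded voxels.  Odd and strictly increasing.
#'
#' @param r correlation value(s) in `[-1, 1]`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  cc_assert(all(abs(r) <= 1 + 1e-12), "domain", "|r| must be <= 1")
  atanh(pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7))
}

#' Mean seed time series over the valid frames
#'
#' @param drun a `denoised_run`.
#' @param atlas a [seed_atlas()].
#' @param label seed label (1-14).
#' @return numeric vector over valid frames.
#' @export
seed_timeseries <- function(drun, atlas, label) {
  vox <- atlas_label_voxels(atlas, label)
  y <- run_matrix(drun$data)[drun$valid, vox, drop = FALSE]
  rowMeans(y)
}

#' Seed-to-voxel Fisher-z connectivity map
#'
#' Pearson correlation, over valid frames, between the seed's mean time
#' series and every voxel inside `mask`, then Fisher z-transformed.
#' Zero-variance voxels get z = 0 and are reported in the result.
#'
#' @param drun a `denoised_run`.
#' @param atlas a [seed_atlas()].
#' @param label seed label.
#' @param mask logical 3D analysis mask (gray matter); defaults to all
#'   voxels.
#' @return an object of class `fisher_zmap`: `values` (z per mask voxel, in
#'   column-major mask order), `mask_index` (linear voxel indices),
#'   `dim` (grid), `seed_label`, `subject_id`, `n_valid_frames`.
#' @export
seed_to_voxel_map <- function(drun, atlas, label, mask = NULL) {
  nvalid <- sum(drun$valid)
  cc_assert(nvalid >= 10, "validation",
            "need >= 10 valid frames for a connectivity map")
  s <- seed_timeseries(drun, atlas, label)
  d3 <- dim(drun$data)[1:3]
  mask_index <- if (is.null(mask)) seq_len(prod(d3)) else which(as.logical(mask))
  y <- run_matrix(drun$data)[drun$valid, mask_index, drop = FALSE]
  sy <- apply(y, 2, sd)
  flat <- which(sy == 0 | !is.finite(sy))
  r <- rep(0, length(mask_index))
  ok <- setdiff(seq_along(mask_index), flat)
  if (sd(s) == 0)
    cc_stop("validation", "seed series has zero variance")
  if (length(ok) > 0)
    r[ok] <- as.vector(cor(s, y[, ok, drop = FALSE]))
  if (length(flat) > 0)
    message(drun$subject_id, " seed ", label, ": ", length(flat),
            " zero-variance voxel(s) set to z = 0")
  structure(list(values = fisher_z(r), mask_index = mask_index, dim = d3,
                 seed_label = label, subject_id = drun$subject_id,
                 n_valid_frames = nvalid, flat_voxels = flat),
            class = "fisher_zmap")
}

#' @export
print.fisher_zmap <- function(x, ...) {
  cat("<fisher_zmap> ", x$subject_id, " seed ", x$seed_label, ": ",
      length(x$values), " voxels, ", x$n_valid_frames, " valid frames\n",
      sep = "")
  invisible(x)
}

#' Expand a flattened map to a 3D volume
#' @param values per-voxel values over `mask_index`.
#' @param mask_index linear voxel indices.
#' @param dim3 grid shape.
#' @export
map_to_volume <- function(values, mask_index, dim3) {
  vol <- array(0, dim3)
  vol[mask_index] <- values
  vol
}

#' Global correlation (GCOR) of a denoised run
#'
#' Average of all pairwise voxel-voxel correlations (self-pairs included)
#' over the mask, computed in closed form as the squared Euclidean norm of
#' the mean of the unit-norm (centred, scaled) voxel time series — identical
#' to the mean of the full correlation matrix but without forming it.
#' Zero-variance voxels are excluded.
#'
#' @param drun a `denoised_run`.
#' @param mask logical 3D mask (gray matter).
#' @return GCOR value in `[0, 1]`.
#' @export
gcor <- function(drun, mask = NULL) {
  d3 <- dim(drun$data)[1:3]
  mask_index <- if (is.null(mask)) seq_len(prod(d3)) else which(as.logical(mask))
  cc_assert(length(mask_index) >= 2, "validation", "need >= 2 voxels for GCOR")
  cc_assert(sum(drun$valid) >= 10, "validation",
            "need >= 10 valid frames for GCOR")
  y <- run_matrix(drun$data)[drun$valid, mask_index, drop = FALSE]
  y <- sweep(y, 2, colMeans(y))
  nrm <- sqrt(colSums(y^2))
  keep <- nrm > 0
  y <- sweep(y[, keep, drop = FALSE], 2, nrm[keep], "/")
  u <- rowMeans(y)
  sum(u^2)
}

#' All seed maps for one subject
#'
#' Vectorised equivalent of calling [seed_to_voxel_map()] for every atlas
#' label: one matrix correlation over the valid frames.
#'
#' @param drun a `denoised_run`.
#' @param atlas a [seed_atlas()].
#' @param mask analysis mask.
#' @return matrix seeds x voxels of Fisher-z values (rows named by seed).
#' @export
all_seed_maps <- function(drun, atlas, mask = NULL) {
  cc_assert(sum(drun$valid) >= 10, "validation",
            "need >= 10 valid frames for connectivity maps")
  d3 <- dim(drun$data)[1:3]
  mask_index <- if (is.null(mask)) seq_len(prod(d3)) else which(as.logical(mask))
  yfull <- run_matrix(drun$data)[drun$valid, , drop = FALSE]
  s <- vapply(seq_along(atlas$names), function(l)
    rowMeans(yfull[, which(atlas$labels == l), drop = FALSE]),
    numeric(nrow(yfull)))
  r <- suppressWarnings(cor(s, yfull[, mask_index, drop = FALSE]))
  r[!is.finite(r)] <- 0
  maps <- fisher_z(r)
  rownames(maps) <- names(atlas$names)
  maps
}
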