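## Motion quality control: framewise displacement (FD) under three
## conventions and censoring of invalid volumes.
##
## All variants define FD[1] = 0 (no predecessor frame), so frame 1 is never
## FD-flagged.  Motion parameters follow the SPM rp_*.txt convention:
## translations in mm, rotations in radians.  The rotation-to-mm conversion
## differs per variant: Power sums absolute increments scaled by a 50 mm
## sphere radius, Jenkinson integrates the displacement of an 80 mm sphere
## under the relative rigid transform, and the ART-style composite takes the
## maximum displacement over the corners of a head-sized bounding box.

check_motion <- function(m) {
  m <- as.matrix(m)
  cc_assert(ncol(m) == 6, "format", "motion parameters must have 6 columns")
  cc_assert(nrow(m) >= 2, "length", "FD needs at least 2 frames")
  cc_assert(all(is.finite(m)), "validation", "motion parameters must be finite")
  m
}

#' Framewise displacement, Power convention
#'
#' `FD[t] = sum(|delta translations|) + sphere_mm * sum(|delta rotations|)`,
#' i.e. absolute backward differences of the six parameters with rotations
#' converted to arc length on a sphere of radius `sphere_mm` (50 mm by
#' convention).
#'
#' @param m frames x 6 motion matrix (tx, ty, tz in mm; rotations in rad).
#' @param sphere_mm rotation-to-translation conversion radius.
#' @return per-frame FD series in mm; `FD[1] = 0`.
#' @export
fd_power <- function(m, sphere_mm = 50) {
  m <- check_motion(m)
  d <- abs(diff(m))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      sphere_mm * rowSums(d[, 4:6, drop = FALSE]))
}

## rigid-body transform from 6 parameters (SPM order of rotations:
## R = Rx(pitch) %*% Ry(roll) %*% Rz(yaw), translation applied last)
rigid_transform <- function(p) {
  cx <- cos(p[4]); sx <- sin(p[4])
  cy <- cos(p[5]); sy <- sin(p[5])
  cz <- cos(p[6]); sz <- sin(p[6])
  rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  t_mat <- diag(4)
  t_mat[1:3, 1:3] <- rx %*% ry %*% rz
  t_mat[1:3, 4] <- p[1:3]
  t_mat
}

#' Framewise displacement, Jenkinson convention
#'
#' Root-mean-square displacement of a sphere of radius `sphere_mm` (80 mm by
#' convention) under the relative transform between consecutive frames:
#' `FD[t] = sqrt(R^2/5 * trace(t(A) %*% A) + t(b) %*% b)` where
#' `[A | b] = T_t %*% solve(T_{t-1}) - I`.
#'
#' @inheritParams fd_power
#' @export
fd_jenkinson <- function(m, sphere_mm = 80) {
  m <- check_motion(m)
  n <- nrow(m)
  tr_list <- lapply(seq_len(n), function(t) rigid_transform(m[t, ]))
  inv_rigid <- function(tt) {       # analytic inverse: [R' | -R'p]
    out <- diag(4)
    r <- t(tt[1:3, 1:3])
    out[1:3, 1:3] <- r
    out[1:3, 4] <- -r %*% tt[1:3, 4]
    out
  }
  fd <- numeric(n)
  for (t in 2:n) {
    rel <- tr_list[[t]] %*% inv_rigid(tr_list[[t - 1]]) - diag(4)
    a <- rel[1:3, 1:3]
    b <- rel[1:3, 4]
    fd[t] <- sqrt(sphere_mm^2 / 5 * sum(a * a) + sum(b * b))
  }
  fd
}

#' Framewise displacement, ART-style composite
#'
#' Maximum Euclidean displacement, between consecutive rigid-body
#' transforms, over the eight corners of a head-sized bounding box centred
#' at the origin.  The box dimensions (mm) are configurable; the published
#' composite is a single-number summary thresholded at 0.5 mm, which this
#' definition preserves.
#'
#' @inheritParams fd_power
#' @param box_mm bounding-box edge lengths (x, y, z) in mm.
#' @export
fd_art <- function(m, box_mm = c(140, 180, 115)) {
  m <- check_motion(m)
  n <- nrow(m)
  half <- box_mm / 2
  corners <- t(as.matrix(expand.grid(c(-1, 1) * half[1],
                                     c(-1, 1) * half[2],
                                     c(-1, 1) * half[3])))
  corners <- rbind(corners, 1)
  prev <- rigid_transform(m[1, ]) %*% corners
  fd <- numeric(n)
  for (t in 2:n) {
    cur <- rigid_transform(m[t, ]) %*% corners
    fd[t] <- sqrt(max(colSums((cur[1:3, ] - prev[1:3, ])^2)))
    prev <- cur
  }
  fd
}

FD_VARIANTS <- c(art = "fd_art", power = "fd_power", jenkinson = "fd_jenkinson")

#' Censor invalid volumes by motion and global-intensity criteria
#'
#' A frame is invalid if its framewise displacement (under the chosen
#' variant; ART composite by default) exceeds `fd_thresh_mm`, or if the
#' global mean intensity over the brain mask deviates from the run's own
#' session mean by more than `z_thresh` standard deviations.  All three FD
#' variants are reported for QC-summary purposes regardless of the variant
#' used for flagging.
#'
#' @param run a [bold_run()].
#' @param m frames x 6 motion matrix.
#' @param brain_mask logical 3D array (defaults to all voxels).
#' @param fd_variant one of "art", "power", "jenkinson".
#' @param fd_thresh_mm FD threshold in mm.
#' @param z_thresh global-intensity z-score threshold.
#' @param variants FD variants to compute (must include `fd_variant`);
#'   restricting to the flagging variant skips the Table-1-style extras.
#' @return an object of class `qc_result` with per-frame FD series
#'   (`fd_art`, `fd_power`, `fd_jenkinson`), `intensity_z`, logical
#'   `invalid`, `pct_invalid`, and per-variant mean FD before/after
#'   censoring (`fd_before`, `fd_after`).
#' @export
censor_volumes <- function(run, m, brain_mask = NULL, fd_variant = "art",
                           fd_thresh_mm = 0.5, z_thresh = 3,
                           variants = names(FD_VARIANTS)) {
  cc_assert(fd_variant %in% names(FD_VARIANTS), "validation",
            "fd_variant must be one of art, power, jenkinson")
  cc_assert(fd_variant %in% variants, "validation",
            "variants must include the flagging fd_variant")
  m <- check_motion(m)
  nt <- n_volumes(run)
  if (nrow(m) != nt)
    cc_stop("consistency", paste0("motion has ", nrow(m),
                                  " frames but the run has ", nt))
  y <- run_matrix(run)
  if (!is.null(brain_mask)) y <- y[, as.logical(brain_mask), drop = FALSE]
  g <- rowMeans(y)
  sg <- sd(g)
  intensity_z <- if (sg > 0) (g - mean(g)) / sg else rep(0, nt)

  fd <- list(art = NULL, power = NULL, jenkinson = NULL)
  for (v in variants) fd[[v]] <- do.call(FD_VARIANTS[[v]], list(m))
  invalid <- (fd[[fd_variant]] > fd_thresh_mm) | (abs(intensity_z) > z_thresh)
  valid <- !invalid
  structure(list(
    fd_art = fd$art, fd_power = fd$power, fd_jenkinson = fd$jenkinson,
    intensity_z = intensity_z, invalid = invalid,
    fd_variant = fd_variant, fd_thresh_mm = fd_thresh_mm,
    z_thresh = z_thresh,
    pct_invalid = 100 * mean(invalid),
    fd_before = vapply(fd[variants], mean, 0),
    fd_after = vapply(fd[variants], function(f)
      if (any(valid)) mean(f[valid]) else NA_real_, 0)),
    class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result> ", sum(x$invalid), "/", length(x$invalid),
      " frames invalid (", round(x$pct_invalid, 1), "%), variant ",
      x$fd_variant, "\n", sep = "")
  invisible(x)
}

#' Cohort-level motion QC summary
#'
#' One row per group: mean (SD) of the per-subject percentage of invalid
#' scans and of mean FD before/after censoring for each FD variant —
#' the layout conventionally reported for motion censoring.
#'
#' @param qc_list list of `qc_result`, one per subject.
#' @param groups group label per subject.
#' @return `data.frame` with one row per group.
#' @export
qc_summary <- function(qc_list, groups) {
  cc_assert(length(qc_list) == length(groups), "consistency",
            "one qc_result per subject required")
  per_subj <- data.frame(
    group = groups,
    pct_invalid = vapply(qc_list, function(q) q$pct_invalid, 0),
    art_before = vapply(qc_list, function(q) q$fd_before["art"], 0),
    power_before = vapply(qc_list, function(q) q$fd_before["power"], 0),
    jenkinson_before = vapply(qc_list, function(q) q$fd_before["jenkinson"], 0),
    art_after = vapply(qc_list, function(q) q$fd_after["art"], 0),
    power_after = vapply(qc_list, function(q) q$fd_after["power"], 0),
    jenkinson_after = vapply(qc_list, function(q) q$fd_after["jenkinson"], 0))
  agg <- function(v, g) tapply(v, g, function(x)
    sprintf("%.2f (%.2f)", mean(x), sd(x)))
  groups_u <- unique(groups)
  out <- data.frame(group = groups_u)
  for (cn in setdiff(names(per_subj), "group"))
    out[[cn]] <- as.vector(agg(per_subj[[cn]], per_subj$group)[groups_u])
  out
}
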