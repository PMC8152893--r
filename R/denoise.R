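## Nuisance removal from voxel time series: aCompCor tissue components,
## motion regressors and their first-order temporal derivatives, spike
## (outlier-frame) indicators, intercept and linear drift; then band-pass
## filtering over the valid frames and optional Gaussian smoothing.
##
## The stages run sequentially (regression, then filtering); the filter is a
## discrete-Fourier-domain mask over the valid frames, and invalid frames
## are excluded from all later correlation sums rather than interpolated.

#' Binary erosion of a 3D mask (6-connectivity)
#' @param mask logical 3D array.
#' @param voxels number of erosion passes.
#' @return eroded logical array.
#' @export
erode_mask <- function(mask, voxels = 1) {
  m <- array(as.logical(mask), dim(mask))
  d <- dim(m)
  shift <- function(a, axis, by) {
    n <- d[axis]
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    pad <- array(FALSE, d)
    idx_dst <- list(1:d[1], 1:d[2], 1:d[3]); idx_dst[[axis]] <- dst
    idx_src <- list(1:d[1], 1:d[2], 1:d[3]); idx_src[[axis]] <- src
    pad[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      a[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    pad
  }
  for (pass in seq_len(voxels)) {
    out <- m
    for (axis in 1:3)
      out <- out & shift(m, axis, 1) & shift(m, axis, -1)
    m <- out
  }
  m
}

#' Principal-component nuisance time courses from a tissue mask (aCompCor)
#'
#' Extracts the top principal-component time courses of the demeaned
#' voxels-by-time matrix inside the (eroded) mask.  Erosion by one voxel is
#' the partial-volume correction surrogate.  Components are unit-norm,
#' mutually orthogonal and ordered by explained variance.
#'
#' @param run a [bold_run()].
#' @param mask logical 3D array (white-matter or CSF mask).
#' @param n_components number of components requested (5 per tissue by
#'   CONN-style convention); capped at the matrix rank with a warning.
#' @param erode_voxels erosion passes applied to the mask before extraction.
#' @return frames x components matrix.
#' @export
acompcor_components <- function(run, mask, n_components = 5,
                                erode_voxels = 1) {
  em <- erode_mask(mask, erode_voxels)
  if (!any(em))
    cc_stop("erosion", paste0(
      "tissue mask erodes to empty with erode_voxels = ", erode_voxels,
      "; reduce erode_voxels"))
  y <- run_matrix(run)[, as.logical(em), drop = FALSE]
  y <- sweep(y, 2, colMeans(y))
  nt <- nrow(y); nv <- ncol(y)
  kmax <- min(nt - 1L, nv)
  if (n_components > kmax) {
    warning("requested ", n_components, " components but rank allows ", kmax)
    n_components <- kmax
  }
  ## time courses are eigenvectors of the T x T Gram matrix
  gram <- tcrossprod(y) / nv
  e <- eigen(gram, symmetric = TRUE)
  comp <- e$vectors[, seq_len(n_components), drop = FALSE]
  colnames(comp) <- paste0("pc", seq_len(n_components))
  comp
}

#' Assemble the confound regressor matrix
#'
#' Columns: `n_compcor` white-matter PCs, `n_compcor` CSF PCs, the six
#' motion parameters, their six backward-difference temporal derivatives
#' (first-frame derivative 0), one indicator column per invalid frame, an
#' intercept, and a linear drift term.  Linearly dependent columns are
#' dropped with a warning.
#'
#' @param run a [bold_run()].
#' @param masks list with logical `white` and `csf` 3D masks.
#' @param motion frames x 6 motion matrix.
#' @param qc a [censor_volumes()] result (or NULL for no spike columns).
#' @param n_compcor components per tissue.
#' @param erode_voxels erosion for the tissue masks.
#' @param drift include intercept + linear drift (on by default).
#' @return frames x regressors numeric matrix with unique column names.
#' @export
build_confounds <- function(run, masks, motion, qc = NULL, n_compcor = 5,
                            erode_voxels = 1, drift = TRUE) {
  nt <- n_volumes(run)
  motion <- check_motion(motion)
  cc_assert(nrow(motion) == nt, "consistency",
            "motion and run frame counts differ")
  invalid <- if (is.null(qc)) rep(FALSE, nt) else qc$invalid
  cc_assert(length(invalid) == nt, "consistency",
            "qc and run frame counts differ")
  if (all(invalid))
    cc_stop("validation", "all frames invalid: nothing left to fit")

  wm <- acompcor_components(run, masks$white, n_compcor, erode_voxels)
  csf <- acompcor_components(run, masks$csf, n_compcor, erode_voxels)
  colnames(wm) <- paste0("wm_", colnames(wm))
  colnames(csf) <- paste0("csf_", colnames(csf))
  dmotion <- rbind(0, diff(motion))
  colnames(dmotion) <- paste0("d_", colnames(motion))
  x <- cbind(wm, csf, motion, dmotion)
  if (any(invalid)) {
    spikes <- sapply(which(invalid), function(t) {
      v <- numeric(nt); v[t] <- 1; v
    })
    colnames(spikes) <- paste0("spike_", which(invalid))
    x <- cbind(x, spikes)
  }
  if (drift) {
    x <- cbind(x, intercept = 1,
               drift = seq(-0.5, 0.5, length.out = nt))
  }
  ## drop linearly dependent columns (pivoted QR)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop_idx <- qx$pivot[(qx$rank + 1):ncol(x)]
    warning("dropping linearly dependent confound column(s): ",
            paste(colnames(x)[drop_idx], collapse = ", "))
    x <- x[, -drop_idx, drop = FALSE]
  }
  x
}

#' Regress confounds out of every voxel time series
#'
#' Per-voxel ordinary-least-squares residuals against the confound matrix.
#' Frames carrying spike indicators are marked invalid in the output (their
#' residuals are exactly zero).  Voxels with non-finite series are masked
#' (residual set to zero) and reported.
#'
#' @param run a [bold_run()].
#' @param confounds matrix from [build_confounds()].
#' @return an object of class `denoised_run`: residual data (4D), logical
#'   `valid` per frame, `passband_hz` (NA until [bandpass()]), and the run
#'   metadata.
#' @export
regress_confounds <- function(run, confounds) {
  nt <- n_volumes(run)
  cc_assert(nrow(confounds) == nt, "consistency",
            "confounds and run frame counts differ")
  y <- run_matrix(run)
  bad <- which(!apply(is.finite(y), 2, all))
  if (length(bad) > 0) {
    message("masking ", length(bad), " non-finite voxel series")
    y[, bad] <- 0
  }
  res <- qr.resid(qr(confounds), y)
  if (length(bad) > 0) res[, bad] <- 0
  spike_cols <- grep("^spike_", colnames(confounds), value = TRUE)
  valid <- rep(TRUE, nt)
  if (length(spike_cols) > 0)
    valid[as.integer(sub("spike_", "", spike_cols))] <- FALSE
  d <- dim(run$data)
  structure(list(data = array(t(res), d), valid = valid,
                 passband_hz = c(NA_real_, NA_real_),
                 tr_seconds = run$tr_seconds, affine = run$affine,
                 subject_id = run$subject_id, masked_voxels = bad),
            class = "denoised_run")
}

#' @export
print.denoised_run <- function(x, ...) {
  cat("<denoised_run> ", x$subject_id, ": ", sum(x$valid), "/",
      length(x$valid), " valid frames, passband ",
      if (all(is.finite(x$passband_hz)))
        paste0(x$passband_hz[1], "-", x$passband_hz[2], " Hz")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Band-pass filter a denoised run
#'
#' Discrete-Fourier mask filter applied to the valid frames (treated as
#' regularly sampled at TR): coefficients at frequencies outside
#' `[low_hz, high_hz]` — including DC — are zeroed and the series inverse
#' transformed.  Invalid frames stay zero and excluded.
#'
#' @param drun a `denoised_run`.
#' @param low_hz,high_hz passband edges; require
#'   `0 <= low < high < 1/(2 TR)`.
#' @return the filtered `denoised_run` with `passband_hz` set.
#' @export
bandpass <- function(drun, low_hz = 0.008, high_hz = 0.09) {
  cc_assert(inherits(drun, "denoised_run"), "validation",
            "bandpass expects a denoised_run")
  nyq <- 1 / (2 * drun$tr_seconds)
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    cc_stop("validation", paste0("passband must satisfy 0 <= low < high < ",
                                 "Nyquist (", signif(nyq, 4), " Hz)"))
  drun$data <- array(t(bandpass_matrix(run_matrix(drun$data), drun$valid,
                                       drun$tr_seconds, low_hz, high_hz)),
                     dim(drun$data))
  drun$passband_hz <- c(low_hz, high_hz)
  drun
}

## DFT mask filter on a frames x voxels matrix over the valid frames;
## invalid frames come back as zeros
bandpass_matrix <- function(y, valid, tr, low_hz, high_hz) {
  vi <- which(valid)
  yv <- y[vi, , drop = FALSE]
  n <- length(vi)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) / (n * tr)
  keep <- freq >= low_hz & freq <= high_hz
  yf <- mvfft(yv)
  yf[!keep, ] <- 0
  y[] <- 0
  y[vi, ] <- Re(mvfft(yf, inverse = TRUE)) / n
  y
}

## 1D Gaussian convolution matrix (zero-padded boundaries)
gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  kern <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  kern <- kern / sum(kern)
  k_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1, i - r):pmin(n, i + r)
    k_mat[i, j] <- kern[j - i + r + 1]
  }
  k_mat
}

#' Gaussian spatial smoothing of a run
#'
#' Per-frame separable 3D Gaussian convolution with
#' `sigma = fwhm / (2 sqrt(2 log 2))`, converted to voxels per axis from
#' the affine's voxel sizes (anisotropic voxels get per-axis sigmas).
#' Boundaries are zero-padded, so total intensity is preserved on interior
#' support.
#'
#' @param run a [bold_run()] (or `denoised_run`).
#' @param fwhm_mm kernel full width at half maximum in mm.
#' @return the smoothed object, same class.
#' @export
smooth_run <- function(run, fwhm_mm = 8) {
  vox_mm <- sqrt(colSums(run$affine[1:3, 1:3]^2))
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / vox_mm
  arr <- run$data
  d <- dim(arr)
  k1 <- gauss_conv_matrix(d[1], sigma_vox[1])
  k2 <- gauss_conv_matrix(d[2], sigma_vox[2])
  k3 <- gauss_conv_matrix(d[3], sigma_vox[3])
  ## axis 1
  arr <- array(k1 %*% matrix(arr, d[1]), d)
  ## axis 2
  arr <- aperm(array(k2 %*% matrix(aperm(arr, c(2, 1, 3, 4)), d[2]),
                     d[c(2, 1, 3, 4)]), c(2, 1, 3, 4))
  ## axis 3
  arr <- aperm(array(k3 %*% matrix(aperm(arr, c(3, 1, 2, 4)), d[3]),
                     d[c(3, 1, 2, 4)]), c(2, 3, 1, 4))
  run$data <- arr
  run
}

#' One-call denoising of a run
#'
#' Convenience wrapper: assemble confounds ([build_confounds()]), regress
#' them out ([regress_confounds()]) and band-pass filter ([bandpass()]).
#' When `analysis_mask` is given, regression and filtering are restricted
#' to those voxels (the confounds still come from the full run); voxels
#' outside the mask are zero in the output.
#'
#' @inheritParams build_confounds
#' @param low_hz,high_hz passband edges.
#' @param analysis_mask optional logical 3D mask of the voxels the later
#'   stages will read (e.g. gray matter).
#' @return a `denoised_run`.
#' @export
denoise_run <- function(run, masks, motion, qc, n_compcor = 5,
                        erode_voxels = 1, low_hz = 0.008, high_hz = 0.09,
                        analysis_mask = NULL) {
  conf <- build_confounds(run, masks, motion, qc, n_compcor = n_compcor,
                          erode_voxels = erode_voxels)
  if (is.null(analysis_mask))
    return(bandpass(regress_confounds(run, conf), low_hz, high_hz))
  idx <- which(as.logical(analysis_mask))
  res <- qr.resid(qr(conf), run_matrix(run)[, idx, drop = FALSE])
  spike_cols <- grep("^spike_", colnames(conf), value = TRUE)
  valid <- rep(TRUE, n_volumes(run))
  if (length(spike_cols) > 0)
    valid[as.integer(sub("spike_", "", spike_cols))] <- FALSE
  res <- bandpass_matrix(res, valid, run$tr_seconds, low_hz, high_hz)
  d <- dim(run$data)
  full <- matrix(0, prod(d[1:3]), d[4])
  full[idx, ] <- t(res)
  structure(list(data = array(full, d), valid = valid,
                 passband_hz = c(low_hz, high_hz),
                 tr_seconds = run$tr_seconds, affine = run$affine,
                 subject_id = run$subject_id, masked_voxels = integer()),
            class = "denoised_run")
}
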