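## small controlled runs for the denoising stages

make_run <- function(y, dim3 = NULL, tr = 2.5) {
  nv <- ncol(y)
  if (is.null(dim3)) dim3 <- c(nv, 1, 1)
  bold_run(array(t(y), c(dim3, nrow(y))), tr_seconds = tr)
}

test_that("aCompCor recovers a shared tissue signal as PC1", {
  set.seed(1)
  nt <- 60
  sig <- rnorm(nt)
  y <- sig %o% rep(1, 64) + matrix(rnorm(nt * 64, sd = 0.01), nt)
  run <- make_run(y, c(4, 4, 4))
  mask <- array(TRUE, c(4, 4, 4))
  comp <- acompcor_components(run, mask, n_components = 3, erode_voxels = 0)
  ## unit-norm, orthogonal, variance-ordered
  expect_equal(colSums(comp^2), rep(1, 3), ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(comp) - diag(3))), 1e-10)
  expect_gt(abs(cor(comp[, 1], sig)), 0.999)
  ## PC1 dominance: compare eigenvalues of the voxel covariance
  ev <- eigen(tcrossprod(sweep(y, 2, colMeans(y))), symmetric = TRUE,
              only.values = TRUE)$values
  expect_gt(ev[1] / sum(pmax(ev, 0)), 0.99)
})

test_that("aCompCor caps components at the rank and errors on empty erosion", {
  set.seed(2)
  run <- make_run(matrix(rnorm(40 * 27), 40), c(3, 3, 3))
  mask <- array(FALSE, c(3, 3, 3)); mask[1:3, 1, 1] <- TRUE
  expect_warning(comp <- acompcor_components(run, mask, n_components = 5,
                                             erode_voxels = 0),
                 "rank")
  expect_equal(ncol(comp), 3)
  expect_error(acompcor_components(run, mask, erode_voxels = 1),
               class = "corticonn_erosion_error")
})

test_that("the confound matrix has the documented composition", {
  fix <- recovery_fixture()
  cohort <- fix$cohort
  run <- cohort_run(cohort, 1)
  motion <- cohort$motion[[1]]

  no_spikes <- build_confounds(run, cohort$masks, motion, qc = NULL)
  expect_equal(ncol(no_spikes), 24)   # 5+5 compcor, 6 motion, 6 deriv, 2 trend

  qc3 <- list(invalid = rep(FALSE, nrow(motion)))
  qc3$invalid[c(5, 9, 20)] <- TRUE
  with_spikes <- build_confounds(run, cohort$masks, motion, qc = qc3)
  expect_equal(ncol(with_spikes), 27)
  expect_equal(sum(grepl("^spike_", colnames(with_spikes))), 3)
  ## derivative columns are backward differences with first frame 0
  expect_equal(with_spikes[, "d_tx"], c(0, diff(motion[, "tx"])),
               ignore_attr = TRUE)

  qc_all <- list(invalid = rep(TRUE, nrow(motion)))
  expect_error(build_confounds(run, cohort$masks, motion, qc = qc_all),
               class = "corticonn_validation_error")
})

test_that("confound regression projects out the nuisance space", {
  set.seed(3)
  nt <- 80
  conf <- cbind(intercept = 1, drift = seq(-0.5, 0.5, length.out = nt),
                wm = rnorm(nt))
  ## voxel 1: a confound column; voxel 2: orthogonal to all confounds
  v1 <- conf[, "wm"]
  raw <- rnorm(nt)
  v2 <- qr.resid(qr(conf), raw)
  y <- cbind(v1, v2 + 5)  # shift so the intercept matters
  run <- make_run(y, c(2, 1, 1))
  dn <- regress_confounds(run, conf)
  res <- run_matrix(dn$data)
  expect_lt(max(abs(res[, 1])), 1e-8)
  expect_equal(res[, 2], v2, tolerance = 1e-8)
  ## residual orthogonality over valid frames
  dots <- crossprod(conf, res)
  norms <- outer(sqrt(colSums(conf^2)), sqrt(pmax(colSums(res^2), 1e-30)))
  expect_lt(max(abs(dots) / norms), 1e-8)
})

test_that("denoising removes most leaked tissue-confound power from gray matter", {
  fix <- recovery_fixture()
  cohort <- fix$cohort
  run <- cohort_run(cohort, 2)
  motion <- cohort$motion[[2]]
  qc <- censor_volumes(run, motion, cohort$masks$brain,
                       fd_variant = "power", variants = "power")
  conf <- build_confounds(run, cohort$masks, motion, qc)
  dn <- regress_confounds(run, conf)

  ## the WM slab's mean series is (a proxy for) the leaked confound
  wm_sig <- rowMeans(run_matrix(run)[, which(cohort$masks$white)])
  gray_idx <- which(cohort$masks$gray)
  before <- run_matrix(run)[, gray_idx]
  after <- run_matrix(dn$data)[, gray_idx]
  pow <- function(y) mean(as.vector(cor(wm_sig, y))^2, na.rm = TRUE)
  expect_lt(pow(after) / pow(before), 0.1)

  ## residuals orthogonal to every confound column (valid frames)
  v <- dn$valid
  dots <- crossprod(conf[v, ], after[v, ])
  ## spike columns vanish on valid frames; guard their zero norms
  norms <- outer(sqrt(pmax(colSums(conf[v, ]^2), 1e-30)),
                 sqrt(pmax(colSums(after[v, ]^2), 1e-30)))
  expect_lt(max(abs(dots) / norms), 1e-8)
})

test_that("the band-pass filter keeps the passband and removes the rest", {
  nt <- 200; tr <- 2.5
  tt <- (0:(nt - 1)) * tr
  inband <- sin(2 * pi * 0.05 * tt)
  outband <- sin(2 * pi * 0.15 * tt)
  dc <- rep(3, nt)
  dn <- drun_from_matrix(cbind(inband, outband, dc), c(3, 1, 1), tr)
  filt <- bandpass(dn)
  out <- run_matrix(filt$data)
  rms <- function(x) sqrt(mean(x^2))
  expect_gt(rms(out[, 1]) / rms(inband), 0.95)
  expect_lt(rms(out[, 1]) / rms(inband), 1.05)
  expect_lt(rms(out[, 2]) / rms(outband), 0.05)
  expect_lt(max(abs(out[, 3])), 1e-10)
  expect_equal(filt$passband_hz, c(0.008, 0.09))
  expect_error(bandpass(dn, 0.01, 0.3),
               class = "corticonn_validation_error")
})

test_that("band-pass filtering uses only the valid frames", {
  nt <- 120; tr <- 2.5
  set.seed(8)
  y <- matrix(rnorm(nt * 3), nt)
  valid <- rep(TRUE, nt); valid[c(10, 60, 61)] <- FALSE
  dn <- drun_from_matrix(y, c(3, 1, 1), tr)
  dn$valid <- valid
  filt <- bandpass(dn)
  out <- run_matrix(filt$data)
  expect_true(all(out[!valid, ] == 0))
  ## the valid-frame sub-series matches filtering the compacted series
  yv <- y[valid, ]
  n <- nrow(yv)
  freq <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * tr)
  keep <- freq >= 0.008 & freq <= 0.09
  ref <- Re(mvfft(mvfft(yv) * keep, inverse = TRUE)) / n
  expect_equal(out[valid, ], ref, tolerance = 1e-10)
})

test_that("Gaussian smoothing has the right kernel width and preserves mass", {
  dim3 <- c(21, 21, 21)
  arr <- array(0, c(dim3, 1))
  arr[11, 11, 11, 1] <- 1
  run <- bold_run(array(arr, c(dim3, 2))[, , , c(1, 1)],
                  tr_seconds = 2.5, affine = diag(c(3, 3, 3, 1)))
  run$data <- array(0, c(dim3, 2)); run$data[11, 11, 11, ] <- 1
  sm <- smooth_run(run, fwhm_mm = 8)
  vol <- sm$data[, , , 1]
  ## recover sigma from the profile through the peak (moment estimate)
  prof <- vol[, 11, 11]
  mu <- sum((1:21) * prof) / sum(prof)
  sigma_fit <- sqrt(sum(((1:21) - mu)^2 * prof) / sum(prof))
  sigma_expect <- 8 / (2 * sqrt(2 * log(2))) / 3
  expect_equal(sigma_fit, sigma_expect, tolerance = 0.02)
  ## mass preserved in the interior, constant images unchanged
  expect_equal(sum(vol), 1, tolerance = 1e-6)
  const <- run; const$data <- array(5, c(dim3, 2))
  smc <- smooth_run(const, 8)
  inner <- smc$data[6:16, 6:16, 6:16, 1]
  expect_equal(inner, array(5, dim(inner)), tolerance = 1e-6)
})

test_that("mask-restricted denoising equals the full computation on the mask", {
  fix <- recovery_fixture()
  cohort <- fix$cohort
  run <- cohort_run(cohort, 5)
  qc <- censor_volumes(run, cohort$motion[[5]], cohort$masks$brain,
                       fd_variant = "power", variants = "power")
  full <- denoise_run(run, cohort$masks, cohort$motion[[5]], qc)
  masked <- denoise_run(run, cohort$masks, cohort$motion[[5]], qc,
                        analysis_mask = cohort$masks$gray)
  gidx <- which(cohort$masks$gray)
  expect_equal(run_matrix(masked$data)[, gidx],
               run_matrix(full$data)[, gidx], tolerance = 1e-12)
  expect_identical(masked$valid, full$valid)
  ## off-mask voxels are zeroed
  expect_true(all(run_matrix(masked$data)[, -gidx] == 0))
})
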