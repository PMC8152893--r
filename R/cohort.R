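## Synthetic multi-group cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes:
## band-limited (0.01-0.08 Hz) latent circuit signals shared between each
## subcortical seed and its cortical target block, group-dependent coupling
## increases (hyperconnectivity) for the affected groups at the affected
## circuits, white noise, linear drift, tissue confounds leaking weakly into
## gray matter, a per-subject global component (to exercise the GCOR
## covariate), motion traces with censorable spikes, and behavioural scores
## negatively coupled to the planted connectivity.

#' Specification of a synthetic cohort
#'
#' Captures the study conditions of the simulated cohort.  The defaults are
#' the package's reference conditions: four groups, 3 mm isotropic desk-scale
#' grid, 150 volumes at TR 2.5 s, 14 latent circuits (7 "cerebellar" +
#' 7 "striatal"), base seed-target loading 0.4 with a +0.3 increase for the
#' affected groups (DCD, COM) at the affected circuits (somatomotor
#' cortico-cerebellar `cereb2`, frontoparietal cortico-striatal `stria6`).
#'
#' @param n_per_group named integer vector of subjects per group (subset of
#'   TYP, DD, DCD, COM), or a single count applied to all four groups.
#' @param grid_shape integer 3-vector of voxel counts.
#' @param n_volumes frames per run.
#' @param tr_seconds repetition time in seconds.
#' @param n_networks number of latent circuits; the seed atlas layout
#'   requires 14 (7 cerebellar + 7 striatal).
#' @param coupling_base seed/target loading of the latent circuit signal,
#'   in `[0, 1)`.
#' @param coupling_delta loading increase for affected groups at affected
#'   circuits; `coupling_base + coupling_delta` must stay below 1.
#' @param spike_rate expected number of motion spikes per run (Poisson).
#' @param global_signal_sd between-subject spread of the global component
#'   amplitude (mean amplitude 0.3).
#' @param behavior_noise_sd noise SD on the M-ABC percentile scale.
#' @param seed master integer RNG seed; all per-subject streams derive from
#'   it.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 15,
                        grid_shape = c(18L, 22L, 18L),
                        n_volumes = 150L,
                        tr_seconds = 2.5,
                        n_networks = 14L,
                        coupling_base = 0.4,
                        coupling_delta = 0.3,
                        spike_rate = 15,
                        global_signal_sd = 0.1,
                        behavior_noise_sd = 8,
                        seed = 1L) {
  if (is.null(names(n_per_group))) {
    cc_assert(length(n_per_group) == 1, "validation",
              "unnamed n_per_group must be a single count for all four groups")
    n_per_group <- setNames(rep(as.integer(n_per_group), 4), GROUP_LEVELS)
  }
  cc_assert(all(names(n_per_group) %in% GROUP_LEVELS), "validation",
            paste("group labels must be among:",
                  paste(GROUP_LEVELS, collapse = ", ")))
  cc_assert(all(n_per_group >= 1), "validation", "need >= 1 subject per group")
  cc_assert(n_networks == 14L, "validation",
            "the seed atlas layout defines exactly 14 circuits")
  cc_assert(coupling_base >= 0 && coupling_delta >= 0 &&
              coupling_base + coupling_delta < 1, "validation",
            "need 0 <= coupling_base + coupling_delta < 1")
  cc_assert(n_volumes >= 2 && tr_seconds > 0, "validation",
            "need n_volumes >= 2 and tr_seconds > 0")
  structure(list(n_per_group = n_per_group,
                 grid_shape = as.integer(grid_shape),
                 n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 n_networks = as.integer(n_networks),
                 coupling_base = coupling_base,
                 coupling_delta = coupling_delta,
                 spike_rate = spike_rate,
                 global_signal_sd = global_signal_sd,
                 behavior_noise_sd = behavior_noise_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", sum(x$n_per_group), " subjects (",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "),
      "), grid ", paste(x$grid_shape, collapse = "x"),
      ", ", x$n_volumes, " volumes @ TR ", x$tr_seconds, " s\n", sep = "")
  cat("  coupling ", x$coupling_base, " (+", x$coupling_delta,
      " in DCD/COM at cereb2, stria6), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

## latent band of the circuit signals; inside the analysis passband so the
## 0.008-0.09 Hz band-pass preserves them
LATENT_BAND_HZ <- c(0.01, 0.08)

#' Band-limited unit-variance Gaussian signal
#'
#' White Gaussian noise restricted in the discrete-Fourier domain to
#' `[low, high]` Hz and rescaled to unit standard deviation.
#' @noRd
band_limited_signal <- function(n, tr, low = LATENT_BAND_HZ[1],
                                high = LATENT_BAND_HZ[2]) {
  x <- rnorm(n)
  xf <- fft(x)
  k <- seq_len(n) - 1L
  freq <- pmin(k, n - k) / (n * tr)  # two-sided frequency axis
  xf[freq < low | freq > high] <- 0
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) y else y / s
}

#' Generate a rigid-body motion trace with planted censorable spikes
#'
#' Produces a smooth low-amplitude six-parameter trace (three translations in
#' mm, three rotations in radians, SPM `rp_*.txt` convention) whose Power
#' framewise displacement stays below 0.2 mm everywhere except at
#' `spike_frames`, where step displacements push FD above 0.5 mm.
#'
#' @param n_volumes number of frames.
#' @param spike_frames integer frame indices (1-based) at which FD must
#'   exceed 0.5 mm; frame 1 is not allowed (FD is frame-to-frame).
#' @param seed integer RNG seed.
#' @return an `n_volumes` x 6 matrix with columns tx, ty, tz (mm) and
#'   pitch, roll, yaw (rad).
#' @export
generate_motion_trace <- function(n_volumes, spike_frames = integer(),
                                  seed = 1L) {
  cc_assert(n_volumes >= 2, "validation", "need at least 2 frames")
  spike_frames <- sort(unique(as.integer(spike_frames)))
  cc_assert(all(spike_frames >= 2L & spike_frames <= n_volumes), "validation",
            "spike frames must lie in 2..n_volumes (frame 1 has no predecessor)")
  with_seed(seed, {
    width <- min(5L, n_volumes)
    m <- sapply(1:6, function(j) {
      x <- cumsum(rnorm(n_volumes))
      k <- stats::filter(x, rep(1 / width, width), sides = 2)
      k[is.na(k)] <- x[is.na(k)]
      as.numeric(k - mean(k))
    })
    colnames(m) <- c("tx", "ty", "tz", "pitch", "roll", "yaw")
    ## rotations on a plausibly smaller scale than translations
    m[, 4:6] <- m[, 4:6] * 0.002
    ## rescale so the baseline Power FD tops out at 0.15 mm (< 0.2 bound);
    ## Power FD is positively homogeneous in the parameter increments
    fd <- fd_power(m)
    peak <- max(fd)
    if (peak > 0) m <- m * (0.15 / peak)
    ## spikes: persistent translation steps of alternating sign, sized so
    ## Power FD > 0.5 mm exactly at the spike frames (0.8 - 0.15 = 0.65)
    sgn <- 1
    for (f in spike_frames) {
      m[f:n_volumes, "tx"] <- m[f:n_volumes, "tx"] + sgn * 0.8
      sgn <- -sgn
    }
    m
  })
}

## loadings of the tissue/confound components in the voxel signal model
TISSUE_MODEL <- list(wm_self = 0.75, csf_self = 0.75,
                     wm_leak = 0.15, csf_leak = 0.10,
                     global_mean_amp = 0.3, drift_sd = 0.2)

#' Simulate one subject's BOLD run
#'
#' @param spec a [cohort_spec()].
#' @param geom geometry from `cohort_geometry()` (internal layout).
#' @param coupling length-14 loading vector for the subject.
#' @param subject_id identifier stored in the run.
#' @param amp_global amplitude of the subject's global component.
#' @param seed RNG seed for the subject stream.
#' @return a [bold_run()].
#' @noRd
simulate_subject_run <- function(spec, geom, coupling, subject_id,
                                 amp_global, seed) {
  nt <- spec$n_volumes; tr <- spec$tr_seconds
  dim3 <- geom$grid_shape
  nv <- prod(dim3)
  with_seed(seed, {
    latent <- sapply(1:14, function(m) band_limited_signal(nt, tr))
    g <- band_limited_signal(nt, tr)
    c_wm <- band_limited_signal(nt, tr)
    c_csf <- band_limited_signal(nt, tr)

    noise_sd <- rep(1, nv)
    wm_idx <- which(geom$masks$white)
    csf_idx <- which(geom$masks$csf)
    loaded <- vector("list", 14)
    for (m in 1:14) {
      vox <- c(which(geom$atlas$labels == m), geom$targets[[m]])
      loaded[[m]] <- vox
      noise_sd[vox] <- sqrt(pmax(0, 1 - coupling[m]^2))
    }
    noise_sd[wm_idx] <- sqrt(1 - TISSUE_MODEL$wm_self^2)
    noise_sd[csf_idx] <- sqrt(1 - TISSUE_MODEL$csf_self^2)

    y <- matrix(rnorm(nt * nv), nt, nv)
    y <- sweep(y, 2, noise_sd, "*")
    for (m in 1:14) y[, loaded[[m]]] <- y[, loaded[[m]]] + coupling[m] * latent[, m]
    y[, wm_idx] <- y[, wm_idx] + TISSUE_MODEL$wm_self * c_wm
    y[, csf_idx] <- y[, csf_idx] + TISSUE_MODEL$csf_self * c_csf
    gray_idx <- which(geom$masks$gray)
    y[, gray_idx] <- y[, gray_idx] + TISSUE_MODEL$wm_leak * c_wm +
      TISSUE_MODEL$csf_leak * c_csf
    ## global component over the whole brain
    y <- y + amp_global * g
    ## per-voxel linear drift
    tt <- seq(-0.5, 0.5, length.out = nt)
    y <- y + tt %o% rnorm(nv, 0, TISSUE_MODEL$drift_sd)

    arr <- array(t(y), c(dim3, nt))
    bold_run(arr, tr_seconds = tr, affine = geom$affine,
             subject_id = subject_id)
  })
}

AFFECTED_GROUPS <- c("DCD", "COM")
AFFECTED_SEEDS <- c(cereb2 = 2L, stria6 = 13L)  # somatomotor c-cereb, frontoparietal c-stria
## M-ABC percentile model: declines with the mean loading of the affected
## circuits (base loading 0.4 -> ~54th percentile; 0.8 -> ~8th)
MABC_MODEL <- c(intercept = 100, slope = -115)
READING_SHIFT <- -1.5   # latent reading ability shift for DD/COM (SD units)
READING_NOISE <- 0.1    # per-test noise -> pairwise r ~ 0.99, PC1 ~ 99%

#' Generate a ground-truth-annotated synthetic cohort
#'
#' Draws demographics, group-dependent circuit couplings, motion spike
#' frames and behavioural scores for every subject, and (optionally)
#' materialises the BOLD runs and motion traces.  Deterministic for a fixed
#' spec: each subject has an RNG stream derived from the master seed, so
#' regenerating any single subject reproduces it bit-identically.
#'
#' @param spec a [cohort_spec()].
#' @param materialize_runs if `FALSE`, BOLD runs are not kept in memory;
#'   regenerate any subject on demand with [cohort_run()].
#' @return an object of class `cohort`: subject table, masks, seed atlas,
#'   affine, ground truth (affected groups/circuits/targets, per-subject
#'   couplings and spike frames, behaviour model), motion traces, and
#'   (optionally) runs.
#' @export
generate_cohort <- function(spec, materialize_runs = TRUE) {
  cc_assert(inherits(spec, "cohort_spec"), "validation",
            "spec must be a cohort_spec")
  geom <- cohort_geometry(spec$grid_shape)
  groups <- rep(names(spec$n_per_group), spec$n_per_group)
  n <- length(groups)

  demo <- with_seed(spec$seed, {
    center <- unlist(lapply(spec$n_per_group, function(k)
      rep(c("A", "B"), length.out = k)), use.names = FALSE)
    gender <- unlist(lapply(spec$n_per_group, function(k)
      sample(rep(c("F", "M"), length.out = k))), use.names = FALSE)
    age <- round(runif(n, 8, 12), 2)
    list(center = center, gender = gender, age = age)
  })

  coupling <- matrix(spec$coupling_base, n, 14,
                     dimnames = list(NULL, seed_names()))
  affected_subj <- groups %in% AFFECTED_GROUPS
  coupling[affected_subj, AFFECTED_SEEDS] <-
    spec$coupling_base + spec$coupling_delta

  truth_draws <- with_seed(child_seed(spec$seed, 7919L), {
    spikes <- lapply(seq_len(n), function(i) {
      k <- min(rpois(1, spec$spike_rate), spec$n_volumes - 1L)
      sort(sample(2:spec$n_volumes, k))
    })
    amp_global <- abs(rnorm(n, TISSUE_MODEL$global_mean_amp,
                            spec$global_signal_sd))
    mabc_raw <- MABC_MODEL["intercept"] +
      MABC_MODEL["slope"] * rowMeans(coupling[, AFFECTED_SEEDS, drop = FALSE]) +
      rnorm(n, 0, spec$behavior_noise_sd)
    latent_read <- rnorm(n) + READING_SHIFT * (groups %in% c("DD", "COM"))
    reading <- vapply(1:4, function(j)
      round(100 + 15 * (latent_read + rnorm(n, 0, READING_NOISE)), 2),
      numeric(n))
    if (is.null(dim(reading))) reading <- matrix(reading, nrow = n)
    list(spikes = spikes, amp_global = amp_global,
         mabc = pmin(100, pmax(0, round(mabc_raw, 1))), reading = reading)
  })

  reading <- truth_draws$reading
  colnames(reading) <- paste0("read", 1:4)
  subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n)),
                         group = groups, center = demo$center,
                         gender = demo$gender, age = demo$age,
                         mabc_percentile = truth_draws$mabc,
                         reading, gcor = NA_real_,
                         stringsAsFactors = FALSE)

  motion <- lapply(seq_len(n), function(i)
    generate_motion_trace(spec$n_volumes, truth_draws$spikes[[i]],
                          seed = child_seed(spec$seed, 2L * i)))

  cohort <- structure(list(
    spec = spec,
    subjects = subjects,
    atlas = geom$atlas,
    masks = geom$masks,
    affine = geom$affine,
    truth = list(affected_groups = AFFECTED_GROUPS,
                 affected_seeds = AFFECTED_SEEDS,
                 affected_targets = geom$targets[AFFECTED_SEEDS],
                 targets = geom$targets,
                 true_coupling = coupling,
                 spike_frames = truth_draws$spikes,
                 amp_global = truth_draws$amp_global,
                 behavior_model = MABC_MODEL),
    motion = motion,
    runs = NULL), class = "cohort")

  if (materialize_runs)
    cohort$runs <- lapply(seq_len(n), function(i) cohort_run(cohort, i))
  cohort
}

#' Regenerate one subject's BOLD run from a cohort
#'
#' Deterministic: uses the subject's own RNG stream derived from the master
#' seed, so the result is identical whether or not runs were materialised at
#' generation time.
#'
#' @param cohort a [generate_cohort()] result.
#' @param i subject index.
#' @return a [bold_run()].
#' @export
cohort_run <- function(cohort, i) {
  if (!is.null(cohort$runs) && !is.null(cohort$runs[[i]]))
    return(cohort$runs[[i]])
  geom <- list(grid_shape = cohort$spec$grid_shape, masks = cohort$masks,
               atlas = cohort$atlas, targets = cohort$truth$targets,
               affine = cohort$affine)
  simulate_subject_run(cohort$spec, geom,
                       coupling = cohort$truth$true_coupling[i, ],
                       subject_id = cohort$subjects$subject_id[i],
                       amp_global = cohort$truth$amp_global[i],
                       seed = child_seed(cohort$spec$seed, 2L * i + 1L))
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects, grid ",
      paste(x$spec$grid_shape, collapse = "x"), ", ",
      x$spec$n_volumes, " volumes", if (is.null(x$runs)) " (runs on demand)",
      "\n", sep = "")
  print(table(x$subjects$group))
  invisible(x)
}
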