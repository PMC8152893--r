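## Shared fixtures and independent oracles for the test suite.
## All fixtures are generated in code; expensive ones are memoised for the
## duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

## compact study geometry used throughout the unit tests
small_spec <- function(seed = 1, coupling_delta = 0.3,
                       n_per_group = c(TYP = 5, COM = 5),
                       n_volumes = 100, ...) {
  cohort_spec(n_per_group = n_per_group, grid_shape = c(15, 18, 14),
              n_volumes = n_volumes, coupling_delta = coupling_delta,
              seed = seed, ...)
}

fast_config <- function(spec, ...) {
  pipeline_config(cohort = spec, smooth_fwhm_mm = 0, fd_variant = "power",
                  qc_variants = "power", ...)
}

## one small recovery cohort (planted effect) with its connectivity maps
recovery_fixture <- function() {
  memo("recovery", {
    spec <- small_spec(seed = 101, coupling_delta = 0.4,
                       n_per_group = c(TYP = 8, DD = 8, DCD = 8, COM = 8))
    cohort <- generate_cohort(spec, materialize_runs = FALSE)
    cm <- cohort_fisher_maps(cohort, fast_config(spec))
    list(cohort = cohort, cm = cm)
  })
}

## a wrapper that treats a raw (not denoised) run as analysis-ready, for
## tests that need controlled voxel time series
as_denoised <- function(run, valid = NULL) {
  structure(list(data = run$data,
                 valid = valid %||% rep(TRUE, dim(run$data)[4]),
                 passband_hz = c(NA_real_, NA_real_),
                 tr_seconds = run$tr_seconds, affine = run$affine,
                 subject_id = run$subject_id, masked_voxels = integer()),
            class = "denoised_run")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## build a denoised_run directly from a frames x voxels matrix on a grid
drun_from_matrix <- function(y, dim3, tr = 2.5) {
  as_denoised(bold_run(array(t(y), c(dim3, nrow(y))), tr_seconds = tr))
}

## small separable/noise feature sets for classifier tests
sep_features <- function(n_per_class = 10, nv = 40, gap = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * nv), 2 * n_per_class)
  y <- rep(c(1, -1), each = n_per_class)
  x[y > 0, 1:5] <- x[y > 0, 1:5] + gap
  list(x = x, y = y)
}

## a matched binary_problem over a roster in the given label order
toy_problem <- function(y) {
  structure(list(class_a = "A", class_b = "B",
                 idx_a = which(y > 0), idx_b = which(y < 0),
                 idx = c(which(y > 0), which(y < 0)),
                 y = rep(c(1, -1), each = sum(y > 0)),
                 n_per_class = sum(y > 0),
                 subject_ids = as.character(seq_along(y))),
            class = "binary_problem")
}

## ---- independent oracles -------------------------------------------------

## BH step-up, written independently of stats::p.adjust
bh_stepup_oracle <- function(p) {
  n <- length(p)
  if (n == 0) return(numeric())
  o <- order(p)
  adj <- numeric(n)
  prev <- Inf
  for (k in n:1) {
    val <- min(prev, p[o[k]] * n / k)
    adj[o[k]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

## recursive flood fill over a logical 3D array
flood_fill_oracle <- function(mask3d, connectivity = 18) {
  d <- dim(mask3d)
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(mask3d)
  for (start in idx) {
    if (lab[start] > 0) next
    nxt <- nxt + 1L
    stack <- start
    lab[start] <- nxt
    while (length(stack) > 0) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      co <- arrayInd(v, d)
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        s <- abs(dx) + abs(dy) + abs(dz)
        if (s < 1 || s > lim) next
        p <- co + c(dx, dy, dz)
        if (any(p < 1) || any(p > d)) next
        q <- p[1] + (p[2] - 1) * d[1] + (p[3] - 1) * d[1] * d[2]
        if (mask3d[q] && lab[q] == 0) {
          lab[q] <- nxt
          stack <- c(stack, q)
        }
      }
    }
  }
  lab
}

## partial F for the group factor via lm() on one voxel
ancova_f_oracle <- function(y, subjects, covariates = c("age", "gender", "gcor")) {
  df <- data.frame(y = y, group = factor(subjects$group),
                   age = subjects$age,
                   gender = as.numeric(subjects$gender == "M"),
                   gcor = subjects$gcor)
  full <- lm(y ~ group + age + gender + gcor, data = df)
  red <- lm(y ~ age + gender + gcor, data = df)
  as.numeric(anova(red, full)$F[2])
}

## GCOR by forming the full correlation matrix
gcor_bruteforce <- function(y) {
  keep <- apply(y, 2, sd) > 0
  mean(cor(y[, keep, drop = FALSE]))
}

## dual SVM objective via kernlab's interior-point QP solver
svm_dual_oracle <- function(K, y, C = 1) {
  n <- length(y)
  ip <- kernlab::ipop(c = rep(-1, n), H = K * (y %o% y), A = t(y), b = 0,
                      l = rep(0, n), u = rep(C, n), r = 0, sigf = 10)
  a <- kernlab::primal(ip)
  sum(a) - 0.5 * sum((a * y) * (K %*% (a * y)))
}

## roster with the real study's printed group marginals (sizes, centers,
## gender counts; ages drawn to match the reported means/SDs)
printed_marginal_roster <- function(seed = 1) {
  set.seed(seed)
  make_group <- function(g, n, n_center_a, n_girls, age_mean, age_sd) {
    center <- c(rep("A", n_center_a), rep("B", n - n_center_a))
    gender <- rep("M", n)
    gender[seq_len(n_girls)] <- "F"
    data.frame(subject_id = paste0(g, seq_len(n)), group = g,
               center = center, gender = sample(gender),
               age = round(rnorm(n, age_mean, age_sd), 2),
               mabc_percentile = 50, read1 = 100, read2 = 100,
               read3 = 100, read4 = 100, gcor = 0,
               stringsAsFactors = FALSE)
  }
  rbind(make_group("TYP", 42, 21, 20, 10.10, 1.16),
        make_group("DD", 45, 25, 20, 10.22, 1.09),
        make_group("DCD", 20, 11, 6, 9.96, 1.23),
        make_group("COM", 29, 15, 10, 10.19, 1.31))
}
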