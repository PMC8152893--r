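## Sparse multiple-kernel SVM classification of connectivity maps.
##
## One linear kernel per seed map (14 in the reference layout), mean-centred
## with training-set statistics and trace-normalised per fold; the MKL
## weights d_m live on the probability simplex, which induces sparsity, and
## are optimised by reduced-gradient descent with line search (SimpleMKL
## formulation) around an SMO inner SVM dual solver (compiled).  Class
## imbalance is handled by matched under-sampling (center x gender strata,
## greedy nearest-age pairing); evaluation is leave-one-subject-per-class-
## out cross-validation, with balanced accuracy, rank-based AUC, and
## significance by global permutation of the training labels.

#' Build one linear kernel per seed map
#'
#' `K_m[i, j] = <x_i_m, x_j_m>` over the flattened analysis mask, where
#' `x_i_m` is subject i's Fisher-z map for seed m.
#'
#' @param maps_by_seed named list (one entry per seed) of subjects x voxels
#'   matrices, all with identical subject order and per-seed voxel masks.
#' @param subject_ids roster of subject identifiers.
#' @return an object of class `kernel_bundle`: named list of n x n kernels,
#'   subject roster, and `centered`/`normalized` flags (both `FALSE`).
#' @export
build_linear_kernels <- function(maps_by_seed, subject_ids = NULL) {
  cc_assert(length(maps_by_seed) >= 1, "validation", "need at least one map set")
  n <- nrow(maps_by_seed[[1]])
  nv <- vapply(maps_by_seed, ncol, 0L)
  cc_assert(all(vapply(maps_by_seed, nrow, 0L) == n), "alignment",
            "all seed map matrices must have the same subjects (rows)")
  cc_assert(length(unique(nv)) == 1, "alignment",
            "all seed map matrices must share the voxel mask (columns)")
  kernels <- lapply(maps_by_seed, tcrossprod)
  ## PSD sanity (Gram matrices are PSD up to round-off); jitter if violated
  for (m in seq_along(kernels)) {
    ev <- eigen(kernels[[m]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev), 1)) {
      warning("kernel ", names(kernels)[m] %||% m,
              " is not PSD; adding 1e-8 jitter")
      kernels[[m]] <- kernels[[m]] + diag(1e-8, n)
    }
  }
  structure(list(kernels = kernels,
                 subject_ids = subject_ids %||% paste0("S", seq_len(n)),
                 centered = FALSE, normalized = FALSE),
            class = "kernel_bundle")
}

#' @export
print.kernel_bundle <- function(x, ...) {
  cat("<kernel_bundle> ", length(x$kernels), " kernels over ",
      length(x$subject_ids), " subjects\n", sep = "")
  invisible(x)
}

#' Mean-center and trace-normalise a kernel with training-set statistics
#'
#' Centering uses the training rows/columns only and is applied
#' consistently to held-out entries:
#' `K'(i,j) = K(i,j) - mean_t K(t,j) - mean_t K(i,t) + mean_tt' K(t,t')`
#' with t, t' over the training set; then the kernel is scaled so the
#' training-block trace equals the training-set size.
#'
#' @param K n x n symmetric kernel.
#' @param train_idx training index set.
#' @return the processed kernel, with the scale factor in `attr(, "tau")`.
#' @export
center_normalize_kernel <- function(K, train_idx = seq_len(nrow(K))) {
  cc_assert(length(train_idx) > 0, "validation", "training set is empty")
  mu <- colMeans(K[train_idx, , drop = FALSE])
  mu_all <- mean(mu[train_idx])
  kc <- K - outer(mu, rep(1, ncol(K))) - outer(rep(1, nrow(K)), mu) + mu_all
  tr <- sum(diag(kc)[train_idx])
  if (tr <= 1e-12)
    cc_stop("normalization", "kernel is (numerically) all-zero after centering")
  tau <- length(train_idx) / tr
  structure(kc * tau, tau = tau)
}

#' Binarise groups and match subjects by under-sampling
#'
#' Builds a balanced binary problem from two classes (single groups or
#' pooled mixtures such as DCD-COM).  Subjects are paired greedily by
#' nearest age within MRI-center x gender strata; leftover subjects are
#' paired within center-only strata (with a warning), then globally, until
#' the smaller class is exhausted; the surplus of the larger class is
#' dropped.  Ties break by roster order, so the matching is deterministic.
#'
#' @param subjects subject table.
#' @param class_a,class_b group label(s); pooled labels form a mixture
#'   class.
#' @param seed kept for interface stability; the greedy matcher is
#'   deterministic and does not consume randomness.
#' @return an object of class `binary_problem`: paired subject indices
#'   `idx_a`/`idx_b` (rows of `subjects`), roster `idx = c(idx_a, idx_b)`,
#'   labels `y` (+1 for `class_a`), and class descriptors.
#' @export
binarize_and_match <- function(subjects, class_a, class_b, seed = 1L) {
  in_a <- which(subjects$group %in% class_a)
  in_b <- which(subjects$group %in% class_b)
  cc_assert(length(in_a) > 0 && length(in_b) > 0, "validation",
            "both classes must be nonempty")
  cc_assert(length(intersect(in_a, in_b)) == 0, "validation",
            "classes overlap")

  pair_stratum <- function(a, b) {
    pairs <- matrix(integer(), 2, 0)
    while (length(a) > 0 && length(b) > 0) {
      dmat <- abs(outer(subjects$age[a], subjects$age[b], "-"))
      k <- arrayInd(which.min(dmat), dim(dmat))
      pairs <- cbind(pairs, c(a[k[1]], b[k[2]]))
      a <- a[-k[1]]; b <- b[-k[2]]
    }
    list(pairs = pairs, rest_a = a, rest_b = b)
  }

  strata_of <- function(idx, vars) {
    interaction(lapply(vars, function(v) subjects[[v]][idx]), drop = FALSE)
  }

  pairs <- matrix(integer(), 2, 0)
  rest_a <- in_a; rest_b <- in_b
  for (level in list(c("center", "gender"), "center", character())) {
    if (length(rest_a) == 0 || length(rest_b) == 0) break
    if (length(level) > 0) {
      sa <- strata_of(rest_a, level); sb <- strata_of(rest_b, level)
      new_a <- integer(); new_b <- integer()
      for (s in union(levels(droplevels(sa)), levels(droplevels(sb)))) {
        a <- rest_a[sa == s]; b <- rest_b[sb == s]
        if (length(a) == 0 || length(b) == 0) {
          new_a <- c(new_a, a); new_b <- c(new_b, b)
          next
        }
        res <- pair_stratum(a, b)
        pairs <- cbind(pairs, res$pairs)
        new_a <- c(new_a, res$rest_a); new_b <- c(new_b, res$rest_b)
      }
      if (identical(level, "center") && ncol(pairs) > 0 &&
          (length(new_a) < length(rest_a) && length(new_b) < length(rest_b)))
        warning("some strata were one-sided; matching fell back to ",
                "coarser strata for part of the roster")
      rest_a <- sort(new_a); rest_b <- sort(new_b)
    } else {
      res <- pair_stratum(rest_a, rest_b)
      pairs <- cbind(pairs, res$pairs)
      rest_a <- res$rest_a; rest_b <- res$rest_b
    }
  }

  ord <- order(pairs[1, ])
  pairs <- pairs[, ord, drop = FALSE]
  idx_a <- pairs[1, ]; idx_b <- pairs[2, ]
  structure(list(class_a = class_a, class_b = class_b,
                 idx_a = idx_a, idx_b = idx_b,
                 idx = c(idx_a, idx_b),
                 y = rep(c(1, -1), each = ncol(pairs)),
                 n_per_class = ncol(pairs),
                 subject_ids = subjects$subject_id[c(idx_a, idx_b)]),
            class = "binary_problem")
}

#' @export
print.binary_problem <- function(x, ...) {
  cat("<binary_problem> ", paste(x$class_a, collapse = "+"), " vs ",
      paste(x$class_b, collapse = "+"), ": ", x$n_per_class,
      " per class\n", sep = "")
  invisible(x)
}

mkl_controls <- function(gap_tol = 1e-4, d_tol = 1e-5, max_outer = 200,
                         smo_tol = 1e-8, smo_max_iter = 100000) {
  list(gap_tol = gap_tol, d_tol = d_tol, max_outer = max_outer,
       smo_tol = smo_tol, smo_max_iter = smo_max_iter)
}

#' Fit the sparse multiple-kernel SVM
#'
#' Minimises the soft-margin SVM dual optimum over simplex kernel weights
#' `d` (`d_m >= 0`, `sum d = 1`) with `K(d) = sum_m d_m K_m`, by
#' reduced-gradient descent with a backtracking line search from the
#' maximal feasible step (which drives weights exactly to zero).  The inner
#' problem for fixed `d` is a standard SVM dual, solved by SMO.
#' Convergence: relative simplex-optimality gap below `gap_tol` or weight
#' update below `d_tol`.
#'
#' @param kernels list (or `kernel_bundle`) of centered/normalised n x n
#'   kernels.
#' @param y labels in {-1, +1}.
#' @param C soft-margin constant (1 by default).
#' @param controls list from `mkl_controls()`.
#' @return an object of class `mkl_fit`: simplex weights `d`, dual
#'   coefficients `alpha`, `bias`, `support` indices, dual `objective`,
#'   per-kernel quadratic forms `S` and convergence flag.
#' @export
simple_mkl_fit <- function(kernels, y, C = 1, controls = mkl_controls()) {
  if (inherits(kernels, "kernel_bundle")) kernels <- kernels$kernels
  n <- length(y)
  cc_assert(all(y %in% c(-1, 1)), "validation", "labels must be -1/+1")
  cc_assert(all(vapply(kernels, function(K) all(dim(K) == n), TRUE)),
            "alignment", "kernel dimensions must match the label length")
  ks <- array(unlist(kernels, use.names = FALSE),
              c(n, n, length(kernels)))
  fit <- .simplemkl_fit_cpp(ks, as.numeric(y), C,
                            controls$gap_tol, controls$d_tol,
                            controls$max_outer, controls$smo_tol,
                            controls$smo_max_iter)
  if (!fit$converged) {
    cond <- structure(
      class = c("corticonn_convergence_error", "error", "condition"),
      list(message = paste0("MKL optimisation did not converge within ",
                            controls$max_outer, " outer iterations"),
           call = NULL, last_iterate = fit))
    stop(cond)
  }
  d <- as.numeric(fit$d)
  names(d) <- names(kernels)
  structure(list(d = d, alpha = as.numeric(fit$alpha), bias = fit$b,
                 support = which(fit$alpha > 1e-8), C = C,
                 objective = fit$objective, S = as.numeric(fit$S),
                 outer_iterations = fit$outer_iterations,
                 converged = fit$converged),
            class = "mkl_fit")
}

#' @export
print.mkl_fit <- function(x, ...) {
  cat("<mkl_fit> ", sum(x$d > 0), "/", length(x$d),
      " active kernels, objective ", signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}

## internal CV engine over a roster: kernels (list over full roster), labels
## and a 2 x nfold pair matrix of held-out roster positions
mkl_cv_engine <- function(kernels, y, pairs, C, controls,
                          keep_fold_fits = TRUE) {
  n <- length(y)
  ks <- array(unlist(kernels, use.names = FALSE), c(n, n, length(kernels)))
  .mkl_cv_cpp(ks, as.numeric(y), pairs - 1L, C,
              controls$gap_tol, controls$d_tol, controls$max_outer,
              controls$smo_tol, controls$smo_max_iter, keep_fold_fits)
}

#' Balanced accuracy from confusion counts
#'
#' Mean of the two class accuracies (sensitivity, specificity), in percent,
#' reported to 2 decimals.
#'
#' @param tp,p_total true positives / total positives.
#' @param tn,n_total true negatives / total negatives.
#' @return percentage, rounded to 2 decimals.
#' @export
balanced_accuracy <- function(tp, p_total, tn, n_total) {
  cc_assert(p_total > 0 && n_total > 0, "validation",
            "class totals must be positive")
  cc_assert(tp >= 0 && tp <= p_total && tn >= 0 && tn <= n_total,
            "validation", "counts must satisfy 0 <= correct <= total")
  round(100 * (tp / p_total + tn / n_total) / 2, 2)
}

#' Rank-based AUC of decision values
#'
#' Mann-Whitney formulation with midranks for ties.
#'
#' @param decisions decision values.
#' @param y labels in {-1, +1}.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(decisions, y) {
  pos <- y > 0
  np <- sum(pos); nn <- sum(!pos)
  cc_assert(np > 0 && nn > 0, "validation", "need both classes for AUC")
  r <- rank(decisions)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Leave-one-subject-per-class-out cross-validation of the MKL model
#'
#' Fold k holds out the k-th matched pair; kernel centering and
#' normalisation are recomputed from each training set; pooled held-out
#' decision values give the confusion counts, balanced accuracy and AUC.
#'
#' @param bundle a [build_linear_kernels()] result over all subjects.
#' @param problem a [binarize_and_match()] result.
#' @param C soft-margin constant.
#' @param controls optimiser controls.
#' @return an object of class `cv_result`: per-fold weights `d_folds`
#'   (kernels x folds), fold details, pooled `decisions`, confusion counts,
#'   `balanced_accuracy`, `auc`; `contributions` and `expected_ranking`
#'   via [kernel_contributions()]; `perm_p` is `NA` until
#'   [permutation_test()].
#' @export
loso_cv <- function(bundle, problem, C = 1, controls = mkl_controls()) {
  cc_assert(problem$n_per_class >= 3, "validation",
            "need at least 3 matched pairs for cross-validation")
  ros <- problem$idx
  kernels <- lapply(bundle$kernels, function(K) K[ros, ros, drop = FALSE])
  nc <- problem$n_per_class
  pairs <- rbind(seq_len(nc), nc + seq_len(nc))
  eng <- mkl_cv_engine(kernels, problem$y, pairs, C, controls)
  summarize_cv(eng, problem, bundle, C, pairs)
}

summarize_cv <- function(eng, problem, bundle, C, pairs) {
  y <- problem$y
  dec <- as.numeric(eng$decisions)
  pred <- ifelse(dec > 0, 1, -1)
  tp <- sum(pred == 1 & y == 1); p_total <- sum(y == 1)
  tn <- sum(pred == -1 & y == -1); n_total <- sum(y == -1)
  d_folds <- eng$d_folds
  rownames(d_folds) <- names(bundle$kernels)
  res <- structure(list(
    class_a = problem$class_a, class_b = problem$class_b,
    subject_ids = problem$subject_ids,
    decisions = dec, y = y, pairs = pairs,
    d_folds = d_folds, tau_folds = eng$tau_folds,
    b_folds = as.numeric(eng$b_folds),
    alphas = lapply(eng$alphas, as.numeric),
    trains = lapply(eng$trains, as.integer),
    tp = tp, p_total = p_total, tn = tn, n_total = n_total,
    balanced_accuracy = balanced_accuracy(tp, p_total, tn, n_total),
    auc = auc_rank(dec, y), C = C, perm_p = NA_real_),
    class = "cv_result")
  contrib <- kernel_contributions(res)
  res$contributions <- contrib$contribution
  res$expected_ranking <- contrib$expected_ranking
  res
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", paste(x$class_a, collapse = "+"), " vs ",
      paste(x$class_b, collapse = "+"), ": BA ", x$balanced_accuracy,
      "% (", x$tp, "/", x$p_total, ", ", x$tn, "/", x$n_total, "), AUC ",
      round(x$auc, 2),
      if (!is.na(x$perm_p)) paste0(", perm p = ", signif(x$perm_p, 3)),
      "\n", sep = "")
  invisible(x)
}

#' Permutation significance of the cross-validated balanced accuracy
#'
#' The full cross-validation is re-run under global permutations of the
#' matched roster's labels.  Folds are re-derived from each labelling by
#' the same deterministic rule that yields the observed folds (the i-th
#' positive subject pairs with the i-th negative subject in roster order —
#' which, for the observed labels, reproduces the matched pairs), so the
#' observed and every permuted labelling pass through an identical
#' labels-to-folds-to-CV procedure and the null is exchangeable.
#' `perm_p = (1 + #{perm BA >= observed BA}) / (n_perm + 1)`.
#'
#' @inheritParams loso_cv
#' @param cv an existing [loso_cv()] result for the observed labels
#'   (computed if missing).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutation draw.
#' @return the `cv_result` with `perm_p` (and `perm_ba` distribution)
#'   attached.
#' @export
permutation_test <- function(bundle, problem, C = 1, n_perm = 1000,
                             seed = 1, cv = NULL,
                             controls = mkl_controls()) {
  cc_assert(n_perm >= 1, "validation", "n_perm must be >= 1")
  if (is.null(cv)) cv <- loso_cv(bundle, problem, C, controls)
  ros <- problem$idx
  kernels <- lapply(bundle$kernels, function(K) K[ros, ros, drop = FALSE])
  n <- length(problem$y)
  perm_ba <- with_seed(seed, vapply(seq_len(n_perm), function(p) {
    yp <- sample(problem$y)
    pairs <- rbind(which(yp > 0), which(yp < 0))
    eng <- mkl_cv_engine(kernels, yp, pairs, C, controls,
                         keep_fold_fits = FALSE)
    dec <- as.numeric(eng$decisions)
    pred <- ifelse(dec > 0, 1, -1)
    balanced_accuracy(sum(pred == 1 & yp == 1), sum(yp == 1),
                      sum(pred == -1 & yp == -1), sum(yp == -1))
  }, 0))
  cv$perm_p <- (1 + sum(perm_ba >= cv$balanced_accuracy)) / (n_perm + 1)
  cv$perm_ba <- perm_ba
  cv
}

#' Kernel contributions and expected ranking across folds
#'
#' Contribution is the across-fold mean of `d_m`, in percent (sums to 100).
#' Expected ranking is the across-fold mean of the kernel's rank when each
#' fold's weights are sorted ascending (largest d gets rank = number of
#' kernels); ties get average ranks and exactly-zero weights are pinned to
#' rank 0.
#'
#' @param cv a `cv_result`.
#' @return data frame with `kernel`, `contribution`, `expected_ranking`,
#'   sorted by decreasing contribution.
#' @export
kernel_contributions <- function(cv) {
  d <- cv$d_folds
  ranks <- apply(d, 2, function(v) {
    r <- rank(v, ties.method = "average")
    r[v == 0] <- 0
    r
  })
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = nrow(d))
  out <- data.frame(kernel = rownames(d) %||% paste0("k", seq_len(nrow(d))),
                    contribution = 100 * rowMeans(d),
                    expected_ranking = rowMeans(ranks),
                    row.names = NULL)
  out[order(-out$contribution), ]
}

#' Voxel weight maps of a cross-validated MKL model
#'
#' Per fold and kernel, the primal weight vector of the linear decision
#' function expressed in the original voxel space:
#' `w_m = d_m * sqrt(tau_m) * sum_i alpha_i y_i (x_i_m - xbar_train_m)`,
#' propagating the kernel centering and trace normalisation to features.
#' Returns the across-fold mean and standard error per voxel.
#'
#' @param cv a [loso_cv()] result.
#' @param maps_by_seed the same per-seed feature matrices (over **all**
#'   subjects, same order as the bundle) used to build the kernels.
#' @param problem the matched problem the model was fit on.
#' @return list per kernel with `mean`, `se` (voxel vectors) and the
#'   per-fold matrix `w_folds`.
#' @export
compute_weight_maps <- function(cv, maps_by_seed, problem) {
  nfold <- ncol(cv$d_folds)
  ros <- problem$idx
  out <- vector("list", length(maps_by_seed))
  names(out) <- names(maps_by_seed)
  for (m in seq_along(maps_by_seed)) {
    x <- maps_by_seed[[m]][ros, , drop = FALSE]
    w <- matrix(0, nfold, ncol(x))
    for (k in seq_len(nfold)) {
      dmk <- cv$d_folds[m, k]
      if (dmk == 0) next
      tr <- cv$trains[[k]]
      alpha <- cv$alphas[[k]]
      ytr <- cv$y[tr]
      xtr <- sweep(x[tr, , drop = FALSE], 2, colMeans(x[tr, , drop = FALSE]))
      w[k, ] <- dmk * sqrt(cv$tau_folds[m, k]) *
        colSums(xtr * (alpha * ytr))
    }
    out[[m]] <- list(mean = colMeans(w),
                     se = apply(w, 2, sd) / sqrt(nfold),
                     w_folds = w)
  }
  out
}
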