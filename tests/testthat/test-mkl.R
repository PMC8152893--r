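library(kernlab)
## sep_features() and toy_problem() fixtures live in helper-fixtures.R

test_that("linear kernel construction matches the dense Gram oracle", {
  d <- sep_features()
  maps <- list(a = d$x, b = d$x * 2, c = matrix(rnorm(20 * 40), 20))
  bundle <- build_linear_kernels(maps)
  expect_length(bundle$kernels, 3)
  expect_equal(bundle$kernels$a, d$x %*% t(d$x), tolerance = 1e-10)
  ## 7 + 7 seed map sets give exactly 14 kernels
  maps14 <- setNames(rep(list(d$x), 14),
                     c(paste0("cereb", 1:7), paste0("stria", 1:7)))
  expect_length(build_linear_kernels(maps14)$kernels, 14)
  ## duplicated subject: identical kernel rows and columns
  xd <- rbind(d$x, d$x[1, ])
  kd <- build_linear_kernels(list(m = xd))$kernels$m
  expect_equal(kd[21, ], kd[1, ])
  expect_equal(kd[, 21], kd[, 1])
  expect_error(build_linear_kernels(list(a = d$x, b = d$x[, 1:10])),
               class = "corticonn_alignment_error")
})

test_that("kernel centering and normalisation follow the training-set rule", {
  d <- sep_features(seed = 2)
  K <- d$x %*% t(d$x)
  train <- 1:16
  Kp <- center_normalize_kernel(K, train)
  ## training-block row sums vanish; training trace equals n_train
  expect_lt(max(abs(rowSums(Kp[train, train]))), 1e-6)
  expect_equal(sum(diag(Kp)[train]), length(train), tolerance = 1e-6)
  ## matches explicit feature-space centering and scaling
  xtr <- sweep(d$x, 2, colMeans(d$x[train, ]))
  Kf <- xtr %*% t(xtr)
  tau <- length(train) / sum(diag(Kf)[train])
  expect_equal(unclass(Kp), Kf * tau, tolerance = 1e-8, ignore_attr = TRUE)
  ## idempotence of centering for an already-centered kernel
  K2 <- center_normalize_kernel(Kp, seq_len(nrow(K)))
  mu <- colMeans(Kp)
  expect_lt(max(abs((K2 / attr(K2, "tau")) -
                      (Kp - outer(mu, rep(1, 20)) - outer(rep(1, 20), mu) +
                         mean(mu)))), 1e-8)
  ## identity kernel keeps trace n (tau = 1) after centering adjustment
  Ki <- diag(5)
  Kpi <- center_normalize_kernel(Ki)
  expect_equal(sum(diag(Kpi)), 5, tolerance = 1e-10)
  expect_error(center_normalize_kernel(matrix(1, 4, 4)),
               class = "corticonn_normalization_error")
})

test_that("matched under-sampling reproduces the printed per-class sizes", {
  roster <- printed_marginal_roster(seed = 3)
  expect_equal(binarize_and_match(roster, "TYP", "DCD")$n_per_class, 20)
  expect_equal(binarize_and_match(roster, "TYP", "DD")$n_per_class, 42)
  expect_equal(binarize_and_match(roster, "TYP", "COM")$n_per_class, 29)
  expect_equal(binarize_and_match(roster, "DD", "DCD")$n_per_class, 20)
  expect_equal(suppressWarnings(
    binarize_and_match(roster, "DD", "COM"))$n_per_class, 29)
  expect_equal(binarize_and_match(roster, "DCD", "COM")$n_per_class, 20)
  ## mixture classes pool labels before matching (strata may be one-sided,
  ## which legitimately falls back with a warning)
  mix <- suppressWarnings(binarize_and_match(roster, "TYP", c("DCD", "COM")))
  expect_equal(mix$n_per_class, 42)
  expect_true(all(roster$group[mix$idx_b] %in% c("DCD", "COM")))
  ## every retained subject appears exactly once
  expect_false(anyDuplicated(mix$idx) > 0)
})

test_that("matching on identical rosters pairs subjects with themselves' ages", {
  half <- printed_marginal_roster(seed = 4)[1:42, ]
  other <- half
  other$subject_id <- paste0("X", other$subject_id)
  other$group <- "DCD"
  both <- rbind(half, other)
  prob <- binarize_and_match(both, "TYP", "DCD")
  expect_equal(prob$n_per_class, 42)
  ## greedy nearest-age pairing on mirrored rosters matches age exactly
  expect_equal(both$age[prob$idx_a], both$age[prob$idx_b])
})

test_that("single-kernel MKL equals the plain SVM dual (independent QP oracle)", {
  for (s in 1:5) {
    d <- sep_features(8, 30, gap = 1.5, seed = s)
    K <- center_normalize_kernel(d$x %*% t(d$x))
    fit <- simple_mkl_fit(list(k = unclass(K)), d$y, C = 1)
    expect_equal(unname(fit$d), 1)
    oracle <- svm_dual_oracle(unclass(K), d$y, C = 1)
    expect_equal(fit$objective, oracle, tolerance = 1e-6)
    ## simplex and box/equality constraints
    expect_true(all(fit$alpha >= -1e-10 & fit$alpha <= 1 + 1e-10))
    expect_lt(abs(sum(fit$alpha * d$y)), 1e-8)
  }
})

test_that("the MKL optimiser is sparse, monotone and simplex-feasible", {
  ## one clearly separating kernel + one pure-noise kernel
  hits <- vapply(1:20, function(s) {
    d <- sep_features(10, 40, gap = 3, seed = 100 + s)
    set.seed(1000 + s)
    noise <- matrix(rnorm(20 * 40), 20)
    ki <- unclass(center_normalize_kernel(tcrossprod(d$x)))
    kn <- unclass(center_normalize_kernel(tcrossprod(noise)))
    fit <- simple_mkl_fit(list(inf = ki, noise = kn), d$y)
    expect_gte(min(fit$d), 0)
    expect_equal(sum(fit$d), 1, tolerance = 1e-8)
    fit$d["noise"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.9)

  ## duplicating a kernel leaves the optimum unchanged (same reachable set)
  d <- sep_features(10, 40, gap = 2, seed = 7)
  k1 <- unclass(center_normalize_kernel(tcrossprod(d$x)))
  f1 <- simple_mkl_fit(list(a = k1), d$y)
  f2 <- simple_mkl_fit(list(a = k1, b = k1), d$y)
  expect_equal(f2$objective, f1$objective, tolerance = 1e-6)
  expect_equal(sum(f2$d), 1, tolerance = 1e-8)
  ## and adding a noise kernel can only improve (or retain) the optimum
  set.seed(8)
  kn <- unclass(center_normalize_kernel(tcrossprod(matrix(rnorm(20 * 40), 20))))
  f3 <- simple_mkl_fit(list(a = k1, n = kn), d$y)
  expect_gte(f3$objective, f1$objective - 1e-6)
})

test_that("balanced accuracy reproduces the printed worked examples", {
  expect_equal(balanced_accuracy(23, 29, 21, 29), 75.86)
  expect_equal(balanced_accuracy(30, 42, 30, 42), 71.43)
  expect_equal(balanced_accuracy(0, 10, 10, 10), 50)
  expect_error(balanced_accuracy(5, 0, 1, 10),
               class = "corticonn_validation_error")
  expect_error(balanced_accuracy(11, 10, 1, 10),
               class = "corticonn_validation_error")
})

test_that("cross-validation separates planted classes and matches naive recomputation", {
  d <- sep_features(10, 40, gap = 4, seed = 9)
  bundle <- build_linear_kernels(list(k1 = d$x,
                                      k2 = matrix(rnorm(20 * 40), 20)))
  prob <- toy_problem(d$y)
  cv <- loso_cv(bundle, prob)
  expect_equal(cv$balanced_accuracy, 100)
  expect_equal(cv$auc, 1)
  ## pooled metrics equal a sample-by-sample naive loop
  pred <- ifelse(cv$decisions > 0, 1, -1)
  tp <- 0; tn <- 0
  for (i in seq_along(cv$y)) {
    if (cv$y[i] == 1 && pred[i] == 1) tp <- tp + 1
    if (cv$y[i] == -1 && pred[i] == -1) tn <- tn + 1
  }
  expect_equal(cv$tp, tp); expect_equal(cv$tn, tn)
  expect_equal(cv$balanced_accuracy,
               balanced_accuracy(tp, sum(cv$y == 1), tn, sum(cv$y == -1)))
  auc_naive <- mean(outer(cv$decisions[cv$y == 1], cv$decisions[cv$y == -1],
                          function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(cv$auc, auc_naive)
  expect_error(loso_cv(bundle, toy_problem(rep(c(1, -1), each = 2))),
               class = "corticonn_validation_error")
})

test_that("fold-level decisions match a manual R re-implementation of the engine", {
  d <- sep_features(5, 15, gap = 2, seed = 10)
  maps <- list(a = d$x, b = matrix(rnorm(10 * 15), 10))
  bundle <- build_linear_kernels(maps)
  prob <- toy_problem(d$y)
  cv <- loso_cv(bundle, prob)
  k <- 2  # recompute fold 2 by hand with the R-level centering function
  test_pos <- c(2, prob$n_per_class + 2)
  train <- setdiff(seq_along(prob$y), test_pos)
  ros <- prob$idx
  kp <- lapply(bundle$kernels, function(K)
    center_normalize_kernel(K[ros, ros], train))
  fit <- simple_mkl_fit(lapply(kp, function(K) unclass(K)[train, train]),
                        prob$y[train])
  kcomb <- Reduce(`+`, Map(function(K, w) unclass(K) * w, kp, fit$d))
  f_manual <- colSums(kcomb[train, test_pos] * (fit$alpha * prob$y[train])) +
    fit$bias
  expect_equal(unname(cv$decisions[test_pos]), unname(f_manual),
               tolerance = 1e-5)
  expect_equal(unname(cv$tau_folds[, k]),
               unname(vapply(kp, attr, 0, "tau")), tolerance = 1e-10)
})

test_that("the permutation test brackets p-values by the add-one rule", {
  d <- sep_features(6, 30, gap = 5, seed = 11)
  bundle <- build_linear_kernels(list(k = d$x))
  prob <- toy_problem(d$y)
  cv <- permutation_test(bundle, prob, n_perm = 49, seed = 12)
  ## perfectly separable data beat (almost) every permutation
  expect_lte(cv$perm_p, 3 / 50)
  expect_gte(cv$perm_p, 1 / 50)
  ## the reported p follows the add-one rule exactly
  expect_equal(cv$perm_p,
               (1 + sum(cv$perm_ba >= cv$balanced_accuracy)) / 50)
  ## an observed BA below every permuted BA yields p = 1
  expect_equal((1 + sum(cv$perm_ba >= 0)) / 50, 1)
})

test_that("kernel contributions and expected ranking summarise folds", {
  cvfake <- list(d_folds = rbind(big = c(0.6, 0.7, 0.5),
                                 mid = c(0.4, 0.3, 0.5),
                                 zero = c(0, 0, 0)))
  out <- kernel_contributions(cvfake)
  expect_equal(sum(out$contribution), 100, tolerance = 1e-6)
  expect_equal(out$expected_ranking[out$kernel == "zero"], 0)
  ## ties share average ranks (fold 3: 0.5 and 0.5 -> ranks 2.5 each)
  expect_equal(out$expected_ranking[out$kernel == "big"], (3 + 3 + 2.5) / 3)
  expect_equal(out$expected_ranking[out$kernel == "mid"], (2 + 2 + 2.5) / 3)
  ## a kernel dominating every fold of a 14-kernel model ranks 14
  d14 <- matrix(1 / 26, 14, 5); d14[3, ] <- 0.5; d14[1, ] <- 0
  out14 <- kernel_contributions(list(d_folds = d14))
  expect_equal(out14$expected_ranking[1], 14)
  expect_equal(out14$contribution[out14$kernel == "k1"], 0)
})

test_that("weight maps back-project the decision function to voxels", {
  d <- sep_features(5, 12, gap = 4, seed = 13)
  maps <- list(inf = d$x, noise = matrix(rnorm(10 * 12), 10))
  bundle <- build_linear_kernels(maps)
  prob <- toy_problem(d$y)
  cv <- loso_cv(bundle, prob)
  wm <- compute_weight_maps(cv, maps, prob)
  ## per-fold weights match the closed form for a checked fold
  k <- 1
  tr <- cv$trains[[k]]
  x <- maps$inf[prob$idx, ][tr, ]
  xc <- sweep(x, 2, colMeans(x))
  w_manual <- cv$d_folds["inf", k] * sqrt(cv$tau_folds[1, k]) *
    colSums(xc * (cv$alphas[[k]] * cv$y[tr]))
  expect_equal(wm$inf$w_folds[k, ], w_manual, tolerance = 1e-10)
  ## zero-contribution kernels give identically zero maps
  if (all(cv$d_folds["noise", ] == 0)) {
    expect_true(all(wm$noise$mean == 0))
  }
  ## informative voxels (1:5) carry the largest mean |w|
  top5 <- order(-abs(wm$inf$mean))[1:5]
  expect_gte(length(intersect(top5, 1:5)), 3)
  ## naive mean/SE recomputation agrees
  expect_equal(wm$inf$se,
               apply(wm$inf$w_folds, 2, sd) / sqrt(nrow(wm$inf$w_folds)),
               tolerance = 1e-12)
})
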