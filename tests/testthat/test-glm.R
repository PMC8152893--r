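## random small subject tables for design-level tests
random_subjects <- function(n_per_group = 4, seed = 1) {
  set.seed(seed)
  n <- n_per_group * 4
  data.frame(subject_id = sprintf("S%02d", 1:n),
             group = rep(c("TYP", "DD", "DCD", "COM"), each = n_per_group),
             center = sample(c("A", "B"), n, replace = TRUE),
             gender = sample(c("F", "M"), n, replace = TRUE),
             age = runif(n, 8, 12), mabc_percentile = runif(n, 1, 99),
             gcor = runif(n, 0, 0.3), stringsAsFactors = FALSE)
}

with_geometry <- function(maps, dim3 = c(4, 4, 4)) {
  attr(maps, "mask_index") <- seq_len(ncol(maps))
  attr(maps, "dim3") <- dim3
  maps
}

test_that("voxelwise ANCOVA F equals the nested-model oracle", {
  for (s in 1:5) {
    subjects <- random_subjects(4, seed = s)
    set.seed(100 + s)
    maps <- with_geometry(matrix(rnorm(16 * 30), 16))
    vs <- fit_voxelwise_ancova(maps, subjects)
    expect_equal(vs$df, c(3, 16 - 7))
    for (v in c(1, 7, 30)) {
      expect_equal(vs$stat[v], ancova_f_oracle(maps[, v], subjects),
                   tolerance = 1e-8)
    }
    ## intercept absorption: adding a constant leaves F unchanged
    vs2 <- fit_voxelwise_ancova(with_geometry(maps + 11.3), subjects)
    expect_equal(vs2$stat, vs$stat, tolerance = 1e-8)
  }
})

test_that("identical data across groups gives zero F", {
  subjects <- random_subjects(3, seed = 2)[1:12, ]
  subjects$group <- rep(c("TYP", "DD"), each = 6)
  one <- rnorm(8)
  maps <- with_geometry(matrix(one, 12, 8, byrow = TRUE), c(2, 2, 2))
  vs <- fit_voxelwise_ancova(maps, subjects)
  expect_equal(vs$stat, rep(0, 8), ignore_attr = TRUE)
})

test_that("rank-deficient designs are rejected with the offending column", {
  subjects <- random_subjects(4, seed = 3)
  subjects$gcor <- subjects$age * 2   # collinear covariate
  maps <- with_geometry(matrix(rnorm(16 * 5), 16))
  expect_error(fit_voxelwise_ancova(maps, subjects),
               class = "corticonn_design_error")
})

test_that("post hoc pairwise t-tests recover the planted group pattern", {
  fix <- recovery_fixture()
  cm <- fix$cm
  cohort <- fix$cohort
  vox <- match(cohort$truth$affected_targets[["cereb2"]], cm$mask_index)
  tmat <- posthoc_pairwise(cm$maps_by_seed[["cereb2"]], cm$subjects,
                           voxel_set = vox)
  mt <- rowMeans(tmat)
  ## hyperconnected groups (DCD, COM) against unaffected (TYP, DD)
  expect_gt(mt["DCD-TYP"], 2)
  expect_gt(mt["COM-TYP"], 2)
  expect_gt(mt["DCD-DD"], 2)
  expect_gt(mt["COM-DD"], 2)
  ## within-level contrasts stay near zero
  expect_lt(abs(mt["DD-TYP"]), 2)
  expect_lt(abs(mt["COM-DCD"]), 2)
  ## empty voxel set gives an empty result
  expect_equal(dim(posthoc_pairwise(cm$maps_by_seed[[1]], cm$subjects,
                                    voxel_set = integer())), c(0, 0))
})

test_that("pairwise t-values are near-null for identical groups", {
  subjects <- random_subjects(12, seed = 4)
  set.seed(5)
  maps <- with_geometry(matrix(rnorm(48 * 50), 48))
  tmat <- posthoc_pairwise(maps, subjects)
  ## pairs share subjects, so the 300 t-values are dependent; allow slack
  ## below the nominal P(|t| < 2.1) ~ 0.95
  expect_gt(mean(abs(tmat) < 2.1), 0.9)
  expect_lt(abs(mean(tmat)), 0.15)
})

test_that("reading PC1 is oriented, dominant and validated", {
  x <- matrix(rep(rnorm(20), 4), 20)
  p <- reading_pc1(x + matrix(rnorm(80, sd = 1e-8), 20))
  expect_gt(p$variance_explained, 99.99)

  fix <- recovery_fixture()
  scores <- as.matrix(fix$cohort$subjects[, paste0("read", 1:4)])
  p2 <- reading_pc1(scores)
  expect_gte(p2$variance_explained, 90)
  ## oriented so higher = better reading
  expect_gt(cor(p2$scores, rowMeans(scores)), 0)
  ## global sign flip of the inputs does not change the oriented scores
  p3 <- reading_pc1(-scores)
  expect_lt(cor(p2$scores, p3$scores), -0.99)

  bad <- scores; bad[, 2] <- 7
  expect_error(reading_pc1(bad), class = "corticonn_validation_error")
})

test_that("bivariate behavioural regression has the expected statistics", {
  fix <- recovery_fixture()
  cm <- fix$cm
  cohort <- fix$cohort
  vox <- match(cohort$truth$affected_targets[["stria6"]], cm$mask_index)
  tmap <- behavioral_regression(cm$maps_by_seed[["stria6"]],
                                score = cm$subjects$mabc_percentile)
  ## higher connectivity, poorer motor scores: negative slope t
  expect_lt(mean(tmap$stat[vox]), -1)

  ## a score equal to a voxel's data gives a degenerate perfect fit
  sc <- cm$maps_by_seed[["stria6"]][, 10]
  t2 <- behavioral_regression(cm$maps_by_seed[["stria6"]], score = sc)
  expect_gt(abs(t2$stat[10]), 1e6)
  expect_lt(t2$p_unc[10], 1e-30)

  ## with independent maps and an unrelated score, p-values are uniform
  set.seed(9)
  null_maps <- with_geometry(matrix(rnorm(32 * 2000), 32), c(2000, 1, 1))
  pu <- behavioral_regression(null_maps, score = rnorm(32))
  expect_gt(suppressWarnings(ks.test(pu$p_unc, "punif")$p.value), 0.01)

  expect_error(behavioral_regression(cm$maps_by_seed[[1]],
                                     score = rep(1, nrow(cm$subjects))),
               class = "corticonn_validation_error")
})

test_that("cluster forming matches connectivity definitions and the flood-fill oracle", {
  dim3 <- c(8, 8, 8)
  stat <- numeric(512)
  p <- rep(1, 512)
  blob <- c(1, 2, 3, 9, 17)      # face-connected 5-voxel blob
  p[blob] <- 1e-5
  vs <- structure(list(stat = stat + (p < 0.001), p_unc = p,
                       df = c(3, 50), type = "F",
                       mask_index = 1:512, dim3 = dim3),
                  class = "voxel_stat_map")
  tab <- form_clusters(vs)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$size, 5)

  ## nothing below threshold
  vs0 <- vs; vs0$p_unc <- rep(0.5, 512)
  expect_equal(nrow(form_clusters(vs0)), 0)

  ## two cubes touching only at a corner: separate under 18, merged under 26
  pc <- rep(1, 512)
  cube <- function(x, y, z) as.vector(outer(outer(x, (y - 1) * 8, "+"),
                                            (z - 1) * 64, "+"))
  pc[cube(1:2, 1:2, 1:2)] <- 1e-5
  pc[cube(3:4, 3:4, 3:4)] <- 1e-5
  vsc <- vs; vsc$p_unc <- pc
  expect_equal(nrow(form_clusters(vsc, connectivity = 18)), 2)
  expect_equal(nrow(form_clusters(vsc, connectivity = 26)), 1)

  ## random maps against the recursive flood-fill oracle
  set.seed(11)
  for (k in 1:10) {
    mask <- array(runif(512) < 0.12, dim3)
    vsr <- vs; vsr$p_unc <- ifelse(as.vector(mask), 1e-5, 0.9)
    for (conn in c(6, 18, 26)) {
      tab <- form_clusters(vsr, connectivity = conn)
      oracle <- flood_fill_oracle(mask, conn)
      expect_equal(nrow(tab), max(oracle))
      sizes <- sort(tabulate(oracle[oracle > 0]))
      expect_equal(sort(tab$size), sizes)
    }
  }
})

test_that("BH adjustment matches the step-up oracle and worked example", {
  p <- c(0.001, 0.01, 0.02, 0.03, 0.5)
  adj <- bh_fdr(p)$adjusted
  expect_equal(adj, c(0.005, 0.025, 1 / 30, 0.0375, 0.5), tolerance = 1e-12)
  expect_equal(bh_fdr(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(bh_fdr(0.013)$adjusted, 0.013)
  expect_equal(bh_fdr(numeric())$adjusted, numeric())
  set.seed(12)
  for (k in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_equal(bh_fdr(p)$adjusted, bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("cluster-extent permutation flags the planted cluster with the add-one bound", {
  fix <- recovery_fixture()
  cm <- fix$cm
  cohort <- fix$cohort
  tab <- cluster_extent_permutation(cm$maps_by_seed[["cereb2"]],
                                    cm$subjects, n_perm = 199, seed = 21)
  expect_gt(nrow(tab), 0)
  ## the largest cluster overlaps the planted target and attains the
  ## smallest achievable permutation p
  vox <- attr(tab, "clusters")[[1]]
  expect_gt(length(intersect(vox, cohort$truth$affected_targets[["cereb2"]])),
            0)
  expect_equal(tab$p_extent[1], 1 / 200)
  expect_true(all(tab$p_fdr >= tab$p_extent))
})

test_that("tiny designs fall back to exhaustive permutation enumeration", {
  subjects <- random_subjects(1, seed = 6)[1:4, ]
  subjects$group <- c("TYP", "TYP", "DD", "DD")
  set.seed(13)
  maps <- with_geometry(matrix(rnorm(4 * 10), 4), c(10, 1, 1))
  tab <- cluster_extent_permutation(maps, subjects,
                                    covariates = character(),
                                    n_perm = 500, seed = 1)
  expect_equal(length(attr(tab, "null_max_size")), factorial(4) - 1)
})

test_that("across-seed pooling adds a BH family over all cluster tables", {
  t1 <- structure(data.frame(cluster = 1:2, size = c(10, 5),
                             peak_index = c(1, 2), peak_x = 1, peak_y = 1,
                             peak_z = 1, p_extent = c(0.004, 0.2),
                             p_fdr = c(0.008, 0.2)),
                  clusters = list(1:10, 11:15),
                  class = c("cluster_table", "data.frame"))
  t2 <- t1[integer(), ]
  attr(t2, "clusters") <- list()
  class(t2) <- c("cluster_table", "data.frame")
  t3 <- t1; t3$p_extent <- c(0.01, 0.03)
  out <- adjust_across_seeds(list(a = t1, b = t2, c = t3))
  pooled <- bh_stepup_oracle(c(0.004, 0.2, 0.01, 0.03))
  expect_equal(out$a$p_fdr_adjusted, pooled[1:2])
  expect_equal(out$c$p_fdr_adjusted, pooled[3:4])
  expect_equal(nrow(out$b), 0)
})

test_that("behavioural-score cluster inference permutes the score", {
  set.seed(17)
  n <- 24
  maps <- matrix(rnorm(n * 64), n)
  score <- rnorm(n)
  ## plant a strong linear association in a 2x2 corner block of the slice
  blk <- c(1, 2, 9, 10)
  maps[, blk] <- maps[, blk] * 0.3 + score
  maps <- with_geometry(maps, c(8, 8, 1))
  tab <- cluster_extent_permutation(maps, subjects = NULL,
                                    n_perm = 199, seed = 3, score = score,
                                    connectivity = 18)
  expect_gt(nrow(tab), 0)
  expect_true(any(vapply(attr(tab, "clusters"), function(v)
    length(intersect(v, blk)) > 0, TRUE)))
  expect_equal(min(tab$p_extent), 1 / 200)
  sm <- attr(tab, "stat_map")
  expect_equal(sm$type, "t")
  expect_gt(mean(sm$stat[blk]), 3)
})
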