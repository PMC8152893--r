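## Voxelwise second-level inference on Fisher-z connectivity maps:
## four-group ANCOVA with age/gender/GCOR covariates, covariate-adjusted
## post hoc pairwise t-tests, bivariate behavioural regressions, cluster
## forming at p < 0.001 with cluster-extent inference by Freedman-Lane
## permutation of the maximum cluster size, and two-level Benjamini-Hochberg
## FDR (within map, then pooled across the 14 seed maps).
##
## Group maps are plain subjects x voxels matrices carrying the voxel
## geometry as attributes `mask_index` (linear indices, x fastest) and
## `dim3` (grid shape); the cohort pipeline attaches these automatically.

DEFAULT_COVARIATES <- c("age", "gender", "gcor")

map_geometry <- function(maps, mask_index, dim3) {
  mask_index <- mask_index %||% attr(maps, "mask_index")
  dim3 <- dim3 %||% attr(maps, "dim3")
  cc_assert(!is.null(mask_index) && !is.null(dim3), "validation",
            "voxel geometry (mask_index, dim3) missing from maps")
  list(mask_index = mask_index, dim3 = dim3)
}

## full and reduced (covariate-only) design matrices; gender coded M = 1,
## group reference level TYP (F statistics are invariant to both codings,
## fixed for reproducibility)
group_design <- function(subjects, covariates = DEFAULT_COVARIATES) {
  groups <- factor(subjects$group,
                   levels = intersect(GROUP_LEVELS, unique(subjects$group)))
  cc_assert(nlevels(groups) >= 2, "design", "need >= 2 groups")
  cc_assert(all(table(groups) >= 2), "design", ">= 2 subjects per group required")
  covs <- matrix(0, nrow(subjects), 0)
  for (cv in covariates) {
    v <- subjects[[cv]]
    cc_assert(!is.null(v), "design", paste0("covariate ", cv, " not found"))
    if (cv == "gender") v <- as.numeric(v == "M")
    covs <- cbind(covs, v)
  }
  if (length(covariates) > 0) colnames(covs) <- covariates
  ind <- sapply(levels(groups)[-1], function(g) as.numeric(groups == g))
  x_full <- cbind(intercept = 1, ind, covs)
  x_red <- cbind(intercept = 1, covs)
  qx <- qr(x_full)
  if (qx$rank < ncol(x_full)) {
    bad <- colnames(x_full)[qx$pivot[(qx$rank + 1):ncol(x_full)]]
    cc_stop("design", paste0("design matrix is rank deficient; collinear ",
                             "column(s): ", paste(bad, collapse = ", ")))
  }
  list(full = x_full, reduced = x_red, groups = groups,
       df_num = nlevels(groups) - 1L,
       df_den = nrow(subjects) - ncol(x_full))
}

#' Voxelwise group ANCOVA
#'
#' Partial F-statistic for the group factor given the covariates, at every
#' voxel: `F = ((RSS0 - RSS1)/q) / (RSS1/(n - p))` comparing the
#' covariate-only model against the full model with group indicators
#' (reference level TYP), with parametric p-values from `F(q, n - p)`.
#'
#' @param maps subjects x voxels matrix of Fisher-z values.
#' @param subjects subject table aligned with `maps` rows.
#' @param covariates covariate column names (default age, gender, gcor).
#' @param mask_index,dim3 voxel geometry (defaults from `maps` attributes).
#' @return an object of class `voxel_stat_map`: `stat`, `p_unc`, `df`,
#'   `type`, plus the voxel geometry.
#' @export
fit_voxelwise_ancova <- function(maps, subjects,
                                 covariates = DEFAULT_COVARIATES,
                                 mask_index = NULL, dim3 = NULL) {
  geom <- map_geometry(maps, mask_index, dim3)
  dsg <- group_design(subjects, covariates)
  qr_full <- qr(dsg$full)
  qr_red <- qr(dsg$reduced)
  rss1 <- colSums(qr.resid(qr_full, maps)^2)
  rss0 <- colSums(qr.resid(qr_red, maps)^2)
  fstat <- pmax(0, (rss0 - rss1) / dsg$df_num) / (rss1 / dsg$df_den)
  ## voxels whose residual variance is numerically zero relative to their
  ## total variance carry no information: define F = 0 there
  tv <- colSums(sweep(maps, 2, colMeans(maps))^2)
  fstat[tv <= 0 | rss1 <= 1e-12 * tv] <- 0
  structure(list(stat = fstat,
                 p_unc = pf(fstat, dsg$df_num, dsg$df_den, lower.tail = FALSE),
                 df = c(dsg$df_num, dsg$df_den), type = "F",
                 mask_index = geom$mask_index, dim3 = geom$dim3),
            class = "voxel_stat_map")
}

#' @export
print.voxel_stat_map <- function(x, ...) {
  cat("<voxel_stat_map> ", x$type, "(", paste(x$df, collapse = ", "), "), ",
      length(x$stat), " voxels, max ", round(max(x$stat), 2), "\n", sep = "")
  invisible(x)
}

#' Covariate-adjusted post hoc pairwise t-tests
#'
#' For every unordered group pair, the two groups' subjects are modelled
#' with an intercept, a group indicator and the covariates; the reported t
#' is for the indicator with sign convention "later group minus earlier
#' group" in TYP < DD < DCD < COM order (so hyperconnectivity in DCD versus
#' TYP appears as positive t in row "DCD-TYP").
#'
#' @inheritParams fit_voxelwise_ancova
#' @param voxel_set column indices of `maps` to test (typically the voxels
#'   of significant clusters); empty set gives an empty result.
#' @return pairs x voxels matrix of t-values (rownames "B-A").
#' @export
posthoc_pairwise <- function(maps, subjects,
                             covariates = DEFAULT_COVARIATES,
                             voxel_set = seq_len(ncol(maps))) {
  if (length(voxel_set) == 0)
    return(matrix(0, 0, 0))
  groups_present <- intersect(GROUP_LEVELS, unique(subjects$group))
  pairs <- utils::combn(groups_present, 2)
  out <- matrix(NA_real_, ncol(pairs), length(voxel_set))
  rn <- character(ncol(pairs))
  y_all <- maps[, voxel_set, drop = FALSE]
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    sel <- subjects$group %in% c(a, b)
    sub <- subjects[sel, , drop = FALSE]
    covs <- sapply(covariates, function(cv) {
      v <- sub[[cv]]
      if (cv == "gender") as.numeric(v == "M") else v
    })
    x <- cbind(1, as.numeric(sub$group == b), covs)
    qx <- qr(x)
    y <- y_all[sel, , drop = FALSE]
    coefs <- qr.coef(qx, y)
    res <- qr.resid(qx, y)
    df <- nrow(x) - ncol(x)
    sigma2 <- colSums(res^2) / df
    xtxinv <- chol2inv(qr.R(qx))
    se <- sqrt(sigma2 * xtxinv[2, 2])
    out[k, ] <- coefs[2, ] / se
    rn[k] <- paste0(b, "-", a)
  }
  rownames(out) <- rn
  out
}

#' First principal component of the reading scores
#'
#' Columns are standardised, PC1 is extracted and its sign oriented so that
#' a higher score means better reading (positive correlation with the mean
#' standardised score).
#'
#' @param reading_scores subjects x 4 numeric matrix.
#' @return list with `scores` (per subject), `variance_explained` (%).
#' @export
reading_pc1 <- function(reading_scores) {
  x <- as.matrix(reading_scores)
  cc_assert(ncol(x) == 4, "validation", "expected 4 reading score columns")
  cc_assert(!anyNA(x), "validation", "reading scores contain missing values")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    cc_stop("validation", "zero-variance reading score column")
  xs <- scale(x)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  scores <- pc$x[, 1]
  if (cor(scores, rowMeans(xs)) < 0) scores <- -scores
  list(scores = as.numeric(scores),
       variance_explained = 100 * pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Voxelwise bivariate behavioural regression
#'
#' Slope t-statistic of the per-voxel connectivity on a behavioural score,
#' with no covariates (bivariate by design).
#'
#' @inheritParams fit_voxelwise_ancova
#' @param score numeric vector (one value per subject), e.g. the M-ABC
#'   percentile or the reading PC1 score.
#' @return a `voxel_stat_map` with `type = "t"` and `df = c(1, n - 2)`.
#' @export
behavioral_regression <- function(maps, subjects = NULL, score,
                                  mask_index = NULL, dim3 = NULL) {
  geom <- map_geometry(maps, mask_index, dim3)
  cc_assert(length(score) == nrow(maps), "consistency",
            "score length must match the number of subjects")
  if (sd(score) == 0)
    cc_stop("validation", "behavioural score is constant")
  n <- nrow(maps)
  r <- suppressWarnings(as.vector(cor(score, maps)))
  r[!is.finite(r)] <- 0
  tt <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  structure(list(stat = tt,
                 p_unc = 2 * pt(abs(tt), n - 2, lower.tail = FALSE),
                 df = c(1L, n - 2L), type = "t",
                 mask_index = geom$mask_index, dim3 = geom$dim3),
            class = "voxel_stat_map")
}

## neighbourhood offsets for 3D connectivity 6 / 18 / 26
neighbor_offsets <- function(connectivity = 18) {
  cc_assert(connectivity %in% c(6, 18, 26), "validation",
            "connectivity must be 6, 18 or 26")
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(g))
  lim <- c(`6` = 1, `18` = 2, `26` = 3)[as.character(connectivity)]
  g[nz >= 1 & nz <= lim, , drop = FALSE]
}

## connected components of a set of linear voxel indices on a grid
label_components <- function(voxel_index, dim3, connectivity = 18) {
  if (length(voxel_index) == 0) return(list())
  off <- neighbor_offsets(connectivity)
  vol <- array(0L, dim3)
  vol[voxel_index] <- seq_along(voxel_index)  # position in the set
  coords <- arrayInd(voxel_index, dim3)
  comp <- integer(length(voxel_index))  # 0 = unvisited
  ncomp <- 0L
  clusters <- list()
  for (s in seq_along(voxel_index)) {
    if (comp[s] > 0) next
    ncomp <- ncomp + 1L
    queue <- s
    comp[s] <- ncomp
    members <- s
    while (length(queue) > 0) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- coords[cur, ]
      nb <- sweep(off, 2, cc, "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= dim3[1] &
        nb[, 2] >= 1 & nb[, 2] <= dim3[2] &
        nb[, 3] >= 1 & nb[, 3] <= dim3[3]
      nb <- nb[ok, , drop = FALSE]
      pos <- vol[nb]
      pos <- pos[pos > 0]
      new <- pos[comp[pos] == 0]
      if (length(new) > 0) {
        comp[new] <- ncomp
        queue <- c(queue, new)
        members <- c(members, new)
      }
    }
    clusters[[ncomp]] <- voxel_index[members]
  }
  clusters
}

#' Form suprathreshold clusters from a voxelwise statistic map
#'
#' Connected components (18-neighbourhood by default) of the voxels with
#' uncorrected p below the cluster-forming threshold.
#'
#' @param stat_map a `voxel_stat_map`.
#' @param p_form cluster-forming voxelwise p threshold.
#' @param connectivity 6, 18 or 26.
#' @return an object of class `cluster_table`: a data frame (size, peak
#'   voxel) plus the member voxel indices per cluster in
#'   `attr(, "clusters")` (linear grid indices).
#' @export
form_clusters <- function(stat_map, p_form = 0.001, connectivity = 18) {
  supra <- stat_map$mask_index[stat_map$p_unc < p_form]
  clusters <- label_components(supra, stat_map$dim3, connectivity)
  ## order by decreasing size
  if (length(clusters) > 0) {
    clusters <- clusters[order(-vapply(clusters, length, 0L))]
    stat_of <- function(vox) {
      pos <- match(vox, stat_map$mask_index)
      stat_map$stat[pos]
    }
    peak <- vapply(clusters, function(v) v[which.max(abs(stat_of(v)))], 0L)
    tab <- data.frame(cluster = seq_along(clusters),
                      size = vapply(clusters, length, 0L),
                      peak_index = peak)
    tab <- cbind(tab, setNames(as.data.frame(arrayInd(peak, stat_map$dim3)),
                               c("peak_x", "peak_y", "peak_z")))
  } else {
    tab <- data.frame(cluster = integer(), size = integer(),
                      peak_index = integer(), peak_x = integer(),
                      peak_y = integer(), peak_z = integer())
  }
  structure(tab, clusters = clusters, class = c("cluster_table", "data.frame"))
}

## all permutations of 1..n (used as the exhaustive fallback in tiny designs)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos)
  }
  out
}

#' Cluster-extent inference by Freedman-Lane permutation
#'
#' Builds the observed statistic map (group ANCOVA, or a behavioural
#' regression when `score` is given), forms clusters at `p_form`, and
#' derives cluster-extent p-values from the permutation null distribution of
#' the maximum cluster size: covariate residuals are permuted
#' (Freedman-Lane), the full model refitted, and the largest suprathreshold
#' cluster size recorded.  `p_extent = (1 + #{perm max >= size}) /
#' (n_perm + 1)`; Benjamini-Hochberg within the map gives `p_fdr`.  When the
#' design admits fewer distinct permutations than `n_perm`, all of them are
#' enumerated instead.
#'
#' @inheritParams fit_voxelwise_ancova
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed for the permutation draw.
#' @param p_form cluster-forming threshold.
#' @param connectivity cluster connectivity (6/18/26).
#' @param score optional behavioural score; when given, the statistic is the
#'   bivariate regression t (two-sided forming threshold) and the score
#'   values are permuted directly.
#' @return a `cluster_table` with `p_extent` and `p_fdr` columns; the
#'   observed `voxel_stat_map` in `attr(, "stat_map")` and the null maximum
#'   sizes in `attr(, "null_max_size")`.
#' @export
cluster_extent_permutation <- function(maps, subjects,
                                       covariates = DEFAULT_COVARIATES,
                                       n_perm = 1000, seed = 1,
                                       p_form = 0.001, connectivity = 18,
                                       score = NULL,
                                       mask_index = NULL, dim3 = NULL) {
  geom <- map_geometry(maps, mask_index, dim3)
  n <- nrow(maps)
  if (is.null(score)) {
    dsg <- group_design(subjects, covariates)
    qr_full <- qr(dsg$full)
    qr_red <- qr(dsg$reduced)
    obs <- fit_voxelwise_ancova(maps, subjects, covariates,
                                geom$mask_index, geom$dim3)
    f_crit <- qf(1 - p_form, dsg$df_num, dsg$df_den)
    ez <- qr.resid(qr_red, maps)  # covariate residuals to permute
    stat_perm <- function(perm) {
      yp <- ez[perm, , drop = FALSE]
      rss1 <- colSums(qr.resid(qr_full, yp)^2)
      rss0 <- colSums(qr.resid(qr_red, yp)^2)
      fs <- pmax(0, (rss0 - rss1) / dsg$df_num) / (rss1 / dsg$df_den)
      fs > f_crit
    }
  } else {
    obs <- behavioral_regression(maps, subjects, score,
                                 geom$mask_index, geom$dim3)
    t_crit <- abs(stats::qt(p_form / 2, n - 2))
    stat_perm <- function(perm) {
      r <- suppressWarnings(as.vector(cor(score[perm], maps)))
      r[!is.finite(r)] <- 0
      tt <- abs(r) * sqrt(n - 2) / sqrt(pmax(1 - r^2, 1e-300))
      tt > t_crit
    }
  }
  observed <- form_clusters(obs, p_form, connectivity)

  exhaustive <- factorial(n) <= n_perm
  perms <- if (exhaustive) {
    all_permutations(n)[-1]  # identity excluded; counted via add-one rule
  } else {
    with_seed(seed, lapply(seq_len(n_perm), function(i) sample.int(n)))
  }
  null_max <- vapply(perms, function(perm) {
    supra <- geom$mask_index[stat_perm(perm)]
    if (length(supra) == 0) return(0L)
    max(vapply(label_components(supra, geom$dim3, connectivity), length, 0L))
  }, 0L)

  m <- length(perms)
  observed$p_extent <- vapply(observed$size, function(sz)
    (1 + sum(null_max >= sz)) / (m + 1), 0)
  observed$p_fdr <- bh_fdr(observed$p_extent)$adjusted
  attr(observed, "stat_map") <- obs
  attr(observed, "null_max_size") <- null_max
  observed
}

#' Pool cluster p-values across seed maps and adjust FDR
#'
#' All clusters from the per-seed tables form one Benjamini-Hochberg family;
#' each table gains a `p_fdr_adjusted` column.
#'
#' @param cluster_tables named list of `cluster_table` objects (one per
#'   seed map).
#' @return the list with `p_fdr_adjusted` filled in.
#' @export
adjust_across_seeds <- function(cluster_tables) {
  sizes <- vapply(cluster_tables, nrow, 0L)
  pooled <- unlist(lapply(cluster_tables, function(tb) tb$p_extent))
  adj <- if (length(pooled) > 0) bh_fdr(pooled)$adjusted else numeric()
  idx <- cumsum(c(0, sizes))
  for (k in seq_along(cluster_tables)) {
    tb <- cluster_tables[[k]]
    tb$p_fdr_adjusted <- if (sizes[k] > 0)
      adj[(idx[k] + 1):idx[k + 1]] else numeric()
    cluster_tables[[k]] <- tb
  }
  cluster_tables
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with rejection flags at level `q`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param q FDR level.
#' @return list with `adjusted` and logical `reject`.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  cc_assert(all(p_values >= 0 & p_values <= 1), "validation",
            "p-values must lie in [0, 1]")
  adjusted <- p.adjust(p_values, method = "BH")
  list(adjusted = adjusted, reject = adjusted <= q)
}
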