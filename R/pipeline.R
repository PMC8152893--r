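## End-to-end orchestration: simulate (or load) -> motion QC -> denoise ->
## seed-to-voxel connectivity + GCOR -> group GLM with cluster-extent
## permutation FDR -> MKL classification with permutation significance ->
## GLM-MKL consensus -> JSON report.  One master seed fans out to
## per-stage, per-subject streams, so stage-level reruns reproduce.

## one-vs-one binarisation of the four groups plus the two posthoc mixture
## models; the clinical class is the positive class (+1) throughout, so
## "true positives" reads as sensitivity to the disorder and weight maps
## point toward the affected group
MKL_DEFAULT_MODELS <- list(
  list(a = "DD", b = "TYP"), list(a = "DCD", b = "TYP"),
  list(a = "COM", b = "TYP"), list(a = "DCD", b = "DD"),
  list(a = "COM", b = "DD"), list(a = "COM", b = "DCD"),
  list(a = c("DCD", "COM"), b = "TYP"), list(a = c("DD", "COM"), b = "TYP"))

#' Pipeline configuration
#'
#' Every stage's defaults are the reference analysis parameters: ART-style
#' censoring at FD > 0.5 mm / intensity z > 3, five aCompCor components per
#' tissue, 0.008-0.09 Hz band-pass, 8 mm smoothing, cluster forming at
#' p < 0.001 with cluster-extent FDR q = 0.05 (18-connectivity), C = 1
#' MKL with 1000 label permutations, 95th-percentile consensus.
#'
#' @param cohort a [cohort_spec()] describing the simulated cohort.
#' @param fd_variant,fd_thresh_mm,z_thresh censoring parameters.
#' @param qc_variants FD variants computed per subject (the flagging
#'   variant is always included; all three are needed for the QC summary).
#' @param n_compcor,band_hz,smooth_fwhm_mm denoising parameters
#'   (`smooth_fwhm_mm = 0` disables smoothing).
#' @param glm_p_form,glm_q,glm_n_perm,glm_connectivity GLM parameters.
#' @param mkl_C,mkl_n_perm,mkl_models MKL parameters; `mkl_models` is a
#'   list of `list(a =, b =)` class descriptors.
#' @param consensus_percentile consensus threshold percentile.
#' @param master_seed master RNG seed for all stages.
#' @param output_dir optional directory for the JSON report and TSV tables.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            fd_variant = "art", fd_thresh_mm = 0.5,
                            z_thresh = 3,
                            qc_variants = c("art", "power", "jenkinson"),
                            n_compcor = 5, band_hz = c(0.008, 0.09),
                            smooth_fwhm_mm = 8,
                            glm_p_form = 0.001, glm_q = 0.05,
                            glm_n_perm = 1000, glm_connectivity = 18,
                            mkl_C = 1, mkl_n_perm = 1000,
                            mkl_models = MKL_DEFAULT_MODELS,
                            consensus_percentile = 95,
                            master_seed = 1L,
                            output_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  cfg$cohort$seed <- as.integer(master_seed)
  cfg
}

## tiny FNV-1a hash of the deparsed config, recorded in every report
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 21661362
  for (b in bytes) h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' Process one subject: censoring, smoothing, denoising, connectivity
#'
#' @param run a [bold_run()].
#' @param motion frames x 6 motion matrix.
#' @param masks mask list (brain, gray, white, csf).
#' @param atlas a [seed_atlas()].
#' @param config a [pipeline_config()].
#' @return list with `maps` (seeds x gray voxels Fisher-z), `gcor`, `qc`.
#' @export
process_subject <- function(run, motion, masks, atlas, config) {
  qc <- censor_volumes(run, motion, masks$brain,
                       fd_variant = config$fd_variant,
                       fd_thresh_mm = config$fd_thresh_mm,
                       z_thresh = config$z_thresh,
                       variants = union(config$qc_variants,
                                        config$fd_variant))
  if (config$smooth_fwhm_mm > 0)
    run <- smooth_run(run, config$smooth_fwhm_mm)
  drun <- denoise_run(run, masks, motion, qc,
                      n_compcor = config$n_compcor,
                      low_hz = config$band_hz[1],
                      high_hz = config$band_hz[2],
                      analysis_mask = masks$gray)
  maps <- all_seed_maps(drun, atlas, masks$gray)
  list(maps = maps, gcor = gcor(drun, masks$gray), qc = qc)
}

#' Compute all per-subject connectivity maps for a cohort
#'
#' Streams subjects (regenerating runs on demand, nothing 4D is retained),
#' returning per-seed subjects-x-voxels Fisher-z matrices with the voxel
#' geometry attached, the subject table with GCOR filled in, and the
#' per-subject QC results.
#'
#' @param cohort a [generate_cohort()] result.
#' @param config a [pipeline_config()].
#' @return list with `maps_by_seed`, `subjects`, `qc_list`, `mask_index`,
#'   `dim3`.
#' @export
cohort_fisher_maps <- function(cohort, config = pipeline_config()) {
  n <- nrow(cohort$subjects)
  mask_index <- which(cohort$masks$gray)
  dim3 <- cohort$spec$grid_shape
  seeds <- names(cohort$atlas$names)
  maps_by_seed <- lapply(seeds, function(s)
    matrix(NA_real_, n, length(mask_index)))
  names(maps_by_seed) <- seeds
  qc_list <- vector("list", n)
  gcors <- numeric(n)
  for (i in seq_len(n)) {
    res <- process_subject(cohort_run(cohort, i), cohort$motion[[i]],
                           cohort$masks, cohort$atlas, config)
    for (s in seq_along(seeds))
      maps_by_seed[[s]][i, ] <- res$maps[s, ]
    gcors[i] <- res$gcor
    qc_list[[i]] <- res$qc
  }
  subjects <- cohort$subjects
  subjects$gcor <- gcors
  for (s in seeds) {
    attr(maps_by_seed[[s]], "mask_index") <- mask_index
    attr(maps_by_seed[[s]], "dim3") <- dim3
  }
  list(maps_by_seed = maps_by_seed, subjects = subjects, qc_list = qc_list,
       mask_index = mask_index, dim3 = dim3)
}

#' Run the full analysis pipeline
#'
#' Simulates the configured cohort and runs every stage, returning (and
#' optionally writing) a report bundle: QC summary, per-seed cluster tables
#' with within-map and across-seed FDR, post hoc pairwise t-summaries,
#' behavioural regressions, MKL model table (balanced accuracy, confusion
#' counts, AUC, permutation p, FDR across models), kernel contributions
#' with expected ranking, and the consensus summary.  Fully deterministic
#' given `master_seed`.
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated cohort (must match the
#'   config's spec; useful for reusing simulations).
#' @return an object of class `pipeline_report` (a nested list).
#' @export
run_full_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  stage <- "simulate"
  report <- list(config_hash = config_hash(config))
  tryCatch({
    if (is.null(cohort)) cohort <- generate_cohort(config$cohort,
                                                   materialize_runs = FALSE)
    stage <- "connectivity"
    cm <- cohort_fisher_maps(cohort, config)
    if (any(vapply(cm$qc_list, function(q) all(q$invalid), TRUE)))
      cc_stop("validation", "a subject has all frames censored; relax QC thresholds")
    report$qc <- qc_summary(cm$qc_list, cm$subjects$group)

    stage <- "glm"
    seeds <- names(cm$maps_by_seed)
    cluster_tables <- list()
    f_maps <- list()
    for (k in seq_along(seeds)) {
      tb <- cluster_extent_permutation(
        cm$maps_by_seed[[k]], cm$subjects,
        n_perm = config$glm_n_perm,
        seed = child_seed(config$master_seed, 100L + k),
        p_form = config$glm_p_form, connectivity = config$glm_connectivity)
      f_maps[[seeds[k]]] <- attr(tb, "stat_map")
      cluster_tables[[seeds[k]]] <- tb
    }
    cluster_tables <- adjust_across_seeds(cluster_tables)
    report$clusters <- lapply(cluster_tables, function(tb)
      as.data.frame(tb)[, c("size", "peak_x", "peak_y", "peak_z",
                            "p_extent", "p_fdr", "p_fdr_adjusted")])

    ## post hoc pairwise tests inside significant clusters
    posthoc <- list()
    for (s in seeds) {
      tb <- cluster_tables[[s]]
      sig <- which(tb$p_fdr <= config$glm_q)
      if (length(sig) == 0) next
      vox <- match(unlist(attr(tb, "clusters")[sig]), cm$mask_index)
      tmat <- posthoc_pairwise(cm$maps_by_seed[[s]], cm$subjects,
                               voxel_set = vox)
      posthoc[[s]] <- data.frame(pair = rownames(tmat),
                                 mean_t = rowMeans(tmat), row.names = NULL)
    }
    report$posthoc <- posthoc

    ## behavioural bivariate regressions (M-ABC and reading PC1)
    pc1 <- reading_pc1(cm$subjects[, paste0("read", 1:4)])
    report$reading_pc1_variance <- pc1$variance_explained
    behav <- list()
    for (s in seeds) {
      for (sc in c("mabc", "reading")) {
        score <- if (sc == "mabc") cm$subjects$mabc_percentile else pc1$scores
        tmap <- behavioral_regression(cm$maps_by_seed[[s]], score = score)
        behav[[paste(s, sc, sep = "_")]] <-
          data.frame(min_t = min(tmap$stat), max_t = max(tmap$stat))
      }
    }
    report$behavioral <- behav

    stage <- "mkl"
    bundle <- build_linear_kernels(cm$maps_by_seed, cm$subjects$subject_id)
    mkl_rows <- list()
    cv_results <- list()
    for (j in seq_along(config$mkl_models)) {
      mdl <- config$mkl_models[[j]]
      have <- table(cm$subjects$group)
      if (!all(c(mdl$a, mdl$b) %in% names(have))) next
      problem <- binarize_and_match(cm$subjects, mdl$a, mdl$b)
      if (problem$n_per_class < 3) next
      cv <- permutation_test(bundle, problem, C = config$mkl_C,
                             n_perm = config$mkl_n_perm,
                             seed = child_seed(config$master_seed, 200L + j))
      id <- paste0(paste(mdl$a, collapse = "-"), "_vs_",
                   paste(mdl$b, collapse = "-"))
      cv_results[[id]] <- list(cv = cv, problem = problem)
      mkl_rows[[id]] <- data.frame(
        model = id, n_per_class = problem$n_per_class,
        balanced_accuracy = cv$balanced_accuracy,
        tp = cv$tp, p_total = cv$p_total, tn = cv$tn, n_total = cv$n_total,
        auc = round(cv$auc, 2), perm_p = cv$perm_p)
    }
    mkl_table <- do.call(rbind, mkl_rows)
    if (!is.null(mkl_table)) {
      mkl_table$perm_p_fdr <- bh_fdr(mkl_table$perm_p)$adjusted
      rownames(mkl_table) <- NULL
    }
    report$mkl <- mkl_table
    report$contributions <- lapply(cv_results, function(r)
      kernel_contributions(r$cv))

    stage <- "consensus"
    consensus <- list()
    sig_models <- names(cv_results)[vapply(cv_results, function(r)
      r$cv$perm_p < 0.05, TRUE)]
    for (id in sig_models) {
      r <- cv_results[[id]]
      wmaps <- compute_weight_maps(r$cv, cm$maps_by_seed, r$problem)
      for (s in seeds) {
        tb <- cluster_tables[[s]]
        if (nrow(tb) == 0 || !any(tb$p_fdr <= config$glm_q)) next
        if (all(r$cv$d_folds[s, ] == 0)) next
        cons <- consensus_map(wmaps[[s]], f_maps[[s]],
                              percentile = config$consensus_percentile,
                              provenance = list(model = id, seed_map = s))
        entry <- list(model = id, seed_map = s,
                      n_voxels = sum(cons$intersection))
        if (!is.null(cohort$truth) &&
            s %in% names(cohort$truth$affected_seeds)) {
          tgt <- cohort$truth$affected_targets[[s]]
          entry$dice_planted <- dice_overlap(cons, tgt)
        }
        consensus[[paste(id, s, sep = ":")]] <- entry
      }
    }
    report$consensus <- consensus
    report$seeds <- seeds
    class(report) <- "pipeline_report"

    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        report_to_json(report),
        file.path(config$output_dir, "report.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.table(report$qc, file.path(config$output_dir, "qc_summary.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    report
  }, error = function(e) {
    if (inherits(e, "condition") && !is.null(conditionMessage(e)))
      cc_stop("stage", paste0("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e)))
  })
}

report_to_json <- function(report) {
  lapply(unclass(report), function(x) {
    if (is.data.frame(x)) x else x
  })
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> hash", x$config_hash, "\n")
  if (!is.null(x$mkl)) {
    cat("MKL models:\n")
    print(x$mkl[, c("model", "n_per_class", "balanced_accuracy", "auc",
                    "perm_p")])
  }
  nsig <- sum(vapply(x$clusters, function(tb)
    sum(tb$p_fdr <= 0.05), 0))
  cat(nsig, "FDR-significant cluster(s) across",
      length(x$clusters), "seed maps;",
      length(x$consensus), "consensus entries\n")
  invisible(x)
}
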