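## Standard-format I/O and the in-memory image model shared by all stages.
## Images are NIfTI-1 (via RNifti), motion traces are 6-column whitespace
## text (SPM rp_*.txt convention: translations in mm, rotations in rad),
## subject tables are TSV, ground truth and model reports are JSON.

#' BOLD run container
#'
#' @param data 4D numeric array in `x, y, z, time` order (x fastest).
#' @param tr_seconds sampling interval (s), > 0.
#' @param affine invertible 4x4 voxel-to-world transform.
#' @param subject_id identifier.
#' @return an object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds, affine = diag(4),
                     subject_id = "subject") {
  cc_assert(length(dim(data)) == 4, "dimensionality",
            "BOLD data must be a 4D array (x, y, z, time)")
  cc_assert(dim(data)[4] >= 2, "validation", "need at least 2 volumes")
  cc_assert(is.numeric(tr_seconds) && tr_seconds > 0, "validation",
            "tr_seconds must be positive")
  cc_assert(all(dim(affine) == c(4, 4)) &&
              abs(det(affine)) > .Machine$double.eps, "validation",
            "affine must be an invertible 4x4 matrix")
  structure(list(data = data, tr_seconds = tr_seconds, affine = affine,
                 subject_id = subject_id), class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat("<bold_run> ", x$subject_id, ": ", paste(d[1:3], collapse = "x"),
      " voxels, ", d[4], " volumes @ TR ", x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

#' Frames-by-voxels matrix view of a run
#'
#' Voxels are flattened in column-major order (x fastest), the package-wide
#' convention for every flattened map.
#' @param run a [bold_run()] or a plain 4D array.
#' @return a `n_volumes` x `n_voxels` matrix.
#' @export
run_matrix <- function(run) {
  arr <- if (inherits(run, "bold_run")) run$data else run
  d <- dim(arr)
  t(matrix(arr, prod(d[1:3]), d[4]))
}

n_volumes <- function(run) dim(run$data)[4]

#' Read / write a 4D BOLD NIfTI
#'
#' `read_bold()` requires a 4D file; the TR is taken from the header
#' (`pixdim[5]`) unless `tr_seconds` is given, and a missing/zero header TR
#' without an explicit argument is an error.  `write_bold()` stores the
#' affine in the sform and the TR in `pixdim[5]`; the round trip preserves
#' data (at stored precision), TR and affine.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param tr_seconds optional explicit TR overriding the header.
#' @param subject_id identifier for the returned run.
#' @return a [bold_run()].
#' @export
read_bold <- function(path, tr_seconds = NULL, subject_id = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4)
    cc_stop("dimensionality",
            paste0(path, " is ", length(d), "D; a 4D BOLD file is required"))
  hdr <- RNifti::niftiHeader(img)
  tr <- if (!is.null(tr_seconds)) tr_seconds else hdr$pixdim[5]
  if (is.null(tr) || !is.finite(tr) || tr <= 0)
    cc_stop("validation",
            "TR missing from header; pass tr_seconds explicitly")
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  bold_run(array(as.numeric(img), d), tr_seconds = tr,
           affine = matrix(as.numeric(aff), 4, 4),
           subject_id = subject_id %||%
             sub("\\.nii(\\.gz)?$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_bold
#' @param run a [bold_run()].
#' @export
write_bold <- function(run, path) {
  cc_assert(inherits(run, "bold_run"), "validation", "run must be a bold_run")
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  img$pixdim <- c(1, abs(diag(run$affine)[1:3]), run$tr_seconds, 0, 0, 0)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write / read a 3D volume (mask, atlas labels, statistic map)
#' @param vol 3D array (logical masks are stored as 0/1 integers).
#' @param path file path.
#' @param affine 4x4 voxel-to-world transform.
#' @export
write_volume <- function(vol, path, affine = diag(4)) {
  cc_assert(length(dim(vol)) == 3, "dimensionality", "expected a 3D array")
  img <- RNifti::asNifti(array(as.numeric(vol), dim(vol)))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  cc_assert(length(dim(img)) == 3, "dimensionality",
            paste0(path, " is not a 3D volume"))
  array(as.numeric(img), dim(img))
}

#' Read a six-parameter rigid-body motion file
#'
#' Whitespace-delimited text with one row per frame and six columns: three
#' translations (mm) followed by three rotations (radians, SPM convention —
#' note that framewise-displacement variants convert rotations to mm via a
#' sphere radius, so units matter).
#'
#' @param path file path.
#' @param n_volumes optional expected frame count (consistency check when
#'   paired with a run).
#' @return numeric matrix with columns tx, ty, tz, pitch, roll, yaw.
#' @export
read_motion <- function(path, n_volumes = NULL) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6)
    cc_stop("format", paste0(path, " has ", ncol(m),
                             " columns; motion files must have 6"))
  if (!is.null(n_volumes) && nrow(m) != n_volumes)
    cc_stop("consistency", paste0("motion file has ", nrow(m),
                                  " frames but the run has ", n_volumes))
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("tx", "ty", "tz", "pitch", "roll", "yaw"))
  m
}

#' @rdname read_motion
#' @param motion frames x 6 matrix.
#' @export
write_motion <- function(motion, path) {
  cc_assert(ncol(motion) == 6, "format", "motion must have 6 columns")
  write.table(format(motion, digits = 10, scientific = FALSE), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

SUBJECT_COLUMNS <- c("subject_id", "group", "center", "age", "gender",
                     "mabc_percentile", paste0("read", 1:4))

#' Load and validate a subject table
#'
#' TSV with one row per subject.  Required columns: `subject_id`, `group`
#' (TYP/DD/DCD/COM), `center` (A/B), `age` (years), `gender` (F/M),
#' `mabc_percentile` (0-100) and the four reading scores `read1..read4`.
#' An optional `gcor` column carries the per-subject global correlation
#' filled in by the connectivity stage.
#'
#' @param path TSV file path.
#' @return validated `data.frame` of subject records.
#' @export
load_subject_table <- function(path) {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE,
               colClasses = c(subject_id = "character", group = "character",
                              center = "character", gender = "character")),
    error = function(e) cc_stop("schema",
      paste0("cannot parse subject table: ", conditionMessage(e))))
  missing <- setdiff(SUBJECT_COLUMNS, names(df))
  if (length(missing) > 0)
    cc_stop("schema", paste0("subject table lacks required column(s): ",
                             paste(missing, collapse = ", ")))
  validate_subjects(df)
}

validate_subjects <- function(df) {
  cc_assert(!anyDuplicated(df$subject_id), "validation",
            "duplicate subject_id in subject table")
  bad <- setdiff(unique(df$group), GROUP_LEVELS)
  if (length(bad) > 0)
    cc_stop("validation", paste0("unknown group label(s): ",
                                 paste(bad, collapse = ", ")))
  cc_assert(all(df$center %in% c("A", "B")), "validation",
            "center must be A or B")
  cc_assert(all(df$gender %in% c("F", "M")), "validation",
            "gender must be F or M")
  cc_assert(all(df$mabc_percentile >= 0 & df$mabc_percentile <= 100),
            "validation", "mabc_percentile must lie in [0, 100]")
  if (is.null(df$gcor)) df$gcor <- NA_real_
  df
}

#' @rdname load_subject_table
#' @param df subject table.
#' @export
write_subject_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort to disk in the standard formats
#'
#' One 4D NIfTI per run, 6-column text motion files, integer-labelled mask
#' and atlas NIfTIs, the subject table as TSV, and the ground truth as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(cohort$subjects)
  for (i in seq_len(n)) {
    id <- cohort$subjects$subject_id[i]
    write_bold(cohort_run(cohort, i), file.path(dir, paste0(id, "_bold.nii.gz")))
    write_motion(cohort$motion[[i]], file.path(dir, paste0("rp_", id, ".txt")))
  }
  for (nm in names(cohort$masks))
    write_volume(cohort$masks[[nm]], file.path(dir, paste0("mask_", nm, ".nii.gz")),
                 cohort$affine)
  write_volume(cohort$atlas$labels, file.path(dir, "seed_atlas.nii.gz"),
               cohort$affine)
  write_subject_table(cohort$subjects, file.path(dir, "subjects.tsv"))
  truth <- cohort$truth
  truth$true_coupling <- unname(as.matrix(truth$true_coupling))
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
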