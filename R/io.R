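COMPARTMENTS <- c("Tumour", "TME", "NAT")

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(what, " file not found: ", path, call. = FALSE)
  }
  x <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  x
}

write_tsv <- function(x, path, digits = 6L) {
  num <- vapply(x, is.numeric, TRUE)
  x[num] <- lapply(x[num], signif, digits = digits)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Case-insensitive canonicalization of compartment labels.
canonical_compartment <- function(x, context = "compartment") {
  idx <- match(tolower(x), tolower(COMPARTMENTS))
  if (anyNA(idx)) {
    bad <- unique(x[is.na(idx)])
    stop("unknown ", context, " label(s): ", paste(bad, collapse = ", "),
         "; allowed values: ", paste(COMPARTMENTS, collapse = ", "),
         call. = FALSE)
  }
  COMPARTMENTS[idx]
}

#' Read a probe count matrix
#'
#' Tab-delimited, first column `roi_id`, one column per probe. Counts must
#' be nonnegative and finite.
#'
#' @param path file path.
#' @return numeric matrix (ROI x probe) with dimnames.
#' @export
read_counts <- function(path) {
  x <- read_tsv_checked(path, "roi_id", "counts")
  if (anyDuplicated(x$roi_id)) {
    stop("counts file has duplicated roi_id(s)", call. = FALSE)
  }
  m <- as.matrix(x[, setdiff(names(x), "roi_id"), drop = FALSE])
  rownames(m) <- x$roi_id
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    stop("non-finite count at roi ", rownames(m)[bad[1]], ", probe ",
         colnames(m)[bad[2]], call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    stop("negative count at roi ", rownames(m)[bad[1]], ", probe ",
         colnames(m)[bad[2]], call. = FALSE)
  }
  m
}

#' Read an ROI metadata table
#'
#' Requires `roi_id` and `compartment`; `patient_id`, `area`, `nuclei` and
#' `shape` are optional. Compartment labels are matched case-insensitively
#' and canonicalized to Tumour/TME/NAT. ROIs without `patient_id`
#' participate only in unpaired analyses.
#'
#' @param path file path.
#' @return validated ROI data frame.
#' @export
read_roi_table <- function(path) {
  x <- read_tsv_checked(path, c("roi_id", "compartment"), "ROI table")
  if (anyDuplicated(x$roi_id)) {
    stop("ROI table has duplicated roi_id(s)", call. = FALSE)
  }
  x$compartment <- canonical_compartment(x$compartment)
  if (!"patient_id" %in% names(x)) x$patient_id <- NA_character_
  x$patient_id[!is.na(x$patient_id) & x$patient_id == ""] <- NA_character_
  if ("area" %in% names(x)) {
    bad <- !is.na(x$area) & x$area <= 0
    if (any(bad)) {
      stop("non-positive area for roi ", x$roi_id[bad][1], call. = FALSE)
    }
  }
  x
}

#' Read a probe panel table
#'
#' Requires `probe_id`, `probe_class`, `module`; optional `host`.
#'
#' @param path file path.
#' @return a `dsp_panel`.
#' @export
read_panel <- function(path) {
  as_dsp_panel(read_tsv_checked(
    path, c("probe_id", "probe_class", "module"), "panel"))
}

#' Read a patient survival table
#'
#' Requires `patient_id`, `time` (months, > 0) and `event` (0/1 or
#' TRUE/FALSE).
#'
#' @param path file path.
#' @return validated survival data frame.
#' @export
read_survival <- function(path) {
  x <- read_tsv_checked(path, c("patient_id", "time", "event"), "survival")
  if (anyDuplicated(x$patient_id)) {
    stop("survival table has duplicated patient_id(s)", call. = FALSE)
  }
  if (any(!is.finite(x$time) | x$time <= 0)) {
    stop("survival times must be positive; offending patient: ",
         x$patient_id[which(!is.finite(x$time) | x$time <= 0)[1]],
         call. = FALSE)
  }
  x$event <- as.logical(x$event)
  if (anyNA(x$event)) {
    stop("survival event flags must be logical or 0/1", call. = FALSE)
  }
  x
}

#' Cross-file consistency validation
#'
#' Checks that every ROI in the count matrix appears in the ROI table and
#' every probe in the panel; any mismatch is a hard error naming the
#' offending identifiers.
#'
#' @param counts ROI x probe matrix.
#' @param roi_table ROI metadata.
#' @param panel a `dsp_panel`.
#' @return invisibly `TRUE`.
#' @export
validate_experiment <- function(counts, roi_table, panel) {
  orphan_roi <- setdiff(rownames(counts), roi_table$roi_id)
  if (length(orphan_roi)) {
    stop("count matrix ROI(s) absent from ROI table: ",
         paste(utils::head(orphan_roi, 5), collapse = ", "), call. = FALSE)
  }
  orphan_probe <- setdiff(colnames(counts), panel$probe_id)
  if (length(orphan_probe)) {
    stop("count matrix probe(s) absent from panel: ",
         paste(utils::head(orphan_probe, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a simulated experiment to tab-delimited files
#'
#' Emits `counts.tsv`, `roi_table.tsv`, `panel.tsv`, `truth_roi.tsv` and
#' `truth_probe_means.tsv` (and `survival.tsv` when given) in the formats
#' the readers accept.
#'
#' @param sim a `dsp_simulation` from [simulate_counts()].
#' @param out_dir output directory (created if absent).
#' @param panel the `dsp_panel` used by the design.
#' @param survival optional survival table from [simulate_survival()].
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, out_dir, panel, survival = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(out_dir, "counts.tsv"),
    roi_table = file.path(out_dir, "roi_table.tsv"),
    panel = file.path(out_dir, "panel.tsv"),
    truth_roi = file.path(out_dir, "truth_roi.tsv"),
    truth_probe_means = file.path(out_dir, "truth_probe_means.tsv"))
  write_counts(sim$counts, paths["counts"])
  write_tsv(sim$roi_table, paths["roi_table"])
  write_tsv(as.data.frame(panel), paths["panel"])
  write_tsv(sim$truth$roi, paths["truth_roi"])
  write_tsv(sim$truth$probe_means, paths["truth_probe_means"])
  if (!is.null(survival)) {
    paths <- c(paths, survival = file.path(out_dir, "survival.tsv"))
    sv <- survival
    sv$event <- as.integer(sv$event)
    write_tsv(sv, paths["survival"])
  }
  invisible(paths)
}

#' Write a count matrix
#'
#' @param counts ROI x probe matrix.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(roi_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write pipeline stage results
#'
#' Writes one delimited file per available stage result: ROI QC, SNR
#' table, robust probe list, normalization factors, normalizer
#' assessment, normalized matrix, differential expression per comparison,
#' cluster assignments and linkage, and Cox screening per compartment.
#' Numeric columns are written at 6 significant digits.
#'
#' @param results named list of stage results (see [run_pipeline()]).
#' @param out_dir output directory (created if absent).
#' @return invisibly, character vector of files written.
#' @export
write_results <- function(results, out_dir) {
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  written <- character(0)
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    written <<- c(written, p)
  }
  if (!is.null(results$roi_qc)) emit(results$roi_qc, "roi_qc.tsv")
  if (!is.null(results$snr)) {
    emit(results$snr$summary, "snr_table.tsv")
    p <- file.path(out_dir, "robust_probes.txt")
    writeLines(results$robust_probes, p)
    written <- c(written, p)
  }
  if (!is.null(results$factors)) emit(results$factors, "factors.tsv")
  if (!is.null(results$assessment)) {
    r <- results$assessment$r
    emit(data.frame(factor = rownames(r), r, check.names = FALSE),
         "normalizer_assessment.tsv")
  }
  if (!is.null(results$normalized)) {
    v <- results$normalized$values
    # 8 significant digits here so the matrix round-trips to 1e-6 relative
    p <- file.path(out_dir, "normalized.tsv")
    write_tsv(data.frame(roi_id = rownames(v), v, check.names = FALSE),
              p, digits = 8L)
    written <- c(written, p)
  }
  for (nm in names(results$de %||% list())) {
    emit(results$de[[nm]], paste0("de_", nm, ".tsv"))
  }
  if (!is.null(results$clusters)) {
    emit(results$clusters$assignments, "clusters.tsv")
    emit(results$clusters$linkage, "linkage.tsv")
  }
  for (nm in names(results$cox %||% list())) {
    emit(results$cox[[nm]], paste0("cox_", nm, ".tsv"))
  }
  invisible(written)
}

#' Read back a normalized matrix written by [write_results()]
#'
#' @param path path to `normalized.tsv`.
#' @return numeric ROI x probe matrix.
#' @export
read_normalized <- function(path) {
  x <- read_tsv_checked(path, "roi_id", "normalized matrix")
  m <- as.matrix(x[, setdiff(names(x), "roi_id"), drop = FALSE])
  rownames(m) <- x$roi_id
  storage.mode(m) <- "double"
  m
}
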