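#' Per-ROI median raw counts with low-count flagging
#'
#' Computes the median raw count over all probes (controls included) for
#' each ROI and flags ROIs whose median falls below `flag_threshold`.
#' Flagged ROIs are reported, never removed automatically.
#'
#' @param counts ROI x probe matrix.
#' @param flag_threshold flag ROIs with median below this (default 50).
#' @return data frame `roi_id`, `median_count`, `low_count_flag` with the
#'   threshold as attribute `"flag_threshold"`.
#' @export
roi_median_counts <- function(counts, flag_threshold = 50) {
  if (is.null(dim(counts)) || nrow(counts) == 0L) {
    stop("counts must be a non-empty matrix", call. = FALSE)
  }
  med <- apply(counts, 1L, stats::median)
  out <- data.frame(roi_id = rownames(counts), median_count = med,
                    low_count_flag = med < flag_threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "flag_threshold") <- flag_threshold
  out
}

#' Per-ROI isotype IgG background
#'
#' Arithmetic mean of all IgG-control probe counts within each ROI; the
#' denominator of all signal-to-noise ratios. ROIs with a zero IgG mean
#' are returned as `NA` with a warning and are excluded from SNR.
#'
#' @param counts ROI x probe matrix.
#' @param panel a `dsp_panel` with at least one `igg_control` probe.
#' @return named numeric vector, one value per ROI (`NA` where excluded).
#' @export
igg_background <- function(counts, panel) {
  igg <- intersect(igg_probes(panel), colnames(counts))
  if (length(igg) < 1L) {
    stop("no igg_control probes present in the count matrix", call. = FALSE)
  }
  bg <- rowMeans(counts[, igg, drop = FALSE])
  if (any(bg <= 0)) {
    warning("excluding ", sum(bg <= 0),
            " ROI(s) with zero IgG background from SNR")
    bg[bg <= 0] <- NA_real_
  }
  bg
}

#' Signal-to-noise table relative to IgG background
#'
#' For every ROI with a positive IgG background, each probe's count is
#' divided by that ROI's mean IgG count. The per-probe robustness summary
#' is the median (default) or mean of these ratios over retained ROIs;
#' a probe is robust when its summary meets `threshold`. IgG controls are
#' summarised like any probe but marked non-filterable (`exempt`), as are
#' housekeepers, which downstream normalization requires.
#'
#' @param counts ROI x probe matrix.
#' @param panel a `dsp_panel`.
#' @param summary_method `"median"` (default) or `"mean"`.
#' @param threshold robustness cutoff on the summary (default 1).
#' @return `snr_table` list: `ratio` (ROI x probe matrix), `summary`
#'   (data frame `probe_id`, `probe_class`, `summary`, `robust`,
#'   `exempt`), `summary_method`, `threshold`.
#' @export
snr <- function(counts, panel, summary_method = c("median", "mean"),
                threshold = 1) {
  summary_method <- match.arg(summary_method)
  if (!is.numeric(threshold) || threshold <= 0) {
    stop("threshold must be > 0", call. = FALSE)
  }
  bg <- igg_background(counts, panel)
  keep <- !is.na(bg)
  if (!any(keep)) {
    stop("IgG background computable for no ROI", call. = FALSE)
  }
  ratio <- counts[keep, , drop = FALSE] / bg[keep]
  fun <- if (summary_method == "median") stats::median else mean
  summ <- apply(ratio, 2L, fun)
  cls <- panel$probe_class[match(colnames(counts), panel$probe_id)]
  out <- list(
    ratio = ratio,
    summary = data.frame(
      probe_id = colnames(counts),
      probe_class = cls,
      summary = summ,
      robust = summ >= threshold,
      exempt = cls %in% c("igg_control", "housekeeper"),
      stringsAsFactors = FALSE, row.names = NULL),
    summary_method = summary_method,
    threshold = threshold)
  class(out) <- "snr_table"
  out
}

#' Select probes passing the signal-to-noise filter
#'
#' Returns the robust target probes plus all housekeepers and IgG
#' controls, which pass through unconditionally because normalization and
#' background assessment need them downstream. Zero robust targets is a
#' hard error suggesting threshold review.
#'
#' @param snr_table an `snr_table` from [snr()].
#' @param panel the same `dsp_panel`.
#' @return character vector of retained probe ids (panel order).
#' @export
filter_probes <- function(snr_table, panel) {
  stopifnot(inherits(snr_table, "snr_table"))
  s <- snr_table$summary
  robust_targets <- s$probe_id[s$probe_class == "target" & s$robust]
  if (length(robust_targets) == 0L) {
    stop("no target probe passed the signal-to-noise threshold (",
         snr_table$threshold, "); review the threshold or the data",
         call. = FALSE)
  }
  keep <- c(robust_targets, housekeeper_probes(panel), igg_probes(panel))
  message(length(robust_targets), " of ",
          sum(s$probe_class == "target"),
          " target probes robust at threshold ", snr_table$threshold)
  intersect(panel$probe_id, keep)
}
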