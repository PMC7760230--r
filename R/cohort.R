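#' Format a cohort percentage
#'
#' Percentage formatting used in clinical characteristics tables: one
#' decimal place below 10 percent, whole percent otherwise (IEEE
#' round-half-even, as printed output typically is).
#'
#' @param count numerator.
#' @param total denominator.
#' @return character, e.g. `"44%"` or `"7.3%"`.
#' @export
format_percent <- function(count, total) {
  p <- 100 * count / total
  ifelse(p %in% c(0, 100), sprintf("%.0f%%", p),
         ifelse(p < 10, sprintf("%.1f%%", p), sprintf("%.0f%%", p)))
}

#' Summarize a categorical cohort characteristic
#'
#' Counts and formatted percentages of each level, within-column (i.e.
#' percentages sum to ~100 within the table column).
#'
#' @param x vector of category labels (one per subject/ROI).
#' @return data frame `level`, `n`, `pct`.
#' @export
summarize_categories <- function(x) {
  tab <- table(x)
  data.frame(level = names(tab), n = as.integer(tab),
             pct = format_percent(as.integer(tab), sum(tab)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROI counts per tissue compartment
#'
#' @param roi_table ROI metadata.
#' @return data frame `compartment`, `n`, `pct`, plus the ROI total as
#'   attribute `"total"`.
#' @export
roi_compartment_summary <- function(roi_table) {
  out <- summarize_categories(roi_table$compartment)
  names(out)[1] <- "compartment"
  attr(out, "total") <- nrow(roi_table)
  out
}
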