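#' Paired t-test on matched compartment values
#'
#' Two-sided paired t-test on per-patient differences `a - b`. With fewer
#' than 2 complete pairs, or zero variance of the differences, the
#' statistic is undefined and `NA` is returned with a warning.
#'
#' @param a,b numeric vectors, matched by position (one entry per
#'   patient).
#' @return list `t`, `df`, `p`, `mean_diff`, `n`.
#' @export
paired_t <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) {
    warning("fewer than 2 complete pairs; paired t undefined")
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = if (n) mean(a - b) else NA_real_, n = n))
  }
  d <- a - b
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; p undefined")
    return(list(t = NA_real_, df = n - 1, p = NA_real_,
                mean_diff = mean(d), n = n))
  }
  ht <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_diff = unname(ht$estimate), n = n)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided test of `a` vs `b` using midranks for ties. The exact
#' distribution is used when both groups have at most 8 observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity corrections. The reported U counts pairs where `a` exceeds
#' `b` (ties as half), i.e. `U = 0` when every `a` is below every `b`.
#'
#' @param a,b numeric vectors.
#' @return list `U`, `p`, `n1`, `n2`, `exact`.
#' @export
mann_whitney <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  if (length(unique(c(a, b))) == 1L) {
    warning("all values identical across both groups")
    return(list(U = length(a) * length(b) / 2, p = 1,
                n1 = length(a), n2 = length(b), exact = FALSE))
  }
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE))
  # W is the midrank-based U for the first sample
  list(U = unname(ht$statistic), p = ht$p.value,
       n1 = length(a), n2 = length(b),
       exact = exact)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Returns adjusted p-values in input order; `NA` entries are preserved
#' and excluded from the family size.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

# Per-patient per-compartment expression: average of the patient's ROI
# values in that compartment, on the analysis scale of `values`.
patient_compartment_values <- function(values, roi_table, compartment) {
  rois <- roi_table$roi_id[roi_table$compartment == compartment &
                             !is.na(roi_table$patient_id)]
  rois <- intersect(rois, rownames(values))
  if (!length(rois)) return(NULL)
  pid <- roi_table$patient_id[match(rois, roi_table$roi_id)]
  t(vapply(split(rois, pid), function(rr) {
    colMeans(values[rr, , drop = FALSE])
  }, numeric(ncol(values))))
}

#' Differential expression between two compartments
#'
#' Paired design: per patient, ROI values of each compartment are
#' averaged, patients with both compartments are paired, and each probe
#' is tested with a paired t-test; effect = mean log2 difference (A - B).
#' Unpaired design: all ROIs of each compartment (patient-matched or
#' not) enter a Mann-Whitney test; effect = difference of group medians.
#' BH adjustment is applied within this comparison only.
#'
#' @param norm a `normalized_matrix` (log2 scale recommended).
#' @param roi_table ROI metadata.
#' @param comparison length-2 character vector `c(A, B)` of compartments.
#' @param design `"paired"` or `"unpaired"`.
#' @param probes probes to test (default: all columns of `norm`).
#' @return data frame with one row per probe: `probe_id`, `comparison`,
#'   `design`, `n`, `effect`, `statistic`, `p_raw`, `p_adj`.
#' @export
run_comparison <- function(norm, roi_table, comparison,
                           design = c("paired", "unpaired"),
                           probes = NULL) {
  design <- match.arg(design)
  stopifnot(inherits(norm, "normalized_matrix"), length(comparison) == 2L)
  comparison <- canonical_compartment(comparison)
  values <- norm$values
  if (!is.null(probes)) values <- values[, probes, drop = FALSE]
  label <- paste0(comparison[1], "_vs_", comparison[2])
  empty <- data.frame(probe_id = character(), comparison = character(),
                      design = character(), n = integer(),
                      effect = numeric(), statistic = numeric(),
                      p_raw = numeric(), p_adj = numeric())
  if (design == "paired") {
    va <- patient_compartment_values(values, roi_table, comparison[1])
    vb <- patient_compartment_values(values, roi_table, comparison[2])
    common <- intersect(rownames(va), rownames(vb))
    if (length(common) < 2L) {
      warning("fewer than 2 patients with both compartments; ",
              "empty result for ", label)
      return(empty)
    }
    res <- lapply(colnames(values), function(p) {
      tt <- paired_t(va[common, p], vb[common, p])
      data.frame(probe_id = p, comparison = label, design = design,
                 n = tt$n, effect = tt$mean_diff, statistic = tt$t,
                 p_raw = tt$p, stringsAsFactors = FALSE)
    })
  } else {
    ra <- roi_table$roi_id[roi_table$compartment == comparison[1]]
    rb <- roi_table$roi_id[roi_table$compartment == comparison[2]]
    ra <- intersect(ra, rownames(values)); rb <- intersect(rb, rownames(values))
    if (!length(ra) || !length(rb)) {
      warning("a compartment has no ROIs; empty result for ", label)
      return(empty)
    }
    res <- lapply(colnames(values), function(p) {
      mw <- mann_whitney(values[ra, p], values[rb, p])
      data.frame(probe_id = p, comparison = label, design = design,
                 n = mw$n1 + mw$n2,
                 effect = stats::median(values[ra, p]) -
                   stats::median(values[rb, p]),
                 statistic = mw$U, p_raw = mw$p, stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p_raw)
  rownames(out) <- NULL
  out
}

#' Within-compartment probe-probe correlation matrix
#'
#' Pairwise Pearson correlations over the ROIs of one compartment, with
#' two-sided p-values from the t transform and a significance mask at
#' `p <= alpha`. Constant probes are reported as `NA` with a warning.
#'
#' @param norm a `normalized_matrix`.
#' @param roi_table ROI metadata.
#' @param compartment compartment to restrict to.
#' @param probes probes to include (default: all columns).
#' @param alpha significance level for the mask (default 0.001).
#' @return list `compartment`, `r`, `p`, `n`, `significant` (logical
#'   matrix), `alpha`.
#' @export
correlation_matrix <- function(norm, roi_table, compartment,
                               probes = NULL, alpha = 0.001) {
  stopifnot(inherits(norm, "normalized_matrix"))
  compartment <- canonical_compartment(compartment)
  rois <- intersect(roi_table$roi_id[roi_table$compartment == compartment],
                    rownames(norm$values))
  if (length(rois) < 3L) {
    stop("need at least 3 ROIs in compartment ", compartment, call. = FALSE)
  }
  v <- norm$values[rois, , drop = FALSE]
  if (!is.null(probes)) v <- v[, probes, drop = FALSE]
  const <- apply(v, 2L, stats::sd) == 0
  if (any(const)) {
    warning("constant probe(s) reported NA: ",
            paste(colnames(v)[const], collapse = ", "))
  }
  n <- nrow(v)
  r <- suppressWarnings(stats::cor(v))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r)[!const] <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  list(compartment = compartment, r = r, p = p, n = n,
       significant = !is.na(p) & p <= alpha, alpha = alpha)
}
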