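#' Pearson product-moment correlation with validation
#'
#' Thin, validated wrapper used for normalizer assessment: requires equal
#' length at least 3 and errors on constant input, where the coefficient
#' is undefined.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Candidate normalization factors per ROI
#'
#' Tabulates every candidate scaling factor considered for empirical
#' normalizer selection: the individual housekeeper counts (GAPDH,
#' Histone H3, S6), their Histone H3/S6 mean (`hk_mean`), the mean IgG
#' count (`igg_mean`), and the geometric ROI properties area and nuclei
#' count when available.
#'
#' @param counts ROI x probe matrix.
#' @param panel a `dsp_panel`.
#' @param roi_table ROI metadata (for `area` and `nuclei`).
#' @return data frame, one row per ROI.
#' @export
build_factor_table <- function(counts, panel, roi_table) {
  get_probe <- function(p) {
    if (p %in% colnames(counts)) counts[, p] else {
      warning("probe ", p, " absent; factor unavailable")
      rep(NA_real_, nrow(counts))
    }
  }
  h3 <- get_probe("Histone H3"); s6 <- get_probe("S6")
  out <- data.frame(
    roi_id = rownames(counts),
    gapdh = get_probe("GAPDH"),
    histone_h3 = h3,
    s6 = s6,
    hk_mean = (h3 + s6) / 2,
    igg_mean = igg_background(counts, panel),
    stringsAsFactors = FALSE, row.names = NULL)
  idx <- match(out$roi_id, roi_table$roi_id)
  out$area <- if ("area" %in% names(roi_table)) roi_table$area[idx] else NA_real_
  out$nuclei <- if ("nuclei" %in% names(roi_table)) {
    roi_table$nuclei[idx]
  } else NA_real_
  out
}

#' Pairwise assessment of candidate normalizers
#'
#' Computes the full pairwise Pearson correlation matrix between factor
#' candidates and recommends a housekeeper-derived factor: the one whose
#' minimum correlation with the non-biological references (IgG mean,
#' area, nuclei) is highest — a factor that tracks ROI-level capture
#' effects while being blind to biology. Constant factors (e.g. area when
#' every ROI has the maximum geometry) are excluded with a warning. The
#' recommendation is advisory; configuration may override it.
#'
#' @param factors data frame from [build_factor_table()].
#' @return `normalizer_assessment` list: `r` (symmetric matrix), `n`
#'   (pairwise complete sizes), `excluded`, `recommended`.
#' @export
assess_normalizers <- function(factors) {
  cand <- setdiff(names(factors), "roi_id")
  m <- as.matrix(factors[, cand, drop = FALSE])
  usable <- vapply(cand, function(j) {
    v <- m[, j]
    sum(is.finite(v)) >= 3L && stats::sd(v[is.finite(v)]) > 0
  }, TRUE)
  excluded <- cand[!usable]
  if (length(excluded)) {
    warning("excluding constant/unavailable factor(s) from assessment: ",
            paste(excluded, collapse = ", "))
  }
  r <- matrix(NA_real_, length(cand), length(cand),
              dimnames = list(cand, cand))
  n <- r
  for (i in seq_along(cand)) {
    for (j in seq_len(i)) {
      ok <- is.finite(m[, i]) & is.finite(m[, j])
      n[i, j] <- n[j, i] <- sum(ok)
      if (usable[i] && usable[j]) {
        r[i, j] <- r[j, i] <- if (i == j) 1 else pearson_r(m[ok, i], m[ok, j])
      }
    }
  }
  hk_derived <- intersect(c("hk_mean", "histone_h3", "s6", "gapdh"),
                          cand[usable])
  refs <- intersect(c("igg_mean", "area", "nuclei"), cand[usable])
  recommended <- NA_character_
  if (length(hk_derived) && length(refs)) {
    min_r <- vapply(hk_derived, function(f) min(r[f, refs]), 1)
    recommended <- hk_derived[which.max(min_r)]
  }
  structure(list(r = r, n = n, excluded = excluded,
                 recommended = recommended),
            class = "normalizer_assessment")
}

new_normalized_matrix <- function(values, method, factors,
                                  log2 = FALSE, pseudo_count = NA_real_) {
  structure(list(values = values, method = method, factors = factors,
                 log2 = log2, pseudo_count = pseudo_count),
            class = "normalized_matrix")
}

#' Housekeeper-mean normalization
#'
#' The per-ROI factor is the mean (arithmetic by default) of the named
#' housekeeper counts. Counts are rescaled by `anchor / factor_r` where
#' the anchor is the grand geometric mean of the factors, so the output
#' stays on the raw-count scale and the grand geometric mean of the
#' factors is preserved. ROIs with a non-positive factor are excluded
#' with a warning.
#'
#' @param counts ROI x probe matrix.
#' @param panel a `dsp_panel`.
#' @param probes housekeeper probes defining the factor (default
#'   Histone H3 and S6).
#' @param average `"arithmetic"` (default) or `"geometric"` combination
#'   of the housekeeper counts.
#' @return a `normalized_matrix` (method `"hk_mean"`).
#' @export
normalize_hk <- function(counts, panel,
                         probes = c("Histone H3", "S6"),
                         average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  missing <- setdiff(probes, colnames(counts))
  if (length(missing)) {
    stop("housekeeper probe(s) absent from counts: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hk <- counts[, probes, drop = FALSE]
  fac <- if (average == "arithmetic") rowMeans(hk) else
    exp(rowMeans(log(pmax(hk, .Machine$double.eps))))
  if (any(fac <= 0)) {
    warning("excluding ", sum(fac <= 0),
            " ROI(s) with non-positive housekeeper factor")
    keep <- fac > 0
    counts <- counts[keep, , drop = FALSE]
    fac <- fac[keep]
  }
  anchor <- exp(mean(log(fac)))
  values <- counts * (anchor / fac)
  new_normalized_matrix(values, "hk_mean", stats::setNames(fac, rownames(counts)))
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Composition factors per ROI computed against a reference ROI (the one
#' whose upper-quartile count fraction is closest to the mean): the
#' weighted mean of log2 count-fraction ratios (M-values) after trimming
#' the most extreme 30 percent of M-values and 5 percent of average
#' intensities, with precision (inverse asymptotic binomial variance)
#' weights. Factors are rescaled to multiply to 1.
#'
#' @param counts ROI x probe matrix of nonnegative counts.
#' @param logratio_trim trim fraction on M-values (default 0.30).
#' @param sum_trim trim fraction on average intensities (default 0.05).
#' @return named factor vector (product 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, sum_trim = 0.05) {
  if (nrow(counts) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  allzero <- colSums(counts) == 0
  if (any(allzero)) {
    warning("dropping ", sum(allzero), " all-zero probe(s) from factor ",
            "computation")
    counts <- counts[, !allzero, drop = FALSE]
  }
  lib <- rowSums(counts)
  f75 <- apply(counts, 1L, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, nobs, rf, nref) {
    logR <- log2((obs / nobs) / (rf / nref))
    absE <- (log2(obs / nobs) + log2(rf / nref)) / 2
    v <- (nobs - obs) / (nobs * obs) + (nref - rf) / (nref * rf)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (!length(logR) || max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
    loS <- floor(n * sum_trim) + 1;      hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
      sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(nrow(counts)), function(r) {
    one_factor(counts[r, ], lib[r], counts[ref, ], lib[ref])
  }, 1)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, rownames(counts))
}

#' Relative-log-expression (median-ratio) scaling factors
#'
#' The factor of an ROI is the median, over probes, of the ratio of its
#' count to the probe's geometric mean across ROIs; probes containing a
#' zero are excluded from the computation. Factors are rescaled to
#' multiply to 1.
#'
#' @param counts ROI x probe matrix of nonnegative counts.
#' @return named factor vector (product 1).
#' @export
rle_factors <- function(counts) {
  if (nrow(counts) < 2L) stop("need at least 2 ROIs", call. = FALSE)
  logc <- log(counts)
  loggeo <- colMeans(logc)  # -Inf wherever a probe has any zero
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    stop("no probe with all-positive counts; RLE factors undefined",
         call. = FALSE)
  }
  if (any(!usable)) {
    warning("excluding ", sum(!usable),
            " probe(s) containing zeros from RLE factor computation")
  }
  f <- apply(logc[, usable, drop = FALSE], 1L, function(x) {
    exp(stats::median(x - loggeo[usable]))
  })
  f <- f / exp(mean(log(f)))
  stats::setNames(f, rownames(counts))
}

#' Global-scaling normalization (TMM or RLE)
#'
#' Divides each ROI's counts by its scaling divisor: for RLE the
#' median-ratio size factor directly; for TMM the composition factor
#' multiplied by the ROI's library size (TMM factors correct composition
#' on top of sequencing/collection depth). Divisors are rescaled to
#' geometric mean 1 so the output remains count-scaled.
#'
#' @param counts ROI x probe matrix.
#' @param method `"tmm"` or `"rle"`.
#' @return a `normalized_matrix`; `factors` holds the divisor actually
#'   applied, attribute `"method_factors"` the product-1 method factors.
#' @export
normalize_global <- function(counts, method = c("tmm", "rle")) {
  method <- match.arg(method)
  mf <- switch(method, tmm = tmm_factors(counts), rle = rle_factors(counts))
  div <- if (method == "tmm") {
    d <- mf * rowSums(counts)
    d / exp(mean(log(d)))
  } else mf
  values <- counts / div
  out <- new_normalized_matrix(values, method, div)
  attr(out, "method_factors") <- mf
  out
}

#' Log2 transform of normalized expression
#'
#' @param norm a `normalized_matrix` (or plain nonnegative matrix).
#' @param pseudo_count added before taking log2 (default 1).
#' @return a `normalized_matrix` with the `log2` flag and pseudo-count
#'   recorded.
#' @export
log2_transform <- function(norm, pseudo_count = 1) {
  if (is.matrix(norm)) norm <- new_normalized_matrix(norm, "none", NULL)
  stopifnot(inherits(norm, "normalized_matrix"))
  if (isTRUE(norm$log2)) {
    stop("matrix is already log2 transformed", call. = FALSE)
  }
  if (any(norm$values < 0)) {
    stop("log2 transform requires nonnegative values", call. = FALSE)
  }
  norm$values <- log2(norm$values + pseudo_count)
  norm$log2 <- TRUE
  norm$pseudo_count <- pseudo_count
  norm
}
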