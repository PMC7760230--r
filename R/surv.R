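#' Univariate Cox proportional-hazards fit
#'
#' Fits the Cox partial likelihood for a single continuous covariate
#' (log2 expression), with Efron handling of tied event times. Requires
#' at least 2 events and a non-constant covariate among patients with
#' values; monotone-likelihood divergence (|beta| > 20) or a failed
#' Newton iteration is reported as `converged = FALSE`, never silently.
#'
#' @param x named numeric covariate vector (names = patient ids).
#' @param surv survival table (`patient_id`, `time`, `event`).
#' @param probe_id label carried into the result.
#' @return one-row data frame: `probe_id`, `n`, `n_events`, `beta`,
#'   `se`, `hr`, `ci_low`, `ci_high`, `p`, `converged`.
#' @export
cox_fit <- function(x, surv, probe_id = NA_character_) {
  idx <- match(surv$patient_id, names(x))
  d <- data.frame(time = surv$time, event = as.integer(surv$event),
                  x = x[idx])
  d <- d[is.finite(d$x) & is.finite(d$time), ]
  skip <- function(msg) {
    warning("probe ", probe_id, ": ", msg)
    data.frame(probe_id = probe_id, n = nrow(d), n_events = sum(d$event),
               beta = NA_real_, se = NA_real_, hr = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
               converged = FALSE, stringsAsFactors = FALSE)
  }
  if (sum(d$event) < 2L) return(skip("fewer than 2 events; skipped"))
  if (stats::sd(d$x) == 0) return(skip("constant covariate; skipped"))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, data = d,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50L)),
    warning = function(w) {
      diverged <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- unname(stats::coef(fit))
  se <- sqrt(max(unname(fit$var[1, 1]), 0))
  converged <- !diverged && is.finite(beta) && abs(beta) <= 20
  p <- if (is.finite(beta) && se > 0) {
    2 * stats::pnorm(abs(beta / se), lower.tail = FALSE)
  } else NA_real_
  data.frame(
    probe_id = probe_id, n = nrow(d), n_events = sum(d$event),
    beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    p = p, converged = converged, stringsAsFactors = FALSE)
}

#' Univariate Cox screen of probes within a compartment
#'
#' For each probe, the per-patient covariate is the mean (log2)
#' expression over that patient's ROIs in the compartment; each probe is
#' fitted unadjusted and univariately, and results are ranked by hazard
#' ratio (protective markers first). No multiplicity adjustment is
#' applied by default; set `adjust = TRUE` to append a BH column.
#'
#' @param norm a `normalized_matrix` (log2 scale recommended).
#' @param roi_table ROI metadata with `patient_id`.
#' @param surv survival table.
#' @param compartment compartment whose expression is screened.
#' @param probes probes to screen (default: all columns of `norm`).
#' @param adjust append a BH-adjusted p column (default `FALSE`).
#' @return data frame of [cox_fit()] rows ranked by `hr`, with
#'   `compartment` attached.
#' @export
screen_compartment <- function(norm, roi_table, surv, compartment,
                               probes = NULL, adjust = FALSE) {
  stopifnot(inherits(norm, "normalized_matrix"))
  compartment <- canonical_compartment(compartment)
  pv <- patient_compartment_values(norm$values, roi_table, compartment)
  if (is.null(pv)) {
    warning("no patient-linked ROIs in compartment ", compartment)
    return(data.frame())
  }
  pv <- pv[rownames(pv) %in% surv$patient_id, , drop = FALSE]
  sv <- surv[surv$patient_id %in% rownames(pv), , drop = FALSE]
  if (is.null(probes)) probes <- colnames(pv)
  res <- do.call(rbind, lapply(probes, function(p) {
    cox_fit(pv[, p], sv, probe_id = p)
  }))
  res$compartment <- compartment
  if (adjust) res$p_adj <- bh_adjust(res$p)
  res[order(res$hr), , drop = FALSE]
}
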