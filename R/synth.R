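#' Compartment pattern of the default simulated cohort
#'
#' Each row describes a set of tissue compartments contributed by a group of
#' patients. The default reproduces a partially paired tissue-microarray
#' cohort of 64 patients and 96 regions of interest (ROIs): 45 tumour,
#' 32 tumour-microenvironment (TME) and 19 normal-adjacent-tissue (NAT)
#' ROIs, giving 18 tumour-TME, 14 tumour-NAT and 8 TME-NAT matched pairs.
#'
#' @return data frame with columns `Tumour`, `TME`, `NAT` (logical) and
#'   `n_patients`.
#' @export
default_pattern <- function() {
  data.frame(
    Tumour     = c(TRUE,  TRUE,  TRUE,  TRUE,  FALSE, FALSE),
    TME        = c(TRUE,  TRUE,  FALSE, FALSE, TRUE,  FALSE),
    NAT        = c(TRUE,  FALSE, TRUE,  FALSE, FALSE, TRUE),
    n_patients = c(8L,    10L,   6L,    21L,   14L,   5L)
  )
}

#' Fully paired compartment pattern
#'
#' All patients contribute the same compartments; useful for matched-pair
#' benchmark designs.
#'
#' @param n_patients number of patients.
#' @param compartments compartments each patient contributes.
#' @return pattern data frame as in [default_pattern()].
#' @export
paired_pattern <- function(n_patients, compartments = c("Tumour", "TME")) {
  compartments <- match.arg(compartments, c("Tumour", "TME", "NAT"),
                            several.ok = TRUE)
  data.frame(
    Tumour = "Tumour" %in% compartments,
    TME    = "TME" %in% compartments,
    NAT    = "NAT" %in% compartments,
    n_patients = as.integer(n_patients)
  )
}

#' Specify a synthetic DSP experiment
#'
#' Collects every data-generating assumption of the simulator: the probe
#' panel, the cohort pattern, per-ROI capture-efficiency (size-factor)
#' spread, isotype-IgG background level, negative-binomial overdispersion,
#' the multiplicative depression of target signal in normal adjacent
#' tissue, compartment-specific log2 enrichments, per-probe log-hazard
#' coefficients for survival, and the master seed. Defaults are calibrated
#' so that simulated per-ROI IgG means concentrate in 50-150 counts and
#' per-ROI median counts fall between 1e2 and 1e3.
#'
#' @param n_patients optional; if given (and `pattern` is not), every
#'   patient contributes all of `compartments`.
#' @param compartments used with `n_patients`.
#' @param pattern compartment pattern data frame (see [default_pattern()]);
#'   default is the partially paired 64-patient cohort.
#' @param panel a `dsp_panel`; default [make_default_panel()].
#' @param rois_per_compartment ROIs drawn per patient per compartment.
#' @param background_mean expected IgG-control count at size factor 1.
#' @param roi_size_factor_sd sd of the per-ROI log size factor.
#' @param nat_depression multiplicative factor in (0, 1] applied to target
#'   probe means in NAT ROIs (housekeepers and IgG are unaffected).
#' @param effect_table data frame `probe_id`, `compartment`, `log2fc` of
#'   compartment-specific target enrichments; `NULL` means no effects.
#' @param dispersion negative-binomial size parameter (larger = closer to
#'   Poisson); must be > 0.
#' @param biological_sd log2-scale sd of patient-level target expression
#'   heterogeneity; the multiplier is shared across all of a patient's
#'   compartments and is mean-one on the linear scale, so population
#'   means stay at the ledger values. Housekeepers and IgG controls are
#'   unaffected.
#' @param survival_betas named numeric vector: log-hazard per log2-unit of
#'   true expression, per probe; `NULL` means no survival signal.
#' @param censor_rate expected fraction of censored patients in `[0, 1)`.
#' @param base_hazard baseline event rate per month.
#' @param target_mean_range range of per-probe baseline means; baselines
#'   are drawn log-uniformly over this range from the design seed.
#' @param hk_means named baseline means for housekeeper probes.
#' @param seed master seed; all stages derive sub-streams from it.
#' @return a `simulation_design` object (list).
#' @export
simulation_design <- function(n_patients = NULL,
                              compartments = c("Tumour", "TME", "NAT"),
                              pattern = NULL,
                              panel = make_default_panel(),
                              rois_per_compartment = 1L,
                              background_mean = 95,
                              roi_size_factor_sd = 0.20,
                              nat_depression = 0.6,
                              effect_table = NULL,
                              dispersion = 150,
                              biological_sd = 0.5,
                              survival_betas = NULL,
                              censor_rate = 0.3,
                              base_hazard = 0.02,
                              target_mean_range = c(50, 3000),
                              hk_means = c("Histone H3" = 600, "S6" = 450,
                                           "GAPDH" = 500),
                              seed = 1L) {
  panel <- as_dsp_panel(panel)
  if (is.null(pattern)) {
    pattern <- if (is.null(n_patients)) default_pattern() else
      paired_pattern(n_patients, compartments)
  }
  stopifnot(is.data.frame(pattern),
            all(c("Tumour", "TME", "NAT", "n_patients") %in% names(pattern)))
  if (sum(pattern$n_patients) < 1L) {
    stop("design must contain at least one patient", call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel must be non-empty", call. = FALSE)
  if (!(nat_depression > 0 && nat_depression <= 1)) {
    stop("nat_depression must be in (0, 1]", call. = FALSE)
  }
  if (!(censor_rate >= 0 && censor_rate < 1)) {
    stop("censor_rate must be in [0, 1)", call. = FALSE)
  }
  if (!(dispersion > 0)) stop("dispersion must be > 0", call. = FALSE)
  if (!is.null(effect_table)) {
    stopifnot(all(c("probe_id", "compartment", "log2fc") %in%
                    names(effect_table)))
    unknown <- setdiff(effect_table$probe_id, panel$probe_id)
    if (length(unknown)) {
      stop("effect_table probes absent from panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(survival_betas)) {
    unknown <- setdiff(names(survival_betas), panel$probe_id)
    if (length(unknown)) {
      stop("survival_betas probes absent from panel: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  design <- list(pattern = pattern, panel = panel,
                 rois_per_compartment = as.integer(rois_per_compartment),
                 background_mean = background_mean,
                 roi_size_factor_sd = roi_size_factor_sd,
                 nat_depression = nat_depression,
                 effect_table = effect_table,
                 dispersion = dispersion,
                 biological_sd = biological_sd,
                 survival_betas = survival_betas,
                 censor_rate = censor_rate,
                 base_hazard = base_hazard,
                 target_mean_range = target_mean_range,
                 hk_means = hk_means,
                 seed = as.integer(seed))
  class(design) <- "simulation_design"
  design
}

# Deterministic sub-stream seeds derived from the master seed; kept below
# 2^31 so they remain valid R integer seeds.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

# Per-probe baseline means at size factor 1: log-uniform for targets,
# fixed for housekeepers, background level for IgG controls.
baseline_means <- function(design) {
  panel <- design$panel
  mu <- numeric(nrow(panel))
  names(mu) <- panel$probe_id
  tg <- panel$probe_class == "target"
  set.seed(sub_seed(design$seed, 1L))
  lo <- log(design$target_mean_range[1]); hi <- log(design$target_mean_range[2])
  mu[tg] <- exp(stats::runif(sum(tg), lo, hi))
  hk <- housekeeper_probes(panel)
  mu[hk] <- ifelse(hk %in% names(design$hk_means),
                   design$hk_means[hk], stats::median(design$hk_means))
  mu[igg_probes(panel)] <- design$background_mean
  mu
}

# Patient/ROI roster implied by the pattern.
build_roster <- function(design) {
  pat <- design$pattern
  rows <- list()
  pid <- 0L
  for (i in seq_len(nrow(pat))) {
    comps <- c("Tumour", "TME", "NAT")[unlist(pat[i, c("Tumour", "TME", "NAT")])]
    for (j in seq_len(pat$n_patients[i])) {
      pid <- pid + 1L
      for (comp in comps) {
        for (k in seq_len(design$rois_per_compartment)) {
          rows[[length(rows) + 1L]] <- data.frame(
            patient_id = sprintf("P%03d", pid), compartment = comp,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  roster <- do.call(rbind, rows)
  roster$roi_id <- sprintf("ROI_%03d", seq_len(nrow(roster)))
  roster[, c("roi_id", "patient_id", "compartment")]
}

#' Simulate a DSP count experiment
#'
#' Draws a probe-count matrix under a negative-binomial model:
#' `count(r, p) ~ NB(mean = sf_r * mu_p * 2^effect(p, c_r) * nat(p, c_r),
#' size = dispersion)` where `sf_r` is a log-normal per-ROI size factor
#' shared by all probes of the ROI, `mu_p` the probe baseline, `effect`
#' the compartment-specific log2 enrichment for target probes and `nat`
#' the NAT depression factor for target probes in NAT ROIs. IgG controls
#' carry only `sf_r * background_mean`; housekeepers only `sf_r * mu_p`.
#' ROI area and nuclei counts are emitted as noisy monotone transforms of
#' the size factor (area capped at the maximum ROI geometry) so that
#' normalizer-assessment correlations have realistic structure.
#'
#' @param design a [simulation_design()].
#' @return list of class `dsp_simulation` with elements `counts` (ROI x
#'   probe matrix), `roi_table`, and `truth` (ground-truth ledger: per-ROI
#'   size factors, per-probe per-compartment true means, seed).
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  panel <- design$panel
  mu <- baseline_means(design)
  roster <- build_roster(design)
  n_roi <- nrow(roster)
  n_probe <- nrow(panel)

  set.seed(sub_seed(design$seed, 2L))
  sf <- exp(stats::rnorm(n_roi, 0, design$roi_size_factor_sd))

  # expected mean per (roi, probe)
  eff <- matrix(0, n_roi, n_probe, dimnames = list(roster$roi_id, panel$probe_id))
  if (!is.null(design$effect_table)) {
    for (i in seq_len(nrow(design$effect_table))) {
      rr <- roster$compartment == design$effect_table$compartment[i]
      eff[rr, design$effect_table$probe_id[i]] <- design$effect_table$log2fc[i]
    }
  }
  nat_fac <- matrix(1, n_roi, n_probe)
  is_target <- panel$probe_class == "target"
  nat_fac[roster$compartment == "NAT", is_target] <- design$nat_depression
  # IgG/housekeepers: no compartment effects
  eff[, !is_target] <- 0

  # patient-level biological heterogeneity of target expression, shared
  # across a patient's compartments; mean-one so population means match
  # the truth ledger
  patients <- unique(roster$patient_id)
  bio <- matrix(1, length(patients), n_probe,
                dimnames = list(patients, panel$probe_id))
  if (design$biological_sd > 0) {
    set.seed(sub_seed(design$seed, 6L))
    raw <- matrix(2^stats::rnorm(length(patients) * sum(is_target), 0,
                                 design$biological_sd),
                  length(patients), sum(is_target))
    bio[, is_target] <- raw / exp((design$biological_sd * log(2))^2 / 2)
  }
  bio_roi <- bio[roster$patient_id, , drop = FALSE]

  mean_mat <- sf * sweep(2^eff * nat_fac * bio_roi, 2L, mu, `*`)

  set.seed(sub_seed(design$seed, 3L))
  counts <- matrix(
    stats::rnbinom(n_roi * n_probe, mu = as.vector(mean_mat),
                   size = design$dispersion),
    n_roi, n_probe, dimnames = dimnames(eff))
  storage.mode(counts) <- "double"

  # area / nuclei: monotone in sf plus noise; some ROIs hit the maximum
  # circular geometry (600 um diameter)
  set.seed(sub_seed(design$seed, 4L))
  area_max <- pi * 300^2
  area <- pmin(area_max, 180000 * sf * exp(stats::rnorm(n_roi, 0, 0.2)))
  nuclei <- pmax(1L, round(250 * sf * exp(stats::rnorm(n_roi, 0, 0.2))))

  roi_table <- data.frame(
    roi_id = roster$roi_id, patient_id = roster$patient_id,
    compartment = roster$compartment, area = area, nuclei = nuclei,
    shape = ifelse(area >= area_max - 1e-6, "geometric", "custom"),
    stringsAsFactors = FALSE)

  comps <- c("Tumour", "TME", "NAT")
  truth_means <- do.call(rbind, lapply(comps, function(cc) {
    e <- rep(0, n_probe)
    if (!is.null(design$effect_table)) {
      sel <- design$effect_table$compartment == cc
      e[match(design$effect_table$probe_id[sel], panel$probe_id)] <-
        design$effect_table$log2fc[sel]
    }
    e[!is_target] <- 0
    nf <- ifelse(is_target & cc == "NAT", design$nat_depression, 1)
    data.frame(probe_id = panel$probe_id, compartment = cc,
               true_mean = mu * 2^e * nf, stringsAsFactors = FALSE)
  }))
  rownames(truth_means) <- NULL

  truth <- list(
    roi = data.frame(roi_id = roster$roi_id, size_factor = sf,
                     stringsAsFactors = FALSE),
    probe_means = truth_means,
    patient_effects = bio,
    seed = design$seed)

  structure(list(counts = counts, roi_table = roi_table, truth = truth),
            class = "dsp_simulation")
}

#' Simulate overall survival linked to true expression
#'
#' Per patient, the log hazard is the sum over probes in
#' `design$survival_betas` of `beta_p * log2(true mean of p)` in the
#' patient's reference compartment (tumour when present, otherwise the
#' first compartment the patient contributes), centred across patients.
#' Event times are exponential with rate `base_hazard * exp(log-hazard)`;
#' censoring is an independent exponential calibrated so that, under the
#' null, the expected censored fraction equals `censor_rate`.
#'
#' @param truth ground-truth ledger from [simulate_counts()].
#' @param design the same [simulation_design()].
#' @param roi_table the ROI table from the same simulation run.
#' @return data frame `patient_id`, `time` (months, > 0), `event`
#'   (logical), plus the true per-patient log-hazard as attribute
#'   `"log_hazard"`.
#' @export
simulate_survival <- function(truth, design, roi_table) {
  stopifnot(inherits(design, "simulation_design"))
  if (!setequal(roi_table$roi_id, truth$roi$roi_id)) {
    stop("truth ledger and roi_table describe different ROI sets",
         call. = FALSE)
  }
  patients <- unique(roi_table$patient_id)
  ref_comp <- vapply(patients, function(p) {
    comps <- roi_table$compartment[roi_table$patient_id == p]
    if ("Tumour" %in% comps) "Tumour" else comps[1]
  }, character(1))

  lh <- rep(0, length(patients))
  if (!is.null(design$survival_betas) && length(design$survival_betas)) {
    for (probe in names(design$survival_betas)) {
      tm <- truth$probe_means
      mu_pc <- stats::setNames(tm$true_mean[tm$probe_id == probe],
                               tm$compartment[tm$probe_id == probe])
      expr <- mu_pc[ref_comp] * truth$patient_effects[patients, probe]
      lh <- lh + design$survival_betas[[probe]] * log2(expr)
    }
    lh <- lh - mean(lh)
  }

  set.seed(sub_seed(design$seed, 5L))
  rate <- design$base_hazard * exp(lh)
  t_event <- stats::rexp(length(patients), rate)
  if (design$censor_rate > 0) {
    rate_c <- design$base_hazard * design$censor_rate /
      (1 - design$censor_rate)
    t_cens <- stats::rexp(length(patients), rate_c)
  } else {
    t_cens <- rep(Inf, length(patients))
  }
  out <- data.frame(
    patient_id = patients,
    time = pmax(pmin(t_event, t_cens), 1e-6),
    event = t_event <= t_cens,
    stringsAsFactors = FALSE)
  attr(out, "log_hazard") <- stats::setNames(lh, patients)
  out
}
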