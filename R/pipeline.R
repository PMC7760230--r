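#' Default run configuration
#'
#' Fills every stage parameter with its default; anything supplied in
#' `config` overrides the default. All effective values are echoed into
#' the run manifest.
#'
#' @param config named list of overrides (possibly nested stage lists).
#' @return complete configuration list.
#' @export
default_config <- function(config = list()) {
  defaults <- list(
    seed = 1L,
    simulate = TRUE,
    paths = list(counts = NULL, roi_table = NULL, panel = NULL,
                 survival = NULL),
    qc = list(summary_method = "median", snr_threshold = 1,
              flag_threshold = 50, drop_flagged = FALSE),
    normalize = list(method = "hk_mean",
                     hk_probes = c("Histone H3", "S6"),
                     log2 = TRUE, pseudo_count = 1),
    de = list(alpha = 0.05,
              comparisons = list(
                list(compartments = c("TME", "NAT"), design = "paired"),
                list(compartments = c("TME", "Tumour"), design = "paired"),
                list(compartments = c("NAT", "TME"), design = "unpaired"),
                list(compartments = c("TME", "Tumour"), design = "unpaired"))),
    cluster = list(k = 3L, seed = 1L, restarts = 25L),
    survival = list(compartments = c("Tumour", "TME"), adjust = FALSE),
    out_dir = NULL)
  out <- utils::modifyList(defaults, config)
  # modifyList cannot merge unnamed lists: a supplied comparison list
  # replaces the default set wholesale
  if (!is.null(config$de$comparisons)) {
    out$de$comparisons <- lapply(config$de$comparisons, function(cmp) {
      cmp$compartments <- unlist(cmp$compartments)
      cmp
    })
  }
  out
}

validate_config <- function(config) {
  if (!config$normalize$method %in% c("hk_mean", "igg", "tmm", "rle")) {
    stop("unknown normalization method: ", config$normalize$method,
         "; allowed: hk_mean, igg, tmm, rle", call. = FALSE)
  }
  if (!config$qc$summary_method %in% c("median", "mean")) {
    stop("unknown SNR summary method: ", config$qc$summary_method,
         call. = FALSE)
  }
  for (cmp in config$de$comparisons) {
    canonical_compartment(cmp$compartments)
    if (!cmp$design %in% c("paired", "unpaired")) {
      stop("unknown DE design: ", cmp$design, call. = FALSE)
    }
  }
  invisible(config)
}

stage_log <- function(quiet, stage, t0, detail) {
  if (!quiet) {
    message(sprintf("[%s] %.2fs %s", stage,
                    as.numeric(Sys.time()) - t0, detail))
  }
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or read) -> QC -> SNR filter -> normalization
#' -> differential expression -> clustering -> survival screening from
#' one configuration, collecting a manifest of every parameter, seed,
#' stage record count and warning. Rerunning with an identical
#' configuration reproduces identical outputs.
#'
#' @param config configuration list (see [default_config()]); when
#'   `config$simulate` is `TRUE` (or a [simulation_design()]), inputs
#'   are simulated, otherwise read from `config$paths`.
#' @param quiet suppress per-stage progress messages.
#' @return list of stage results plus `manifest`; if `config$out_dir`
#'   is set, all stage files and `manifest.json` are written there.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  config <- validate_config(default_config(config))
  t0 <- as.numeric(Sys.time())
  warnings_seen <- character(0)
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # ---- inputs -------------------------------------------------------
  if (isTRUE(config$simulate) || inherits(config$simulate,
                                          "simulation_design")) {
    design <- if (inherits(config$simulate, "simulation_design")) {
      config$simulate
    } else simulation_design(seed = config$seed)
    sim <- simulate_counts(design)
    counts <- sim$counts; roi_table <- sim$roi_table
    panel <- design$panel
    surv <- simulate_survival(sim$truth, design, roi_table)
    truth <- sim$truth
  } else {
    counts <- read_counts(config$paths$counts)
    roi_table <- read_roi_table(config$paths$roi_table)
    panel <- read_panel(config$paths$panel)
    surv <- if (!is.null(config$paths$survival)) {
      read_survival(config$paths$survival)
    } else NULL
    truth <- NULL
  }
  check_panel_usable(panel)
  validate_experiment(counts, roi_table, panel)
  stage_log(quiet, "input", t0,
            sprintf("%d ROIs x %d probes", nrow(counts), ncol(counts)))

  # ---- qc -----------------------------------------------------------
  roi_qc <- roi_median_counts(counts, config$qc$flag_threshold)
  if (isTRUE(config$qc$drop_flagged) && any(roi_qc$low_count_flag)) {
    drop <- roi_qc$roi_id[roi_qc$low_count_flag]
    counts <- counts[!rownames(counts) %in% drop, , drop = FALSE]
    warnings_seen <- c(warnings_seen,
                       paste("dropped low-count ROIs:",
                             paste(drop, collapse = ", ")))
  }
  snr_tab <- collect(snr(counts, panel,
                         summary_method = config$qc$summary_method,
                         threshold = config$qc$snr_threshold))
  robust <- collect(suppressMessages(filter_probes(snr_tab, panel)))
  robust_targets <- intersect(robust, target_probes(panel))
  stage_log(quiet, "qc", t0, sprintf("%d robust targets, %d ROIs flagged",
                                     length(robust_targets),
                                     sum(roi_qc$low_count_flag)))

  # ---- normalization ------------------------------------------------
  kept <- counts[, robust, drop = FALSE]
  factors <- collect(build_factor_table(counts, panel, roi_table))
  assessment <- collect(assess_normalizers(factors))
  norm <- collect(switch(
    config$normalize$method,
    hk_mean = normalize_hk(kept, panel, probes = config$normalize$hk_probes),
    igg = {
      bg <- igg_background(kept, panel)
      keep <- !is.na(bg)
      anchor <- exp(mean(log(bg[keep])))
      new_normalized_matrix(kept[keep, , drop = FALSE] * (anchor / bg[keep]),
                            "igg", bg[keep])
    },
    tmm = normalize_global(kept, "tmm"),
    rle = normalize_global(kept, "rle")))
  if (isTRUE(config$normalize$log2)) {
    norm <- log2_transform(norm, config$normalize$pseudo_count)
  }
  stage_log(quiet, "normalize", t0,
            sprintf("method=%s recommended=%s", config$normalize$method,
                    assessment$recommended))

  # ---- differential expression -------------------------------------
  de <- list()
  for (cmp in config$de$comparisons) {
    label <- paste0(paste(cmp$compartments, collapse = "_vs_"),
                    "_", cmp$design)
    de[[label]] <- collect(run_comparison(
      norm, roi_table, cmp$compartments, design = cmp$design,
      probes = robust_targets))
  }
  stage_log(quiet, "de", t0, sprintf("%d comparisons", length(de)))

  # ---- clustering ---------------------------------------------------
  clusters <- collect(cluster_rois(
    norm, roi_table, k = config$cluster$k, seed = config$cluster$seed))
  stage_log(quiet, "cluster", t0, sprintf("k=%d", config$cluster$k))

  # ---- survival -----------------------------------------------------
  cox <- list()
  if (!is.null(surv)) {
    for (comp in config$survival$compartments) {
      cox[[comp]] <- collect(screen_compartment(
        norm, roi_table, surv, comp, probes = robust_targets,
        adjust = config$survival$adjust))
    }
  }
  stage_log(quiet, "survival", t0,
            sprintf("%d compartments screened", length(cox)))

  results <- list(
    roi_qc = roi_qc, snr = snr_tab, robust_probes = robust,
    factors = factors, assessment = assessment, normalized = norm,
    de = de, clusters = clusters, cox = cox, truth = truth,
    survival_table = surv)

  manifest <- list(
    config = config,
    n_rois = nrow(counts), n_probes = ncol(counts),
    n_robust_targets = length(robust_targets),
    stages = list(
      roi_qc = nrow(roi_qc), snr = nrow(snr_tab$summary),
      factors = nrow(factors),
      normalized = nrow(norm$values),
      de = vapply(de, nrow, 1L),
      clusters = nrow(clusters$assignments),
      cox = vapply(cox, nrow, 1L)),
    warnings = warnings_seen)
  results$manifest <- manifest

  if (!is.null(config$out_dir)) {
    files <- write_results(results, config$out_dir)
    manifest$files <- basename(files)
    results$manifest <- manifest
    jsonlite::write_json(manifest, file.path(config$out_dir,
                                             "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE)
  }
  invisible(results)
}

#' Read a YAML run configuration
#'
#' @param path YAML file with the fields of [default_config()].
#' @return configuration list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  # yaml turns comparison entries into lists already; nothing to coerce
  default_config(cfg)
}
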