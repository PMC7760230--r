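#' Default DSP protein probe panel
#'
#' Builds the probe panel used throughout the package: 52 target proteins
#' organised into five DSP modules (immune cell profiling, IO drug targets,
#' immune activation status, immune cell typing, pan-tumour), plus the
#' control module containing three isotype IgG background probes
#' (rabbit IgG, mouse IgG1, mouse IgG2a) and three housekeeper probes
#' (Histone H3, S6, GAPDH).
#'
#' @return A `dsp_panel` data frame with columns `probe_id`, `probe_class`
#'   (`"target"`, `"igg_control"` or `"housekeeper"`), `module`, and `host`
#'   (antibody host species, `NA` except for IgG controls).
#' @export
#' @examples
#' panel <- make_default_panel()
#' table(panel$probe_class)
make_default_panel <- function() {
  modules <- list(
    "Immune Cell Profiling" = c(
      "PD-1", "CD68", "HLA-DR", "Ki-67", "Beta-2M", "CD11c", "CD20", "CD3",
      "CD4", "CD45", "CD56", "CD8", "CTLA4", "GZMB", "PD-L1", "PanCk",
      "SMA", "Fibronectin"),
    "IO Drug Target" = c(
      "4-1BB", "LAG3", "OX40L", "Tim-3", "VISTA", "ARG1", "B7-H3", "IDO1",
      "STING", "GITR"),
    "Immune Activation Status" = c(
      "CD127", "CD25", "CD80", "ICOS", "PD-L2", "CD40", "CD44", "CD27"),
    "Immune Cell Typing" = c(
      "CD45RO", "FOXP3", "CD34", "CD66b", "FAP-alpha", "CD14", "CD163"),
    "Pan-Tumour Module" = c(
      "MART1", "NY-ESO-1", "S100B", "Bcl-2", "EpCAM", "Her2", "PTEN",
      "ER-alpha", "PR")
  )
  targets <- data.frame(
    probe_id    = unlist(modules, use.names = FALSE),
    probe_class = "target",
    module      = rep(names(modules), vapply(modules, length, 1L)),
    host        = NA_character_,
    stringsAsFactors = FALSE
  )
  controls <- data.frame(
    probe_id    = c("Rb IgG", "Ms IgG1", "Ms IgG2a",
                    "Histone H3", "S6", "GAPDH"),
    probe_class = c(rep("igg_control", 3L), rep("housekeeper", 3L)),
    module      = "Controls",
    host        = c("Rb", "Ms", "Ms", NA, NA, NA),
    stringsAsFactors = FALSE
  )
  panel <- rbind(controls, targets)
  rownames(panel) <- NULL
  as_dsp_panel(panel)
}

#' Coerce and validate a probe panel
#'
#' @param x data frame with columns `probe_id`, `probe_class`, `module`
#'   and optionally `host`.
#' @return validated `dsp_panel` data frame.
#' @export
as_dsp_panel <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  required <- c("probe_id", "probe_class", "module")
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop("panel is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"host" %in% names(x)) x$host <- NA_character_
  allowed <- c("target", "igg_control", "housekeeper")
  bad <- setdiff(unique(x$probe_class), allowed)
  if (length(bad)) {
    stop("unknown probe_class value(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(allowed, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(x$probe_id)) {
    stop("duplicated probe_id(s): ",
         paste(unique(x$probe_id[duplicated(x$probe_id)]), collapse = ", "),
         call. = FALSE)
  }
  class(x) <- c("dsp_panel", "data.frame")
  x
}

#' @rdname panel_probes
#' @export
target_probes <- function(panel) panel$probe_id[panel$probe_class == "target"]

#' Probe subsets by class
#'
#' Convenience accessors returning probe identifiers of a given class.
#'
#' @param panel a `dsp_panel`.
#' @return character vector of probe ids.
#' @name panel_probes
#' @export
igg_probes <- function(panel) panel$probe_id[panel$probe_class == "igg_control"]

#' @rdname panel_probes
#' @export
housekeeper_probes <- function(panel) {
  panel$probe_id[panel$probe_class == "housekeeper"]
}

# Pipeline entry requirement: at least one IgG control and two housekeepers.
check_panel_usable <- function(panel) {
  if (length(igg_probes(panel)) < 1L) {
    stop("panel must contain at least one igg_control probe", call. = FALSE)
  }
  if (length(housekeeper_probes(panel)) < 2L) {
    stop("panel must contain at least two housekeeper probes", call. = FALSE)
  }
  invisible(panel)
}
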