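#' Relative expression (per-probe z-scores)
#'
#' Standardizes each probe to mean 0, sd 1 across ROIs — the "relative
#' expression" scale used for heatmap display and clustering. Intended
#' for log2 normalized values. Constant probes carry no contrast and are
#' dropped with a warning.
#'
#' @param norm a `normalized_matrix` or plain ROI x probe matrix.
#' @return numeric matrix of z-scores (possibly fewer columns).
#' @export
relative_expression <- function(norm) {
  v <- if (inherits(norm, "normalized_matrix")) norm$values else norm
  if (nrow(v) < 2L || ncol(v) < 2L) {
    stop("need at least 2 ROIs and 2 probes", call. = FALSE)
  }
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant probe(s): ",
            paste(colnames(v)[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(v, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Ward.D2 agglomerative clustering
#'
#' Euclidean distances with Ward's minimum-variance criterion in the
#' squared-distance formulation; merge heights are the square root of
#' the Ward criterion and are monotone nondecreasing.
#'
#' @param x scaled matrix (items in rows when `on = "rois"`).
#' @param on cluster ROIs (rows) or probes (columns).
#' @return an `hclust` object.
#' @export
ward_d2 <- function(x, on = c("rois", "probes")) {
  on <- match.arg(on)
  if (on == "probes") x <- t(x)
  if (any(!is.finite(x))) {
    stop("non-finite entries in clustering input", call. = FALSE)
  }
  if (nrow(x) < 2L) stop("need at least 2 items", call. = FALSE)
  stats::hclust(stats::dist(x), method = "ward.D2")
}

#' k-means class assignment
#'
#' Best of `restarts` random starts by total within-cluster sum of
#' squares; deterministic given `seed`.
#'
#' @param x scaled matrix (items in rows).
#' @param k number of classes (>= 2, <= number of items).
#' @param seed RNG seed.
#' @param restarts number of random restarts (default 25).
#' @return integer labels in `1..k`, named by row, with the fitted
#'   `kmeans` object as attribute `"fit"`.
#' @export
kmeans_classes <- function(x, k = 3L, seed = 1L, restarts = 25L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (k > nrow(x)) stop("k cannot exceed the number of items", call. = FALSE)
  set.seed(seed)
  fit <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100L)
  structure(stats::setNames(fit$cluster, rownames(x)), fit = fit)
}

#' Cluster ROIs on relative expression
#'
#' Convenience wrapper: z-scores, Ward.D2 linkage of ROIs, and k-means
#' classes, returning heatmap-ready artifacts.
#'
#' @param norm a `normalized_matrix` (log2 scale recommended).
#' @param roi_table ROI metadata (for compartment labels in the output).
#' @param k number of k-means classes (default 3).
#' @param seed RNG seed for k-means.
#' @return list `scaled` (ordered by the dendrogram), `linkage` (merge
#'   table), `hclust`, `assignments` (`roi_id`, `kmeans_class`,
#'   `compartment`), `k`, `seed`.
#' @export
cluster_rois <- function(norm, roi_table, k = 3L, seed = 1L) {
  scaled <- relative_expression(norm)
  hc <- ward_d2(scaled, on = "rois")
  labels <- kmeans_classes(scaled, k = k, seed = seed)
  linkage <- data.frame(
    step = seq_len(nrow(hc$merge)),
    node_a = hc$merge[, 1], node_b = hc$merge[, 2],
    height = hc$height)
  assignments <- data.frame(
    roi_id = rownames(scaled),
    kmeans_class = unname(labels[rownames(scaled)]),
    compartment = roi_table$compartment[
      match(rownames(scaled), roi_table$roi_id)],
    stringsAsFactors = FALSE)
  list(scaled = scaled[hc$order, , drop = FALSE], linkage = linkage,
       hclust = hc, assignments = assignments, k = k, seed = seed)
}
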