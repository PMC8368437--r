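#' Select virtual sensors from a source map
#'
#' Virtual sensors are reconstructed source-space time series at selected
#' voxels. Two deterministic selection rules are provided: `"top_fraction"`
#' keeps the `floor(fraction * n_voxels)` voxels of greatest accumulated
#' strength (ties resolved towards lower voxel indices); `"roi_seeded"`
#' keeps every voxel of an atlas region plus the global top fraction.
#'
#' @param src A [beamform()] result (provides the signals).
#' @param asi The matching [accumulate_source_imaging()] map.
#' @param rule `"top_fraction"` or `"roi_seeded"`.
#' @param fraction Fraction of voxels kept by strength (default 0.01).
#' @param roi Atlas label for `"roi_seeded"` (default `"MFC"`).
#' @param atlas A [region_atlas()]; required for `"roi_seeded"`.
#' @return Object of class `virtual_sensor_set`: list with `node_voxels`
#'   (grid indices), `signals` (nodes x samples), `selection_rule`, `grid`.
#' @export
extract_virtual_sensors <- function(src, asi, rule = c("top_fraction", "roi_seeded"),
                                    fraction = 0.01, roi = "MFC", atlas = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(src, "meg_source_activity"), inherits(asi, "asi_map"))
  nv <- nrow(src$Q)
  if (length(asi$strength) != nv)
    stop_config("map (%d voxels) does not match source activity (%d voxels)",
                length(asi$strength), nv)
  n_top <- floor(fraction * nv)
  top <- if (n_top > 0L) order(-asi$strength, seq_len(nv))[seq_len(n_top)] else integer()
  nodes <- switch(rule,
    top_fraction = top,
    roi_seeded = {
      if (is.null(atlas)) stop_config("roi_seeded selection requires an atlas")
      union(region_voxels(src$grid, atlas, roi), top)
    })
  nodes <- sort(nodes)
  if (length(nodes) < 2L)
    stop_config("virtual sensor selection produced %d node(s); at least 2 are required",
                length(nodes))
  structure(list(node_voxels = nodes,
                 signals = src$Q[nodes, , drop = FALSE],
                 selection_rule = if (rule == "top_fraction")
                   sprintf("top_fraction(%g)", fraction)
                 else sprintf("roi_seeded(%s, %g)", roi, fraction),
                 grid = src$grid),
            class = "virtual_sensor_set")
}

#' @export
print.virtual_sensor_set <- function(x, ...) {
  cat(sprintf("<virtual_sensor_set> %d nodes x %d samples, rule %s\n",
              nrow(x$signals), ncol(x$signals), x$selection_rule))
  invisible(x)
}

#' All-pairs Pearson correlation of virtual sensors
#'
#' Product-moment correlation `R(xa, xb)` for every unordered node pair.
#' Zero-variance signals are excluded with a warning (their rows/columns
#' are dropped, never silently set to NaN).
#'
#' @param vs A [extract_virtual_sensors()] result, or a nodes x samples
#'   matrix.
#' @return Symmetric correlation matrix with unit diagonal; attribute
#'   `excluded` lists dropped node indices, attribute `K` the sample count.
#' @export
pairwise_correlation <- function(vs) {
  signals <- if (inherits(vs, "virtual_sensor_set")) vs$signals else as.matrix(vs)
  if (ncol(signals) < 2L) stop_config("at least 2 samples are required")
  v <- apply(signals, 1L, var)
  excluded <- which(v == 0 | !is.finite(v))
  if (length(excluded)) {
    warning(sprintf("excluding %d zero-variance virtual sensor(s): %s",
                    length(excluded), paste(excluded, collapse = ", ")))
    signals <- signals[-excluded, , drop = FALSE]
  }
  if (nrow(signals) < 2L)
    stop_config("fewer than 2 virtual sensors with nonzero variance")
  R <- cor(t(signals))
  attr(R, "excluded") <- excluded
  attr(R, "K") <- ncol(signals)
  R
}

#' t-statistic of a correlation coefficient
#'
#' `Tp = R * sqrt(K - 2) / sqrt(1 - R^2)`, where `K` is the number of
#' connected data points (time samples). `|R| = 1` maps to a signed
#' infinite t (always significant). Vectorized over `R`.
#'
#' @param R Correlation value(s) in `[-1, 1]`.
#' @param K Number of data points (>= 3).
#' @return t value(s).
#' @examples
#' tp_threshold(0.5, 6)   # 1.1547
#' @export
tp_threshold <- function(R, K) {
  if (!is_number(K) || K < 3) stop_config("K must be >= 3 (got %s)", format(K))
  if (any(abs(R) > 1 + 1e-12, na.rm = TRUE)) stop_config("|R| must not exceed 1")
  R <- pmin(1, pmax(-1, R))
  ifelse(abs(R) == 1, sign(R) * Inf, R * sqrt((K - 2) / (1 - R^2)))
}

#' Critical t value of the connectivity threshold
#'
#' Two-sided critical t at level `alpha` with `K - 2` degrees of freedom:
#' an edge survives iff `|Tp| >= tp_critical(K, alpha)`.
#'
#' @inheritParams tp_threshold
#' @param alpha Significance level (default 0.05).
#' @return Critical t value.
#' @export
tp_critical <- function(K, alpha = 0.05) {
  if (!is_number(K) || K < 3) stop_config("K must be >= 3")
  qt(1 - alpha / 2, df = K - 2)
}

#' Build a thresholded functional connectivity network
#'
#' Evaluates all unordered virtual-sensor pairs, converts each correlation
#' to its t value and keeps the pairs whose `|Tp|` reaches the two-sided
#' critical t at `alpha` (p < alpha defines the network threshold).
#' Surviving edges carry the correlation, t value and sign (positive /
#' negative connection).
#'
#' @param vs A [extract_virtual_sensors()] result.
#' @param alpha Per-pair significance level (default 0.05; no correction
#'   across pairs -- multiplicity is handled across bands at the group
#'   level).
#' @return Object of class `connectivity_network`: list with `edges`
#'   (data.frame: `node_a`, `node_b` as grid voxel indices with
#'   `node_a < node_b`, `R`, `Tp`, `sign`), `threshold_Tp`, `K`, `alpha`,
#'   `n_nodes`, `node_voxels`, `grid`.
#' @export
build_network <- function(vs, alpha = 0.05) {
  stopifnot(inherits(vs, "virtual_sensor_set"))
  R <- pairwise_correlation(vs)
  K <- attr(R, "K")
  kept_nodes <- setdiff(seq_along(vs$node_voxels), attr(R, "excluded"))
  voxels <- vs$node_voxels[kept_nodes]
  tcrit <- tp_critical(K, alpha)
  n <- nrow(R)
  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]
  tp <- tp_threshold(r, K)
  keep <- abs(tp) >= tcrit
  edges <- data.frame(
    node_a = voxels[ut[keep, 1L]],
    node_b = voxels[ut[keep, 2L]],
    R = r[keep],
    Tp = tp[keep],
    sign = ifelse(r[keep] >= 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  swap <- edges$node_a > edges$node_b
  if (any(swap)) edges[swap, c("node_a", "node_b")] <- edges[swap, c("node_b", "node_a")]
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, threshold_Tp = tcrit, K = K, alpha = alpha,
                 n_nodes = n, node_voxels = voxels, grid = vs$grid),
            class = "connectivity_network")
}

#' @export
print.connectivity_network <- function(x, ...) {
  cat(sprintf(
    "<connectivity_network> %d nodes, %d edges (%d+/%d-), |Tp| >= %.3f (alpha %g, K %d)\n",
    x$n_nodes, nrow(x$edges), sum(x$edges$sign == "positive"),
    sum(x$edges$sign == "negative"), x$threshold_Tp, x$alpha, x$K))
  invisible(x)
}

#' Summarize a network around a region of interest
#'
#' Counts edges internal to the frontal territory (labels FC, MFC, LFL)
#' and edges crossing the anterior/posterior boundary (the y = 0 plane of
#' the head frame), split by connection sign.
#'
#' @param network A [build_network()] result.
#' @param atlas A [region_atlas()] covering the grid.
#' @param roi ROI label recorded with the summary (default `"MFC"`).
#' @return Object of class `roi_network_summary`: list with `roi_label`,
#'   `n_edges`, `n_local_frontal_edges`, `n_anterior_posterior_edges`,
#'   `n_positive`, `n_negative`.
#' @export
summarize_roi <- function(network, atlas, roi = "MFC") {
  stopifnot(inherits(network, "connectivity_network"))
  if (!roi %in% atlas_labels(atlas))
    stop_config("unknown ROI label '%s'", roi)
  grid <- network$grid
  labels <- assign_regions(grid, atlas)
  e <- network$edges
  frontal <- c("FC", "MFC", "LFL")
  lab_a <- labels[e$node_a]
  lab_b <- labels[e$node_b]
  y_a <- grid$voxels[e$node_a, 2L]
  y_b <- grid$voxels[e$node_b, 2L]
  local_frontal <- lab_a %in% frontal & lab_b %in% frontal
  ant_post <- (y_a > 0 & y_b < 0) | (y_a < 0 & y_b > 0)
  structure(list(roi_label = roi,
                 n_edges = nrow(e),
                 n_local_frontal_edges = sum(local_frontal),
                 n_anterior_posterior_edges = sum(ant_post),
                 n_positive = sum(e$sign == "positive"),
                 n_negative = sum(e$sign == "negative")),
            class = "roi_network_summary")
}

#' @export
print.roi_network_summary <- function(x, ...) {
  cat(sprintf(
    "<roi_network_summary> ROI %s: %d edges (%d+/%d-), %d local frontal, %d anterior-posterior\n",
    x$roi_label, x$n_edges, x$n_positive, x$n_negative,
    x$n_local_frontal_edges, x$n_anterior_posterior_edges))
  invisible(x)
}

#' Export a network as an edge-list TSV (and optionally GraphML)
#'
#' The TSV has columns `node_a`, `node_b`, `R`, `Tp`, `sign`, `region_a`,
#' `region_b`. When the igraph package is available and `graphml_path` is
#' given, the same network is also written as GraphML.
#'
#' @param network A [build_network()] result.
#' @param atlas A [region_atlas()] for the region columns.
#' @param path TSV output path.
#' @param graphml_path Optional GraphML output path (requires igraph).
#' @return `path`, invisibly.
#' @export
export_network <- function(network, atlas, path, graphml_path = NULL) {
  labels <- assign_regions(network$grid, atlas)
  e <- network$edges
  df <- cbind(e, region_a = labels[e$node_a], region_b = labels[e$node_b])
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(graphml_path)) {
    if (!requireNamespace("igraph", quietly = TRUE))
      stop_config("GraphML export requires the igraph package")
    g <- igraph::graph_from_data_frame(
      df[, c("node_a", "node_b", "R", "Tp", "sign")], directed = FALSE)
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  invisible(path)
}
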