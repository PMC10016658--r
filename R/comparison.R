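# Three-level group comparison: global metrics, nodal metrics within
# the anxiety circuit plus the vermis control region (left/right
# hemispheres averaged), and region-level connection strengths.

#' Average nodal metrics over left/right hemispheres
#'
#' Collapses node-level metric values to region level: bilateral
#' regions get the arithmetic mean of their L and R nodal values,
#' midline regions pass through unchanged. When one hemisphere is
#' missing (disconnected node), the available side is used.
#'
#' @param nodal long data.frame with columns `subject_id`, `group`,
#'   `density`, `metric`, `node`, `value` (the `level == "node"` rows of
#'   [cohort_metrics()] output).
#' @param atlas an `fc_atlas`.
#' @return data.frame with `subject_id`, `group`, `density`, `metric`,
#'   `region`, `value`.
#' @export
nodal_lr_average <- function(nodal, atlas) {
  stopifnot(all(c("subject_id", "node", "metric", "value") %in% colnames(nodal)))
  map <- atlas$regions$region
  names(map) <- atlas$regions$node
  unknown <- setdiff(unique(nodal$node), names(map))
  if (length(unknown) > 0) {
    stop("unknown nodes: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  nodal$region <- unname(map[nodal$node])
  agg <- stats::aggregate(
    value ~ subject_id + group + density + metric + region,
    data = nodal, FUN = function(v) mean(v, na.rm = TRUE),
    na.action = stats::na.pass)
  agg$value[!is.finite(agg$value)] <- NA_real_
  agg
}

#' Region-level connection strength of one subject
#'
#' Averages the z values over all node pairs spanning two regions
#' (bilateral x bilateral: 4 pairs; bilateral x midline: 2; midline x
#' midline: 1; `region_a == region_b` requests the homotopic L-R pair of
#' one bilateral region) at each density, then over the density grid.
#' Sub-threshold connections contribute genuine zeros: a z of zero
#' means the correlation fell below threshold at that density.
#'
#' @param conn an `fc_connectivity` for one subject.
#' @param atlas an `fc_atlas`.
#' @param region_a,region_b region names.
#' @return Single numeric density-averaged z value.
#' @export
edge_region_average <- function(conn, atlas, region_a, region_b) {
  stopifnot(inherits(conn, "fc_connectivity"))
  np <- region_pair_nodes(atlas, region_a, region_b)
  per_density <- vapply(conn$z_networks,
                        function(w) mean(w[np]), numeric(1))
  mean(per_density)
}

#' Connection-strength table for a cohort
#'
#' Density-averaged region-level z values for every requested region
#' pair and subject. By default all 10 unordered pairs among the five
#' anxiety-circuit regions are tested; homotopic pairs of the bilateral
#' circuit regions can be added.
#'
#' @param subjects list of subject records (`subject_id`, `group`,
#'   `data`).
#' @param atlas an `fc_atlas`.
#' @param grid a [density_grid()].
#' @param pairs optional two-column character matrix/data.frame of
#'   region pairs; default the circuit pairs.
#' @param include_homotopic add the L-R pair of each bilateral circuit
#'   region.
#' @return data.frame with `subject_id`, `group`, `region_a`,
#'   `region_b`, `z`.
#' @export
edge_value_table <- function(subjects, atlas, grid = density_grid(),
                             pairs = NULL, include_homotopic = FALSE) {
  if (is.null(pairs)) {
    circ <- atlas$circuit_regions
    pairs <- t(utils::combn(circ, 2))
    if (include_homotopic) {
      bilat <- circ[vapply(circ, function(r)
        length(atlas_nodes(atlas, r)) == 2L, logical(1))]
      pairs <- rbind(pairs, cbind(bilat, bilat))
    }
  }
  pairs <- as.matrix(pairs)
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    s <- subjects[[si]]
    conn <- build_connectivity(s$data, grid, subject_id = s$subject_id)
    z <- vapply(seq_len(nrow(pairs)), function(k)
      edge_region_average(conn, atlas, pairs[k, 1], pairs[k, 2]), numeric(1))
    out[[si]] <- data.frame(subject_id = s$subject_id, group = s$group,
                            region_a = pairs[, 1], region_b = pairs[, 2],
                            z = z, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

compare_one <- function(x_control, x_patient, mode, seed = NULL,
                        n_resamples = 1e5) {
  x_control <- x_control[!is.na(x_control)]
  x_patient <- x_patient[!is.na(x_patient)]
  mw <- mann_whitney_u(x_patient, x_control, mode = mode, seed = seed,
                       n_resamples = n_resamples)
  list(u = mw$u, p = mw$p,
       direction = sign(stats::median(x_patient) - stats::median(x_control)),
       median_control = stats::median(x_control),
       median_patient = stats::median(x_patient),
       iqr_control = stats::IQR(x_control),
       iqr_patient = stats::IQR(x_patient))
}

comparison_rows <- function(level, targets, values_c, values_p, mode, seed,
                            n_resamples = 1e5) {
  rows <- vector("list", length(targets))
  for (k in seq_along(targets)) {
    cmp <- compare_one(values_c[[k]], values_p[[k]], mode,
                       seed = if (is.null(seed)) NULL else seed + k,
                       n_resamples = n_resamples)
    rows[[k]] <- data.frame(
      level = level, target = targets[k], u = cmp$u, p_raw = cmp$p,
      p_fdr = NA_real_, direction = cmp$direction,
      median_control = cmp$median_control, median_patient = cmp$median_patient,
      iqr_control = cmp$iqr_control, iqr_patient = cmp$iqr_patient,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Three-level group comparison
#'
#' Mann-Whitney U tests with Benjamini-Hochberg FDR correction at three
#' levels: (1) global — the density-averaged global metrics, FDR across
#' metrics; (2) nodal — the five anxiety-circuit regions plus the
#' vermis control region, five metrics each (L/R-averaged), FDR within
#' each metric across the six regions; (3) connection — region-level z
#' strengths, FDR across the tested connections.
#'
#' @param metrics long metric table from [cohort_metrics()].
#' @param edges connection-strength table from [edge_value_table()],
#'   or NULL to skip the connection level.
#' @param atlas an `fc_atlas`.
#' @param mode Mann-Whitney mode (see [mann_whitney_u()]).
#' @param seed optional seed (used only when ties force a permutation
#'   null).
#' @param n_resamples permutation resamples when ties force a
#'   resampling null.
#' @return data.frame of class `fc_comparison` with one row per test:
#'   `level`, `target`, `u`, `p_raw`, `p_fdr`, `direction` (sign of
#'   patient median minus control median), group medians and IQRs.
#' @export
run_three_level_comparison <- function(metrics, edges, atlas,
                                       mode = "auto", seed = NULL,
                                       n_resamples = 1e5) {
  stopifnot(all(c("subject_id", "group", "density", "level", "metric",
                  "value") %in% colnames(metrics)))
  groups <- unique(metrics[, c("subject_id", "group")])
  if (length(unique(groups$group)) != 2) {
    stop("need both a control and a patient group", call. = FALSE)
  }
  out <- list()

  # (1) global level: FDR family across the density-averaged metrics
  gl <- metrics[metrics$level == "global" & metrics$density == "avg", ]
  g_metrics <- intersect(metric_names_global, unique(gl$metric))
  g_metrics <- g_metrics[vapply(g_metrics, function(m)
    !anyNA(gl$value[gl$metric == m]), logical(1))]
  if (length(g_metrics) > 0) {
    vc <- lapply(g_metrics, function(m)
      gl$value[gl$metric == m & gl$group == "control"])
    vp <- lapply(g_metrics, function(m)
      gl$value[gl$metric == m & gl$group == "patient"])
    g_rows <- comparison_rows("global", g_metrics, vc, vp, mode, seed,
                              n_resamples)
    g_rows$p_fdr <- fdr_adjust(g_rows$p_raw)
    out$global <- g_rows
  }

  # (2) nodal level: circuit + control region; FDR within each metric
  nd <- metrics[metrics$level == "node" & metrics$density == "avg", ]
  if (nrow(nd) > 0) {
    reg <- nodal_lr_average(nd, atlas)
    test_regions <- c(atlas$circuit_regions, atlas$control_region)
    reg <- reg[reg$region %in% test_regions, ]
    n_rows <- list()
    for (m in intersect(metric_names_nodal, unique(reg$metric))) {
      sub <- reg[reg$metric == m, ]
      regions_here <- intersect(test_regions, unique(sub$region))
      vc <- lapply(regions_here, function(r)
        sub$value[sub$region == r & sub$group == "control"])
      vp <- lapply(regions_here, function(r)
        sub$value[sub$region == r & sub$group == "patient"])
      rows <- comparison_rows("nodal", paste(regions_here, m, sep = " | "),
                              vc, vp, mode, seed, n_resamples)
      rows$p_fdr <- fdr_adjust(rows$p_raw)
      n_rows[[m]] <- rows
    }
    out$nodal <- do.call(rbind, n_rows)
  }

  # (3) connection level: FDR across the tested region pairs
  if (!is.null(edges) && nrow(edges) > 0) {
    edges$pair <- paste(edges$region_a, edges$region_b, sep = " - ")
    pairs <- unique(edges$pair)
    vc <- lapply(pairs, function(p)
      edges$z[edges$pair == p & edges$group == "control"])
    vp <- lapply(pairs, function(p)
      edges$z[edges$pair == p & edges$group == "patient"])
    e_rows <- comparison_rows("edge", pairs, vc, vp, mode, seed,
                              n_resamples)
    e_rows$p_fdr <- fdr_adjust(e_rows$p_raw)
    out$edge <- e_rows
  }

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("fc_comparison", "data.frame")
  res
}
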