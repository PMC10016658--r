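# Brain-behaviour correlations: Spearman rank correlation between
# network features and the 13 C-BARQ behaviour scales across patients,
# with BH-FDR applied within the connection-strength family (matching
# the analysis convention) and pairwise deletion of missing scores.

#' Patient network-feature table
#'
#' Assembles the features entered into the behaviour-correlation stage:
#' the density-averaged global metrics, the L/R-averaged nodal degree,
#' global efficiency and clustering coefficient of the anxiety-circuit
#' regions, and the region-level connection strengths.
#'
#' @param metrics long metric table from [cohort_metrics()] (patients
#'   are selected internally).
#' @param edges connection-strength table from [edge_value_table()]
#'   (may include homotopic pairs); NULL to omit the strength family.
#' @param atlas an `fc_atlas`.
#' @return data.frame with `subject_id`, `family` (`"global"`,
#'   `"nodal"`, `"strength"`), `feature`, `value`.
#' @export
patient_feature_table <- function(metrics, edges, atlas) {
  pats <- metrics[metrics$group == "patient", ]
  out <- list()
  gl <- pats[pats$level == "global" & pats$density == "avg", ]
  gl <- gl[!is.na(gl$value), ]
  if (nrow(gl) > 0) {
    out$global <- data.frame(subject_id = gl$subject_id, family = "global",
                             feature = paste0("global:", gl$metric),
                             value = gl$value, stringsAsFactors = FALSE)
  }
  nd <- pats[pats$level == "node" & pats$density == "avg", ]
  nd <- nd[nd$metric %in% c("degree", "eglob", "cp"), ]
  if (nrow(nd) > 0) {
    reg <- nodal_lr_average(nd, atlas)
    reg <- reg[reg$region %in% atlas$circuit_regions, ]
    out$nodal <- data.frame(subject_id = reg$subject_id, family = "nodal",
                            feature = paste0(reg$metric, ":", reg$region),
                            value = reg$value, stringsAsFactors = FALSE)
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    ep <- edges[edges$group == "patient", ]
    out$strength <- data.frame(
      subject_id = ep$subject_id, family = "strength",
      feature = paste0("strength:", ep$region_a, "-", ep$region_b),
      value = ep$z, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Correlate network features with behaviour scores
#'
#' Spearman rank correlation of every feature against every behaviour
#' scale across patients. Missing scores (ND) are dropped pairwise and
#' the usable sample size recorded; results with fewer than `min_n`
#' usable pairs are marked not-computed. BH-FDR is applied within the
#' connection-strength family only (`fdr_scope = "strength"`, the
#' default) or across every test (`fdr_scope = "all"`).
#'
#' @param features feature table from [patient_feature_table()].
#' @param behavior behaviour table with `subject_id` and the
#'   [cbarq_scales] columns.
#' @param fdr_scope `"strength"` or `"all"`.
#' @param min_n minimum usable pairs per correlation (default 5).
#' @return data.frame of class `fc_correlation`: `family`, `feature`,
#'   `scale`, `rho`, `p_raw`, `p_fdr` (NA outside the corrected
#'   family), `n_used`, `computed`.
#' @export
correlate_features <- function(features, behavior,
                               fdr_scope = c("strength", "all"),
                               min_n = 5) {
  fdr_scope <- match.arg(fdr_scope)
  scales <- intersect(cbarq_scales, colnames(behavior))
  if (length(scales) == 0) stop("behavior table has no known scale columns",
                                call. = FALSE)
  ids <- unique(features$subject_id)
  missing_ids <- setdiff(ids, behavior$subject_id)
  if (length(missing_ids) > 0) {
    stop("subjects without behaviour scores: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  feats <- unique(features[, c("family", "feature")])
  rows <- vector("list", nrow(feats) * length(scales))
  k <- 0L
  for (f in seq_len(nrow(feats))) {
    sub <- features[features$feature == feats$feature[f], ]
    fv <- sub$value[match(ids, sub$subject_id)]
    for (sc in scales) {
      bv <- behavior[[sc]][match(ids, behavior$subject_id)]
      sp <- spearman_rho(fv, bv, min_n = min_n)
      k <- k + 1L
      rows[[k]] <- data.frame(
        family = feats$family[f], feature = feats$feature[f], scale = sc,
        rho = sp$rho, p_raw = sp$p, p_fdr = NA_real_, n_used = sp$n_used,
        computed = sp$computed, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  in_family <- if (fdr_scope == "strength") res$family == "strength"
               else rep(TRUE, nrow(res))
  adj_idx <- which(in_family & res$computed)
  if (length(adj_idx) > 0) {
    res$p_fdr[adj_idx] <- fdr_adjust(res$p_raw[adj_idx])
  }
  rownames(res) <- NULL
  class(res) <- c("fc_correlation", "data.frame")
  res
}
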