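# Synthetic cohorts: band-limited multi-region time series drawn from
# group-specific target correlation matrices, plus behaviour-scale
# scores monotonically linked to chosen network features. The defaults
# reproduce the study conditions: 25 controls vs 13 patients, 30
# regions, TR = 2 s signals band-limited to 0.01-0.1 Hz, patient
# hyperconnectivity on six anxiety-circuit edges and one hypoconnected
# hippocampus-mesencephalon edge.

#' The 13 C-BARQ behaviour scale names
#'
#' Column names used by every behaviour table in the package. For
#' trainability a higher score means better trainability; for all other
#' scales a higher score means a worse behaviour problem (carried as
#' metadata, never numerically flipped).
#' @export
cbarq_scales <- c(
  "trainability", "stranger_directed_aggression",
  "owner_directed_aggression", "dog_directed_aggression",
  "familiar_dog_aggression", "chasing", "stranger_directed_fear",
  "nonsocial_fear", "separation_related_problems", "touch_sensitivity",
  "excitability", "attachment_attention_seeking", "energy"
)

#' Implanted anxiety-circuit group differences
#'
#' The connectivity contrast implanted in patient cohorts: six
#' hyperconnected circuit edges (amygdala-hippocampus,
#' amygdala-mesencephalon, amygdala-thalamus, frontal lobe-hippocampus,
#' frontal lobe-thalamus, hippocampus-thalamus) and one hypoconnected
#' edge (hippocampus-mesencephalon).
#'
#' @param delta correlation-scale effect size applied (+ for the six
#'   hyper edges, - for the hypo edge).
#' @return data.frame with columns `region_a`, `region_b`, `delta_r`.
#' @export
anxiety_circuit_effects <- function(delta = 0.25) {
  data.frame(
    region_a = c("amygdala", "amygdala", "amygdala", "frontal lobe",
                 "frontal lobe", "hippocampus", "hippocampus"),
    region_b = c("hippocampus", "mesencephalon", "thalamus", "hippocampus",
                 "thalamus", "thalamus", "mesencephalon"),
    delta_r = c(rep(delta, 6), -delta),
    stringsAsFactors = FALSE
  )
}

#' Default behaviour-score links
#'
#' Ties a few C-BARQ scales monotonically to network features, echoing
#' the qualitative pattern seen in anxious dogs (amygdala connectivity
#' vs stranger-directed fear and excitability, hippocampal degree vs
#' touch sensitivity, amygdala-thalamus strength vs attachment).
#'
#' @return data.frame with columns `scale`, `feature`, `rho` (target
#'   Spearman correlation).
#' @export
default_behavior_links <- function() {
  data.frame(
    scale = c("stranger_directed_fear", "excitability",
              "touch_sensitivity", "attachment_attention_seeking"),
    feature = c("degree:amygdala", "degree:amygdala",
                "degree:hippocampus", "strength:amygdala-thalamus"),
    rho = c(0.6, -0.6, 0.8, 0.9),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_control,n_patient group sizes (defaults 25 and 13).
#' @param n_roi number of atlas regions (30).
#' @param n_timepoints fMRI volumes per subject (default 180; the scan
#'   duration is a free parameter of the emulation).
#' @param tr_seconds repetition time in seconds (2.0).
#' @param passband frequency band retained, in Hz (0.01-0.1).
#' @param base_connectivity baseline off-diagonal correlation in [0, 1).
#' @param effect_edges data.frame (`region_a`, `region_b`, `delta_r`) of
#'   implanted patient-vs-control correlation differences; default
#'   [anxiety_circuit_effects()].
#' @param behavior_links data.frame (`scale`, `feature`, `rho`) linking
#'   behaviour scales to network features; default
#'   [default_behavior_links()].
#' @param noise_sd sd of additive white measurement noise mixed into
#'   each channel before filtering (0 = none; attenuates correlations by
#'   `1/(1 + noise_sd^2)`).
#' @param seed integer seed; the full generation is deterministic in it.
#' @return Validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 25, n_patient = 13, n_roi = 30,
                          n_timepoints = 180, tr_seconds = 2.0,
                          passband = c(0.01, 0.1),
                          base_connectivity = 0.3,
                          effect_edges = anxiety_circuit_effects(),
                          behavior_links = default_behavior_links(),
                          noise_sd = 0, seed = 1) {
  if (n_control < 2 || n_patient < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  if (n_timepoints <= n_roi) {
    stop("n_timepoints must exceed n_roi", call. = FALSE)
  }
  if (base_connectivity < 0 || base_connectivity >= 1) {
    stop("base_connectivity must lie in [0, 1)", call. = FALSE)
  }
  if (length(passband) != 2 || passband[1] <= 0 ||
      passband[2] <= passband[1] ||
      passband[2] > 1 / (2 * tr_seconds)) {
    stop("passband must be 0 < low < high <= Nyquist", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (nrow(effect_edges) > 0 &&
      any(abs(base_connectivity + effect_edges$delta_r) >= 1)) {
    stop("|base_connectivity + delta_r| must stay below 1", call. = FALSE)
  }
  structure(
    list(n_control = n_control, n_patient = n_patient, n_roi = n_roi,
         n_timepoints = n_timepoints, tr_seconds = tr_seconds,
         passband = passband, base_connectivity = base_connectivity,
         effect_edges = effect_edges, behavior_links = behavior_links,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# project onto the nearest correlation matrix (Higham alternating
# projections via Matrix::nearPD) when the target is not positive
# definite; no-op otherwise
repair_psd <- function(s, floor_ev = 1e-7) {
  ev <- eigen(s, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= floor_ev) return(s)
  s2 <- as.matrix(Matrix::nearPD(s, corr = TRUE, maxit = 200,
                                 eig.tol = 1e-8, posd.tol = 1e-6)$mat)
  (s2 + t(s2)) / 2
}

# session cache for repaired target matrices (the nearest-correlation
# projection is iterative and identical across generator calls)
.target_cache <- new.env(parent = emptyenv())

# group-level target correlation matrix: compound-symmetric baseline
# plus implanted region-level edge deltas (patients only)
target_correlation <- function(config, atlas, group) {
  key <- paste(config$n_roi, config$base_connectivity, group,
               paste(unlist(config$effect_edges), collapse = "|"),
               sep = "@")
  cached <- .target_cache[[key]]
  if (!is.null(cached)) return(cached)
  R <- config$n_roi
  s <- matrix(config$base_connectivity, R, R)
  diag(s) <- 1
  edges <- config$effect_edges
  if (group == "patient" && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      np <- region_pair_nodes(atlas, edges$region_a[k], edges$region_b[k])
      for (r in seq_len(nrow(np))) {
        i <- np[r, 1]; j <- np[r, 2]
        s[i, j] <- s[j, i] <- s[i, j] + edges$delta_r[k]
      }
    }
  }
  s2 <- repair_psd(s)
  if (group == "patient" && nrow(edges) > 0) {
    bad <- character(0)
    for (k in seq_len(nrow(edges))) {
      np <- region_pair_nodes(atlas, edges$region_a[k], edges$region_b[k])
      dev <- max(abs(s2[np] - s[np]))
      if (dev > 0.05) {
        bad <- c(bad, paste(edges$region_a[k], edges$region_b[k], sep = "-"))
      }
    }
    if (length(bad) > 0) {
      stop("target covariance not positive semi-definite; repair distorted ",
           "edges beyond tolerance: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  .target_cache[[key]] <- s2
  s2
}

#' Zero-phase band-pass filter (frequency domain)
#'
#' Ideal (brick-wall) band-pass: FFT per column, zero every bin whose
#' frequency falls outside the passband, inverse FFT. Exactly
#' zero-phase and exactly band-limited.
#'
#' @param x numeric T x R matrix.
#' @param tr_seconds sampling interval (s).
#' @param passband `c(low, high)` in Hz.
#' @return Filtered matrix of the same dimensions.
#' @export
band_limit <- function(x, tr_seconds, passband) {
  x <- as.matrix(x)
  T <- nrow(x)
  bins <- 0:(T - 1)
  freq <- pmin(bins, T - bins) / (T * tr_seconds)
  keep <- freq >= passband[1] & freq <= passband[2]
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / T
}

generate_subject_ts <- function(config, sigma_chol, atlas) {
  T <- config$n_timepoints
  R <- config$n_roi
  x <- matrix(stats::rnorm(T * R), T, R) %*% sigma_chol
  if (config$noise_sd > 0) {
    x <- x + matrix(stats::rnorm(T * R, sd = config$noise_sd), T, R)
  }
  x <- band_limit(x, config$tr_seconds, config$passband)
  x <- scale(x)
  attr(x, "scaled:center") <- NULL
  attr(x, "scaled:scale") <- NULL
  colnames(x) <- atlas_node_names(atlas)[seq_len(R)]
  x
}

# density-averaged network feature of one subject's connectivity.
# Feature strings: "degree:<region>", "eglob:<region>", "cp:<region>",
# "strength:<regionA>-<regionB>" (region-level z strength, homotopic
# when A == B), "global:<metric>".
network_feature_value <- function(conn, atlas, feature) {
  parts <- strsplit(feature, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2) stop("malformed feature: '", feature, "'",
                               call. = FALSE)
  kind <- parts[1]; arg <- parts[2]
  if (kind == "strength") {
    regs <- strsplit(arg, "-", fixed = TRUE)[[1]]
    if (length(regs) != 2) stop("malformed strength feature: '", feature, "'",
                                call. = FALSE)
    return(edge_region_average(conn, atlas, regs[1], regs[2]))
  }
  if (kind == "degree") {
    nodes <- atlas_nodes(atlas, arg)
    per_density <- vapply(conn$z_networks,
                          function(w) mean(rowSums(w)[nodes]), numeric(1))
    return(mean(per_density))
  }
  if (kind %in% c("eglob", "cp")) {
    nodes <- atlas_nodes(atlas, arg)
    per_density <- vapply(conn$z_networks, function(w) {
      if (kind == "eglob") mean(global_efficiency(w)$nodal[nodes])
      else mean(clustering_onnela(w)$nodal[nodes])
    }, numeric(1))
    return(mean(per_density))
  }
  if (kind == "global") {
    per_density <- vapply(conn$z_networks, function(w) {
      m <- network_metrics(w)
      unname(m$global[arg])
    }, numeric(1))
    return(mean(per_density))
  }
  stop("unknown feature kind: '", kind, "'", call. = FALSE)
}

# behaviour scores: a rank-preserving (Gaussian-copula) transform of
# the patient's network feature plus latent Gaussian noise, mapped
# monotonically into [0, 5]. The latent Pearson correlation
# r = 2 sin(pi * rho_s / 6) yields population Spearman rho_s.
generate_behavior <- function(config, atlas, patients) {
  n <- length(patients)
  ids <- vapply(patients, function(s) s$subject_id, character(1))
  scores <- matrix(NA_real_, n, length(cbarq_scales),
                   dimnames = list(ids, cbarq_scales))
  links <- config$behavior_links
  linked <- if (nrow(links) > 0) links$scale else character(0)
  feat_cache <- list()
  grid <- density_grid()
  for (k in seq_len(NROW(links))) {
    f <- links$feature[k]
    if (is.null(feat_cache[[f]])) {
      vals <- vapply(patients, function(s) {
        conn <- build_connectivity(s$data, grid, subject_id = s$subject_id)
        network_feature_value(conn, atlas, f)
      }, numeric(1))
      feat_cache[[f]] <- vals
    }
    zf <- stats::qnorm((rank(feat_cache[[f]]) - 0.375) / (n + 0.25))
    zf <- as.numeric(scale(zf))
    r <- 2 * sin(pi * links$rho[k] / 6)
    latent <- r * zf + sqrt(1 - r^2) * stats::rnorm(n)
    scores[, links$scale[k]] <- round(5 * stats::pnorm(latent), 2)
  }
  for (sc in setdiff(cbarq_scales, linked)) {
    scores[, sc] <- round(5 * stats::pnorm(stats::rnorm(n)), 2)
  }
  data.frame(subject_id = ids, scores, stringsAsFactors = FALSE,
             row.names = NULL, check.names = FALSE)
}

#' Generate a synthetic cohort
#'
#' Draws every subject's T x R time-series matrix from the group's
#' target correlation matrix (multivariate Gaussian, Cholesky), applies
#' zero-phase band-pass filtering, re-standardises each column, and
#' generates patient behaviour scores monotonically linked to the
#' configured network features. Fully deterministic given
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @param atlas an `fc_atlas` (default [canine_atlas()]).
#' @return List of class `fc_cohort`: `subjects` (list of records with
#'   `subject_id`, `group`, `data`), `behavior` (patient behaviour
#'   table), `config`, `atlas`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(cohort_config(seed = 7))
#' length(coh$subjects)  # 38
#' }
#' @export
generate_cohort <- function(config, atlas = canine_atlas()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_roi != nrow(atlas$regions)) {
    stop("n_roi must match the atlas size (", nrow(atlas$regions), ")",
         call. = FALSE)
  }
  sig_c <- target_correlation(config, atlas, "control")
  sig_p <- target_correlation(config, atlas, "patient")
  chol_c <- chol(repair_psd(sig_c, 1e-8))
  chol_p <- chol(repair_psd(sig_p, 1e-8))
  subjects <- vector("list", config$n_control + config$n_patient)
  with_seed(config$seed, {
    for (i in seq_len(config$n_control)) {
      subjects[[i]] <- list(
        subject_id = sprintf("ctrl%02d", i), group = "control",
        data = generate_subject_ts(config, chol_c, atlas))
    }
    for (i in seq_len(config$n_patient)) {
      subjects[[config$n_control + i]] <- list(
        subject_id = sprintf("pat%02d", i), group = "patient",
        data = generate_subject_ts(config, chol_p, atlas))
    }
  })
  patients <- subjects[vapply(subjects, function(s) s$group, character(1)) ==
                         "patient"]
  behavior <- with_seed(config$seed + 500000L,
                        generate_behavior(config, atlas, patients))
  structure(list(subjects = subjects, behavior = behavior,
                 config = config, atlas = atlas),
            class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$group, character(1))
  cat("Synthetic cohort:", sum(groups == "control"), "controls,",
      sum(groups == "patient"), "patients;",
      nrow(x$subjects[[1]]$data), "time points x",
      ncol(x$subjects[[1]]$data), "regions\n")
  invisible(x)
}

#' C-BARQ scores of the 13 anxiety patients
#'
#' The published behaviour-scale scores of the 13 patient dogs, verbatim,
#' with not-detectable (ND) entries encoded as NA. Familiar dog
#' aggression has 8 usable values.
#'
#' @return data.frame with `subject_id`, `age_months`, `breed`, `sex`
#'   and the 13 scale columns of [cbarq_scales].
#' @export
cbarq_patient_scores <- function() {
  path <- system.file("extdata", "cbarq_patients.csv", package = "caninefc",
                      mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                       na.strings = "ND")
  for (sc in cbarq_scales) d[[sc]] <- as.numeric(d[[sc]])
  d
}

#' Write a cohort to disk
#'
#' One tab-separated time-series file per subject (header = atlas node
#' names), a cohort manifest CSV (`subject_id`, `group`, `file`) and a
#' behaviour CSV.
#'
#' @param cohort an `fc_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data.frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "fc_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    files[i] <- paste0(s$subject_id, ".tsv")
    utils::write.table(format(s$data, digits = 10, trim = TRUE),
                       file.path(dir, files[i]),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- data.frame(
    subject_id = vapply(cohort$subjects, function(s) s$subject_id, character(1)),
    group = vapply(cohort$subjects, function(s) s$group, character(1)),
    file = files, stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(cohort$behavior, file.path(dir, "behavior.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort from disk
#'
#' Reads the manifest, per-subject TSV files (headers are checked
#' against the atlas node names) and the behaviour CSV written by
#' [write_cohort()].
#'
#' @param dir directory containing `manifest.csv`, subject TSVs and
#'   optionally `behavior.csv`.
#' @param atlas an `fc_atlas` used for header validation.
#' @return An `fc_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir, atlas = canine_atlas()) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  expected <- atlas_node_names(atlas)
  subjects <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    d <- utils::read.delim(file.path(dir, manifest$file[i]),
                           check.names = FALSE)
    if (!identical(colnames(d), expected)) {
      bad <- setdiff(colnames(d), expected)
      stop("time-series header of ", manifest$file[i],
           " does not match the atlas; unexpected columns: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    subjects[[i]] <- list(subject_id = manifest$subject_id[i],
                          group = manifest$group[i],
                          data = as.matrix(d))
  }
  beh_path <- file.path(dir, "behavior.csv")
  behavior <- if (file.exists(beh_path)) {
    utils::read.csv(beh_path, check.names = FALSE, na.strings = c("ND", "NA"),
                    stringsAsFactors = FALSE)
  } else NULL
  structure(list(subjects = subjects, behavior = behavior,
                 config = NULL, atlas = atlas),
            class = "fc_cohort")
}
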