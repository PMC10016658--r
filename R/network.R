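#' Density grid for network thresholding
#'
#' The analysis thresholds each correlation matrix at a range of network
#' densities (proportion of retained edges out of the R(R-1)/2 possible
#' ones). The default grid runs from 20% to 50% in 5% steps.
#'
#' @param levels strictly increasing densities in (0, 1).
#' @return Numeric vector of densities (class `density_grid`).
#' @export
density_grid <- function(levels = seq(0.20, 0.50, by = 0.05)) {
  levels <- as.numeric(levels)
  if (length(levels) == 0 || any(!is.finite(levels)) ||
      any(levels <= 0) || any(levels >= 1)) {
    stop("density levels must lie in (0, 1)", call. = FALSE)
  }
  if (any(diff(levels) <= 0)) {
    stop("density levels must be strictly increasing", call. = FALSE)
  }
  structure(levels, class = "density_grid")
}

#' Pearson correlation matrix of a subject's ROI time series
#'
#' @param x numeric T x R matrix (rows = time points, columns = regions).
#'   Column names, when present, are preserved.
#' @return Symmetric R x R correlation matrix with unit diagonal.
#' @details Fails explicitly (naming the region) if any column has zero
#'   variance, since Pearson correlation is undefined there.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3)
#' r <- correlation_matrix(ts)
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 time points", call. = FALSE)
  if (anyNA(x)) stop("time series contains missing values", call. = FALSE)
  v <- apply(x, 2, stats::var)
  if (any(v == 0)) {
    bad <- colnames(x)[v == 0]
    if (is.null(bad)) bad <- which(v == 0)
    stop("zero-variance ROI time series: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(x)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# round half away from zero (k is always >= 0 here)
round_half_up <- function(x) floor(x + 0.5)

#' Threshold a correlation matrix at a target network density
#'
#' Keeps the `k = round(density * R(R-1)/2)` largest strictly positive
#' correlations (negative and sub-threshold correlations become zero, as
#' only positive weights enter the connectome) and zeroes the diagonal.
#' Ties at the cutoff are broken by lexicographic (row, column) order so
#' the result is deterministic. If fewer than `k` positive correlations
#' exist, all of them are kept and a warning is issued.
#'
#' @param r symmetric correlation matrix.
#' @param density target density in (0, 1).
#' @return Symmetric weighted adjacency on the correlation scale, zero
#'   diagonal, with attribute `n_edges` (number of retained edges).
#' @export
threshold_density <- function(r, density) {
  r <- as.matrix(r)
  R <- nrow(r)
  if (R != ncol(r) || max(abs(r - t(r))) > 1e-10) {
    stop("matrix must be square and symmetric", call. = FALSE)
  }
  if (length(density) != 1 || density <= 0 || density >= 1) {
    stop("density must be a single value in (0, 1)", call. = FALSE)
  }
  n_possible <- R * (R - 1) / 2
  k <- round_half_up(density * n_possible)
  ut <- which(upper.tri(r), arr.ind = TRUE)
  vals <- r[ut]
  pos <- which(vals > 0)
  if (length(pos) < k) {
    warning(sprintf(
      "only %d positive correlations available for %d requested edges (density %.2f)",
      length(pos), k, density), call. = FALSE)
    keep <- pos
  } else {
    ord <- pos[order(-vals[pos], ut[pos, 1], ut[pos, 2])]
    keep <- ord[seq_len(k)]
  }
  w <- matrix(0, R, R, dimnames = dimnames(r))
  if (length(keep) > 0) {
    w[ut[keep, , drop = FALSE]] <- vals[keep]
    w[ut[keep, c(2, 1), drop = FALSE]] <- vals[keep]
  }
  attr(w, "n_edges") <- length(keep)
  w
}

#' Fisher r-to-z transform of a thresholded adjacency
#'
#' Applies `atanh` to every nonzero weight (zeros stay zero, encoding
#' sub-threshold connections). Weights at or above 1 are clipped to
#' `1 - 1e-7` with a warning before transforming.
#'
#' @param w nonnegative weighted adjacency on the correlation scale.
#' @return Weighted adjacency on the z scale.
#' @export
fisher_z <- function(w) {
  w <- as.matrix(w)
  if (any(w[w != 0] >= 1)) {
    warning("correlation weights >= 1 clipped to 1 - 1e-7", call. = FALSE)
    w[w >= 1] <- 1 - 1e-7
  }
  nz <- w != 0
  w[nz] <- atanh(w[nz])
  w
}

#' Build a subject's family of density-thresholded z-scale networks
#'
#' Composes [correlation_matrix()], [threshold_density()] at each grid
#' level and [fisher_z()]. The raw (unthresholded) correlation matrix is
#' preserved because the connection-level group analysis averages z
#' values across densities.
#'
#' @param ts numeric T x R time-series matrix, or a subject list with
#'   elements `subject_id`, `group`, `data`.
#' @param grid a [density_grid()].
#' @param subject_id identifier stored with the result (taken from `ts`
#'   when it is a subject list).
#' @return Object of class `fc_connectivity`: list with `subject_id`,
#'   `r_matrix`, `z_networks` (named list, one z-scale adjacency per
#'   density level) and `edge_counts` (retained edges per level).
#' @export
build_connectivity <- function(ts, grid = density_grid(), subject_id = NULL) {
  if (is.list(ts) && !is.null(ts$data)) {
    if (is.null(subject_id)) subject_id <- ts$subject_id
    ts <- ts$data
  }
  r <- correlation_matrix(ts)
  z_networks <- list()
  edge_counts <- integer(length(grid))
  for (i in seq_along(grid)) {
    w <- threshold_density(r, grid[i])
    edge_counts[i] <- attr(w, "n_edges")
    z <- fisher_z(w)
    attr(z, "n_edges") <- NULL
    z_networks[[sprintf("%.2f", grid[i])]] <- z
  }
  names(edge_counts) <- names(z_networks)
  structure(
    list(subject_id = subject_id, r_matrix = r, z_networks = z_networks,
         densities = as.numeric(grid), edge_counts = edge_counts),
    class = "fc_connectivity"
  )
}

#' @export
print.fc_connectivity <- function(x, ...) {
  cat("Functional connectivity for subject",
      if (is.null(x$subject_id)) "<unnamed>" else x$subject_id, "\n")
  cat("  ", nrow(x$r_matrix), "nodes;",
      length(x$z_networks), "density levels:",
      paste(names(x$z_networks), collapse = " "), "\n")
  cat("  retained edges:", paste(x$edge_counts, collapse = " "), "\n")
  invisible(x)
}
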