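# Nonparametric statistics used by the group-comparison and
# behaviour-correlation stages. The U statistic is reported with the
# min(U1, U2) convention; exact p-values come from the tie-free
# Wilcoxon null distribution or, with ties, from a label permutation of
# the observed data.

#' Two-sided Mann-Whitney U test
#'
#' @param x,y numeric samples (n >= 2 each).
#' @param mode `"exact"` (tie-free null via the exact Wilcoxon
#'   distribution; with ties, a label permutation with `n_resamples`
#'   draws), `"approximate"` (normal approximation with tie-corrected
#'   variance and continuity correction) or `"auto"` (exact when
#'   `n1 + n2 <= 30` and tie-free, else approximate).
#' @param n_resamples permutation resamples used when ties force a
#'   resampling null (>= 1e5 by default).
#' @param seed optional seed for the permutation null.
#' @return List with `u` (min of the two U statistics), `p` (two-sided),
#'   `u1` (U of `x`) and `mode_used`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate"),
                           n_resamples = 1e5, seed = NULL) {
  mode <- match.arg(mode)
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA", call. = FALSE)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("both samples need at least 2 values", call. = FALSE)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u2 <- n1 * n2 - u1
  u <- min(u1, u2)
  ties <- anyDuplicated(pooled) > 0
  if (all(pooled == pooled[1])) {
    warning("all values identical in both samples; p = 1", call. = FALSE)
    return(list(u = u, p = 1, u1 = u1, mode_used = "degenerate"))
  }
  if (mode == "auto") {
    mode <- if (n1 + n2 <= 30 && !ties) "exact" else "approximate"
  }
  if (mode == "exact") {
    if (!ties) {
      p <- min(1, 2 * stats::pwilcox(u, n1, n2))
      mode_used <- "exact"
    } else {
      # permutation over the observed data, two-sided via |U1 - E[U1]|
      obs <- abs(u1 - n1 * n2 / 2)
      n_tot <- n1 + n2
      exceed <- with_seed(seed, {
        cnt <- 0L
        for (b in seq_len(n_resamples)) {
          idx <- sample.int(n_tot, n1)
          u1b <- sum(rk[idx]) - n1 * (n1 + 1) / 2
          if (abs(u1b - n1 * n2 / 2) >= obs - 1e-9) cnt <- cnt + 1L
        }
        cnt
      })
      p <- (exceed + 1) / (n_resamples + 1)
      mode_used <- "permutation"
    }
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(pooled)
    n <- n1 + n2
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
    z <- (abs(u1 - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    mode_used <- "approximate"
  }
  list(u = u, p = p, u1 = u1, mode_used = mode_used)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in the sorted order, capped at 1,
#' returned in the original order).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# rho for all permutations of rx against ry: enumeration used for the
# exact Spearman p at small n
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  for (pos in seq_len(n)) {
    rows <- (pos - 1) * nrow(sub) + seq_len(nrow(sub))
    out[rows, pos] <- n
    out[rows, -pos] <- sub
  }
  out
}

#' Spearman rank correlation with missing-data handling
#'
#' Pairs with a missing value in either variable are dropped
#' (pairwise deletion); the correlation is the Pearson correlation of
#' midranks. The two-sided p-value comes from the exact permutation
#' distribution when `n_used <= 9` and from the t approximation
#' otherwise. Results are marked not-computed when fewer than `min_n`
#' usable pairs remain or when either variable has zero rank variance.
#'
#' @param x,y numeric vectors of equal length; NA allowed.
#' @param min_n minimum usable pairs (default 5).
#' @return List with `rho`, `p`, `n_used`, `computed` (logical) and
#'   `reason` (NA or why the result is missing).
#' @export
spearman_rho <- function(x, y, min_n = 5) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n,
                computed = FALSE, reason = "too few usable pairs"))
  }
  rx <- rank(x[ok]); ry <- rank(y[ok])
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n_used = n,
                computed = FALSE, reason = "zero rank variance"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9) {
    perms <- all_perms(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rho_all <- as.vector(matrix(rxc[perms], nrow(perms)) %*% ryc) / denom
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = min(1, p), n_used = n, computed = TRUE,
       reason = NA_character_)
}
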