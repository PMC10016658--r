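# Independent brute-force oracles used to validate the package's graph
# metrics and statistics. These deliberately share no code with the
# implementation: distances come from exhaustive enumeration over all
# simple paths, the Mann-Whitney null from full enumeration of group
# labelings, and BH-FDR from the step-up formula applied directly.

# random symmetric weighted adjacency with approximately the requested
# edge density
random_graph <- function(n, density = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- matrix(0, n, n)
  ut <- which(upper.tri(w))
  on <- ut[stats::runif(length(ut)) < density]
  w[on] <- stats::runif(length(on), 0.1, 1)
  w + t(w)
}

# exhaustive shortest-path distances: minimum over all simple paths of
# the sum of 1/w along the path
oracle_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  best <- function(current, target, visited, len) {
    if (current == target) return(len)
    b <- Inf
    for (nxt in seq_len(n)) {
      if (!visited[nxt] && w[current, nxt] > 0) {
        visited[nxt] <- TRUE
        cand <- best(nxt, target, visited, len + 1 / w[current, nxt])
        visited[nxt] <- FALSE
        if (cand < b) b <- cand
      }
    }
    b
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      visited <- rep(FALSE, n)
      visited[i] <- TRUE
      d[i, j] <- d[j, i] <- best(i, j, visited, 0)
    }
  }
  d
}

oracle_lp <- function(w) {
  d <- oracle_distances(w)
  diag(d) <- NA
  vals <- d[is.finite(d)]
  mean(vals)
}

oracle_lp_nodal <- function(w) {
  d <- oracle_distances(w)
  diag(d) <- NA
  apply(d, 1, function(r) {
    v <- r[is.finite(r)]
    if (length(v) == 0) NA_real_ else mean(v)
  })
}

oracle_eglob_nodal <- function(w) {
  d <- oracle_distances(w)
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    inv <- 1 / d[i, -i]
    inv[!is.finite(inv)] <- 0
    sum(inv) / (n - 1)
  })
}

# Onnela weighted clustering by direct triple loop
oracle_onnela_nodal <- function(w) {
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(rep(0, n))
  wh <- w / mx
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    acc <- 0
    for (a in seq_len(k - 1)) {
      for (b in seq(a + 1, k)) {
        j <- nb[a]; h <- nb[b]
        acc <- acc + (wh[i, j] * wh[i, h] * wh[j, h])^(1 / 3)
      }
    }
    2 * acc / (k * (k - 1))
  })
}

oracle_eloc_nodal <- function(w) {
  n <- nrow(w)
  sapply(seq_len(n), function(i) {
    nb <- which(w[i, ] > 0)
    if (length(nb) < 2) return(0)
    mean(oracle_eglob_nodal(w[nb, nb, drop = FALSE]))
  })
}

# full-enumeration Mann-Whitney: two-sided p over all C(n1+n2, n1)
# labelings, statistic |U1 - n1 n2 / 2|
oracle_mwu <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)
  u1_of <- function(idx) sum(rk[idx]) - n1 * (n1 + 1) / 2
  obs <- abs(u1_of(seq_len(n1)) - n1 * n2 / 2)
  labelings <- utils::combn(n1 + n2, n1)
  stats <- apply(labelings, 2, function(idx) abs(u1_of(idx) - n1 * n2 / 2))
  u1 <- u1_of(seq_len(n1))
  list(u = min(u1, n1 * n2 - u1), p = mean(stats >= obs - 1e-9))
}

# Benjamini-Hochberg step-up from the definition:
# p_adj_(i) = min_{j >= i} ( m * p_(j) / j ), capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in seq(m, 1)) {
    running <- min(running, m * ps[i] / i)
    adj[i] <- min(1, running)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

oracle_spearman <- function(x, y) stats::cor(rank(x), rank(y))

# circuit + control-region node indices in the default atlas
circuit_test_nodes <- function(atlas = canine_atlas()) {
  regions <- c(atlas$circuit_regions, atlas$control_region)
  sort(unique(unlist(lapply(regions, atlas_nodes, atlas = atlas))))
}
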