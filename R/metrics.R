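# Weighted graph metrics on nonnegative symmetric adjacency matrices
# (zero diagonal). Edge lengths for path-based measures are 1/weight,
# the usual convention for correlation-derived connectomes, so stronger
# connections are shorter.

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_adjacency <- function(w) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("adjacency must be square", call. = FALSE)
  if (any(w < 0)) stop("adjacency weights must be nonnegative", call. = FALSE)
  if (any(diag(w) != 0)) stop("adjacency diagonal must be zero", call. = FALSE)
  w
}

#' Shortest-path distance matrix of a weighted network
#'
#' Distances are computed on edge lengths `1/weight` (Floyd-Warshall on
#' the dense length matrix); unreachable pairs are `Inf`, the diagonal 0.
#'
#' @param w nonnegative symmetric weighted adjacency, zero diagonal.
#' @return R x R distance matrix.
#' @examples
#' w <- matrix(0, 2, 2); w[1, 2] <- w[2, 1] <- 2
#' shortest_path_lengths(w)[1, 2]  # 0.5
#' @export
shortest_path_lengths <- function(w) {
  w <- check_adjacency(w)
  n <- nrow(w)
  d <- matrix(Inf, n, n, dimnames = dimnames(w))
  d[w > 0] <- 1 / w[w > 0]
  diag(d) <- 0
  .fw_dist(d)
}

#' Characteristic path length (global and nodal)
#'
#' Nodal `Lp_i` is the mean of the finite distances from node i to all
#' other nodes; the global value is the mean over all ordered finite
#' pairs. Unreachable pairs are excluded from the means (their count is
#' reported) rather than imputed, so low-density networks with isolated
#' nodes still yield finite path lengths.
#'
#' @param w weighted adjacency, or a precomputed distance matrix passed
#'   via `distances`.
#' @param distances optional distance matrix from
#'   [shortest_path_lengths()].
#' @return List with `global`, `nodal` (NA for nodes with no reachable
#'   partner) and `n_unreachable` (ordered pairs excluded).
#' @export
char_path_length <- function(w, distances = NULL) {
  d <- if (is.null(distances)) shortest_path_lengths(w) else distances
  n <- nrow(d)
  off <- d
  diag(off) <- NA
  finite <- is.finite(off)
  nodal <- rowSums(ifelse(finite, off, 0)) / rowSums(finite)
  nodal[rowSums(finite) == 0] <- NA_real_
  vals <- off[finite]
  list(global = if (length(vals)) mean(vals) else NA_real_,
       nodal = nodal,
       n_unreachable = sum(!finite, na.rm = TRUE) - sum(is.na(off) & !finite))
}

#' Global efficiency (global and nodal)
#'
#' Nodal `Eglob_i = mean_{j != i} 1/d(i,j)` with `1/Inf = 0`; the global
#' value is the mean over nodes. Robust to disconnected pairs, which
#' contribute zero.
#'
#' @inheritParams char_path_length
#' @return List with `global` and `nodal`.
#' @export
global_efficiency <- function(w, distances = NULL) {
  d <- if (is.null(distances)) shortest_path_lengths(w) else distances
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  nodal <- rowSums(inv) / (n - 1)
  list(global = mean(nodal), nodal = nodal)
}

#' Weighted clustering coefficient (Onnela variant)
#'
#' Weights are normalised by the maximum weight in the network, then
#' `Cp_i = 2 / (k_i (k_i - 1)) * sum_{j<h} (w_ij w_ih w_jh)^(1/3)` over
#' neighbour pairs, with `k_i` the binary degree; nodes with fewer than
#' two neighbours have `Cp_i = 0`. The global value is the mean over all
#' nodes.
#'
#' @param w nonnegative symmetric weighted adjacency, zero diagonal.
#' @return List with `global` and `nodal` (values in [0, 1]).
#' @export
clustering_onnela <- function(w) {
  w <- check_adjacency(w)
  n <- nrow(w)
  mx <- max(w)
  if (mx == 0) return(list(global = 0, nodal = rep(0, n)))
  a <- (w / mx)^(1 / 3)
  k <- rowSums(w > 0)
  cyc <- diag(a %*% a %*% a)          # 2 * sum over neighbour pairs of the triple product
  nodal <- ifelse(k >= 2, cyc / (k * (k - 1)), 0)
  list(global = mean(nodal), nodal = nodal)
}

#' Weighted local efficiency (global and nodal)
#'
#' `Eloc_i` is the global efficiency of the subnetwork induced by the
#' neighbours of node i (node i removed), computed on the original
#' weights; nodes with fewer than two neighbours have `Eloc_i = 0`. The
#' global value is the mean over all nodes.
#'
#' @param w nonnegative symmetric weighted adjacency, zero diagonal.
#' @param nodes optional integer vector: compute `Eloc_i` only for these
#'   nodes (the global value is then the mean over that subset's
#'   complement-free values and reported as NA).
#' @return List with `global` and `nodal`.
#' @export
local_efficiency <- function(w, nodes = NULL) {
  w <- check_adjacency(w)
  n <- nrow(w)
  target <- if (is.null(nodes)) seq_len(n) else as.integer(nodes)
  nodal <- rep(NA_real_, n)
  nodal[target] <- .local_eff(w, target)
  list(global = if (is.null(nodes)) mean(nodal) else NA_real_, nodal = nodal)
}

#' Node strength (weighted degree)
#'
#' `degree_i = sum_j w_ij`; the global value is the mean over nodes.
#'
#' @param w nonnegative symmetric weighted adjacency, zero diagonal.
#' @return List with `global` and `nodal`.
#' @export
node_strength <- function(w) {
  w <- check_adjacency(w)
  nodal <- rowSums(w)
  list(global = mean(nodal), nodal = nodal)
}

# one degree-preserving (Maslov-Sneppen) null: rewire the binary
# topology with >= 10 edge swaps per edge, then reassign the original
# weights to the rewired edges in random order
rewire_null <- function(w) {
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  m <- igraph::ecount(g)
  g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = 10 * m))
  el <- igraph::as_edgelist(g2, names = FALSE)
  wts <- sample(w[upper.tri(w)][w[upper.tri(w)] > 0])
  wn <- matrix(0, nrow(w), ncol(w))
  wn[el] <- wts
  wn[el[, c(2, 1), drop = FALSE]] <- wts
  wn
}

#' Small-worldness against degree-preserving rewired nulls
#'
#' `sigma = (Cp / Cp_rand) / (Lp / Lp_rand)`, where `Cp_rand` and
#' `Lp_rand` are means over `n_nulls` Maslov-Sneppen surrogates: the
#' binary topology is rewired with at least 10 edge swaps per edge
#' (preserving the degree sequence) and the original weights are
#' reassigned to the rewired edges in random order. `sigma > 1` marks a
#' network with random-like path length but above-random clustering.
#'
#' @param w nonnegative symmetric weighted adjacency, zero diagonal.
#' @param n_nulls number of surrogate networks (>= 10).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @param max_retries surrogates with undefined path length are redrawn
#'   at most this many extra times before failing.
#' @return Single numeric sigma value.
#' @export
small_worldness <- function(w, n_nulls = 100, seed = NULL, max_retries = NULL) {
  w <- check_adjacency(w)
  if (n_nulls < 10) stop("n_nulls must be at least 10", call. = FALSE)
  if (is.null(max_retries)) max_retries <- n_nulls
  obs_cp <- clustering_onnela(w)$global
  obs_lp <- char_path_length(w)$global
  if (!is.finite(obs_lp) || obs_lp <= 0 || obs_cp <= 0) {
    stop("small-worldness undefined: observed Cp or Lp not positive and finite",
         call. = FALSE)
  }
  with_seed(seed, {
    cp_null <- lp_null <- numeric(n_nulls)
    retries <- 0L
    i <- 1L
    while (i <= n_nulls) {
      wn <- rewire_null(w)
      lp <- char_path_length(wn)$global
      cp <- clustering_onnela(wn)$global
      if (!is.finite(lp) || lp <= 0 || cp <= 0) {
        retries <- retries + 1L
        if (retries > max_retries) {
          stop("null networks with undefined path length or clustering; ",
               "retry cap exceeded", call. = FALSE)
        }
        next
      }
      lp_null[i] <- lp
      cp_null[i] <- cp
      i <- i + 1L
    }
    (obs_cp / mean(cp_null)) / (obs_lp / mean(lp_null))
  })
}

metric_names_nodal <- c("degree", "lp", "eglob", "cp", "eloc")
metric_names_global <- c("degree", "lp", "eglob", "cp", "eloc", "sigma")

# all metrics for one network; nodes restricts the (expensive) nodal
# computations, sigma computed only when n_nulls > 0
network_metrics <- function(w, nodes = NULL, n_nulls = 0, seed = NULL) {
  w <- check_adjacency(w)
  d <- shortest_path_lengths(w)
  str <- node_strength(w)
  lp <- char_path_length(w, distances = d)
  eg <- global_efficiency(w, distances = d)
  cp <- clustering_onnela(w)
  el <- local_efficiency(w, nodes = nodes)
  glob <- c(degree = str$global, lp = lp$global, eglob = eg$global,
            cp = cp$global,
            eloc = if (is.null(nodes)) el$global else NA_real_,
            sigma = NA_real_)
  if (n_nulls > 0) {
    glob["sigma"] <- small_worldness(w, n_nulls = n_nulls, seed = seed)
  }
  nodal <- cbind(degree = str$nodal, lp = lp$nodal, eglob = eg$nodal,
                 cp = cp$nodal, eloc = el$nodal)
  rownames(nodal) <- rownames(w)
  list(global = glob, nodal = nodal, n_unreachable = lp$n_unreachable)
}

#' Network metrics across the density grid, with density-averaging
#'
#' Computes every global and nodal metric at each density level of a
#' subject's [build_connectivity()] result and adds the density-averaged
#' value (arithmetic mean over levels; nodal values missing at a level
#' because a node is disconnected are excluded from that node's mean).
#'
#' @param conn an `fc_connectivity` object.
#' @param n_nulls rewired surrogates per density for small-worldness;
#'   0 skips sigma.
#' @param seed optional integer seed for the null ensembles.
#' @param nodes optional node indices to restrict nodal metrics to.
#' @return List with `global` (metrics x densities matrix including an
#'   `"avg"` column) and `nodal` (3-d array node x metric x density,
#'   with an `"avg"` slice).
#' @export
metrics_over_densities <- function(conn, n_nulls = 0, seed = NULL,
                                   nodes = NULL) {
  stopifnot(inherits(conn, "fc_connectivity"))
  lev <- names(conn$z_networks)
  n <- nrow(conn$r_matrix)
  glob <- matrix(NA_real_, length(metric_names_global), length(lev),
                 dimnames = list(metric_names_global, lev))
  nod <- array(NA_real_,
               dim = c(n, length(metric_names_nodal), length(lev)),
               dimnames = list(rownames(conn$r_matrix), metric_names_nodal, lev))
  for (i in seq_along(lev)) {
    s <- if (is.null(seed)) NULL else seed + i
    m <- network_metrics(conn$z_networks[[i]], nodes = nodes,
                         n_nulls = n_nulls, seed = s)
    glob[, i] <- m$global
    nod[, , i] <- m$nodal
  }
  glob_avg <- rowMeans(glob)
  nod_avg <- apply(nod, c(1, 2), mean, na.rm = TRUE)
  nod_avg[!is.finite(nod_avg)] <- NA_real_
  list(global = cbind(glob, avg = glob_avg),
       nodal = abind3(nod, nod_avg))
}

# append a node x metric slice named "avg" to a node x metric x density array
abind3 <- function(arr, slice) {
  out <- array(NA_real_, dim = dim(arr) + c(0, 0, 1),
               dimnames = c(dimnames(arr)[1:2],
                            list(c(dimnames(arr)[[3]], "avg"))))
  out[, , seq_len(dim(arr)[3])] <- arr
  out[, , dim(out)[3]] <- slice
  out
}

#' Metrics for a whole cohort in long format
#'
#' Runs [build_connectivity()] and [metrics_over_densities()] for every
#' subject and stacks the results into one long data.frame suitable for
#' export and for the group-comparison stage.
#'
#' @param subjects list of subject records (`subject_id`, `group`,
#'   `data`), e.g. from [generate_cohort()].
#' @param grid a [density_grid()].
#' @param n_nulls surrogates per density for sigma (0 skips sigma).
#' @param seed integer seed governing all null ensembles.
#' @param nodes optional node indices restricting nodal metrics.
#' @return data.frame with columns `subject_id`, `group`, `density`
#'   (`"0.20"` ... `"avg"`), `level` (`"global"`/`"node"`), `node`
#'   (label or NA), `metric`, `value`.
#' @export
cohort_metrics <- function(subjects, grid = density_grid(), n_nulls = 0,
                           seed = NULL, nodes = NULL) {
  out <- vector("list", length(subjects))
  for (si in seq_along(subjects)) {
    sub <- subjects[[si]]
    conn <- build_connectivity(sub$data, grid, subject_id = sub$subject_id)
    s <- if (is.null(seed)) NULL else seed + 100L * si
    m <- metrics_over_densities(conn, n_nulls = n_nulls, seed = s,
                                nodes = nodes)
    dens <- colnames(m$global)
    g <- data.frame(
      subject_id = sub$subject_id, group = sub$group,
      density = rep(dens, each = nrow(m$global)),
      level = "global", node = NA_character_,
      metric = rep(rownames(m$global), length(dens)),
      value = as.vector(m$global), stringsAsFactors = FALSE
    )
    node_lab <- dimnames(m$nodal)[[1]]
    if (is.null(node_lab)) node_lab <- as.character(seq_len(dim(m$nodal)[1]))
    keep_nodes <- if (is.null(nodes)) seq_along(node_lab) else nodes
    nd <- expand.grid(node = node_lab[keep_nodes],
                      metric = dimnames(m$nodal)[[2]],
                      density = dimnames(m$nodal)[[3]],
                      stringsAsFactors = FALSE)
    nd$value <- as.vector(m$nodal[keep_nodes, , ])
    nd <- data.frame(subject_id = sub$subject_id, group = sub$group,
                     density = nd$density, level = "node", node = nd$node,
                     metric = nd$metric, value = nd$value,
                     stringsAsFactors = FALSE)
    out[[si]] <- rbind(g, nd)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
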