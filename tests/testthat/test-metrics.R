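test_that("path-based metrics agree with closed forms on canonical graphs", {
  # single edge of weight 2: distance 1/2
  w2 <- matrix(0, 2, 2); w2[1, 2] <- w2[2, 1] <- 2
  expect_equal(shortest_path_lengths(w2)[1, 2], 0.5)

  # unit-weight line A-B-C: d(A,C) = 2, Lp = (1+1+2)*2/6 = 4/3
  line <- matrix(0, 3, 3)
  line[1, 2] <- line[2, 1] <- line[2, 3] <- line[3, 2] <- 1
  expect_equal(shortest_path_lengths(line)[1, 3], 2)
  expect_equal(char_path_length(line)$global, 4 / 3)

  # complete unit-weight graphs: Lp = Eglob = 1
  k5 <- matrix(1, 5, 5); diag(k5) <- 0
  expect_equal(char_path_length(k5)$global, 1)
  expect_equal(global_efficiency(k5)$global, 1)

  # empty graph: Eglob = 0, all pairs unreachable
  e4 <- matrix(0, 4, 4)
  expect_equal(global_efficiency(e4)$global, 0)
  expect_equal(char_path_length(e4)$n_unreachable, 12)
})

test_that("clustering and local efficiency behave on triangle, star, clique", {
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(clustering_onnela(tri)$global, 1)
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(clustering_onnela(star)$global, 0)
  expect_equal(local_efficiency(star)$nodal[2], 0)
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  expect_equal(local_efficiency(k4)$global, 1)
  # uniform weights reduce to the binary clustering coefficient
  g <- random_graph(6, 0.6, seed = 31)
  gb <- (g > 0) * 0.7
  a <- g > 0
  k <- rowSums(a)
  tri_count <- diag(a %*% a %*% a)
  cp_bin <- ifelse(k >= 2, tri_count / (k * (k - 1)), 0)
  expect_equal(clustering_onnela(gb)$nodal, cp_bin)
})

test_that("strength satisfies the handshake identity", {
  w <- random_graph(8, 0.4, seed = 5)
  s <- node_strength(w)
  expect_equal(sum(s$nodal), 2 * sum(w[upper.tri(w)]))
  w[3, ] <- w[, 3] <- 0  # isolate a node
  expect_equal(node_strength(w)$nodal[3], 0)
})

test_that("all five metrics match brute-force enumeration on small graphs", {
  n_checked <- 0
  for (seed in 1:200) {
    n <- sample(3:6, 1)
    w <- random_graph(n, stats::runif(1, 0.3, 0.9), seed = seed)
    d <- shortest_path_lengths(w)
    expect_equal(d, oracle_distances(w), tolerance = 1e-12)
    expect_equal(char_path_length(w)$nodal, oracle_lp_nodal(w),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(w)$nodal, oracle_eglob_nodal(w),
                 tolerance = 1e-12)
    expect_equal(clustering_onnela(w)$nodal, oracle_onnela_nodal(w),
                 tolerance = 1e-12)
    expect_equal(local_efficiency(w)$nodal, oracle_eloc_nodal(w),
                 tolerance = 1e-12)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("distances agree with an independent graph library", {
  for (seed in c(2, 17, 99)) {
    w <- random_graph(12, 0.35, seed = seed)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    d_ig <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(shortest_path_lengths(w)), unname(d_ig),
                 tolerance = 1e-12)
  }
})

test_that("metrics are invariant under node relabeling and bounded", {
  w <- random_graph(10, 0.5, seed = 77)
  perm <- sample(10)
  wp <- w[perm, perm]
  expect_equal(char_path_length(wp)$global, char_path_length(w)$global)
  expect_equal(global_efficiency(wp)$global, global_efficiency(w)$global)
  expect_equal(clustering_onnela(wp)$global, clustering_onnela(w)$global)
  cp <- clustering_onnela(w)$nodal
  expect_true(all(cp >= 0 & cp <= 1))
  wn <- w / max(w)
  expect_true(global_efficiency(wn)$global <= 1)
})

test_that("adding edges never lengthens paths: Eglob rises with density", {
  set.seed(123)
  ts <- matrix(rnorm(100 * 30), 100, 30) + rnorm(100)
  conn <- build_connectivity(ts, density_grid())
  eg <- sapply(conn$z_networks, function(z) global_efficiency(z)$global)
  expect_true(all(diff(eg) >= 0))
  md <- sapply(conn$z_networks, function(z) node_strength(z)$global)
  expect_true(all(diff(md) >= 0))
})

test_that("small-worldness is ~1 on random graphs and >1 on lattices", {
  # a random weighted network is its own null model up to noise
  set.seed(20)
  w <- random_graph(30, 0.3)
  sig <- small_worldness(w, n_nulls = 100, seed = 1)
  expect_gt(sig, 0.8)
  expect_lt(sig, 1.2)

  # ring lattice with a few shortcuts: canonical small-world regime
  n <- 30
  lat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (off in 1:3) {
      j <- ((i + off - 1) %% n) + 1
      lat[i, j] <- lat[j, i] <- 1
    }
  }
  set.seed(4)
  shortcuts <- matrix(sample(n, 8), ncol = 2)
  for (r in seq_len(nrow(shortcuts))) {
    i <- shortcuts[r, 1]; j <- shortcuts[r, 2]
    if (i != j) lat[i, j] <- lat[j, i] <- 1
  }
  expect_gt(small_worldness(lat, n_nulls = 50, seed = 2), 1)

  # uniform weight rescaling cancels in the sigma ratio
  s1 <- small_worldness(w, n_nulls = 20, seed = 9)
  s2 <- small_worldness(w * 3.7, n_nulls = 20, seed = 9)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("sigma concentrates near 1 over an ensemble of random networks", {
  sig <- numeric(50)
  for (k in 1:50) {
    w <- random_graph(30, 0.3, seed = 1000 + k)
    sig[k] <- small_worldness(w, n_nulls = 50, seed = k)
  }
  expect_gt(mean(sig), 0.9)
  expect_lt(mean(sig), 1.1)
})

test_that("density-averaged metrics equal the mean of per-level values", {
  set.seed(55)
  ts <- matrix(rnorm(120 * 30), 120, 30) + rnorm(120)
  conn <- build_connectivity(ts, density_grid())
  m <- metrics_over_densities(conn)
  lev <- sprintf("%.2f", density_grid())
  expect_equal(m$global[, "avg"], rowMeans(m$global[, lev]))
  for (metric in c("degree", "lp", "eglob", "cp", "eloc")) {
    expect_equal(m$nodal[, metric, "avg"],
                 rowMeans(m$nodal[, metric, lev], na.rm = TRUE))
  }
})
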