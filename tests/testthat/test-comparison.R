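# helper: tiny two-group cohort with a known structure
small_cohort <- function(seed = 1, n_control = 6, n_patient = 5,
                         effect_edges = data.frame()) {
  cfg <- cohort_config(n_control = n_control, n_patient = n_patient,
                       n_timepoints = 80, effect_edges = effect_edges,
                       behavior_links = data.frame(), seed = seed)
  generate_cohort(cfg)
}

test_that("hemisphere averaging collapses bilateral pairs and passes midline", {
  atl <- canine_atlas()
  nodal <- data.frame(
    subject_id = "s1", group = "patient", density = "avg",
    metric = "degree",
    node = c("amygdala L", "amygdala R", "mesencephalon"),
    value = c(2, 4, 5))
  reg <- nodal_lr_average(nodal, atl)
  expect_equal(reg$value[reg$region == "amygdala"], 3)
  expect_equal(reg$value[reg$region == "mesencephalon"], 5)
  # swapping the hemisphere labels leaves region values unchanged
  nodal2 <- nodal
  nodal2$node <- c("amygdala R", "amygdala L", "mesencephalon")
  expect_equal(nodal_lr_average(nodal2, atl), reg)
  # one disconnected hemisphere: the available side is used
  nodal3 <- nodal
  nodal3$value[2] <- NA
  reg3 <- nodal_lr_average(nodal3, atl)
  expect_equal(reg3$value[reg3$region == "amygdala"], 2)
  expect_error(nodal_lr_average(transform(nodal, node = "nowhere"), atl),
               "unknown nodes")
})

test_that("region-level connection strength averages the spanning node pairs", {
  atl <- canine_atlas()
  grid <- density_grid(c(0.2, 0.3))
  # synthetic connectivity with known z networks
  conn <- structure(list(
    subject_id = "s1", r_matrix = diag(30),
    z_networks = list("0.20" = matrix(0, 30, 30),
                      "0.30" = matrix(0, 30, 30)),
    densities = c(0.2, 0.3)), class = "fc_connectivity")
  np <- region_pair_nodes(atl, "amygdala", "hippocampus")
  for (lev in names(conn$z_networks)) {
    for (r in seq_len(nrow(np))) {
      conn$z_networks[[lev]][np[r, 1], np[r, 2]] <- 0.6
      conn$z_networks[[lev]][np[r, 2], np[r, 1]] <- 0.6
    }
  }
  # all node pairs equal at every density -> that constant
  expect_equal(edge_region_average(conn, atl, "amygdala", "hippocampus"), 0.6)
  # absent everywhere -> exactly zero (sub-threshold semantics)
  expect_equal(edge_region_average(conn, atl, "amygdala", "thalamus"), 0)
  # zeros are genuine values: knock out one density level -> mean halves
  conn$z_networks[["0.30"]][np] <- 0
  conn$z_networks[["0.30"]][np[, c(2, 1)]] <- 0
  expect_equal(edge_region_average(conn, atl, "amygdala", "hippocampus"), 0.3)
  # independent recomputation on an arbitrary matrix
  set.seed(10)
  for (lev in names(conn$z_networks)) {
    m <- matrix(abs(rnorm(900)), 30, 30); m <- (m + t(m)) / 2; diag(m) <- 0
    conn$z_networks[[lev]] <- m
  }
  byhand <- mean(c(mean(conn$z_networks[[1]][np]),
                   mean(conn$z_networks[[2]][np])))
  expect_equal(edge_region_average(conn, atl, "amygdala", "hippocampus"),
               byhand)
  expect_error(edge_region_average(conn, atl, "amygdala", "nowhere"),
               "unknown atlas region")
})

test_that("edge table covers the 10 circuit pairs, plus homotopic on request", {
  coh <- small_cohort(seed = 4, n_control = 2, n_patient = 2)
  et <- edge_value_table(coh$subjects, coh$atlas)
  expect_equal(nrow(et), 4 * 10)
  et_h <- edge_value_table(coh$subjects, coh$atlas, include_homotopic = TRUE)
  # four bilateral circuit regions add one homotopic pair each
  expect_equal(nrow(et_h), 4 * 14)
  expect_true(all(et$z >= 0))
})

test_that("identical groups produce uniform large p-values", {
  coh <- small_cohort(seed = 6, n_control = 4, n_patient = 4)
  # make the patient group an exact copy of the control group
  for (i in 1:4) {
    coh$subjects[[4 + i]]$data <- coh$subjects[[i]]$data
  }
  metrics <- cohort_metrics(coh$subjects)
  edges <- edge_value_table(coh$subjects, coh$atlas)
  res <- run_three_level_comparison(metrics, edges, coh$atlas,
                                    mode = "exact", seed = 2,
                                    n_resamples = 2000)
  expect_true(all(res$p_raw > 0.9))
  expect_true(all(res$p_fdr >= res$p_raw - 1e-12))
  expect_true(all(res$u <= 16))
  expect_false(any(res$p_fdr < 0.05))
})

test_that("comparison output structure follows the three-level design", {
  coh <- small_cohort(seed = 9)
  metrics <- cohort_metrics(coh$subjects)
  edges <- edge_value_table(coh$subjects, coh$atlas)
  res <- run_three_level_comparison(metrics, edges, coh$atlas)
  expect_setequal(unique(res$level), c("global", "nodal", "edge"))
  # global level: 5 metrics without sigma (no null ensembles requested)
  expect_equal(sum(res$level == "global"), 5)
  # nodal: 6 regions x 5 metrics
  expect_equal(sum(res$level == "nodal"), 30)
  # edge: 10 circuit pairs
  expect_equal(sum(res$level == "edge"), 10)
  # the nodal FDR family is within metric across regions: each family of
  # 6 adjusted values must be a BH image of its raw values
  nod <- res[res$level == "nodal", ]
  nod$metric <- sub(".* \\| ", "", nod$target)
  for (m in unique(nod$metric)) {
    fam <- nod[nod$metric == m, ]
    expect_equal(fam$p_fdr, oracle_bh(fam$p_raw), tolerance = 1e-12)
  }
  expect_true(all(res$direction %in% c(-1, 0, 1)))
})
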