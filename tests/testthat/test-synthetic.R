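test_that("generation is fully deterministic given the seed", {
  cfg <- cohort_config(n_control = 3, n_patient = 3, n_timepoints = 60,
                       seed = 7)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$behavior, b$behavior)
})

test_that("independent signals decorrelate at long scan lengths", {
  cfg <- cohort_config(n_control = 3, n_patient = 3, n_timepoints = 2000,
                       base_connectivity = 0, effect_edges = data.frame(),
                       behavior_links = data.frame(), seed = 2)
  coh <- generate_cohort(cfg)
  mean_offdiag <- sapply(coh$subjects, function(s) {
    r <- correlation_matrix(s$data)
    mean(abs(r[upper.tri(r)]))
  })
  expect_true(all(mean_offdiag < 0.1))
})

test_that("generated signals carry no power outside the passband", {
  cfg <- cohort_config(n_control = 2, n_patient = 2, seed = 3)
  coh <- generate_cohort(cfg)
  x <- coh$subjects[[1]]$data
  T <- nrow(x)
  spec <- abs(stats::mvfft(x))^2
  f <- pmin(0:(T - 1), T - (0:(T - 1))) / (T * cfg$tr_seconds)
  inband <- f >= cfg$passband[1] & f <= cfg$passband[2]
  expect_lt(sum(spec[!inband, ]) / sum(spec), 0.05)
})

test_that("implanted correlation deltas are recovered at scale", {
  # Monte-Carlo check against the generator's own target covariance:
  # one +0.3 amygdala-hippocampus edge, 200 subjects per group, T = 500
  cfg <- cohort_config(
    n_control = 200, n_patient = 200, n_timepoints = 500,
    base_connectivity = 0.3,
    effect_edges = data.frame(region_a = "amygdala",
                              region_b = "hippocampus", delta_r = 0.3),
    behavior_links = data.frame(), seed = 11)
  coh <- generate_cohort(cfg)
  atl <- coh$atlas
  np <- region_pair_nodes(atl, "amygdala", "hippocampus")
  edge_r <- sapply(coh$subjects, function(s) {
    r <- correlation_matrix(s$data)
    mean(r[np])
  })
  grp <- sapply(coh$subjects, `[[`, "group")
  diff_r <- mean(edge_r[grp == "patient"]) - mean(edge_r[grp == "control"])
  expect_equal(diff_r, 0.3, tolerance = 0.1)
  # sample correlations converge to target off the implanted edges too
  ctrl_mean_r <- Reduce(`+`, lapply(coh$subjects[grp == "control"],
                                    function(s) correlation_matrix(s$data))) /
    sum(grp == "control")
  off <- ctrl_mean_r[upper.tri(ctrl_mean_r)]
  expect_lt(max(abs(off - 0.3)), 0.05)
})

test_that("behaviour links reach the target Spearman correlation", {
  # target rho 0.8, 50 patients: recovered sample rho in [0.6, 0.95]
  # in at least 90% of seeds
  hits <- 0
  n_seeds <- 100
  links <- data.frame(scale = "touch_sensitivity",
                      feature = "degree:hippocampus", rho = 0.8)
  for (s in seq_len(n_seeds)) {
    cfg <- cohort_config(n_control = 2, n_patient = 50,
                         behavior_links = links, seed = 3000 + s)
    coh <- generate_cohort(cfg)
    grid <- density_grid()
    feat <- sapply(coh$subjects[sapply(coh$subjects, `[[`, "group") ==
                                  "patient"], function(sub) {
      conn <- build_connectivity(sub$data, grid)
      mean(sapply(conn$z_networks, function(w)
        mean(rowSums(w)[atlas_nodes(coh$atlas, "hippocampus")])))
    })
    rho <- spearman_rho(feat, coh$behavior$touch_sensitivity)$rho
    if (rho >= 0.6 && rho <= 0.95) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("impossible correlation structures fail naming the edges", {
  bad <- data.frame(
    region_a = c("mesencephalon", "mesencephalon", "diencephalon"),
    region_b = c("diencephalon", "amygdala", "amygdala"),
    delta_r = c(0.95, 0.95, -0.95))
  cfg <- cohort_config(base_connectivity = 0, effect_edges = bad, seed = 1)
  expect_error(generate_cohort(cfg), "positive semi-definite")
})

test_that("cohort files round-trip through the TSV/CSV writers", {
  cfg <- cohort_config(n_control = 2, n_patient = 2, n_timepoints = 40,
                       seed = 5)
  coh <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back$subjects), 4)
  expect_equal(back$subjects[[1]]$group, "control")
  expect_equal(unname(back$subjects[[3]]$data),
               unname(coh$subjects[[3]]$data), tolerance = 1e-8)
  expect_equal(back$behavior$touch_sensitivity,
               coh$behavior$touch_sensitivity)
  # header validation catches atlas mismatches
  tsv <- file.path(dir, "ctrl01.tsv")
  d <- read.delim(tsv, check.names = FALSE)
  colnames(d)[2] <- "not a region"
  write.table(d, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(dir), "not a region")
})

test_that("published behaviour scores load verbatim with ND as missing", {
  tab <- cbarq_patient_scores()
  expect_equal(nrow(tab), 13)
  expect_equal(tab$trainability[1], 1.50)
  expect_equal(tab$breed[1], "Jack Russell terrier")
  expect_true(is.na(tab$familiar_dog_aggression[5]))  # Akita Inu, ND
  expect_equal(sum(!is.na(tab$familiar_dog_aggression)), 8)
  expect_true(all(cbarq_scales %in% colnames(tab)))
})
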