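test_that("generation is bit-identical for equal seeds and differs across seeds", {
  cfg <- small_config()
  a <- generate_roi(cfg, seed = 7)
  b <- generate_roi(cfg, seed = 7)
  expect_identical(as.data.frame(a$table), as.data.frame(b$table))
  expect_identical(a$truth, b$truth)
  c3 <- generate_roi(cfg, seed = 8)
  expect_false(identical(as.data.frame(a$table), as.data.frame(c3$table)))
})

test_that("infeasible geometry is rejected", {
  expect_error(generator_config(
    roi = roi_spec(c(0, 0), c(1500, 1500)), margin = c(900, 900)),
    "margin")
})

test_that("fit_p defaults to the passing interval; QC-stress exercises the filter", {
  sim <- generate_roi(small_config(), seed = 3)
  expect_true(all(sim$table$fit_p >= 0.25))
  filtered <- filter_by_fit_quality(sim$table)
  expect_equal(nrow(filtered), nrow(sim$table))   # pass-through

  stress <- generate_roi(small_config(qc_stress_fraction = 0.2), seed = 3)
  f2 <- filter_by_fit_quality(stress$table)
  removed <- attr(f2, "qc_removed")
  n_par <- sum(stress$table$channel == "Jph2")
  expect_equal(unname(removed["RyR2"]), 0L)
  expect_gt(removed["Jph2"] / n_par, 0.1)
  expect_lt(removed["Jph2"] / n_par, 0.3)
})

test_that("well-separated zero-background scenes are recovered exactly", {
  ## wide gaps, no background, no deletion: every planted anchor comes back
  cfg <- small_config(
    within_row_gap = list(mean = 1500, sd = 100, min = 1200),
    locs_per_cluster = list(meanlog = log(40), sdlog = 0.3, min = 15,
                            max = 200),
    cluster_radius = list(mean = 60, sd = 5, min = 40, max = 100,
                          n_ref = 30),
    reference_background_density = 0,
    partner_background_density = 0,
    planted_empty_prob = 0)
  n_match <- 0; n_tot <- 0
  cen_err <- c()
  for (s in 1:8) {
    sim <- generate_roi(cfg, seed = 200 + s)
    k <- nrow(sim$truth$anchors)
    ref <- channel_table(sim$table, "reference")
    cs <- build_clusters(ref)
    n_tot <- n_tot + k
    n_match <- n_match + nrow(cs$clusters)
    ## DBSCAN partition must equal the planted membership exactly
    memb <- sim$truth$membership[sim$table$channel == "RyR2"]
    expect_true(same_partition(cs$labels,
                               as.integer(memb) - 1L))
    ## centroid recovery
    cen <- cluster_centroids(cs)
    for (i in seq_len(k)) {
      dd <- sqrt(rowSums((cen - matrix(sim$truth$anchors[i, ], nrow(cen),
                                       2, byrow = TRUE))^2))
      cen_err <- c(cen_err, min(dd))
    }
  }
  expect_equal(n_match, n_tot)   # exact cluster-count recovery
  ## anchor-to-centroid distance stays within a few true-footprint SEs
  expect_lt(mean(cen_err), 30)
})

test_that("membership ground truth accounts for every localization", {
  sim <- generate_roi(small_config(), seed = 11)
  expect_equal(length(sim$truth$membership), nrow(sim$table))
  k <- nrow(sim$truth$anchors)
  expect_true(all(sim$truth$membership %in% 0:k))
  ## planted-empty anchors contribute no partner localizations
  empt <- which(sim$truth$empty_flags)
  par_member <- sim$truth$membership[sim$table$channel == "Jph2"]
  expect_false(any(par_member %in% empt))
})

test_that("planted empty fraction is recovered within binomial error", {
  cfg <- small_config(planted_empty_prob = 0.1)
  hits <- 0; tot <- 0
  for (s in 1:15) {
    sim <- generate_roi(cfg, seed = 300 + s)
    res <- analyze_roi(sim$table)
    hits <- hits + sum(res$coloc$per_cluster_counts == 0)
    tot <- tot + length(res$coloc$per_cluster_counts)
  }
  se <- sqrt(0.1 * 0.9 / tot)
  expect_lt(abs(hits / tot - 0.1), 3 * se + 0.01)
})

test_that("recovered centroid error scales like precision / sqrt(n)", {
  cfg <- small_config(
    within_row_gap = list(mean = 1500, sd = 100, min = 1200),
    locs_per_cluster = list(meanlog = log(50), sdlog = 0.1, min = 40,
                            max = 80),
    cluster_radius = list(mean = 1e-3, sd = 1e-4, min = 1e-4, max = 1,
                          n_ref = 30),   # point-like: noise dominates
    reference_background_density = 0, partner_background_density = 0)
  errs <- c()
  ns <- c()
  for (s in 1:10) {
    sim <- generate_roi(cfg, seed = 400 + s)
    cs <- build_clusters(channel_table(sim$table, "reference"))
    cen <- cluster_centroids(cs)
    for (i in seq_len(nrow(sim$truth$anchors))) {
      dd <- sqrt(rowSums((cen - matrix(sim$truth$anchors[i, ], nrow(cen),
                                       2, byrow = TRUE))^2))
      j <- which.min(dd)
      errs <- c(errs, cen[j, ] - sim$truth$anchors[i, ])
      ns <- c(ns, cs$clusters$n_locs[j])
    }
  }
  ## per-axis SD of the centroid error ~ 20 / sqrt(n)
  expected_sd <- mean(20 / sqrt(ns))
  expect_lt(abs(mean(errs)), 3 * expected_sd / sqrt(length(errs) / 2))
  expect_lt(abs(sd(errs) - expected_sd) / expected_sd, 0.2)
})

test_that("presets round-trip through YAML and honor their condition axes", {
  eu <- preset("EU2D")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(eu, path)
  back <- read_config(path)
  expect_equal(config_to_list(back), config_to_list(eu), tolerance = 1e-12)
  expect_error(preset("NOPE"), "unknown preset")

  ## PTU deletes clusters: fewer retained clusters at equal seeds
  ptu <- preset("PTU2D")
  n_eu <- n_ptu <- 0
  for (s in 1:3) {
    n_eu <- n_eu + nrow(analyze_roi(
      generate_roi(eu, seed = 500 + s)$table)$clusters$clusters)
    n_ptu <- n_ptu + nrow(analyze_roi(
      generate_roi(ptu, seed = 500 + s)$table)$clusters$clusters)
  }
  expect_lt(n_ptu, n_eu)
})

test_that("simulation export writes table, ground truth and manifest", {
  dir <- withr::local_tempdir()
  cfg <- small_config()
  sim <- generate_roi(cfg, seed = 9,
                      metadata = list(cell = "c1", animal = "a1",
                                      group = "EU"))
  write_simulation(sim, dir, config = cfg)
  back <- read_localizations(file.path(dir, "localizations.csv"),
                             channels = c(reference = "RyR2",
                                          partner = "Jph2"))
  expect_equal(as.data.frame(back), as.data.frame(sim$table),
               ignore_attr = TRUE)
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(gt$planted_cluster, sim$truth$membership)
  an <- read.csv(file.path(dir, "anchors.csv"))
  expect_equal(nrow(an), nrow(sim$truth$anchors))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_localizations, nrow(sim$table))
  expect_equal(man$config$within_row_gap$mean, cfg$within_row_gap$mean)
})

test_that("calibration recovers a known planted-empty target", {
  cfg <- small_config(planted_empty_prob = 0.02)
  out <- calibrate_preset(cfg, targets = c(empty_fraction = 10),
                          tolerance = 0.1, n_cells = 4, rois_per_cell = 2,
                          seed = 99, verbose = FALSE)
  expect_gt(out$planted_empty_prob, 0.05)
  expect_lt(out$planted_empty_prob, 0.16)
  tr <- attr(out, "calibration_trace")
  expect_s3_class(tr, "data.frame")
  expect_gt(nrow(tr), 1)
})
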