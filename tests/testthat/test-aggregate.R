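test_that("ROI summary reflects a fully planted construction", {
  ## 30 clusters of exactly 20 locs each plus 100 reference background locs
  centers <- as.matrix(expand.grid(seq(500, 7700, 1200),
                                   seq(500, 5300, 1200)))[1:30, ]
  blobs <- make_blobs(centers, n_per = 20, sd = 25, seed = 41)
  set.seed(42)
  ## background kept clear of the planted clusters so counts stay exact
  bg <- matrix(numeric(), 0, 2)
  while (nrow(bg) < 100) {
    cand <- matrix(runif(200, 0, 8200), 100, 2)
    d2 <- outer(rowSums(cand^2), rowSums(centers^2), "+") -
      2 * cand %*% t(centers)
    bg <- rbind(bg, cand[sqrt(apply(d2, 1, min)) > 400, , drop = FALSE])
  }
  bg <- bg[1:100, ]
  pts <- rbind(blobs$pts, bg)
  tab <- loc_table(pts, channel = rep("RyR2", nrow(pts)),
                   channels = c(reference = "RyR2", partner = "Jph2"),
                   metadata = list(cell = "c1", animal = "a1", group = "EU"))
  cs <- build_clusters(tab)
  expect_equal(nrow(cs$clusters), 30)
  ## background points falling into a cluster's eps-reach would inflate
  ## counts; at this density none do
  expect_equal(sum(cs$clusters$n_locs), 600)
  nnd <- nearest_neighbor_distances(cs)
  coloc <- count_partners(cs, matrix(numeric(), 0, 2))
  s <- summarize_roi(cs, coloc, nnd, tab, roi_id = "r1")
  expect_equal(s$cluster_count, 30)
  expect_equal(s$mean_locs_per_cluster, 20)
  expect_equal(s$clustered_fraction, 100 * 600 / 700, tolerance = 1e-12)
  expect_equal(s$empty_fraction, 100)
  expect_equal(s$total_reference_locs, 700)

  ## zero clusters: flags set, no error
  sparse <- loc_table(matrix(runif(20, 0, 1e4), 10, 2),
                      channel = rep("RyR2", 10),
                      channels = c(reference = "RyR2", partner = "Jph2"))
  cs0 <- build_clusters(sparse)
  s0 <- summarize_roi(cs0, NULL, NULL, sparse)
  expect_equal(s0$cluster_count, 0)
  expect_true(is.na(s0$mean_span))
})

test_that("cell and animal aggregation are arithmetic means over units", {
  mk_row <- function(cell, animal, vals) {
    df <- summarize_roi(
      structure(list(clusters = data.frame(), members = list(),
                     labels = integer(0), n_input_locs = 0L,
                     n_clustered_locs = 0L, dimensionality = 2,
                     params = cluster_params()), class = "cluster_set"),
      NULL, NULL, NULL)
    df$cell <- cell; df$animal <- animal; df$group <- "EU"
    for (m in names(vals)) df[[m]] <- vals[[m]]
    df
  }
  rois <- rbind(mk_row("c1", "a1", list(mean_span = 10, mean_nnd = 100)),
                mk_row("c1", "a1", list(mean_span = 20, mean_nnd = 300)),
                mk_row("c2", "a1", list(mean_span = 40, mean_nnd = 500)))
  expect_warning(cells <- aggregate_cells(rois), "undefined")
  c1 <- cells[cells$cell == "c1", ]
  expect_equal(c1$mean_span, 15)
  expect_equal(c1$mean_nnd, 200)
  expect_equal(cells[cells$cell == "c2", ]$mean_span, 40)  # identity
  an <- aggregate_animals(cells)
  expect_equal(an$mean_span, mean(c(15, 40)))

  ## permutation invariance within a level
  perm <- rois[c(3, 1, 2), ]
  expect_warning(cells_p <- aggregate_cells(perm), "undefined")
  expect_equal(cells_p[order(cells_p$cell), "mean_span"],
               cells[order(cells$cell), "mean_span"])
})

test_that("random two-ROI cells match the brute-force mean oracle", {
  set.seed(43)
  rois <- do.call(rbind, lapply(1:6, function(ci) {
    do.call(rbind, lapply(1:2, function(ri) {
      s <- summarize_roi(
        structure(list(clusters = data.frame(), members = list(),
                       labels = integer(0), n_input_locs = 0L,
                       n_clustered_locs = 0L, dimensionality = 2,
                       params = cluster_params()), class = "cluster_set"),
        NULL, NULL, NULL)
      s$cell <- paste0("c", ci); s$animal <- "a1"; s$group <- "EU"
      s$mean_span <- runif(1, 100, 400)
      s$cluster_count <- rpois(1, 100)
      s
    }))
  }))
  suppressWarnings(cells <- aggregate_cells(rois))
  for (ci in unique(rois$cell)) {
    expect_equal(cells$mean_span[cells$cell == ci],
                 mean(rois$mean_span[rois$cell == ci]))
  }
})

## helper: cell summaries with prescribed group values for one metric
fake_cells <- function(values_by_group) {
  do.call(rbind, lapply(names(values_by_group), function(g) {
    v <- values_by_group[[g]]
    data.frame(cell = paste0(g, seq_along(v)),
               animal = paste0(g, "_a", seq_along(v)), group = g,
               n_rois = 2, cluster_count = v, mean_locs_per_cluster = v,
               mean_span = v, mean_hull_measure = v, mean_nnd = v,
               median_nnd = v, mean_partner_per_cluster = v,
               empty_fraction = 0, clustered_fraction = 50,
               total_reference_locs = v, total_partner_locs = v)
  }))
}

test_that("ANOVA F matches the closed-form oracle and edge cases", {
  ## identical group means, nonzero within-group variance -> F = 0, p = 1
  cells <- fake_cells(list(EU = c(1, 2, 3), PTU = c(1, 2, 3),
                           T3 = c(3, 2, 1)))
  cmp <- compare_groups(cells, metrics = "mean_span")
  expect_equal(cmp$metrics$mean_span$F, 0)
  expect_equal(cmp$metrics$mean_span$p, 1)

  ## hand-computed sums of squares: groups {1,2,3},{2,3,4},{9,10,11}
  cells <- fake_cells(list(EU = c(1, 2, 3), PTU = c(2, 3, 4),
                           T3 = c(9, 10, 11)))
  cmp <- compare_groups(cells, metrics = "mean_span")
  expect_equal(cmp$metrics$mean_span$F, 57, tolerance = 1e-12)
  expect_equal(cmp$metrics$mean_span$F,
               oracle_anova_F(list(c(1, 2, 3), c(2, 3, 4), c(9, 10, 11))),
               tolerance = 1e-12)
  ## Tukey-adjusted p >= the unadjusted pooled-variance pairwise p
  tk <- cmp$metrics$mean_span$tukey
  vals <- list(EU = c(1, 2, 3), PTU = c(2, 3, 4), T3 = c(9, 10, 11))
  mse <- 1   # within-group mean square, from the hand computation above
  for (r in seq_len(nrow(tk))) {
    gs <- strsplit(tk$pair[r], "-", fixed = TRUE)[[1]]
    tstat <- abs(diff(vapply(vals[gs], mean, numeric(1)))) /
      sqrt(mse * (1 / 3 + 1 / 3))
    p_unadj <- 2 * pt(-tstat, df = 6)
    expect_gte(tk$p_adj[r] + 1e-12, p_unadj)
  }
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))

  ## group with < 2 observations errors by name
  bad <- fake_cells(list(EU = c(1, 2), PTU = 3))
  expect_error(compare_groups(bad, metrics = "mean_span"), "PTU")
})

test_that("two-group Tukey equals the pooled-variance t-test", {
  set.seed(44)
  g1 <- rnorm(8, 10, 2); g2 <- rnorm(9, 12, 2)
  cells <- fake_cells(list(EU = g1, PTU = g2))
  cmp <- compare_groups(cells, metrics = "mean_span")
  p_t <- t.test(g1, g2, var.equal = TRUE)$p.value
  expect_equal(cmp$metrics$mean_span$tukey$p_adj, p_t, tolerance = 1e-6)
})

test_that("ANOVA F is invariant under shift and scale of the data", {
  set.seed(45)
  vals <- list(EU = rnorm(6, 5), PTU = rnorm(6, 6), T3 = rnorm(6, 7))
  f0 <- compare_groups(fake_cells(vals),
                       metrics = "mean_span")$metrics$mean_span$F
  shifted <- lapply(vals, function(v) v + 100)
  scaled <- lapply(vals, function(v) v * 37)
  expect_equal(compare_groups(fake_cells(shifted),
                              metrics = "mean_span")$metrics$mean_span$F, f0,
               tolerance = 1e-9)
  expect_equal(compare_groups(fake_cells(scaled),
                              metrics = "mean_span")$metrics$mean_span$F, f0,
               tolerance = 1e-9)
})

test_that("the extreme pair has the smallest Tukey p when means are ordered", {
  set.seed(46)
  noise <- rnorm(8, 0, 0.5)
  cells <- fake_cells(list(EU = 1 + noise, PTU = 3 + noise, T3 = 6 + noise))
  tk <- compare_groups(cells, metrics = "mean_span")$metrics$mean_span$tukey
  extreme <- tk$p_adj[tk$pair == "T3-EU"]
  expect_true(all(extreme <= tk$p_adj + 1e-12))
})

test_that("animal-level comparison first averages cells within animal", {
  cells <- fake_cells(list(EU = c(1, 2, 3, 4), PTU = c(5, 6, 7, 8)))
  cells$animal <- rep(c("a1", "a1", "a2", "a2", "b1", "b1", "b2", "b2"))
  cmp <- compare_groups(cells, metrics = "mean_span", level = "animal")
  gs <- cmp$metrics$mean_span$groups
  expect_equal(gs$n, c(2, 2))
  expect_equal(gs$mean, c(mean(c(1.5, 3.5)), mean(c(5.5, 7.5))))

  ## welch option adds a p per pair
  cmpw <- compare_groups(cells, metrics = "mean_span", welch = TRUE)
  expect_true("p_welch" %in% names(cmpw$metrics$mean_span$tukey))
})
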