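test_that("dbscan_labels matches the textbook cases", {
  expect_equal(dbscan_labels(matrix(numeric(), 0, 2), 100, 10), integer(0))

  ## three well-separated blobs: 3 clusters, no noise
  blobs <- make_blobs(rbind(c(0, 0), c(2000, 0), c(0, 2000)),
                      n_per = 20, sd = 10, seed = 2)
  lab <- dbscan_labels(blobs$pts, eps = 100, min_pts = 10)
  expect_equal(sort(unique(lab)), 0:2)
  expect_true(same_partition(lab, blobs$membership - 1L))

  ## 9 coincident points below the core threshold are all noise
  nine <- matrix(rep(c(5, 5), each = 9), 9, 2)
  expect_equal(dbscan_labels(nine, 100, 10), rep(-1L, 9))
  ## ... and 10 coincident points are one cluster
  ten <- matrix(rep(c(5, 5), each = 10), 10, 2)
  expect_equal(dbscan_labels(ten, 100, 10), rep(0L, 10))
})

test_that("dbscan_labels equals the brute-force density-reachability oracle", {
  set.seed(42)
  for (rep_i in 1:25) {
    n <- sample(20:250, 1)
    d <- sample(2:3, 1)
    ## mixture of blobs and uniform background to exercise border cases
    k <- sample(1:5, 1)
    centers <- matrix(runif(k * d, 0, 2000), k, d)
    blobs <- do.call(rbind, lapply(seq_len(k), function(i) {
      m <- sample(5:30, 1)
      matrix(rnorm(m * d, 0, 40), m, d) +
        matrix(centers[i, ], m, d, byrow = TRUE)
    }))
    bg <- matrix(runif(max(0, n - nrow(blobs)) * d, 0, 2000),
                 max(0, n - nrow(blobs)), d)
    pts <- rbind(blobs, bg)
    eps <- runif(1, 30, 150)
    mp <- sample(3:12, 1)
    expect_identical(dbscan_labels(pts, eps, mp),
                     oracle_dbscan(pts, eps, mp))
  }
})

test_that("dbscan partition is invariant under point permutation", {
  set.seed(9)
  pts <- rbind(make_blobs(rbind(c(0, 0), c(600, 0)), 15, 30, seed = 4)$pts,
               matrix(runif(60, 0, 1500), 30, 2))
  lab <- dbscan_labels(pts, 80, 8)
  for (i in 1:5) {
    perm <- sample(nrow(pts))
    lab_p <- dbscan_labels(pts[perm, ], 80, 8)
    expect_true(same_partition(lab_p, lab[perm]))
  }
})

test_that("increasing eps never increases the noise count", {
  set.seed(10)
  pts <- matrix(runif(400, 0, 2000), 200, 2)
  noise <- vapply(c(20, 50, 100, 200, 400),
                  function(e) sum(dbscan_labels(pts, e, 5) == -1L),
                  numeric(1))
  expect_true(all(diff(noise) <= 0))
})

test_that("span, centroid and hull match their oracles", {
  expect_equal(cluster_span(rbind(c(0, 0), c(0, 100))), 100)
  expect_equal(cluster_span(matrix(c(1, 2), 1, 2)), 0)
  expect_error(cluster_span(matrix(numeric(), 0, 2)), "empty")

  expect_equal(cluster_centroid(rbind(c(0, 0), c(100, 0))), c(50, 0))
  sym <- rbind(c(1, 2), c(-1, -2), c(3, -4), c(-3, 4))
  expect_equal(cluster_centroid(sym), c(0, 0))

  set.seed(13)
  for (d in 2:3) {
    pts <- matrix(rnorm(50 * d, 0, 100), 50, d)
    expect_equal(cluster_span(pts), oracle_span(pts), tolerance = 1e-12)
    expect_equal(cluster_centroid(pts), colMeans(pts), tolerance = 1e-9)
  }

  ## hull: unit square scaled to 100 nm; collinear points are degenerate
  sq <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100), c(50, 50))
  expect_equal(cluster_hull(sq), 10000)
  expect_equal(cluster_hull(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)

  ## 3-D: known tetrahedron, coplanar degenerate, random vs facet oracle
  tet <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
  expect_equal(cluster_hull(tet), 1e6 / 6, tolerance = 1e-9)
  plane <- cbind(matrix(runif(20, 0, 100), 10, 2), 0)
  expect_equal(cluster_hull(plane), 0)
  set.seed(14)
  for (i in 1:8) {
    pts <- matrix(rnorm(3 * sample(10:30, 1), 0, 100), ncol = 3)
    expect_equal(cluster_hull(pts), oracle_hull_volume(pts),
                 tolerance = 1e-6)
  }
})

test_that("cube hull volume is exact and unaffected by interior points", {
  cube <- as.matrix(expand.grid(c(0, 200), c(0, 200), c(0, 200)))
  set.seed(15)
  inner <- matrix(runif(90, 1, 199), 30, 3)
  expect_equal(cluster_hull(rbind(cube, inner)), 200^3, tolerance = 1e-9)
})

test_that("build_clusters applies span and count constraints", {
  ## a 60-point blob with ~200 nm footprint survives
  set.seed(16)
  blob <- matrix(rnorm(120, 0, 50), 60, 2)
  cs <- build_clusters(ref_table(blob))
  expect_equal(nrow(cs$clusters), 1)
  expect_equal(cs$clusters$n_locs, 60)
  expect_equal(cs$clusters$span, oracle_span(blob), tolerance = 1e-12)
  expect_true(cs$clusters$span >= 50 && cs$clusters$span <= 800)

  ## 12 coincident points: span 0 < 50 -> discarded
  co <- matrix(rep(c(10, 10), each = 12), 12, 2)
  cs <- build_clusters(ref_table(co))
  expect_equal(nrow(cs$clusters), 0)
  expect_equal(cs$n_clustered_locs, 0)

  ## a 1,200-member 3-D candidate dies under the 1,000-loc cap
  set.seed(17)
  big <- matrix(rnorm(3600, 0, 80), 1200, 3)
  cs3 <- build_clusters(ref_table(big), cluster_params_default(3))
  expect_equal(nrow(cs3$clusters), 0)
  ## ... but survives without the cap
  cs3b <- build_clusters(ref_table(big), cluster_params(max_locs = Inf))
  expect_equal(nrow(cs3b$clusters), 1)

  ## partner-channel rows are rejected
  expect_error(build_clusters(tiny_table()), "partner")
})

test_that("small-cluster mode retains only 4-9 localization clusters", {
  set.seed(18)
  mk_blob <- function(n, cx) matrix(rnorm(2 * n, 0, 20), n, 2) +
    matrix(c(cx, 0), n, 2, byrow = TRUE)
  pts <- rbind(mk_blob(5, 0), mk_blob(8, 3000), mk_blob(30, 6000))
  cs <- build_clusters(ref_table(pts), cluster_params(small_mode = TRUE))
  expect_equal(sort(cs$clusters$n_locs), c(5, 8))
  ## default pass sees only the large one
  cs_def <- build_clusters(ref_table(pts))
  expect_equal(cs_def$clusters$n_locs, 30)
})

test_that("retained clusters satisfy the hull/span geometry invariants", {
  set.seed(19)
  sim <- generate_roi(small_config(), seed = 5)
  cs <- build_clusters(channel_table(sim$table, "reference"))
  expect_gt(nrow(cs$clusters), 3)
  cc <- as.matrix(
    as.data.frame(channel_table(sim$table, "reference"))[, c("x", "y")])
  for (i in seq_len(nrow(cs$clusters))) {
    pts <- cc[cs$members[[i]], , drop = FALSE]
    span <- cs$clusters$span[i]
    ## hull vertices' diameter equals the span
    h <- chull(pts)
    expect_equal(oracle_span(pts[h, , drop = FALSE]), span,
                 tolerance = 1e-9)
    ## hull area bounded by the disk with the span as diameter
    expect_lte(cs$clusters$hull_measure[i], pi * (span / 2)^2 + 1e-9)
    ## centroid inside the members' bounding box
    expect_true(cs$clusters$cx[i] >= min(pts[, 1]) &&
                cs$clusters$cx[i] <= max(pts[, 1]))
  }
  ## conservation
  expect_equal(cs$n_clustered_locs, sum(cs$clusters$n_locs))
  expect_lte(cs$n_clustered_locs, cs$n_input_locs)
})

test_that("planted well-separated clusters are recovered exactly", {
  set.seed(20)
  centers <- as.matrix(expand.grid(seq(500, 6500, by = 1500),
                                   seq(500, 6500, by = 1500)))
  blobs <- make_blobs(centers, n_per = 25, sd = 30, seed = 20)
  cs <- build_clusters(ref_table(blobs$pts))
  expect_equal(nrow(cs$clusters), nrow(centers))
  cen <- cluster_centroids(cs)
  for (i in seq_len(nrow(centers))) {
    dists <- sqrt(rowSums((cen - matrix(centers[i, ], nrow(cen), 2,
                                        byrow = TRUE))^2))
    expect_lt(min(dists), 3 * 30 / sqrt(25))
  }
})
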