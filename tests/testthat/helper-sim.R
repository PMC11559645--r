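## Small fixtures built in code.

## a tiny two-channel table with known coordinates
tiny_table <- function(dim3 = FALSE) {
  cc <- cbind(x = c(100, 200, 300, 4000),
              y = c(100, 150, 120, 4000))
  if (dim3) cc <- cbind(cc, z = c(50, 60, 70, 800))
  loc_table(cc, channel = c("RyR2", "RyR2", "Jph2", "Jph2"),
            channels = c(reference = "RyR2", partner = "Jph2"),
            frame = 1:4, fit_p = c(0.9, 0.5, 0.3, 0.1),
            metadata = list(cell = "c1", animal = "a1", group = "EU"))
}

## random table for round-trip / property tests
random_table <- function(n = 200, dim3 = FALSE, seed = 1) {
  set.seed(seed)
  d <- if (dim3) 3 else 2
  cc <- matrix(runif(n * d, 0, 10000), n, d)
  loc_table(cc, channel = sample(c("RyR2", "Jph2"), n, replace = TRUE),
            channels = c(reference = "RyR2", partner = "Jph2"),
            frame = sample.int(5000, n, replace = TRUE),
            fit_p = runif(n))
}

## isotropic Gaussian blobs at given centers; returns list(pts, membership)
make_blobs <- function(centers, n_per = 20, sd = 10, seed = 1, dim3 = FALSE) {
  set.seed(seed)
  centers <- as.matrix(centers)
  d <- ncol(centers)
  pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * d, 0, sd), n_per, d) +
      matrix(centers[i, ], n_per, d, byrow = TRUE)
  }))
  list(pts = pts, membership = rep(seq_len(nrow(centers)), each = n_per))
}

## cluster_set stub with given centroids (spatial stats only read centroids
## and n_locs)
stub_clusters <- function(cen, n_locs = NULL) {
  cen <- as.matrix(cen)
  d <- ncol(cen)
  if (is.null(n_locs)) n_locs <- rep(20, nrow(cen))
  df <- data.frame(id = seq_len(nrow(cen)), label = seq_len(nrow(cen)) - 1,
                   n_locs = n_locs, cx = cen[, 1], cy = cen[, 2])
  if (d == 3) df$cz <- cen[, 3]
  df$span <- 100; df$hull_measure <- 1
  structure(list(clusters = df[, c("id", "label", "n_locs",
                                   if (d == 3) c("cx", "cy", "cz")
                                   else c("cx", "cy"),
                                   "span", "hull_measure")],
                 members = list(), labels = integer(0),
                 n_input_locs = sum(n_locs), n_clustered_locs = sum(n_locs),
                 dimensionality = d, params = cluster_params()),
            class = "cluster_set")
}

## reference-only loc_table from a coordinate matrix
ref_table <- function(pts, metadata = list()) {
  loc_table(pts, channel = rep("RyR2", nrow(pts)),
            channels = c(reference = "RyR2", partner = "Jph2"),
            metadata = metadata)
}

## a small, fast generator config (ROI 8 x 8 um); ... overrides defaults
small_config <- function(..., dim3 = FALSE) {
  base <- if (dim3) {
    list(dimensionality = 3,
         roi = roi_spec(c(0, 0, 0), c(8000, 8000, 1500)),
         margin = c(900, 900, 150),
         within_row_gap = list(mean = 600, sd = 100, min = 350),
         locs_per_cluster = list(meanlog = log(25), sdlog = 0.8,
                                 min = 10, max = 1000),
         cluster_radius = list(mean = 80, sd = 10, min = 30, max = 200,
                               n_ref = 30),
         partner_mean_per_cluster = 8,
         partner_background_density = 5e-9,
         reference_background_density = 1e-8)
  } else {
    list(dimensionality = 2,
         roi = roi_spec(c(0, 0), c(8000, 8000)),
         margin = c(900, 900),
         within_row_gap = list(mean = 600, sd = 100, min = 350),
         locs_per_cluster = list(meanlog = log(25), sdlog = 0.8,
                                 min = 10, max = 400),
         cluster_radius = list(mean = 70, sd = 10, min = 30, max = 200,
                               n_ref = 30),
         partner_mean_per_cluster = 10,
         partner_background_density = 3e-5,
         reference_background_density = 2e-5)
  }
  args <- utils::modifyList(base, list(...))
  do.call(generator_config, args)
}
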