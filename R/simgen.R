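## Synthetic two-channel SMLM scene generator with planted dyad geometry.
##
## The generator emulates what the real data look like at the level the
## analysis sees: RyR2 clusters laid out in rows along sarcomere z-lines
## (~1.85 um period), heavy-tailed localization counts per cluster,
## localization-precision noise, partner (Jph2/CaV1.2) localizations
## concentrated near cluster anchors plus diffuse background, a planted
## fraction of partner-free clusters, and disease presets with cluster
## deletion, row disarray and partner loss. Every emitted localization is
## tracked in a ground-truth membership map for recovery tests.

#' Synthetic scene configuration
#'
#' All lengths in nm, densities per nm^2 (2-D) or nm^3 (3-D).
#'
#' @param dimensionality 2 or 3.
#' @param roi an [roi_spec()]; default geometry per dimensionality.
#' @param margin per-axis clearance inside which no anchor is planted
#'   (keeps edge bias out of NND and colocalization statistics).
#' @param row_spacing z-line period along the cell's long axis (x).
#' @param row_jitter_sd lateral (off-row) anchor jitter SD.
#' @param off_row_fraction fraction of anchors relocated uniformly
#'   (row disarray).
#' @param within_row_gap list(mean, sd, min): truncated-normal gaps between
#'   consecutive anchors along a row.
#' @param cluster_deletion_prob probability an anchor is deleted (cluster
#'   loss in disease).
#' @param locs_per_cluster list(meanlog, sdlog, min, max): truncated
#'   lognormal localization count per regular cluster.
#' @param small_cluster_fraction fraction of anchors that are small
#'   clusters with 4-9 localizations (uniform).
#' @param cluster_radius list(mean, sd, min, max, n_ref): truncated-normal
#'   base footprint radius for a cluster of `n_ref` localizations; a
#'   cluster of n localizations gets radius `base * (n/n_ref)^(1/2)` in 2-D
#'   or `(n/n_ref)^(1/3)` in 3-D (constant packing density up to jitter).
#' @param axial_flattening 3-D footprint axial semi-axis / lateral.
#' @param loc_precision_sd c(lateral, axial) localization noise SD.
#' @param partner_mean_per_cluster Poisson mean partner localizations per
#'   non-empty cluster.
#' @param partner_scatter_sd SD of partner scatter about the anchor.
#' @param planted_empty_prob probability a cluster is planted partner-free.
#' @param empty_exclusion if `TRUE`, partner background is excluded from a
#'   `partner_exclusion_radius` zone around planted-empty anchors
#'   (a partner-free cluster is modeled as locally depleted of partner
#'   protein, not merely unlucky).
#' @param partner_exclusion_radius radius of that exclusion zone.
#' @param partner_background_density uniform partner background density.
#' @param reference_background_density uniform unclustered reference
#'   density.
#' @param qc_stress_fraction fraction of partner localizations given
#'   fit_p below 0.25 (exercises the QC filter; 0 in the standard presets,
#'   where all fit_p are drawn in the passing interval).
#' @param seed default seed used by [generate_roi()].
#' @return A `generator_config` list.
#' @export
generator_config <- function(dimensionality = 2,
                             roi = roi_spec_default(dimensionality),
                             margin = if (dimensionality == 3)
                               c(900, 900, 150) else c(900, 900),
                             row_spacing = 1850,
                             row_jitter_sd = 40,
                             off_row_fraction = 0,
                             within_row_gap = list(mean = 600, sd = 130,
                                                   min = 300),
                             cluster_deletion_prob = 0,
                             locs_per_cluster = list(meanlog = log(30),
                                                     sdlog = 1.3,
                                                     min = 10, max = 1500),
                             small_cluster_fraction = 0,
                             cluster_radius = list(mean = 95, sd = 20,
                                                   min = 40, max = 350,
                                                   n_ref = 30),
                             axial_flattening = 0.6,
                             loc_precision_sd = c(lateral = 20, axial = 50),
                             partner_mean_per_cluster = 18,
                             partner_scatter_sd = 90,
                             planted_empty_prob = 0.06,
                             empty_exclusion = TRUE,
                             partner_exclusion_radius = 240,
                             partner_background_density = 6e-5,
                             reference_background_density = 3.8e-5,
                             qc_stress_fraction = 0,
                             seed = 1L) {
  .assert(dimensionality %in% c(2, 3), "dimensionality must be 2 or 3")
  .assert(roi$dimensionality == dimensionality, "roi dimensionality mismatch")
  margin <- rep(margin, length.out = dimensionality)
  .assert(all(margin >= 0) && all(roi$extent > 2 * margin),
          "infeasible geometry: margin must be < half the ROI extent")
  probs <- c(off_row_fraction, cluster_deletion_prob,
             small_cluster_fraction, planted_empty_prob, qc_stress_fraction)
  .assert(all(probs >= 0 & probs <= 1), "probabilities must lie in [0, 1]")
  .assert(partner_background_density >= 0 &&
            reference_background_density >= 0, "densities must be >= 0")
  .assert(within_row_gap$min >= 0 && within_row_gap$mean > 0 &&
            within_row_gap$sd >= 0, "invalid within_row_gap")
  .assert(locs_per_cluster$min >= 1 &&
            locs_per_cluster$min < locs_per_cluster$max,
          "locs_per_cluster truncation bounds must be ordered")
  .assert(cluster_radius$min > 0 && cluster_radius$min < cluster_radius$max,
          "cluster_radius truncation bounds must be ordered")
  structure(list(dimensionality = dimensionality, roi = roi, margin = margin,
                 row_spacing = row_spacing, row_jitter_sd = row_jitter_sd,
                 off_row_fraction = off_row_fraction,
                 within_row_gap = within_row_gap,
                 cluster_deletion_prob = cluster_deletion_prob,
                 locs_per_cluster = locs_per_cluster,
                 small_cluster_fraction = small_cluster_fraction,
                 cluster_radius = cluster_radius,
                 axial_flattening = axial_flattening,
                 loc_precision_sd = loc_precision_sd,
                 partner_mean_per_cluster = partner_mean_per_cluster,
                 partner_scatter_sd = partner_scatter_sd,
                 planted_empty_prob = planted_empty_prob,
                 empty_exclusion = isTRUE(empty_exclusion),
                 partner_exclusion_radius = partner_exclusion_radius,
                 partner_background_density = partner_background_density,
                 reference_background_density = reference_background_density,
                 qc_stress_fraction = qc_stress_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## truncated draws by rejection (truncation mass is small in all presets)
.rtrunc <- function(n, draw, lo, hi, max_rounds = 200) {
  out <- numeric(0)
  rounds <- 0
  batch <- max(n, 16L)
  while (length(out) < n && rounds < max_rounds) {
    v <- draw(batch)
    out <- c(out, v[v >= lo & v <= hi])
    batch <- min(2L * batch, 65536L)   # adapt to low acceptance rates
    rounds <- rounds + 1
  }
  .assert(length(out) >= n,
          "truncated sampler failed to converge (acceptance region too small)")
  out[seq_len(n)]
}

## anchor layout: rows of anchors along y at x = phase + k*row_spacing
.plant_anchors <- function(config) {
  d <- config$dimensionality
  ext <- config$roi$extent
  m <- config$margin
  gap <- config$within_row_gap
  phase <- runif(1, 0, config$row_spacing)
  xs <- seq(phase, ext[1] - m[1], by = config$row_spacing)
  xs <- xs[xs >= m[1]]
  anchors <- list()
  for (rx in xs) {
    y <- m[2] + runif(1, 0, gap$mean)
    ys <- numeric(0)
    while (y < ext[2] - m[2]) {
      ys <- c(ys, y)
      y <- y + .rtrunc(1, function(k) rnorm(k, gap$mean, gap$sd),
                       gap$min, Inf)
    }
    if (!length(ys)) next
    ax <- rx + rnorm(length(ys), 0, config$row_jitter_sd)
    a <- cbind(ax, ys)
    if (d == 3) a <- cbind(a, runif(length(ys), m[3], ext[3] - m[3]))
    anchors[[length(anchors) + 1L]] <- a
  }
  A <- do.call(rbind, anchors)
  if (is.null(A)) A <- matrix(numeric(), 0, d)
  ## row disarray: relocate a fraction uniformly inside ROI-minus-margin
  if (nrow(A) && config$off_row_fraction > 0) {
    off <- runif(nrow(A)) < config$off_row_fraction
    for (a in seq_len(d)) {
      A[off, a] <- runif(sum(off), m[a], ext[a] - m[a])
    }
  }
  ## cluster deletion
  if (nrow(A) && config$cluster_deletion_prob > 0) {
    A <- A[runif(nrow(A)) >= config$cluster_deletion_prob, , drop = FALSE]
  }
  ## clamp any jittered anchor into the margin box
  for (a in seq_len(d)) A[, a] <- pmin(pmax(A[, a], m[a]), ext[a] - m[a])
  A
}

## uniform scatter in a disk (2-D) or flattened ellipsoid (3-D)
.scatter_members <- function(n, center, radius, config) {
  d <- config$dimensionality
  if (d == 2) {
    r <- radius * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    pts <- cbind(center[1] + r * cos(th), center[2] + r * sin(th))
  } else {
    g <- matrix(rnorm(3 * n), n, 3)
    g <- g / sqrt(rowSums(g * g))
    u <- runif(n)^(1 / 3)
    semi <- c(radius, radius, radius * config$axial_flattening)
    pts <- sweep(g * u, 2, semi, "*")
    pts <- sweep(pts, 2, center, "+")
  }
  sdv <- if (d == 2) rep(config$loc_precision_sd[["lateral"]], 2)
         else c(rep(config$loc_precision_sd[["lateral"]], 2),
                config$loc_precision_sd[["axial"]])
  pts + matrix(rnorm(n * d, 0, rep(sdv, each = n)), n, d)
}

.inside_roi <- function(pts, ext) {
  keep <- rep(TRUE, nrow(pts))
  for (a in seq_len(ncol(pts))) {
    keep <- keep & pts[, a] >= 0 & pts[, a] < ext[a]
  }
  keep
}

#' Generate one synthetic two-channel ROI with ground truth
#'
#' Deterministic given `seed`: all randomness flows from one seed through
#' per-stage substreams (layout, cluster scatter, backgrounds, partner,
#' shuffle), so stages are individually reproducible.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (default `config$seed`).
#' @param metadata named list (cell, animal, group, ...) stored in the
#'   table.
#' @param channels channel labels, default
#'   `c(reference = "RyR2", partner = "Jph2")`.
#' @return List with `table` (a [loc_table()], rows shuffled) and `truth`:
#'   `anchors` (planted cluster centers), `true_counts`, `small_flags`,
#'   `empty_flags`, and `membership` — for every table row, the planted
#'   cluster index (1-based) or 0 for background.
#' @export
generate_roi <- function(config, seed = config$seed, metadata = list(),
                         channels = c(reference = "RyR2",
                                      partner = "Jph2")) {
  d <- config$dimensionality
  ext <- config$roi$extent
  lpc <- config$locs_per_cluster
  cr <- config$cluster_radius

  anchors <- .with_seed(seed, "layout", .plant_anchors(config))
  k <- nrow(anchors)

  flags <- .with_seed(seed, "flags", {
    small <- runif(k) < config$small_cluster_fraction
    empty <- runif(k) < config$planted_empty_prob
    list(small = small, empty = empty)
  })

  clus <- .with_seed(seed, "clusters", {
    n_true <- integer(k)
    n_true[flags$small] <- sample(4:9, sum(flags$small), replace = TRUE)
    n_reg <- sum(!flags$small)
    if (n_reg) {
      n_true[!flags$small] <- as.integer(round(.rtrunc(
        n_reg, function(m) rlnorm(m, lpc$meanlog, lpc$sdlog),
        lpc$min, lpc$max)))
    }
    base_r <- .rtrunc(k, function(m) rnorm(m, cr$mean, cr$sd), cr$min, cr$max)
    radius <- base_r * (n_true / cr$n_ref)^(1 / d)
    pts <- vector("list", k)
    for (i in seq_len(k)) {
      pts[[i]] <- .scatter_members(n_true[i], anchors[i, ], radius[i], config)
    }
    list(n_true = n_true, pts = pts)
  })

  ref_pts <- do.call(rbind, c(clus$pts, list(matrix(numeric(), 0, d))))
  ref_member <- rep(seq_len(k), clus$n_true)
  keep <- .inside_roi(ref_pts, ext)
  ref_pts <- ref_pts[keep, , drop = FALSE]
  ref_member <- ref_member[keep]

  ref_bg <- .with_seed(seed, "refbg", {
    nb <- rpois(1, config$reference_background_density * config$roi$measure)
    matrix(runif(nb * d, 0, rep(ext, each = nb)), nb, d)
  })

  partner <- .with_seed(seed, "partner", {
    pts <- vector("list", k)
    for (i in seq_len(k)) {
      if (flags$empty[i]) { pts[[i]] <- matrix(numeric(), 0, d); next }
      np <- rpois(1, config$partner_mean_per_cluster)
      p <- matrix(rnorm(np * d, 0, config$partner_scatter_sd), np, d)
      pts[[i]] <- sweep(p, 2, anchors[i, ], "+")
    }
    pts
  })
  par_pts <- do.call(rbind, c(partner, list(matrix(numeric(), 0, d))))
  par_member <- rep(seq_len(k), vapply(partner, nrow, integer(1)))
  keep <- .inside_roi(par_pts, ext)
  par_pts <- par_pts[keep, , drop = FALSE]
  par_member <- par_member[keep]

  par_bg <- .with_seed(seed, "partnerbg", {
    nb <- rpois(1, config$partner_background_density * config$roi$measure)
    b <- matrix(runif(nb * d, 0, rep(ext, each = nb)), nb, d)
    if (config$empty_exclusion && any(flags$empty) && nb > 0) {
      ea <- anchors[flags$empty, , drop = FALSE]
      d2 <- .cross_dist2(b, ea)
      b <- b[apply(d2, 1, min) > config$partner_exclusion_radius^2, ,
             drop = FALSE]
    }
    b
  })

  coords <- rbind(ref_pts, ref_bg, par_pts, par_bg)
  channel <- c(rep(channels[["reference"]], nrow(ref_pts) + nrow(ref_bg)),
               rep(channels[["partner"]], nrow(par_pts) + nrow(par_bg)))
  membership <- c(ref_member, rep(0L, nrow(ref_bg)),
                  par_member, rep(0L, nrow(par_bg)))
  n <- nrow(coords)

  aux <- .with_seed(seed, "aux", {
    fit_p <- runif(n, 0.25, 1)
    is_par <- channel == channels[["partner"]]
    if (config$qc_stress_fraction > 0 && any(is_par)) {
      stress <- is_par & runif(n) < config$qc_stress_fraction
      fit_p[stress] <- runif(sum(stress), 0, 0.25 - 1e-9)
    }
    list(fit_p = fit_p, frame = sample.int(5000, n, replace = TRUE),
         ord = sample.int(n))
  })

  ord <- aux$ord
  table <- loc_table(coords[ord, , drop = FALSE], channel[ord],
                     channels = channels, frame = aux$frame[ord],
                     fit_p = aux$fit_p[ord], metadata = metadata)
  truth <- list(anchors = anchors, true_counts = clus$n_true,
                small_flags = flags$small, empty_flags = flags$empty,
                membership = membership[ord])
  list(table = table, truth = truth)
}

#' Write a simulated ROI to disk
#'
#' Writes the localization table as canonical CSV (`localizations.csv`),
#' the ground truth as a localization-to-planted-cluster map
#' (`ground_truth.csv`: row id, channel, planted cluster id or 0 for
#' background) plus per-anchor truth (`anchors.csv`), and a JSON scene
#' manifest (`manifest.json`) holding the generator configuration and
#' scene counts.
#'
#' @param sim a list with `table` and `truth` as returned by
#'   [generate_roi()].
#' @param dir output directory (created if missing).
#' @param config the [generator_config()] used (stored in the manifest);
#'   optional.
#' @return Invisibly, the directory path.
#' @export
write_simulation <- function(sim, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_localizations(sim$table, file.path(dir, "localizations.csv"))
  gt <- data.frame(row = seq_len(nrow(sim$table)),
                   channel = sim$table$channel,
                   planted_cluster = sim$truth$membership)
  write.csv(gt, file.path(dir, "ground_truth.csv"), row.names = FALSE)
  k <- nrow(sim$truth$anchors)
  anchors <- as.data.frame(sim$truth$anchors)
  names(anchors) <- c("x_nm", "y_nm", "z_nm")[seq_len(ncol(anchors))]
  anchors <- cbind(data.frame(cluster = seq_len(k)), anchors,
                   data.frame(true_count = sim$truth$true_counts,
                              small = sim$truth$small_flags,
                              planted_empty = sim$truth$empty_flags))
  write.csv(anchors, file.path(dir, "anchors.csv"), row.names = FALSE)
  manifest <- list(
    n_localizations = nrow(sim$table),
    n_planted_clusters = k,
    n_planted_empty = sum(sim$truth$empty_flags),
    n_planted_small = sum(sim$truth$small_flags),
    metadata = attr(sim$table, "metadata"),
    config = if (!is.null(config)) config_to_list(config) else NULL)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Simulate a multi-cell experiment for one condition
#'
#' Generates `n_cells * rois_per_cell` ROIs, assigning cells round-robin to
#' `n_animals` animals. Each ROI gets its own substream seed, so the
#' experiment is deterministic given `seed`.
#'
#' @param config a [generator_config()] (e.g. from [preset()]).
#' @param n_cells number of cells.
#' @param rois_per_cell ROIs per cell (default 2, as in the standard
#'   protocol).
#' @param seed experiment seed.
#' @param group group label stored in each table's metadata.
#' @param n_animals number of animals the cells are spread over.
#' @param channels channel labels, see [generate_roi()].
#' @return List of ROI records: each has `table`, `truth`, `cell`,
#'   `animal`, `roi`.
#' @export
simulate_experiment <- function(config, n_cells, rois_per_cell = 2,
                                seed = 1L, group = "EU", n_animals = 5,
                                channels = c(reference = "RyR2",
                                             partner = "Jph2")) {
  out <- list()
  for (ci in seq_len(n_cells)) {
    animal <- sprintf("%s_a%d", group, ((ci - 1L) %% n_animals) + 1L)
    cell <- sprintf("%s_c%d", group, ci)
    for (ri in seq_len(rois_per_cell)) {
      rseed <- .substream_seed(seed, sprintf("cell%d_roi%d", ci, ri))
      md <- list(cell = cell, animal = animal, group = group)
      sim <- generate_roi(config, seed = rseed, metadata = md,
                          channels = channels)
      out[[length(out) + 1L]] <- list(table = sim$table, truth = sim$truth,
                                      cell = cell, animal = animal,
                                      roi = sprintf("%s_r%d", cell, ri))
    }
  }
  out
}
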