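## End-to-end drivers: single-ROI analysis, preset-level summary
## statistics, and the config-driven pipeline with on-disk artifacts.

#' Analyze one ROI table end to end
#'
#' Applies the fit-quality filter, splits channels, clusters the reference
#' channel, counts partner localizations around each cluster centroid,
#' computes NNDs (when at least two clusters were retained) and assembles
#' the per-ROI summary.
#'
#' @param table a two-channel [loc_table()] already cropped to the ROI.
#' @param params a [cluster_params()]; default chosen by dimensionality.
#' @param coloc a [coloc_params()].
#' @param qc a [qc_params()], or `NULL` to skip quality filtering.
#' @param roi_id identifier stored in the summary row.
#' @return List with `clusters`, `coloc`, `nnd` (or `NULL`), `summary`,
#'   and the filtered `table`.
#' @export
analyze_roi <- function(table, params = NULL, coloc = coloc_params(),
                        qc = qc_params(), roi_id = NA) {
  if (!is.null(qc)) table <- filter_by_fit_quality(table, qc)
  if (is.null(params)) params <- cluster_params_default(.loc_dim(table))
  ref <- channel_table(table, "reference")
  par <- channel_table(table, "partner")
  clusters <- build_clusters(ref, params)
  cres <- count_partners(clusters, par, coloc)
  nres <- if (nrow(clusters$clusters) >= 2)
    nearest_neighbor_distances(clusters) else NULL
  summ <- summarize_roi(clusters, cres, nres, table, roi_id = roi_id)
  list(clusters = clusters, coloc = cres, nnd = nres, summary = summ,
       table = table)
}

#' Pipeline summary statistics of a generator preset
#'
#' Generates a synthetic experiment from `config`, runs the default
#' clustering pass on every ROI (and optionally the min-4 pass) and pools
#' the statistics the condition presets are benchmarked on.
#'
#' @param config a [generator_config()].
#' @param n_cells,rois_per_cell,seed,group passed to
#'   [simulate_experiment()].
#' @param include_small if `TRUE`, also runs the `min_pts = 4` pass and
#'   reports `small_share`.
#' @return A list: `mean_span`, `mean_locs` (pooled over retained
#'   clusters), `mean_nnd` (pooled per-cluster NNDs), `median_nnd_cells`
#'   (median over cells of the cell-averaged per-ROI median NND),
#'   `empty_fraction`, `clustered_fraction`, `partner_in_search`
#'   (means over ROIs), `low_size_share` (% clusters with < 50
#'   localizations, pooled), `mean_cluster_count` (per ROI), and
#'   `small_share` when requested.
#' @export
preset_summary_stats <- function(config, n_cells = 10, rois_per_cell = 2,
                                 seed = 1L, group = "EU",
                                 include_small = FALSE) {
  sims <- simulate_experiment(config, n_cells = n_cells,
                              rois_per_cell = rois_per_cell, seed = seed,
                              group = group)
  spans <- numeric(0); locs <- numeric(0); nnds <- numeric(0)
  empty <- numeric(0); clfrac <- numeric(0); pis <- numeric(0)
  counts <- numeric(0)
  med_roi <- numeric(0); cell_of_roi <- character(0)
  small_n <- 0L; all_n <- 0L
  for (s in sims) {
    res <- analyze_roi(s$table, roi_id = s$roi)
    cl <- res$clusters$clusters
    spans <- c(spans, cl$span)
    locs <- c(locs, cl$n_locs)
    counts <- c(counts, nrow(cl))
    if (!is.null(res$nnd)) {
      nnds <- c(nnds, res$nnd$per_cluster_nnd)
      med_roi <- c(med_roi, res$nnd$median_nnd)
      cell_of_roi <- c(cell_of_roi, s$cell)
    }
    if (isTRUE(res$coloc$defined)) {
      empty <- c(empty, res$coloc$empty_fraction)
      pis <- c(pis, res$coloc$partner_in_search_fraction)
    }
    clfrac <- c(clfrac, res$summary$clustered_fraction)
    if (include_small) {
      p4 <- cluster_params(min_pts = 4,
                           max_locs = if (config$dimensionality == 3)
                             1000 else Inf)
      cs4 <- build_clusters(channel_table(
        filter_by_fit_quality(s$table), "reference"), p4)
      n4 <- cs4$clusters$n_locs
      small_n <- small_n + sum(n4 >= 4 & n4 <= 9)
      all_n <- all_n + length(n4)
    }
  }
  cell_medians <- tapply(med_roi, cell_of_roi, mean)
  out <- list(
    mean_span = mean(spans),
    mean_locs = mean(locs),
    mean_nnd = mean(nnds),
    median_nnd_cells = median(as.numeric(cell_medians)),
    empty_fraction = mean(empty),
    clustered_fraction = mean(clfrac, na.rm = TRUE),
    partner_in_search = mean(pis, na.rm = TRUE),
    low_size_share = 100 * mean(locs < 50),
    mean_cluster_count = mean(counts),
    n_clusters = length(locs),
    n_rois = length(sims),
    n_cells = n_cells)
  if (include_small) {
    out$small_share <- if (all_n > 0) 100 * small_n / all_n else NA_real_
    out$n_clusters_min4 <- all_n
  }
  out
}

## ---------------------------------------------------------------------------
## Config-driven pipeline

.log_line <- function(log, fmt, ...) {
  line <- sprintf(fmt, ...)
  message(line)
  c(log, line)
}

#' Run the full analysis pipeline from a run configuration
#'
#' Drives read/generate -> quality filter -> ROI -> cluster -> colocalize
#' -> NND -> bin -> aggregate -> compare, writing tidy CSV/JSON artifacts
#' and a run log to `out_dir`. Re-running with the same resolved
#' configuration and seed reproduces every output file.
#'
#' @param run_config a list, or path to a YAML file, with fields:
#'   \describe{
#'     \item{mode}{`"simulate"` or `"files"`.}
#'     \item{simulate}{for simulate mode: `presets` (named character
#'       vector group -> preset name, or a single name), `n_cells`,
#'       `rois_per_cell` (default 2), `seed`.}
#'     \item{files}{for file mode: `manifest` — a data frame or CSV path
#'       with columns path, cell, animal, group; `roi` — `"full"` (each
#'       file is one ROI) or `"propose"` (place `roi_n` default-geometry
#'       ROIs per file by density grid search with `roi_margin` nm
#'       clearance); `channels` — list(reference =, partner =) channel
#'       labels (default RyR2/Jph2).}
#'     \item{qc}{list(p_min, p_max), optional.}
#'     \item{cluster}{list(eps, min_pts, span_min, span_max, max_locs,
#'       small_mode), optional.}
#'     \item{coloc}{list(radius, unique_assignment), optional.}
#'     \item{bins}{list passed to [bin_spec()], optional.}
#'     \item{level}{`"cell"` (default) or `"animal"` for group stats.}
#'     \item{out_dir}{output directory (created if missing).}
#'   }
#' @return Invisibly, a list with the collected summaries and the paths of
#'   the written artifacts.
#' @export
run_pipeline <- function(run_config) {
  if (is.character(run_config) && length(run_config) == 1) {
    run_config <- yaml::read_yaml(run_config)
  }
  rc <- run_config
  .assert(!is.null(rc$mode) && rc$mode %in% c("simulate", "files"),
          "run config must set mode = 'simulate' or 'files'")
  .assert(!is.null(rc$out_dir), "run config must set out_dir")
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  log <- .log_line(log, "dyadSTORM %s pipeline run, mode=%s",
                   as.character(utils::packageVersion("dyadSTORM")), rc$mode)

  qc <- if (!is.null(rc$qc)) do.call(qc_params, rc$qc) else qc_params()
  cpar_args <- if (!is.null(rc$cluster)) rc$cluster else list()
  copar <- if (!is.null(rc$coloc)) do.call(coloc_params, rc$coloc)
           else coloc_params()
  bins <- if (!is.null(rc$bins)) do.call(bin_spec, rc$bins) else bin_spec()
  level <- if (!is.null(rc$level)) rc$level else "cell"

  rois <- list()   # each: table + ids
  if (rc$mode == "simulate") {
    sm <- rc$simulate
    .assert(!is.null(sm$presets) && !is.null(sm$n_cells) &&
              !is.null(sm$seed), "simulate mode needs presets, n_cells, seed")
    presets <- sm$presets
    if (is.null(names(presets))) names(presets) <- presets
    rpc <- if (!is.null(sm$rois_per_cell)) sm$rois_per_cell else 2
    for (g in names(presets)) {
      cfg <- if (inherits(presets[[g]], "generator_config")) presets[[g]]
             else preset(presets[[g]])
      seed_g <- .substream_seed(sm$seed, g)
      sims <- simulate_experiment(cfg, n_cells = sm$n_cells,
                                  rois_per_cell = rpc, seed = seed_g,
                                  group = g)
      log <- .log_line(log, "simulated %d ROIs for group %s (preset seed %d)",
                       length(sims), g, seed_g)
      rois <- c(rois, sims)
    }
  } else {
    fl <- rc$files
    manifest <- fl$manifest
    if (is.character(manifest)) {
      .assert(file.exists(manifest), "manifest file not found: %s", manifest)
      manifest <- read.csv(manifest, stringsAsFactors = FALSE)
    }
    .assert(all(c("path", "cell", "animal", "group") %in% names(manifest)),
            "manifest needs columns path, cell, animal, group")
    missing <- manifest$path[!file.exists(manifest$path)]
    .assert(length(missing) == 0, "input file not found: %s",
            if (length(missing)) missing[1] else "")
    roi_mode <- if (!is.null(fl$roi)) fl$roi else "full"
    file_channels <- if (!is.null(fl$channels)) {
      c(reference = fl$channels$reference, partner = fl$channels$partner)
    } else c(reference = "RyR2", partner = "Jph2")
    for (i in seq_len(nrow(manifest))) {
      md <- list(cell = manifest$cell[i], animal = manifest$animal[i],
                 group = manifest$group[i])
      tab <- read_localizations(manifest$path[i], channels = file_channels,
                                metadata = md)
      log <- .log_line(log, "read %d localizations from %s", nrow(tab),
                       manifest$path[i])
      if (identical(roi_mode, "full")) {
        rois[[length(rois) + 1L]] <- list(
          table = tab, cell = md$cell, animal = md$animal,
          roi = sprintf("%s_r1", md$cell))
      } else {
        n_roi <- if (!is.null(fl$roi_n)) fl$roi_n else 2
        margin <- if (!is.null(fl$roi_margin)) fl$roi_margin else 0
        tmpl <- roi_spec_default(.loc_dim(tab))
        specs <- propose_rois(tab, tmpl, n = n_roi, margin = margin)
        for (ri in seq_along(specs)) {
          rois[[length(rois) + 1L]] <- list(
            table = crop_roi(tab, specs[[ri]]), cell = md$cell,
            animal = md$animal, roi = sprintf("%s_r%d", md$cell, ri))
        }
      }
    }
  }

  ## per-ROI analysis
  roi_summaries <- list()
  cluster_rows <- list()
  coloc_rows <- list()
  nnd_values <- list()
  for (r in rois) {
    d <- .loc_dim(r$table)
    params <- do.call(cluster_params, c(
      cpar_args,
      if (is.null(cpar_args$max_locs) && d == 3) list(max_locs = 1000)))
    res <- analyze_roi(r$table, params = params, coloc = copar, qc = qc,
                       roi_id = r$roi)
    n_in <- nrow(r$table)
    log <- .log_line(log,
      "ROI %s: %d locs in, %d after QC, %d clusters, %d clustered locs",
      r$roi, n_in, nrow(res$table), nrow(res$clusters$clusters),
      res$clusters$n_clustered_locs)
    if (nrow(res$clusters$clusters) == 0)
      log <- .log_line(log, "WARNING: ROI %s has zero clusters; %s",
                       r$roi, "downstream metrics undefined")
    roi_summaries[[length(roi_summaries) + 1L]] <- res$summary
    cl <- res$clusters$clusters
    if (nrow(cl)) {
      cl$roi <- r$roi
      cl$group <- res$summary$group
      cl$partner_count <- res$coloc$per_cluster_counts
      cl$partner_ratio <- res$coloc$ratio_per_cluster
      cl$nnd <- if (!is.null(res$nnd)) res$nnd$per_cluster_nnd else NA_real_
      cluster_rows[[length(cluster_rows) + 1L]] <- cl
    }
  }
  roi_df <- do.call(rbind, roi_summaries)
  cluster_df <- if (length(cluster_rows)) do.call(rbind, cluster_rows)
                else data.frame()
  cells <- aggregate_cells(roi_df)
  animals <- aggregate_animals(cells)

  ## histograms per group (pooled clusters)
  size_hists <- list()
  nnd_hists <- list()
  if (nrow(cluster_df)) {
    for (g in unique(cluster_df$group)) {
      sub <- cluster_df[cluster_df$group == g, ]
      fake <- list(clusters = sub)   # bin_by_cluster_size reads $clusters
      partner <- list(per_cluster_counts = sub$partner_count)
      nndl <- list(per_cluster_nnd = sub$nnd)
      h <- bin_by_cluster_size(fake, partner = partner,
                               nnd = if (!all(is.na(sub$nnd))) nndl else NULL,
                               spec = bins)
      h$group <- g
      size_hists[[g]] <- h
      vals <- sub$nnd[!is.na(sub$nnd)]
      if (length(vals)) {
        hh <- nnd_frequency_distribution(
          structure(list(per_cluster_nnd = vals), class = "nnd_result"),
          spec = bins)
        hh$group <- g
        nnd_hists[[g]] <- hh
      }
    }
  }

  comparison <- NULL
  grp_sizes <- table(cells$group)
  if (length(grp_sizes) >= 2 && all(grp_sizes >= 2)) {
    comparison <- compare_groups(cells, level = level)
    log <- .log_line(log, "group comparison at %s level over %s",
                     level, paste(names(grp_sizes), collapse = ", "))
  } else {
    log <- .log_line(log, "group comparison skipped (need >= 2 groups with >= 2 observations)")
  }

  ## artifacts
  paths <- list(
    roi = file.path(rc$out_dir, "roi_summaries.csv"),
    cell = file.path(rc$out_dir, "cell_summaries.csv"),
    animal = file.path(rc$out_dir, "animal_summaries.csv"),
    clusters = file.path(rc$out_dir, "clusters.csv"),
    size_hist = file.path(rc$out_dir, "size_histograms.csv"),
    nnd_hist = file.path(rc$out_dir, "nnd_histograms.csv"),
    comparison = file.path(rc$out_dir, "group_comparison.json"),
    log = file.path(rc$out_dir, "run_log.txt"))
  write.csv(roi_df, paths$roi, row.names = FALSE)
  write.csv(cells, paths$cell, row.names = FALSE)
  write.csv(animals, paths$animal, row.names = FALSE)
  write.csv(cluster_df, paths$clusters, row.names = FALSE)
  if (length(size_hists))
    write.csv(do.call(rbind, size_hists), paths$size_hist, row.names = FALSE)
  if (length(nnd_hists))
    write.csv(do.call(rbind, nnd_hists), paths$nnd_hist, row.names = FALSE)
  if (!is.null(comparison)) {
    jsonlite::write_json(
      lapply(comparison$metrics, function(m) {
        list(F = m$F, p = m$p, groups = m$groups, tukey = m$tukey)
      }),
      paths$comparison, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  log <- .log_line(log, "resolved config: %s",
                   jsonlite::toJSON(rc[setdiff(names(rc), "files")],
                                    auto_unbox = TRUE, force = TRUE))
  writeLines(log, paths$log)
  invisible(list(roi_summaries = roi_df, cell_summaries = cells,
                 animal_summaries = animals, clusters = cluster_df,
                 comparison = comparison, paths = paths))
}
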