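## Rolling metrics up the ROI -> cell -> animal -> group hierarchy, plus
## one-way ANOVA with Tukey HSD pairwise group comparisons.

.ROI_METRICS <- c("cluster_count", "mean_locs_per_cluster", "mean_span",
                  "mean_hull_measure", "mean_nnd", "median_nnd",
                  "mean_partner_per_cluster", "empty_fraction",
                  "clustered_fraction", "total_reference_locs",
                  "total_partner_locs")

#' Summarize one ROI
#'
#' Assembles the per-ROI metric vector from the clustering, colocalization
#' and NND results plus the ROI's full two-channel localization table.
#' `clustered_fraction` is 100 * clustered reference localizations / total
#' reference localizations in the ROI. With zero clusters the downstream
#' metrics are `NA`.
#'
#' @param clusters a `cluster_set`.
#' @param coloc a `coloc_result` or `NULL`.
#' @param nnd an `nnd_result` or `NULL`.
#' @param table the ROI's [loc_table()] (both channels), used for totals
#'   and identifiers.
#' @param roi_id optional ROI identifier stored in the summary.
#' @return A one-row data frame (class `roi_summary`) with the metric
#'   vector and cell/animal/group identifiers from the table metadata.
#' @export
summarize_roi <- function(clusters, coloc = NULL, nnd = NULL, table = NULL,
                          roi_id = NA) {
  cl <- clusters$clusters
  n_ref <- clusters$n_input_locs
  n_partner <- NA_integer_
  md <- list()
  if (!is.null(table)) {
    ch <- attr(table, "channels")
    n_ref <- sum(table$channel == ch[["reference"]])
    n_partner <- sum(table$channel == ch[["partner"]])
    md <- attr(table, "metadata")
  }
  has <- nrow(cl) > 0
  out <- data.frame(
    roi = roi_id,
    cell = if (!is.null(md$cell)) md$cell else NA,
    animal = if (!is.null(md$animal)) md$animal else NA,
    group = if (!is.null(md$group)) md$group else NA,
    cluster_count = nrow(cl),
    mean_locs_per_cluster = if (has) mean(cl$n_locs) else NA_real_,
    mean_span = if (has) mean(cl$span) else NA_real_,
    mean_hull_measure = if (has) mean(cl$hull_measure) else NA_real_,
    mean_nnd = if (!is.null(nnd)) nnd$mean_nnd else NA_real_,
    median_nnd = if (!is.null(nnd)) nnd$median_nnd else NA_real_,
    mean_partner_per_cluster = if (!is.null(coloc) && isTRUE(coloc$defined))
      coloc$mean_count else NA_real_,
    empty_fraction = if (!is.null(coloc) && isTRUE(coloc$defined))
      coloc$empty_fraction else NA_real_,
    clustered_fraction = if (n_ref > 0)
      100 * clusters$n_clustered_locs / n_ref else NA_real_,
    total_reference_locs = n_ref,
    total_partner_locs = n_partner,
    stringsAsFactors = FALSE)
  class(out) <- c("roi_summary", "data.frame")
  out
}

#' Average ROI summaries within cells
#'
#' The two ROIs measured per cell are averaged metric-by-metric
#' (arithmetic mean). `NA` metrics are dropped from the mean with a
#' warning, and a cell whose ROIs are all `NA` for a metric stays `NA`.
#'
#' @param roi_summaries data frame of stacked [summarize_roi()] rows.
#' @return Data frame with one row per cell (columns: cell, animal, group,
#'   n_rois and the metric means).
#' @export
aggregate_cells <- function(roi_summaries) {
  df <- as.data.frame(roi_summaries)
  .assert(nrow(df) > 0, "no ROI summaries")
  key <- interaction(df$cell, df$animal, df$group, drop = TRUE)
  if (anyNA(df[, .ROI_METRICS]))
    warning("undefined ROI metrics excluded from cell means")
  pieces <- lapply(split(df, key), function(g) {
    means <- vapply(.ROI_METRICS, function(m) {
      v <- g[[m]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(cell = g$cell[1], animal = g$animal[1],
                     group = g$group[1], n_rois = nrow(g),
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Average cell summaries within animals
#'
#' @param cell_summaries output of [aggregate_cells()].
#' @return Data frame with one row per animal.
#' @export
aggregate_animals <- function(cell_summaries) {
  df <- as.data.frame(cell_summaries)
  key <- interaction(df$animal, df$group, drop = TRUE)
  pieces <- lapply(split(df, key), function(g) {
    means <- vapply(.ROI_METRICS, function(m) {
      v <- g[[m]]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
    cbind(data.frame(animal = g$animal[1], group = g$group[1],
                     n_cells = nrow(g), stringsAsFactors = FALSE),
          as.data.frame(as.list(means)))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' One-way ANOVA with Tukey HSD group comparisons
#'
#' For each metric: per-group mean, SD and SE, the one-way fixed-effects
#' ANOVA F and p, and Tukey-adjusted pairwise p-values (studentized range
#' distribution). At `level = "animal"`, cells are first averaged within
#' animal so each animal contributes one observation. Welch's unequal-
#' variance t-test is available as a secondary pairwise comparison.
#'
#' @param cell_summaries output of [aggregate_cells()].
#' @param metrics metric column names (default all ROI metrics).
#' @param level `"cell"` (default) or `"animal"`.
#' @param welch if `TRUE`, adds Welch t-test p-values per pair.
#' @return A `group_comparison`: list with `level` and `metrics`, a named
#'   list holding, per metric, `groups` (mean/sd/se/n per group),
#'   `F`, `p`, and `tukey` (data frame: pair, diff, p_adj\[, p_welch\]).
#' @export
compare_groups <- function(cell_summaries, metrics = .ROI_METRICS,
                           level = c("cell", "animal"), welch = FALSE) {
  level <- match.arg(level)
  df <- if (level == "animal") aggregate_animals(cell_summaries)
        else as.data.frame(cell_summaries)
  df$group <- factor(df$group)
  .assert(nlevels(df$group) >= 2, "need at least 2 groups")
  res <- list()
  for (m in metrics) {
    v <- df[[m]]
    ok <- !is.na(v)
    small <- names(which(tapply(ok, df$group, sum) < 2))
    .assert(length(small) == 0,
            "group '%s' has fewer than 2 observations for metric '%s'",
            if (length(small)) small[1] else "", m)
    d <- data.frame(value = v[ok], group = droplevels(df$group[ok]))
    fit <- aov(value ~ group, data = d)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$group
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"], row.names = NULL,
                        stringsAsFactors = FALSE)
    if (welch) {
      tukey$p_welch <- vapply(tukey$pair, function(pr) {
        gs <- strsplit(pr, "-", fixed = TRUE)[[1]]
        t.test(d$value[d$group == gs[1]], d$value[d$group == gs[2]])$p.value
      }, numeric(1))
    }
    gstats <- do.call(rbind, lapply(split(d$value, d$group), function(g) {
      data.frame(n = length(g), mean = mean(g), sd = sd(g),
                 se = sd(g) / sqrt(length(g)))
    }))
    gstats$group <- rownames(gstats)
    rownames(gstats) <- NULL
    res[[m]] <- list(groups = gstats[, c("group", "n", "mean", "sd", "se")],
                     F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                     tukey = tukey)
  }
  structure(list(level = level, metrics = res), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> level = %s, %d metrics\n",
              x$level, length(x$metrics)))
  for (m in names(x$metrics)) {
    r <- x$metrics[[m]]
    cat(sprintf("  %s: F = %.3g, p = %.3g\n", m, r$F, r$p))
  }
  invisible(x)
}
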