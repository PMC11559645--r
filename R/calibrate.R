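## One-dimensional secant calibration of generator parameters against the
## full analysis pipeline. Each calibration target is paired with the
## generator knob that controls it monotonically:
##
##   mean_span         -> cluster_radius$mean        (nm)
##   mean_locs         -> locs_per_cluster$meanlog
##   low_size_share    -> locs_per_cluster$sdlog
##   mean_nnd          -> within_row_gap$mean        (nm)
##   median_nnd_cells  -> within_row_gap$mean        (nm)
##   empty_fraction    -> planted_empty_prob
##   small_share       -> small_cluster_fraction

.CAL_KNOBS <- list(
  mean_span = list(
    get = function(cfg) cfg$cluster_radius$mean,
    set = function(cfg, v) { cfg$cluster_radius$mean <- v; cfg },
    lo = 20, hi = 400),
  mean_locs = list(
    get = function(cfg) cfg$locs_per_cluster$meanlog,
    set = function(cfg, v) { cfg$locs_per_cluster$meanlog <- v; cfg },
    lo = -3, hi = 6),
  low_size_share = list(
    get = function(cfg) cfg$locs_per_cluster$sdlog,
    set = function(cfg, v) { cfg$locs_per_cluster$sdlog <- v; cfg },
    lo = 0.2, hi = 3.5),
  mean_nnd = list(
    get = function(cfg) cfg$within_row_gap$mean,
    set = function(cfg, v) { cfg$within_row_gap$mean <- v; cfg },
    lo = 320, hi = 1600),
  median_nnd_cells = list(
    get = function(cfg) cfg$within_row_gap$mean,
    set = function(cfg, v) { cfg$within_row_gap$mean <- v; cfg },
    lo = 320, hi = 1600),
  empty_fraction = list(
    get = function(cfg) cfg$planted_empty_prob,
    set = function(cfg, v) { cfg$planted_empty_prob <- v; cfg },
    lo = 0, hi = 0.9),
  small_share = list(
    get = function(cfg) cfg$small_cluster_fraction,
    set = function(cfg, v) { cfg$small_cluster_fraction <- v; cfg },
    lo = 0, hi = 0.95))

#' Calibrate generator parameters to pipeline targets
#'
#' Adjusts, for each named target metric, its designated generator knob by
#' a one-dimensional secant search, using the full pipeline's Monte-Carlo
#' metric estimate (fixed seeds, `n_cells * rois_per_cell` ROIs per
#' evaluation) as the objective. Targets are cycled in the order given
#' (sizes before spans before spacings, if you follow the default order)
#' until all lie within `tolerance`; interactions between knobs are
#' absorbed by the outer cycles.
#'
#' @param config starting [generator_config()].
#' @param targets named numeric vector; names from
#'   `mean_span`, `mean_locs`, `low_size_share`, `mean_nnd`,
#'   `median_nnd_cells`, `empty_fraction`, `small_share` (shares and
#'   fractions in percent).
#' @param tolerance relative tolerance per target (default 0.05).
#' @param n_cells,rois_per_cell,seed Monte-Carlo evaluation size (default
#'   10 cells x 2 ROIs = 20 ROIs, fixed seed).
#' @param max_iter maximum total knob updates before giving up.
#' @param verbose print a trace line per evaluation.
#' @return The calibrated `generator_config`, with attribute
#'   `calibration_trace` (data frame of iterations).
#' @export
calibrate_preset <- function(config, targets, tolerance = 0.05,
                             n_cells = 10, rois_per_cell = 2, seed = 1L,
                             max_iter = 25, verbose = TRUE) {
  .assert(length(targets) > 0 && !is.null(names(targets)) &&
            all(names(targets) %in% names(.CAL_KNOBS)),
          "targets must be a named vector of calibratable metrics")
  include_small <- "small_share" %in% names(targets)
  measure <- function(cfg) {
    preset_summary_stats(cfg, n_cells = n_cells,
                         rois_per_cell = rois_per_cell, seed = seed,
                         include_small = include_small)
  }
  ## mean_locs and low_size_share both hang off the size lognormal, so a
  ## low_size_share (sdlog) step re-solves meanlog for the mean target
  ## before the share is measured (nested one-dimensional solves).
  nested_size <- all(c("mean_locs", "low_size_share") %in% names(targets))
  solve_meanlog <- function(cfg) {
    tgt <- targets[["mean_locs"]]
    p0 <- cfg$locs_per_cluster$meanlog
    m0 <- measure(cfg)$mean_locs
    if (abs(m0 - tgt) <= 0.5 * tolerance * tgt) return(cfg)
    p1 <- p0 + 0.15
    cfg1 <- cfg; cfg1$locs_per_cluster$meanlog <- p1
    m1 <- measure(cfg1)$mean_locs
    for (it in 1:6) {
      if (abs(m1 - m0) < 1e-9) break
      p2 <- p1 + (tgt - m1) * (p1 - p0) / (m1 - m0)
      p2 <- min(6, max(-6, p2))
      cfg2 <- cfg1; cfg2$locs_per_cluster$meanlog <- p2
      m2 <- measure(cfg2)$mean_locs
      p0 <- p1; m0 <- m1; p1 <- p2; m1 <- m2; cfg1 <- cfg2
      if (abs(m1 - tgt) <= 0.5 * tolerance * tgt) break
    }
    cfg1
  }
  trace <- list()
  note <- function(metric, param, value, got, target) {
    trace[[length(trace) + 1L]] <<- data.frame(
      metric = metric, param = param, metric_value = got, target = target)
    if (verbose)
      message(sprintf("  calibrate %s: knob=%.5g -> metric=%.4g (target %.4g)",
                      metric, param, got, target))
  }

  stats <- measure(config)
  iter <- 0L
  repeat {
    miss <- vapply(names(targets), function(m) {
      abs(stats[[m]] - targets[[m]]) > tolerance * abs(targets[[m]])
    }, logical(1))
    if (!any(miss)) break
    .assert(iter < max_iter,
            "calibration did not converge in %d iterations (see trace)",
            max_iter)
    dirty <- FALSE
    active <- names(targets)[miss]
    if (nested_size && "low_size_share" %in% active)
      active <- setdiff(active, "mean_locs")   # handled by the nested solve
    for (m in active) {
      knob <- .CAL_KNOBS[[m]]
      nest <- nested_size && m == "low_size_share"
      apply_knob <- function(cfg, v) {
        cfg <- knob$set(cfg, v)
        if (nest) cfg <- solve_meanlog(cfg)
        cfg
      }
      p0 <- knob$get(config)
      cfg0 <- if (nest) solve_meanlog(config) else config
      if (dirty || nest) stats <- measure(cfg0)
      config <- cfg0
      m0 <- stats[[m]]
      note(m, p0, p0, m0, targets[[m]])
      ## probe step: 15% of the knob (or a small absolute step near zero)
      step <- if (abs(p0) > 1e-6) 0.15 * abs(p0) else 0.02
      p1 <- min(knob$hi, max(knob$lo, p0 + step))
      cfg1 <- apply_knob(config, p1)
      m1 <- measure(cfg1)[[m]]
      note(m, p1, p1, m1, targets[[m]])
      if (abs(m1 - m0) < 1e-12) next   # insensitive; try again next cycle
      ## secant iterations on this knob, trust-region limited so a locally
      ## flat response cannot fling the knob across its whole range
      for (it in 1:6) {
        p2 <- p1 + (targets[[m]] - m1) * (p1 - p0) / (m1 - m0)
        p2 <- min(p1 + 5 * abs(p1 - p0), max(p1 - 5 * abs(p1 - p0), p2))
        p2 <- min(knob$hi, max(knob$lo, p2))
        if (abs(p2 - p1) < 1e-10) break
        cfg2 <- apply_knob(config, p2)
        m2 <- measure(cfg2)[[m]]
        note(m, p2, p2, m2, targets[[m]])
        p0 <- p1; m0 <- m1; p1 <- p2; m1 <- m2
        cfg1 <- cfg2
        if (abs(m1 - targets[[m]]) <= tolerance * abs(targets[[m]]))
          break
      }
      config <- cfg1
      dirty <- TRUE
      iter <- iter + 1L
    }
    stats <- measure(config)
  }
  attr(config, "calibration_trace") <- do.call(rbind, trace)
  config
}
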