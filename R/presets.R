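## Condition presets: frozen generator configurations emulating the three
## study conditions (euthyroid EU, hypothyroid PTU, T3-restored PTU+T3) in
## 2-D and 3-D. The EU/PTU axes that the analysis is benchmarked against
## (cluster size distribution, span, NND, empty fraction, small-cluster
## share) were fixed once by calibrate_preset() against the full pipeline
## and are shipped as YAML files under inst/extdata/presets.

#' Convert a generator config to a plain list (YAML-ready)
#' @param config a [generator_config()].
#' @return A nested plain list.
#' @export
config_to_list <- function(config) {
  list(dimensionality = config$dimensionality,
       roi = list(origin = config$roi$origin, extent = config$roi$extent),
       margin = config$margin,
       row_spacing = config$row_spacing,
       row_jitter_sd = config$row_jitter_sd,
       off_row_fraction = config$off_row_fraction,
       within_row_gap = config$within_row_gap,
       cluster_deletion_prob = config$cluster_deletion_prob,
       locs_per_cluster = config$locs_per_cluster,
       small_cluster_fraction = config$small_cluster_fraction,
       cluster_radius = config$cluster_radius,
       axial_flattening = config$axial_flattening,
       loc_precision_sd = as.list(config$loc_precision_sd),
       partner_mean_per_cluster = config$partner_mean_per_cluster,
       partner_scatter_sd = config$partner_scatter_sd,
       planted_empty_prob = config$planted_empty_prob,
       empty_exclusion = config$empty_exclusion,
       partner_exclusion_radius = config$partner_exclusion_radius,
       partner_background_density = config$partner_background_density,
       reference_background_density = config$reference_background_density,
       qc_stress_fraction = config$qc_stress_fraction,
       seed = config$seed)
}

#' Rebuild a generator config from a plain list
#' @param x a list as produced by [config_to_list()].
#' @return A [generator_config()].
#' @export
config_from_list <- function(x) {
  generator_config(
    dimensionality = x$dimensionality,
    roi = roi_spec(unlist(x$roi$origin), unlist(x$roi$extent)),
    margin = unlist(x$margin),
    row_spacing = x$row_spacing,
    row_jitter_sd = x$row_jitter_sd,
    off_row_fraction = x$off_row_fraction,
    within_row_gap = x$within_row_gap,
    cluster_deletion_prob = x$cluster_deletion_prob,
    locs_per_cluster = x$locs_per_cluster,
    small_cluster_fraction = x$small_cluster_fraction,
    cluster_radius = x$cluster_radius,
    axial_flattening = x$axial_flattening,
    loc_precision_sd = c(lateral = x$loc_precision_sd$lateral,
                         axial = x$loc_precision_sd$axial),
    partner_mean_per_cluster = x$partner_mean_per_cluster,
    partner_scatter_sd = x$partner_scatter_sd,
    planted_empty_prob = x$planted_empty_prob,
    empty_exclusion = x$empty_exclusion,
    partner_exclusion_radius = x$partner_exclusion_radius,
    partner_background_density = x$partner_background_density,
    reference_background_density = x$reference_background_density,
    qc_stress_fraction = x$qc_stress_fraction,
    seed = x$seed)
}

#' Write a generator config as YAML
#' @param config a [generator_config()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path, precision = 15)
  invisible(path)
}

#' Read a generator config from YAML
#' @param path YAML file path.
#' @return A [generator_config()].
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "config file not found: %s", path)
  config_from_list(yaml::read_yaml(path))
}

#' Available preset names
#' @return Character vector of shipped preset names.
#' @export
preset_names <- function() {
  dir <- system.file("extdata", "presets", package = "dyadSTORM")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Load a shipped condition preset
#'
#' `EU2D`, `PTU2D`, `T32D` are 2-D presets (Jph2 partner channel);
#' `EU3D`, `PTU3D`, `T33D` are 3-D presets. EU presets emulate euthyroid
#' control cells; PTU presets encode the three hypothyroid disease axes
#' (cluster deletion, row disarray, partner loss); T3 presets are EU-like
#' with mildly widened spacing.
#'
#' @param name preset name, see [preset_names()].
#' @return A [generator_config()].
#' @export
preset <- function(name) {
  dir <- system.file("extdata", "presets", package = "dyadSTORM")
  path <- file.path(dir, paste0(name, ".yaml"))
  .assert(file.exists(path), "unknown preset '%s' (available: %s)",
          name, paste(preset_names(), collapse = ", "))
  read_config(path)
}
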