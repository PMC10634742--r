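#' Default pipeline configuration
#'
#' Nested list mirroring the component configurations (phantom, sampler,
#' augment, network, train, inference) plus a global seed that propagates to
#' every stochastic stage.  [read_run_config()] merges a YAML file over
#' these defaults.
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(seed = 1L,
       phantom = list(cube_edge = 160L, pad = 14L, n_tubes = 6L,
                      tube_radius = c(1L, 3L), axon_intensity_mean = 6000,
                      background_intensity_mean = 800,
                      artifact_intensity_mean = 9000, noise_sd = 300,
                      n_artifact_blobs = 2L,
                      sparse_stride = 20L, sparse_start = 15L),
       sampler = list(input_size = 64L, margin = 14L, oversample_p = 0.3,
                      samples_per_cube = 100L),
       augment = list(enable_flips = TRUE, enable_rotation = FALSE,
                      enable_elastic = FALSE, rotation_range = 15,
                      elastic_alpha = c(0, 200), elastic_sigma = c(9, 13),
                      intensity_scale_range = c(0.8, 1.2),
                      intensity_offset_range = c(-0.05, 0.05),
                      max_intensity = 65535),
       network = list(depth = 3L, base_filters = 8L, use_batchnorm = TRUE,
                      layer_selection = "full"),
       train = list(epochs = 100L, batch_size = 6L, learning_rate = 1e-4,
                    scheduler = "fixed", plateau_factor = 0.1,
                    plateau_patience = 10L, plateau_min_lr = 1e-6),
       inference = list(gaussian = TRUE, sigma = NULL, stride = NULL,
                        threshold = 0.5))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a YAML run configuration merged over the defaults
#'
#' @param path YAML file; keys mirror [default_run_config()].
#' @return Nested configuration list.
#' @export
read_run_config <- function(path) {
  check_that(file.exists(path), "no such config file: %s", path)
  merge_config(default_run_config(), yaml::read_yaml(path))
}

#' Write the resolved configuration snapshot next to run outputs
#'
#' @param config Nested configuration list.
#' @param dir Output directory.
#' @return The snapshot path, invisibly.
#' @export
write_config_snapshot <- function(config, dir) {
  path <- file.path(dir, "config_used.yaml")
  yaml::write_yaml(config, path)
  invisible(path)
}
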