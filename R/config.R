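# YAML experiment configuration: sectioned schema with strict key checking.
# Every stochastic component must carry an explicit seed, so that a config
# file fully determines an experiment.

config_schema <- list(
  geometry = c("num_angles", "angular_range", "offset", "num_detector_pixels",
               "image_size", "detector_pixel_size"),
  phantom = c("kind", "size", "depth", "num_features", "seed", "T_steps",
              "start_step", "growth_rate", "num_materials", "C",
              "num_steps_group", "angles_per_step", "jitter_sd"),
  noise = c("incident_photon_count", "virtual_time_fraction", "dark_level",
            "seed", "type", "sigma"),
  split = c("kind", "J", "K"),
  model = c("depth", "dilation_cycle", "weight_init_seed", "context"),
  training = c("iterations", "batch_size", "learning_rate", "shuffle_seed",
               "strategy"),
  evaluation = c("metrics"),
  tv = c("lambda", "iterations", "step_safety")
)

required_seeds <- list(phantom = "seed", noise = "seed",
                       model = "weight_init_seed", training = "shuffle_seed")

#' Read and validate an experiment configuration
#'
#' Parses a YAML config with sections `geometry`, `phantom`, `noise`,
#' `split`, `model`, `training`, `evaluation`, `tv`.  Unknown sections or
#' keys are rejected (typos should fail loudly, not silently fall back to a
#' default), and each stochastic section must name its seed explicitly.
#'
#' @param path YAML file.
#' @return Named list of validated sections, class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_invalid("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop_invalid("config must be a YAML mapping")
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop_invalid("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop_invalid("unknown key(s) in [", sec, "]: ", paste(bad, collapse = ", "))
    if (!is.null(required_seeds[[sec]]) &&
        is.null(cfg[[sec]][[required_seeds[[sec]]]]))
      stop_invalid("section [", sec, "] must set '", required_seeds[[sec]],
                   "' explicitly")
  }
  # angular_range may be written symbolically
  if (!is.null(cfg$geometry$angular_range) &&
      is.character(cfg$geometry$angular_range)) {
    cfg$geometry$angular_range <- switch(cfg$geometry$angular_range,
      "pi" = pi, "2pi" = 2 * pi,
      stop_invalid("angular_range must be numeric, 'pi' or '2pi'"))
  }
  structure(cfg, class = "experiment_config")
}

config_geometry <- function(cfg) {
  g <- cfg$geometry
  make_geometry(g$num_angles,
                if (is.null(g$angular_range)) pi else g$angular_range,
                if (is.null(g$offset)) 0 else g$offset,
                g$num_detector_pixels, g$image_size,
                if (is.null(g$detector_pixel_size)) 1 else g$detector_pixel_size)
}

config_noise <- function(cfg) {
  n <- cfg$noise
  noise_config(n$incident_photon_count,
               if (is.null(n$virtual_time_fraction)) 1 else n$virtual_time_fraction,
               if (is.null(n$dark_level)) 0 else n$dark_level,
               n$seed,
               if (is.null(n$type)) "poisson" else n$type,
               if (is.null(n$sigma)) 0.1 else n$sigma)
}
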