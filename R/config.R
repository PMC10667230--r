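#' Default run configuration tree
#'
#' The full configuration accepted by the command-line interface and the
#' pipeline helpers: `synth` (generator), `influence` (weight scheme),
#' `flow` (integration), `optim` (fitting), `template` (birth-average
#' estimation). [load_config()] merges a YAML file over these defaults
#' and rejects unknown keys (typo safety); every run writes the fully
#' resolved configuration next to its outputs.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    synth = list(grid_shape = c(48L, 24L),
                 semi_axes = c(49, 60, 45),
                 n_subjects = 200, noise_sd = 0.5,
                 age_dist = "exponential", age_mean_days = 1100,
                 age_range = c(0, 3650),
                 rigid_max_deg = 5, rigid_max_mm = 3,
                 v_decline = 30, z0 = 0.04, z_decline = 10),
    influence = list(k = 0.5, sigma = 50, support_threshold = 1e-8),
    flow = list(dt_days = 5, t_max = 3650),
    anchors = list(spacing_mm = 20),
    optim = list(lr = 0.01, iters = 400, optimize_shape = TRUE,
                 optimize_rigid = TRUE),
    template = list(bandwidth_days = 90)
  )
}

#' Load and validate a run configuration
#'
#' @param path YAML file, or NULL for pure defaults.
#' @param overrides Named list merged last (e.g. from CLI flags).
#' @return Fully resolved configuration list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user, "")
  }
  if (length(overrides)) cfg <- merge_config(cfg, overrides, "")
  cfg
}

merge_config <- function(base, user, prefix) {
  if (is.null(user)) return(base)
  for (key in names(user)) {
    full <- paste0(prefix, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", full)
    if (is.list(base[[key]]) && !is.null(names(base[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a section")
      base[[key]] <- merge_config(base[[key]], user[[key]], paste0(full, "."))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Write the resolved configuration next to run outputs
#'
#' @param cfg Configuration list.
#' @param out_dir Output directory.
#' @return Path of the written file, invisibly.
#' @export
write_resolved_config <- function(cfg, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir, "config.resolved.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# synth_config from a resolved configuration tree
config_to_synth <- function(cfg, seed, fused = character(0)) {
  s <- cfg$synth
  synth_config(grid_shape = s$grid_shape, semi_axes = s$semi_axes,
               v_decline = s$v_decline, z0 = s$z0, z_decline = s$z_decline,
               noise_sd = s$noise_sd, n_subjects = s$n_subjects,
               age_range = s$age_range, age_mean_days = s$age_mean_days,
               age_dist = s$age_dist,
               rigid_max_deg = s$rigid_max_deg, rigid_max_mm = s$rigid_max_mm,
               anchor_spacing_mm = cfg$anchors$spacing_mm,
               dt_days = cfg$flow$dt_days,
               k = cfg$influence$k, sigma_mm = cfg$influence$sigma,
               fused_sutures = fused, seed = seed)
}

config_to_fit <- function(cfg, seed) {
  fit_config(spacing_mm = cfg$anchors$spacing_mm, dt = cfg$flow$dt_days,
             iters = cfg$optim$iters, lr = cfg$optim$lr, seed = seed,
             k_init = cfg$influence$k, sigma_init = cfg$influence$sigma,
             optimize_shape = cfg$optim$optimize_shape,
             optimize_rigid = cfg$optim$optimize_rigid,
             support_threshold = cfg$influence$support_threshold)
}
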