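#' True model objects implied by a synthetic configuration
#'
#' Builds the complete ground-truth model for a configuration: the birth
#' template, its suture anchors, the influence weight field and the true
#' velocity parameters. Growth rates follow `v(t) = 1/(p0 + p1 t)` with
#' `v(0) = v0[suture]` declining by the configured factor over 10 years;
#' base displacement rates are analogous. Deterministic given the config.
#'
#' @param config A [synth_config()].
#' @return List with `template`, `anchors`, `weights`, `shape`, `vel`.
#' @export
synth_model <- function(config) {
  template <- make_template(config)
  anchors <- sample_suture_anchors(template, config$anchor_spacing_mm)
  shape <- weight_shape(k = config$k, sigma_mm = config$sigma_mm)
  weights <- build_weights(template, anchors, shape)
  vel <- true_velocity_params(anchors, config)
  list(template = template, anchors = anchors, weights = weights,
       shape = shape, vel = vel)
}

true_velocity_params <- function(anchors, config) {
  A <- n_anchors(anchors)
  t_span <- 3650
  p_v <- t(vapply(seq_len(A), function(a) {
    v0 <- config$v0[[anchors$suture[a]]]
    c(1 / v0, (config$v_decline - 1) / (v0 * t_span), 0)
  }, numeric(3)))
  p_z <- matrix(0, A, 3)
  base <- row_norms(anchors$y) > 0
  if (config$z0 != 0 && any(base)) {
    row <- c(1 / config$z0, (config$z_decline - 1) / (config$z0 * t_span), 0)
    p_z[base, ] <- matrix(row, sum(base), 3, byrow = TRUE)
  }
  velocity_params(p_v, p_z)
}

draw_ages <- function(config, n) {
  lo <- config$age_range[1]; hi <- config$age_range[2]
  if (config$age_dist == "uniform") return(stats::runif(n, lo, hi))
  # truncated exponential, young-skewed like a trauma-referral cohort
  rate <- 1 / config$age_mean_days
  u <- stats::runif(n)
  lo - log(1 - u * (1 - exp(-rate * (hi - lo)))) / rate
}

draw_rigid <- function(config) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, config$rigid_max_deg * pi / 180)
  tau <- stats::runif(3, -1, 1)
  tau <- tau / max(1, sqrt(sum(tau^2))) * config$rigid_max_mm
  c(ax * ang, tau)
}

#' Generate a cross-sectional synthetic cohort
#'
#' For each subject an age is drawn from the configured distribution, the
#' true forward model is integrated from birth to that age (one shared
#' trajectory sampled at each subject's age rounded to the Euler step),
#' iid Gaussian coordinate noise is added, and a small random rigid pose
#' perturbation is applied. The perturbation and all true parameters are
#' recorded as ground truth for parameter-recovery studies.
#'
#' @param config A [synth_config()]; `config$fused_sutures` is honoured,
#'   so a pathological cohort config generates fused-growth anatomies.
#' @param model Optional precomputed [synth_model()] for the config.
#' @return Object of class `cohort`: list with `maps` (list of
#'   `spherical_map`), `ages` (days), `subject_ids`, and a `truth` record
#'   (config, rigid parameters, velocity parameters).
#' @export
generate_cohort <- function(config, model = synth_model(config)) {
  set.seed(config$seed)
  n <- config$n_subjects
  ages <- draw_ages(config, n)
  snap_ages <- round(ages / config$dt_days) * config$dt_days
  maps <- vector("list", n)
  rigids <- matrix(0, n, 6)
  t_top <- max(snap_ages)
  states <- trajectory_snapshots(model, t_top, config$dt_days, snap_ages,
                                 config$fused_sutures)
  for (s in seq_len(n)) {
    X <- states[[s]]
    if (config$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X), 3)
    th <- draw_rigid(config)
    rigids[s, ] <- th
    maps[[s]] <- spherical_map(apply_rigid(X, th), model$template$label,
                               config$grid_shape, age_days = ages[s],
                               subject_id = sprintf("synth%04d", s))
  }
  structure(list(maps = maps, ages = ages, snap_ages = snap_ages,
                 subject_ids = vapply(maps, `[[`, character(1), "subject_id"),
                 truth = list(config = config, rigids = rigids,
                              vel = model$vel, shape = model$shape,
                              template = model$template)),
            class = "cohort")
}

# States of the shared true trajectory at each requested age.
trajectory_snapshots <- function(model, t_top, dt, ages, fused = character(0)) {
  if (t_top == 0) return(lapply(ages, function(a) model$template$coords))
  res <- integrate_flow(model$template, model$anchors, model$weights,
                        model$vel, flow_spec(0, t_top, dt, fused),
                        trajectory = TRUE)
  idx <- round(ages / dt) + 1
  lapply(idx, function(i) res$trajectory[, , i])
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d maps, ages %.0f-%.0f days (mean %.0f)",
              length(x$maps), min(x$ages), max(x$ages), mean(x$ages)))
  if (!is.null(x$pair_of)) cat(" [longitudinal pairs]")
  fused <- x$truth$config$fused_sutures
  if (length(fused)) cat(" [fused:", paste(fused, collapse = ","), "]")
  cat("\n")
  invisible(x)
}

#' Generate a longitudinal cohort of linked image pairs
#'
#' Each subject receives two observation ages `t1` and `t2 = t1 + interval`
#' on the same per-subject trajectory of the true model: both shapes share
#' the subject's rigid pose perturbation but carry independent noise, and
#' are linked by `subject_id`.
#'
#' @param config A [synth_config()]; `n_subjects` is the number of pairs.
#' @param interval_days Interval draw bounds (days), uniform.
#' @param model Optional precomputed [synth_model()].
#' @return A `cohort` whose `maps` hold the pairs in order
#'   (2 s - 1, 2 s); fields `pair_of` and `visit` link them.
#' @export
generate_longitudinal <- function(config, interval_days = c(180, 720),
                                  model = synth_model(config)) {
  set.seed(config$seed)
  n <- config$n_subjects
  t1 <- draw_ages(config, n)
  iv <- stats::runif(n, interval_days[1], interval_days[2])
  for (s in seq_len(n)) {
    tries <- 0
    while (t1[s] + iv[s] > 3650 && tries < 100) {
      iv[s] <- stats::runif(1, interval_days[1], interval_days[2])
      tries <- tries + 1
    }
    if (t1[s] + iv[s] > 3650) {
      warning("interval clamped to the model span for pair ", s)
      iv[s] <- 3650 - t1[s]
    }
  }
  ages <- as.vector(rbind(t1, t1 + iv))
  snap_ages <- round(ages / config$dt_days) * config$dt_days
  states <- trajectory_snapshots(model, max(snap_ages), config$dt_days,
                                 snap_ages, config$fused_sutures)
  maps <- vector("list", 2 * n)
  rigids <- matrix(0, 2 * n, 6)
  for (s in seq_len(n)) {
    th <- draw_rigid(config)
    for (v in 1:2) {
      i <- 2 * (s - 1) + v
      X <- states[[i]]
      if (config$noise_sd > 0)
        X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X), 3)
      rigids[i, ] <- th
      maps[[i]] <- spherical_map(apply_rigid(X, th), model$template$label,
                                 config$grid_shape, age_days = ages[i],
                                 subject_id = sprintf("pair%04d", s))
    }
  }
  structure(list(maps = maps, ages = ages, snap_ages = snap_ages,
                 subject_ids = vapply(maps, `[[`, character(1), "subject_id"),
                 pair_of = rep(seq_len(n), each = 2), visit = rep(1:2, n),
                 truth = list(config = config, rigids = rigids,
                              vel = model$vel, shape = model$shape,
                              template = model$template)),
            class = "cohort")
}

#' Generate a single-suture craniosynostosis cohort
#'
#' Identical to [generate_cohort()] except that the true forward
#' simulation zeroes the growth rates within the fused suture from birth,
#' emulating patients whose suture fused prenatally.
#'
#' @param config A [synth_config()].
#' @param fused_suture Suture label(s) fused from birth.
#' @param model Optional precomputed [synth_model()].
#' @return A `cohort`.
#' @export
generate_synostosis_cohort <- function(config, fused_suture,
                                       model = synth_model(config)) {
  config$fused_sutures <- unique(fused_suture)
  bad <- setdiff(config$fused_sutures, suture_labels())
  if (length(bad)) stop("unknown suture label(s): ", paste(bad, collapse = ", "))
  generate_cohort(config, model)
}
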