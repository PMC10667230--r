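#' Rational velocity parameters of the growth model
#'
#' Cranial expansion follows a semi-logarithmic temporal profile, so both
#' the suture growth rate and the cranial-base displacement rate are
#' modeled as reciprocals of quadratics in age:
#' `v_a(t) = 1 / (p0 + p1 t + p2 t^2)` (1/day) and
#' `z_a(t) = 1 / (q0 + q1 t + q2 t^2)` (mm/day).
#' The growth-rate denominator must stay positive on the whole model span
#' (v strictly positive); the displacement denominator must stay bounded
#' away from zero but may be negative (inward drift allowed). Both are
#' verified on a dense 1-day grid at construction.
#'
#' @param p_v A x 3 matrix of growth-rate coefficients, one row per anchor.
#' @param p_z A x 3 matrix of displacement-rate coefficients; an all-zero
#'   row is the conventional encoding of "no base displacement"
#'   (`z_a == 0` exactly), which is also the default.
#' @param t_max Model span in days over which positivity is enforced.
#' @param eps_den Minimum allowed |denominator|.
#' @return Object of class `velocity_params`.
#' @export
velocity_params <- function(p_v, p_z = NULL, t_max = 3650, eps_den = 1e-4) {
  p_v <- as_triples(p_v)
  if (is.null(p_z)) p_z <- matrix(0, nrow(p_v), 3)
  p_z <- as_triples(p_z)
  if (nrow(p_z) != nrow(p_v)) stop("p_v and p_z must have the same number of rows")
  tg <- seq(0, t_max, by = 1)
  qv <- rational_denominator(p_v, tg)
  if (any(qv < eps_den))
    stop("growth-rate denominator drops below ", eps_den,
         " within [0, ", t_max, "] days (anchor ",
         which(apply(qv < eps_den, 1, any))[1], "): v_a must stay positive")
  live <- rowSums(p_z != 0) > 0          # all-zero row encodes z == 0
  if (any(live)) {
    qz <- rational_denominator(p_z[live, , drop = FALSE], tg)
    if (any(abs(qz) < eps_den))
      stop("displacement-rate denominator approaches zero within the model span")
  }
  structure(list(p_v = p_v, p_z = p_z, t_max = t_max, eps_den = eps_den),
            class = "velocity_params")
}

as_triples <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3, byrow = TRUE)
  storage.mode(p) <- "double"
  if (ncol(p) != 3) stop("parameter triples must have 3 columns")
  p
}

# A x length(t) matrix of denominator values
rational_denominator <- function(p, t) {
  outer(p[, 1], rep(1, length(t))) + outer(p[, 2], t) + outer(p[, 3], t^2)
}

#' Suture growth rate and base displacement rate
#'
#' Evaluate the rational rate functions at ages `t` (days).
#' `growth_rate()` is strictly positive (1/day) and errors if its
#' denominator falls below the positivity floor; `base_displacement_rate()`
#' (mm/day) may take either sign but its denominator must stay away from
#' zero.
#'
#' @param t Ages in days (vector allowed).
#' @param p Coefficient triple `c(p0, p1, p2)`.
#' @param eps_den Positivity floor for the denominator.
#' @return Numeric vector of rates.
#' @export
growth_rate <- function(t, p, eps_den = 1e-4) {
  q <- p[1] + p[2] * t + p[3] * t^2
  if (any(q < eps_den))
    stop("growth-rate denominator below ", eps_den, " at t = ",
         t[which(q < eps_den)[1]], " days")
  1 / q
}

#' @rdname growth_rate
#' @export
base_displacement_rate <- function(t, p, eps_den = 1e-4) {
  q <- p[1] + p[2] * t + p[3] * t^2
  if (any(abs(q) < eps_den))
    stop("displacement-rate denominator within ", eps_den, " of zero at t = ",
         t[which(abs(q) < eps_den)[1]], " days")
  1 / q
}

#' Flow specification
#'
#' Time window and discretization of a growth simulation: start and end
#' ages (days), Euler step (default 5 days) and an optional set of fused
#' sutures whose growth rates are forced to zero (craniosynostosis mode).
#'
#' @param t0,t1 Start and end age in days, `t0 <= t1`.
#' @param dt Positive Euler step in days.
#' @param fused_sutures Character vector of suture labels fused over the
#'   whole interval.
#' @return Object of class `flow_spec`.
#' @export
flow_spec <- function(t0, t1, dt = 5, fused_sutures = character(0)) {
  stopifnot(t0 <= t1, dt > 0)
  bad <- setdiff(fused_sutures, suture_labels())
  if (length(bad)) stop("unknown suture label(s): ", paste(bad, collapse = ", "))
  if (any(fused_sutures %in% c("LL", "RL")))
    warning("lambdoid fusion is mechanically supported but not validated ",
            "against clinical observations")
  structure(list(t0 = t0, t1 = t1, dt = dt,
                 fused_sutures = unique(fused_sutures)),
            class = "flow_spec")
}

# Step times and sizes for a flow window; last step clamped to hit t1.
flow_steps <- function(spec) {
  span <- spec$t1 - spec$t0
  if (span == 0) return(list(t = numeric(0), dt = numeric(0)))
  n <- ceiling(span / spec$dt - 1e-12)
  if (spec$dt > span)
    warning("dt exceeds the integration window; taking a single clamped step")
  t <- spec$t0 + (seq_len(n) - 1) * spec$dt
  dtv <- rep(spec$dt, n)
  dtv[n] <- spec$t1 - t[n]
  list(t = t, dt = dtv)
}

# Per-step rate matrices (N x A) for the integrator; fused sutures get
# v identically zero, z only acts where y_a is nonzero.
rate_matrices <- function(anchors, vel, times, fused = character(0)) {
  A <- n_anchors(anchors)
  N <- length(times)
  V <- matrix(0, N, A)
  Z <- matrix(0, N, A)
  has_base <- row_norms(anchors$y) > 0
  for (a in seq_len(A)) {
    V[, a] <- if (anchors$suture[a] %in% fused) 0 else
      growth_rate(times, vel$p_v[a, ], vel$eps_den)
    Z[, a] <- if (has_base[a] && any(vel$p_z[a, ] != 0))
      base_displacement_rate(times, vel$p_z[a, ], vel$eps_den) else 0
  }
  list(V = V, Z = Z)
}

#' Integrate the combined growth flow
#'
#' Advances every grid point of a calvaria map from age `t0` to `t1` by
#' explicit forward Euler accumulation of the combined locally-affine
#' velocity field: per step, each anchor contributes its scaling term
#' `v_a(t) <x - x_a, u_a> u_a` plus the base displacement term
#' `z_a(t) y_a`, weighted by the fixed normalized influence weights.
#' Both the point and the anchors are advected by the same combined flow,
#' so relative vectors are taken between current positions. Static points
#' (zero total weight) never move, and anchors of fused sutures contribute
#' no scaling velocity.
#'
#' @param map A `spherical_map` giving the initial geometry.
#' @param anchors `suture_anchors` consistent with the map.
#' @param weights `weight_field` computed on the reference geometry.
#' @param vel `velocity_params`.
#' @param spec `flow_spec`.
#' @param trajectory Keep all intermediate states (needed by
#'   [invert_flow()] with `use_trajectory` and by strain series).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation; bitwise-comparable results).
#' @return Object of class `flow_result`: list with the final `map`, the
#'   final `coords`, per-step `anchor_coords`, step times, and optionally
#'   the full `trajectory` (M x 3 x (N+1) array).
#' @export
integrate_flow <- function(map, anchors, weights, vel, spec,
                           trajectory = FALSE, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  check_flow_inputs(map, anchors, weights, spec)
  st <- flow_steps(spec)
  if (length(st$t) == 0) {
    out_map <- map; out_map$age_days <- spec$t1
    res <- list(map = out_map, coords = map$coords,
                times = c(spec$t0), trajectory = NULL,
                anchor_coords = map$coords[anchors$m, , drop = FALSE])
    class(res) <- "flow_result"
    return(res)
  }
  rm_ <- rate_matrices(anchors, vel, st$t, spec$fused_sutures)
  run <- run_flow(map$coords, anchors, weights, rm_$V, rm_$Z, st$dt,
                  save_traj = trajectory, engine = engine)
  if (run$error_step > 0)
    stop("non-finite coordinates at integration step ", run$error_step,
         " (t = ", st$t[run$error_step], " days)")
  out_map <- map
  out_map$coords <- run$X
  out_map$age_days <- spec$t1
  res <- list(map = out_map, coords = run$X,
              times = c(st$t, spec$t1),
              trajectory = if (trajectory) run$traj else NULL,
              anchor_coords = run$X[anchors$m, , drop = FALSE])
  class(res) <- "flow_result"
  res
}

#' @export
print.flow_result <- function(x, ...) {
  cat(sprintf("flow_result: %d points advanced to age %.0f days (%d steps)\n",
              nrow(x$coords), x$map$age_days, length(x$times) - 1))
  invisible(x)
}

check_flow_inputs <- function(map, anchors, weights, spec) {
  M <- nrow(map$coords)
  if (nrow(weights$w) != M)
    stop("weight field does not match map size")
  if (ncol(weights$w) != n_anchors(anchors))
    stop("weight field does not match anchor count")
  if (any(anchors$m > M)) stop("anchor grid indices outside map")
  missing <- setdiff(spec$fused_sutures, unique(anchors$suture))
  if (length(missing))
    stop("fused suture(s) not present among anchors: ",
         paste(missing, collapse = ", "))
}

# dispatch to the compiled kernel or the plain-R reference loop
run_flow <- function(X0, anchors, weights, V, Z, dtv, save_traj, engine) {
  if (engine == "cpp") {
    out <- cpp_flow(X0, anchors$u, anchors$y, weights$w,
                    as.integer(anchors$m - 1L), V, Z, dtv, save_traj)
    list(X = out$X, traj = out$traj, error_step = out$error_step)
  } else {
    r_flow(X0, anchors, weights, V, Z, dtv, save_traj)
  }
}

# Reference integrator in plain R; kept for cross-checking the compiled
# kernel and for readability.
r_flow <- function(X0, anchors, weights, V, Z, dtv, save_traj) {
  X <- X0
  N <- length(dtv)
  U <- anchors$u; Y <- anchors$y; W <- weights$w
  traj <- if (save_traj) array(NA_real_, c(nrow(X), 3, N + 1)) else NULL
  if (save_traj) traj[, , 1] <- X
  for (n in seq_len(N)) {
    proj <- X %*% t(U)
    off <- rowSums(X[anchors$m, , drop = FALSE] * U)
    proj <- sweep(proj, 2, off)
    E <- sweep(W * proj, 2, V[n, ], `*`)
    vel <- E %*% U + W %*% (Z[n, ] * Y)
    X <- X + dtv[n] * vel
    if (save_traj) traj[, , n + 1] <- X
    if (!all(is.finite(X)))
      return(list(X = X, traj = traj, error_step = n))
  }
  list(X = X, traj = traj, error_step = -1)
}

#' Simulate craniosynostosis by suture fusion
#'
#' Identical to [integrate_flow()] with the growth rates of the fused
#' sutures forced to zero over the whole interval (fusion assumed from
#' `t0`); base displacement is unaffected. Growth perpendicular to the
#' fused suture is thereby constrained, reproducing the characteristic
#' phenotypes (trigonocephaly for metopic, scaphocephaly for sagittal,
#' anterior plagiocephaly for unicoronal fusion).
#'
#' @inheritParams integrate_flow
#' @param fused_sutures Non-empty set of suture labels to fuse.
#' @return A `flow_result`.
#' @export
simulate_synostosis <- function(map, anchors, weights, vel, spec,
                                fused_sutures = spec$fused_sutures,
                                trajectory = FALSE, engine = c("cpp", "r")) {
  spec$fused_sutures <- unique(fused_sutures)
  bad <- setdiff(spec$fused_sutures, suture_labels())
  if (length(bad)) stop("unknown suture label(s): ", paste(bad, collapse = ", "))
  integrate_flow(map, anchors, weights, vel, spec,
                 trajectory = trajectory, engine = match.arg(engine))
}

#' Per-suture integrated growth curves
#'
#' Cumulative integral of the mean growth rate of each suture's anchors
#' over age (trapezoidal rule): the dimensionless accumulated expansion
#' profile that summarizes a fitted or true model per suture.
#'
#' @param vel `velocity_params`.
#' @param anchors Matching `suture_anchors`.
#' @param t_grid Increasing age grid, days.
#' @return Matrix `length(t_grid)` x n_sutures (named columns) with
#'   attribute `t_grid`.
#' @export
suture_growth_curves <- function(vel, anchors,
                                 t_grid = seq(0, vel$t_max, by = 5)) {
  sut <- sort(unique(anchors$suture))
  out <- matrix(0, length(t_grid), length(sut), dimnames = list(NULL, sut))
  for (l in sut) {
    rows <- which(anchors$suture == l)
    vm <- rowMeans(vapply(rows, function(a)
      growth_rate(t_grid, vel$p_v[a, ], vel$eps_den), numeric(length(t_grid))))
    out[, l] <- c(0, cumsum((vm[-1] + vm[-length(vm)]) / 2 * diff(t_grid)))
  }
  attr(out, "t_grid") <- t_grid
  out
}

#' Relative error between two sets of growth curves
#'
#' Per-suture relative L2 distance between integrated growth curves of a
#' fitted and a reference model, the headline parameter-recovery metric.
#'
#' @param vel_fit,vel_ref `velocity_params` to compare.
#' @param anchors Shared `suture_anchors`.
#' @param t_grid Age grid, days.
#' @return Named numeric vector of relative L2 errors per suture.
#' @export
growth_curve_error <- function(vel_fit, vel_ref, anchors,
                               t_grid = seq(0, 3650, by = 5)) {
  cf <- suture_growth_curves(vel_fit, anchors, t_grid)
  cr <- suture_growth_curves(vel_ref, anchors, t_grid)
  vapply(colnames(cr), function(l)
    sqrt(sum((cf[, l] - cr[, l])^2) / sum(cr[, l]^2)), numeric(1))
}

#' Invert a growth flow
#'
#' Integrates the negated combined velocity field backward from `t1` to
#' `t0`, starting from the final coordinates of a forward flow. Because
#' the model is a discretized diffeomorphic flow, the round trip returns
#' to the original coordinates up to the first-order discretization error,
#' which vanishes as `dt -> 0`.
#'
#' @param result `flow_result` of the forward integration.
#' @param anchors,weights,vel As used in the forward flow.
#' @param spec The forward `flow_spec`.
#' @param engine Integration engine, as in [integrate_flow()].
#' @return M x 3 matrix of recovered coordinates at `t0`.
#' @export
invert_flow <- function(result, anchors, weights, vel, spec,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  st <- flow_steps(spec)
  if (length(st$t) == 0) return(result$coords)
  rm_ <- rate_matrices(anchors, vel, st$t, spec$fused_sutures)
  N <- length(st$t)
  rev_idx <- rev(seq_len(N))
  run <- run_flow(result$coords, anchors, weights,
                  -rm_$V[rev_idx, , drop = FALSE],
                  -rm_$Z[rev_idx, , drop = FALSE],
                  st$dt[rev_idx], save_traj = FALSE, engine = engine)
  if (run$error_step > 0)
    stop("non-finite coordinates at backward step ", run$error_step)
  run$X
}
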