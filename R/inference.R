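#' Population objective of the growth model
#'
#' Mean normalized discrepancy between the model-predicted development of
#' the birth template and the observed anatomies of a cross-sectional
#' cohort:
#' `L = (1/N) sum_s (1/M) sum_m ||Phi(I0(m), t_s) - R(theta_s) I_s(m)|| / ||I_s(m)||`
#' where `Phi` integrates the growth flow from birth to the subject's age
#' (rounded to the Euler step), and `R(theta_s)` is a per-subject rigid
#' nuisance transform compensating pose-standardization inaccuracies (not
#' part of the model). The per-point scaling by `1/||I_s(m)||` equalizes
#' the contribution of subjects with different cranial size. Points with
#' near-zero coordinate norm are excluded from the sum (with a message).
#'
#' @param template `spherical_map` at birth (the average anatomy).
#' @param cohort A `cohort` (maps + ages).
#' @param anchors `suture_anchors` on the template.
#' @param weights `weight_field` on the template geometry.
#' @param vel `velocity_params`.
#' @param rigids N x 6 matrix of per-subject `c(omega, tau)` nuisance
#'   parameters (default: all identity).
#' @param dt Euler step, days.
#' @return List with `loss` (the scalar objective), `per_subject` mean
#'   fitting error in mm (unnormalized distances), and `t_top`.
#' @export
growth_objective <- function(template, cohort, anchors, weights, vel,
                             rigids = NULL, dt = 5) {
  n <- length(cohort$maps)
  if (is.null(rigids)) rigids <- matrix(0, n, 6)
  snap <- round(cohort$ages / dt)
  t_top <- max(snap) * dt
  states <- if (t_top > 0) {
    res <- integrate_flow(template, anchors, weights, vel,
                          flow_spec(0, t_top, dt), trajectory = TRUE)
    lapply(snap + 1, function(i) res$trajectory[, , i])
  } else {
    lapply(seq_len(n), function(s) template$coords)
  }
  loss <- 0
  per_subject <- numeric(n)
  for (s in seq_len(n)) {
    obs <- apply_rigid(cohort$maps[[s]]$coords, rigids[s, ])
    nrm <- row_norms(cohort$maps[[s]]$coords)
    keep <- nrm > 1e-9
    if (!all(keep)) message(sum(!keep), " zero-norm point(s) excluded for subject ", s)
    d <- row_norms(states[[s]] - obs)
    loss <- loss + sum(d[keep] / nrm[keep]) / sum(keep)
    per_subject[s] <- mean(d[keep])
  }
  list(loss = loss / n, per_subject = per_subject, t_top = t_top)
}

# ---- internal differentiable objective -------------------------------------
# Parameters are optimized in a preconditioned space. Growth-rate
# denominators are q_v(t) = s_v exp(c0) (1 + B c1 tau + B c2 tau^2) with
# tau = t / t_ref and B = TAU_SCALE: the log-amplitude c0 makes shrinking
# or growing a rate multiplicative (reaching near-zero rates in tens of
# Adam steps instead of thousands), and B matches the magnitude of
# realistic ten-year rate declines to unit-scale coefficients.
# Displacement denominators stay affine, q_z(t) = s_z (c0 + B c1 tau +
# B c2 tau^2), so z keeps its sign freedom. Weight-shape parameters enter
# as log(k), log(sigma); rigids as axis-angle + translation per subject.
# All of this is invertible bookkeeping: the exported model is always the
# literal rational-coefficient triple (p0, p1, p2).

TAU_SCALE <- 10

fit_state_init <- function(A, base_idx, n_subj, v_init, z_init, k, sigma) {
  list(cv = matrix(0, A, 3),
       cz = matrix(rep(c(1, 0, 0), each = length(base_idx)),
                   length(base_idx), 3),
       logk = log(k), logsigma = log(sigma),
       rig = matrix(0, n_subj, 6),
       s_v = 1 / v_init, s_z = 1 / z_init, base_idx = base_idx)
}

state_to_vec <- function(st, opt_shape, opt_rigid) {
  v <- c(st$cv, st$cz)
  if (opt_shape) v <- c(v, st$logk, st$logsigma)
  if (opt_rigid) v <- c(v, st$rig)
  v
}

vec_to_state <- function(vec, st, opt_shape, opt_rigid) {
  A <- nrow(st$cv); B <- nrow(st$cz)
  i <- 0
  st$cv <- matrix(vec[i + seq_len(3 * A)], A, 3); i <- i + 3 * A
  if (B > 0) { st$cz <- matrix(vec[i + seq_len(3 * B)], B, 3); i <- i + 3 * B }
  if (opt_shape) {
    st$logk <- vec[i + 1]; st$logsigma <- vec[i + 2]; i <- i + 2
  }
  if (opt_rigid) {
    st$rig <- matrix(vec[i + seq_len(6 * nrow(st$rig))], nrow(st$rig), 6)
  }
  st
}

# velocity_params equivalent of a fit state (literal rational coefficients)
state_to_velocity <- function(st, t_ref = 3650) {
  A <- nrow(st$cv)
  amp <- st$s_v * exp(st$cv[, 1])
  p_v <- cbind(amp,
               amp * TAU_SCALE * st$cv[, 2] / t_ref,
               amp * TAU_SCALE * st$cv[, 3] / t_ref^2)
  p_z <- matrix(0, A, 3)
  if (length(st$base_idx))
    p_z[st$base_idx, ] <- cbind(st$s_z * st$cz[, 1],
                                st$s_z * TAU_SCALE * st$cz[, 2] / t_ref,
                                st$s_z * TAU_SCALE * st$cz[, 3] / t_ref^2)
  list(p_v = p_v, p_z = p_z)
}

# Full loss + analytic gradient of the objective (data term + denominator
# positivity penalty) with respect to the fit state. Returns NULL gradient
# entries for frozen blocks.
fit_loss_grad <- function(st, prep, want_grad = TRUE) {
  A <- nrow(st$cv)
  B <- TAU_SCALE
  tau <- prep$times / prep$t_ref        # per-step scaled times
  N <- length(prep$times)
  Pv <- 1 + B * (cbind(tau, tau^2) %*% t(st$cv[, 2:3, drop = FALSE]))  # N x A
  amp <- exp(st$cv[, 1])
  V <- 1 / (Pv * rep(st$s_v * amp, each = N))
  Z <- matrix(0, N, A)
  if (length(st$base_idx)) {
    qz <- rep(st$cz[, 1], each = N) +
      B * (cbind(tau, tau^2) %*% t(st$cz[, 2:3, drop = FALSE]))
    Z[, st$base_idx] <- 1 / (st$s_z * qz)
  }

  k <- exp(st$logk); sigma <- exp(st$logsigma)
  raw <- exp(-k * prep$D_loc - (0.5 / sigma^2) * prep$R2)
  raw[raw < prep$support_threshold] <- 0
  tot <- rowSums(raw)
  static <- tot < prep$support_threshold
  W <- raw
  W[!static, ] <- raw[!static, , drop = FALSE] / tot[!static]
  W[static, ] <- 0

  fwd <- cpp_flow(prep$X0, prep$U, prep$Y, W, prep$arow0, V, Z,
                  prep$dtv, TRUE)
  if (fwd$error_step > 0) return(list(loss = NaN))

  loss <- 0
  inj <- list(); inj_idx <- integer(0)
  g_rig <- if (want_grad) matrix(0, nrow(st$rig), 6) else NULL
  inj_acc <- new.env(parent = emptyenv())
  for (s in seq_len(prep$n_subj)) {
    theta <- st$rig[s, ]
    R <- rotation_matrix(theta[1:3])
    obs0 <- prep$obs[[s]]
    obs <- sweep(obs0 %*% t(R), 2, theta[4:6], `+`)
    Xp <- fwd$traj[, , prep$snap[s] + 1]
    diff <- Xp - obs
    dn <- row_norms(diff)
    wgt <- prep$point_w[[s]]              # 1/(n M ||I_s(m)||), 0 for excluded
    loss <- loss + sum(wgt * dn)
    if (want_grad) {
      gs <- diff * (wgt / pmax(dn, 1e-12))   # dL/dXp
      key <- as.character(prep$snap[s])
      if (is.null(inj_acc[[key]])) inj_acc[[key]] <- gs else
        inj_acc[[key]] <- inj_acc[[key]] + gs
      h <- -gs                               # dL/d(R obs + tau)
      g_rig[s, 4:6] <- colSums(h)
      Rth <- t(R) %*% t(h)                   # 3 x M
      crossm <- cbind(obs0[, 2] * Rth[3, ] - obs0[, 3] * Rth[2, ],
                      obs0[, 3] * Rth[1, ] - obs0[, 1] * Rth[3, ],
                      obs0[, 1] * Rth[2, ] - obs0[, 2] * Rth[1, ])
      g_rig[s, 1:3] <- t(so3_right_jacobian(theta[1:3])) %*% colSums(crossm)
    }
  }

  # denominator positivity penalty (scaled units, 30-day grid): the
  # polynomial part of q_v must stay positive, |q_z| away from zero
  taup <- prep$pen_tau
  Pvp <- 1 + B * (cbind(taup, taup^2) %*% t(st$cv[, 2:3, drop = FALSE]))
  viol_v <- pmax(prep$pen_margin - Pvp, 0)
  pen <- prep$pen_weight * sum(viol_v^2)
  gqz_pen <- NULL
  if (length(st$base_idx)) {
    qzp <- rep(st$cz[, 1], each = length(taup)) +
      B * (cbind(taup, taup^2) %*% t(st$cz[, 2:3, drop = FALSE]))
    viol_z <- pmax(prep$pen_margin - abs(qzp), 0)
    pen <- pen + prep$pen_weight * sum(viol_z^2)
    if (want_grad)
      gqz_pen <- -2 * prep$pen_weight * viol_z * sign(qzp)
  }
  loss <- loss + pen
  if (!want_grad) return(list(loss = loss))

  keys <- ls(inj_acc)
  inj <- lapply(keys, function(kk) inj_acc[[kk]])
  inj_idx <- as.integer(keys)
  adj <- cpp_flow_adjoint(fwd$traj, prep$U, prep$Y, W, prep$arow0, V, Z,
                          prep$dtv, inj_idx, inj)

  # chain per-step rate gradients to the preconditioned coefficients:
  # dV/dc0 = -V, dV/dc1 = -V B tau / P, dV/dc2 = -V B tau^2 / P
  GVV <- adj$gV * V
  g_cv <- cbind(-colSums(GVV),
                -B * colSums(GVV * tau / Pv),
                -B * colSums(GVV * tau^2 / Pv))
  g_cv[, 2] <- g_cv[, 2] - 2 * prep$pen_weight * B * colSums(viol_v * taup)
  g_cv[, 3] <- g_cv[, 3] - 2 * prep$pen_weight * B * colSums(viol_v * taup^2)
  g_cz <- NULL
  if (length(st$base_idx)) {
    gz_eff <- adj$gZ[, st$base_idx, drop = FALSE] *
      (Z[, st$base_idx, drop = FALSE])^2 * st$s_z
    g_cz <- cbind(-colSums(gz_eff),
                  -B * colSums(gz_eff * tau),
                  -B * colSums(gz_eff * tau^2))
    g_cz <- g_cz + t(gqz_pen) %*% cbind(1, B * taup, B * taup^2)
  }

  # chain weight gradients to log k, log sigma through the normalization
  gW <- adj$gW
  gRaw <- matrix(0, nrow(gW), ncol(gW))
  ok <- !static
  gRaw[ok, ] <- (gW[ok, , drop = FALSE] -
                   rowSums(gW[ok, , drop = FALSE] * W[ok, , drop = FALSE])) /
    tot[ok]
  g_logk <- -k * sum(gRaw * raw * prep$D_loc)
  g_logsigma <- sum(gRaw * raw * prep$R2) / sigma^2

  list(loss = loss,
       g = list(cv = g_cv, cz = g_cz, logk = g_logk, logsigma = g_logsigma,
                rig = g_rig))
}

grad_to_vec <- function(g, opt_shape, opt_rigid) {
  v <- c(g$cv, g$cz)
  if (opt_shape) v <- c(v, g$logk, g$logsigma)
  if (opt_rigid) v <- c(v, g$rig)
  v
}

# Fixed per-fit quantities: geometry, distances, observations, weights of
# the loss terms.
fit_prepare <- function(template, cohort, anchors, config) {
  M <- nrow(template$coords)
  n <- length(cohort$maps)
  snap <- as.integer(round(cohort$ages / config$dt))
  t_top <- max(snap) * config$dt
  if (t_top == 0) stop("cohort has no post-natal observations to fit")
  times <- (seq_len(t_top / config$dt) - 1) * config$dt
  adjacency <- bone_adjacency(template)
  A <- n_anchors(anchors)
  D_loc <- matrix(0, M, A)
  dist_cache <- list()
  for (a in seq_len(A)) {
    l <- anchors$suture[a]
    if (is.null(dist_cache[[l]]))
      dist_cache[[l]] <- suture_distance(template, l, adjacency)
    D_loc[, a] <- dist_cache[[l]]
  }
  R2 <- matrix(0, M, A)
  for (a in seq_len(A)) {
    D <- sweep(template$coords, 2, anchors$x[a, ])
    R2[, a] <- rowSums(D * D)
  }
  obs <- lapply(cohort$maps, `[[`, "coords")
  point_w <- lapply(obs, function(X) {
    nrm <- row_norms(X)
    w <- ifelse(nrm > 1e-9, 1 / nrm, 0)
    w / (n * sum(nrm > 1e-9))
  })
  list(X0 = template$coords, U = anchors$u, Y = anchors$y,
       arow0 = as.integer(anchors$m - 1L),
       dtv = rep(config$dt, length(times)), times = times,
       t_ref = 3650, snap = snap, n_subj = n, obs = obs, point_w = point_w,
       D_loc = D_loc, R2 = R2,
       support_threshold = config$support_threshold,
       pen_tau = seq(0, 3650, by = 30) / 3650,
       pen_margin = config$pen_margin, pen_weight = config$pen_weight)
}

#' Fit configuration for growth-model inference
#'
#' @param spacing_mm Anchor spacing on the template, mm.
#' @param dt Euler step, days.
#' @param iters Adam iterations.
#' @param lr Initial Adam learning rate (on the scaled parameters).
#' @param seed RNG seed recorded with the fit (the default full-batch
#'   optimization is deterministic; the seed also covers any stochastic
#'   extension).
#' @param v_init,z_init Initial growth and displacement rates defining the
#'   parameter scaling (1/day, mm/day).
#' @param k_init,sigma_init Initial weight-shape parameters (1/mm, mm).
#' @param optimize_shape,optimize_rigid Optimize `k`/`sigma` and the
#'   per-subject rigid nuisances (both default TRUE).
#' @param support_threshold Weight sparsity threshold.
#' @param pen_margin,pen_weight Soft denominator-positivity penalty:
#'   margin in scaled units and weight.
#' @return List of class `fit_config`.
#' @export
fit_config <- function(spacing_mm = 20, dt = 5, iters = 400, lr = 0.01,
                       seed = 1, v_init = 5e-4, z_init = 0.02,
                       k_init = 0.5, sigma_init = 50,
                       optimize_shape = TRUE, optimize_rigid = TRUE,
                       support_threshold = 1e-8,
                       pen_margin = 0.05, pen_weight = 10) {
  structure(list(spacing_mm = spacing_mm, dt = dt, iters = iters, lr = lr,
                 seed = as.integer(seed), v_init = v_init, z_init = z_init,
                 k_init = k_init, sigma_init = sigma_init,
                 optimize_shape = optimize_shape, optimize_rigid = optimize_rigid,
                 support_threshold = support_threshold,
                 pen_margin = pen_margin, pen_weight = pen_weight),
            class = "fit_config")
}

#' Fit the growth model to a cross-sectional cohort
#'
#' Estimates all model parameters -- per-anchor growth-rate coefficients,
#' base displacement coefficients, the weight-shape parameters `k` and
#' `sigma`, and per-subject rigid nuisance transforms -- by Adam gradient
#' descent on the population objective, using analytic adjoint gradients
#' through the discretized flow. Denominator positivity of the rational
#' rate functions is enforced by a soft penalty during optimization and a
#' hard validity check on the returned parameters. If the loss turns
#' non-finite the learning rate is halved and optimization restarts from
#' the last valid state (at most 3 times). Deterministic given the
#' configuration.
#'
#' @param cohort A `cohort` of at least 2 subjects.
#' @param template Birth template (`spherical_map`), e.g. from
#'   [estimate_template()].
#' @param config A [fit_config()].
#' @param anchors Optional precomputed anchors on the template.
#' @return Object of class `fit_report`: the fitted model bundle
#'   (`template`, `anchors`, `weights`, `shape`, `vel`, `rigids`), the
#'   loss trajectory, per-subject mean fitting errors (mm), and a
#'   convergence flag.
#' @export
fit_growth_model <- function(cohort, template, config = fit_config(),
                             anchors = NULL) {
  if (length(cohort$maps) < 2) stop("cohort must contain at least 2 subjects")
  if (is.null(anchors)) anchors <- sample_suture_anchors(template, config$spacing_mm)
  set.seed(config$seed)
  prep <- fit_prepare(template, cohort, anchors, config)
  A <- n_anchors(anchors)
  base_idx <- which(row_norms(anchors$y) > 0)
  st <- fit_state_init(A, base_idx, prep$n_subj, config$v_init, config$z_init,
                       config$k_init, config$sigma_init)
  opt_shape <- config$optimize_shape
  opt_rigid <- config$optimize_rigid

  theta <- state_to_vec(st, opt_shape, opt_rigid)
  m <- v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- config$lr
  loss_traj <- numeric(0)
  best <- list(loss = Inf, theta = theta)
  last_valid <- theta
  restarts <- 0
  it <- 1
  while (it <= config$iters) {
    st <- vec_to_state(theta, st, opt_shape, opt_rigid)
    lg <- fit_loss_grad(st, prep, want_grad = TRUE)
    if (!is.finite(lg$loss)) {
      restarts <- restarts + 1
      if (restarts > 3) stop("optimization diverged after 3 learning-rate restarts")
      lr <- lr / 2
      theta <- last_valid
      m <- v <- numeric(length(theta))
      next
    }
    last_valid <- theta
    loss_traj <- c(loss_traj, lg$loss)
    if (lg$loss < best$loss) best <- list(loss = lg$loss, theta = theta)
    g <- grad_to_vec(lg$g, opt_shape, opt_rigid)
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mhat <- m / (1 - b1^it); vhat <- v / (1 - b2^it)
    theta <- theta - lr * mhat / (sqrt(vhat) + eps)
    it <- it + 1
  }
  st <- vec_to_state(best$theta, st, opt_shape, opt_rigid)
  pv <- state_to_velocity(st, prep$t_ref)
  vel <- velocity_params(pv$p_v, pv$p_z)   # hard validity check
  shape <- weight_shape(k = exp(st$logk), sigma_mm = exp(st$logsigma))
  weights <- build_weights(template, anchors, shape, config$support_threshold)
  obj <- growth_objective(template, cohort, anchors, weights, vel,
                          rigids = st$rig, dt = config$dt)
  structure(list(template = template, anchors = anchors, weights = weights,
                 shape = shape, vel = vel, rigids = st$rig,
                 loss = best$loss, loss_trajectory = loss_traj,
                 per_subject_error = obj$per_subject,
                 converged = restarts <= 3 && is.finite(best$loss),
                 config = config, state = st),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf(paste0("fit_report: loss %.5g after %d iterations; ",
                     "fitting error %.2f +/- %.2f mm; k=%.3g sigma=%.3g\n"),
              x$loss, length(x$loss_trajectory),
              mean(x$per_subject_error), stats::sd(x$per_subject_error),
              x$shape$k, x$shape$sigma_mm))
  invisible(x)
}

#' Average birth anatomy from a cohort
#'
#' Nadaraya-Watson kernel average of coordinates over age, centered at
#' birth with a Gaussian kernel (default bandwidth 90 days): the
#' standardized grid makes per-point averaging across subjects meaningful.
#'
#' @param cohort A `cohort`.
#' @param bandwidth_days Gaussian kernel bandwidth.
#' @return `spherical_map` at age 0.
#' @export
estimate_template <- function(cohort, bandwidth_days = 90) {
  ages <- cohort$ages
  if (!any(ages <= 3 * bandwidth_days))
    stop("no subjects within 3 bandwidths (", 3 * bandwidth_days,
         " days) of birth")
  w <- stats::dnorm(ages, 0, bandwidth_days)
  w <- w / sum(w)
  X <- Reduce(`+`, Map(function(mp, wi) wi * mp$coords, cohort$maps, w))
  spherical_map(X, cohort$maps[[1]]$label, cohort$maps[[1]]$grid_shape,
                age_days = 0, subject_id = "template")
}

#' Personalize suture anchors to a subject
#'
#' Keeps the standardized grid locations of the anchors but recomputes
#' their coordinates, growth directions `u_a` and base displacement
#' directions `y_a` from the subject's own geometry (grid correspondence
#' makes the label structure identical).
#'
#' @param anchors Template `suture_anchors`.
#' @param map Subject `spherical_map`.
#' @return `suture_anchors` on the subject geometry.
#' @export
personalize_anchors <- function(anchors, map) {
  frames <- surface_frames(map)
  adjacency <- bone_adjacency(map)
  base_adj <- base_adjacent_points(map)
  out <- anchors
  out$x <- map$coords[anchors$m, , drop = FALSE]
  for (i in seq_along(anchors$m)) {
    mgp <- anchors$m[i]
    l <- anchors$suture[i]
    idx <- which(map$label == l)
    s_dir <- suture_tangent(map, mgp, idx, radius = 3L)
    n_vec <- frames$normal[mgp, ]
    u <- cross3(n_vec, s_dir)
    u <- u / sqrt(sum(u^2))
    if (sum(u * bone_pair_direction(map, adjacency[[l]])) < 0) u <- -u
    out$u[i, ] <- u
    out$y[i, ] <- if (base_adj[mgp]) n_vec else c(0, 0, 0)
  }
  out
}

#' Predict personalized growth for a subject
#'
#' Starting from a subject's observed anatomy at its current age, the
#' anchors' coordinates and direction vectors are personalized to the
#' subject geometry, the influence weights of the standardized domain are
#' reused unchanged, and the fitted growth flow is integrated to the
#' target age -- optionally with fused sutures to predict growth in the
#' presence of craniosynostosis.
#'
#' @param map Subject `spherical_map` at its observation age (`t0`).
#' @param fit A `fit_report` (or a model bundle with `anchors`, `weights`,
#'   `vel`).
#' @param target_age Target age in days, `>= map$age_days`.
#' @param fused_sutures Optional suture labels fused over the prediction.
#' @param dt Euler step, days.
#' @return A `flow_result` with the predicted map at `target_age`.
#' @export
predict_subject <- function(map, fit, target_age, fused_sutures = character(0),
                            dt = 5) {
  if (target_age < map$age_days)
    stop("target_age precedes the subject's current age")
  if (target_age > fit$vel$t_max)
    warning("target_age exceeds the model span (", fit$vel$t_max,
            " days); extrapolating")
  anchors <- personalize_anchors(fit$anchors, map)
  spec <- flow_spec(map$age_days, target_age, dt, fused_sutures)
  integrate_flow(map, anchors, fit$weights, fit$vel, spec)
}
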