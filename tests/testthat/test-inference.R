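# Small fitting/inference instances; the full-scale parameter recovery
# study lives in test-acceptance.R.

test_that("the population objective is zero for self-consistent cohorts", {
  mdl <- fx_model()
  cfg <- fx_config(n_subjects = 5, noise_sd = 0,
                   rigid_max_deg = 0, rigid_max_mm = 0)
  coh <- generate_cohort(cfg, mdl)
  obj <- growth_objective(mdl$template, coh, mdl$anchors, mdl$weights,
                          mdl$vel, dt = cfg$dt_days)
  expect_lt(obj$loss, 1e-10)
  # a subject identical to the template at age 0 contributes zero without
  # any integration step
  coh0 <- coh
  coh0$maps <- list(mdl$template)
  coh0$ages <- 0
  obj0 <- growth_objective(mdl$template, coh0, mdl$anchors, mdl$weights,
                           mdl$vel)
  expect_identical(obj0$loss, 0)
  expect_identical(obj0$t_top, 0)
})

test_that("a single offset point contributes its normalized distance", {
  mdl <- fx_model()
  e <- c(0.3, -0.4, 1.2)
  m_off <- 137
  obs <- mdl$template
  obs$coords[m_off, ] <- obs$coords[m_off, ] + e
  coh <- list(maps = list(obs), ages = 0)
  class(coh) <- "cohort"
  obj <- growth_objective(mdl$template, coh, mdl$anchors, mdl$weights, mdl$vel)
  M <- nrow(mdl$template$coords)
  expected <- sqrt(sum(e^2)) / sqrt(sum(obs$coords[m_off, ]^2)) / M
  expect_equal(obj$loss, expected, tolerance = 1e-12)
})

test_that("the objective is invariant to consistently transformed subjects", {
  mdl <- fx_model()
  cfg <- fx_config(n_subjects = 3, noise_sd = 0.4,
                   rigid_max_deg = 0, rigid_max_mm = 0)
  coh <- generate_cohort(cfg, mdl)
  base <- growth_objective(mdl$template, coh, mdl$anchors, mdl$weights,
                           mdl$vel)
  # rotating a subject and assigning the inverse rigid nuisance keeps the
  # residuals identical; the 1/||I_s|| size normalization changes, so the
  # invariance is checked on the unnormalized per-subject errors
  theta <- c(0.1, -0.05, 0.2, 0, 0, 0)
  coh2 <- coh
  coh2$maps[[2]] <- transform_map(coh$maps[[2]], theta)
  rig <- matrix(0, 3, 6)
  rig[2, 1:3] <- -theta[1:3]
  obj2 <- growth_objective(mdl$template, coh2, mdl$anchors, mdl$weights,
                           mdl$vel, rigids = rig)
  expect_equal(obj2$per_subject, base$per_subject, tolerance = 1e-9)
})

test_that("analytic adjoint gradients agree with finite differences", {
  cfg <- synth_config(grid_shape = c(24, 12), n_subjects = 5,
                      age_range = c(0, 60), age_dist = "uniform",
                      noise_sd = 0.3, anchor_spacing_mm = 40, seed = 7)
  mdl <- suppressWarnings(suturegrowth:::synth_model(cfg))
  coh <- suppressWarnings(generate_cohort(cfg, mdl))
  fcfg <- fit_config(spacing_mm = 40, dt = 5, seed = 3)
  prep <- suturegrowth:::fit_prepare(mdl$template, coh, mdl$anchors, fcfg)
  A <- length(mdl$anchors$m)
  base_idx <- which(sqrt(rowSums(mdl$anchors$y^2)) > 0)
  st <- suturegrowth:::fit_state_init(A, base_idx, 5, fcfg$v_init,
                                      fcfg$z_init, fcfg$k_init,
                                      fcfg$sigma_init)
  set.seed(42)
  # keep the positivity hinge inactive: its kink is non-smooth by design
  st$cv <- st$cv + cbind(stats::rnorm(A, 0, 0.1), stats::rnorm(A, 0, 0.02),
                         stats::rnorm(A, 0, 0.02))
  if (length(base_idx))
    st$cz <- st$cz + cbind(stats::rnorm(length(base_idx), 0, 0.1),
                           stats::rnorm(length(base_idx), 0, 0.02),
                           stats::rnorm(length(base_idx), 0, 0.02))
  st$logk <- st$logk + 0.1
  st$logsigma <- st$logsigma - 0.1
  st$rig <- matrix(stats::rnorm(5 * 6, 0, 0.02), 5, 6)
  lg <- suturegrowth:::fit_loss_grad(st, prep)
  theta <- suturegrowth:::state_to_vec(st, TRUE, TRUE)
  g <- suturegrowth:::grad_to_vec(lg$g, TRUE, TRUE)
  f_at <- function(th) {
    s2 <- suturegrowth:::vec_to_state(th, st, TRUE, TRUE)
    suturegrowth:::fit_loss_grad(s2, prep, want_grad = FALSE)$loss
  }
  rig_start <- 3 * A + 3 * length(base_idx) + 3
  fd_at <- function(i) {
    # fourth-order central difference; rigid components need a smaller
    # step because point-scale rotations sweep residuals of noise size
    # through the norm terms (huge but finite curvature)
    h <- if (i >= rig_start) 2.5e-4 else 1e-3
    ev <- function(d) { t2 <- theta; t2[i] <- t2[i] + d; f_at(t2) }
    (8 * (ev(h) - ev(-h)) - (ev(2 * h) - ev(-2 * h))) / (12 * h)
  }
  # compare on components whose gradient is numerically resolvable
  set.seed(1)
  resolvable <- which(abs(g) > 1e-6)
  expect_gt(length(resolvable), 20)
  for (i in sample(resolvable, 12)) {
    fd <- fd_at(i)
    expect_true(abs(fd - g[i]) <= 1e-4 * max(abs(fd), abs(g[i])),
                label = sprintf("component %d: fd %.3e vs adjoint %.3e",
                                i, fd, g[i]))
  }
  # components with negligible analytic gradient are negligible in FD too
  for (i in sample(which(abs(g) <= 1e-6), 3))
    expect_lt(abs(fd_at(i)), 1e-5)
})

test_that("template estimation kernel-averages the youngest subjects", {
  mdl <- fx_model()
  cfg <- fx_config(n_subjects = 4, noise_sd = 0,
                   rigid_max_deg = 0, rigid_max_mm = 0,
                   fused_sutures = suture_labels(), z0 = 0)
  # growthless cohort: all subjects equal the template at every age
  coh <- suppressWarnings(generate_cohort(cfg, suppressWarnings(
    suturegrowth:::synth_model(cfg))))
  est <- estimate_template(coh)
  expect_equal(est$coords, mdl$template$coords, tolerance = 1e-12)
  expect_identical(est$age_days, 0)
  # two subjects at age 0: plain midpoint
  c2 <- coh
  c2$maps <- coh$maps[1:2]
  c2$maps[[2]]$coords <- c2$maps[[2]]$coords + 4
  c2$ages <- c(0, 0)
  est2 <- estimate_template(c2)
  expect_equal(est2$coords, c2$maps[[1]]$coords + 2, tolerance = 1e-12)
  # no subjects anywhere near birth: rejected
  c3 <- coh
  c3$ages <- rep(3000, 4)
  expect_error(estimate_template(c3), "bandwidth")
  # averaging beats the noise: per-point error < 3 sd / sqrt(n_eff)
  cfgn <- fx_config(n_subjects = 50, noise_sd = 1.5, age_range = c(0, 80),
                    age_dist = "uniform", rigid_max_deg = 0, rigid_max_mm = 0,
                    fused_sutures = suture_labels(), z0 = 0)
  cohn <- suppressWarnings(generate_cohort(cfgn, suppressWarnings(
    suturegrowth:::synth_model(cfgn))))
  estn <- estimate_template(cohn)
  w <- stats::dnorm(cohn$ages, 0, 90); w <- w / sum(w)
  n_eff <- 1 / sum(w^2)
  err <- abs(estn$coords - mdl$template$coords)
  expect_lt(max(err), 3 * 1.5 / sqrt(n_eff) * 1.5)  # max over 3M gaussians
})

test_that("subject prediction is an identity at the current age and rigid-equivariant", {
  mdl <- fx_model()
  fitlike <- list(template = mdl$template, anchors = mdl$anchors,
                  weights = mdl$weights, shape = mdl$shape, vel = mdl$vel)
  subj <- mdl$template
  subj$age_days <- 200
  same <- predict_subject(subj, fitlike, 200)
  expect_identical(same$coords, subj$coords)
  expect_error(predict_subject(subj, fitlike, 100), "precedes")
  expect_warning(predict_subject(subj, fitlike, 4000), "span")
  # equivariance: predicting a rigidly moved subject moves the prediction
  theta <- c(0.15, -0.1, 0.2, 6, -3, 4)
  pred <- predict_subject(subj, fitlike, 600)
  predr <- predict_subject(transform_map(subj, theta), fitlike, 600)
  expect_lt(max(abs(predr$coords - apply_rigid(pred$coords, theta))), 1e-6)
})

test_that("predictions track the true trajectory of a longitudinal pair", {
  mdl <- fx_model()
  cfg <- fx_config(n_subjects = 3, noise_sd = 0,
                   rigid_max_deg = 0, rigid_max_mm = 0)
  pairs <- generate_longitudinal(cfg, interval_days = c(360, 370), model = mdl)
  fitlike <- list(template = mdl$template, anchors = mdl$anchors,
                  weights = mdl$weights, shape = mdl$shape, vel = mdl$vel)
  for (s in 1) {
    first <- pairs$maps[[2 * s - 1]]
    second <- pairs$maps[[2 * s]]
    first$age_days <- pairs$snap_ages[2 * s - 1]
    pred <- predict_subject(first, fitlike, pairs$snap_ages[2 * s])
    err <- pointwise_error(pred$coords, second$coords)
    # the residual combines Euler discretization with the drift between
    # the birth-age direction frames of the generating trajectory and the
    # frames personalized from the later observation
    expect_lt(err$mean, 0.5)
    expect_lt(err$mean, 0.02 * mean(sqrt(rowSums(second$coords^2))))
  }
})

test_that("fitting is deterministic and recovers a null model from noise", {
  # zero-growth cohort: template plus noise at every age
  cfg <- synth_config(n_subjects = 12, noise_sd = 0.5, age_dist = "uniform",
                      rigid_max_deg = 0, rigid_max_mm = 0,
                      fused_sutures = suture_labels(), z0 = 0,
                      grid_shape = c(24, 12), anchor_spacing_mm = 30,
                      age_range = c(0, 1825), seed = 101)
  mdl0 <- suppressWarnings(suturegrowth:::synth_model(cfg))
  coh <- suppressWarnings(generate_cohort(cfg, mdl0))
  fc <- fit_config(spacing_mm = 30, iters = 150, lr = 0.05, seed = 5,
                   optimize_shape = FALSE, optimize_rigid = FALSE)
  fit <- fit_growth_model(coh, mdl0$template, fc, anchors = mdl0$anchors)
  # implied growth displacement over 10 years stays below the noise level
  curves <- suture_growth_curves(fit$vel, fit$anchors)
  lever <- 40   # typical projection lever arm, mm
  expect_lt(max(curves[nrow(curves), ]) * lever, 3 * 0.5)
  # determinism: identical config, identical result
  fit2 <- fit_growth_model(coh, mdl0$template, fc, anchors = mdl0$anchors)
  expect_identical(fit$loss_trajectory, fit2$loss_trajectory)
  expect_identical(fit$vel$p_v, fit2$vel$p_v)
  expect_identical(fit$rigids, fit2$rigids)
})
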