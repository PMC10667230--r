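test_that("rational rate functions evaluate and guard their denominators", {
  expect_equal(growth_rate(c(0, 10, 123), c(1, 0, 0)), c(1, 1, 1))
  expect_equal(growth_rate(0, c(2, 0, 0)), 0.5)
  expect_equal(growth_rate(1, c(1, 1, 0)), 0.5)
  expect_error(growth_rate(10, c(1, -0.2, 0)), "denominator")
  expect_equal(base_displacement_rate(0, c(1, 0, 0)), 1)
  expect_equal(base_displacement_rate(0, c(-1, 0, 0)), -1)
  expect_equal(base_displacement_rate(2, c(1, 0, 1)), 0.2)
  # construction-time validation over the whole model span
  expect_error(velocity_params(matrix(c(1, -1 / 3000, 0), 1)), "positive")
  expect_silent(velocity_params(matrix(c(1, 0, 0), 1)))
})

test_that("zero-parameter flow is the exact identity", {
  mdl <- fx_model()
  vel0 <- velocity_params(mdl$vel$p_v)          # p_z all zero
  expect_warning(spec <- flow_spec(0, 365, 5, fused_sutures = suture_labels()),
                 "lambdoid")
  res <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, vel0, spec)
  expect_identical(res$coords, mdl$template$coords)
})

test_that("a single Euler step reproduces the hand-computed update", {
  sp <- sphere_band_map()
  m_anchor <- which(sp$label == "M")[5]
  su <- single_anchor_setup(sp, m_anchor, c(1, 0.5, -0.2), v_const = 2e-3)
  dt <- 5
  res <- integrate_flow(sp, su$anchors, su$weights, su$vel, flow_spec(0, dt, dt))
  u <- su$anchors$u[1, ]
  s0 <- drop((sp$coords - matrix(sp$coords[m_anchor, ], nrow(sp$coords), 3,
                                 byrow = TRUE)) %*% u)
  expected <- sp$coords + dt * 2e-3 * s0 %o% u
  expect_equal(res$coords, expected, tolerance = 1e-14)
})

test_that("constant-rate single-anchor flow matches the exponential solution", {
  sp <- sphere_band_map()
  m_anchor <- which(sp$label == "M")[5]
  v <- 2e-3
  su <- single_anchor_setup(sp, m_anchor, c(1, 0, 0), v_const = v)
  u <- su$anchors$u[1, ]
  span <- 365
  proj0 <- drop((sp$coords - matrix(sp$coords[m_anchor, ], nrow(sp$coords), 3,
                                    byrow = TRUE)) %*% u)
  exact <- proj0 * exp(v * span)
  err <- sapply(c(5, 1, 0.2), function(dt) {
    res <- integrate_flow(sp, su$anchors, su$weights, su$vel,
                          flow_spec(0, span, dt))
    projT <- drop((res$coords - matrix(res$coords[m_anchor, ],
                                       nrow(sp$coords), 3, byrow = TRUE)) %*% u)
    max(abs(projT - exact) / pmax(abs(exact), 1e-9))
  })
  # first-order convergence: error ratio ~ dt ratio
  expect_gt(err[1] / err[2], 3.5)
  expect_lt(err[1] / err[2], 6.5)
  expect_gt(err[2] / err[3], 3.5)
  expect_lt(err[2] / err[3], 6.5)
  expect_lt(err[2], 1e-3)
})

test_that("compiled and reference integrators agree to machine precision", {
  mdl <- fx_model()
  spec <- flow_spec(0, 200, 5)
  rc <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel, spec,
                       engine = "cpp")
  rr <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel, spec,
                       engine = "r")
  expect_lt(max(abs(rc$coords - rr$coords)), 1e-12)
})

test_that("flows compose across aligned step boundaries", {
  mdl <- fx_model()
  full <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel,
                         flow_spec(0, 300, 5))
  half <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel,
                         flow_spec(0, 150, 5))
  mid <- half$map
  rest <- integrate_flow(mid, mdl$anchors, mdl$weights, mdl$vel,
                         flow_spec(150, 300, 5))
  expect_lt(max(abs(rest$coords - full$coords)), 1e-9)
})

test_that("the flow is invertible with first-order round-trip error", {
  mdl <- fx_model()
  spec <- flow_spec(0, 365, 5)
  fwd <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel, spec)
  back <- invert_flow(fwd, mdl$anchors, mdl$weights, mdl$vel, spec)
  err5 <- max(sqrt(rowSums((back - mdl$template$coords)^2)))
  expect_lt(err5, 0.5)
  spec1 <- flow_spec(0, 365, 1)
  fwd1 <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel, spec1)
  back1 <- invert_flow(fwd1, mdl$anchors, mdl$weights, mdl$vel, spec1)
  err1 <- max(sqrt(rowSums((back1 - mdl$template$coords)^2)))
  expect_gt(err5 / err1, 3)
  expect_lt(err5 / err1, 8)
  # rigid equivariance of the round trip
  theta <- c(0.1, -0.2, 0.15, 4, -6, 2)
  tmr <- transform_map(mdl$template, theta)
  anr <- personalize_anchors(mdl$anchors, tmr)
  fwdr <- integrate_flow(tmr, anr, mdl$weights, mdl$vel, spec)
  backr <- invert_flow(fwdr, anr, mdl$weights, mdl$vel, spec)
  errr <- max(sqrt(rowSums((backr - tmr$coords)^2)))
  expect_lt(abs(errr - err5), 1e-9)
})

test_that("growth is local: an isolated suture cannot move far bones", {
  mdl <- fx_model()
  # activate only the metopic suture (all others fused), no base drift
  vel <- velocity_params(mdl$vel$p_v)
  spec <- suppressWarnings(
    flow_spec(0, 730, 5, fused_sutures = setdiff(suture_labels(), "M")))
  res <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, vel, spec)
  moved <- sqrt(rowSums((res$coords - mdl$template$coords)^2))
  raw <- anchor_kernel(mdl$template, mdl$anchors, mdl$shape)
  far <- apply(raw[, mdl$anchors$suture == "M", drop = FALSE], 1, max) < 1e-8
  expect_true(any(far))
  expect_lt(max(moved[far]), 1e-6)
  # and the frontal bones did move
  expect_gt(max(moved[mdl$template$label %in% c("LF", "RF")]), 0.5)
})

test_that("mirror-symmetric inputs produce mirror-symmetric growth", {
  mdl <- fx_model()
  res <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel,
                        flow_spec(0, 730, 5))
  gs <- mdl$template$grid_shape
  ia <- suturegrowth:::grid_col_index(gs)
  ie <- suturegrowth:::grid_row_index(gs)
  perm <- suturegrowth:::grid_index(gs[1] + 1L - ia, ie, gs)
  mirrored <- res$coords[perm, , drop = FALSE]
  mirrored[, 1] <- -mirrored[, 1]
  expect_lt(max(abs(mirrored - res$coords)), 1e-6)
})

test_that("suture fusion reproduces craniosynostosis growth constraints", {
  mdl <- fx_model()
  spec <- flow_spec(0, 730, 5)
  # no fusion: bitwise identical to the plain flow
  plain <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel, spec)
  nofuse <- simulate_synostosis(mdl$template, mdl$anchors, mdl$weights,
                                mdl$vel, spec, fused_sutures = character(0))
  expect_identical(plain$coords, nofuse$coords)
  expect_error(simulate_synostosis(mdl$template, mdl$anchors, mdl$weights,
                                   mdl$vel, spec, fused_sutures = "QQ"),
               "unknown suture")
  # every suture fused with no base drift: identity
  vel0 <- velocity_params(mdl$vel$p_v)
  all_fused <- suppressWarnings(
    simulate_synostosis(mdl$template, mdl$anchors, mdl$weights, vel0, spec,
                        fused_sutures = suture_labels()))
  expect_identical(all_fused$coords, mdl$template$coords)
  # sagittal fusion: lateral growth strictly reduced, antero-posterior
  # growth within 5% of normative (scaphocephaly direction)
  sag <- simulate_synostosis(mdl$template, mdl$anchors, mdl$weights,
                             mdl$vel, spec, fused_sutures = "S")
  lat <- function(X) diff(range(X[, 1]))
  ap <- function(X) diff(range(X[, 2]))
  expect_lt(lat(sag$coords), lat(plain$coords))
  expect_lt(abs(ap(sag$coords) - ap(plain$coords)) / ap(plain$coords), 0.05)
})

test_that("fusing a suture never amplifies growth along its own direction", {
  mdl <- fx_model()
  vel <- velocity_params(mdl$vel$p_v)        # isolate suture growth (no z)
  spec <- flow_spec(0, 730, 5)
  plain <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, vel, spec)
  adj <- bone_adjacency(mdl$template)
  for (l in c("M", "S", "LC")) {
    fus <- simulate_synostosis(mdl$template, mdl$anchors, mdl$weights, vel,
                               spec, fused_sutures = l)
    rows <- mdl$anchors$suture == l
    u_mean <- colMeans(mdl$anchors$u[rows, , drop = FALSE])
    u_mean <- u_mean / sqrt(sum(u_mean^2))
    pts <- mdl$template$label %in% adj[[l]]
    d_plain <- abs((plain$coords[pts, ] - mdl$template$coords[pts, ]) %*% u_mean)
    d_fused <- abs((fus$coords[pts, ] - mdl$template$coords[pts, ]) %*% u_mean)
    # fusion suppresses growth along the suture direction in aggregate
    # and at the large majority of substantially-moving points; a strict
    # pointwise inequality does not hold in a combined flow, because
    # where another suture contributes an opposing component along u the
    # normative terms partially cancel and removing one can increase the
    # residual magnitude
    expect_lt(mean(d_fused), 0.7 * mean(d_plain))
    big <- d_plain > 0.5
    expect_true(any(big))
    expect_gt(mean(d_fused[big] <= d_plain[big] + 0.05), 0.8)
  }
})

test_that("degenerate flow windows are handled per contract", {
  mdl <- fx_model()
  # zero-length window: identity without stepping
  same <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel,
                         flow_spec(100, 100, 5))
  expect_identical(same$coords, mdl$template$coords)
  # dt longer than the window: one clamped step with a warning
  expect_warning(
    one <- integrate_flow(mdl$template, mdl$anchors, mdl$weights, mdl$vel,
                          flow_spec(0, 3, 5)),
    "clamped")
  expect_equal(length(one$times), 2)
})

test_that("integrated growth curves summarize rate parameters per suture", {
  mdl <- fx_model()
  curves <- suture_growth_curves(mdl$vel, mdl$anchors, seq(0, 3650, by = 5))
  expect_setequal(colnames(curves), suture_labels())
  expect_true(all(diff(curves[, "M"]) > 0))          # v > 0
  expect_equal(unname(curves[1, ]), rep(0, 6))
  # trapezoid oracle on one suture with the known rational profile
  a <- which(mdl$anchors$suture == "S")[1]
  tg <- seq(0, 3650, by = 5)
  v <- growth_rate(tg, mdl$vel$p_v[a, ])
  manual <- c(0, cumsum((v[-1] + v[-length(v)]) / 2 * diff(tg)))
  expect_equal(unname(curves[, "S"]), manual, tolerance = 1e-12)
  expect_equal(unname(growth_curve_error(mdl$vel, mdl$vel, mdl$anchors)),
               rep(0, 6))
})
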