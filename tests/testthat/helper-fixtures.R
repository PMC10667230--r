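# Shared fixtures, built once per test run. All synthetic, seeded.

fx_env <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(fx_env[[name]])) fx_env[[name]] <- builder()
  fx_env[[name]]
}

fx_config <- function(...) synth_config(grid_shape = c(48, 24), seed = 101, ...)

fx_template <- function() fx_get("template", function() make_template(fx_config()))

fx_model <- function() fx_get("model", function() suturegrowth:::synth_model(fx_config()))

# A labeled sphere-patch map with a single meridian suture band (M)
# separating two hemibones; analytic geometry for oracle tests.
sphere_band_map <- function(n_az = 32, n_el = 16, radius = 50) {
  theta <- -pi + (seq_len(n_az) - 0.5) * 2 * pi / n_az
  phi <- (seq_len(n_el) - 1) / (n_el - 1) * 80 * pi / 180
  th <- rep(theta, times = n_el); ph <- rep(phi, each = n_az)
  coords <- radius * cbind(cos(ph) * sin(th), cos(ph) * cos(th), sin(ph))
  lab <- ifelse(sin(th) > 0, "LF", "RF")
  # single-column meridian band on the anterior side
  jpos <- which.min(ifelse(sin(theta) > 0 & cos(theta) > 0, sin(theta), Inf))
  ia <- rep(seq_len(n_az), times = n_el)
  lab[ia == jpos] <- "M"
  lab[rep(seq_len(n_el), each = n_az) == 1] <- "BASE"
  spherical_map(coords, lab, c(n_az, n_el))
}

# Minimal single-anchor setup on a map: uniform unit weights, anchor at
# grid point m with direction u (y = 0), constant growth rate v.
single_anchor_setup <- function(map, m, u, v_const) {
  anchors <- structure(list(suture = "M", m = as.integer(m),
                            x = map$coords[m, , drop = FALSE],
                            u = matrix(u / sqrt(sum(u^2)), 1),
                            y = matrix(0, 1, 3)),
                       class = "suture_anchors")
  weights <- structure(list(w = matrix(1, nrow(map$coords), 1),
                            static = rep(FALSE, nrow(map$coords))),
                       class = "weight_field")
  vel <- velocity_params(matrix(c(1 / v_const, 0, 0), 1))
  list(anchors = anchors, weights = weights, vel = vel)
}

# mirror image (x -> -x) of a map: permuted grid columns, negated x,
# left/right labels swapped
mirror_map <- function(map) {
  gs <- map$grid_shape
  ia <- suturegrowth:::grid_col_index(gs); ie <- suturegrowth:::grid_row_index(gs)
  perm <- suturegrowth:::grid_index(gs[1] + 1L - ia, ie, gs)
  X <- map$coords[perm, , drop = FALSE]
  X[, 1] <- -X[, 1]
  spherical_map(X, suturegrowth:::mirror_label(map$label[perm]), gs,
                age_days = map$age_days, subject_id = map$subject_id)
}

expect_rows_unit <- function(X, tol = 1e-9) {
  expect_lt(max(abs(sqrt(rowSums(X^2)) - 1)), tol)
}
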