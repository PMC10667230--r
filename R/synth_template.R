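#' Configuration for the synthetic calvaria generator
#'
#' Bundles every quantity the synthetic-data module needs: grid shape,
#' template ellipsoid semi-axes, the true per-suture growth-rate and
#' base-displacement parameters used to simulate growth, observation
#' noise, cohort size, age distribution, rigid pose perturbation bounds
#' and the mandatory seed.
#'
#' Defaults emulate a normative pediatric cohort: a birth calvaria with
#' lateral/antero-posterior semi-axes 49/60 mm (cephalic index 81.7
#' percent), vertical semi-axis 45 mm; young-skewed ages from a truncated
#' exponential with mean 1100 days on 0--3650 days; 0.5 mm iid coordinate
#' noise; pose perturbations up to 5 degrees / 3 mm. True growth rates
#' follow the semi-logarithmic profile `v(t) = 1/(p0 + p1 t)` with faster
#' coronal growth; see the package vignette for the rationale of each
#' value.
#'
#' @param grid_shape Integer pair (n_az, n_el), each >= 8.
#' @param semi_axes Named or plain numeric triple (lateral, AP, vertical), mm.
#' @param elevation_max_deg Highest parallel of the grid (degrees above the
#'   base plane); the grid stops short of the pole.
#' @param v0,v_decline Per-suture initial growth rate (1/day) and the
#'   factor by which it declines by 10 years; together they fix the true
#'   `p_v` triples (p2 = 0).
#' @param z0,z_decline Same for the cranial-base displacement rate (mm/day).
#' @param noise_sd Coordinate noise standard deviation, mm.
#' @param n_subjects Cohort size.
#' @param age_range Age support in days.
#' @param age_mean_days Mean of the truncated-exponential age draw; set
#'   `age_dist = "uniform"` for uniform ages.
#' @param age_dist `"exponential"` (young-skewed, the default) or `"uniform"`.
#' @param rigid_max_deg,rigid_max_mm Bounds of the random rigid pose
#'   perturbation applied to each subject (recorded as ground truth).
#' @param anchor_spacing_mm Arc-length spacing of suture control points.
#' @param dt_days Euler step of the simulated true flow.
#' @param k,sigma_mm True weight-shape parameters (locality decay 1/mm and
#'   isotropic kernel scale mm).
#' @param fused_sutures Character vector of suture labels fused from birth
#'   (pathological cohorts), or empty.
#' @param seed Mandatory integer seed.
#' @return Object of class `synth_config` (a validated list).
#' @export
synth_config <- function(grid_shape = c(48, 24),
                         semi_axes = c(lateral = 49, ap = 60, vertical = 45),
                         elevation_max_deg = 82,
                         v0 = c(M = 1e-3, LC = 3e-3, RC = 3e-3,
                                S = 1e-3, LL = 1.2e-3, RL = 1.2e-3),
                         v_decline = 30,
                         z0 = 0.04, z_decline = 10,
                         noise_sd = 0.5,
                         n_subjects = 200,
                         age_range = c(0, 3650),
                         age_mean_days = 1100,
                         age_dist = c("exponential", "uniform"),
                         rigid_max_deg = 5, rigid_max_mm = 3,
                         anchor_spacing_mm = 20,
                         dt_days = 5,
                         k = 0.5, sigma_mm = 50,
                         fused_sutures = character(0),
                         seed = NULL) {
  if (is.null(seed)) stop("synth_config requires an explicit seed")
  age_dist <- match.arg(age_dist)
  stopifnot(noise_sd >= 0, all(age_range >= 0), all(age_range <= 3650),
            length(grid_shape) == 2, all(grid_shape >= 8),
            all(v0 > 0), v_decline >= 1, k > 0, sigma_mm > 0)
  structure(list(grid_shape = as.integer(grid_shape),
                 semi_axes = unname(semi_axes),
                 elevation_max_deg = elevation_max_deg,
                 v0 = v0, v_decline = v_decline,
                 z0 = z0, z_decline = z_decline,
                 noise_sd = noise_sd, n_subjects = n_subjects,
                 age_range = age_range, age_mean_days = age_mean_days,
                 age_dist = age_dist,
                 rigid_max_deg = rigid_max_deg, rigid_max_mm = rigid_max_mm,
                 anchor_spacing_mm = anchor_spacing_mm, dt_days = dt_days,
                 k = k, sigma_mm = sigma_mm,
                 fused_sutures = fused_sutures, seed = as.integer(seed)),
            class = "synth_config")
}

#' Build the synthetic birth template
#'
#' Samples the upper part of an ellipsoid on the azimuth x elevation grid
#' and paints the anatomical label layout: five bone plates, six suture
#' bands (obtained as sign-change cell bands of smooth separating
#' functions, so they are connected, two cells thick and meet the
#' anatomically correct bones), and the base boundary ring on elevation
#' row 1. Deterministic given the configuration.
#'
#' Layout (normalized coordinates, +y anterior, +x left): the coronal
#' plane sits at y = 0.30 and the lambdoid plane at y = -0.55; the
#' midline plane x = 0 carries the metopic suture anteriorly of the
#' coronal band and the sagittal suture between the coronal and lambdoid
#' bands; the top grid row closes the sagittal band over the vertex.
#'
#' @param config A [synth_config()].
#' @return A `spherical_map` at age 0.
#' @export
make_template <- function(config = synth_config(seed = 1)) {
  gs <- config$grid_shape
  n_az <- gs[1]; n_el <- gs[2]
  ax <- config$semi_axes
  # azimuth offset by half a cell: the grid is mirror-symmetric in x and
  # no point sits exactly on the midline plane
  theta <- -pi + (seq_len(n_az) - 0.5) * 2 * pi / n_az
  phi <- (seq_len(n_el) - 1) / (n_el - 1) * config$elevation_max_deg * pi / 180
  th <- rep(theta, times = n_el)
  ph <- rep(phi, each = n_az)
  xn <- cos(ph) * sin(th)     # unit-sphere coordinates
  yn <- cos(ph) * cos(th)
  zn <- sin(ph)
  coords <- cbind(ax[1] * xn, ax[2] * yn, ax[3] * zn)

  y_c <- 0.30; y_o <- -0.55
  lab <- rep(NA_character_, n_az * n_el)
  lab[yn >  y_c] <- ifelse(xn[yn >  y_c] > 0, "LF", "RF")
  lab[yn <= y_c & yn >= y_o] <- ifelse(xn[yn <= y_c & yn >= y_o] > 0, "LP", "RP")
  lab[yn < y_o] <- "O"

  # midline suture band: sign-change cells of x; metopic anterior of the
  # coronal plane, sagittal between coronal and lambdoid planes
  mid <- sign_change_band(xn, gs)
  lab[mid & yn > y_c] <- "M"
  lab[mid & yn <= y_c & yn >= y_o] <- "S"

  # coronal and lambdoid bands: sign-change cells of (y - plane), split
  # left/right at the midline; they override the midline band at junctions
  cor_band <- sign_change_band(yn - y_c, gs)
  lab[cor_band] <- ifelse(xn[cor_band] > 0, "LC", "RC")
  lam_band <- sign_change_band(yn - y_o, gs)
  lab[lam_band] <- ifelse(xn[lam_band] > 0, "LL", "RL")

  # vertex cap: top row joins the anterior and posterior sagittal strips
  top <- grid_row_index(gs) == n_el
  lab[top] <- "S"
  if (max(cos(phi[n_el - 1]), 0) >= y_c)
    stop("suture band width too large for grid: raise elevation_max_deg or n_el")

  lab[grid_row_index(gs) == 1L] <- "BASE"
  spherical_map(coords, lab, gs, age_days = 0, subject_id = "template")
}

# Cells where a smooth separating function changes sign against the next
# cell in azimuth or elevation (both cells of each crossing marked): a
# connected band two cells thick along the zero level set.
sign_change_band <- function(f, gs) {
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  nxt_az <- grid_index(ia + 1L, ie, gs)
  band <- f * f[nxt_az] < 0
  band[nxt_az[band]] <- TRUE
  up_ok <- ie < gs[2]
  nxt_el <- grid_index(ia, pmin(ie + 1L, gs[2]), gs)
  flip <- up_ok & (f * f[nxt_el] < 0)
  band[flip] <- TRUE
  band[nxt_el[flip]] <- TRUE
  band
}
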