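#' Trace of the Green-Lagrange surface strain
#'
#' Quantifies local expansion between a reference map and a deformed
#' configuration of the same grid. Tangent vectors along the two grid
#' directions are estimated by central finite differences (periodic in
#' azimuth, one-sided at elevation edges); with reference metric
#' `G = E^T E` and deformed metric `C` (from the deformed tangents), the
#' strain tensor is `E_GL = (C - G)/2` and the reported scalar is the
#' intrinsic trace `tr(G^-1 E_GL)` -- the 2D surface realization of
#' `tr((grad d + grad d^T + grad d grad d^T)/2)`, summing the two
#' tangential principal directions. A uniform in-plane stretch by factor
#' `s` therefore yields `s^2 - 1`, and any rigid motion yields zero.
#'
#' @param ref_map Reference `spherical_map`.
#' @param deformed M x 3 matrix (or `flow_result`) of deformed coordinates.
#' @return Object of class `strain_field`: list with per-point `epsilon`
#'   (NaN at degenerate cells), the reference cell `area` weights and the
#'   map labels.
#' @export
strain_trace <- function(ref_map, deformed) {
  if (inherits(deformed, "flow_result")) deformed <- deformed$coords
  if (!all(dim(deformed) == dim(ref_map$coords)))
    stop("deformed coordinates do not match the reference grid")
  gs <- ref_map$grid_shape
  dr <- grid_derivatives(ref_map$coords, gs)
  dd <- grid_derivatives(deformed, gs)
  g11 <- rowSums(dr$d_az * dr$d_az); g12 <- rowSums(dr$d_az * dr$d_el)
  g22 <- rowSums(dr$d_el * dr$d_el)
  c11 <- rowSums(dd$d_az * dd$d_az); c12 <- rowSums(dd$d_az * dd$d_el)
  c22 <- rowSums(dd$d_el * dd$d_el)
  det_g <- g11 * g22 - g12^2
  degenerate <- det_g < 1e-12
  if (any(degenerate))
    message(sum(degenerate), " degenerate metric cell(s) marked NaN")
  # tr(G^-1 (C - G)) / 2
  tr_num <- g22 * (c11 - g11) - 2 * g12 * (c12 - g12) + g11 * (c22 - g22)
  eps <- ifelse(degenerate, NaN, 0.5 * tr_num / det_g)
  structure(list(epsilon = eps, area = sqrt(pmax(det_g, 0)),
                 label = ref_map$label, age_days = NA_real_),
            class = "strain_field")
}

#' @export
print.strain_field <- function(x, ...) {
  cat(sprintf("strain_field: %d points, mean %.4f, range [%.4f, %.4f]\n",
              length(x$epsilon), mean(x$epsilon, na.rm = TRUE),
              min(x$epsilon, na.rm = TRUE), max(x$epsilon, na.rm = TRUE)))
  invisible(x)
}

#' Temporal strain rate from a strain series
#'
#' Central finite differences of per-point strain over age (one-sided at
#' the series ends), reported per year (365.25 days).
#'
#' @param series M x T matrix of strain values (or list of
#'   `strain_field`s) at increasing `ages_days`.
#' @param ages_days Strictly increasing ages, days.
#' @return M x T matrix of strain rates, 1/year.
#' @export
strain_rate <- function(series, ages_days) {
  if (is.list(series))
    series <- do.call(cbind, lapply(series, `[[`, "epsilon"))
  if (length(ages_days) != ncol(series))
    stop("ages must match the number of strain columns")
  if (is.unsorted(ages_days, strictly = TRUE))
    stop("ages must be strictly increasing")
  if (ncol(series) < 2) stop("at least 2 ages required")
  Tn <- ncol(series)
  out <- matrix(NA_real_, nrow(series), Tn)
  t <- ages_days / 365.25
  for (j in seq_len(Tn)) {
    j0 <- max(1, j - 1); j1 <- min(Tn, j + 1)
    out[, j] <- (series[, j1] - series[, j0]) / (t[j1] - t[j0])
  }
  out
}

#' Area-weighted per-bone average of a point field
#'
#' Averages a per-grid-point scalar over each bone plate, weighting by the
#' local reference cell area (from the surface metric); NaN points are
#' excluded. Bones without any grid point are reported as NA.
#'
#' @param field Numeric vector of length M, or a `strain_field`.
#' @param map `spherical_map` supplying labels and geometry.
#' @param labels Labels to average over (default the five bones).
#' @return Named numeric vector.
#' @export
per_bone_average <- function(field, map, labels = bone_labels()) {
  if (inherits(field, "strain_field")) field <- field$epsilon
  gs <- map$grid_shape
  dr <- grid_derivatives(map$coords, gs)
  area <- row_norms(row_cross(dr$d_az, dr$d_el))
  out <- stats::setNames(rep(NA_real_, length(labels)), labels)
  for (l in labels) {
    idx <- which(map$label == l & is.finite(field))
    if (length(idx))
      out[l] <- sum(field[idx] * area[idx]) / sum(area[idx])
  }
  out
}

#' Cephalic index of a calvaria map
#'
#' 100 times the ratio of the maximal lateral extent (x range) to the
#' maximal antero-posterior extent (y range) in the standardized pose; the
#' extent-based convention of this package (coordinate ranges rather than
#' landmark distances).
#'
#' @param map A `spherical_map` (or M x 3 coordinate matrix).
#' @return Cephalic index in percent.
#' @export
cephalic_index <- function(map) {
  X <- if (inherits(map, "spherical_map")) map$coords else map
  lat <- diff(range(X[, 1]))
  ap <- diff(range(X[, 2]))
  if (ap < 1e-9) stop("degenerate antero-posterior extent")
  100 * lat / ap
}

#' Point-wise prediction/fitting error
#'
#' Per-point Euclidean distances between corresponding grid points of a
#' predicted and an observed map, with mean and standard deviation.
#' Optionally removes a best-fit rigid transform first (Kabsch algorithm),
#' mirroring the rigid nuisance of the fitting objective; alignment is off
#' by default, as appropriate for evaluating predictions in a shared
#' standardized pose.
#'
#' @param pred,obs `spherical_map`s or M x 3 matrices with identical grid.
#' @param align Remove the best-fit rigid transform before measuring.
#' @return Object of class `error_summary`: per-point `distances` (mm),
#'   `mean`, `sd`, and the `align` flag.
#' @export
pointwise_error <- function(pred, obs, align = FALSE) {
  P <- if (inherits(pred, "spherical_map")) pred$coords else
    if (inherits(pred, "flow_result")) pred$coords else pred
  O <- if (inherits(obs, "spherical_map")) obs$coords else obs
  if (!all(dim(P) == dim(O))) stop("prediction and observation shapes differ")
  if (align) P <- kabsch_align(P, O)
  d <- row_norms(P - O)
  structure(list(distances = d, mean = mean(d), sd = stats::sd(d),
                 align = align), class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("%.2f +/- %.2f mm%s\n", x$mean, x$sd,
              if (x$align) " (rigidly aligned)" else ""))
  invisible(x)
}

# Best-fit rigid superposition of X onto Y (rotation + translation).
kabsch_align <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  s <- svd(t(Xc) %*% Yc)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sweep(Xc %*% t(R), 2, cy, `+`)
}
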