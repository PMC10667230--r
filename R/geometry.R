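#' Standardized spherical-map calvaria representation
#'
#' A spherical map is a 2D azimuth x elevation grid in which every grid
#' point carries the 3D Euclidean coordinates (mm) of the corresponding
#' anatomical location on the calvarial surface plus a categorical
#' bone/suture label. Grid point correspondence is anatomical: the same
#' grid index refers to the same location across subjects. The azimuth
#' index wraps (periodic); elevation does not, and elevation row 1 is the
#' calvaria--cranial-base boundary ring.
#'
#' Axis convention: +x left, +y anterior, +z superior; units mm.
#'
#' @param coords Numeric matrix (n_az*n_el) x 3 of positions in mm; row
#'   `m = i_az + (i_el - 1) * n_az`.
#' @param label Character vector of length n_az*n_el with values from
#'   [all_labels()].
#' @param grid_shape Integer pair `c(n_az, n_el)`, both >= 8.
#' @param age_days Non-negative subject age in days.
#' @param subject_id Opaque identifier.
#' @return Object of class `spherical_map`.
#' @seealso [validate_map()], [make_template()]
#' @export
spherical_map <- function(coords, label, grid_shape, age_days = 0,
                          subject_id = "template") {
  map <- structure(
    list(coords = coords, label = as.character(label),
         grid_shape = as.integer(grid_shape),
         age_days = as.numeric(age_days),
         subject_id = as.character(subject_id)),
    class = "spherical_map")
  validate_map(map)
  map
}

#' @export
print.spherical_map <- function(x, ...) {
  cat(sprintf("spherical_map: %d x %d grid (%d points), age %.0f days, subject '%s'\n",
              x$grid_shape[1], x$grid_shape[2], nrow(x$coords),
              x$age_days, x$subject_id))
  tab <- table(factor(x$label, levels = all_labels()))
  cat("labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Validate a spherical map
#'
#' Checks the structural invariants of the representation: finite
#' coordinates, grid dimensions >= 8, known labels, base labels confined
#' to the boundary ring (lowest elevation row), and that every suture
#' present forms a connected band separating exactly two bone plates with
#' the canonical anatomical pairing (metopic between the frontals,
#' sagittal between the parietals, each coronal between a frontal and a
#' parietal, each lambdoid between a parietal and the occipital).
#'
#' @param map A `spherical_map`.
#' @param check_sutures Also verify suture-band topology (connectivity and
#'   adjacency); set `FALSE` for deliberately degenerate fixtures.
#' @return Invisibly `TRUE`; stops with a message on violation.
#' @export
validate_map <- function(map, check_sutures = TRUE) {
  gs <- map$grid_shape
  if (length(gs) != 2 || any(gs < 8))
    stop("grid dimensions must be >= 8 in each direction, got ",
         paste(gs, collapse = "x"))
  M <- gs[1] * gs[2]
  if (!is.matrix(map$coords) || nrow(map$coords) != M || ncol(map$coords) != 3)
    stop("coords must be a ", M, " x 3 matrix")
  if (!all(is.finite(map$coords))) stop("non-finite coordinates in map")
  if (length(map$label) != M) stop("label length must equal number of grid points")
  bad <- setdiff(unique(map$label), all_labels())
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (map$age_days < 0) stop("age_days must be non-negative")
  base_rows <- grid_row_index(gs)
  if (any(map$label == "BASE" & base_rows != 1L))
    stop("BASE labels must occur only on the boundary ring (elevation row 1)")
  if (check_sutures) {
    adj <- bone_adjacency(map)   # errors if a suture separates != 2 bones
    canon <- canonical_adjacency()
    for (l in names(adj)) {
      if (!setequal(adj[[l]], canon[[l]]))
        stop(sprintf("suture %s separates {%s}, expected {%s}", l,
                     paste(sort(adj[[l]]), collapse = ","),
                     paste(sort(canon[[l]]), collapse = ",")))
      if (!band_connected(map, l))
        stop("suture band ", l, " is not connected")
    }
  }
  invisible(TRUE)
}

canonical_adjacency <- function() {
  list(M = c("LF", "RF"), LC = c("LF", "LP"), RC = c("RF", "RP"),
       S = c("LP", "RP"), LL = c("LP", "O"), RL = c("RP", "O"))
}

# ---- grid index helpers -----------------------------------------------------
# m = i_az + (i_el - 1) * n_az; azimuth wraps, elevation does not.

grid_row_index <- function(gs) rep(seq_len(gs[2]), each = gs[1])
grid_col_index <- function(gs) rep(seq_len(gs[1]), times = gs[2])

grid_index <- function(i_az, i_el, gs) {
  i_az <- ((i_az - 1L) %% gs[1]) + 1L
  i_az + (i_el - 1L) * gs[1]
}

# 4-neighbours of every grid point (azimuth periodic, elevation clipped).
# Returns an M x 4 integer matrix with NA where no neighbour exists.
grid_neighbours <- function(gs) {
  n_az <- gs[1]; n_el <- gs[2]
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  left  <- grid_index(ia + 1L, ie, gs)
  right <- grid_index(ia - 1L, ie, gs)
  up    <- ifelse(ie < n_el, grid_index(ia, ie + 1L, gs), NA_integer_)
  down  <- ifelse(ie > 1L,  grid_index(ia, ie - 1L, gs), NA_integer_)
  cbind(left, right, up, down)
}

# 8-neighbour version, used for band connectivity only.
grid_neighbours8 <- function(gs) {
  n_az <- gs[1]; n_el <- gs[2]
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  out <- matrix(NA_integer_, n_az * n_el, 8)
  k <- 0
  for (da in c(-1L, 0L, 1L)) for (de in c(-1L, 0L, 1L)) {
    if (da == 0L && de == 0L) next
    k <- k + 1
    iel <- ie + de
    ok <- iel >= 1L & iel <= n_el
    out[ok, k] <- grid_index(ia[ok] + da, iel[ok], gs)
  }
  out
}

band_connected <- function(map, lab) {
  idx <- which(map$label == lab)
  if (length(idx) <= 1) return(TRUE)
  nb <- grid_neighbours8(map$grid_shape)
  inband <- logical(nrow(map$coords)); inband[idx] <- TRUE
  seen <- logical(nrow(map$coords))
  queue <- idx[1]; seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (n in nb[cur, ]) {
      if (!is.na(n) && inband[n] && !seen[n]) {
        seen[n] <- TRUE
        queue <- c(queue, n)
      }
    }
  }
  all(seen[idx])
}

# ---- surface frames ---------------------------------------------------------

#' Per-grid-point orthonormal surface frames
#'
#' Estimates, for every grid point, an outward unit surface normal and two
#' unit tangents spanning the tangent plane, by central finite differences
#' of the coordinate grid (periodic in azimuth, one-sided at the elevation
#' edges). Normals are oriented outward: positive inner product with the
#' vector from the map centroid.
#'
#' @param map A `spherical_map`.
#' @return List with M x 3 matrices `normal`, `t1` (azimuthal tangent) and
#'   `t2 = normal x t1`.
#' @export
surface_frames <- function(map) {
  gs <- map$grid_shape
  d <- grid_derivatives(map$coords, gs)
  nrm <- row_cross(d$d_az, d$d_el)
  nn <- row_norms(nrm)
  if (any(nn < 1e-12)) {
    bad <- which(nn < 1e-12)[1]
    stop(sprintf("degenerate grid cell at azimuth %d, elevation %d (repeated coordinates)",
                 grid_col_index(gs)[bad], grid_row_index(gs)[bad]))
  }
  nrm <- nrm / nn
  ctr <- colMeans(map$coords)
  outward <- rowSums(nrm * sweep(map$coords, 2, ctr)) < 0
  nrm[outward, ] <- -nrm[outward, ]
  t1 <- d$d_az / row_norms(d$d_az)
  # re-orthogonalize t1 against the normal, then t2 completes the frame
  t1 <- t1 - rowSums(t1 * nrm) * nrm
  t1 <- t1 / row_norms(t1)
  t2 <- row_cross(nrm, t1)
  list(normal = nrm, t1 = t1, t2 = t2)
}

# Central differences of a gridded M x 3 field: azimuth periodic,
# elevation one-sided at rows 1 and n_el.
grid_derivatives <- function(X, gs) {
  n_az <- gs[1]; n_el <- gs[2]
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  d_az <- X[grid_index(ia + 1L, ie, gs), , drop = FALSE] -
          X[grid_index(ia - 1L, ie, gs), , drop = FALSE]
  up <- grid_index(ia, pmin(ie + 1L, n_el), gs)
  dn <- grid_index(ia, pmax(ie - 1L, 1L), gs)
  d_el <- X[up, , drop = FALSE] - X[dn, , drop = FALSE]
  list(d_az = d_az, d_el = d_el,
       h_az = 2, h_el = ifelse(ie == 1L | ie == n_el, 1, 2))
}

row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(x) sqrt(rowSums(x * x))

normalize_rows <- function(x) x / row_norms(x)

# ---- bone adjacency ---------------------------------------------------------

#' Bone pairs separated by each suture
#'
#' Derives, from 4-neighbour label adjacency on the grid, the pair of bone
#' plates each suture band separates. Growth at a suture only affects
#' these two bones, so this mapping drives the influence weights.
#'
#' @param map A `spherical_map`.
#' @return Named list: suture label -> character pair of bone labels.
#'   A suture adjacent to a number of bones different from two is an
#'   error (the labeling is anatomically inconsistent).
#' @export
bone_adjacency <- function(map) {
  nb <- grid_neighbours(map$grid_shape)
  lab <- map$label
  sut <- intersect(suture_labels(), unique(lab))
  out <- list()
  for (l in sut) {
    idx <- which(lab == l)
    nbl <- lab[nb[idx, ]]
    bones <- sort(unique(nbl[!is.na(nbl) & nbl %in% bone_labels()]))
    if (length(bones) != 2)
      stop(sprintf("suture %s is adjacent to %d bone(s): {%s}; expected exactly 2",
                   l, length(bones), paste(bones, collapse = ",")))
    out[[l]] <- bones
  }
  out
}

# ---- suture anchors ---------------------------------------------------------

#' Sample suture control points (anchors)
#'
#' Each suture band is reduced to an ordered centerline and sampled
#' uniformly by arc length at approximately `spacing_mm` intervals. Every
#' anchor carries: its grid point `m_a` and coordinates `x_a`; the unit
#' growth direction `u_a`, tangential to the cranial surface and
#' perpendicular to the local suture direction; and, for anchors adjacent
#' to the base boundary ring, the unit outward surface normal `y_a` along
#' which cranial-base displacement acts (`y_a = 0` elsewhere).
#'
#' The sign of `u_a` is irrelevant to the flow (the affine scaling term is
#' even in `u_a`); it is fixed reproducibly by a positive inner product
#' with the direction between the centroids of the two bones the suture
#' separates. The local suture tangent is estimated by PCA of the
#' suture-labeled grid points within a 3-grid-step neighbourhood.
#'
#' @param map A `spherical_map` containing at least one suture band.
#' @param spacing_mm Positive target arc-length spacing between anchors.
#' @return Object of class `suture_anchors`: data frame with columns
#'   `anchor`, `suture`, `m` (grid index) plus matrices `x` (positions),
#'   `u`, `y` in its attributes-free list fields.
#' @export
sample_suture_anchors <- function(map, spacing_mm = 20) {
  stopifnot(spacing_mm > 0)
  adj <- bone_adjacency(map)
  if (!length(adj)) stop("map contains no suture-labeled band")
  frames <- surface_frames(map)
  nb8 <- grid_neighbours8(map$grid_shape)
  base_adjacent <- base_adjacent_points(map)

  rows <- list()
  for (l in names(adj)) {
    idx <- which(map$label == l)
    if (length(idx) < 2) {
      message("suture ", l, " has fewer than 2 labeled grid points; skipped")
      next
    }
    line <- band_centerline(map, idx, nb8)
    L <- line$total_length
    n_anchor <- max(1L, round(L / spacing_mm))
    if (spacing_mm > L && length(idx) > 1) {
      warning("spacing (", spacing_mm, " mm) exceeds length of suture ", l,
              " (", signif(L, 4), " mm); placing a single midpoint anchor")
      n_anchor <- 1L
    }
    targets <- if (n_anchor == 1L) L / 2 else seq(0, L, length.out = n_anchor + 1L)
    # representative band cell of the level nearest each target arc length
    pick <- vapply(targets, function(s) line$cell[which.min(abs(line$arc - s))],
                   integer(1))
    pick <- unique(pick)
    # on a mirror-symmetric map, a suture on the midline plane gets the
    # mirror twin of every sampled cell, keeping the anchor set (and the
    # flow it induces) exactly left-right symmetric
    pick <- add_mirror_twins(map, pick, l)
    ref_dir <- bone_pair_direction(map, adj[[l]])
    for (m in pick) {
      s_dir <- suture_tangent(map, m, idx, radius = 3L)
      n_vec <- frames$normal[m, ]
      u <- cross3(n_vec, s_dir)
      nu <- sqrt(sum(u^2))
      if (nu < 1e-12) next
      u <- u / nu
      if (sum(u * ref_dir) < 0) u <- -u
      y <- if (base_adjacent[m]) n_vec else c(0, 0, 0)
      rows[[length(rows) + 1]] <- list(suture = l, m = m, x = map$coords[m, ],
                                       u = u, y = y)
    }
  }
  if (!length(rows)) stop("no anchors could be placed")
  anchors <- structure(list(
    suture = vapply(rows, `[[`, character(1), "suture"),
    m = vapply(rows, `[[`, integer(1), "m"),
    x = do.call(rbind, lapply(rows, `[[`, "x")),
    u = do.call(rbind, lapply(rows, `[[`, "u")),
    y = do.call(rbind, lapply(rows, `[[`, "y"))
  ), class = "suture_anchors")
  anchors
}

#' @export
print.suture_anchors <- function(x, ...) {
  tab <- table(x$suture)
  cat(sprintf("suture_anchors: %d anchors (%s); %d base-adjacent\n",
              length(x$m), paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
              sum(row_norms(x$y) > 0)))
  invisible(x)
}

n_anchors <- function(anchors) length(anchors$m)

# grid points within one 4-step of a BASE cell
base_adjacent_points <- function(map) {
  nb <- grid_neighbours(map$grid_shape)
  isb <- map$label == "BASE"
  nbb <- matrix(isb[nb], nrow = nrow(nb))
  nbb[is.na(nb)] <- FALSE
  rowSums(nbb) > 0
}

# Ordered centerline of a suture band. BFS graph distance from a
# geometrically chosen start cell (lowest elevation row, then most
# anterior, then most lateral) groups the cells into levels across the
# (about two cells wide) band; level centroids form the centerline and
# carry the cumulative arc length. The geometric start rule makes the
# ordering mirror-consistent between left and right sutures.
band_centerline <- function(map, idx, nb8) {
  rows <- grid_row_index(map$grid_shape)[idx]
  score <- order(rows, -map$coords[idx, 2], -abs(map$coords[idx, 1]), idx)
  start <- idx[score[1]]
  dist <- band_bfs(idx, start, nb8)
  levels <- sort(unique(dist))
  cent <- t(vapply(levels, function(d)
    colMeans(map$coords[idx[dist == d], , drop = FALSE]), numeric(3)))
  seglen <- c(0, row_norms(cent[-1, , drop = FALSE] - cent[-nrow(cent), , drop = FALSE]))
  arc <- cumsum(seglen)
  # representative grid cell per level: band cell nearest its level centroid
  cell <- vapply(seq_along(levels), function(i) {
    cand <- idx[dist == levels[i]]
    P <- map$coords[cand, , drop = FALSE]
    dd <- row_norms(P - matrix(cent[i, ], length(cand), 3, byrow = TRUE))
    # quantize the distance key so ulp-level summation differences cannot
    # flip near-ties; ties then break on mirror-invariant geometry
    cand[order(round(dd / 1e-6), -P[, 2], -P[, 3], -abs(P[, 1]), cand)[1]]
  }, integer(1))
  list(cell = cell, arc = arc, total_length = arc[length(arc)])
}

# If the azimuth-mirrored grid cell carries the same suture label (the
# contralateral half of a midline suture band), include it as an anchor
# twin. A label-only rule: it is rigid-equivariant and keeps the anchor
# set of a left-right symmetric template exactly symmetric.
add_mirror_twins <- function(map, pick, l) {
  gs <- map$grid_shape
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  out <- pick
  for (m in pick) {
    tw <- grid_index(gs[1] + 1L - ia[m], ie[m], gs)
    if (tw != m && map$label[tw] == l) out <- c(out, tw)
  }
  unique(out)
}

band_bfs <- function(idx, from, nb8) {
  inband <- integer(0)
  pos <- match(seq_len(nrow(nb8)), idx)  # map grid index -> band position
  dist <- rep(NA_real_, length(idx))
  dist[match(from, idx)] <- 0
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    dc <- dist[match(cur, idx)]
    for (n in nb8[cur, ]) {
      if (is.na(n)) next
      p <- pos[n]
      if (!is.na(p) && is.na(dist[p])) {
        dist[p] <- dc + 1
        queue <- c(queue, n)
      }
    }
  }
  dist[is.na(dist)] <- max(dist, na.rm = TRUE) + 1
  dist
}

# Local suture direction at grid point m: leading PC of suture-labeled
# points within `radius` grid steps, projected into the tangent plane.
suture_tangent <- function(map, m, idx, radius = 3L) {
  gs <- map$grid_shape
  ia <- grid_col_index(gs); ie <- grid_row_index(gs)
  da <- abs(ia[idx] - ia[m])
  da <- pmin(da, gs[1] - da)            # azimuth wraps
  de <- abs(ie[idx] - ie[m])
  near <- idx[da <= radius & de <= radius]
  X <- map$coords[near, , drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  pc <- svd(X, nu = 0, nv = 1)$v[, 1]
  pc / sqrt(sum(pc^2))
}

bone_pair_direction <- function(map, bones) {
  c1 <- colMeans(map$coords[map$label == bones[1], , drop = FALSE])
  c2 <- colMeans(map$coords[map$label == bones[2], , drop = FALSE])
  d <- c2 - c1
  d / sqrt(sum(d^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# ---- rigid transforms -------------------------------------------------------

#' Rigid transforms from axis-angle parameters
#'
#' `rotation_matrix(omega)` is the Rodrigues rotation for the axis-angle
#' vector `omega` (radians); `apply_rigid(X, theta)` applies the rigid
#' transform `R(omega) x + tau` with `theta = c(omega, tau)` to the rows
#' of `X`.
#'
#' @param omega Length-3 axis-angle vector (radians).
#' @param X M x 3 coordinate matrix.
#' @param theta Length-6 vector `c(omega, tau)` with `tau` in mm.
#' @return 3 x 3 rotation matrix, or transformed coordinates.
#' @export
rotation_matrix <- function(omega) {
  th <- sqrt(sum(omega^2))
  K <- skew3(omega)
  if (th < 1e-12) return(diag(3) + K)   # first-order near identity
  diag(3) + sin(th) / th * K + (1 - cos(th)) / th^2 * (K %*% K)
}

#' @rdname rotation_matrix
#' @export
apply_rigid <- function(X, theta) {
  R <- rotation_matrix(theta[1:3])
  sweep(X %*% t(R), 2, theta[4:6], `+`)
}

skew3 <- function(w) {
  matrix(c(0, w[3], -w[2],
           -w[3], 0, w[1],
           w[2], -w[1], 0), 3, 3)
}

# Right Jacobian of SO(3) exponential at omega: exp((omega + d)^) ~
# exp(omega^) exp((J_r d)^).
so3_right_jacobian <- function(omega) {
  th <- sqrt(sum(omega^2))
  K <- skew3(omega)
  if (th < 1e-8) return(diag(3) - 0.5 * K)
  diag(3) - (1 - cos(th)) / th^2 * K + (th - sin(th)) / th^3 * (K %*% K)
}

# Geodesic rotation angle (radians) between two axis-angle vectors.
rotation_angle_between <- function(om1, om2) {
  R <- rotation_matrix(om1) %*% t(rotation_matrix(om2))
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2)))
}

#' Apply a rigid transform to a whole map
#'
#' Convenience wrapper returning a new `spherical_map` with transformed
#' coordinates; labels and metadata unchanged.
#'
#' @inheritParams rotation_matrix
#' @param map A `spherical_map`.
#' @return Transformed `spherical_map`.
#' @export
transform_map <- function(map, theta) {
  out <- map
  out$coords <- apply_rigid(map$coords, theta)
  out
}
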