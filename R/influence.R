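#' Weight-shape parameters of the suture influence model
#'
#' `k` (1/mm) controls how fast a suture's influence decays with the
#' Euclidean distance to the bones it separates; `Sigma_l` (1/mm^2) is the
#' symmetric positive-definite concentration matrix of the Gaussian kernel
#' that distributes influence among the control points along a suture.
#' Although conventionally named a variance matrix, it enters the kernel
#' exponent directly (without inversion), i.e. larger eigenvalues mean a
#' tighter kernel. By default a single isotropic `sigma_mm^-2 * I` is
#' shared by all sutures; a named list of full SPD matrices per suture is
#' also accepted.
#'
#' @param k Positive locality decay, 1/mm.
#' @param sigma_mm Isotropic kernel scale, mm (`Sigma = sigma_mm^-2 I`).
#' @param Sigma Optional named list (by suture label) of 3x3 SPD matrices
#'   overriding `sigma_mm`.
#' @return Object of class `weight_shape`.
#' @export
weight_shape <- function(k = 0.5, sigma_mm = 20, Sigma = NULL) {
  if (k <= 0) stop("k must be positive")
  if (!is.null(Sigma)) {
    for (l in names(Sigma)) {
      S <- Sigma[[l]]
      if (!isTRUE(all.equal(S, t(S))) || any(eigen(S, symmetric = TRUE,
                                                   only.values = TRUE)$values <= 0))
        stop("Sigma for suture ", l, " is not symmetric positive-definite")
    }
  } else {
    if (sigma_mm <= 0) stop("sigma_mm must be positive")
  }
  structure(list(k = k, sigma_mm = sigma_mm, Sigma = Sigma),
            class = "weight_shape")
}

sigma_for <- function(shape, l) {
  if (!is.null(shape$Sigma)) {
    if (is.null(shape$Sigma[[l]])) stop("no Sigma entry for suture ", l)
    shape$Sigma[[l]]
  } else {
    diag(3) / shape$sigma_mm^2
  }
}

#' Suture locality field
#'
#' `w_l(x) = exp(-k d_l(x))` where `d_l(x)` is the Euclidean distance from
#' grid point `x` to the nearest point labeled with either bone the suture
#' separates or with the suture itself, so the field equals one on those
#' bones and on the suture band and decays exponentially outside them.
#'
#' @param map A `spherical_map`.
#' @param l Suture label present in the map.
#' @param k Positive decay, 1/mm.
#' @param adjacency Optional precomputed [bone_adjacency()] result.
#' @return Numeric vector of length M with values in (0, 1].
#' @export
suture_locality <- function(map, l, k, adjacency = NULL) {
  if (k <= 0) stop("k must be positive")
  exp(-k * suture_distance(map, l, adjacency))
}

# d_l(x): distance to the set {bones separated by l} union {l}
suture_distance <- function(map, l, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- bone_adjacency(map)
  if (is.null(adjacency[[l]])) stop("no adjacency defined for suture ", l)
  target <- map$label %in% c(adjacency[[l]], l)
  d <- nearest_point_distance(map$coords, map$coords[target, , drop = FALSE])
  d[target] <- 0   # exact zero on the set itself (cancellation-proof)
  d
}

# For every row of X, the distance to the nearest row of S (blocked to
# bound memory; exact, not approximate).
nearest_point_distance <- function(X, S) {
  out <- numeric(nrow(X))
  s2 <- rowSums(S * S)
  block <- max(1L, floor(2e6 / nrow(S)))
  for (i0 in seq(1L, nrow(X), by = block)) {
    i1 <- min(i0 + block - 1L, nrow(X))
    Xi <- X[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(Xi * Xi), s2, `+`) - 2 * Xi %*% t(S)
    out[i0:i1] <- sqrt(pmax(0, apply(d2, 1, min)))
  }
  out
}

#' Raw anchor influence weights
#'
#' For each anchor `a` on suture `l`, the unnormalized spatial weight
#' `w_l^a(x) = w_l(x) * exp(-0.5 (x - x_a)^T Sigma_l (x - x_a))`:
#' the suture locality field modulated by a Gaussian kernel centered at
#' the control point, creating growth-rate gradients along the suture.
#'
#' @param map A `spherical_map`.
#' @param anchors A `suture_anchors` object.
#' @param shape A [weight_shape()].
#' @return M x A matrix of non-negative raw weights.
#' @export
anchor_kernel <- function(map, anchors, shape) {
  A <- n_anchors(anchors)
  M <- nrow(map$coords)
  adjacency <- bone_adjacency(map)
  loc <- list()
  W <- matrix(0, M, A)
  for (a in seq_len(A)) {
    l <- anchors$suture[a]
    if (is.null(loc[[l]])) loc[[l]] <- suture_locality(map, l, shape$k, adjacency)
    D <- sweep(map$coords, 2, anchors$x[a, ])
    Sg <- sigma_for(shape, l)
    q <- rowSums((D %*% Sg) * D)
    W[, a] <- loc[[l]] * exp(-0.5 * q)
  }
  W
}

#' Normalized weight field
#'
#' Normalizes raw anchor weights per grid point so they sum to one (the
#' discrete counterpart of the unit-integral weight constraint). Raw
#' weights below `support_threshold` are treated as exactly zero, and grid
#' points whose total raw weight falls below the threshold are flagged
#' static: they receive zero velocity from every anchor.
#'
#' @param raw M x A matrix of raw weights (from [anchor_kernel()]).
#' @param support_threshold Sparsity/static cutoff on raw weights.
#' @return Object of class `weight_field`: list with the normalized M x A
#'   matrix `w` and logical vector `static`.
#' @export
normalize_weights <- function(raw, support_threshold = 1e-8) {
  if (ncol(raw) < 1) stop("at least one anchor required")
  raw[raw < support_threshold] <- 0
  tot <- rowSums(raw)
  static <- tot < support_threshold
  w <- raw
  w[!static, ] <- raw[!static, , drop = FALSE] / tot[!static]
  w[static, ] <- 0
  structure(list(w = w, static = static), class = "weight_field")
}

#' Build the full influence weight field for a map
#'
#' Convenience composition of [anchor_kernel()] and [normalize_weights()].
#' Weights are computed once on the reference geometry and held fixed
#' during flow integration; in the standardized spherical domain they are
#' shared across subjects.
#'
#' @inheritParams anchor_kernel
#' @inheritParams normalize_weights
#' @return A `weight_field`.
#' @export
build_weights <- function(map, anchors, shape = weight_shape(),
                          support_threshold = 1e-8) {
  normalize_weights(anchor_kernel(map, anchors, shape), support_threshold)
}

#' @export
print.weight_field <- function(x, ...) {
  cat(sprintf("weight_field: %d grid points x %d anchors; %d static points; density %.1f%%\n",
              nrow(x$w), ncol(x$w), sum(x$static),
              100 * mean(x$w > 0)))
  invisible(x)
}
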