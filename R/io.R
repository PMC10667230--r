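#' Read and write spherical maps
#'
#' Maps are stored in a versioned plain-text container: a header block
#' (`#suturegrowth-map v2`, grid shape, age, subject id) followed by one
#' row per grid point with azimuth index, elevation index, the three
#' coordinates (full double precision) and the integer label code from
#' [label_codes()]. Round trips are lossless. Version-1 files (without a
#' subject id header) are accepted with a migration note.
#'
#' @param map A `spherical_map`.
#' @param path File path.
#' @return `read_map()` returns a `spherical_map`; `write_map()` returns
#'   the path invisibly.
#' @export
write_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#suturegrowth-map v2",
               sprintf("#grid %d %d", map$grid_shape[1], map$grid_shape[2]),
               sprintf("#age_days %.17g", map$age_days),
               sprintf("#subject_id %s", map$subject_id),
               "az el x y z label"), con)
  gs <- map$grid_shape
  codes <- label_codes()[map$label]
  df <- cbind(grid_col_index(gs), grid_row_index(gs))
  lines <- sprintf("%d %d %.17g %.17g %.17g %d", df[, 1], df[, 2],
                   map$coords[, 1], map$coords[, 2], map$coords[, 3], codes)
  writeLines(lines, con)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- readLines(path)
  if (!grepl("^#suturegrowth-map v[12]$", lines[1]))
    stop("not a suturegrowth map file (bad version tag): ", path)
  version <- sub("^#suturegrowth-map v", "", lines[1])
  if (version == "1")
    message("migrating version-1 map file: ", path)
  hdr <- grep("^#", lines)
  get_hdr <- function(key, default = NULL) {
    ln <- grep(paste0("^#", key, " "), lines[hdr], value = TRUE)
    if (!length(ln)) {
      if (is.null(default)) stop("missing header '", key, "' in ", path)
      return(default)
    }
    sub(paste0("^#", key, " "), "", ln[1])
  }
  gs <- as.integer(strsplit(get_hdr("grid"), " ")[[1]])
  age <- as.numeric(get_hdr("age_days"))
  sid <- get_hdr("subject_id", default = "unknown")
  body <- lines[-seq_len(max(hdr) + 1)]    # skip headers + column line
  con <- textConnection(body)
  on.exit(close(con))
  dat <- utils::read.table(con, col.names = c("az", "el", "x", "y", "z", "code"),
                           colClasses = c("integer", "integer", "numeric",
                                          "numeric", "numeric", "integer"))
  if (nrow(dat) != gs[1] * gs[2])
    stop("map body has ", nrow(dat), " rows, expected ", gs[1] * gs[2])
  codes <- label_codes()
  bad <- setdiff(unique(dat$code), unname(codes))
  if (length(bad))
    stop("unknown label code(s) in ", path, ": ", paste(bad, collapse = ", "))
  ord <- order(dat$el, dat$az)
  dat <- dat[ord, ]
  lab <- names(codes)[match(dat$code, codes)]
  X <- as.matrix(dat[, c("x", "y", "z")])
  dimnames(X) <- NULL
  spherical_map(X, lab, gs, age_days = age, subject_id = sid)
}

#' Read and write fitted model bundles
#'
#' A model bundle (template, anchors, weight-shape parameters and
#' velocity parameters) is serialized to a single JSON file with full
#' numeric precision; the influence weights are recomputed from the
#' template on read.
#'
#' @param fit A `fit_report` or compatible bundle.
#' @param path JSON file path.
#' @return `read_model()` returns a bundle usable by [predict_subject()].
#' @export
write_model <- function(fit, path) {
  obj <- list(
    format = "suturegrowth-model v1",
    template = list(coords = fit$template$coords,
                    label = fit$template$label,
                    grid_shape = fit$template$grid_shape),
    anchors = list(suture = fit$anchors$suture, m = fit$anchors$m,
                   x = fit$anchors$x, u = fit$anchors$u, y = fit$anchors$y),
    shape = list(k = fit$shape$k, sigma_mm = fit$shape$sigma_mm),
    vel = list(p_v = fit$vel$p_v, p_z = fit$vel$p_z,
               t_max = fit$vel$t_max, eps_den = fit$vel$eps_den))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "suturegrowth-model v1"))
    stop("not a suturegrowth model file: ", path)
  template <- spherical_map(matrix(obj$template$coords, ncol = 3),
                            obj$template$label,
                            obj$template$grid_shape)
  anchors <- structure(list(suture = obj$anchors$suture,
                            m = as.integer(obj$anchors$m),
                            x = matrix(obj$anchors$x, ncol = 3),
                            u = matrix(obj$anchors$u, ncol = 3),
                            y = matrix(obj$anchors$y, ncol = 3)),
                       class = "suture_anchors")
  shape <- weight_shape(k = obj$shape$k, sigma_mm = obj$shape$sigma_mm)
  vel <- velocity_params(matrix(obj$vel$p_v, ncol = 3),
                         matrix(obj$vel$p_z, ncol = 3),
                         t_max = obj$vel$t_max, eps_den = obj$vel$eps_den)
  weights <- build_weights(template, anchors, shape)
  list(template = template, anchors = anchors, shape = shape, vel = vel,
       weights = weights)
}

#' Read and write cohorts
#'
#' A cohort is stored as a directory: one map file per subject plus a
#' JSON manifest with ages, subject ids, pair links and (for synthetic
#' cohorts) the generating configuration and ground-truth rigid
#' parameters.
#'
#' @param cohort A `cohort`.
#' @param dir Directory path (created if needed).
#' @return `read_cohort()` returns a `cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("subject%04d.map", seq_along(cohort$maps))
  for (i in seq_along(cohort$maps))
    write_map(cohort$maps[[i]], file.path(dir, files[i]))
  manifest <- list(format = "suturegrowth-cohort v1",
                   files = files, ages = cohort$ages,
                   subject_ids = cohort$subject_ids,
                   pair_of = cohort$pair_of, visit = cohort$visit,
                   truth = if (!is.null(cohort$truth))
                     list(rigids = cohort$truth$rigids,
                          config = unclass(cohort$truth$config)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) stop("cohort manifest not found: ", mf)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(manifest$format, "suturegrowth-cohort v1"))
    stop("not a suturegrowth cohort directory: ", dir)
  maps <- lapply(file.path(dir, manifest$files), read_map)
  truth <- NULL
  if (!is.null(manifest$truth) && length(manifest$truth))
    truth <- list(rigids = matrix(manifest$truth$rigids, ncol = 6),
                  config = manifest$truth$config)
  structure(list(maps = maps, ages = manifest$ages,
                 subject_ids = manifest$subject_ids,
                 pair_of = manifest$pair_of, visit = manifest$visit,
                 truth = truth),
            class = "cohort")
}

#' Export a map as a surface mesh
#'
#' Triangulates the quad grid with a fixed diagonal rule, welds the
#' azimuth seam (shared vertices), closes the vertex cap with a fan to
#' the top-ring centroid, and writes ASCII PLY (optionally with a
#' per-vertex scalar as the `quality` property) or OBJ (labels as
#' comments).
#'
#' @param map `spherical_map` or `flow_result`.
#' @param path Output path; format from extension if not given.
#' @param format `"ply"` or `"obj"`.
#' @param scalar Optional per-vertex scalar (e.g. strain) for PLY.
#' @return The path, invisibly.
#' @export
export_mesh <- function(map, path, format = c("auto", "ply", "obj"),
                        scalar = NULL) {
  if (inherits(map, "flow_result")) map <- map$map
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  X <- map$coords
  if (!all(is.finite(X)))
    stop("NaN/Inf coordinates at point index(es): ",
         paste(utils::head(which(!is.finite(rowSums(X))), 10), collapse = ", "))
  gs <- map$grid_shape
  n_az <- gs[1]; n_el <- gs[2]
  # quad faces between consecutive rings, fixed diagonal (v1 v2 v4 / v2 v3 v4)
  faces <- list()
  for (ie in seq_len(n_el - 1)) for (ia in seq_len(n_az)) {
    v1 <- grid_index(ia, ie, gs); v2 <- grid_index(ia + 1L, ie, gs)
    v3 <- grid_index(ia + 1L, ie + 1L, gs); v4 <- grid_index(ia, ie + 1L, gs)
    faces[[length(faces) + 1]] <- c(v1, v2, v4)
    faces[[length(faces) + 1]] <- c(v2, v3, v4)
  }
  # close the vertex cap with a fan to the top-ring centroid
  apex <- nrow(X) + 1L
  top <- grid_index(seq_len(n_az), n_el, gs)
  Xall <- rbind(X, colMeans(X[top, , drop = FALSE]))
  for (ia in seq_len(n_az))
    faces[[length(faces) + 1]] <- c(grid_index(ia, n_el, gs),
                                    grid_index(ia + 1L, n_el, gs), apex)
  F <- do.call(rbind, faces)
  if (!is.null(scalar)) scalar <- c(scalar, mean(scalar[top]))
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "ply") {
    writeLines(c("ply", "format ascii 1.0",
                 "comment suturegrowth calvaria mesh",
                 sprintf("element vertex %d", nrow(Xall)),
                 "property float x", "property float y", "property float z",
                 if (!is.null(scalar)) "property float quality",
                 sprintf("element face %d", nrow(F)),
                 "property list uchar int vertex_indices",
                 "end_header"), con)
    if (is.null(scalar))
      writeLines(sprintf("%.8g %.8g %.8g", Xall[, 1], Xall[, 2], Xall[, 3]), con)
    else
      writeLines(sprintf("%.8g %.8g %.8g %.8g", Xall[, 1], Xall[, 2],
                         Xall[, 3], scalar), con)
    writeLines(sprintf("3 %d %d %d", F[, 1] - 1L, F[, 2] - 1L, F[, 3] - 1L), con)
  } else {
    writeLines("# suturegrowth calvaria mesh", con)
    labs <- c(map$label, "APEX")
    writeLines(sprintf("v %.8g %.8g %.8g # %s", Xall[, 1], Xall[, 2],
                       Xall[, 3], labs), con)
    writeLines(sprintf("f %d %d %d", F[, 1], F[, 2], F[, 3]), con)
  }
  invisible(path)
}
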