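#' Labelled point cloud container
#'
#' The universal exchange object of the package: an `N x 3` coordinate matrix
#' with optional per-point integer class labels and optional unit normals.
#' Coordinates are in scanner units (mm) unless the cloud has been passed
#' through [normalize_cloud()].
#'
#' @param points numeric `N x 3` matrix of coordinates.
#' @param labels optional integer vector of length `N` with values in
#'   `[0, n_classes)`; `NULL` for unlabelled clouds.
#' @param normals optional `N x 3` matrix of unit normals (each row must have
#'   Euclidean norm 1 within `1e-6`).
#' @param n_classes number of classes the labels are drawn from (default 33,
#'   the FDI scheme of [fdi_label_scheme()]).
#' @return An object of class `labeled_cloud`.
#' @examples
#' cl <- labeled_cloud(matrix(rnorm(30), 10, 3), labels = rep(0L, 10))
#' cl
#' @export
labeled_cloud <- function(points, labels = NULL, normals = NULL, n_classes = 33L) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 3L || nrow(points) < 1L) {
    stop("`points` must be a numeric N x 3 matrix with N >= 1")
  }
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  n <- nrow(points)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("`labels` must have one entry per point")
    bad <- which(labels < 0L | labels >= n_classes | is.na(labels))
    if (length(bad)) {
      stop("labels outside [0, ", n_classes, ") at indices: ",
           paste(utils::head(bad, 10L), collapse = ", "),
           if (length(bad) > 10L) " ..." else "")
    }
  }
  if (!is.null(normals)) {
    normals <- as.matrix(normals)
    storage.mode(normals) <- "double"
    if (!all(dim(normals) == c(n, 3L))) stop("`normals` must be N x 3")
    nn <- sqrt(rowSums(normals^2))
    if (any(abs(nn - 1) > 1e-6)) stop("normals must be unit vectors (|norm - 1| <= 1e-6)")
  }
  structure(
    list(points = points, labels = labels, normals = normals,
         n_classes = as.integer(n_classes)),
    class = "labeled_cloud"
  )
}

#' @export
print.labeled_cloud <- function(x, ...) {
  cat("labeled_cloud:", nrow(x$points), "points,",
      if (is.null(x$labels)) "unlabelled" else
        paste0(length(unique(x$labels)), " classes present (C=", x$n_classes, ")"),
      if (!is.null(x$normals)) "+ normals" else "", "\n")
  rng <- apply(x$points, 2, range)
  cat(sprintf("  extent: x[%.3g, %.3g] y[%.3g, %.3g] z[%.3g, %.3g]\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

#' Normalize a cloud to the cube [-1, 1]^3
#'
#' Centers the points at their centroid, then scales isotropically by the
#' reciprocal of the largest absolute coordinate after centering, so every
#' coordinate lies in `[-1, 1]` and the extremal one touches +/-1. Isotropic
#' scaling preserves shape, so neighbourhood distances keep their relative
#' ordering. A single-point (or fully degenerate) cloud maps to the origin
#' with scale 1.
#'
#' @param cloud a [labeled_cloud()].
#' @return A list with `cloud` (the normalized cloud) and `transform`, a list
#'   `(centroid, scale)` such that original = normalized / scale + centroid.
#' @seealso [denormalize_points()]
#' @export
normalize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  p <- cloud$points
  centroid <- colMeans(p)
  pc <- sweep(p, 2, centroid)
  m <- max(abs(pc))
  scale <- if (m > 0) 1 / m else 1
  out <- cloud
  out$points <- pc * scale
  if (!is.null(cloud$normals)) out$normals <- cloud$normals  # unit vectors unaffected
  list(cloud = out, transform = list(centroid = centroid, scale = scale))
}

#' Map normalized coordinates back to original units
#'
#' @param points `N x 3` matrix in normalized coordinates.
#' @param transform the transform returned by [normalize_cloud()].
#' @return `N x 3` matrix in the original coordinate frame.
#' @export
denormalize_points <- function(points, transform) {
  sweep(points / transform$scale, 2, transform$centroid, `+`)
}

#' Sample points uniformly over a mesh surface
#'
#' Draws `n_points` points area-uniformly: each triangle is chosen with
#' probability proportional to its area and the point is placed uniformly
#' (barycentric) within it. Used to convert scanner meshes into point clouds.
#'
#' @param mesh a `mesh` object from [read_mesh()].
#' @param n_points number of points to draw (>= 1).
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return An unlabelled [labeled_cloud()].
#' @export
sample_surface <- function(mesh, n_points, seed = 1L) {
  stopifnot(inherits(mesh, "mesh"), n_points >= 1L)
  v <- mesh$vertices
  f <- mesh$faces
  if (nrow(f) < 1L) stop("mesh has no faces to sample")
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  cr <- cross3(b - a, c_ - a)
  area <- 0.5 * sqrt(rowSums(cr^2))
  if (sum(area) <= 0) stop("geometry error: all faces have zero area")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  tri <- sample.int(nrow(f), n_points, replace = TRUE, prob = area)
  # uniform barycentric via the square-root trick
  r1 <- sqrt(stats::runif(n_points))
  r2 <- stats::runif(n_points)
  w1 <- 1 - r1
  w2 <- r1 * (1 - r2)
  w3 <- r1 * r2
  pts <- a[tri, , drop = FALSE] * w1 + b[tri, , drop = FALSE] * w2 +
    c_[tri, , drop = FALSE] * w3
  labeled_cloud(pts)
}

#' Use mesh vertices directly as a point cloud
#'
#' Shortcut that skips surface resampling: scanner meshes are dense enough
#' (~2e5 vertices) that the vertex set is itself a usable cloud.
#'
#' @param mesh a `mesh` object.
#' @return An unlabelled [labeled_cloud()].
#' @export
mesh_vertices_cloud <- function(mesh) {
  stopifnot(inherits(mesh, "mesh"))
  labeled_cloud(mesh$vertices)
}

# cross product of rows of two N x 3 matrices
cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Seed handling: set a local RNG state, restore afterwards, so library calls
# do not disturb the caller's stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# round-trip doubles through 32-bit floats (file coordinate precision)
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          n = length(x), size = 4L)
}
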