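#' Farthest point sampling
#'
#' Greedy max-min subsampling: starting from `start_index`, each successive
#' center is the point whose minimum Euclidean distance to the already
#' selected set is largest. This spreads the `m` centers uniformly over the
#' cloud, so sparse regions are still represented after heavy subsampling
#' (the default pipeline keeps 2048 of ~2e5 scan points). Ties are broken by
#' the lowest point index, making the result deterministic for a fixed start;
#' if `start_index` is `NULL` the start is drawn from `seed`.
#'
#' @param points numeric `N x 3` matrix.
#' @param m number of centers to select (`1 <= m <= N`).
#' @param start_index 1-based index of the first center (default 1).
#' @param seed used only when `start_index` is `NULL`.
#' @return Integer vector of `m` distinct 1-based center indices, in selection
#'   order.
#' @export
farthest_point_sampling <- function(points, m, start_index = 1L, seed = 1L) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  if (m < 1L || m > n) stop("size error: need 1 <= m <= N (m=", m, ", N=", n, ")")
  if (is.null(start_index)) {
    old <- local_seed(seed)
    start_index <- sample.int(n, 1L)
    restore_seed(old)
  }
  stopifnot(start_index >= 1L, start_index <= n)
  sel <- integer(m)
  sel[1] <- as.integer(start_index)
  if (m == 1L) return(sel)
  px <- points[, 1]; py <- points[, 2]; pz <- points[, 3]
  d2 <- (px - px[sel[1]])^2 + (py - py[sel[1]])^2 + (pz - pz[sel[1]])^2
  for (i in 2:m) {
    nxt <- which.max(d2)  # which.max returns the first (lowest-index) maximum
    sel[i] <- nxt
    cand <- (px - px[nxt])^2 + (py - py[nxt])^2 + (pz - pz[nxt])^2
    d2 <- pmin.int(d2, cand)
  }
  sel
}

#' k-nearest-neighbour grouping around sampled centers
#'
#' For each center, finds the `k` points of the cloud with smallest Euclidean
#' distance to it. The center itself is one of its own neighbours (distance
#' 0), so each neighbourhood is never empty and pooled features are defined
#' even for isolated points. Ties are broken by the lowest point index.
#' Computed by exact brute-force distances, chunked over centers to bound
#' memory.
#'
#' @param points numeric `N x 3` matrix.
#' @param center_indices 1-based indices of the centers.
#' @param k neighbourhood size (`1 <= k <= N`).
#' @return Integer `m x k` matrix of 1-based neighbour indices, each row in
#'   increasing distance order.
#' @export
knn_group <- function(points, center_indices, k) {
  if (!is.matrix(points)) points <- as.matrix(points)
  n <- nrow(points)
  if (k < 1L || k > n) stop("size error: need 1 <= k <= N (k=", k, ", N=", n, ")")
  m <- length(center_indices)
  out <- matrix(0L, m, k)
  ptt <- t(points)
  sq <- colSums(ptt^2)
  chunk <- max(1L, floor(4e6 / n))
  for (s in seq(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    idx <- center_indices[s:e]
    centers <- points[idx, , drop = FALSE]
    # squared distances: |c|^2 - 2 c.p + |p|^2
    d2 <- outer(rowSums(centers^2), sq, `+`) - 2 * centers %*% ptt
    for (r in seq_len(e - s + 1L)) {
      # radix sort is stable, so ties resolve to the lowest point index
      ord <- order(d2[r, ], method = "radix")
      out[s + r - 1L, ] <- ord[seq_len(k)]
    }
  }
  out
}

#' Relative-coordinate neighbourhood encoding
#'
#' Describes each neighbour `j` of center `i` by its offset from the center,
#' `r_ij = p_j - p_i`, and the Euclidean distance `d_ij = ||r_ij||`, rather
#' than by absolute position alone. Relative encoding is translation
#' invariant, which is what lets the network separate crowded teeth whose
#' absolute positions vary across arches. The per-neighbour feature row is
#' controlled by `layout`:
#' \describe{
#'   \item{`"rel_dist_abs"`}{`[r_ij (3), d_ij (1), p_j (3)]`, F = 7 (default;
#'     absolute position appended so global arch position is still visible).}
#'   \item{`"rel_dist"`}{`[r_ij, d_ij]`, F = 4 (strictly relative).}
#'   \item{`"abs_only"`}{`[p_j]`, F = 3 (ablation: no relative encoding).}
#' }
#'
#' @param points numeric `N x 3` matrix.
#' @param center_indices 1-based center indices (length `m`).
#' @param neighbor_indices `m x k` matrix from [knn_group()].
#' @param layout one of `"rel_dist_abs"`, `"rel_dist"`, `"abs_only"`.
#' @return An object of class `grouped_encoding`: list with
#'   `center_indices`, `neighbor_indices`, `rel_pos` (`(m*k) x 3`, rows grouped
#'   by center), `dist` (`m x k`), `features` (`(m*k) x F`), and `m`, `k`,
#'   `layout`.
#' @export
relative_encoding <- function(points, center_indices, neighbor_indices,
                              layout = c("rel_dist_abs", "rel_dist", "abs_only")) {
  layout <- match.arg(layout)
  if (!is.matrix(points)) points <- as.matrix(points)
  m <- length(center_indices)
  k <- ncol(neighbor_indices)
  stopifnot(nrow(neighbor_indices) == m)
  nidx <- as.integer(t(neighbor_indices))      # row-major: neighbours of center 1, 2, ...
  pj <- points[nidx, , drop = FALSE]
  pi_ <- points[rep(center_indices, each = k), , drop = FALSE]
  r <- pj - pi_
  d <- sqrt(rowSums(r^2))
  features <- switch(layout,
    rel_dist_abs = cbind(r, d, pj),
    rel_dist = cbind(r, d),
    abs_only = pj
  )
  dimnames(features) <- NULL
  structure(
    list(center_indices = as.integer(center_indices),
         neighbor_indices = neighbor_indices,
         rel_pos = r,
         dist = matrix(d, m, k, byrow = TRUE),
         features = features,
         m = m, k = k, layout = layout),
    class = "grouped_encoding"
  )
}

#' Run the full preprocessing stage on a cloud
#'
#' Convenience wrapper: farthest point sampling of `num_centers` centers
#' (clamped to N with a warning for small clouds), k-NN grouping and relative
#' encoding in one call.
#'
#' @param cloud a [labeled_cloud()] (normalized coordinates expected).
#' @param num_centers number of FPS centers (default 2048).
#' @param k neighbourhood size (default 64).
#' @param layout encoding layout, see [relative_encoding()].
#' @param start_index FPS start (default 1).
#' @return A `grouped_encoding`.
#' @export
preprocess_cloud <- function(cloud, num_centers = 2048L, k = 64L,
                             layout = "rel_dist_abs", start_index = 1L) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  n <- nrow(cloud$points)
  if (num_centers > n) {
    warning("num_centers = ", num_centers, " clamped to cloud size N = ", n)
    num_centers <- n
  }
  centers <- farthest_point_sampling(cloud$points, num_centers,
                                     start_index = start_index)
  neigh <- knn_group(cloud$points, centers, min(k, n))
  relative_encoding(cloud$points, centers, neigh, layout = layout)
}
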