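# Shared fixtures and independent oracles used across the test files.

random_cloud <- function(n, seed = 1L) {
  set.seed(seed)
  matrix(stats::rnorm(3 * n), n, 3)
}

# exhaustive greedy farthest-point oracle: recomputes every min-distance from
# scratch at each step (O(m * N^2)), independent of the package's incremental
# implementation
fps_oracle <- function(points, m, start_index = 1L) {
  n <- nrow(points)
  dmat <- as.matrix(stats::dist(points))
  sel <- start_index
  while (length(sel) < m) {
    mind <- apply(dmat[, sel, drop = FALSE], 1L, min)
    mind[sel] <- -Inf
    sel <- c(sel, which.max(mind))
  }
  as.integer(sel)
}

# brute-force k-NN oracle via the full distance matrix
knn_oracle <- function(points, center_indices, k) {
  dmat <- as.matrix(stats::dist(points))
  rows <- lapply(center_indices, function(ci) {
    order(dmat[ci, ], seq_len(nrow(points)))[seq_len(k)]
  })
  matrix(unlist(rows), nrow = length(center_indices), ncol = k, byrow = TRUE)
}

# independent per-class Jaccard / F1 reference built from label-set
# operations rather than confusion-matrix algebra
jaccard_f1_oracle <- function(pred, truth, classes) {
  t(vapply(classes, function(cl) {
    p <- which(pred == cl)
    g <- which(truth == cl)
    inter <- length(intersect(p, g))
    uni <- length(union(p, g))
    jac <- if (uni == 0) NA_real_ else inter / uni
    f1 <- if (length(p) + length(g) == 0) NA_real_ else
      2 * inter / (length(p) + length(g))
    c(jaccard = jac, f1 = f1)
  }, numeric(2)))
}

tiny_config <- function(num_classes = 3L, ...) {
  model_config(num_centers = 12L, k = 4L, mlp_hidden = c(4L, 6L),
               attn_heads = 2L, head_dim = 3L, head_hidden = c(8L),
               num_classes = num_classes, ...)
}

# a minimal two-triangle unit-square mesh
unit_square_mesh <- function() {
  v <- matrix(c(0, 0, 0,  1, 0, 0,  1, 1, 0,  0, 1, 0), 4, 3, byrow = TRUE)
  f <- matrix(c(1L, 2L, 3L,  1L, 3L, 4L), 2, 3, byrow = TRUE)
  structure(list(vertices = v, faces = f), class = "mesh")
}

expect_rows_sum_to_one <- function(M, tol = 1e-5) {
  expect_lt(max(abs(rowSums(M) - 1)), tol)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
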