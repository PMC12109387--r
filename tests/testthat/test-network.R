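test_that("default configuration yields the reference widths", {
  cfg <- model_config()
  expect_equal(cfg$num_centers, 2048L)
  expect_equal(cfg$k, 64L)
  expect_equal(cfg$local_dim, 128L)
  expect_equal(cfg$attn_heads * cfg$head_dim, 256L)
  expect_equal(cfg$d_model, 256L)
  expect_equal(cfg$num_classes, 33L)
})

test_that("local feature extraction gives local_dim channels and is neighbour-symmetric", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 3)
  pts <- random_cloud(40, seed = 4)
  centers <- farthest_point_sampling(pts, cfg$num_centers)
  nn <- knn_group(pts, centers, cfg$k)
  enc <- relative_encoding(pts, centers, nn, cfg$encoding_layout)
  L <- local_feature_extract(enc, model)
  expect_equal(dim(L), c(cfg$num_centers, cfg$local_dim))

  # permuting each neighbourhood leaves the max-pooled features unchanged
  nn_perm <- t(apply(nn, 1L, sample))
  enc_p <- relative_encoding(pts, centers, nn_perm, cfg$encoding_layout)
  expect_equal(local_feature_extract(enc_p, model), L, tolerance = 1e-10)

  # identical neighbour rows: max of equals collapses to the single MLP output
  enc_same <- enc
  enc_same$features[seq_len(enc$k), ] <- enc$features[rep(1L, enc$k), ]
  L_same <- local_feature_extract(enc_same, model)
  enc_one <- enc
  enc_one$features <- enc$features[1L, , drop = FALSE]
  enc_one$m <- 1L
  enc_one$k <- 1L
  expect_equal(L_same[1, ], local_feature_extract(enc_one, model)[1, ],
               tolerance = 1e-10)

  # wrong feature width is a config error
  enc_bad <- enc
  enc_bad$features <- enc$features[, 1:3]
  expect_error(local_feature_extract(enc_bad, model), "config error")
})

test_that("full default model emits 128-dim local and 256-dim attention features", {
  cfg <- model_config(num_centers = 32L, k = 8L)   # default widths, small cloud
  model <- init_model(cfg, seed = 1)
  pts <- random_cloud(200, seed = 6)
  enc <- preprocess_cloud(labeled_cloud(pts), cfg$num_centers, cfg$k)
  fw <- toothseg:::forward_model(model, enc, pts[enc$center_indices, ])
  expect_equal(dim(fw$cache$L), c(32L, 128L))
  expect_equal(dim(fw$cache$T_), c(32L, 256L))
  seg <- segment(labeled_cloud(pts), model)
  expect_equal(ncol(seg$probabilities), 33L)
})

test_that("self-attention is row-stochastic and matches a hand-computed 2x2 case", {
  # identity projections, head_dim = 2, X = I2: scores QK' = I/sqrt(2)
  X <- diag(2)
  heads <- list(list(Wq = diag(2), Wk = diag(2), Wv = diag(2)))
  Z <- self_attention(X, heads, scale_mode = "sqrt_dhead")
  s <- 1 / sqrt(2)
  a11 <- exp(s) / (exp(s) + exp(0))
  A_expect <- matrix(c(a11, 1 - a11, 1 - a11, a11), 2, 2, byrow = TRUE)
  A <- attr(Z, "attention")[[1]]
  expect_equal(A, A_expect, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unclass(Z), A_expect %*% diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)

  # single token: A = [[1]] and Z = V exactly
  X1 <- matrix(c(0.3, -1.2), 1, 2)
  Wv <- matrix(rnorm(4), 2, 2)
  Z1 <- self_attention(X1, list(list(Wq = diag(2), Wk = diag(2), Wv = Wv)))
  expect_equal(attr(Z1, "attention")[[1]], matrix(1, 1, 1), ignore_attr = TRUE)
  expect_equal(unclass(Z1), X1 %*% Wv, tolerance = 1e-12, ignore_attr = TRUE)

  # random tokens: every attention row sums to 1
  set.seed(8)
  Xr <- matrix(rnorm(60), 10, 6)
  heads_r <- lapply(1:3, function(h) {
    list(Wq = matrix(rnorm(12), 6, 2), Wk = matrix(rnorm(12), 6, 2),
         Wv = matrix(rnorm(12), 6, 2))
  })
  Zr <- self_attention(Xr, heads_r)
  for (A in attr(Zr, "attention")) expect_rows_sum_to_one(A)
  expect_equal(dim(Zr), c(10L, 6L))
})

test_that("attention pooling weights form a simplex and saturate correctly", {
  set.seed(9)
  X <- matrix(rnorm(40), 8, 5)
  w <- rnorm(5)
  ap <- attention_pool(X, w)
  expect_equal(sum(ap$alpha), 1, tolerance = 1e-5)
  expect_equal(ap$f_out, as.vector(crossprod(X, ap$alpha)), tolerance = 1e-12)

  # identical rows: uniform weights, output equals the row
  Xi <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  api <- attention_pool(Xi, rnorm(3))
  expect_equal(api$alpha, rep(1 / 6, 6), tolerance = 1e-12)
  expect_equal(api$f_out, c(1, 2, 3), tolerance = 1e-12)

  # single row: output is that row regardless of w
  ap1 <- attention_pool(X[1, , drop = FALSE], rnorm(5))
  expect_equal(ap1$f_out, X[1, ], tolerance = 1e-12)

  # score gap > 50 saturates the softmax onto one row
  Xs <- rbind(c(100, 1, 1, 1, 1), matrix(0, 5, 5))
  aps <- attention_pool(Xs, c(1, 0, 0, 0, 0))
  expect_lt(max(abs(aps$f_out - Xs[1, ])), 1e-6)
})

test_that("soft pooling matches direct evaluation of the exponential weighting", {
  # two rows, channel values {0, ln 3}: pooled = (0*1 + ln3*3) / 4
  X <- matrix(c(0, log(3)), 2, 1)
  expect_equal(soft_pool(X), 3 * log(3) / 4, tolerance = 1e-12)
  # identical rows / single row pass through
  Xi <- matrix(rep(c(2, -1), each = 4), 4, 2)
  expect_equal(soft_pool(Xi), c(2, -1), tolerance = 1e-12)
  expect_equal(soft_pool(matrix(c(5, -2), 1, 2)), c(5, -2))
  # overflow guard: huge activations stay finite
  expect_true(all(is.finite(soft_pool(matrix(c(1e4, 0, 1e4, 5), 2, 2)))))
})

test_that("fusion concatenates in (local, global) order with summed widths", {
  L <- matrix(1:6, 2, 3)
  g <- c(9, 8)
  Ff <- fuse(L, g)
  expect_equal(dim(Ff), c(2L, 5L))
  expect_equal(Ff[, 1:3], L, ignore_attr = TRUE)
  expect_equal(Ff[1, 4:5], g)
  expect_equal(Ff[2, 4:5], g)
  # zero global leaves the local block intact
  expect_equal(fuse(L, c(0, 0))[, 1:3], L, ignore_attr = TRUE)
  # width example: 128 + 256 = 384
  expect_equal(ncol(fuse(matrix(0, 4, 128), numeric(256))), 384L)
})

test_that("segmentation output is a probability field with argmax labels", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 2)
  cl <- labeled_cloud(random_cloud(50, seed = 12))
  seg <- segment(cl, model)
  expect_equal(dim(seg$probabilities), c(50L, 3L))
  expect_rows_sum_to_one(seg$probabilities)
  expect_true(all(seg$probabilities >= 0))
  expect_true(all(seg$labels >= 0L & seg$labels < 3L))

  # a point coincident with a center inherits that center's distribution
  ci <- seg$center_indices[3]
  center_probs <- toothseg:::row_softmax(seg$center_logits)[3, ]
  expect_equal(seg$probabilities[ci, ], center_probs, tolerance = 1e-6)

  # zeroed classifier weights give uniform probabilities everywhere
  m0 <- model
  m0$params$dec$W2[] <- 0
  m0$params$dec$b2[] <- 0
  seg0 <- segment(cl, m0)
  expect_equal(seg0$probabilities,
               matrix(1 / 3, 50, 3), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("permuting the input points permutes the per-point outputs", {
  cfg <- tiny_config()
  model <- init_model(cfg, seed = 4)
  pts <- random_cloud(60, seed = 13)
  cl <- labeled_cloud(pts)
  prep <- toothseg:::prepare_indices(pts, cfg)
  seg <- segment(cl, model, prep = prep)

  set.seed(99)
  perm <- sample.int(60)
  inv <- order(perm)
  pts_p <- pts[perm, ]
  # same center set, re-indexed through the permutation
  prep_p <- list(centers = inv[prep$centers],
                 neigh = matrix(inv[prep$neigh], nrow(prep$neigh)),
                 interp_idx = prep$interp_idx[perm, , drop = FALSE],
                 m = prep$m, u = prep$u)
  seg_p <- segment(labeled_cloud(pts_p), model, prep = prep_p)
  expect_equal(seg_p$probabilities, seg$probabilities[perm, ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(seg_p$labels, seg$labels[perm])
})

test_that("ablation variants all build and run forward passes on one input", {
  pts <- random_cloud(48, seed = 21)
  cl <- labeled_cloud(pts)
  variants <- list(
    full = tiny_config(),
    no_rel = tiny_config(use_rel_encoding = FALSE),
    no_pool = tiny_config(use_attention_pooling = FALSE),
    no_transformer = tiny_config(use_transformer = FALSE))
  expect_equal(variants$no_rel$encoding_layout, "abs_only")
  for (nm in names(variants)) {
    model <- init_model(variants[[nm]], seed = 7)
    seg <- segment(cl, model)
    expect_rows_sum_to_one(seg$probabilities)
  }
})

test_that("cross-entropy matches closed forms and hand evaluation", {
  # perfect one-hot predictions: loss 0 (up to the 1e-12 clamp)
  P <- diag(3)
  expect_equal(cross_entropy_loss(P, 0:2), 0, tolerance = 1e-9)
  # uniform over 33 classes: ln 33
  U <- matrix(1 / 33, 5, 33)
  expect_equal(cross_entropy_loss(U, rep(7L, 5)), log(33), tolerance = 1e-12)
  # hand-computed two-point case
  P2 <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(cross_entropy_loss(P2, c(0L, 1L)),
               -(log(0.9) + log(0.8)) / 2, tolerance = 1e-12)
  expect_error(cross_entropy_loss(P2, c(0L, 1L, 0L)), "size error")
})

test_that("scale_mode dmodel preserves the literal large-divisor reading", {
  X <- matrix(rnorm(20), 5, 4)
  heads <- lapply(1:2, function(h) {
    list(Wq = matrix(rnorm(8), 4, 2), Wk = matrix(rnorm(8), 4, 2),
         Wv = matrix(rnorm(8), 4, 2))
  })
  Z1 <- self_attention(X, heads, scale_mode = "sqrt_dhead")
  Z2 <- self_attention(X, heads, scale_mode = "dmodel")
  expect_false(isTRUE(all.equal(unclass(Z1), unclass(Z2))))
  # the d_model divisor flattens the attention towards uniform
  A2 <- attr(Z2, "attention")[[1]]
  expect_rows_sum_to_one(A2)
})
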