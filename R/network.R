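#' Initialize a segmentation model
#'
#' Creates the full weight set for the network: the shared point-wise MLP
#' (linear + batch-norm + ReLU per layer) that turns neighbourhood encodings
#' into local features, the projection and the 8 self-attention heads of the
#' global branch, the attention-pooling score vector, and the per-center
#' segmentation head. Linear weights use He initialisation; batch-norm starts
#' at identity (gamma 1, beta 0) with zeroed running means and unit running
#' variances.
#'
#' @param config a [model_config()].
#' @param seed RNG seed for the weight draw.
#' @return An object of class `toothseg_model`: list with `config`, `params`
#'   (named weight arrays) and `state` (batch-norm running statistics).
#' @export
init_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  he <- function(n_in, n_out) {
    matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
  }
  params <- list()
  state <- list()
  # local MLP
  widths <- c(encoding_width(config), config$mlp_hidden)
  params$mlp <- vector("list", length(config$mlp_hidden))
  state$mlp <- vector("list", length(config$mlp_hidden))
  for (l in seq_along(config$mlp_hidden)) {
    # no bias ahead of batch-norm: BN centers each channel, so a pre-BN
    # bias is exactly inert (beta provides the shift)
    params$mlp[[l]] <- list(W = he(widths[l], widths[l + 1]),
                            gamma = rep(1, widths[l + 1]),
                            beta = numeric(widths[l + 1]))
    state$mlp[[l]] <- list(run_mean = numeric(widths[l + 1]),
                           run_var = rep(1, widths[l + 1]))
  }
  # transformer branch
  if (config$use_transformer) {
    params$proj <- list(W = he(config$local_dim, config$d_model),
                        b = numeric(config$d_model))
    params$attn <- lapply(seq_len(config$attn_heads), function(h) {
      list(Wq = he(config$d_model, config$head_dim),
           Wk = he(config$d_model, config$head_dim),
           Wv = he(config$d_model, config$head_dim))
    })
  }
  # attention pooling score vector over the global tokens
  dg <- global_token_width(config)
  if (config$use_attention_pooling) {
    params$pool_w <- matrix(stats::rnorm(dg, sd = sqrt(1 / dg)), dg, 1L)
  }
  # segmentation head (plain linear + ReLU: per-cloud batch statistics would
  # cancel the broadcast global descriptors, so the head is norm-free)
  hw <- c(fusion_width(config), config$head_hidden)
  params$head <- vector("list", length(config$head_hidden))
  for (l in seq_along(config$head_hidden)) {
    params$head[[l]] <- list(W = he(hw[l], hw[l + 1]), b = numeric(hw[l + 1]))
  }
  # point-wise decoder classifier on [interpolated center features,
  # point position, offset to nearest center]
  din <- hw[length(hw)] + 6L
  params$dec <- list(W1 = he(din, config$dec_hidden),
                     b1 = numeric(config$dec_hidden),
                     W2 = he(config$dec_hidden, config$num_classes),
                     b2 = numeric(config$num_classes))
  structure(list(config = config, params = params, state = state),
            class = "toothseg_model")
}

#' @export
print.toothseg_model <- function(x, ...) {
  np <- sum(unlist(rapply(x$params, length, how = "list")))
  cat("toothseg_model:", format(np, big.mark = ","), "parameters\n")
  print(x$config)
  invisible(x)
}

# Full forward pass over one encoded cloud: neighbourhood encoding ->
# per-center feature field. `center_pts` are the m center coordinates,
# concatenated into the fusion vector as a raw positional skip. Returns the
# cache needed by backward_model() and, when training = TRUE, updated
# running statistics in `state`.
forward_model <- function(model, enc, center_pts, training = FALSE) {
  cfg <- model$config
  p <- model$params
  st <- model$state
  m <- enc$m
  k <- enc$k
  H <- enc$features
  if (ncol(H) != encoding_width(cfg)) {
    stop("config error: encoding width ", ncol(H), " does not match layout '",
         cfg$encoding_layout, "' (expected ", encoding_width(cfg), ")")
  }
  cache <- list(m = m, k = k, enc = enc)
  # local MLP: linear -> BN -> ReLU per layer
  cache$mlp <- vector("list", length(p$mlp))
  for (l in seq_along(p$mlp)) {
    lay <- p$mlp[[l]]
    Z <- H %*% lay$W
    bn <- bn_forward(Z, lay$gamma, lay$beta, st$mlp[[l]]$run_mean,
                     st$mlp[[l]]$run_var, training)
    Y <- relu_forward(bn$Y)
    cache$mlp[[l]] <- list(X = H, bn = bn$cache, Y = Y)
    if (training) st$mlp[[l]] <- list(run_mean = bn$run_mean, run_var = bn$run_var)
    H <- Y
  }
  mp <- maxpool_forward(H, m, k)
  L <- mp$L                                   # m x local_dim
  cache$maxpool <- mp$arg
  # global branch tokens
  if (cfg$use_transformer) {
    Xt <- linear_forward(L, p$proj$W, p$proj$b)
    scale <- attention_scale(cfg)
    heads <- vector("list", cfg$attn_heads)
    Zs <- vector("list", cfg$attn_heads)
    for (h in seq_len(cfg$attn_heads)) {
      ah <- attention_head_forward(Xt, p$attn[[h]]$Wq, p$attn[[h]]$Wk,
                                   p$attn[[h]]$Wv, scale)
      heads[[h]] <- ah$cache
      Zs[[h]] <- ah$Z
    }
    T_ <- do.call(cbind, Zs)                  # m x d_model
    cache$Xt <- Xt
    cache$heads <- heads
  } else {
    T_ <- L
  }
  cache$L <- L
  cache$T_ <- T_
  # global descriptors: attention pooling + soft pooling over centers
  if (cfg$use_attention_pooling) {
    ap <- attention_pool_forward(T_, p$pool_w)
    g_att <- ap$f
    cache$alpha <- ap$alpha
  } else {
    g_att <- colMeans(T_)
  }
  sp <- softpool_forward(T_)
  cache$soft_S <- sp$S
  cache$g_soft <- sp$g
  cache$g_att <- g_att
  F_global <- c(g_att, sp$g)
  Hf <- if (cfg$use_transformer) {
    cbind(L, T_, row_broadcast(F_global, m), center_pts)
  } else {
    cbind(L, row_broadcast(F_global, m), center_pts)
  }
  cache$Hf_in <- Hf
  # head: per-center linear + ReLU layers ending in the center feature field
  nh <- length(p$head)
  cache$head <- vector("list", nh)
  H2 <- Hf
  for (l in seq_len(nh)) {
    lay <- p$head[[l]]
    Y <- relu_forward(linear_forward(H2, lay$W, lay$b))
    cache$head[[l]] <- list(X = H2, Y = Y)
    H2 <- Y
  }
  list(center_feat = H2, cache = cache, state = st)
}

# Feature-propagation decoder: inverse-distance interpolation of the center
# feature field to every point, concatenated with the point's position and
# its offset to the nearest center, then a shared point-wise classifier.
decode_points <- function(model, center_feat, points, center_points,
                          interp_idx, interp_w) {
  Fp <- interpolate_logits(center_feat, interp_idx, interp_w)
  off <- points - center_points[interp_idx[, 1L], , drop = FALSE]
  X <- cbind(Fp, points, off)
  d <- model$params$dec
  H <- relu_forward(linear_forward(X, d$W1, d$b1))
  logits <- linear_forward(H, d$W2, d$b2)
  list(logits = logits,
       cache = list(X = X, H = H, interp_idx = interp_idx,
                    interp_w = interp_w, nf = ncol(center_feat),
                    m = nrow(center_feat)))
}

# backward through the decoder; returns decoder grads and the gradient
# w.r.t. the per-center feature field
decode_backward <- function(model, cache, dlogits) {
  d <- model$params$dec
  lb2 <- linear_backward(dlogits, cache$H, d$W2)
  dH <- relu_backward(lb2$dX, cache$H)
  lb1 <- linear_backward(dH, cache$X, d$W1)
  dFp <- lb1$dX[, seq_len(cache$nf), drop = FALSE]
  dC <- matrix(0, cache$m, cache$nf)
  for (j in seq_len(ncol(cache$interp_idx))) {
    rs <- rowsum(dFp * cache$interp_w[, j], group = cache$interp_idx[, j])
    rows <- as.integer(rownames(rs))
    dC[rows, ] <- dC[rows, ] + rs
  }
  list(grads = list(W1 = lb1$dW, b1 = lb1$db, W2 = lb2$dW, b2 = lb2$db),
       dcenter_feat = dC)
}

# ---- spec-surface operations --------------------------------------------

#' Extract per-center local features
#'
#' Applies the shared point-wise MLP to every neighbour encoding row and
#' max-pools channel-wise over each center's k neighbours, yielding one
#' local feature vector per center (width 128 under the default
#' configuration). Runs the model in evaluation mode (batch-norm running
#' statistics).
#'
#' @param encoding a `grouped_encoding` from [relative_encoding()].
#' @param model a [init_model()] model.
#' @return `m x local_dim` feature matrix.
#' @export
local_feature_extract <- function(encoding, model) {
  cfg <- model$config
  H <- encoding$features
  if (ncol(H) != encoding_width(cfg)) {
    stop("config error: encoding width ", ncol(H),
         " does not match the model's layout '", cfg$encoding_layout, "'")
  }
  st <- model$state
  for (l in seq_along(model$params$mlp)) {
    lay <- model$params$mlp[[l]]
    Z <- H %*% lay$W
    bn <- bn_forward(Z, lay$gamma, lay$beta, st$mlp[[l]]$run_mean,
                     st$mlp[[l]]$run_var, training = FALSE)
    H <- relu_forward(bn$Y)
  }
  maxpool_forward(H, encoding$m, encoding$k)$L
}

#' Multi-head self-attention over center tokens
#'
#' For each head h, projects the tokens to queries, keys and values
#' (`Q = X W_Q`, `K = X W_K`, `V = X W_V`), forms the row-stochastic
#' attention matrix `A = softmax(Q K' / s)` and mixes the values, `Z = A V`.
#' The per-head outputs are concatenated. The scaling `s` is
#' `sqrt(head_dim)` by default (`scale_mode = "sqrt_dhead"`) or the total
#' attention width (`"dmodel"`).
#'
#' @param X `m x d` token matrix.
#' @param heads list of head weights, each `list(Wq, Wk, Wv)` with `d` rows.
#' @param scale_mode see [model_config()].
#' @param head_dim per-head width (inferred from the weights by default).
#' @return `m x (heads * head_dim)` matrix; the per-head attention matrices
#'   are attached as attribute `"attention"`.
#' @export
self_attention <- function(X, heads, scale_mode = c("sqrt_dhead", "dmodel"),
                           head_dim = ncol(heads[[1]]$Wq)) {
  scale_mode <- match.arg(scale_mode)
  d_model <- length(heads) * head_dim
  scale <- if (scale_mode == "sqrt_dhead") sqrt(head_dim) else d_model
  outs <- lapply(heads, function(h) {
    attention_head_forward(X, h$Wq, h$Wk, h$Wv, scale)
  })
  Z <- do.call(cbind, lapply(outs, `[[`, "Z"))
  attr(Z, "attention") <- lapply(outs, function(o) o$cache$A)
  Z
}

#' Attention pooling of a feature set
#'
#' Learns (or is given) a scalar score per feature vector, softmax-normalizes
#' the scores into weights `alpha` that sum to one, and returns the weighted
#' sum of the features — a global descriptor that emphasises the most
#' informative centers.
#'
#' @param features `n x d` matrix, one feature vector per row.
#' @param w score weight vector of length `d` (or `d x 1` matrix).
#' @return list with `f_out` (length-d pooled vector) and `alpha` (the n
#'   softmax weights).
#' @export
attention_pool <- function(features, w) {
  features <- as.matrix(features)
  out <- attention_pool_forward(features, matrix(as.numeric(w), ncol = 1L))
  list(f_out = out$f, alpha = out$alpha)
}

#' Soft pooling of a feature set
#'
#' Channel-wise exponential-weighted aggregation (the SoftPool scheme): each
#' channel's output is the average of the activations weighted by the softmax
#' of the activations themselves, retaining global structure that a plain max
#' would discard.
#'
#' @param features `n x d` matrix.
#' @return length-d pooled vector.
#' @export
soft_pool <- function(features) {
  softpool_forward(as.matrix(features))$g
}

#' Concatenate local and global features
#'
#' Broadcasts the global descriptor to every center and concatenates it to the
#' per-center local block, in the fixed order (local, global).
#'
#' @param F_local `m x d_l` per-center local features.
#' @param F_global length-`d_g` global feature vector.
#' @return `m x (d_l + d_g)` fused feature matrix.
#' @export
fuse <- function(F_local, F_global) {
  F_local <- as.matrix(F_local)
  cbind(F_local, row_broadcast(as.numeric(F_global), nrow(F_local)))
}

#' Mean cross-entropy of per-point class probabilities
#'
#' The training objective: mean over points of the negative log predicted
#' probability at the true class, with the log clamped at 1e-12.
#'
#' @param probabilities `N x C` matrix of per-point class probabilities
#'   (rows sum to 1).
#' @param labels integer vector of true classes in `0..C-1`.
#' @return scalar loss.
#' @export
cross_entropy_loss <- function(probabilities, labels) {
  probabilities <- as.matrix(probabilities)
  if (nrow(probabilities) != length(labels)) {
    stop("size error: ", nrow(probabilities), " probability rows vs ",
         length(labels), " labels")
  }
  if (any(labels < 0L) || any(labels >= ncol(probabilities))) {
    stop("size error: labels outside [0, C)")
  }
  p <- probabilities[cbind(seq_along(labels), as.integer(labels) + 1L)]
  mean(-log(pmax(p, 1e-12)))
}

# ---- cloud preparation and segmentation ---------------------------------

# static per-cloud indices: FPS centers, k-NN neighbourhoods and the
# upsampling neighbours. All are invariant under the similarity transforms
# used for augmentation, so they are computed once per cloud.
prepare_indices <- function(points, config) {
  n <- nrow(points)
  m <- min(config$num_centers, n)
  if (m < config$num_centers) {
    warning("num_centers = ", config$num_centers, " clamped to N = ", n)
  }
  centers <- farthest_point_sampling(points, m)
  neigh <- knn_group(points, centers, min(config$k, n))
  u <- min(config$upsample_neighbors, m)
  interp <- nearest_centers(points, points[centers, , drop = FALSE], u)
  list(centers = centers, neigh = neigh, interp_idx = interp, m = m,
       u = u)
}

# u nearest centers for every point (indices into the center list)
nearest_centers <- function(points, center_points, u) {
  n <- nrow(points)
  m <- nrow(center_points)
  out <- matrix(0L, n, u)
  ct <- t(center_points)
  c2 <- colSums(ct^2)
  chunk <- max(1L, floor(4e6 / m))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    P <- points[s:e, , drop = FALSE]
    d2 <- outer(rowSums(P^2), c2, `+`) - 2 * P %*% ct
    for (j in seq_len(u)) {
      nj <- max.col(-d2, ties.method = "first")
      out[s:e, j] <- nj
      d2[cbind(seq_len(e - s + 1L), nj)] <- Inf
    }
  }
  out
}

# per-point interpolation weights from the current coordinates: inverse
# distance over the cached nearest centers, normalized per point
interp_weights <- function(points, center_points, interp_idx) {
  u <- ncol(interp_idx)
  w <- matrix(0, nrow(points), u)
  for (j in seq_len(u)) {
    d <- sqrt(rowSums((points - center_points[interp_idx[, j], , drop = FALSE])^2))
    w[, j] <- 1 / (d + 1e-8)
  }
  w / rowSums(w)
}

# logits at every point by inverse-distance interpolation of center logits
interpolate_logits <- function(center_logits, interp_idx, interp_w) {
  out <- matrix(0, nrow(interp_idx), ncol(center_logits))
  for (j in seq_len(ncol(interp_idx))) {
    out <- out + center_logits[interp_idx[, j], , drop = FALSE] * interp_w[, j]
  }
  out
}

#' Segment a point cloud
#'
#' Runs the full pipeline on a normalized cloud: farthest point sampling,
#' k-NN grouping, relative encoding, the network forward pass (evaluation
#' mode), and feature propagation back to the points — the per-center
#' feature field is interpolated to every point by inverse distance over its
#' nearest centers and a shared point-wise classifier (which also sees the
#' point's coordinates and its offset to the nearest center) produces the
#' class logits. Per-point probabilities are the softmax of those logits;
#' predicted labels are the row argmax with ties to the lowest class index.
#' A point coincident with a center receives exactly the distribution the
#' decoder assigns at that center (`center_logits`).
#'
#' @param cloud a [labeled_cloud()] in normalized coordinates
#'   (see [normalize_cloud()]).
#' @param model a `toothseg_model`.
#' @param prep optional precomputed index set from an earlier call (internal
#'   use; lets tests pin the center set).
#' @return An object of class `segmentation_output`: list with
#'   `probabilities` (`N x C`, rows sum to 1), `labels` (N integers in
#'   `0..C-1`), `center_indices` and `center_logits`.
#' @export
segment <- function(cloud, model, prep = NULL) {
  stopifnot(inherits(cloud, "labeled_cloud"), inherits(model, "toothseg_model"))
  pts <- cloud$points
  if (nrow(pts) < 1L) stop("size error: empty cloud")
  cfg <- model$config
  if (is.null(prep)) prep <- suppressWarnings(prepare_indices(pts, cfg))
  enc <- relative_encoding(pts, prep$centers, prep$neigh,
                           layout = cfg$encoding_layout)
  cpts <- pts[prep$centers, , drop = FALSE]
  fw <- forward_model(model, enc, cpts, training = FALSE)
  w <- interp_weights(pts, cpts, prep$interp_idx)
  dec <- decode_points(model, fw$center_feat, pts, cpts, prep$interp_idx, w)
  probs <- row_softmax(dec$logits)
  labels <- max.col(probs, ties.method = "first") - 1L
  # the decoder evaluated at the center positions themselves (offset zero,
  # interpolated feature = the center's own): what a coincident point gets
  self_idx <- matrix(rep(seq_len(prep$m), prep$u), prep$m)
  self_w <- matrix(c(rep(1, prep$m), rep(0, prep$m * (prep$u - 1L))), prep$m)
  center_logits <- decode_points(model, fw$center_feat, cpts, cpts,
                                 self_idx, self_w)$logits
  structure(list(probabilities = probs, labels = labels,
                 center_indices = prep$centers, center_logits = center_logits),
            class = "segmentation_output")
}

#' @export
print.segmentation_output <- function(x, ...) {
  cat("segmentation_output:", nrow(x$probabilities), "points,",
      ncol(x$probabilities), "classes;",
      length(unique(x$labels)), "distinct predicted labels\n")
  invisible(x)
}

# mean per-point cross-entropy and its gradient w.r.t. the decoder logits
softmax_ce_grad <- function(logits, labels) {
  P <- row_softmax(logits)
  n <- length(labels)
  li <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- mean(-log(pmax(P[li], 1e-12)))
  dL <- P
  dL[li] <- dL[li] - 1
  list(loss = loss, dlogits = dL / n)
}
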