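# Analytic backward pass through the network body, mirroring
# forward_model(). Takes the gradient of the loss w.r.t. the per-center
# feature field (from decode_backward()) and returns gradients with the
# same nested structure as model$params.

backward_model <- function(model, cache, d_center_feat, dec_grads = NULL) {
  cfg <- model$config
  p <- model$params
  m <- cache$m
  k <- cache$k
  g <- list()
  if (!is.null(dec_grads)) g$dec <- dec_grads

  # head layers (ReLU -> linear), from the feature field backwards
  nh <- length(p$head)
  g$head <- vector("list", nh)
  dH <- d_center_feat
  for (l in rev(seq_len(nh))) {
    lay <- p$head[[l]]
    ch <- cache$head[[l]]
    dH <- relu_backward(dH, ch$Y)
    lb <- linear_backward(dH, ch$X, lay$W)
    g$head[[l]] <- list(W = lb$dW, b = lb$db)
    dH <- lb$dX
  }

  # split fused input: (local | per-center tokens | broadcast global block)
  dl <- cfg$local_dim
  dL <- dH[, seq_len(dl), drop = FALSE]
  off <- dl
  dT_direct <- NULL
  if (cfg$use_transformer) {
    dT_direct <- dH[, off + seq_len(cfg$d_model), drop = FALSE]
    off <- off + cfg$d_model
  }
  # last 3 columns are the raw center coordinates (no parameters behind them)
  dGlob <- colSums(dH[, (off + 1L):(ncol(dH) - 3L), drop = FALSE])
  dg_width <- global_token_width(cfg)
  dg_att <- dGlob[seq_len(dg_width)]
  dg_soft <- dGlob[dg_width + seq_len(dg_width)]

  T_ <- cache$T_
  dT <- softpool_backward(dg_soft, T_, cache$soft_S, cache$g_soft)
  if (!is.null(dT_direct)) dT <- dT + dT_direct
  if (cfg$use_attention_pooling) {
    ab <- attention_pool_backward(dg_att, T_, p$pool_w, cache$alpha)
    dT <- dT + ab$dT
    g$pool_w <- ab$dw
  } else {
    dT <- dT + row_broadcast(dg_att / m, m)
  }

  if (cfg$use_transformer) {
    # split dT over heads, run attention backward, then the projection
    Xt <- cache$Xt
    dXt <- matrix(0, m, cfg$d_model)
    g$attn <- vector("list", cfg$attn_heads)
    for (h in seq_len(cfg$attn_heads)) {
      cols <- (h - 1L) * cfg$head_dim + seq_len(cfg$head_dim)
      hb <- attention_head_backward(dT[, cols, drop = FALSE], Xt,
                                    p$attn[[h]]$Wq, p$attn[[h]]$Wk,
                                    p$attn[[h]]$Wv, cache$heads[[h]])
      dXt <- dXt + hb$dX
      g$attn[[h]] <- list(Wq = hb$dWq, Wk = hb$dWk, Wv = hb$dWv)
    }
    lb <- linear_backward(dXt, cache$L, p$proj$W)
    g$proj <- list(W = lb$dW, b = lb$db)
    dL <- dL + lb$dX
  } else {
    dL <- dL + dT
  }

  # max pooling over neighbours, then the local MLP
  dHmlp <- maxpool_backward(dL, cache$maxpool, m, k, ncol(dL))
  g$mlp <- vector("list", length(p$mlp))
  for (l in rev(seq_along(p$mlp))) {
    lay <- p$mlp[[l]]
    ch <- cache$mlp[[l]]
    dHmlp <- relu_backward(dHmlp, ch$Y)
    bb <- bn_backward(dHmlp, ch$bn)
    g$mlp[[l]] <- list(W = crossprod(ch$X, bb$dX),
                       gamma = bb$dgamma, beta = bb$dbeta)
    dHmlp <- bb$dX %*% t(lay$W)
  }
  g[names(p)]   # same ordering as model$params so nested arithmetic pairs up
}

# ---- nested parameter-list arithmetic -----------------------------------

zeros_like <- function(x) {
  if (is.list(x)) lapply(x, zeros_like) else x * 0
}

params_add <- function(a, b) {
  if (is.list(a)) mapply(params_add, a, b, SIMPLIFY = FALSE) else a + b
}

params_scale <- function(a, s) {
  if (is.list(a)) lapply(a, params_scale, s = s) else a * s
}

# ---- Adam optimizer ------------------------------------------------------

adam_init <- function(params) {
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(upd, p, g, m, v, SIMPLIFY = FALSE)
      list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
           v = lapply(out, `[[`, "v"))
    } else {
      m <- beta1 * m + (1 - beta1) * g
      v <- beta2 * v + (1 - beta2) * g^2
      p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
      list(p = p, m = m, v = v)
    }
  }
  out <- upd(params, grads, opt$m, opt$v)
  list(params = out$p, opt = list(m = out$m, v = out$v, t = opt$t))
}
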