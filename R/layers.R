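# Forward/backward primitives for the network. Everything is plain matrix
# algebra; each *_forward returns its output plus the cache its *_backward
# needs. Shapes follow the (rows = tokens/points, cols = channels) convention.

# fast helpers: per-row and per-column broadcasting without aperm()
row_max <- function(S) {
  v <- S[, 1L]
  nc <- ncol(S)
  if (nc > 1L) for (j in 2:nc) v <- pmax.int(v, S[, j])
  v
}

col_add <- function(M, v) M + rep(v, each = nrow(M))

col_mul <- function(M, v) M * rep(v, each = nrow(M))

row_broadcast <- function(v, n) matrix(rep(v, each = n), n)

row_softmax <- function(S) {
  E <- exp(S - row_max(S))          # length-n vector recycles down columns
  E / rowSums(E)
}

linear_forward <- function(X, W, b) {
  col_add(X %*% W, b)
}

linear_backward <- function(dY, X, W) {
  list(dX = dY %*% t(W), dW = crossprod(X, dY), db = colSums(dY))
}

# Batch normalization over rows, per channel. training=TRUE uses batch
# statistics and returns updated running stats; evaluation uses the stored
# running statistics so single-cloud inference does not depend on batch
# composition.
bn_forward <- function(X, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xc <- col_add(X, -mu)
    v <- colMeans(xc^2)
    invstd <- 1 / sqrt(v + eps)
    xhat <- col_mul(xc, invstd)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v
  } else {
    invstd <- 1 / sqrt(run_var + eps)
    xhat <- col_mul(col_add(X, -run_mean), invstd)
  }
  Y <- col_add(col_mul(xhat, gamma), beta)
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dY, cache) {
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- col_mul(dY, cache$gamma)
  n <- nrow(dY)
  dX <- col_mul(
    col_add(dxhat - col_mul(xhat, colMeans(dxhat * xhat)), -colMeans(dxhat)),
    cache$invstd)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) pmax(X, 0)

relu_backward <- function(dY, Y) dY * (Y > 0)

# channel-wise max over each center's k neighbours; H is (m*k) x C with rows
# grouped by center (neighbour-major). Ties go to the first (lowest) neighbour.
maxpool_forward <- function(H, m, k) {
  C <- ncol(H)
  rows1 <- seq.int(1L, by = k, length.out = m)
  vals <- H[rows1, , drop = FALSE]
  arg <- matrix(1L, m, C)
  if (k > 1L) {
    for (j in 2:k) {
      Hj <- H[rows1 + (j - 1L), , drop = FALSE]
      upd <- Hj > vals
      vals[upd] <- Hj[upd]
      arg[upd] <- j
    }
  }
  list(L = vals, arg = arg)
}

maxpool_backward <- function(dL, arg, m, k, C) {
  dH <- matrix(0, m * k, C)
  rows <- rep.int((seq_len(m) - 1L) * k, C) + as.vector(arg)
  dH[cbind(rows, rep(seq_len(C), each = m))] <- as.vector(dL)
  dH
}

attention_scale <- function(config) {
  if (config$scale_mode == "sqrt_dhead") sqrt(config$head_dim) else config$d_model
}

# one attention head; X is m x d_model
attention_head_forward <- function(X, Wq, Wk, Wv, scale) {
  Q <- X %*% Wq
  K <- X %*% Wk
  V <- X %*% Wv
  A <- row_softmax(tcrossprod(Q, K) / scale)
  list(Z = A %*% V, cache = list(Q = Q, K = K, V = V, A = A, scale = scale))
}

attention_head_backward <- function(dZ, X, Wq, Wk, Wv, cache) {
  A <- cache$A
  dA <- tcrossprod(dZ, cache$V)
  dV <- crossprod(A, dZ)
  dS <- A * (dA - rowSums(A * dA))          # softmax backward, row-wise
  dU <- dS / cache$scale
  dQ <- dU %*% cache$K
  dK <- crossprod(dU, cache$Q)
  list(dX = dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv),
       dWq = crossprod(X, dQ), dWk = crossprod(X, dK), dWv = crossprod(X, dV))
}

# learned scalar-score softmax pooling over rows: alpha = softmax(T w),
# f_out = t(T) alpha
attention_pool_forward <- function(T_, w) {
  s <- as.vector(T_ %*% w)
  a <- exp(s - max(s))
  a <- a / sum(a)
  list(f = as.vector(crossprod(T_, a)), alpha = a)
}

attention_pool_backward <- function(df, T_, w, alpha) {
  dT <- alpha %*% t(df)                     # from f = sum_i alpha_i T_i
  dalpha <- as.vector(T_ %*% df)
  ds <- alpha * (dalpha - sum(alpha * dalpha))
  dT <- dT + ds %*% t(as.vector(w))
  list(dT = dT, dw = crossprod(T_, ds))
}

# SoftPool aggregation: each channel is averaged with weights softmax of the
# activations themselves (exponential weighting), guarded by max-subtraction.
softpool_forward <- function(T_) {
  mx <- vapply(seq_len(ncol(T_)), function(j) max(T_[, j]), numeric(1))
  E <- exp(col_add(T_, -mx))
  S <- col_mul(E, 1 / colSums(E))
  list(g = colSums(S * T_), S = S)
}

softpool_backward <- function(dg, T_, S, g) {
  # d g_c / d T_ic = S_ic (1 + T_ic - g_c)
  col_mul(S * (1 + col_add(T_, -g)), dg)
}
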