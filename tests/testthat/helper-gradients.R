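# Central-difference gradient checks of the analytic backward pass on a tiny
# model, covering one parameter in every block of the architecture.

grad_fixture <- function(cfg, data_seed = 2L, init_seed = 5L) {
  set.seed(data_seed)
  pts <- matrix(rnorm(60), 20, 3)
  lab <- sample(0:2, 20, TRUE)
  prep <- toothseg:::prepare_indices(pts, cfg)
  enc <- relative_encoding(pts, prep$centers, prep$neigh, cfg$encoding_layout)
  cpts <- pts[prep$centers, , drop = FALSE]
  w <- toothseg:::interp_weights(pts, cpts, prep$interp_idx)
  model <- init_model(cfg, seed = init_seed)
  loss_of <- function(m) {
    fw <- toothseg:::forward_model(m, enc, cpts, training = TRUE)
    dec <- toothseg:::decode_points(m, fw$center_feat, pts, cpts,
                                    prep$interp_idx, w)
    toothseg:::softmax_ce_grad(dec$logits, lab)$loss
  }
  fw <- toothseg:::forward_model(model, enc, cpts, training = TRUE)
  dec <- toothseg:::decode_points(model, fw$center_feat, pts, cpts,
                                  prep$interp_idx, w)
  lg <- toothseg:::softmax_ce_grad(dec$logits, lab)
  db <- toothseg:::decode_backward(model, dec$cache, lg$dlogits)
  grads <- toothseg:::backward_model(model, fw$cache, db$dcenter_feat,
                                     dec_grads = db$grads)
  list(model = model, grads = grads, loss_of = loss_of)
}

# relative error of central difference vs analytic for one parameter entry;
# the 1e-6 floor keeps exactly-zero gradients from amplifying roundoff noise
check_param <- function(fx, get, set, idx, eps = 1e-6) {
  v <- get(fx$model$params)
  m_plus <- fx$model; m_minus <- fx$model
  vp <- v; vp[idx] <- vp[idx] + eps
  vm <- v; vm[idx] <- vm[idx] - eps
  m_plus$params <- set(m_plus$params, vp)
  m_minus$params <- set(m_minus$params, vm)
  num <- (fx$loss_of(m_plus) - fx$loss_of(m_minus)) / (2 * eps)
  ana <- get(fx$grads)[idx]
  abs(num - ana) / max(abs(num), abs(ana), 1e-6)
}

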