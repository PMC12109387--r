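#' Randomly augment a normalized cloud
#'
#' Applies, in order: a rotation drawn uniformly from `rotation_range`
#' (degrees, about the vertical z axis unless `full_3d` is set), an isotropic
#' scale from `scale_range`, and a per-axis translation from
#' `translation_range` (normalized coordinate units). Labels, normals and
#' point count are untouched. The draw is reproducible for a fixed `seed`;
#' with `seed = NULL` the current RNG stream is used (as the training loop
#' does).
#'
#' @param cloud a [labeled_cloud()] in normalized coordinates.
#' @param rotation_range,scale_range,translation_range see [train_config()].
#' @param full_3d rotate about a uniformly random axis instead of z.
#' @param seed integer seed or `NULL`.
#' @return The augmented [labeled_cloud()].
#' @export
augment_cloud <- function(cloud, rotation_range = c(-30, 30),
                          scale_range = c(0.9, 1.1),
                          translation_range = c(-0.05, 0.05),
                          full_3d = FALSE, seed = NULL) {
  stopifnot(inherits(cloud, "labeled_cloud"))
  if (!is.null(seed)) {
    old <- local_seed(seed)
    on.exit(restore_seed(old), add = TRUE)
  }
  theta <- stats::runif(1, rotation_range[1], rotation_range[2]) * pi / 180
  s <- stats::runif(1, scale_range[1], scale_range[2])
  tr <- stats::runif(3, translation_range[1], translation_range[2])
  R <- if (full_3d) {
    ax <- stats::rnorm(3)
    ax <- ax / sqrt(sum(ax^2))
    rotation_about_axis(ax, theta)
  } else {
    rotation_about_axis(c(0, 0, 1), theta)
  }
  out <- cloud
  out$points <- sweep(cloud$points %*% t(R) * s, 2, tr, `+`)
  if (!is.null(cloud$normals)) out$normals <- cloud$normals %*% t(R)
  out
}

rotation_about_axis <- function(axis, theta) {
  c_ <- cos(theta); s_ <- sin(theta); C <- 1 - c_
  x <- axis[1]; y <- axis[2]; z <- axis[3]
  matrix(c(x * x * C + c_, x * y * C - z * s_, x * z * C + y * s_,
           y * x * C + z * s_, y * y * C + c_, y * z * C - x * s_,
           z * x * C - y * s_, z * y * C + x * s_, z * z * C + c_),
         3, 3, byrow = TRUE)
}

#' Train a segmentation model
#'
#' Minimizes the mean per-point cross-entropy with Adam. Each epoch shuffles
#' the training clouds, augments each cloud (rotation/scale/translation),
#' rebuilds its neighbourhood encoding and takes one optimizer step per batch
#' of `batch_size` clouds (gradients averaged over the batch). After every
#' epoch the validation clouds are segmented and the mean IoU recorded;
#' training stops at `max_epochs` or when validation mIoU has not improved
#' for `patience` epochs, and the best-validation weights are restored.
#'
#' Farthest-point centers, neighbourhoods and upsampling neighbours are
#' computed once per cloud: the augmentations are similarity transforms, so
#' nearest-neighbour structure is preserved exactly and only the coordinate
#' encodings need recomputing each epoch.
#'
#' @param train_clouds,val_clouds lists of labelled, normalized clouds.
#' @param config a [model_config()].
#' @param tconfig a [train_config()].
#' @param model optional starting model (defaults to a fresh
#'   [init_model()] seeded from `tconfig$seed`).
#' @return An object of class `toothseg_fit`: list with `model` (best
#'   weights), `history` (data.frame: epoch, train_loss, val_loss, val_miou),
#'   `best_epoch`, `config`, `tconfig`.
#' @export
train_model <- function(train_clouds, val_clouds, config = small_model_config(),
                        tconfig = train_config(), model = NULL) {
  if (!length(train_clouds)) stop("size error: empty training set")
  stopifnot(inherits(config, "model_config"), inherits(tconfig, "train_config"))
  old <- local_seed(tconfig$seed)
  on.exit(restore_seed(old), add = TRUE)
  if (is.null(model)) model <- init_model(config, seed = tconfig$seed)
  opt <- adam_init(model$params)

  prep_tr <- lapply(train_clouds, function(cl) {
    suppressWarnings(prepare_indices(cl$points, config))
  })
  prep_va <- lapply(val_clouds, function(cl) {
    suppressWarnings(prepare_indices(cl$points, config))
  })

  nt <- length(train_clouds)
  best <- list(miou = -Inf, params = model$params, state = model$state,
               epoch = 0L)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric(), val_miou = numeric())
  wait <- 0L

  lr <- tconfig$learning_rate
  for (epoch in seq_len(tconfig$max_epochs)) {
    ord <- sample.int(nt)
    ep_loss <- 0
    batches <- split(ord, ceiling(seq_along(ord) / tconfig$batch_size))
    for (batch in batches) {
      gsum <- NULL
      for (ci in batch) {
        cl <- train_clouds[[ci]]
        if (tconfig$augment) {
          cl <- augment_cloud(cl, tconfig$rotation_range, tconfig$scale_range,
                              tconfig$translation_range,
                              full_3d = tconfig$full_3d_rotation)
        }
        pr <- prep_tr[[ci]]
        enc <- relative_encoding(cl$points, pr$centers, pr$neigh,
                                 layout = config$encoding_layout)
        cpts <- cl$points[pr$centers, , drop = FALSE]
        fw <- forward_model(model, enc, cpts, training = TRUE)
        model$state <- fw$state
        n_cl <- nrow(cl$points)
        sub <- if (is.finite(tconfig$loss_points) &&
                   tconfig$loss_points < n_cl) {
          sample.int(n_cl, tconfig$loss_points)
        } else seq_len(n_cl)
        pts_s <- cl$points[sub, , drop = FALSE]
        idx_s <- pr$interp_idx[sub, , drop = FALSE]
        w <- interp_weights(pts_s, cpts, idx_s)
        dec <- decode_points(model, fw$center_feat, pts_s, cpts, idx_s, w)
        lg <- softmax_ce_grad(dec$logits, cl$labels[sub])
        if (!is.finite(lg$loss)) {
          stop("NaN/Inf loss at epoch ", epoch, ", cloud ", ci,
               "; lower the learning rate or check the inputs")
        }
        ep_loss <- ep_loss + lg$loss
        db <- decode_backward(model, dec$cache, lg$dlogits)
        gcl <- backward_model(model, fw$cache, db$dcenter_feat,
                              dec_grads = db$grads)
        gsum <- if (is.null(gsum)) gcl else params_add(gsum, gcl)
      }
      gavg <- params_scale(gsum, 1 / length(batch))
      st <- adam_step(model$params, gavg, opt, lr)
      model$params <- st$params
      opt <- st$opt
    }
    ep_loss <- ep_loss / nt
    lr <- lr * (tconfig$lr_decay %||% 1)

    val <- evaluate_model(model, val_clouds, prep_va,
                          eval_points = tconfig$eval_points %||% Inf)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = ep_loss,
      val_loss = val$loss, val_miou = val$miou))
    if (tconfig$verbose) {
      message(sprintf("epoch %3d  train_loss %.4f  val_loss %.4f  val_mIoU %.4f",
                      epoch, ep_loss, val$loss, val$miou))
    }
    if (is.finite(val$miou) && val$miou > best$miou + 1e-12) {
      best <- list(miou = val$miou, params = model$params,
                   state = model$state, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tconfig$patience) break
    }
  }

  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 config = config, tconfig = tconfig),
            class = "toothseg_fit")
}

# mean per-point loss and mIoU of a model over clouds (evaluation mode);
# eval_points, if finite, subsamples each cloud's points deterministically
# for a cheap early-stopping monitor
evaluate_model <- function(model, clouds, preps = NULL, eval_points = Inf) {
  if (!length(clouds)) return(list(loss = NA_real_, miou = NA_real_))
  cfg <- model$config
  cm <- matrix(0L, cfg$num_classes, cfg$num_classes)
  loss <- 0
  for (i in seq_along(clouds)) {
    cl <- clouds[[i]]
    pr <- if (is.null(preps)) {
      suppressWarnings(prepare_indices(cl$points, cfg))
    } else preps[[i]]
    enc <- relative_encoding(cl$points, pr$centers, pr$neigh,
                             layout = cfg$encoding_layout)
    cpts <- cl$points[pr$centers, , drop = FALSE]
    fw <- forward_model(model, enc, cpts, training = FALSE)
    n_cl <- nrow(cl$points)
    sub <- if (is.finite(eval_points) && eval_points < n_cl) {
      seq.int(1L, n_cl, length.out = eval_points)   # deterministic stride
    } else seq_len(n_cl)
    pts_s <- cl$points[sub, , drop = FALSE]
    idx_s <- pr$interp_idx[sub, , drop = FALSE]
    w <- interp_weights(pts_s, cpts, idx_s)
    dec <- decode_points(model, fw$center_feat, pts_s, cpts, idx_s, w)
    P <- row_softmax(dec$logits)
    loss <- loss + cross_entropy_loss(P, cl$labels[sub])
    pred <- max.col(P, ties.method = "first") - 1L
    cm <- cm + confusion_matrix(pred, cl$labels[sub], cfg$num_classes)
  }
  rep_ <- compute_metrics(cm)
  list(loss = loss / length(clouds), miou = rep_$overall$mIoU, confusion = cm)
}

#' @export
print.toothseg_fit <- function(x, ...) {
  n <- nrow(x$history)
  cat("toothseg_fit:", n, paste0("epochs (best epoch ", x$best_epoch, ")\n"))
  if (n) {
    last <- x$history[n, ]
    cat(sprintf("  final: train_loss %.4f  val_loss %.4f  val_mIoU %.4f\n",
                last$train_loss, last$val_loss, last$val_miou))
    cat(sprintf("  best val mIoU: %.4f\n", max(x$history$val_miou)))
  }
  invisible(x)
}

#' Split a dataset into train/validation/test parts
#'
#' Seeded shuffle followed by a 70/15/15 split (by default), the convention
#' used throughout for the synthetic experiments.
#'
#' @param n number of clouds.
#' @param fractions length-3 nonneg vector summing to 1.
#' @param seed shuffle seed.
#' @return list of integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, n >= 1L)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  ord <- sample.int(n)
  n_tr <- round(fractions[1] * n)
  n_va <- round(fractions[2] * n)
  list(train = ord[seq_len(n_tr)],
       val = ord[n_tr + seq_len(min(n_va, n - n_tr))],
       test = if (n_tr + n_va < n) ord[(n_tr + n_va + 1L):n] else integer())
}
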