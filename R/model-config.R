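#' Model configuration
#'
#' Collects every architecture hyperparameter. Defaults reproduce the
#' reference configuration: 2048 farthest-point centers with 64-point
#' neighbourhoods, a point-wise MLP of widths 32-64-128 giving 128-dimensional
#' local features, and an 8-head self-attention branch with 32 dimensions per
#' head (total width 256).
#'
#' @param num_centers number of FPS centers per cloud.
#' @param k neighbourhood size.
#' @param mlp_hidden widths of the shared point-wise MLP; the last entry is
#'   the local feature width.
#' @param attn_heads number of self-attention heads.
#' @param head_dim feature dimension per head; `attn_heads * head_dim` is the
#'   attention width (256 by default).
#' @param head_hidden hidden widths of the per-center segmentation head.
#' @param dec_hidden hidden width of the shared point-wise decoder classifier
#'   that maps interpolated center features (plus the point's coordinates and
#'   its offset to the nearest center) to class logits.
#' @param num_classes number of output classes (33: gingiva + 32 FDI teeth).
#' @param upsample_neighbors how many nearest centers interpolate each point's
#'   logits when predictions are propagated from centers back to the cloud.
#' @param encoding_layout neighbourhood feature layout, see
#'   [relative_encoding()].
#' @param scale_mode attention-score scaling: `"sqrt_dhead"` divides scores by
#'   `sqrt(head_dim)` (the Transformer convention, default); `"dmodel"`
#'   divides by the full attention width.
#' @param use_rel_encoding ablation flag; `FALSE` switches the encoding layout
#'   to `"abs_only"` (absolute coordinates only).
#' @param use_attention_pooling ablation flag; `FALSE` replaces the learned
#'   attention pooling by an unweighted mean.
#' @param use_transformer ablation flag; `FALSE` removes the self-attention
#'   branch (global pooling then aggregates the local features instead).
#' @return An object of class `model_config` (a validated list).
#' @export
model_config <- function(num_centers = 2048L, k = 64L,
                         mlp_hidden = c(32L, 64L, 128L),
                         attn_heads = 8L, head_dim = 32L,
                         head_hidden = c(256L, 128L),
                         dec_hidden = 64L,
                         num_classes = 33L,
                         upsample_neighbors = 3L,
                         encoding_layout = c("rel_dist_abs", "rel_dist", "abs_only"),
                         scale_mode = c("sqrt_dhead", "dmodel"),
                         use_rel_encoding = TRUE,
                         use_attention_pooling = TRUE,
                         use_transformer = TRUE) {
  encoding_layout <- match.arg(encoding_layout)
  scale_mode <- match.arg(scale_mode)
  if (!use_rel_encoding) encoding_layout <- "abs_only"
  cfg <- list(
    num_centers = as.integer(num_centers), k = as.integer(k),
    mlp_hidden = as.integer(mlp_hidden),
    local_dim = as.integer(mlp_hidden[length(mlp_hidden)]),
    attn_heads = as.integer(attn_heads), head_dim = as.integer(head_dim),
    d_model = as.integer(attn_heads * head_dim),
    head_hidden = as.integer(head_hidden),
    dec_hidden = as.integer(dec_hidden),
    num_classes = as.integer(num_classes),
    upsample_neighbors = as.integer(upsample_neighbors),
    encoding_layout = encoding_layout, scale_mode = scale_mode,
    use_rel_encoding = isTRUE(use_rel_encoding),
    use_attention_pooling = isTRUE(use_attention_pooling),
    use_transformer = isTRUE(use_transformer)
  )
  stopifnot(cfg$num_centers >= 1L, cfg$k >= 1L, length(cfg$mlp_hidden) >= 1L,
            cfg$attn_heads >= 1L, cfg$head_dim >= 1L, cfg$num_classes >= 2L,
            cfg$upsample_neighbors >= 1L)
  structure(cfg, class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat("model_config:\n")
  cat("  centers:", x$num_centers, " k:", x$k,
      " encoding:", x$encoding_layout, "(F =", encoding_width(x), ")\n")
  cat("  local MLP:", paste(x$mlp_hidden, collapse = "-"),
      " attention:", x$attn_heads, "x", x$head_dim, "=", x$d_model, "\n")
  cat("  head:", paste(x$head_hidden, collapse = "-"), "->", x$num_classes,
      "classes; upsample over", x$upsample_neighbors, "centers\n")
  flags <- c(rel_encoding = x$use_rel_encoding,
             attention_pooling = x$use_attention_pooling,
             transformer = x$use_transformer)
  cat("  flags:", paste(names(flags), flags, sep = "=", collapse = " "), "\n")
  invisible(x)
}

encoding_width <- function(config) {
  switch(config$encoding_layout, rel_dist_abs = 7L, rel_dist = 4L, abs_only = 3L)
}

# width of the tokens fed to the global pooling branch
global_token_width <- function(config) {
  if (config$use_transformer) config$d_model else config$local_dim
}

# fused per-center feature width: local block, per-center attention tokens
# (when the transformer branch is on), the two pooled global descriptors,
# and the center's own coordinates (PointNet-style skip of the raw position)
fusion_width <- function(config) {
  config$local_dim +
    (if (config$use_transformer) config$d_model else 0L) +
    2L * global_token_width(config) + 3L
}

#' A reduced configuration for desk-scale experiments
#'
#' Halves every width of the default architecture and shrinks the sampling
#' budget (256 centers, 16 neighbours), which keeps single-CPU training of a
#' few hundred synthetic arches in the minutes range while preserving every
#' structural element of the full model.
#'
#' @param ... overrides passed on to [model_config()].
#' @return A `model_config`.
#' @export
small_model_config <- function(...) {
  args <- list(...)
  defaults <- list(num_centers = 256L, k = 16L, mlp_hidden = c(16L, 32L, 64L),
                   attn_heads = 8L, head_dim = 16L, head_hidden = c(128L, 64L),
                   dec_hidden = 32L)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size clouds per optimizer step (default 16).
#' @param max_epochs maximum training epochs (default 200).
#' @param patience early-stopping patience in epochs without validation mIoU
#'   improvement (default 20); the best-validation weights are restored.
#' @param rotation_range augmentation rotation range in degrees about the
#'   z axis (default [-30, 30]).
#' @param scale_range isotropic scale factor range (default [0.9, 1.1]).
#' @param translation_range per-axis translation range in normalized
#'   coordinates (default [-0.05, 0.05]).
#' @param augment whether to augment training clouds.
#' @param full_3d_rotation rotate about a random axis instead of z only.
#' @param seed RNG seed controlling shuffling, augmentation and weight
#'   initialisation; a fixed seed makes the whole run reproducible.
#' @param loss_points if finite, the per-step training loss is computed on a
#'   random subset of this many points per cloud (an unbiased stochastic
#'   estimator of the full per-point mean that cuts decoder cost); validation
#'   always uses every point.
#' @param lr_decay multiplicative learning-rate decay applied after each
#'   epoch (1 = constant rate, the default).
#' @param eval_points if finite, the per-epoch validation metrics are
#'   computed on this many sampled points per cloud (cheap early-stopping
#'   monitor); final reported metrics should always use every point.
#' @param verbose print one line per epoch.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16L,
                         max_epochs = 200L, patience = 20L,
                         rotation_range = c(-30, 30),
                         scale_range = c(0.9, 1.1),
                         translation_range = c(-0.05, 0.05),
                         augment = TRUE, full_3d_rotation = FALSE,
                         seed = 1L, loss_points = Inf, lr_decay = 1,
                         eval_points = Inf, verbose = FALSE) {
  stopifnot(patience >= 1L, batch_size >= 1L, max_epochs >= 1L,
            learning_rate >= 0,
            rotation_range[1] <= 0 && rotation_range[2] >= 0,
            scale_range[1] <= 1 && scale_range[2] >= 1,
            translation_range[1] <= 0 && translation_range[2] >= 0)
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    rotation_range = rotation_range, scale_range = scale_range,
    translation_range = translation_range,
    augment = isTRUE(augment), full_3d_rotation = isTRUE(full_3d_rotation),
    seed = as.integer(seed), loss_points = loss_points,
    lr_decay = lr_decay, eval_points = eval_points,
    verbose = isTRUE(verbose)
  ), class = "train_config")
}
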