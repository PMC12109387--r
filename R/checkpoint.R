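#' Save and load model checkpoints
#'
#' A checkpoint is a single `.rds` file holding the model configuration
#' (also mirrored as a JSON string for inspection outside R), the named
#' weight arrays, the batch-norm running statistics, and — when saving a fit —
#' the training history. [load_checkpoint()] restores a `toothseg_model`
#' (or a full `toothseg_fit`).
#'
#' @param x a `toothseg_model` or `toothseg_fit`.
#' @param path output file path (`.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(x, path) {
  if (inherits(x, "toothseg_fit")) {
    model <- x$model
    extra <- list(history = x$history, best_epoch = x$best_epoch,
                  tconfig = x$tconfig)
  } else if (inherits(x, "toothseg_model")) {
    model <- x
    extra <- list()
  } else {
    stop("expected a toothseg_model or toothseg_fit")
  }
  obj <- c(list(
    config = model$config,
    config_json = jsonlite::toJSON(unclass(model$config), auto_unbox = TRUE),
    params = model$params,
    state = model$state), extra)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  model <- structure(list(config = obj$config, params = obj$params,
                          state = obj$state), class = "toothseg_model")
  if (!is.null(obj$history)) {
    structure(list(model = model, history = obj$history,
                   best_epoch = obj$best_epoch, config = obj$config,
                   tconfig = obj$tconfig), class = "toothseg_fit")
  } else {
    model
  }
}
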