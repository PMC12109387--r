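make_norm_cloud <- function(seed, n = 256L) {
  sp <- arch_spec(scenario = "normal",
                  jaw = if (seed %% 2 == 0) "upper" else "lower",
                  points_per_cloud = n, seed = seed)
  normalize_cloud(generate_arch(sp))$cloud
}

test_that("augmentation collapses to the identity at degenerate ranges", {
  cl <- make_norm_cloud(1)
  out <- augment_cloud(cl, rotation_range = c(0, 0), scale_range = c(1, 1),
                       translation_range = c(0, 0), seed = 3)
  expect_equal(out$points, cl$points, tolerance = 1e-12)
  expect_identical(out$labels, cl$labels)
})

test_that("rotation preserves pairwise distances and scaling multiplies them", {
  cl <- make_norm_cloud(2, n = 128L)
  d0 <- stats::dist(cl$points)
  rot <- augment_cloud(cl, rotation_range = c(-30, 30), scale_range = c(1, 1),
                       translation_range = c(0, 0), seed = 11)
  expect_lt(max(abs(stats::dist(rot$points) - d0)), 1e-6)

  set.seed(21)
  s_seed <- 21
  scl <- augment_cloud(cl, rotation_range = c(0, 0),
                       scale_range = c(0.9, 1.1),
                       translation_range = c(0, 0), seed = s_seed)
  # recover the drawn factor and compare all pairwise distances
  s <- stats::dist(scl$points)[1] / d0[1]
  expect_gte(s, 0.9); expect_lte(s, 1.1)
  expect_lt(max(abs(stats::dist(scl$points) - s * d0)), 1e-6)

  # labels and point count are never altered
  expect_identical(scl$labels, cl$labels)
  expect_equal(nrow(scl$points), nrow(cl$points))
  # determinism per seed
  again <- augment_cloud(cl, rotation_range = c(0, 0),
                         scale_range = c(0.9, 1.1),
                         translation_range = c(0, 0), seed = s_seed)
  expect_identical(scl$points, again$points)
})

test_that("zero learning rate leaves the weights unchanged", {
  clouds <- lapply(1:3, make_norm_cloud)
  cfg <- tiny_config(num_classes = 33L)
  tc <- train_config(learning_rate = 0, batch_size = 2L, max_epochs = 1L,
                     patience = 5L, augment = FALSE, seed = 4)
  model0 <- init_model(cfg, seed = 4)
  fit <- train_model(clouds, clouds[1], cfg, tc, model = model0)
  expect_equal(fit$model$params, model0$params, tolerance = 1e-12)
})

test_that("a constant validation metric stops after patience epochs", {
  clouds <- lapply(1:3, make_norm_cloud)
  cfg <- tiny_config(num_classes = 33L)
  # lr 0 freezes the model so val mIoU is constant; patience 1 stops at epoch 2
  tc <- train_config(learning_rate = 0, batch_size = 3L, max_epochs = 50L,
                     patience = 1L, augment = FALSE, seed = 5)
  fit <- train_model(clouds, clouds[1], cfg, tc)
  expect_equal(nrow(fit$history), 2L)
})

test_that("training loss decreases monotonically when overfitting one batch", {
  cl <- make_norm_cloud(3, n = 256L)
  cfg <- tiny_config(num_classes = 33L)
  tc <- train_config(learning_rate = 3e-3, batch_size = 1L, max_epochs = 10L,
                     patience = 20L, augment = FALSE, seed = 6)
  fit <- train_model(list(cl), list(cl), cfg, tc)
  expect_equal(nrow(fit$history), 10L)
  expect_true(all(diff(fit$history$train_loss) < 0))
})

test_that("identical seeds reproduce the training history exactly", {
  clouds <- lapply(1:6, make_norm_cloud)
  cfg <- tiny_config(num_classes = 33L)
  tc <- train_config(learning_rate = 1e-3, batch_size = 2L, max_epochs = 3L,
                     patience = 10L, seed = 7)
  f1 <- train_model(clouds[1:4], clouds[5:6], cfg, tc)
  f2 <- train_model(clouds[1:4], clouds[5:6], cfg, tc)
  expect_equal(f1$history, f2$history, tolerance = 1e-6)
  expect_equal(f1$model$params, f2$model$params, tolerance = 1e-10)
})

test_that("an empty training set is a size error", {
  expect_error(train_model(list(), list(), tiny_config(), train_config()),
               "size error")
})

test_that("checkpoints round-trip models and fits", {
  cl <- make_norm_cloud(9)
  cfg <- tiny_config(num_classes = 33L)
  tc <- train_config(learning_rate = 1e-3, batch_size = 1L, max_epochs = 2L,
                     patience = 5L, seed = 9)
  fit <- train_model(list(cl), list(cl), cfg, tc)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(fit, f)
  back <- load_checkpoint(f)
  expect_s3_class(back, "toothseg_fit")
  expect_equal(back$model$params, fit$model$params)
  expect_equal(back$history, fit$history)
  # prediction parity between the original and restored models
  seg1 <- segment(cl, fit$model)
  seg2 <- segment(cl, back$model)
  expect_identical(seg1$labels, seg2$labels)
})

test_that("a two-class plane-vs-sphere toy is learned to near-perfect IoU", {
  # 50 clouds of 1024 points: a flat patch (class 0) and a sphere above it
  # (class 1); the small model should separate them almost immediately
  make_toy <- function(seed) {
    set.seed(seed)
    n <- 512L
    plane <- cbind(runif(n, -1, 1), runif(n, -1, 1), rnorm(n, 0, 0.01))
    u <- matrix(rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    sphere <- sweep(u * 0.35, 2, c(0, 0, 0.6), `+`) +
      matrix(rnorm(3 * n, 0, 0.01), n, 3)
    cl <- labeled_cloud(rbind(plane, sphere),
                        labels = rep(c(0L, 1L), each = n), n_classes = 2L)
    normalize_cloud(cl)$cloud
  }
  clouds <- lapply(1:50, function(i) make_toy(1000 + i))
  sp <- split_dataset(50, seed = 3)
  cfg <- small_model_config(num_centers = 64L, k = 8L, num_classes = 2L)
  tc <- train_config(learning_rate = 3e-3, batch_size = 1L, max_epochs = 6L,
                     patience = 6L, augment = FALSE, seed = 3)
  fit <- train_model(clouds[sp$train], clouds[sp$val], cfg, tc)
  expect_gte(max(fit$history$val_miou), 0.95)
})

test_that("dataset splitting is a seeded 70/15/15 partition", {
  sp <- split_dataset(100, seed = 3)
  expect_equal(length(sp$train), 70L)
  expect_equal(length(sp$val), 15L)
  expect_equal(length(sp$test), 15L)
  expect_setequal(c(sp$train, sp$val, sp$test), 1:100)
  expect_identical(split_dataset(100, seed = 3), sp)
})
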