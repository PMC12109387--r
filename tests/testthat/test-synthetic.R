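test_that("generated arches are valid labelled clouds and reproducible", {
  sp <- arch_spec(scenario = "normal", jaw = "upper", points_per_cloud = 2000,
                  seed = 42)
  cl <- generate_arch(sp)
  expect_s3_class(cl, "labeled_cloud")
  expect_equal(nrow(cl$points), 2000L)
  expect_true(all(cl$labels >= 0L & cl$labels < 33L))
  # an upper arch holds quadrant 1-2 classes (1..16) plus gingiva
  expect_true(all(cl$labels %in% c(0L, 1:16)))
  expect_true(0L %in% cl$labels)
  # normalizes into the unit cube
  expect_true(all(abs(normalize_cloud(cl)$cloud$points) <= 1 + 1e-12))
  # determinism
  cl2 <- generate_arch(sp)
  expect_identical(cl$points, cl2$points)
  expect_identical(cl$labels, cl2$labels)
})

test_that("noise-free tooth points satisfy their superquadric surface equation", {
  for (jaw in c("upper", "lower")) {
    sp <- arch_spec(scenario = "normal", jaw = jaw, points_per_cloud = 3000,
                    noise_sd = 0, seed = 17)
    cl <- generate_arch(sp)
    meta <- attr(cl, "arch_meta")
    for (th in meta$teeth[c(1, 8, 16)]) {
      idx <- which(cl$labels == th$class)
      expect_gt(length(idx), 10)
      # world = local %*% t(Rz(angle)) => local = world %*% Rz(angle);
      # the jaw mirror flips z of points and centers alike and the
      # superquadric is symmetric in |z|, so no unflip is needed
      loc <- sweep(cl$points[idx, , drop = FALSE], 2, th$center) %*%
        toothseg:::rot_z(th$angle)
      f <- toothseg:::superquadric_value(loc, th$axes, th$p)
      expect_lt(max(abs(f - 1)), 1e-6)
    }
  }
})

test_that("gingiva points never lie inside a tooth beyond noise tolerance", {
  sp <- arch_spec(scenario = "crowded", jaw = "lower", points_per_cloud = 4000,
                  noise_sd = 0.1, seed = 23)
  cl <- generate_arch(sp)
  meta <- attr(cl, "arch_meta")
  gum <- cl$points[cl$labels == 0L, , drop = FALSE]
  for (th in meta$teeth) {
    loc <- sweep(gum, 2, th$center) %*% toothseg:::rot_z(th$angle)
    f <- toothseg:::superquadric_value(loc, th$axes, th$p)
    # a point at surface value f < 1 sits inside; allow 3 * noise_sd of slack
    # converted through the smallest half-axis
    depth <- (1 - f) * min(th$axes)
    expect_lt(max(depth), 3 * sp$noise_sd + 1e-9)
  }
})

test_that("a missing-tooth arch with full quadrants keeps 31 tooth classes", {
  sp <- arch_spec(scenario = "missing", jaw = "both", teeth_per_quadrant = 8L,
                  points_per_cloud = 16000, seed = 5)
  cl <- generate_arch(sp)
  tooth_classes <- setdiff(unique(cl$labels), 0L)
  expect_equal(length(tooth_classes), 31L)
  expect_true(0L %in% cl$labels)
})

test_that("scenario modifiers change the geometry as specified", {
  # partial eruption: the affected molar is clipped to a crown sliver
  sp <- arch_spec(scenario = "partial_eruption", jaw = "lower",
                  points_per_cloud = 4000, seed = 31)
  cl <- generate_arch(sp)
  meta <- attr(cl, "arch_meta")
  erupted <- Filter(function(th) th$eruption < 1, meta$teeth)
  expect_equal(length(erupted), 1L)
  th <- erupted[[1]]
  expect_gte(th$eruption, 0.2)
  expect_lte(th$eruption, 0.6)
  pts <- cl$points[cl$labels == th$class, 3]
  expect_gte(min(pts), th$z_cut - 3 * sp$noise_sd)

  # malformed: exactly one tooth departs from the shape table beyond jitter
  spm <- arch_spec(scenario = "malformed", jaw = "lower",
                   points_per_cloud = 2000, seed = 8)
  clm <- generate_arch(spm)
  shapes <- toothseg:::tooth_shape_table()
  ratio <- vapply(attr(clm, "arch_meta")$teeth, function(th) {
    ref <- unlist(shapes[shapes$pos == th$pos, c("a", "b", "c")])
    max(abs(log(th$axes / ref)))
  }, numeric(1))
  expect_equal(sum(ratio > log(1.15)), 1L)
})

test_that("dataset generation follows the scenario mix and manifests it", {
  mix <- c(normal = 0.5, missing = 0.5)
  full_mix <- c(normal = 0.5, crowded = 0, missing = 0.5, malformed = 0,
                partial_eruption = 0)
  n <- 200L
  ds <- generate_dataset(n, scenario_mix = full_mix, seed = 77,
                         points_per_cloud = 400L)
  expect_equal(length(ds$clouds), n)
  counts <- table(ds$manifest$scenario)
  expect_setequal(names(counts), c("normal", "missing"))
  # 4 sigma binomial bound around 100
  expect_lt(abs(counts[["normal"]] - 100), 4 * sqrt(n * 0.25) + 1)
  # manifest bookkeeping: gingiva present everywhere, hashes and counts filled
  inv <- strsplit(ds$manifest$classes, ";")
  expect_true(all(vapply(inv, function(v) "0" %in% v, logical(1))))
  expect_true(all(ds$manifest$n_points == 400L))
  expect_true(all(nchar(ds$manifest$spec_hash) == 8L))
  # determinism of the whole dataset
  ds2 <- generate_dataset(5L, scenario_mix = full_mix, seed = 12,
                          points_per_cloud = 300L)
  ds3 <- generate_dataset(5L, scenario_mix = full_mix, seed = 12,
                          points_per_cloud = 300L)
  expect_identical(lapply(ds2$clouds, `[[`, "points"),
                   lapply(ds3$clouds, `[[`, "points"))
  expect_error(generate_dataset(3L, scenario_mix = c(normal = 0.7)),
               "sum to 1")
})
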