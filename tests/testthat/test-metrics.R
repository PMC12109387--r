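test_that("confusion matrices count, accumulate and validate", {
  pred <- c(0L, 0L, 1L, 1L)
  truth <- c(0L, 1L, 1L, 1L)
  cm <- confusion_matrix(pred, truth, 2L)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4L)

  # perfect prediction: diagonal with full trace
  cmp <- confusion_matrix(rep(0:2, c(50, 30, 20)), rep(0:2, c(50, 30, 20)), 3L)
  expect_equal(sum(diag(cmp)), 100L)
  expect_true(all(cmp[upper.tri(cmp) | lower.tri(cmp)] == 0))

  # additivity across clouds
  cm1 <- confusion_matrix(c(0L, 1L), c(0L, 0L), 2L)
  cm2 <- confusion_matrix(c(1L, 1L), c(1L, 0L), 2L)
  both <- confusion_matrix(c(0L, 1L, 1L, 1L), c(0L, 0L, 1L, 0L), 2L)
  expect_equal(unclass(cm1) + unclass(cm2), unclass(both), ignore_attr = TRUE)
  expect_equal(unclass(accumulate(cm1, c(1L, 1L), c(1L, 0L))), unclass(both),
               ignore_attr = TRUE)

  # all predictions in one class: single nonzero column
  cm0 <- confusion_matrix(rep(0L, 10), sample(0:2, 10, TRUE), 3L)
  expect_true(all(cm0[, 2:3] == 0))

  expect_error(confusion_matrix(0L, c(0L, 1L), 2L), "size error")
  expect_error(confusion_matrix(5L, 0L, 2L), "size error")
})

test_that("metrics match the hand-evaluated 2-class matrix", {
  m <- matrix(c(8L, 2L, 1L, 9L), 2, 2, byrow = TRUE)
  class(m) <- c("confusion_matrix", class(m))
  rep_ <- compute_metrics(m)
  expect_equal(rep_$per_class$IoU, c(8 / 11, 9 / 12), tolerance = 1e-12)
  expect_equal(rep_$overall$OA, 17 / 20, tolerance = 1e-12)
  expect_equal(rep_$overall$mIoU, mean(c(8 / 11, 0.75)), tolerance = 1e-12)
  # perfect predictions: all metrics are 1
  d <- confusion_matrix(rep(0:1, 5), rep(0:1, 5), 2L)
  rp <- compute_metrics(d)
  expect_equal(unlist(rp$overall), c(OA = 1, mAcc = 1, mIoU = 1, mDice = 1))
  expect_error(compute_metrics(matrix(0L, 2, 2)), "value error")
})

test_that("Dice and IoU satisfy their algebraic identity per class", {
  set.seed(31)
  pred <- sample(0:32, 4000, TRUE)
  truth <- sample(0:32, 4000, TRUE)
  rep_ <- compute_metrics(confusion_matrix(pred, truth))
  ok <- !is.na(rep_$per_class$IoU)
  expect_lt(max(abs(rep_$per_class$Dice[ok] -
                      2 * rep_$per_class$IoU[ok] / (1 + rep_$per_class$IoU[ok]))),
            1e-12)
})

test_that("metrics agree with an independent Jaccard/F1 reference", {
  for (trial in 1:20) {
    set.seed(100 + trial)
    n <- sample(200:2000, 1)
    C <- sample(c(2L, 5L, 33L), 1)
    pred <- sample(0:(C - 1L), n, TRUE)
    truth <- sample(0:(C - 1L), n, TRUE)
    rep_ <- compute_metrics(confusion_matrix(pred, truth, C),
                            scheme = fdi_label_scheme())
    orc <- jaccard_f1_oracle(pred, truth, 0:(C - 1L))
    present <- tabulate(truth + 1L, C) > 0
    expect_lt(max(abs(rep_$per_class$IoU[present] - orc[present, "jaccard"])),
              1e-10)
    expect_lt(max(abs(rep_$per_class$Dice[present] - orc[present, "f1"])),
              1e-10)
    expect_equal(rep_$overall$OA, mean(pred == truth), tolerance = 1e-12)
  }
})

test_that("mIoU never exceeds mDice", {
  for (trial in 1:50) {
    set.seed(300 + trial)
    C <- sample(2:10, 1)
    pred <- sample(0:(C - 1L), 500, TRUE)
    truth <- sample(0:(C - 1L), 500, TRUE)
    rep_ <- compute_metrics(confusion_matrix(pred, truth, C))
    expect_lte(rep_$overall$mIoU, rep_$overall$mDice + 1e-12)
  }
})

test_that("classes absent from the ground truth are excluded unless requested", {
  pred <- c(0L, 0L, 1L, 2L)
  truth <- c(0L, 0L, 1L, 1L)       # class 2 absent from ground truth
  cm <- confusion_matrix(pred, truth, 3L)
  rep_ex <- compute_metrics(cm)
  expect_true(is.na(rep_ex$per_class$IoU[3]))
  expect_equal(rep_ex$overall$mIoU, mean(c(1, 1 / 2)), tolerance = 1e-12)
  rep_in <- compute_metrics(cm, include_absent = TRUE)
  expect_equal(rep_in$overall$mIoU, mean(c(1, 1 / 2, 0)), tolerance = 1e-12)
})

test_that("tooth-type rows merge quadrants in the confusion matrix", {
  sch <- fdi_label_scheme()
  # all four first molars (FDI 16,26,36,46) predicted as each other:
  # merged matrix sees them as one perfectly-predicted type
  molars <- fdi_to_class(c(16, 26, 36, 46))
  truth <- rep(molars, each = 10)
  pred <- rep(rev(molars), each = 10)   # wrong quadrant, right type
  rep_ <- compute_metrics(confusion_matrix(pred, truth), scheme = sch)
  t6 <- rep_$per_type[rep_$per_type$type == "T6", ]
  expect_equal(t6$IoU, 1, tolerance = 1e-12)
  # per-class view is 0 (every quadrant missed)
  expect_true(all(rep_$per_class$IoU[molars + 1] == 0))
  # averaged convention keeps the distinction
  rep_avg <- compute_metrics(confusion_matrix(pred, truth), scheme = sch,
                             type_convention = "averaged")
  expect_equal(rep_avg$per_type$IoU[rep_avg$per_type$type == "T6"], 0)
})

test_that("report renders as an aligned table and JSON", {
  set.seed(9)
  pred <- sample(0:32, 2000, TRUE)
  rep_ <- compute_metrics(confusion_matrix(pred, pred))
  txt <- format_metrics_table(rep_)
  expect_true(any(grepl("^T6", txt)))
  expect_true(any(grepl("mIoU\\s+100.00", txt)))
  f <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep_, f)
  parsed <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(parsed$overall$OA, 1)
})
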