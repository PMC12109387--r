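#' Build or accumulate a confusion matrix
#'
#' Rows are true classes, columns predicted classes, both indexed 0..C-1.
#' Matrices from different clouds add, so a dataset-level matrix is the sum
#' of the per-cloud ones.
#'
#' @param pred_labels,true_labels equal-length integer vectors in `0..C-1`.
#' @param n_classes number of classes C.
#' @return `C x C` integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(pred_labels, true_labels, n_classes = 33L) {
  if (length(pred_labels) != length(true_labels)) {
    stop("size error: ", length(pred_labels), " predictions vs ",
         length(true_labels), " references")
  }
  pred_labels <- as.integer(pred_labels)
  true_labels <- as.integer(true_labels)
  if (any(pred_labels < 0L | pred_labels >= n_classes) ||
      any(true_labels < 0L | true_labels >= n_classes)) {
    stop("size error: labels outside [0, ", n_classes, ")")
  }
  counts <- tabulate(true_labels * n_classes + pred_labels + 1L,
                     nbins = n_classes * n_classes)
  m <- matrix(counts, n_classes, n_classes, byrow = TRUE)
  dimnames(m) <- list(true = 0:(n_classes - 1L), pred = 0:(n_classes - 1L))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' @rdname confusion_matrix
#' @param matrix an existing confusion matrix to add new counts into.
#' @export
accumulate <- function(matrix, pred_labels, true_labels) {
  m2 <- confusion_matrix(pred_labels, true_labels, nrow(matrix))
  out <- unclass(matrix) + unclass(m2)
  class(out) <- c("confusion_matrix", class(out))
  out
}

per_class_stats <- function(mat) {
  mat <- unclass(mat)
  tp <- diag(mat)
  fn <- rowSums(mat) - tp
  fp <- colSums(mat) - tp
  iou <- tp / (tp + fn + fp)
  dice <- 2 * tp / (fn + 2 * tp + fp)
  acc <- tp / (tp + fn)
  list(tp = tp, fn = fn, fp = fp, iou = iou, dice = dice, acc = acc,
       present = rowSums(mat) > 0)
}

#' Compute segmentation metrics from a confusion matrix
#'
#' Per class c: `IoU_c = TP_c / (TP_c + FN_c + FP_c)`,
#' `Dice_c = 2 TP_c / (FN_c + 2 TP_c + FP_c)` and recall
#' `Acc_c = TP_c / (TP_c + FN_c)`. Overall accuracy is the multiclass
#' trace/total. The macro means mIoU, mDice and mAcc average over the classes
#' present in the ground truth; classes absent from the reference are
#' reported as `NA` and excluded (set `include_absent = TRUE` to score them 0
#' instead). The per-tooth-type table merges the four quadrant instances of
#' each FDI position in the confusion matrix before computing IoU/Dice, so it
#' reports one row per type T1..T8 plus gum.
#'
#' All values are proportions in `[0, 1]`; multiply by 100 for percentages.
#'
#' @param matrix a [confusion_matrix()].
#' @param scheme a [fdi_label_scheme()] (used for the tooth-type table when
#'   the matrix has 33 classes).
#' @param include_absent score ground-truth-absent classes as 0 in the means.
#' @param type_convention `"merged"` (default) computes per-type metrics from
#'   the quadrant-merged matrix; `"averaged"` averages the per-class metrics
#'   within each type.
#' @return An object of class `metrics_report`: list with `overall`
#'   (OA, mAcc, mIoU, mDice), `per_class` and `per_type` data.frames, and the
#'   confusion matrix.
#' @export
compute_metrics <- function(matrix, scheme = fdi_label_scheme(),
                            include_absent = FALSE,
                            type_convention = c("merged", "averaged")) {
  type_convention <- match.arg(type_convention)
  mat <- unclass(matrix)
  total <- sum(mat)
  if (total <= 0) stop("value error: empty confusion matrix")
  C <- nrow(mat)
  st <- per_class_stats(mat)
  iou <- st$iou; dice <- st$dice; acc <- st$acc
  if (include_absent) {
    iou[!st$present] <- 0; dice[!st$present] <- 0; acc[!st$present] <- 0
    keep <- rep(TRUE, C)
  } else {
    iou[!st$present] <- NA; dice[!st$present] <- NA; acc[!st$present] <- NA
    keep <- st$present
  }
  overall <- list(
    OA = sum(diag(mat)) / total,
    mAcc = mean(acc[keep]),
    mIoU = mean(iou[keep]),
    mDice = mean(dice[keep])
  )
  per_class <- data.frame(
    class = 0:(C - 1L),
    name = if (C == scheme$n_classes) scheme$class_names else as.character(0:(C - 1L)),
    present = st$present, support = rowSums(mat),
    IoU = iou, Dice = dice, Acc = acc, row.names = NULL)

  per_type <- NULL
  if (C == scheme$n_classes) {
    types <- c("gum", paste0("T", 1:8))
    A <- vapply(types, function(tt) as.numeric(scheme$tooth_type == tt),
                numeric(C))                      # C x 9 indicator
    if (type_convention == "merged") {
      m9 <- t(A) %*% mat %*% A
      st9 <- per_class_stats(m9)
      iou9 <- st9$iou; dice9 <- st9$dice; acc9 <- st9$acc
      iou9[!st9$present] <- NA; dice9[!st9$present] <- NA; acc9[!st9$present] <- NA
      per_type <- data.frame(type = types, support = rowSums(m9),
                             IoU = iou9, Dice = dice9, Acc = acc9,
                             row.names = NULL)
    } else {
      agg <- function(v) {
        vapply(types, function(tt) {
          sel <- scheme$tooth_type == tt & st$present
          if (!any(sel)) NA_real_ else mean(v[sel])
        }, numeric(1))
      }
      per_type <- data.frame(type = types,
                             support = as.vector(t(A) %*% rowSums(mat)),
                             IoU = agg(st$iou), Dice = agg(st$dice),
                             Acc = agg(st$acc), row.names = NULL)
    }
  }
  structure(list(overall = overall, per_class = per_class,
                 per_type = per_type, confusion = matrix),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(x), sep = "\n")
  invisible(x)
}

#' Format a metrics report as an aligned text table
#'
#' One row per tooth type (T1..T8 and gum) with IoU and Dice, followed by the
#' overall OA/mAcc/mIoU/mDice block, all as percentages.
#'
#' @param report a `metrics_report`.
#' @return character vector of lines.
#' @export
format_metrics_table <- function(report) {
  pc <- function(v) ifelse(is.na(v), "   -  ", sprintf("%6.2f", 100 * v))
  lines <- c(sprintf("%-6s %10s %7s %7s", "Type", "Support", "IoU", "Dice"))
  if (!is.null(report$per_type)) {
    tt <- report$per_type
    ord <- c(paste0("T", 1:8), "gum")
    tt <- tt[match(ord, tt$type), ]
    for (i in seq_len(nrow(tt))) {
      lines <- c(lines, sprintf("%-6s %10d %s %s", tt$type[i],
                                as.integer(tt$support[i]),
                                pc(tt$IoU[i]), pc(tt$Dice[i])))
    }
  }
  ov <- report$overall
  lines <- c(lines, "Overall",
             sprintf("  OA    %s", pc(ov$OA)),
             sprintf("  mAcc  %s", pc(ov$mAcc)),
             sprintf("  mDice %s", pc(ov$mDice)),
             sprintf("  mIoU  %s", pc(ov$mIoU)))
  lines
}

#' Serialize a metrics report to JSON
#'
#' @param report a `metrics_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  out <- list(overall = report$overall,
              per_class = report$per_class,
              per_type = report$per_type)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
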