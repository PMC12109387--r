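#' FDI label scheme for tooth/gingiva segmentation
#'
#' Builds the fixed 33-class labelling used throughout the package: class 0 is
#' gingiva and classes 1..32 are the permanent teeth in FDI two-digit notation,
#' enumerated quadrant by quadrant (11-18, 21-28, 31-38, 41-48). The scheme
#' also carries the tooth-type map that merges the four quadrant instances of
#' each tooth position into one of T1..T8 (central incisor .. third molar),
#' with gingiva kept as its own "gum" group, which is how per-type results are
#' reported.
#'
#' @return An object of class `label_scheme`: a list with
#'   \describe{
#'     \item{n_classes}{33.}
#'     \item{fdi}{integer vector of length 33; `NA` for gingiva, otherwise the
#'       FDI code of each internal class index (position `i + 1` holds class
#'       `i`).}
#'     \item{class_names}{character labels ("gingiva", "FDI_11", ...).}
#'     \item{tooth_type}{character vector of length 33 mapping each class to
#'       "gum" or "T1".."T8".}
#'   }
#' @examples
#' sch <- fdi_label_scheme()
#' sch$n_classes
#' sch$tooth_type[fdi_to_class(16, sch) + 1]  # first molar -> "T6"
#' @export
fdi_label_scheme <- function() {
  quadrants <- c(1L, 2L, 3L, 4L)
  fdi <- c(NA_integer_, as.integer(outer(1:8, quadrants * 10L, `+`)))
  type <- c("gum", rep(paste0("T", 1:8), times = 4))
  names <- c("gingiva", paste0("FDI_", fdi[-1]))
  structure(
    list(n_classes = 33L, fdi = fdi, class_names = names, tooth_type = type),
    class = "label_scheme"
  )
}

#' Convert between FDI codes and internal class indices
#'
#' Internal labels are contiguous integers 0..32 (0 = gingiva) so confusion
#' matrices stay dense; files and reports use these indices too. These helpers
#' translate to and from two-digit FDI codes.
#'
#' @param fdi integer vector of FDI codes (e.g. 11, 48).
#' @param scheme a [fdi_label_scheme()] object.
#' @return `fdi_to_class`: internal class indices in 1..32. `class_to_fdi`:
#'   FDI codes (`NA` for class 0).
#' @export
fdi_to_class <- function(fdi, scheme = fdi_label_scheme()) {
  idx <- match(as.integer(fdi), scheme$fdi) - 1L
  if (anyNA(idx)) {
    stop("unknown FDI code(s): ", paste(fdi[is.na(idx)], collapse = ", "))
  }
  idx
}

#' @rdname fdi_to_class
#' @param class_index internal class indices in 0..32.
#' @export
class_to_fdi <- function(class_index, scheme = fdi_label_scheme()) {
  stopifnot(all(class_index >= 0L), all(class_index < scheme$n_classes))
  scheme$fdi[class_index + 1L]
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("FDI label scheme:", x$n_classes, "classes",
      "(gingiva + 32 permanent teeth, types T1..T8)\n")
  invisible(x)
}
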