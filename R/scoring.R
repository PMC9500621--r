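# subset an image matrix (values[row, col], 1-based) by a 0-based box
crop_to_box <- function(values, b) {
  values[(b$y_min + 1L):(b$y_max + 1L), (b$x_min + 1L):(b$x_max + 1L),
         drop = FALSE]
}

#' Edge mass S of a candidate box
#'
#' S is the sum of normalized edge-map intensities over every pixel of the
#' box. It grows when the box covers the bright tumor-boundary edges, i.e.
#' with the box's true-positive pixel content.
#'
#' @param em An `edge_map`.
#' @param roi A box lying within the map.
#' @return S, a value in \[0, area(roi)\].
#' @export
indicator_S <- function(em, roi) {
  if (!box_in_frame(roi, em$size)) stop("roi lies outside the edge map")
  sum(crop_to_box(em$values, roi))
}

#' Edge density D of a candidate box
#'
#' D is the fraction of box pixels whose binarized edge value is 1, i.e. the
#' share of high-intensity edge pixels among all M x N pixels of the box. It
#' shrinks when the box drags in background area (false-positive pixels).
#'
#' @param bem A `binary_edge_map`.
#' @param roi A box lying within the map.
#' @return D in \[0, 1\].
#' @export
indicator_D <- function(bem, roi) {
  if (!box_in_frame(roi, bem$size)) stop("roi lies outside the edge map")
  mean(crop_to_box(bem$values, roi))
}

#' Combined selection score SD = S x D
#'
#' `roi_score()` packages the two indicators and their product; `score_roi()`
#' computes them for a box from an edge map and its binarization. SD is kept
#' at full precision; round it for reporting.
#'
#' @param S Edge mass (non-negative).
#' @param D Edge density in \[0, 1\].
#' @return An object of class `"roi_score"` with fields `S`, `D`, `SD`.
#' @examples
#' roi_score(12683, 0.26)$SD # 3297.58, reported as 3298
#' @export
roi_score <- function(S, D) {
  if (!is.finite(S) || S < 0) stop("S must be a non-negative number")
  if (!is.finite(D) || D < 0 || D > 1) stop("D must lie in [0, 1]")
  structure(list(S = S, D = D, SD = S * D), class = "roi_score")
}

#' @export
print.roi_score <- function(x, ...) {
  cat(sprintf("<roi_score S=%.2f D=%.4f SD=%.2f>\n", x$S, x$D, x$SD))
  invisible(x)
}

#' @rdname roi_score
#' @param em An `edge_map`.
#' @param bem The `binary_edge_map` derived from `em`.
#' @param roi A box within the shared frame.
#' @export
score_roi <- function(em, bem, roi) {
  if (!identical(unclass(em$size), unclass(bem$size)))
    stop("edge map and binary edge map differ in size")
  roi_score(indicator_S(em, roi), indicator_D(bem, roi))
}
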