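#' busroi: edge-based ROI selection for breast ultrasound
#'
#' Scores candidate tumor bounding boxes against an edge map and selects the
#' box that maximizes SD = S x D, where S is the sum of normalized edge
#' intensities inside the box (edge mass) and D is the fraction of
#' above-threshold edge pixels inside the box (edge density). Also provides
#' baseline box combiners, pixel-overlap evaluation, artificial-RGB
#' preprocessing, and a synthetic phantom generator.
#'
#' @section Coordinate convention:
#' Boxes use 0-based, inclusive pixel indices: `x_min`/`x_max` index columns,
#' `y_min`/`y_max` index rows, origin at the top-left. A box therefore spans
#' `N = x_max - x_min + 1` columns and `M = y_max - y_min + 1` rows. Image
#' matrices are stored the R way, `values[row, col]`, 1-based; conversion
#' happens inside the accessors.
#'
#' @keywords internal
"_PACKAGE"

# round half away from zero (round() in R rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Construct an axis-aligned bounding box
#'
#' A box is an axis-aligned integer-pixel rectangle with 0-based inclusive
#' corners; see the package help for the full coordinate convention.
#'
#' @param x_min,y_min Column/row index of the top-left pixel (0-based).
#' @param x_max,y_max Column/row index of the bottom-right pixel (inclusive).
#' @return An object of class `"box"`.
#' @examples
#' b <- make_box(0, 0, 9, 9)
#' box_area(b) # 100
#' @export
make_box <- function(x_min, y_min, x_max, y_max) {
  co <- c(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
  if (any(!is.finite(co)) || any(co != floor(co)))
    stop("box coordinates must be finite integers")
  co <- stats::setNames(as.integer(co), names(co))
  for (f in c("x_min", "y_min", "x_max", "y_max"))
    if (co[[f]] < 0) stop(sprintf("%s is negative (%d)", f, co[[f]]))
  if (co[["x_min"]] > co[["x_max"]]) stop("x_min > x_max")
  if (co[["y_min"]] > co[["y_max"]]) stop("y_min > y_max")
  structure(as.list(co), class = "box")
}

#' @export
print.box <- function(x, ...) {
  cat(sprintf("<box (%d,%d)-(%d,%d) %dx%d>\n", x$x_min, x$y_min,
              x$x_max, x$y_max, box_width(x), box_height(x)))
  invisible(x)
}

#' @export
format.box <- function(x, ...) {
  sprintf("(%d,%d,%d,%d)", x$x_min, x$y_min, x$x_max, x$y_max)
}

#' Box width, height and area in pixels
#'
#' Inclusive bounds: a single-pixel box has width, height and area 1.
#'
#' @param b A [make_box()] object.
#' @return An integer pixel count.
#' @export
box_area <- function(b) box_width(b) * box_height(b)

#' @rdname box_area
#' @export
box_width <- function(b) b$x_max - b$x_min + 1L

#' @rdname box_area
#' @export
box_height <- function(b) b$y_max - b$y_min + 1L

#' Image size descriptor
#'
#' @param width,height Image dimensions in pixels (>= 1).
#' @return An object of class `"image_size"`.
#' @export
image_size <- function(width, height) {
  width <- as.integer(width); height <- as.integer(height)
  if (is.na(width) || is.na(height) || width < 1L || height < 1L)
    stop("width and height must be >= 1")
  structure(list(width = width, height = height), class = "image_size")
}

#' @export
print.image_size <- function(x, ...) {
  cat(sprintf("<image_size %dx%d>\n", x$width, x$height)); invisible(x)
}

# is the box contained in a width x height frame?
box_in_frame <- function(b, size) {
  b$x_min >= 0L && b$y_min >= 0L &&
    b$x_max <= size$width - 1L && b$y_max <= size$height - 1L
}

#' Intersection of two boxes
#'
#' @param a,b Boxes.
#' @return The maximal box contained in both, or `NULL` when the boxes share
#'   no pixel.
#' @examples
#' intersect_boxes(make_box(0, 0, 10, 10), make_box(5, 5, 20, 20))
#' @export
intersect_boxes <- function(a, b) {
  x1 <- max(a$x_min, b$x_min); y1 <- max(a$y_min, b$y_min)
  x2 <- min(a$x_max, b$x_max); y2 <- min(a$y_max, b$y_max)
  if (x1 > x2 || y1 > y2) return(NULL)
  make_box(x1, y1, x2, y2)
}

#' Smallest box enclosing a set of boxes
#'
#' @param bs A non-empty list of boxes.
#' @return The componentwise min/max envelope.
#' @export
enclose_boxes <- function(bs) {
  if (length(bs) == 0L) stop("enclose_boxes() needs at least one box")
  make_box(min(vapply(bs, `[[`, 0L, "x_min")),
           min(vapply(bs, `[[`, 0L, "y_min")),
           max(vapply(bs, `[[`, 0L, "x_max")),
           max(vapply(bs, `[[`, 0L, "y_max")))
}

#' Do two boxes share at least one pixel?
#'
#' With inclusive bounds, boxes that touch at a single corner pixel overlap.
#' This is the detection criterion: a predicted box counts as a detection when
#' it overlaps the gold-standard box partially or completely.
#'
#' @param a,b Boxes.
#' @return `TRUE` iff the intersection is non-empty.
#' @export
boxes_overlap <- function(a, b) !is.null(intersect_boxes(a, b))

#' Rescale a box between image frames
#'
#' Maps a box given in the coordinates of a `from`-sized image (for example a
#' detector's model-input frame) into a `to`-sized image (the original
#' ultrasound frame). Each corner coordinate is multiplied by the axis scale
#' factor, rounded to the nearest integer (ties away from zero), and clamped
#' into the target frame.
#'
#' @param b A box lying within `from`.
#' @param from,to [image_size()] objects.
#' @return A valid box in the `to` frame.
#' @examples
#' rescale_box(make_box(64, 64, 127, 127),
#'             image_size(640, 640), image_size(320, 320))
#' @export
rescale_box <- function(b, from, to) {
  if (!box_in_frame(b, from))
    stop("box does not lie within the source frame")
  sx <- to$width / from$width
  sy <- to$height / from$height
  cl <- function(v, hi) pmin(pmax(v, 0), hi)
  make_box(cl(round_half_away(b$x_min * sx), to$width - 1L),
           cl(round_half_away(b$y_min * sy), to$height - 1L),
           cl(round_half_away(b$x_max * sx), to$width - 1L),
           cl(round_half_away(b$y_max * sy), to$height - 1L))
}
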