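#' Baseline box-combining methods
#'
#' Combine the boxes proposed by several detection models into a single box,
#' excluding models that failed to detect:
#' \describe{
#'   \item{`combine_average()`}{corner averaging — the combined box's
#'     upper-left corner is the mean of the present boxes' upper-left corners
#'     and likewise for the lower-right corner, each coordinate rounded to the
#'     nearest integer (ties away from zero).}
#'   \item{`combine_union()`}{the smallest box enclosing every present box.}
#'   \item{`combine_intersection()`}{the box common to all present boxes;
#'     `NULL` when they share no pixel.}
#' }
#' All three return `NULL` when no model produced a box; a `NULL` result
#' counts as a detection failure in evaluation.
#'
#' @param candidates A [candidate_set()].
#' @return A box or `NULL`.
#' @examples
#' cs <- candidate_set("img1", list(a = make_box(0, 0, 10, 10),
#'                                  b = make_box(10, 10, 20, 20),
#'                                  c = NULL))
#' combine_average(cs) # (5,5,15,15)
#' combine_union(cs) # (0,0,20,20)
#' combine_intersection(cs) # the shared corner pixel (10,10)
#' @export
combine_average <- function(candidates) {
  pb <- present_boxes(candidates)
  if (length(pb) == 0L) return(NULL)
  avg <- function(f) round_half_away(mean(vapply(pb, `[[`, 0L, f)))
  make_box(avg("x_min"), avg("y_min"), avg("x_max"), avg("y_max"))
}

#' @rdname combine_average
#' @export
combine_union <- function(candidates) {
  pb <- present_boxes(candidates)
  if (length(pb) == 0L) return(NULL)
  enclose_boxes(pb)
}

#' @rdname combine_average
#' @export
combine_intersection <- function(candidates) {
  pb <- present_boxes(candidates)
  if (length(pb) == 0L) return(NULL)
  Reduce(function(a, b) if (is.null(a)) NULL else intersect_boxes(a, b), pb)
}

# dispatch a combiner by name ("average", "union", "intersection")
combiner_by_name <- function(method) {
  switch(method,
         average = combine_average,
         union = combine_union,
         intersection = combine_intersection,
         stop("unknown combining method: ", method))
}
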