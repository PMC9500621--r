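#' Per-image candidate boxes from several detection models
#'
#' Holds, for one image, an ordered mapping from model name to an optional
#' box. A missing entry (`NULL`) records that the model failed to produce a
#' detection for that image. The model order is fixed and used for
#' deterministic tie-breaking during selection.
#'
#' @param image_id Image identifier.
#' @param boxes A named list, each element a [make_box()] or `NULL`.
#' @return An object of class `"candidate_set"`.
#' @export
candidate_set <- function(image_id, boxes) {
  nms <- names(boxes)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms))
    stop("boxes must be uniquely named by model")
  ok <- vapply(boxes, function(b) is.null(b) || inherits(b, "box"), TRUE)
  if (!all(ok)) stop("each candidate must be a box or NULL")
  structure(list(image_id = image_id, boxes = boxes), class = "candidate_set")
}

# candidates that actually produced a box
present_boxes <- function(cs) Filter(Negate(is.null), cs$boxes)

#' @export
print.candidate_set <- function(x, ...) {
  pb <- present_boxes(x)
  cat(sprintf("<candidate_set %s: %d/%d models detected>\n", x$image_id,
              length(pb), length(x$boxes)))
  invisible(x)
}

#' Index of the highest-SD score
#'
#' Ties are broken in favor of the earliest score in the list, i.e. the first
#' model in the configured order.
#'
#' @param scores A non-empty list of [roi_score()] objects.
#' @return The 1-based index of the maximal SD.
#' @export
select_from_scores <- function(scores) {
  if (length(scores) == 0L) stop("no scores to select from")
  unname(which.max(vapply(scores, `[[`, 0, "SD")))
}

#' Edge-based selection of the best candidate box
#'
#' The selection procedure: binarize the edge map once with the intermode
#' threshold, score every candidate box that is present (S, D, SD = S x D),
#' and return the candidate with the highest SD. Models that failed to detect
#' are skipped; when every model failed the result carries no box and counts
#' as a detection failure downstream.
#'
#' @param em The image's `edge_map`.
#' @param candidates A [candidate_set()]; all present boxes must lie within
#'   the edge-map frame.
#' @param bem Optional precomputed `binary_edge_map` (to reuse a threshold).
#' @param max_iterations Passed to [intermode_threshold()].
#' @return An object of class `"selection_result"`: `selected_model` (name or
#'   `NA`), `selected_box` (box or `NULL`), and `scores` (named list of
#'   `roi_score` for present candidates).
#' @export
select_roi <- function(em, candidates, bem = NULL, max_iterations = 10000L) {
  stopifnot(inherits(candidates, "candidate_set"))
  pb <- present_boxes(candidates)
  if (length(pb) == 0L)
    return(structure(list(image_id = candidates$image_id,
                          selected_model = NA_character_,
                          selected_box = NULL, scores = list()),
                     class = "selection_result"))
  if (is.null(bem))
    bem <- binarize_edge_map(em, intermode_threshold(em, max_iterations))
  scores <- lapply(pb, function(b) score_roi(em, bem, b))
  k <- select_from_scores(scores)
  structure(list(image_id = candidates$image_id,
                 selected_model = names(pb)[k],
                 selected_box = pb[[k]],
                 scores = scores),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  if (is.null(x$selected_box)) {
    cat(sprintf("<selection_result %s: no candidate available>\n", x$image_id))
  } else {
    cat(sprintf("<selection_result %s: %s %s, SD=%.1f>\n", x$image_id,
                x$selected_model, format(x$selected_box),
                x$scores[[x$selected_model]]$SD))
  }
  invisible(x)
}
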