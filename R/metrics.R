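#' Pixel-overlap precision, recall and F1 of a predicted box
#'
#' With gold-standard box G and predicted box P,
#' precision = |G n P| / |P|, recall = |G n P| / |G|, and the F1-score is
#' their harmonic mean, taken as 0 when both are 0 (disjoint boxes). Counts
#' are exact integer pixel counts under the inclusive-bound convention.
#'
#' @param gold,pred Boxes in the same image frame.
#' @return A named numeric vector `c(precision, recall, f1)`.
#' @examples
#' roi_metrics(make_box(0, 0, 9, 9), make_box(0, 0, 9, 4))
#' @export
roi_metrics <- function(gold, pred) {
  ov <- intersect_boxes(gold, pred)
  n_ov <- if (is.null(ov)) 0L else box_area(ov)
  p <- n_ov / box_area(pred)
  r <- n_ov / box_area(gold)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Build per-image evaluation records
#'
#' One record per gold-standard box: whether the method under evaluation
#' detected the tumor (its box overlaps gold by at least one pixel) and, when
#' it did, the pixel-overlap metrics. Images with no predicted box, or a
#' predicted box disjoint from gold, are detection failures: they lower the
#' detection rate and are excluded from the precision/recall/F1 means.
#'
#' @param gold Named list of gold boxes, `image_id -> box`.
#' @param pred Named list of predicted boxes, `image_id -> box or NULL`;
#'   images absent from `pred` count as failures.
#' @param labels Named character vector, `image_id -> "benign"|"malignant"`.
#' @return A data.frame of class `"eval_records"` with columns `image_id`,
#'   `class_label`, `detected`, `precision`, `recall`, `f1` (metrics `NA`
#'   when not detected).
#' @export
eval_records <- function(gold, pred, labels) {
  ids <- names(gold)
  if (is.null(ids)) stop("gold must be a named list of boxes")
  missing_lab <- setdiff(ids, names(labels))
  if (length(missing_lab))
    stop("no class label for image(s): ", paste(missing_lab, collapse = ", "))
  rows <- lapply(ids, function(id) {
    g <- gold[[id]]
    p <- if (id %in% names(pred)) pred[[id]] else NULL
    if (!is.null(p) && boxes_overlap(g, p)) {
      m <- roi_metrics(g, p)
      data.frame(image_id = id, class_label = unname(labels[[id]]),
                 detected = TRUE, precision = m[["precision"]],
                 recall = m[["recall"]], f1 = m[["f1"]])
    } else {
      data.frame(image_id = id, class_label = unname(labels[[id]]),
                 detected = FALSE, precision = NA_real_, recall = NA_real_,
                 f1 = NA_real_)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("eval_records", class(out))
  out
}

#' Detection rate of a set of evaluation records
#'
#' Percentage of images whose predicted box overlaps the gold-standard box
#' partially or completely.
#'
#' @param records An [eval_records()] data.frame.
#' @return A percentage in \[0, 100\].
#' @export
detection_rate <- function(records) {
  if (nrow(records) == 0L) stop("no evaluation records")
  100 * mean(records$detected)
}

#' Aggregate metrics for one class group
#'
#' Filters the records to `group` ("benign", "malignant", or "all"), computes
#' the detection rate over all its images, and the mean and sample standard
#' deviation (n - 1 denominator) of precision, recall and F1 over the
#' detected images only.
#'
#' @param records An [eval_records()] data.frame.
#' @param group `"benign"`, `"malignant"`, or `"all"`.
#' @return A one-row data.frame: `group`, `n_images`, `n_detected`,
#'   `detection_rate`, and `<metric>_mean` / `<metric>_sd` for precision,
#'   recall, f1. Means are `NA` (with all detections failed) when
#'   `n_detected` is 0.
#' @export
aggregate_metrics <- function(records, group = c("all", "benign", "malignant")) {
  group <- match.arg(group)
  sub <- if (group == "all") records else records[records$class_label == group, ]
  if (nrow(sub) == 0L) stop("no images in group '", group, "'")
  det <- sub[sub$detected, ]
  stat <- function(f, v) if (nrow(det) == 0L) NA_real_ else f(det[[v]])
  data.frame(group = group,
             n_images = nrow(sub),
             n_detected = nrow(det),
             detection_rate = 100 * nrow(det) / nrow(sub),
             precision_mean = stat(mean, "precision"),
             precision_sd = stat(stats::sd, "precision"),
             recall_mean = stat(mean, "recall"),
             recall_sd = stat(stats::sd, "recall"),
             f1_mean = stat(mean, "f1"),
             f1_sd = stat(stats::sd, "f1"))
}

#' Per-class summary table (benign / malignant / all)
#'
#' @param records An [eval_records()] data.frame.
#' @return A data.frame with one [aggregate_metrics()] row per group present
#'   in the records, plus the pooled "all" row.
#' @export
summarize_metrics <- function(records) {
  groups <- intersect(c("benign", "malignant"), unique(records$class_label))
  do.call(rbind, lapply(c(groups, "all"),
                        function(g) aggregate_metrics(records, g)))
}
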