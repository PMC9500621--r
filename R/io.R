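#' Box tables: the CSV/JSON interchange format
#'
#' Box tables are data.frames with columns
#' `image_id, source, x_min, y_min, x_max, y_max`, where `source` is a model
#' name, `"gold"`, or a combiner name. A missing detection may be encoded on
#' read either as a row with empty coordinate fields or by the absence of the
#' `(image_id, source)` row; on write, absences are simply not written.
#'
#' @param path CSV (`.csv`) or JSON (`.json`) file in the documented dialect.
#' @param max_size Optional [image_size()]; boxes exceeding it are rejected
#'   with the offending `image_id` named.
#' @return `read_boxes()`: a validated data.frame (absent rows kept with `NA`
#'   coordinates).
#' @export
read_boxes <- function(path, max_size = NULL) {
  ext <- tolower(tools::file_ext(path))
  df <- switch(ext,
    csv = utils::read.csv(path, stringsAsFactors = FALSE),
    json = as.data.frame(jsonlite::fromJSON(path)),
    stop("unsupported box-table extension: ", ext)
  )
  needed <- c("image_id", "source", "x_min", "y_min", "x_max", "y_max")
  if (!all(needed %in% names(df)))
    stop("box table must have columns: ", paste(needed, collapse = ", "))
  df <- df[needed]
  for (col in needed[3:6]) {
    v <- df[[col]]
    if (is.character(v)) v[v == ""] <- NA
    df[[col]] <- suppressWarnings(as.integer(v))
  }
  absent <- apply(is.na(df[needed[3:6]]), 1L, all)
  bad <- which(!absent & apply(is.na(df[needed[3:6]]), 1L, any))
  if (length(bad))
    stop("malformed box row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))
  for (i in which(!absent)) { # validate via the box constructor
    b <- tryCatch(make_box(df$x_min[i], df$y_min[i], df$x_max[i], df$y_max[i]),
                  error = function(e)
                    stop(sprintf("line %d (image %s): %s", i + 1L,
                                 df$image_id[i], conditionMessage(e))))
    if (!is.null(max_size) && !box_in_frame(b, max_size))
      stop("box exceeds the image frame for image_id ", df$image_id[i])
  }
  df
}

#' @rdname read_boxes
#' @param df A box-table data.frame; rows with `NA` coordinates are dropped
#'   on write.
#' @export
write_boxes <- function(df, path) {
  keep <- !apply(is.na(df[c("x_min", "y_min", "x_max", "y_max")]), 1L, any)
  utils::write.csv(df[keep, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

# one box-table row
box_row <- function(image_id, source, b) {
  if (is.null(b))
    return(data.frame(image_id = image_id, source = source,
                      x_min = NA_integer_, y_min = NA_integer_,
                      x_max = NA_integer_, y_max = NA_integer_))
  data.frame(image_id = image_id, source = source, x_min = b$x_min,
             y_min = b$y_min, x_max = b$x_max, y_max = b$y_max)
}

#' Convert between box tables and package objects
#'
#' `candidates_to_df()` flattens a [candidate_set()] to table rows;
#' `df_to_candidates()` rebuilds per-image candidate sets from a table,
#' preserving a configured model order and treating missing rows as detection
#' failures. `df_to_boxes()` extracts a single source (e.g. `"gold"`) as a
#' named list of boxes.
#'
#' @param cs A [candidate_set()].
#' @return `candidates_to_df()`: a box-table data.frame.
#' @export
candidates_to_df <- function(cs) {
  do.call(rbind, lapply(names(cs$boxes),
                        function(m) box_row(cs$image_id, m, cs$boxes[[m]])))
}

#' @rdname candidates_to_df
#' @param df A box-table data.frame.
#' @param model_order Character vector of model names; unknown sources in the
#'   table trigger a warning.
#' @export
df_to_candidates <- function(df, model_order) {
  known <- unique(df$source)
  extra <- setdiff(known, c(model_order, "gold"))
  if (length(extra))
    warning("unknown source name(s) ignored: ", paste(extra, collapse = ", "))
  ids <- unique(df$image_id)
  out <- lapply(ids, function(id) {
    sub <- df[df$image_id == id, ]
    boxes <- stats::setNames(vector("list", length(model_order)), model_order)
    for (m in model_order) {
      r <- sub[sub$source == m, ]
      if (nrow(r) == 1L && !is.na(r$x_min))
        boxes[[m]] <- make_box(r$x_min, r$y_min, r$x_max, r$y_max)
    }
    candidate_set(id, boxes)
  })
  stats::setNames(out, ids)
}

#' @rdname candidates_to_df
#' @param source Source name to extract.
#' @export
df_to_boxes <- function(df, source) {
  sub <- df[df$source == source & !is.na(df$x_min), ]
  stats::setNames(
    lapply(seq_len(nrow(sub)),
           function(i) make_box(sub$x_min[i], sub$y_min[i],
                                sub$x_max[i], sub$y_max[i])),
    sub$image_id)
}

#' Read an image-class label table
#'
#' @param path CSV with columns `image_id,class_label`
#'   (`benign`/`malignant`).
#' @return Named character vector `image_id -> class_label`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("image_id", "class_label") %in% names(df)))
    stop("labels table must have columns image_id, class_label")
  bad <- setdiff(unique(df$class_label), c("benign", "malignant"))
  if (length(bad)) stop("unknown class label(s): ", paste(bad, collapse = ", "))
  stats::setNames(df$class_label, df$image_id)
}
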