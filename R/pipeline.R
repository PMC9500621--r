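#' Evaluate selection, combiners and single models over a set of images
#'
#' The shared evaluation core: for every image the edge map is binarized once
#' (intermode threshold), the edge-based selection and the requested
#' combiners are applied to the candidate boxes, and every method — each
#' single model, the selection, and the combiners — is evaluated against the
#' gold-standard box with the pixel-overlap metrics.
#'
#' @param images A list, e.g. a [generate_benchmark()] result: per image a
#'   list with `image_id`, `edge_map`, `gold`, `class_label`, `candidates`.
#' @param methods Methods to evaluate besides the single models; any of
#'   `"selection"`, `"average"`, `"union"`, `"intersection"`.
#' @param max_iterations Intermode smoothing cap per image.
#' @return A list with `records` (named list of [eval_records()] per method),
#'   `summaries` (named list of [summarize_metrics()] tables), `selections`
#'   (per-image data.frame of chosen model and SD), and `counters`
#'   (intermode fallbacks, all-models-failed images, empty intersections).
#' @export
evaluate_images <- function(images,
                            methods = c("selection", "average", "union",
                                        "intersection"),
                            max_iterations = 10000L) {
  methods <- match.arg(methods, several.ok = TRUE)
  model_names <- names(images[[1]]$candidates$boxes)
  all_methods <- c(model_names, methods)
  preds <- lapply(stats::setNames(all_methods, all_methods),
                  function(m) list())
  gold <- list(); labels <- character()
  counters <- c(intermode_fallbacks = 0L, all_models_failed = 0L,
                empty_intersections = 0L)
  sel_rows <- list()
  for (img in images) {
    id <- img$image_id
    gold[[id]] <- img$gold
    labels[[id]] <- img$class_label
    for (m in model_names)
      preds[[m]][[id]] <- img$candidates$boxes[[m]]
    if ("selection" %in% methods) {
      thr <- withCallingHandlers(
        intermode_threshold(img$edge_map, max_iterations),
        warning = function(w) {
          counters["intermode_fallbacks"] <<- counters[["intermode_fallbacks"]] + 1L
          invokeRestart("muffleWarning")
        })
      bem <- binarize_edge_map(img$edge_map, thr)
      sel <- select_roi(img$edge_map, img$candidates, bem = bem)
      preds[["selection"]][[id]] <- sel$selected_box
      if (is.null(sel$selected_box)) {
        counters["all_models_failed"] <- counters[["all_models_failed"]] + 1L
        sel_rows[[id]] <- data.frame(image_id = id, model = NA_character_,
                                     SD = NA_real_, threshold = thr)
      } else {
        sel_rows[[id]] <- data.frame(image_id = id, model = sel$selected_model,
                                     SD = sel$scores[[sel$selected_model]]$SD,
                                     threshold = thr)
      }
    }
    for (comb in intersect(methods, c("average", "union", "intersection"))) {
      b <- combiner_by_name(comb)(img$candidates)
      if (comb == "intersection" && is.null(b) &&
          length(present_boxes(img$candidates)) > 0L)
        counters["empty_intersections"] <- counters[["empty_intersections"]] + 1L
      preds[[comb]][[id]] <- b
    }
  }
  preds <- lapply(preds, function(p) Filter(Negate(is.null), p))
  records <- lapply(preds, function(p) eval_records(gold, p, labels))
  list(records = records,
       summaries = lapply(records, summarize_metrics),
       selections = do.call(rbind, sel_rows),
       counters = counters)
}

#' Run the full file-based pipeline
#'
#' Loads edge maps, candidate boxes, gold boxes and labels from disk, applies
#' the edge-based selection and the baseline combiners, evaluates everything,
#' and writes per-image tables plus an aggregate JSON report. The run is a
#' pure function of its inputs: re-running a configuration reproduces the
#' outputs bit for bit.
#'
#' @param config A list (or YAML path, see [read_run_config()]) with:
#'   `edge_dir` (directory of `<image_id>.png`/`.tif` edge maps),
#'   `candidates` (box-table CSV/JSON), `gold` (box-table with source
#'   `"gold"`), `labels` (labels CSV), `model_order` (character vector),
#'   optional `model_input_sizes` (named list `model -> c(width, height)`
#'   to rescale each model's boxes into the edge-map frame), optional
#'   `methods`, `max_iterations`, and `out_dir`.
#' @return The [evaluate_images()] result, invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(!is.null(config$edge_dir), !is.null(config$candidates),
            !is.null(config$gold), !is.null(config$labels),
            !is.null(config$model_order))
  methods <- config$methods %||% c("selection", "average", "union",
                                   "intersection")
  max_it <- config$max_iterations %||% 10000L
  cand_df <- read_boxes(config$candidates)
  gold <- df_to_boxes(read_boxes(config$gold), "gold")
  labels <- read_labels(config$labels)
  cands <- df_to_candidates(cand_df, config$model_order)
  ids <- names(gold)
  files <- vapply(ids, function(id) {
    hits <- list.files(config$edge_dir, full.names = TRUE,
                       pattern = paste0("^", id, "\\.(png|tif|tiff)$"))
    if (length(hits)) hits[1] else NA_character_
  }, "")
  if (anyNA(files))
    stop("missing edge map for image(s): ",
         paste(ids[is.na(files)], collapse = ", "))
  images <- lapply(ids, function(id) {
    em <- read_edge_map(files[[id]])
    cs <- cands[[id]]
    if (is.null(cs))
      cs <- candidate_set(id, stats::setNames(
        vector("list", length(config$model_order)), config$model_order))
    if (!is.null(config$model_input_sizes)) {
      for (m in names(cs$boxes)) {
        sz <- config$model_input_sizes[[m]]
        if (!is.null(cs$boxes[[m]]) && !is.null(sz))
          cs$boxes[[m]] <- rescale_box(cs$boxes[[m]],
                                       image_size(sz[1], sz[2]), em$size)
      }
    }
    list(image_id = id, edge_map = em, gold = gold[[id]],
         class_label = unname(labels[[id]]), candidates = cs)
  })
  res <- evaluate_images(images, methods = methods, max_iterations = max_it)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$selections))
      utils::write.csv(res$selections,
                       file.path(config$out_dir, "selections.csv"),
                       row.names = FALSE)
    for (m in names(res$records))
      utils::write.csv(res$records[[m]],
                       file.path(config$out_dir, paste0("records_", m, ".csv")),
                       row.names = FALSE)
    report <- list(counters = as.list(res$counters),
                   summaries = res$summaries)
    jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(res))
  }
  res
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the `config` argument of
#'   [run_pipeline()].
#' @return A config list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$model_order) || anyDuplicated(cfg$model_order))
    stop("config must give a non-empty, duplicate-free model_order")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a
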