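#' Normalize a raw 8-bit edge image to an edge map
#'
#' Edge detectors emit 8-bit grayscale images whose bright pixels mark the
#' tumor boundary. The edge map used for scoring is that image divided by 255,
#' so every intensity lies in \[0, 1\].
#'
#' @param raw A numeric matrix (`values[row, col]`) of integers in 0..255.
#' @return An object of class `"edge_map"` with elements `values` (matrix in
#'   \[0, 1\]) and `size` ([image_size()]).
#' @export
normalize_edge_map <- function(raw) {
  if (!is.matrix(raw) || length(raw) == 0L)
    stop("raw edge image must be a non-empty matrix")
  if (any(!is.finite(raw)) || any(raw < 0) || any(raw > 255))
    stop("raw edge intensities must lie in [0, 255]")
  structure(list(values = raw / 255,
                 size = image_size(ncol(raw), nrow(raw))),
            class = "edge_map")
}

#' @export
print.edge_map <- function(x, ...) {
  cat(sprintf("<edge_map %dx%d, range [%.3f, %.3f]>\n", x$size$width,
              x$size$height, min(x$values), max(x$values)))
  invisible(x)
}

#' Read or write edge maps as 8-bit PNG/TIFF
#'
#' `read_edge_map()` loads a single-channel 8-bit image and normalizes it;
#' multi-channel files are accepted when the channels are identical.
#' `write_binary_edge_map()` writes a binarized map as a 0/255 PNG for
#' visual inspection.
#'
#' @param path File path; the extension picks the reader (`.png`, `.tif`,
#'   `.tiff`).
#' @return `read_edge_map()`: an `edge_map`.
#' @export
read_edge_map <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(v)) == 3L) {
    if (dim(v)[3] > 1L && any(v[, , 1] != v[, , 2]))
      warning("multi-channel edge image; using the first channel")
    v <- v[, , 1]
  }
  normalize_edge_map(round(v * 255))
}

#' @rdname read_edge_map
#' @param bem A `binary_edge_map`.
#' @export
write_binary_edge_map <- function(bem, path) {
  png::writePNG(bem$values, path)
  invisible(path)
}

# 256-bin histogram of an edge map rescaled back to 0..255
edge_histogram <- function(em) {
  bins <- floor(em$values * 255 + 0.5)
  tabulate(as.integer(bins) + 1L, nbins = 256L)
}

# strict local maxima of a histogram, zero-padded at both ends
count_modes <- function(h) {
  hp <- c(0, h, 0)
  which(hp[2:257] > hp[1:256] & hp[2:257] > hp[3:258])
}

#' Adaptive intermode threshold of an edge map
#'
#' Builds the 256-bin histogram of the edge map (rescaled to 0..255) and
#' repeatedly smooths it with a 3-bin moving average until exactly two local
#' maxima remain; the threshold is the midpoint of the two mode bins, mapped
#' back to \[0, 1\]. If the histogram never becomes bimodal within
#' `max_iterations` passes (for example a constant or strongly unimodal map),
#' the histogram mean divided by 255 is returned with a warning.
#'
#' @param em An `edge_map`.
#' @param max_iterations Cap on smoothing passes (default 10000).
#' @return A threshold in \[0, 1\].
#' @export
intermode_threshold <- function(em, max_iterations = 10000L) {
  if (!inherits(em, "edge_map")) stop("em must be an edge_map")
  h <- as.numeric(edge_histogram(em))
  for (iter in seq_len(max_iterations)) {
    modes <- count_modes(h)
    if (length(modes) == 2L)
      return(mean(modes - 1L) / 255)
    if (length(modes) < 2L) break # smoothing cannot split a unimodal histogram
    hp <- c(0, h, 0)
    h <- (hp[1:256] + hp[2:257] + hp[3:258]) / 3
  }
  fallback <- sum((0:255) * edge_histogram(em)) / sum(edge_histogram(em)) / 255
  warning(sprintf(
    "intermode thresholding did not reach bimodality; using histogram mean %.4f",
    fallback))
  fallback
}

#' Binarize an edge map at a threshold
#'
#' Pixels strictly above the threshold become 1 (high edge intensity), the
#' rest 0. The threshold is computed once per image on the full edge map, not
#' per candidate box.
#'
#' @param em An `edge_map`.
#' @param threshold A value in \[0, 1\], typically from
#'   [intermode_threshold()].
#' @return An object of class `"binary_edge_map"` with `values` (0/1 matrix),
#'   `threshold_used`, and `size`.
#' @export
binarize_edge_map <- function(em, threshold = intermode_threshold(em)) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  structure(list(values = (em$values > threshold) + 0,
                 threshold_used = threshold,
                 size = em$size),
            class = "binary_edge_map")
}

#' @export
print.binary_edge_map <- function(x, ...) {
  cat(sprintf("<binary_edge_map %dx%d, threshold %.4f, %.1f%% set>\n",
              x$size$width, x$size$height, x$threshold_used,
              100 * mean(x$values)))
  invisible(x)
}
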