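# validate an 8-bit grayscale image matrix
check_gray <- function(img) {
  if (!is.matrix(img) || length(img) == 0L)
    stop("image must be a non-empty matrix")
  if (any(!is.finite(img)) || any(img < 0) || any(img > 255))
    stop("image intensities must lie in [0, 255]")
  img
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Unsharp-mask sharpening of a grayscale image
#'
#' Returns `original + amount * (original - blurred)` where the blur is a
#' Gaussian of standard deviation `radius`, clipped back into \[0, 255\] and
#' rounded. `amount = 0` is the identity.
#'
#' @param img Numeric matrix of intensities 0..255 (`values[row, col]`).
#' @param radius Gaussian blur standard deviation in pixels (> 0).
#' @param amount Strength of the high-frequency boost (>= 0).
#' @return A matrix of the same size, intensities 0..255.
#' @export
sharpen <- function(img, radius = 2, amount = 1) {
  check_gray(img)
  if (radius <= 0) stop("radius must be > 0")
  if (amount < 0) stop("amount must be >= 0")
  if (amount == 0) return(img)
  blurred <- EBImage::gblur(img / 255, sigma = radius) * 255
  round(clip255(img + amount * (img - blurred)))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Equalizes contrast locally over a `tile` x `tile` grid of contextual
#' regions with clipping of the local histogram (CLAHE). The image is padded
#' by edge replication to a multiple of the grid and cropped back, so any
#' image size is accepted.
#'
#' @param img Numeric matrix of intensities 0..255.
#' @param clip_limit Contrast (histogram clipping) limit; higher gives more
#'   contrast.
#' @param tile Number of contextual regions per axis (>= 2).
#' @return A matrix of the same size, intensities 0..255.
#' @export
contrast_enhance <- function(img, clip_limit = 2, tile = 8) {
  check_gray(img)
  if (clip_limit <= 0) stop("clip_limit must be > 0")
  tile <- as.integer(tile)
  if (tile < 2L) stop("tile must be >= 2")
  nr <- nrow(img); nc <- ncol(img)
  # pad by edge replication to a multiple of the tile grid
  pr <- (tile - nr %% tile) %% tile
  pc <- (tile - nc %% tile) %% tile
  padded <- img[c(seq_len(nr), rep(nr, pr)), c(seq_len(nc), rep(nc, pc)),
                drop = FALSE]
  eq <- EBImage::clahe(padded / 255, nx = tile, ny = tile, limit = clip_limit)
  round(clip255(as.matrix(eq)[seq_len(nr), seq_len(nc), drop = FALSE] * 255))
}

#' Artificial RGB construction from a grayscale ultrasound image
#'
#' Stacks the original image, its sharpened version and its
#' contrast-enhanced version as the three channels of an artificial RGB
#' image, the input representation used by color-pretrained object
#' detectors. Channel 1 is always the unmodified input.
#'
#' @param img Numeric matrix of intensities 0..255.
#' @param sharpen_radius,sharpen_amount Passed to [sharpen()].
#' @param clip_limit,tile Passed to [contrast_enhance()].
#' @return An `height x width x 3` array of intensities 0..255.
#' @export
to_artificial_rgb <- function(img, sharpen_radius = 2, sharpen_amount = 1,
                              clip_limit = 2, tile = 8) {
  check_gray(img)
  out <- array(0, dim = c(nrow(img), ncol(img), 3L))
  out[, , 1] <- img
  out[, , 2] <- sharpen(img, sharpen_radius, sharpen_amount)
  out[, , 3] <- contrast_enhance(img, clip_limit, tile)
  out
}

#' Bilinear image resizing
#'
#' Resizes a grayscale matrix or a 3-channel array to the target frame,
#' e.g. to a detector's fixed input size or back to the original ultrasound
#' frame.
#'
#' @param img Matrix (`values[row, col]`) or `H x W x 3` array, 0..255.
#' @param to Target [image_size()].
#' @return The resized image, same kind as the input, intensities 0..255.
#' @export
resize_image <- function(img, to) {
  if (to$height == dim(img)[1] && to$width == dim(img)[2]) return(img)
  out <- EBImage::resize(img / 255, w = to$height, h = to$width,
                         filter = "bilinear")
  round(clip255(as.array(out) * 255))
}

#' Read and write 8-bit grayscale / RGB images
#'
#' Thin wrappers over the PNG and TIFF readers that convert between files
#' and the 0..255 matrices/arrays this package works with.
#'
#' @param path File path; extension selects the format.
#' @return `read_gray_image()`: a matrix 0..255; `write_image()` is called
#'   for its side effect.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  v <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext)
  )
  if (length(dim(v)) == 3L) v <- v[, , 1]
  round(v * 255)
}

#' @rdname read_gray_image
#' @param img Matrix or 3-channel array, 0..255.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  v <- img / 255
  switch(ext,
    png = png::writePNG(v, path),
    tif = ,
    tiff = tiff::writeTIFF(v, path, bits.per.sample = 8L),
    stop("unsupported image extension: ", ext)
  )
  invisible(path)
}
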