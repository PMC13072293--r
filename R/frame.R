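#' 8-bit RGB frame container
#'
#' An `rgb_frame` is the unit all image operations in fluopix act on: a
#' `height x width x 3` integer array of 8-bit intensities (red, green, blue
#' planes), as delivered by the surgical microscope's fluorescence mode.
#'
#' @param x A numeric array with dimensions `height x width x 3`, values in
#'   `[0, 255]`. Non-integer values are rounded.
#' @return An object of class `rgb_frame` (an integer array).
#' @examples
#' f <- rgb_frame(array(0L, c(4, 4, 3)))
#' frame_dim(f)
#' @export
rgb_frame <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("an rgb_frame needs a height x width x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("frame dimensions must be at least 1 x 1", call. = FALSE)
  if (anyNA(x) || min(x) < 0 || max(x) > 255)
    stop("intensities must lie in [0, 255] with no missing values", call. = FALSE)
  y <- array(as.integer(round(x)), dim = dim(x))
  class(y) <- c("rgb_frame", class(y))
  y
}

#' @rdname rgb_frame
#' @export
is_rgb_frame <- function(x) inherits(x, "rgb_frame")

#' @rdname rgb_frame
#' @export
frame_dim <- function(x) {
  d <- dim(x)
  c(height = d[1], width = d[2])
}

# channel name -> plane index
channel_index <- function(channel) {
  idx <- match(channel, c("red", "green", "blue"))
  if (is.na(idx)) stop("channel must be one of 'red', 'green', 'blue'", call. = FALSE)
  idx
}

#' Read and write frames and masks
#'
#' Frames are read from PNG or JPEG (the formats the microscope video export
#' produces) and always written as lossless PNG. Masks are single-channel
#' PNG images with 0 = outside, 255 = inside.
#'
#' @param path File path. The reader dispatches on the file extension
#'   (`.png`, `.jpg`, `.jpeg`).
#' @param frame An `rgb_frame`.
#' @param mask A logical matrix.
#' @return `read_frame` returns an `rgb_frame`; `read_mask` a logical matrix;
#'   the writers return `path` invisibly.
#' @export
read_frame <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop("reading JPEG requires the 'jpeg' package", call. = FALSE)
      jpeg::readJPEG(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  rgb_frame(img * 255)
}

#' @rdname read_frame
#' @export
write_frame <- function(frame, path) {
  stopifnot(is_rgb_frame(frame))
  png::writePNG(unclass(frame) / 255, path)
  invisible(path)
}

#' @rdname read_frame
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img >= 0.5
}

#' @rdname read_frame
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @export
print.rgb_frame <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_frame %d x %d, intensities %d..%d>\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}
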