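#' Raster images
#'
#' All transforms in this package operate on an H x W x 3 integer array of
#' RGB intensities in \[0, 255\] ("raster image").  `as_raster()` coerces and
#' validates such an array; `read_image()` and `write_image()` move rasters
#' between files and arrays (PNG is lossless and is the required output
#' format; JPEG-sourced arrays are accepted but value-conservation checks
#' only hold across lossless round trips).
#'
#' @param x an H x W x 3 numeric array with values in \[0, 255\].
#' @return `as_raster()` returns the validated integer array with class
#'   `xshuffle_raster` prepended.
#' @examples
#' img <- as_raster(array(0:26 %% 256, dim = c(3, 3, 3)))
#' dim(img)
#' @export
as_raster <- function(x) {
  if (is.null(dim(x)) || length(dim(x)) != 3L || dim(x)[3] != 3L)
    stop("a raster image must be an H x W x 3 array", call. = FALSE)
  if (dim(x)[1] < 1L || dim(x)[2] < 1L)
    stop("raster image dimensions must be positive", call. = FALSE)
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("raster intensities must lie in [0, 255]", call. = FALSE)
  if (any(x != round(x)))
    stop("raster intensities must be integers", call. = FALSE)
  storage.mode(x) <- "integer"
  class(x) <- unique(c("xshuffle_raster", class(x)))
  x
}

#' @rdname as_raster
#' @export
is_raster <- function(x) {
  !is.null(dim(x)) && length(dim(x)) == 3L && dim(x)[3] == 3L &&
    !anyNA(x) && all(x >= 0 & x <= 255) && all(x == round(x))
}

# Internal: stop unless x is a valid raster; returns integer array (class
# stripped so arithmetic stays plain).
check_raster <- function(x) {
  if (!is_raster(x)) x <- as_raster(x) # will raise a precise error
  storage.mode(x) <- "integer"
  unclass(x)
}

#' Read and write raster images as PNG
#'
#' @param path file path.  `read_image()` accepts any raster PNG (grayscale
#'   is expanded to three identical channels, alpha is dropped);
#'   `write_image()` always writes 8-bit RGB PNG.
#' @param img a raster image (see [as_raster()]).
#' @return `read_image()` returns a raster image; `write_image()` returns
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (is.null(dim(a))) stop("not a raster PNG: ", path, call. = FALSE)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  if (dim(a)[3] == 1L) a <- a[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(a)[3] >= 4L) a <- a[, , 1:3, drop = FALSE]
  as_raster(round(a * 255))
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  img <- check_raster(img)
  png::writePNG(img / 255, target = path)
  invisible(path)
}

# ---- row-major pixel indexing --------------------------------------------
#
# The randomness contract of every shuffle is stated over the row-major
# scan of pixel locations (left-to-right within a row, rows top to bottom),
# matching how the flattening transform is defined.  R arrays are
# column-major, so these helpers translate.

# Column-major within-channel offsets of the row-major pixel scan.
rm_index <- function(h, w) {
  k <- seq_len(h * w) - 1L
  (k %/% w + 1L) + (k %% w) * h
}

# n x 3 integer matrix of pixels in row-major order.
pixels_rm <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  matrix(img, h * w, 3L)[rm_index(h, w), , drop = FALSE]
}

# Inverse of pixels_rm: rebuild an image from a row-major pixel matrix.
image_from_pixels_rm <- function(px, h, w) {
  cm <- matrix(0L, h * w, 3L)
  cm[rm_index(h, w), ] <- px
  array(as.integer(cm), dim = c(h, w, 3L))
}

# Evaluate `code` under a fixed seed when one is supplied, restoring the
# caller's RNG state afterwards; with seed = NULL the current stream is
# consumed in place (used to compose multi-stage transforms).
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash used wherever one master seed must drive many
#' independent operations (one per stimulus, one per simulated observer).
#' Results are always in \[1, 2^31 - 2\] so they are valid `set.seed()`
#' inputs on any platform.
#'
#' @param seed master seed (single integer).
#' @param index which child stream (1, 2, ...).
#' @return an integer seed.
#' @examples
#' derive_seed(42, 1:3)
#' @export
derive_seed <- function(seed, index) {
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + as.numeric(index) * 16807
  as.integer(x %% (m - 1)) + 1L
}
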