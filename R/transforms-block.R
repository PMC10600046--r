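#' Full random pixel shuffle
#'
#' Relocates whole (R,G,B) pixels within the image.  Each of the H x W
#' pixel locations is independently selected with probability `p`; the
#' pixels at the selected locations are then rearranged by a uniform random
#' permutation over exactly those locations.  Unselected pixels stay put,
#' so `p = 0` is the identity, while `p = 1` permutes every pixel and turns
#' a natural image into noise.  The multiset of pixel values is always
#' conserved exactly.
#'
#' Randomness contract (given a seed): first H x W uniform draws in
#' row-major location order form the selection mask (`draw < p`), then one
#' `sample.int(m)` call permutes the `m` selected locations.  Identical
#' seeds give bit-identical output.
#'
#' @param img a raster image (H x W x 3 integer array, see [as_raster()]).
#' @param p shuffle probability in \[0, 1\].
#' @param seed integer seed; `NULL` consumes the current RNG stream.
#' @return a raster image of identical dimensions.
#' @examples
#' img <- make_toy_image(4, 4)
#' out <- full_random_shuffle(img, p = 1, seed = 1)
#' identical(sort(as.vector(img)), sort(as.vector(out)))
#' @export
full_random_shuffle <- function(img, p, seed = NULL) {
  img <- check_raster(img)
  check_prob(p)
  with_seed_(seed, full_random_shuffle_impl(img, p))
}

check_prob <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    stop("shuffle probability must be a single number in [0, 1]", call. = FALSE)
  invisible(p)
}

full_random_shuffle_impl <- function(img, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pixels_rm(img)
  out <- shuffle_rows_impl(px, p)
  as_raster(image_from_pixels_rm(out, h, w))
}

# Shared kernel: Bernoulli(p) selection over rows of a pixel matrix (in the
# order given), then a uniform permutation among the selected rows only.
shuffle_rows_impl <- function(px, p) {
  n <- nrow(px)
  sel <- which(stats::runif(n) < p)
  perm <- sel[sample.int(length(sel))]
  px[sel, ] <- px[perm, , drop = FALSE]
  px
}

#' Partition an image into square blocks
#'
#' Divides the image into non-overlapping `block_size` x `block_size`
#' squares, returned in row-major grid order together with the layout
#' needed for reassembly.  Both image dimensions must be divisible by
#' `block_size`; otherwise an error names the offending axis.
#'
#' @inheritParams full_random_shuffle
#' @param block_size side length of the square blocks, in pixels.
#' @return a list with `blocks` (list of raster arrays in row-major grid
#'   order) and `layout` (grid rows/cols, block size, image size).
#' @examples
#' pb <- partition_blocks(make_toy_image(4, 4), 2)
#' length(pb$blocks)
#' @export
partition_blocks <- function(img, block_size) {
  img <- check_raster(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (!is.numeric(block_size) || length(block_size) != 1L || block_size < 1 ||
      block_size != round(block_size))
    stop("block_size must be a single positive integer", call. = FALSE)
  b <- as.integer(block_size)
  if (h %% b != 0L)
    stop("image height ", h, " is not divisible by block size ", b, call. = FALSE)
  if (w %% b != 0L)
    stop("image width ", w, " is not divisible by block size ", b, call. = FALSE)
  gr <- h %/% b; gc <- w %/% b
  blocks <- vector("list", gr * gc)
  i <- 0L
  for (r in seq_len(gr)) {
    for (c in seq_len(gc)) {
      i <- i + 1L
      blocks[[i]] <- img[((r - 1L) * b + 1L):(r * b),
                         ((c - 1L) * b + 1L):(c * b), , drop = FALSE]
    }
  }
  list(blocks = blocks,
       layout = list(grid_rows = gr, grid_cols = gc, block_size = b,
                     height = h, width = w))
}

#' Reassemble blocks into an image
#'
#' Inverse of [partition_blocks()]: with unpermuted blocks,
#' `assemble_blocks(partition_blocks(img, b))` reproduces `img` exactly.
#'
#' @param blocks list of square blocks in row-major grid order.
#' @param layout the layout returned by [partition_blocks()].
#' @return a raster image.
#' @export
assemble_blocks <- function(blocks, layout) {
  gr <- layout$grid_rows; gc <- layout$grid_cols; b <- layout$block_size
  if (length(blocks) != gr * gc)
    stop("expected ", gr * gc, " blocks, got ", length(blocks), call. = FALSE)
  ok <- vapply(blocks, function(bl) identical(dim(bl)[1:2], c(b, b)), logical(1))
  if (!all(ok))
    stop("all blocks must be ", b, " x ", b, " to match the layout", call. = FALSE)
  out <- array(0L, dim = c(layout$height, layout$width, 3L))
  i <- 0L
  for (r in seq_len(gr)) {
    for (c in seq_len(gc)) {
      i <- i + 1L
      out[((r - 1L) * b + 1L):(r * b),
          ((c - 1L) * b + 1L):(c * b), ] <- blocks[[i]]
    }
  }
  as_raster(out)
}

#' Grid shuffle
#'
#' Divides the image into equal square blocks and rearranges the blocks by
#' a uniform random permutation.  Block interiors are untouched, so only
#' global structure is altered; with `block_size` equal to the image side
#' there is a single block and the transform is the identity.
#'
#' Randomness contract: one `sample.int(n_blocks)` draw permuting the
#' row-major block order.
#'
#' @inheritParams partition_blocks
#' @param seed integer seed; `NULL` consumes the current RNG stream.
#' @return a raster image.
#' @export
grid_shuffle <- function(img, block_size, seed = NULL) {
  img <- check_raster(img)
  with_seed_(seed, grid_shuffle_impl(img, block_size))
}

grid_shuffle_impl <- function(img, block_size) {
  pb <- partition_blocks(img, block_size)
  perm <- sample.int(length(pb$blocks))
  assemble_blocks(pb$blocks[perm], pb$layout)
}

#' Within-grid shuffle
#'
#' Keeps every block in place but applies [full_random_shuffle()] with
#' probability `p` independently inside each block, so no pixel ever
#' crosses a block boundary and every per-block pixel multiset is
#' conserved.  Alters only local structure.
#'
#' Randomness contract: blocks are visited in row-major grid order; each
#' block consumes a selection mask (its pixels in row-major order) followed
#' by one permutation draw, exactly as in [full_random_shuffle()].
#'
#' @inheritParams grid_shuffle
#' @param p per-pixel shuffle probability inside each block.
#' @return a raster image.
#' @export
within_grid_shuffle <- function(img, block_size, p, seed = NULL) {
  img <- check_raster(img)
  check_prob(p)
  with_seed_(seed, within_grid_shuffle_impl(img, block_size, p))
}

within_grid_shuffle_impl <- function(img, block_size, p) {
  pb <- partition_blocks(img, block_size)
  pb$blocks <- lapply(pb$blocks, full_random_shuffle_impl, p = p)
  assemble_blocks(pb$blocks, pb$layout)
}

#' Local structure shuffle
#'
#' Composition of [within_grid_shuffle()] followed by [grid_shuffle()] with
#' the same block size: pixels are shuffled inside each block, then the
#' blocks themselves are relocated, altering both local and global
#' structure.  The global pixel multiset is conserved (both stages
#' conserve it).
#'
#' Randomness contract: the within-grid stage consumes its draws first,
#' then the grid stage consumes one block-permutation draw from the same
#' stream.
#'
#' @inheritParams within_grid_shuffle
#' @return a raster image.
#' @export
local_structure_shuffle <- function(img, block_size, p, seed = NULL) {
  img <- check_raster(img)
  check_prob(p)
  with_seed_(seed, grid_shuffle_impl(within_grid_shuffle_impl(img, block_size, p),
                                     block_size))
}

#' Colour flatten
#'
#' Separates the three RGB channels and flattens each to a 1-D vector of
#' length H x W in row-major scan order, destroying all 2-D structure
#' while keeping every intensity.  [color_unflatten()] is the exact
#' inverse; [render_flattened()] produces the 2-D display rendering used
#' for human stimuli.
#'
#' @inheritParams full_random_shuffle
#' @return an object of class `flattened_channels`: a list with integer
#'   vectors `red`, `green`, `blue` and the source `height` and `width`.
#' @examples
#' fc <- color_flatten(make_toy_image(2, 2))
#' length(fc$red)
#' @export
color_flatten <- function(img) {
  img <- check_raster(img)
  px <- pixels_rm(img)
  structure(list(red = px[, 1], green = px[, 2], blue = px[, 3],
                 height = dim(img)[1], width = dim(img)[2]),
            class = "flattened_channels")
}

#' @rdname color_flatten
#' @param fc a `flattened_channels` object.
#' @param height,width target dimensions; default to those recorded in `fc`.
#' @export
color_unflatten <- function(fc, height = fc$height, width = fc$width) {
  n <- height * width
  if (length(fc$red) != n || length(fc$green) != n || length(fc$blue) != n)
    stop("channel vectors of length ", length(fc$red),
         " do not match ", height, " x ", width, " pixels", call. = FALSE)
  as_raster(image_from_pixels_rm(cbind(fc$red, fc$green, fc$blue), height, width))
}

#' @rdname color_flatten
#' @details The display rendering concatenates the red, green and blue
#'   vectors into one length 3HW sequence and reshapes it row-major into an
#'   H x W x 3 raster (channel index fastest).  It is deterministic and
#'   value-conserving, and isolated here so an alternative rendering can be
#'   swapped in without touching the flatten/unflatten pair.
#' @export
render_flattened <- function(fc) {
  v <- c(fc$red, fc$green, fc$blue)
  h <- fc$height; w <- fc$width
  # row-major (h, w, 3): v[((r-1)*w + (c-1))*3 + ch]
  k <- seq_len(h * w) - 1L
  r <- k %/% w; cc <- k %% w
  base <- (r * w + cc) * 3L
  px <- cbind(v[base + 1L], v[base + 2L], v[base + 3L])
  as_raster(image_from_pixels_rm(px, h, w))
}

#' @export
print.flattened_channels <- function(x, ...) {
  cat("<flattened_channels> ", x$height, " x ", x$width,
      " image as three row-major vectors of length ", x$height * x$width,
      "\n", sep = "")
  invisible(x)
}

#' Serialize flattened channels
#'
#' Writes the three channel vectors as a three-column CSV
#' (`red,green,blue`) plus a JSON sidecar recording the geometry
#' (`height`, `width`, `order = "row-major"`, `channels = "RGB"`), and
#' reads them back.
#'
#' @param fc a `flattened_channels` object.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.json`.
#' @return `write_flattened()` returns `path` invisibly; `read_flattened()`
#'   returns a `flattened_channels` object.
#' @export
write_flattened <- function(fc, path) {
  utils::write.csv(data.frame(red = fc$red, green = fc$green, blue = fc$blue),
                   path, row.names = FALSE)
  jsonlite::write_json(list(height = fc$height, width = fc$width,
                            order = "row-major", channels = "RGB"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_flattened
#' @export
read_flattened <- function(path) {
  d <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  structure(list(red = as.integer(d$red), green = as.integer(d$green),
                 blue = as.integer(d$blue),
                 height = meta$height, width = meta$width),
            class = "flattened_channels")
}
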