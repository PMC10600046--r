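# Straight-line reference implementations of every transform, written as
# explicit coordinate loops with no code shared with the package.  Each
# consumes random draws in the documented order (selection mask over the
# row-major pixel scan, then one permutation draw), so given the same RNG
# state it must reproduce the package output bit for bit.

oracle_coords <- function(h, w) {
  out <- vector("list", h * w); k <- 0L
  for (r in seq_len(h)) for (c in seq_len(w)) {
    k <- k + 1L
    out[[k]] <- c(r, c)
  }
  out
}

oracle_full_random <- function(img, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  co <- oracle_coords(h, w)
  u <- runif(h * w)
  sel <- which(u < p)
  perm <- sel[sample.int(length(sel))]
  out <- img
  for (i in seq_along(sel)) {
    d <- co[[sel[i]]]; s <- co[[perm[i]]]
    out[d[1], d[2], ] <- img[s[1], s[2], ]
  }
  out
}

oracle_block_list <- function(img, b) {
  h <- dim(img)[1]; w <- dim(img)[2]
  blocks <- list()
  for (br in seq_len(h / b)) for (bc in seq_len(w / b)) {
    blocks[[length(blocks) + 1L]] <-
      img[((br - 1) * b + 1):(br * b), ((bc - 1) * b + 1):(bc * b), , drop = FALSE]
  }
  blocks
}

oracle_block_paste <- function(blocks, h, w, b) {
  out <- array(0L, c(h, w, 3))
  i <- 0L
  for (br in seq_len(h / b)) for (bc in seq_len(w / b)) {
    i <- i + 1L
    out[((br - 1) * b + 1):(br * b), ((bc - 1) * b + 1):(bc * b), ] <- blocks[[i]]
  }
  out
}

oracle_grid <- function(img, b) {
  h <- dim(img)[1]; w <- dim(img)[2]
  blocks <- oracle_block_list(img, b)
  perm <- sample.int(length(blocks))
  oracle_block_paste(blocks[perm], h, w, b)
}

oracle_within_grid <- function(img, b, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  blocks <- oracle_block_list(img, b)
  for (i in seq_along(blocks)) blocks[[i]] <- oracle_full_random(blocks[[i]], p)
  oracle_block_paste(blocks, h, w, b)
}

oracle_local_structure <- function(img, b, p) {
  oracle_grid(oracle_within_grid(img, b, p), b)
}

oracle_color_flatten <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  red <- integer(0); green <- integer(0); blue <- integer(0)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    red <- c(red, img[r, c, 1])
    green <- c(green, img[r, c, 2])
    blue <- c(blue, img[r, c, 3])
  }
  list(red = red, green = green, blue = blue)
}

oracle_seg_within <- function(img, labels, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  co <- oracle_coords(h, w)
  lab_rm <- integer(h * w)
  for (i in seq_len(h * w)) lab_rm[i] <- labels[co[[i]][1], co[[i]][2]]
  out <- img
  for (l in sort(unique(lab_rm))) {
    pos <- which(lab_rm == l)
    u <- runif(length(pos))
    sel <- which(u < p)
    perm <- sel[sample.int(length(sel))]
    for (i in seq_along(sel)) {
      d <- co[[pos[sel[i]]]]; s <- co[[pos[perm[i]]]]
      out[d[1], d[2], ] <- img[s[1], s[2], ]
    }
  }
  out
}

oracle_transfer <- function(src, target) {
  m <- nrow(src)
  if (target > m) {
    extra <- sample.int(m, target - m, replace = TRUE)
    pool <- rbind(src, src[extra, , drop = FALSE])
    pool[sample.int(target), , drop = FALSE]
  } else {
    src[sample.int(m)[seq_len(target)], , drop = FALSE]
  }
}

oracle_seg_displacement <- function(img, labels) {
  h <- dim(img)[1]; w <- dim(img)[2]
  co <- oracle_coords(h, w)
  lab_rm <- integer(h * w)
  for (i in seq_len(h * w)) lab_rm[i] <- labels[co[[i]][1], co[[i]][2]]
  k <- length(unique(lab_rm))
  mapping <- sample.int(k)
  out <- img
  for (i in seq_len(k)) {
    j <- mapping[i]
    src_pos <- which(lab_rm == i)
    src <- matrix(0L, length(src_pos), 3)
    for (t in seq_along(src_pos)) src[t, ] <- img[co[[src_pos[t]]][1], co[[src_pos[t]]][2], ]
    dst_pos <- which(lab_rm == j)
    fill <- oracle_transfer(src, length(dst_pos))
    for (t in seq_along(dst_pos))
      out[co[[dst_pos[t]]][1], co[[dst_pos[t]]][2], ] <- fill[t, ]
  }
  out
}
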