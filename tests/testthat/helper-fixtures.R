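# Multiset of (R,G,B) triplets as a sorted character vector.
px_multiset <- function(img) {
  n <- prod(dim(img)[1:2])
  px <- matrix(img, n, 3)
  sort(paste(px[, 1], px[, 2], px[, 3]))
}

same_multiset <- function(a, b) identical(px_multiset(a), px_multiset(b))

# Multiset of a pixel matrix (rows are triplets).
row_multiset <- function(px) sort(paste(px[, 1], px[, 2], px[, 3]))

# Pixels of `img` at the row-major positions `idx` (n x 3 matrix).
pixels_at <- function(img, idx) {
  h <- dim(img)[1]; w <- dim(img)[2]
  k <- idx - 1L
  r <- k %/% w + 1L; c <- k %% w + 1L
  cbind(img[cbind(r, c, 1L)], img[cbind(r, c, 2L)], img[cbind(r, c, 3L)])
}

# Row-major positions of each region of a segmentation map.
region_positions <- function(seg) {
  split(seq_along(as.vector(t(seg$labels))), as.vector(t(seg$labels)))
}

# A small stack of class images sized for the full condition grid.
grid_images <- function(n, size = 160) {
  imgs <- vector("list", n); cls <- character(n)
  for (i in seq_len(n)) {
    ci <- make_class_image((i - 1) %% 10, size, size, seed = 1000 + i)
    imgs[[i]] <- ci$image; cls[i] <- ci$class
  }
  list(images = imgs, classes = cls)
}
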