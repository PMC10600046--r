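#' Segmentation maps
#'
#' The segmentation shuffles act on a per-pixel region labelling
#' ("segmentation map"), normally produced by [compute_superpixels()] but
#' equally by [make_manual_segmentation()] or any hand-built label matrix
#' via `as_segmentation()`.  Labels are stored 1-based (1..k_actual),
#' relabelled by first appearance in the row-major pixel scan; region
#' sizes always sum to H x W.
#'
#' @param labels an H x W integer matrix of region labels.
#' @param k_requested the region count originally asked for (recorded;
#'   superpixel algorithms are approximate so the realised `k_actual` may
#'   differ).
#' @param compactness recorded compactness weight, if any.
#' @return an object of class `segmentation_map`: a list with `labels`
#'   (relabelled matrix), `k_requested`, `k_actual`, `region_sizes` and
#'   `compactness`.
#' @export
as_segmentation <- function(labels, k_requested = NULL, compactness = NA_real_) {
  if (!is.matrix(labels) || anyNA(labels) || any(labels != round(labels)))
    stop("labels must be an integer matrix without missing values", call. = FALSE)
  labels_rm <- as.vector(t(labels))
  lev <- unique(labels_rm)                      # first-appearance order
  relab <- match(labels_rm, lev)
  k <- length(lev)
  lab_mat <- t(matrix(as.integer(relab), ncol(labels), nrow(labels)))
  structure(list(labels = lab_mat,
                 k_requested = if (is.null(k_requested)) k else as.integer(k_requested),
                 k_actual = k,
                 region_sizes = as.integer(tabulate(relab, k)),
                 compactness = compactness),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat("<segmentation_map> ", nrow(x$labels), " x ", ncol(x$labels),
      ", ", x$k_actual, " regions (", x$k_requested, " requested)\n", sep = "")
  invisible(x)
}

check_segmentation <- function(img, seg) {
  if (!inherits(seg, "segmentation_map"))
    stop("seg must be a segmentation_map", call. = FALSE)
  if (!identical(dim(seg$labels), dim(img)[1:2]))
    stop("segmentation map (", nrow(seg$labels), " x ", ncol(seg$labels),
         ") does not match image (", dim(img)[1], " x ", dim(img)[2], ")",
         call. = FALSE)
  invisible(seg)
}

#' SLIC superpixel segmentation
#'
#' Simple linear iterative clustering (SLIC): k-means over a joint
#' CIELAB-colour / image-plane space, initialised on a regular grid with
#' spacing S = sqrt(HW/k), seeds perturbed to the lowest-gradient position
#' in their 3 x 3 neighbourhood, assignment restricted to a 2S window
#' around each centre, followed by connectivity enforcement that merges
#' stray components smaller than S^2/4 into an adjacent region.  The
#' algorithm is fully deterministic given its inputs; `k_actual` may
#' differ from `k` because the initial grid and the merging step are
#' approximate, and a warning is emitted when fewer regions are realised
#' than requested.
#'
#' @inheritParams full_random_shuffle
#' @param k target number of regions (the study grid draws it from
#'   8, 16 or 64).
#' @param compactness weight of spatial against colour distance; larger
#'   values give squarer regions.  Default 10, the common choice for
#'   CIELAB intensities.
#' @param max_iter number of assignment/update sweeps.
#' @return a `segmentation_map` (see [as_segmentation()]).
#' @export
compute_superpixels <- function(img, k, compactness = 10, max_iter = 10,
                                seed = NULL) {
  img <- check_raster(img)
  h <- dim(img)[1]; w <- dim(img)[2]; n <- h * w
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be a single positive integer", call. = FALSE)
  if (k > n)
    stop("cannot request more regions (", k, ") than pixels (", n, ")",
         call. = FALSE)
  k <- as.integer(k)

  rgb <- matrix(img, n, 3L) / 255
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  L <- matrix(lab[, 1], h, w); A <- matrix(lab[, 2], h, w)
  B <- matrix(lab[, 3], h, w)

  S <- sqrt(n / k)
  nr <- max(1L, as.integer(round(h / S)))
  nc <- max(1L, as.integer(round(w / S)))
  cy <- (seq_len(nr) - 0.5) * h / nr
  cx <- (seq_len(nc) - 0.5) * w / nc
  centers <- cbind(y = rep(cy, each = nc), x = rep(cx, times = nr))
  centers <- round(centers)
  centers[, 1] <- pmin(pmax(centers[, 1], 1), h)
  centers[, 2] <- pmin(pmax(centers[, 2], 1), w)

  # gradient magnitude (Lab, central differences, replicated borders)
  shift <- function(M, dy, dx) {
    ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
    M[ri, ci, drop = FALSE]
  }
  grad <- (shift(L, 0, 1) - shift(L, 0, -1))^2 +
    (shift(A, 0, 1) - shift(A, 0, -1))^2 +
    (shift(B, 0, 1) - shift(B, 0, -1))^2 +
    (shift(L, 1, 0) - shift(L, -1, 0))^2 +
    (shift(A, 1, 0) - shift(A, -1, 0))^2 +
    (shift(B, 1, 0) - shift(B, -1, 0))^2

  # perturb each seed to the minimum-gradient spot in its 3x3 neighbourhood;
  # the unmoved position is listed first so ties keep the seed in place
  offs <- rbind(c(0, 0), c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  for (i in seq_len(nrow(centers))) {
    yy <- pmin(pmax(centers[i, 1] + offs[, 1], 1), h)
    xx <- pmin(pmax(centers[i, 2] + offs[, 2], 1), w)
    g <- grad[cbind(yy, xx)]
    j <- which.min(g)
    centers[i, ] <- c(yy[j], xx[j])
  }

  nk <- nrow(centers)
  cl <- L[centers]; ca <- A[centers]; cb <- B[centers]
  cyv <- centers[, 1]; cxv <- centers[, 2]
  invS2 <- (compactness / S)^2

  rowidx <- matrix(seq_len(h), h, w)
  colidx <- matrix(seq_len(w), h, w, byrow = TRUE)
  label <- matrix(1L, h, w)
  prev <- NULL

  for (iter in seq_len(max_iter)) {
    best <- matrix(Inf, h, w)
    for (i in seq_len(nk)) {
      y0 <- max(1L, as.integer(cyv[i] - 2 * S)); y1 <- min(h, as.integer(cyv[i] + 2 * S))
      x0 <- max(1L, as.integer(cxv[i] - 2 * S)); x1 <- min(w, as.integer(cxv[i] + 2 * S))
      ys <- y0:y1; xs <- x0:x1
      d <- (L[ys, xs, drop = FALSE] - cl[i])^2 +
        (A[ys, xs, drop = FALSE] - ca[i])^2 +
        (B[ys, xs, drop = FALSE] - cb[i])^2 +
        invS2 * ((rowidx[ys, xs, drop = FALSE] - cyv[i])^2 +
                   (colidx[ys, xs, drop = FALSE] - cxv[i])^2)
      upd <- d < best[ys, xs, drop = FALSE]
      best[ys, xs][upd] <- d[upd]
      label[ys, xs][upd] <- i
    }
    # update centres from their assigned pixels; empty centres are dropped
    f <- factor(label, levels = seq_len(nk))
    sizes <- tabulate(as.integer(f), nk)
    keep <- sizes > 0L
    cl <- as.numeric(tapply(as.vector(L), f, mean))[keep]
    ca <- as.numeric(tapply(as.vector(A), f, mean))[keep]
    cb <- as.numeric(tapply(as.vector(B), f, mean))[keep]
    cyv <- as.numeric(tapply(as.vector(rowidx), f, mean))[keep]
    cxv <- as.numeric(tapply(as.vector(colidx), f, mean))[keep]
    label <- matrix(match(as.vector(label), which(keep)), h, w)
    nk <- sum(keep)
    if (identical(label, prev)) break   # assignments converged
    prev <- label
  }

  label <- enforce_connectivity(label, min_size = max(1L, as.integer(S * S / 4)))
  seg <- as_segmentation(label, k_requested = k, compactness = compactness)
  if (seg$k_actual < k)
    warning("realised ", seg$k_actual, " regions for ", k, " requested",
            call. = FALSE)
  seg
}

# Merge 4-connected components smaller than min_size into an adjacent
# component.  Components are found by vectorised min-index propagation.
enforce_connectivity <- function(label, min_size) {
  h <- nrow(label); w <- ncol(label)
  for (pass in 1:5) {
    comp <- components4(label)
    sizes <- tabulate(comp, max(comp))
    small <- which(sizes < min_size)
    if (length(small) == 0L || max(comp) == 1L) break
    # adjacency between distinct components (horizontal + vertical edges)
    la <- c(comp[, -w], comp[-h, ]); lb <- c(comp[, -1], comp[-1, ])
    lab_b <- c(label[, -1], label[-1, ])
    lab_a <- c(label[, -w], label[-h, ])
    dif <- la != lb
    pairs <- rbind(cbind(la[dif], lab_b[dif]), cbind(lb[dif], lab_a[dif]))
    # first-listed neighbour label for each component
    first <- pairs[!duplicated(pairs[, 1]), , drop = FALSE]
    repl <- rep(NA_integer_, max(comp))
    repl[first[, 1]] <- first[, 2]
    idx <- comp %in% small & !is.na(repl[comp])
    if (!any(idx)) break
    label[idx] <- repl[comp[idx]]
  }
  label
}

# 4-connected components of a label matrix, as small integer component ids.
# Vectorised min-index propagation: each pixel repeatedly adopts the
# smallest component id among itself and its same-label neighbours until a
# fixed point.
components4 <- function(label) {
  h <- nrow(label); w <- ncol(label)
  same_up <- rbind(label[1, , drop = FALSE], label[-h, , drop = FALSE]) == label
  same_dn <- rbind(label[-1, , drop = FALSE], label[h, , drop = FALSE]) == label
  same_lf <- cbind(label[, 1, drop = FALSE], label[, -w, drop = FALSE]) == label
  same_rt <- cbind(label[, -1, drop = FALSE], label[, w, drop = FALSE]) == label
  comp <- matrix(seq_len(h * w), h, w)
  big <- h * w + 1L
  repeat {
    up <- rbind(comp[1, , drop = FALSE], comp[-h, , drop = FALSE]); up[!same_up] <- big
    dn <- rbind(comp[-1, , drop = FALSE], comp[h, , drop = FALSE]); dn[!same_dn] <- big
    lf <- cbind(comp[, 1, drop = FALSE], comp[, -w, drop = FALSE]); lf[!same_lf] <- big
    rt <- cbind(comp[, -1, drop = FALSE], comp[, w, drop = FALSE]); rt[!same_rt] <- big
    new <- pmin(comp, up, dn, lf, rt)
    if (identical(new, comp)) break
    comp <- new
  }
  matrix(match(as.vector(comp), sort(unique(as.vector(comp)))), h, w)
}

# Row-major pixel positions of each region, in region-label order.
region_indices_rm <- function(seg) {
  labels_rm <- as.vector(t(seg$labels))
  split(seq_along(labels_rm), labels_rm)
}

#' Segmentation within-region shuffle
#'
#' Applies the full-random-shuffle semantics independently inside each
#' region of a segmentation map: within a region, every pixel location is
#' selected with probability `p` and the selected pixels are permuted
#' among themselves.  No pixel ever crosses a region boundary, so both the
#' global and every per-region pixel multiset are conserved exactly.
#'
#' Randomness contract: regions are visited in increasing label order;
#' each consumes a selection mask over its pixels (row-major scan order)
#' then one permutation draw.
#'
#' @inheritParams full_random_shuffle
#' @param seg a `segmentation_map` matching the image dimensions.
#' @return a raster image.
#' @export
segmentation_within_shuffle <- function(img, seg, p, seed = NULL) {
  img <- check_raster(img)
  check_segmentation(img, seg)
  check_prob(p)
  with_seed_(seed, segmentation_within_shuffle_impl(img, seg, p))
}

segmentation_within_shuffle_impl <- function(img, seg, p) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pixels_rm(img)
  for (idx in region_indices_rm(seg))
    px[idx, ] <- shuffle_rows_impl(px[idx, , drop = FALSE], p)
  as_raster(image_from_pixels_rm(px, h, w))
}

#' Resample or drop pixels to fit a target region size
#'
#' The size-adaptation rule used when a region's pixels are moved into a
#' region of a different size.  If the destination is larger than the
#' source (m pixels), the deficit is filled by resampling uniformly with
#' replacement from the source and the combined pool is shuffled; if it is
#' smaller or equal, the source is shuffled and the surplus pixels are
#' dropped.  The result always has exactly `target_size` rows and every
#' value originates from the source.
#'
#' Randomness contract: for a deficit, `sample.int(m, deficit,
#' replace = TRUE)` first, then one `sample.int(target_size)` permutation;
#' for a drop, a single `sample.int(m)` permutation.
#'
#' @param source_pixels an m x 3 integer matrix of (R,G,B) rows.
#' @param target_size desired number of rows (>= 0).
#' @param seed integer seed; `NULL` consumes the current RNG stream.
#' @return a `target_size` x 3 integer matrix.
#' @export
region_transfer <- function(source_pixels, target_size, seed = NULL) {
  if (!is.matrix(source_pixels) || ncol(source_pixels) != 3L)
    stop("source_pixels must be an m x 3 matrix", call. = FALSE)
  if (target_size < 0 || target_size != round(target_size))
    stop("target_size must be a non-negative integer", call. = FALSE)
  if (nrow(source_pixels) == 0L && target_size > 0)
    stop("cannot fill ", target_size, " pixels from an empty source", call. = FALSE)
  with_seed_(seed, region_transfer_impl(source_pixels, as.integer(target_size)))
}

region_transfer_impl <- function(src, target) {
  m <- nrow(src)
  if (target > m) {
    extra <- sample.int(m, target - m, replace = TRUE)
    pool <- rbind(src, src[extra, , drop = FALSE])
    pool[sample.int(target), , drop = FALSE]
  } else {
    src[sample.int(m)[seq_len(target)], , drop = FALSE]
  }
}

#' Segmentation displacement shuffle
#'
#' Shuffles whole regions across the segmentation map: a uniform random
#' permutation assigns each source region a destination region, and the
#' destination's pixel locations (row-major scan order) are filled with
#' the source's pixels via [region_transfer()] — resampling with
#' replacement when the destination is larger, dropping surplus pixels
#' when it is smaller.  Every output region's values therefore originate
#' from exactly one input region; when all regions have equal size the
#' global pixel multiset is conserved exactly.  With a single region the
#' transform reduces to a within-region permutation of the whole image.
#'
#' Randomness contract: one `sample.int(k)` draw for the region
#' permutation, then the transfer draws for source regions in increasing
#' label order.
#'
#' @inheritParams segmentation_within_shuffle
#' @return a raster image; the drawn permutation is attached as attribute
#'   `region_mapping` (`mapping[i]` is the destination of source region
#'   `i`).
#' @export
segmentation_displacement_shuffle <- function(img, seg, seed = NULL) {
  img <- check_raster(img)
  check_segmentation(img, seg)
  with_seed_(seed, segmentation_displacement_shuffle_impl(img, seg))
}

segmentation_displacement_shuffle_impl <- function(img, seg) {
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- pixels_rm(img)
  idx <- region_indices_rm(seg)
  k <- seg$k_actual
  mapping <- sample.int(k)
  out <- px
  for (i in seq_len(k)) {
    j <- mapping[i]
    out[idx[[j]], ] <- region_transfer_impl(px[idx[[i]], , drop = FALSE],
                                            length(idx[[j]]))
  }
  res <- as_raster(image_from_pixels_rm(out, h, w))
  attr(res, "region_mapping") <- mapping
  res
}

#' Serialize a segmentation map
#'
#' Writes the label matrix as a single-channel PNG (label minus one, as an
#' 8-bit grey level; at most 256 regions) with a JSON sidecar recording
#' `k_requested`, `k_actual` and `compactness`, and reads the pair back.
#'
#' @param seg a `segmentation_map`.
#' @param path PNG path; the sidecar is `<path>.json`.
#' @return `write_segmentation()` returns `path` invisibly;
#'   `read_segmentation()` returns a `segmentation_map`.
#' @export
write_segmentation <- function(seg, path) {
  if (seg$k_actual > 256L)
    stop("PNG label serialization supports at most 256 regions", call. = FALSE)
  png::writePNG((seg$labels - 1L) / 255, target = path)
  jsonlite::write_json(list(k_requested = seg$k_requested,
                            k_actual = seg$k_actual,
                            compactness = seg$compactness),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1]
  meta <- jsonlite::read_json(paste0(path, ".json"))
  seg <- as_segmentation(matrix(as.integer(round(a * 255)) + 1L,
                                nrow(a), ncol(a)),
                         k_requested = meta$k_requested,
                         compactness = if (is.null(meta$compactness)) NA_real_
                                       else meta$compactness)
  seg
}
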