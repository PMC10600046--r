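#' Synthetic 10-class shape images
#'
#' Stand-ins for a 10-class natural-image set: each class is a distinct
#' centred shape in a distinct fill colour on a seeded speckle background,
#' so classes are separable by both contour and colour, images have
#' structure for superpixel segmentation to latch onto, and everything is
#' generated offline and deterministically.  The default 320 x 320 size is
#' divisible by all four block sizes in the condition grid.
#'
#' @param class_id class index 0..9, or one of the class names in
#'   `xshuffle_classes()`.
#' @param height,width image size; 320 x 320 satisfies every divisibility
#'   constraint in the condition grid.
#' @param seed seed for the background texture.
#' @return a list with `image` (raster) and `class` (character label).
#' @examples
#' img <- make_class_image(0, 80, 80, seed = 1)
#' img$class
#' @export
make_class_image <- function(class_id, height = 320, width = 320, seed = 1) {
  classes <- xshuffle_classes()
  if (is.character(class_id)) {
    cls <- match(class_id, classes)
    if (is.na(cls)) stop("unknown class: ", class_id, call. = FALSE)
  } else {
    if (is.na(class_id) || class_id < 0 || class_id > 9)
      stop("class_id must be in 0..9", call. = FALSE)
    cls <- as.integer(class_id) + 1L
  }
  h <- height; w <- width
  fill <- class_fills()[cls, ]

  img <- withr::with_seed(seed, {
    bg <- array(0L, dim = c(h, w, 3L))
    base <- c(40L, 60L, 50L)
    for (ch in 1:3)
      bg[, , ch] <- pmin(255L, pmax(0L, base[ch] +
        matrix(as.integer(round(stats::rnorm(h * w, 0, 18))), h, w)))
    bg
  })

  y <- matrix(seq_len(h), h, w); x <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  r <- min(h, w) * 0.3
  dy <- y - cy; dx <- x - cx
  mask <- switch(xshuffle_classes()[cls],
    disk     = dy^2 + dx^2 <= r^2,
    square   = abs(dy) <= r & abs(dx) <= r,
    triangle = dy >= -r & dy <= r & abs(dx) <= (dy + r) / 2,
    cross    = (abs(dy) <= r / 3 & abs(dx) <= r) | (abs(dx) <= r / 3 & abs(dy) <= r),
    ring     = dy^2 + dx^2 <= r^2 & dy^2 + dx^2 >= (r / 2)^2,
    diamond  = abs(dy) + abs(dx) <= r,
    hbars    = abs(dy) <= r & abs(dx) <= r & (floor((dy + r) / (r / 2)) %% 2 == 0),
    vbars    = abs(dy) <= r & abs(dx) <= r & (floor((dx + r) / (r / 2)) %% 2 == 0),
    checker  = abs(dy) <= r & abs(dx) <= r &
      ((floor((dy + r) / (r / 2)) + floor((dx + r) / (r / 2))) %% 2 == 0),
    frame    = abs(dy) <= r & abs(dx) <= r & pmax(abs(dy), abs(dx)) >= r / 2)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- fill[ch]
    img[, , ch] <- plane
  }
  list(image = as_raster(img), class = classes[cls])
}

#' @rdname make_class_image
#' @export
xshuffle_classes <- function() {
  c("disk", "square", "triangle", "cross", "ring",
    "diamond", "hbars", "vbars", "checker", "frame")
}

class_fills <- function() {
  rbind(c(220, 40, 40), c(40, 180, 60), c(50, 90, 220), c(230, 200, 40),
        c(200, 60, 200), c(40, 200, 200), c(240, 140, 30), c(150, 240, 120),
        c(240, 240, 240), c(140, 90, 50))
}

#' Toy image with pairwise-distinct pixels
#'
#' An image whose (R,G,B) triplets are all distinct, so any permutation of
#' pixels can be tracked exactly — the substrate for oracle and
#' conservation tests.  Limited to 64 pixels so distinctness fits
#' comfortably in 8-bit channels.
#'
#' @param height,width dimensions with `height * width <= 64`.
#' @return a raster image.
#' @export
make_toy_image <- function(height, width) {
  n <- height * width
  if (n > 64) stop("toy images are limited to 64 pixels", call. = FALSE)
  i <- seq_len(n) - 1L
  px <- cbind(i, 255L - 2L * i, (i * 5L) %% 256L)
  as_raster(image_from_pixels_rm(px, height, width))
}

#' Manual segmentation maps with known geometry
#'
#' Builds a segmentation map directly, bypassing the superpixel
#' algorithm, so displacement and within-region rules can be tested
#' against exactly known region sizes — including deliberately unequal
#' sizes that exercise the resample/drop rule.
#'
#' @param height,width map dimensions.
#' @param layout `"halves"` (top/bottom), `"quadrants"`, `"bands"`
#'   (`n_bands` horizontal bands), or a numeric vector of region sizes
#'   assigned to consecutive runs of the row-major pixel scan (must sum
#'   to `height * width`).
#' @param n_bands number of bands for `layout = "bands"`.
#' @return a `segmentation_map`.
#' @examples
#' make_manual_segmentation(4, 4, c(6, 10))$region_sizes
#' @export
make_manual_segmentation <- function(height, width, layout = "halves",
                                     n_bands = 4) {
  h <- height; w <- width
  if (is.numeric(layout)) {
    if (sum(layout) != h * w)
      stop("region sizes sum to ", sum(layout), ", expected ", h * w,
           call. = FALSE)
    if (any(layout < 1)) stop("region sizes must be positive", call. = FALSE)
    lab_rm <- rep(seq_along(layout), times = layout)
    labels <- matrix(lab_rm, h, w, byrow = TRUE)
  } else {
    labels <- switch(layout,
      halves = {
        if (h %% 2 != 0) stop("halves layout needs even height", call. = FALSE)
        matrix(rep(c(1L, 2L), each = h / 2 * 1L)[rep(seq_len(h), w)], h, w)
      },
      quadrants = {
        if (h %% 2 != 0 || w %% 2 != 0)
          stop("quadrants layout needs even dimensions", call. = FALSE)
        q <- matrix(0L, h, w)
        q[seq_len(h / 2), seq_len(w / 2)] <- 1L
        q[seq_len(h / 2), (w / 2 + 1):w] <- 2L
        q[(h / 2 + 1):h, seq_len(w / 2)] <- 3L
        q[(h / 2 + 1):h, (w / 2 + 1):w] <- 4L
        q
      },
      bands = {
        if (h %% n_bands != 0)
          stop("bands layout needs height divisible by n_bands", call. = FALSE)
        matrix(rep(seq_len(n_bands), each = h / n_bands)[row(matrix(0, h, w))], h, w)
      },
      stop("unknown layout: ", layout, call. = FALSE))
  }
  as_segmentation(labels, k_requested = max(labels))
}

#' Simulated observer cohorts
#'
#' `human_observer_spec()` and `network_observer_spec()` build observer
#' descriptions; [simulate_trials()] turns a list of them into a trial
#' table emulating the psychophysics design: per condition,
#' `n_trials_per_condition` Bernoulli trials at the observer's planted
#' accuracy, wrong answers uniform over the nine foil classes, and a
#' confidence report.  Human-like confidence is an affine map of the
#' planted per-condition accuracy plus Gaussian noise, rounded and clipped
#' to the 1-5 scale, so over conditions confidence tracks accuracy
#' linearly; network-like confidence is drawn independently of accuracy
#' (uniform on \[0, 1\]).  Catch trials (easy baseline items) are appended
#' at the observer's `catch_accuracy`.
#'
#' @param observer_id identifier string.
#' @param accuracy planted per-condition accuracy: scalar or vector of
#'   length `nrow(conditions)`.
#' @param conf_intercept,conf_slope,conf_noise_sd parameters of the
#'   human confidence model `round(intercept + slope * accuracy + noise)`
#'   clipped to 1..5.
#' @param catch_accuracy planted accuracy on catch trials (near 1 for an
#'   attentive observer).
#' @return an observer spec (a plain list).
#' @export
human_observer_spec <- function(observer_id, accuracy,
                                conf_intercept = 0.5, conf_slope = 4.5,
                                conf_noise_sd = 0.3, catch_accuracy = 0.98) {
  list(observer_id = observer_id, observer_type = "human",
       accuracy = accuracy, conf_model = "affine",
       conf_intercept = conf_intercept, conf_slope = conf_slope,
       conf_noise_sd = conf_noise_sd, catch_accuracy = catch_accuracy)
}

#' @rdname human_observer_spec
#' @export
network_observer_spec <- function(observer_id, accuracy,
                                  catch_accuracy = 1.0) {
  list(observer_id = observer_id, observer_type = "network",
       accuracy = accuracy, conf_model = "independent",
       catch_accuracy = catch_accuracy)
}

#' @rdname human_observer_spec
#' @param observers list of observer specs.
#' @param conditions condition grid (tibble with `condition_id`), default
#'   the full 34-condition grid.
#' @param n_trials_per_condition trials per observer per condition (the
#'   study showed 3 images per condition).
#' @param n_catch catch trials per observer.
#' @param seed master seed; each observer gets a derived child seed.
#' @param classes class label set (10 labels).
#' @return a trial tibble with columns `observer_id`, `observer_type`,
#'   `condition_id`, `true_class`, `predicted_class`, `confidence`,
#'   `response_time`, `is_catch`.
#' @export
simulate_trials <- function(observers, conditions = enumerate_all_conditions(),
                            n_trials_per_condition = 3, n_catch = 5,
                            seed = 1, classes = xshuffle_classes()) {
  if (nrow(conditions) == 0L) stop("condition list is empty", call. = FALSE)
  rows <- vector("list", length(observers))
  for (oi in seq_along(observers)) {
    ob <- observers[[oi]]
    acc <- ob$accuracy
    if (length(acc) == 1L) acc <- rep(acc, nrow(conditions))
    if (length(acc) != nrow(conditions))
      stop("accuracy vector length ", length(acc), " does not match ",
           nrow(conditions), " conditions", call. = FALSE)
    rows[[oi]] <- withr::with_seed(derive_seed(seed, oi), {
      sim_one_observer(ob, conditions$condition_id, acc,
                       n_trials_per_condition, n_catch, classes)
    })
  }
  dplyr::bind_rows(rows)
}

sim_one_observer <- function(ob, condition_ids, acc, n_per, n_catch, classes) {
  nc <- length(condition_ids)
  n_main <- nc * n_per
  cond <- rep(condition_ids, each = n_per)
  p_correct <- rep(acc, each = n_per)
  is_catch <- rep(FALSE, n_main)
  if (n_catch > 0) {
    cond <- c(cond, rep("catch", n_catch))
    p_correct <- c(p_correct, rep(ob$catch_accuracy, n_catch))
    is_catch <- c(is_catch, rep(TRUE, n_catch))
  }
  n <- length(cond)
  true_class <- sample(classes, n, replace = TRUE)
  correct <- stats::runif(n) < p_correct
  predicted <- true_class
  wrong <- which(!correct)
  for (i in wrong)
    predicted[i] <- sample(setdiff(classes, true_class[i]), 1)
  confidence <- if (identical(ob$conf_model, "affine")) {
    pmin(5, pmax(1, round(ob$conf_intercept + ob$conf_slope * p_correct +
                            stats::rnorm(n, 0, ob$conf_noise_sd))))
  } else {
    stats::runif(n)
  }
  tibble::tibble(observer_id = ob$observer_id,
                 observer_type = ob$observer_type,
                 condition_id = cond,
                 true_class = true_class,
                 predicted_class = predicted,
                 confidence = as.numeric(confidence),
                 response_time = round(stats::rlnorm(n, log(2.5), 0.4), 3),
                 is_catch = is_catch)
}
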