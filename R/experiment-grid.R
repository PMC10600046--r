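#' The experiment condition grid
#'
#' The study design spans a 3-variable transform space (block or segment
#' granularity, shuffle probability, whether units are relocated).
#' `enumerate_block_configs()` lists the 23 block-structured conditions:
#' full random shuffle at p in \{0.5, 0.8, 1.0\} (3), grid shuffle at block
#' sizes \{20, 40, 80, 160\} (4), within-grid shuffle (8) and local
#' structure shuffle (8) over those block sizes crossed with p in
#' \{0.5, 1.0\}.  `enumerate_segmentation_configs()` lists the 9 superpixel
#' conditions: displacement shuffle at k in \{8, 16, 64\} (3) and
#' within-region shuffle over those k crossed with p in \{0.5, 1.0\} (6).
#' `enumerate_all_conditions()` adds the untransformed baseline and colour
#' flatten for the full 34-condition psychophysics grid.  Ordering is
#' lexicographic by (family, granularity parameter, probability) and
#' therefore identical on every call.
#'
#' @return a tibble with columns `condition_id`, `family`, `block_size`,
#'   `n_segments`, `probability`; parameters not applicable to a family
#'   are `NA`.
#' @examples
#' nrow(enumerate_block_configs())   # 23
#' nrow(enumerate_all_conditions())  # 34
#' @export
enumerate_block_configs <- function() {
  rows <- list()
  for (p in c(0.5, 0.8, 1.0))
    rows[[length(rows) + 1L]] <- cond_row("full_random", probability = p)
  for (b in c(20L, 40L, 80L, 160L))
    rows[[length(rows) + 1L]] <- cond_row("grid", block_size = b)
  for (b in c(20L, 40L, 80L, 160L)) for (p in c(0.5, 1.0))
    rows[[length(rows) + 1L]] <- cond_row("local_structure", block_size = b,
                                          probability = p)
  for (b in c(20L, 40L, 80L, 160L)) for (p in c(0.5, 1.0))
    rows[[length(rows) + 1L]] <- cond_row("within_grid", block_size = b,
                                          probability = p)
  dplyr::bind_rows(rows)
}

#' @rdname enumerate_block_configs
#' @export
enumerate_segmentation_configs <- function() {
  rows <- list()
  for (k in c(8L, 16L, 64L))
    rows[[length(rows) + 1L]] <- cond_row("seg_displacement", n_segments = k)
  for (k in c(8L, 16L, 64L)) for (p in c(0.5, 1.0))
    rows[[length(rows) + 1L]] <- cond_row("seg_within", n_segments = k,
                                          probability = p)
  dplyr::bind_rows(rows)
}

#' @rdname enumerate_block_configs
#' @export
enumerate_all_conditions <- function() {
  out <- dplyr::bind_rows(cond_row("baseline"), cond_row("color_flatten"),
                          enumerate_block_configs(),
                          enumerate_segmentation_configs())
  param <- ifelse(is.na(out$block_size), out$n_segments, out$block_size)
  out[order(out$family, param, out$probability, method = "radix"), ]
}

cond_row <- function(family, block_size = NA_integer_, n_segments = NA_integer_,
                     probability = NA_real_) {
  tibble::tibble(condition_id = condition_id(family, block_size, n_segments,
                                             probability),
                 family = family,
                 block_size = as.integer(block_size),
                 n_segments = as.integer(n_segments),
                 probability = probability)
}

#' Condition identifiers
#'
#' `condition_id()` builds the stable string key for one transform
#' condition (e.g. `"within_grid_b040_p1.00"`, `"seg_displacement_k64"`);
#' `parse_condition_id()` inverts it.  Identifiers are deterministic in
#' the parameters, unique within the grid, and round-trip exactly.
#'
#' @param family transform family name.
#' @param block_size,n_segments,probability condition parameters (`NA`
#'   when not applicable to the family).
#' @return `condition_id()` a character scalar; `parse_condition_id()` a
#'   tibble with columns `condition_id`, `family`, `block_size`,
#'   `n_segments`, `probability`.  Unrecognised ids parse to
#'   `family = condition_id` with `NA` parameters, so externally labelled
#'   conditions (e.g. catch trials) flow through the statistics unharmed.
#' @export
condition_id <- function(family, block_size = NA, n_segments = NA,
                         probability = NA) {
  id <- family
  if (!is.na(block_size)) id <- paste0(id, sprintf("_b%03d", as.integer(block_size)))
  if (!is.na(n_segments)) id <- paste0(id, sprintf("_k%02d", as.integer(n_segments)))
  if (!is.na(probability)) id <- paste0(id, sprintf("_p%.2f", probability))
  id
}

#' @rdname condition_id
#' @param id character vector of condition ids.
#' @export
parse_condition_id <- function(id) {
  one <- function(s) {
    m <- regmatches(s, regexec(
      "^([a-z_]+?)(?:_b([0-9]{3}))?(?:_k([0-9]{2}))?(?:_p([0-9.]+))?$", s,
      perl = TRUE))[[1]]
    fams <- c("baseline", "color_flatten", "full_random", "grid",
              "local_structure", "seg_displacement", "seg_within", "within_grid")
    if (length(m) == 0L || !(m[2] %in% fams))
      return(tibble::tibble(condition_id = s, family = s,
                            block_size = NA_integer_, n_segments = NA_integer_,
                            probability = NA_real_))
    tibble::tibble(
      condition_id = s, family = m[2],
      block_size = if (nzchar(m[3])) as.integer(m[3]) else NA_integer_,
      n_segments = if (nzchar(m[4])) as.integer(m[4]) else NA_integer_,
      probability = if (nzchar(m[5])) as.numeric(m[5]) else NA_real_)
  }
  dplyr::bind_rows(lapply(id, one))
}

#' Apply one grid condition to an image
#'
#' Dispatches a condition row (one row of [enumerate_all_conditions()], or
#' anything with the same fields) to the matching transform.  The baseline
#' family returns the input unchanged; colour flatten returns a
#' `flattened_channels` object; segmentation families compute the
#' superpixel map first with [compute_superpixels()].
#'
#' @inheritParams full_random_shuffle
#' @param spec a single condition (one-row data frame or list with
#'   `family`, `block_size`, `n_segments`, `probability`).
#' @return a raster image, or a `flattened_channels` object for the
#'   colour-flatten family.
#' @export
apply_condition <- function(img, spec, seed = NULL) {
  img <- check_raster(img)
  fam <- spec$family
  switch(fam,
    baseline = as_raster(img),
    color_flatten = color_flatten(img),
    full_random = full_random_shuffle(img, spec$probability, seed = seed),
    grid = grid_shuffle(img, spec$block_size, seed = seed),
    within_grid = within_grid_shuffle(img, spec$block_size, spec$probability,
                                      seed = seed),
    local_structure = local_structure_shuffle(img, spec$block_size,
                                              spec$probability, seed = seed),
    seg_within = {
      seg <- compute_superpixels(img, spec$n_segments)
      segmentation_within_shuffle(img, seg, spec$probability, seed = seed)
    },
    seg_displacement = {
      seg <- compute_superpixels(img, spec$n_segments)
      segmentation_displacement_shuffle(img, seg, seed = seed)
    },
    stop("unknown transform family: ", fam, call. = FALSE)
  )
}

#' Build a psychophysics stimulus set
#'
#' For every condition in the grid, samples `n_per_condition` source
#' images, applies the condition with a per-stimulus seed derived from the
#' master seed, writes the stimuli as PNG files and returns (and writes)
#' the manifest.  With `unique_across_conditions = TRUE` (the study
#' design: 34 conditions x 3 images = 102 unique stimuli, no source image
#' reused anywhere) sampling is without replacement across the whole
#' grid, so at least `34 * n_per_condition` source images are required;
#' otherwise images may repeat across (but never within) conditions.
#'
#' Colour-flatten stimuli are written as the 2-D display rendering
#' ([render_flattened()]) plus a `<name>_vectors.csv` sidecar holding the
#' three channel vectors.
#'
#' @param images list of raster images.
#' @param classes character vector of true class labels, one per image.
#' @param n_per_condition stimuli per condition (the study used 3).
#' @param seed master seed; every per-stimulus seed is derived from it
#'   with [derive_seed()] and recorded in the manifest.
#' @param out_dir output directory (created if needed).
#' @param conditions condition grid; defaults to
#'   [enumerate_all_conditions()].
#' @param unique_across_conditions logical, see above.
#' @param image_ids optional character ids for the source images.
#' @return the manifest tibble (`condition_id`, `family`, `block_size`,
#'   `n_segments`, `probability`, `source_image`, `seed`, `output_path`,
#'   `true_class`), also written to `out_dir/manifest.csv`.
#' @export
build_stimulus_set <- function(images, classes, n_per_condition = 3,
                               seed = 1, out_dir,
                               conditions = enumerate_all_conditions(),
                               unique_across_conditions = TRUE,
                               image_ids = NULL) {
  stopifnot(length(images) == length(classes))
  if (is.null(image_ids))
    image_ids <- sprintf("img%03d", seq_along(images))
  ncond <- nrow(conditions)
  need <- if (unique_across_conditions) ncond * n_per_condition else n_per_condition
  if (length(images) < need)
    stop("need at least ", need, " source images, got ", length(images),
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  pick <- withr::with_seed(seed, {
    if (unique_across_conditions) {
      ord <- sample.int(length(images))[seq_len(ncond * n_per_condition)]
      matrix(ord, nrow = n_per_condition)
    } else {
      vapply(seq_len(ncond),
             function(i) sample.int(length(images), n_per_condition),
             integer(n_per_condition))
    }
  })
  pick <- matrix(pick, nrow = n_per_condition)

  rows <- vector("list", ncond * n_per_condition)
  stim <- 0L
  for (ci in seq_len(ncond)) {
    spec <- conditions[ci, ]
    for (r in seq_len(n_per_condition)) {
      stim <- stim + 1L
      src <- pick[r, ci]
      s <- derive_seed(seed, stim)
      out <- apply_condition(images[[src]], spec, seed = s)
      fname <- sprintf("%s_%s.png", spec$condition_id, image_ids[src])
      path <- file.path(out_dir, fname)
      if (inherits(out, "flattened_channels")) {
        write_image(render_flattened(out), path)
        write_flattened(out, file.path(out_dir, sub("\\.png$", "_vectors.csv", fname)))
      } else {
        write_image(out, path)
      }
      rows[[stim]] <- tibble::tibble(
        condition_id = spec$condition_id, family = spec$family,
        block_size = spec$block_size, n_segments = spec$n_segments,
        probability = spec$probability, source_image = image_ids[src],
        seed = s, output_path = fname, true_class = classes[src])
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}
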