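Package: xshuffle
Title: Extreme Image Transformations for Psychophysics and Network
    Robustness Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded, invariant-tested implementations of seven extreme
    image transformations that scramble pixel positions while conserving
    pixel values: full random shuffle, grid shuffle, within-grid shuffle,
    local structure shuffle, colour flatten, superpixel within-region
    shuffle and superpixel displacement shuffle.  Includes the full
    experiment condition grid (23 block + 9 segmentation + baseline +
    colour-flatten conditions), a psychophysics stimulus-set builder with
    manifest output, trial-table statistics (catch-trial and median
    absolute deviation participant filtering, per-condition accuracy and
    confidence, transform difficulty ranking, paired t, Pearson
    correlation, ordinary least squares), and synthetic fixtures
    (class-distinct shape images, distinct-valued toy images, manual
    segmentation maps, simulated observers) so everything runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    grDevices,
    jsonlite,
    png,
    stats,
    tibble,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
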