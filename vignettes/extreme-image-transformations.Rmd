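---
title: "Extreme image transformations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extreme image transformations: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xshuffle)
```

## The transform model

All transforms in this package relocate whole (R,G,B) pixels while
keeping every pixel value intact. This is the defining constraint:
first-order intensity statistics of the image are preserved exactly, so
any change in an observer's recognition performance must come from the
destruction of *spatial arrangement* — local texture, global shape, or
both. The transforms span a three-variable space: a granularity
parameter (square block side `b`, or superpixel count `k`), a shuffle
probability `p`, and whether units are relocated.

"Shuffled with probability p" is realised as Bernoulli(p) selection of
pixel locations followed by a uniform random permutation over exactly
the selected locations. This reading makes every probability-driven
shuffle value-conserving by construction (the permutation is a bijection
on the selected set) and gives clean limits: `p = 0` is the identity and
`p = 1` permutes every pixel. A uniform permutation may have fixed
points — a "shuffled" pixel can land on its own location. The
alternative reading (a derangement with no fixed points) would change
the expected number of moved pixels from `np - 1` to `np`; we chose the
uniform permutation because it is the simplest mechanism consistent with
a per-pixel selection probability, and the choice is isolated in one
kernel (`shuffle_rows_impl`) shared by all probability-driven shuffles,
so a derangement sampler could be swapped in at a single point.

Pixels always move as whole (R,G,B) triplets; channels are never
decoupled except by `color_flatten()`, which is a deterministic
reshaping, not a shuffle. Per-channel shuffling would be a different —
and colour-statistics-destroying — transform.

### Randomness contract

Every stochastic operation consumes draws from the R stream in a fixed,
documented order: a selection mask over the row-major pixel scan first,
then one permutation draw (`sample.int`). Blocks are visited in
row-major grid order; segmentation regions in increasing label order;
the displacement shuffle draws its region permutation before any
transfer. Fixing the order makes outputs bit-reproducible under a seed
and lets the two-stage transforms be verified compositionally: under one
seeded stream, `local_structure_shuffle()` is exactly
`within_grid_shuffle()` followed by `grid_shuffle()`, and the tests
assert this equality bit for bit, alongside equivalence with independent
straight-line reference implementations on small toys.

### Divisibility and degenerate inputs

Non-divisible image dimensions raise an error naming the offending axis
rather than padding or cropping: the canonical 320 × 320 stimulus size
is divisible by all four block sizes {20, 40, 80, 160}, and silent
padding would break the conservation invariant that the whole test
suite is built on. Degenerate limits are defined, not errors: one block
means grid shuffle is the identity; one region means displacement is a
whole-image permutation; a 1 × 1 image round-trips through flatten.

### Colour flatten rendering

The flatten itself is defined exactly (row-major scan per channel); the
2-D rendering shown to human observers is not. We render by
concatenating red‖green‖blue and reshaping row-major to H × W × 3
(channel index fastest). This is deterministic and value-conserving, and
it lives in `render_flattened()`, separate from the invertible
flatten/unflatten pair, so a different display convention can be
substituted without touching the transform.

## Superpixel segmentation

The segmentation shuffles need a SLIC-style oversegmentation.
`compute_superpixels()` implements SLIC directly: k-means over joint
CIELAB + (x, y) space, centres initialised on a regular grid with
spacing S = sqrt(HW/k), each seed perturbed to the lowest-gradient
position in its 3 × 3 neighbourhood, assignment restricted to a 2S
window per centre, ten sweeps (with early exit on convergence), and a
connectivity pass that merges 4-connected fragments smaller than S²/4
into an adjacent region. Compactness defaults to 10, the customary
weight for CIELAB intensities: lower values track colour boundaries
more tightly, higher values give squarer regions. The algorithm is
deterministic given its inputs.

Two approximations matter to users. First, the realised region count
`k_actual` can differ from the request (the initial grid rounds
`h/S × w/S`, and merging can remove regions); both numbers are recorded
on the `segmentation_map`, and a warning is emitted when fewer regions
are realised than requested. Second, labels are stored 1-based,
relabelled by first appearance in the row-major scan, which makes label
identity reproducible across runs.

### The displacement size-adaptation rule

When region i's pixels are moved into region j and the sizes differ,
the deficit (destination larger) is filled by resampling uniformly
*with replacement* from the source and shuffling the combined pool;
a surplus (destination smaller) is handled by shuffling the source and
dropping the tail. Resampling with replacement is the only reading that
works when the deficit exceeds the source size, so it is used for all
deficits. The region-to-region assignment is a uniform permutation with
fixed points allowed — "moved to another region" could be read as a
derangement, but the uniform permutation is simpler and the sampler is
one line, isolated, and swappable. Destination locations are filled in
row-major order; since the fill itself is shuffled, any fixed order is
equivalent in distribution, and fixing it buys seed-reproducibility.

## The condition grid and stimulus builder

The grid enumerates 23 block conditions (full random × p ∈
{0.5, 0.8, 1.0}; grid × b ∈ {20, 40, 80, 160}; within-grid and local
structure × those b × p ∈ {0.5, 1.0}), 9 segmentation conditions
(displacement × k ∈ {8, 16, 64}; within-region × those k × p ∈
{0.5, 1.0}), plus baseline and colour flatten: 34 in all. Condition
ordering is lexicographic by (family, granularity, probability) — no
ordering is inherent to the design, so we fix one for determinism.
Condition ids such as `within_grid_b040_p1.00` are deterministic,
unique, and parse back to their parameters.

The stimulus builder samples source images without replacement across
the whole grid by default (`unique_across_conditions = TRUE`),
reflecting a design in which 34 conditions × 3 images give 102 unique
stimuli and no source image repeats anywhere; a flag relaxes this to
reuse across (never within) conditions. Each stimulus records a child
seed derived from the master seed by a fixed integer hash
(`derive_seed()`), so the manifest alone — (source image, condition id,
seed) — regenerates every file byte for byte.

## Behavioural statistics

Participant filtering is the standard two-stage rule: drop observers
below 2/3 accuracy on catch trials (easy untransformed items), then
drop observers whose overall accuracy deviates from the cohort median
by more than 3 × MAD (consistency constant 1.4826). Both thresholds are
arguments; the defaults are the conventional robust choices. With a
zero MAD (identical observers) only non-zero deviations are excluded,
so a homogeneous cohort passes intact.

The paired t test on matched per-condition accuracies uses the
classical n − 1 degrees of freedom by default. The study convention of
quoting the statistic at 3 degrees of freedom (the number of
independent variables in the transform space) is nonstandard, so it is
supported as an explicit `df` override rather than a default. Pearson
correlation and OLS go through `cor.test()` and `lm()`; the package
adds input validation (degenerate variance is an error, not an `NA`)
and a uniform tidy return shape. Both the transform-level and the
condition-level pairing of the t test are possible: the comparison
functions accept any matched vectors, and `condition_accuracy()` /
`transform_ranking()` produce either granularity.

## What the synthetic fixtures emulate — and what they do not

`make_class_image()` produces ten classes of centred shapes in distinct
fill colours on seeded speckle backgrounds. These images give the
transforms everything they are sensitive to — divisible dimensions,
colour structure for SLIC, class-distinctive contours — while being
generated offline in milliseconds. They are *not* natural images: they
have no clutter, no pose or scale variation, and near-piecewise-constant
colour statistics, so SLIC segments them more cleanly than it would
photographs. Passing tests therefore demonstrate the correctness of the
transform machinery and statistics, not recognition difficulty of any
natural-image dataset.

`make_toy_image()` produces images whose ≤ 64 pixels are pairwise
distinct triplets, enabling exact permutation tracking; these underpin
the oracle-equivalence and conservation tests.

Simulated observers plant a per-condition accuracy vector. Correctness
is Bernoulli at the planted rate with errors uniform over the nine foil
classes. Human-like confidence is `round(0.5 + 4.5·accuracy + ε)`,
ε ~ N(0, 0.3), clipped to the 1–5 scale — an affine confidence–accuracy
map with modest noise, which at 34 conditions yields correlations near
0.99, matching the qualitative human pattern; network-like confidence
is uniform on [0, 1], independent of accuracy, yielding correlations
scattered around zero with sampling spread ≈ 1/√33 ≈ 0.17 at 34
conditions. The planted accuracy profiles used in the examples (a
linear spread 0.05–0.95 across conditions for the correlation analyses;
eight distinct family means for ranking recovery) are choices of
convenience with wide separation relative to binomial noise, not
estimates of any empirical difficulty.

## Problem sizes and numerical notes

The test suite works mostly on 4 × 4 distinct-pixel toys (where
invariants are exact and enumerable) with a smaller number of full
320 × 320 runs exercising the production path; the stimulus-builder
tests use 160 × 160 images, the smallest size divisible by all four
block sizes, and the acceptance script builds the full 102-stimulus set
at 320 × 320. Ranking recovery uses 1 000 trials per condition, at
which point binomial noise (≤ 0.016 SD) is far below the planted
family-mean gaps (≥ 0.05) and Kendall's tau reaches exactly 1.
Monte-Carlo distributional checks (permutation uniformity over the 24
arrangements of a 2 × 2 toy; subset uniformity over the C(5,3) drops)
run a few thousand fixed seeds and test within 3–3.5 standard errors.

Known limitations: SLIC here is a faithful but plain-R implementation —
adequate for 320 × 320 stimuli (seconds per image), not tuned for bulk
dataset generation; the displacement shuffle does not conserve the
global pixel multiset when regions are unequal (by design — the
resample/drop rule changes counts); and JPEG input survives I/O but
breaks conservation testing, so PNG is the required stimulus format.
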