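---
title: "Quantifying tumor-map heterogeneity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-map heterogeneity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Multiplex immunofluorescence "tumor mapping" images one tissue section
several times — once per stain, on a monochrome camera — and assembles the
fields of view into a whole-section montage at sub-micrometre resolution
(0.75 µm/px by default here). Each metastatic lesion in the section then
becomes a region of interest (ROI), and the questions are quantitative: how
is marker staining distributed within each lesion, how different are lesions
from one another (inter-metastatic heterogeneity) and within themselves
(intra-tumoral heterogeneity), how cellular is each lesion, and how close is
each lesion's tissue to its vasculature.

`tumormapr` implements that pipeline end to end: raster IO and montage
assembly, channel alignment, nuclei and vessel segmentation, per-ROI
metrics, and rank-based heterogeneity statistics — plus a synthetic section
generator with retained ground truth, because section images of this kind
are rarely publishable alongside the analysis.

## Per-ROI metrics

**Intensity histograms.** For a ROI of area `A` px the histogram bin at
level `v` is `100 · #{pixels = v} / A`, so bins sum to 100 exactly and the
histogram-weighted mean equals the direct pixel mean to numerical precision
(both identities are asserted in the tests at 1e-9). Artifact pixels carry
label −1 and are excluded from every area normalization — they are *removed*
tissue, not background.

**Heat maps.** Pixels of a marker channel are classified weak / moderate /
strong by two cutpoints. The cutpoints default to equal thirds of the 8-bit
range (85, 170) — a neutral choice, since published pseudocolor figures of
this kind rarely state their binning — and are configurable and echoed into
every output so a rendering is reproducible from its manifest.

**Cellularity** is the percent of ROI area covered by the nuclei mask
(thresholded nuclear channel, 8-connected particles of at least
`min_object_px` pixels) together with the mean nuclear intensity over the
ROI.

**Vascular density** is the mean Euclidean distance from each ROI pixel to
the nearest CD31-positive pixel *anywhere in the section*. The search is
deliberately not restricted to the ROI: a lesion sitting next to organ
vasculature is well-perfused, and restricting the search would make
undefined values common in small lesions. The distance transform is exact
(it is validated against brute-force all-pairs averaging to 1e-9), and
`min_object_px = 1` recovers a raw positive-pixel reading where object-level
filtering is not wanted. A section with no CD31-positive pixel yields a
flagged undefined density — flags propagate to the profile table and
downstream statistics exclude (and count) flagged lesions; nothing is
imputed.

## Heterogeneity statistics

The Kruskal–Wallis statistic is computed from pooled mid-ranks with the tie
correction `C = 1 − Σ(t³ − t)/(N³ − N)`; the p-value uses the χ² upper tail
on k − 1 df. The χ² approximation is the only mode offered — per-lesion
pixel samples here number in the thousands, where exact permutation is both
infeasible and unnecessary. Two degenerate cases are defined rather than
fatal: an all-ties pooled sample returns H = 0, p = 1 with a
`"degenerate: all ties"` flag, and empty/undersized group structures are
rejected with errors. The implementation is cross-checked in the tests
against `stats::kruskal.test` on tied data, against a hand-ranked two-group
value, and by a 2000-replicate null simulation whose rejection rate must sit
in [0.04, 0.06] at α = 0.05.

Pixel samples entering the test are capped at 10⁴ per lesion by seeded
subsampling without replacement. The cap bounds runtime, and it also guards
against the practical degeneracy of rank tests fed millions of pixels, where
trivial effect sizes reach arbitrarily small p-values; the full-sample mode
remains available by raising `subsample_n_max`. Per-lesion subsample seeds
derive deterministically from the run seed plus the region id, so a rerun of
the same config is byte-identical. No multiple-testing correction is
applied: the pipeline reports single per-section tests, and says so in its
outputs rather than silently adjusting.

Boxplot summaries use type-7 (linear-interpolation) quartiles and 1.5·IQR
whiskers clamped to the most extreme observations inside the fences. The
report stage draws boxplot figures *from the summary table*, not from raw
values, so figure and table cannot disagree. The vascular-density vs
expression relationship is summarized by Spearman's ρ on mid-ranks with the
t-approximation p-value.

## Segmentation choices

- **8-connectivity everywhere.** Connectivity conventions are rarely stated
  in imaging methods; 8-connectivity is the more permissive choice for
  blob-like nuclei and vessel cross-sections, and is used consistently for
  particles, objects and lesion components (labelling is validated against a
  flood-fill oracle).
- **Otsu's method** is the default auto-threshold; a constant channel makes
  the histogram degenerate and raises an error asking for an explicit
  threshold rather than guessing.
- **Lesion proposal** closes the nuclei mask with a disk (default radius
  10 px — of the order of one cell diameter at 0.75 µm/px, enough to bridge
  touching nuclei), fills holes, and keeps 8-connected components of at
  least `min_lesion_px` (default 500 px ≈ a 280 µm² tissue fragment —
  smaller clusters are not meaningfully "lesions" at this resolution). Ids
  are assigned by decreasing area with a first-pixel tie-break, making
  labels deterministic.
- **Manual override.** Automated proposal stands in for expert screening but
  is not claimed to reproduce it; the pipeline accepts a manual label image
  that either *replaces* the proposal (`roi_source: "manual"`, the default
  when a mask is supplied, matching fully manual outlining) or *overrides it
  locally* (`"manual_over_auto"`), with −1 marking excluded artifacts.

## Channel alignment

Stains imaged sequentially on one physical section differ essentially by
translation, so registration searches integer (row, col) shifts only —
rotation, scaling and subpixel refinement are out of scope. The zero-mean
normalized cross-correlation is evaluated exhaustively over a ±`max_shift`
window (default 20 px), on the overlap region of each candidate shift.
Exhaustive search is exact and deterministic; candidates are ordered by
|Δr| + |Δc| so exact ties resolve to the smallest shift, with (0, 0) first.
Zero-variance (featureless) channels cannot be correlated and resolve to
(0, 0) with a `degenerate_correlation` flag; a best shift on the window
boundary is flagged, since the true shift may lie outside. Simulated
channels are born aligned, so the pipeline leaves alignment off unless the
config enables it.

## The synthetic generator: what it does and does not emulate

The generator renders, per channel, a noiseless "scene" and then applies
additive Gaussian camera noise, clips to [0, 255] and rounds to integers
(8-bit quantization). Within one channel overlapping objects composite by
maximum; channels are rendered independently.

- **Lesions** are non-overlapping disks (an error names any intersecting
  pair). Real lesions are irregular, but no implemented statistic depends on
  lesion shape. Each lesion carries channel-specific mean intensities — the
  ground truth for inter-metastatic heterogeneity — and an optional radial
  gradient, `mean + g·(1 − 2d/R)` (center high, rim low), for intra-tumoral
  heterogeneity. The ground-truth table records the *spatial average* of the
  noiseless scene, which is what an unbiased analysis should recover.
- **Nuclei** are filled disks of uniform random radius 2–4 px at
  Poisson-placed centers, dense inside lesions (per-lesion
  `nuclei_density`, in expected nuclei per 100×100 px) and sparse outside
  (`background_nuclei_density`, default 2 — isolated stromal nuclei).
  Lesion nuclei are clipped at the lesion boundary: the nuclei belong to
  the tumor cell cluster, and clipping makes the saturating-density limit
  of the nuclei mask exactly the lesion disk. The ground-truth nuclei area
  fraction is computed from the rendered mask, so it is exact by
  construction.
- **Vessels** are disk cross-sections placed by a homogeneous spatial
  Poisson process per region (everywhere, normal tissue, or one lesion).
  Real vasculature is a branched network; the point-process model is chosen
  because it admits the closed-form mean nearest-point distance
  `E[d] = 1/(2√λ)`, giving the distance metric an analytic oracle. With
  `wrap = TRUE` the section is a torus, removing boundary effects from that
  check (the torus distance transform is computed by 3×3 tiling).
- **Not modeled:** spectral overlap and unmixing, autofluorescence
  gradients, staining batch effects, 3-D structure, and diffuse marker
  release from dying cells into surrounding tissue — background levels are
  a single per-channel mean. Passing tests therefore demonstrate correctness
  of the *measurement pipeline* under a controlled generative model, not
  robustness to every artifact of real sections.

Determinism is strict: the seed lives in the spec, generation runs in a
private RNG stream (the caller's `.Random.seed` is untouched), and identical
specs produce bit-identical channels and ground truth.

## Numerical and degenerate-input conventions

- Quantization uses `round()`; with continuous noise, exact .5 values have
  probability zero. 16-bit TIFF input is max-normalized to 8 bits with
  half-up rounding, and the rescaling is logged.
- Coordinates are (row, col) with the origin at top-left; montage blocks are
  half-open ranges; tiles may neither overlap nor blend (no overlap
  parameters exist in this acquisition style).
- Empty ROIs error; zero-lesion sections analyze to an empty profile table
  with a warning and exit success; vessel-free sections flag vascular
  density; all-ties samples return the defined degenerate KW result.

## Validation regimes and problem sizes

The test suite works at sizes chosen to make each property sharp while
keeping the whole suite quick: brute-force distance oracles on ≤32×32 masks
(200 replicates), the Poisson limit at λ ∈ {0.002, 0.01} on a 1024² torus
(where λ·area ≥ 2000 puts the Monte-Carlo error well under the 5% band),
six-lesion 448×512 sections for parameter recovery (means spanning 40–220,
noise sd 10, lesion radii ≥ 38 px), and 100-replicate null sections for
test calibration. Exact lesion-partition recovery by the automated proposal
is asserted on zero-noise sections at a saturating nuclei density of 5000
per 100×100 px — the regime where the rendered nuclei tile the lesion disk;
below roughly that density, uncovered single pixels on the convex rim of the
digital disk cannot be restored by morphological closing (closing fills
concavities, not missing extremities), and recovery is near-exact but not
pixel-perfect. Realistic densities (tens per 100×100 px) are used everywhere
recovery is measured in intensity levels rather than pixels.

## Known limitations

- Alignment is integer-shift only and exhaustive; at large `max_shift` on
  large sections it is slow by design (exactness over speed).
- The lesion proposer merges lesions closer than twice the closing radius
  and cannot separate touching lesions; the manual-ROI path is the remedy,
  as it is in practice.
- Heat-map cutpoints, segmentation thresholds and the subsampling cap are
  scientific knobs, not fitted quantities; every output records the values
  used.
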