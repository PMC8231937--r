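# tumormapr

Quantitative per-lesion analysis of multiplex immunofluorescence **tumor
maps** — whole tissue sections stained for a nuclear dye (Hoechst), tumor
markers (e.g. Her2/neu, mKate) and an endothelial marker (CD31), imaged one
stain at a time and stitched into a section-scale montage. The package is
aimed at researchers quantifying **inter-metastatic and intra-tumoral
heterogeneity** in preclinical metastasis models: how strongly does each
lesion express a marker, how does expression vary within and between lesions
and organs, and how densely is each lesion vascularized.

## What it computes

For every lesion (region of interest, ROI) of a section:

- **Intensity histogram** — the distribution of ROI pixels across intensity
  levels 0–255 as percent of total ROI pixels, and its mean.
- **Heat-map classification** — each ROI pixel labelled weak / moderate /
  strong by two configurable cutpoints (default 85, 170 — equal thirds).
- **Cellularity** — percent of ROI area covered by the thresholded,
  particle-filtered nuclei mask, plus mean nuclear intensity.
- **Vascular density** — the mean Euclidean distance d̄ from each ROI pixel
  to the nearest CD31-positive pixel (exact distance transform; larger d̄ =
  sparser vasculature), reported in px and µm (default 0.75 µm/px).

Across lesions, heterogeneity is tested with the tie-corrected
**Kruskal–Wallis** statistic

H = [ 12/(N(N+1)) · Σᵢ Rᵢ²/nᵢ − 3(N+1) ] / C,  C = 1 − Σ(t³−t)/(N³−N),

with p from the χ²_{k−1} upper tail, applied to per-lesion pixel-intensity
samples (capped at 10⁴ seeded-subsampled pixels per lesion) and to
per-lesion vascular densities grouped by organ; box-and-whisker summaries
(type-7 quartiles, 1.5·IQR whiskers) and the Spearman correlation between
vascular density and marker expression complete the statistics.

Because section images of this kind are rarely shareable, the package
includes a **synthetic tumor-map generator** with full ground truth:
disk-shaped lesions with channel-specific means and optional radial
gradients, Poisson-placed nuclei and CD31 vessel objects, additive Gaussian
noise and 8-bit quantization. For a homogeneous Poisson vessel field the
mean nearest-vessel distance has the closed form E[d] = 1/(2√λ), which the
test suite uses as an analytic oracle.

## Worked example

Simulate a six-lesion "liver" section (Her2 means 40–220, camera noise
sd 10), analyze it against the ground-truth ROI labels, and render figures:

```r
library(tumormapr)

cfg <- list(
  out_dir = "liver_run", seed = 42,
  synthetic = list(
    image_shape = c(448L, 512L), seed = 42, noise_sd = 10,
    section_id = "liver_a", organ = "liver",
    background_means = list(hoechst = 8, mkate = 5, her2 = 5, cd31 = 3),
    lesions = lapply(1:6, function(i)
      list(id = i,
           center = list(c(90,90), c(90,260), c(90,430),
                         c(300,90), c(300,260), c(300,430))[[i]],
           radius = c(45,40,42,48,38,44)[i],
           means = list(her2 = c(40,76,112,148,184,220)[i], mkate = 120),
           nuclei_density = 60)),
    vessels = list(list(rate = 0.0015, radius = 2, intensity = 200,
                        region = "everywhere"))),
  roi_source = "manual",
  manual_roi_tiff = "liver_run/masks/liver_a_truth_labels.tif",
  manual_roi_csv  = "liver_run/tables/liver_a_truth_rois.csv")

res <- tm_run_all(cfg)
res$profiles[, c("roi_id", "mean_her2", "cellularity_pct", "vascular_density_um")]
#>   roi_id mean_her2 cellularity_pct vascular_density_um
#> 1      1     39.90           17.95              10.005
#> 2      2     75.94           10.19               6.761
#> 3      3    111.92           13.00               7.353
#> 4      4    148.03           16.10               7.096
#> 5      5    183.93           11.72               7.883
#> 6      6    220.03           16.54              12.340
res$stats[, c("grouping", "k", "N", "H", "df", "p")]
#>       grouping k     N         H df      p
#> 1 pixels_mkate 6 34714     6.173  5 0.2897
#> 2  pixels_her2 6 34714 33579.721  5 0.0000
```

The recovered per-lesion Her2 means sit within a fraction of an intensity
level of the generating means (40, 76, …, 220) — the simulated
inter-metastatic heterogeneity is detected by the Kruskal–Wallis test on the
Her2 channel (p ≪ 0.05), while the mKate channel, simulated homogeneous at
mean 120, is not rejected (p ≈ 0.29). Cellularity reflects the ~60 nuclei
per 100×100 px lesion density; vascular density is the mean distance to the
nearest vessel in µm. Outputs land under `liver_run/tables`,
`liver_run/figures` (histogram overlays, boxplots, heat map,
density-vs-expression scatter) and `liver_run/masks`, with checksummed run
manifests in `liver_run/`.

The same pipeline runs from a shell via the bundled driver:

```sh
inst/cli/tumormap all -c config.yml
```

with subcommands `simulate`, `analyze`, `report`, `all`.

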