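# slicethick

Thickness morphometry for vibratome-cut tissue slices, from calibrated
cross-section images to study-level accuracy statistics.

Precision-cut slices (liver, brain, ...) are cut at a nominal vibratome
*step size*, but the hydrated slice that reaches the culture dish is
usually thicker: soft tissue deforms under the blade and swells during
equilibration. The standard way to quantify the actual thickness is to
embed the equilibrated slice in agarose, cut a cross-section, photograph
it, and measure the width of the dark tissue band. `slicethick` makes that
measurement scriptable and reproducible, and adds the statistics layer a
sectioning-accuracy study needs.

## What it computes

**Per image** — the band is thresholded (Otsu by default), oriented as
foreground, aligned so its principal axis is vertical, and measured over
*n* ≥ 3 rectangular segments. Per segment, with calibration *s* in
µm/pixel:

```
thickness = (Σ pixel values / number of pixel rows) × s
```

i.e. the mean per-row foreground width in µm. The slice summary is
mean ± SD over segments, with the coefficient of variation CV = SD/mean
and an `irregular` flag when CV > 0.25 (a quality-control warning for
highly irregular slices).

**Per study** — from slice records labelled (tissue, step size, speed):

```
thickness error (%) = (mean actual thickness − step size) / step size × 100
```

per condition, the per-tissue overall error (mean over defined
conditions), one/two-way fixed-effects ANOVA of thickness on the
sectioning factors, and Tukey HSD comparisons rendered as a compact letter
display (groups share a letter iff adjusted p ≥ 0.05).

A synthetic generator (`generate_band()`, `generate_study()`) produces
cross-section images with analytic ground truth and labelled study tables,
so every stage is testable without microscope data.

## Worked example

```r
library(slicethick)

# a synthetic cross-section: 12 px wide band at 25 deg, rough edges,
# noisy, calibrated at 8.1 um/px  (true width = 97.2 um)
b <- generate_band(band_spec(true_width = 12, length = 120, angle = 25,
                             edge_roughness = 1, noise_sd = 0.08,
                             pixel_size = 8.1, seed = 42))
measure_image(b$image)
#> Slice thickness: 97.76 +/- 1.19 um (CV 0.012, n = 3 segments)
```

The three segment values were 96.52, 98.89 and 97.88 µm — the 12-pixel
(97.2 µm) band is recovered within a fraction of a pixel, and the low CV
confirms a regular slice.

```r
# simulate a study of PFA-fixed brain: 3 step sizes x 2 speeds, 6 slices
# per cell at the bundled reference means/SDs, then analyse it
recs <- generate_study(reference_design("pfa_brain", n = 6), seed = 42)
report <- run_study(recs)
report$anova$pfa_brain
#>              term df      sumsq     meansq  statistic      p_value
#> 1       step_size  2 926957.069 463478.535 171.071827 3.946023e-17
#> 2           speed  1   6260.359   6260.359   2.310724 1.389547e-01
#> 3 step_size:speed  2   9614.758   4807.379   1.774423 1.869196e-01
#> 4       Residuals 30  81277.884   2709.263         NA           NA
report$tukey$pfa_brain
#> Tukey HSD grouping (alpha = 0.05)
#>     group n     mean letters
#>  100x0.05 6 160.7774       a
#>  200x0.05 6 204.1178       a
#>  400x0.05 6 555.6240       b
#>   100x0.2 6 213.5628       a
#>   200x0.2 6 250.1389       a
#>   400x0.2 6 535.9399       b
```

The step-size effect dominates (p ≈ 4e-17) while speed and the
interaction are non-significant — thickness depends on the step size
only, and the letter display groups the cells accordingly.

`reference_measurements()` ships the published per-condition reference
summaries (fresh porcine liver, fresh and PFA-fixed murine brain) used
for validation and as a ready-made simulation design.

## Command line

```sh
Rscript inst/scripts/slicethick.R synth band --seed 5 --out demo --width 12 --pixel-size 5
Rscript inst/scripts/slicethick.R measure demo/band_seed5.png --pixel-size 5 --out demo/measured
Rscript inst/scripts/slicethick.R synth study --seed 9 --out demo
Rscript inst/scripts/slicethick.R study demo/study_seed9.csv --out demo/report
```

Exit codes: 0 success, 1 partial failure (some images failed and were
logged), 2 fatal.

## Vignette

`vignettes/slice-thickness-methods.Rmd` documents the measurement model
and its assumptions, the numerical choices (nearest-neighbour rotation,
sample SD, segment-row normalisation), what the synthetic generator does
and does not emulate, and known limitations.
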