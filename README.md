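# punctacoloc

Quantitative image analysis for multi-channel live-cell microscopy of
punctate organelles — the kind of data produced when a fluorescent
lipid-biosensor (e.g. a GFP fusion) is imaged alongside endosomal or
lysosomal membrane markers (Rab5, Rab7, Lamp1) and the question is: *does
the probe sit on these compartments, and does it leave them when the lipid
it reports is destroyed?*

The package implements the full analysis chain for that question:

* **nMDP colocalization.** Within a whole-cell ROI, each channel's pixel
  intensities are normalized to its mean and scaled into `[-1, 1]`
  (mean → 0, brightest → 1, dimmest → −1, two-sided). The *normalized mean
  deviation product* is the pixelwise product of two such images:
  co-varying pixels score positive, anti-varying pixels negative. The
  per-cell nMDP score is the mean product over the ROI. The conventional
  display ramps positive products black → gold and negative products
  black → green, with mutually-dim pixels blacked out *after* scoring.
* **Wavelet compartment masking.** Marker-positive puncta are segmented
  per frame by an à-trous (undecimated) B3-spline wavelet decomposition:
  detail coefficients are hard-thresholded at `k` robust noise sigmas
  (noise floor estimated from the finest plane and propagated with the
  kernel's exact per-scale attenuation), and significant positive
  coefficients at the spot-bearing scale define the mask.
* **Normalized intensity time-courses.** Each probe frame is divided by
  its whole-cell ROI mean (so the cell average is exactly 1), and the mean
  normalized intensity over the compartment mask is tracked through a
  perturbation — dissociation pulls the trace toward 1, persistence leaves
  it flat.
* **Cohort statistics.** Per-cell scores are compared by one-way ANOVA
  with Tukey's multiple comparison; representative cells are chosen
  nearest the cohort median (always inside the interquartile range).
* **Synthetic scenes with ground truth.** A simulator renders cell-shaped
  ROIs filled with Gaussian puncta, programmable channel overlap, kinetic
  programs (constant / exponential dissociation / drifting persistence),
  Poisson shot noise, detector gain/offset and read noise — so every stage
  above is testable against known truth, with no microscope required.

## Worked example

```r
library(punctacoloc)

## --- colocalization panel -------------------------------------------------
scene <- scenario_coloc(seed = 11, overlap_fraction = 0.8)
img   <- render_frame(scene, 1)                     # H x W x 2 counts
a <- normalize_channel(img[, , 1], scene$cell_mask)
b <- normalize_channel(img[, , 2], scene$cell_mask)
nmdp_image(a, b, channel_pair = c("probe", "marker"))
#> <nmdp_result> probe vs marker: score 0.0985611 over 3769 ROI px

low <- scenario_coloc(seed = 11, overlap_fraction = 0.2)
im0 <- render_frame(low, 1)
nmdp_score(im0[, , 1], im0[, , 2], low$cell_mask)
#> [1] 0.04537553
```

With 80% of puncta shared between the channels the score is ~0.099; with
20% shared it falls to ~0.045 — the score tracks the programmed degree of
colocalization.

```r
## --- dissociation time-course --------------------------------------------
tl <- render_timelapse(scenario_dissociation(seed = 11))  # decay 3x -> 1x at frame 5
tc <- timecourse(tl, "probe", "marker")
percent_change(tc, event_frame = 5)
#>   probe_channel baseline  plateau percent_change
#> 1         probe 10.33291 4.235069      -59.01378
```

Before the event the probe is ~10-fold enriched at marker-positive
compartments relative to the whole cell; after the programmed dissociation
the enrichment drops by 59%. The matched `scenario_persistence()` program
(no dissociation, +5% drift) reports a small *positive* change instead —
the discriminating readout between a lipid-dependent and a
lipid-independent probe.

End to end, on a simulated cohort:

```r
cfg <- system.file("extdata", "demo_config.yaml", package = "punctacoloc")
run_pipeline(cfg, "results/demo")   # TIFFs, masks, scores, time-courses,
                                    # ANOVA/Tukey tables, plot, manifest
```

A command-line front end covering `simulate`, `nmdp`, `mask`,
`timecourse`, `stats` and `run` ships at
`system.file("cli", "punctacoloc.R", package = "punctacoloc")`.

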