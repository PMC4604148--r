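---
title: "Methods: colocalization scoring, wavelet masking and intensity time-courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colocalization scoring, wavelet masking and intensity time-courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(punctacoloc)
```

This vignette records the models, parameter choices and numerical decisions
behind `punctacoloc`, in the spirit of a methods section: what is computed,
under which assumptions, and where the genuinely open choices were made.

## The measurement problem

A fluorescent biosensor is imaged together with one or more membrane-marker
channels in living cells. Two quantitative questions recur:

1. **Colocalization** — do the biosensor and a marker decorate the same
   punctate structures? Answered per cell by a pixel-based score (nMDP)
   computed inside a whole-cell ROI.
2. **Dissociation** — when the biosensor's binding partner is acutely
   destroyed (drug addition, enzyme recruitment), does the biosensor leave
   the marker-positive compartments? Answered by tracking the mean
   whole-cell-normalized biosensor intensity over an automatically
   segmented compartment mask, frame by frame.

The whole-cell ROI is always a user input (or, here, the simulator's
ground-truth cell mask). The package deliberately does not auto-segment
cells: conflating cell segmentation with compartment masking would let
errors in one contaminate the other.

## nMDP: normalized mean deviation product

Within the ROI, each channel is normalized by its mean deviation: with ROI
mean $m$, maximum $M$ and minimum $L$, a pixel of intensity $I$ maps to

$$ v = \begin{cases} (I-m)/(M-m) & I \ge m \\ (I-m)/(m-L) & I < m \end{cases} $$

so that the mean maps to 0, the brightest pixel to exactly $+1$ and the
dimmest to exactly $-1$. The two-sided denominators are what make both
extremes hit $\pm 1$; the older one-sided convention (divide everything by
$M-m$) is available as `method = "one.sided"` for comparison but is not the
default, because only the two-sided form realizes the stated
mean/brightest/dimmest anchors on both sides. The map is monotone in $I$
and invariant to any positive affine rescaling of the raw data, so detector
gain and offset cancel (asserted to `1e-9` in the tests).

The nMDP image is the pixelwise product $v_A v_B$ of two normalized
channels; the **score** is its arithmetic mean over ROI pixels. The mean
(rather than a sum or an above-threshold mean) is the only reduction that
is comparable across cells of different sizes, and it uses *all* ROI pixels
with their signs. This is stated prominently because the reduction is a
genuine design choice: summaries restricted to above-threshold pixels exist
in the literature, but any threshold would introduce a tuning parameter
into what is otherwise a parameter-free score.

Two degenerate decisions: a channel that is constant on the ROI normalizes
to all zeros (score contribution 0, the "no information" value) instead of
erroring; pixels outside the ROI are excluded from every statistic and
carry value 0 only for display.

The display convention ramps positive products linearly black → gold
(RGB 255,215,0 at $+1$) and negative products black → green (0,255,0 at
$-1$); pixels that are *dim in both channels* (both $v<0$, hence a positive
product) are rendered black for clarity. The blanking is purely cosmetic —
the score is computed before it, and mutually-dim pixels contribute their
positive products to it.

## À-trous wavelet masking

Compartment masks are built from the marker channel by the undecimated
("à trous") B3-spline wavelet transform: $A_0$ is the image, $A_j$ is
$A_{j-1}$ convolved separably with the kernel $(1,4,6,4,1)/16$ whose taps
are spaced $2^{j-1}$ pixels apart, and the detail planes are
$W_j = A_{j-1} - A_j$. The transform reconstructs exactly
($\sum_j W_j + A_J = $ input; a telescoping identity, tested to `1e-6`
relative and verified against a dense spaced-kernel convolution oracle to
`1e-9`). Mirror padding is the default boundary; periodic padding is
available and makes the transform exactly shift-equivariant (also tested).

**Noise floor.** Coefficients are hard-thresholded at $k\,\sigma_j$ with
$k = 3$ by default. The naive estimator $\sigma_j = \mathrm{MAD}(W_j)/0.67449$
is offered (`sigma_method = "per.plane"`) but is *not* the default: at
realistic puncta densities the coarse planes are dominated by spot
responses, whose footprints cover most of the cell, so their MAD measures
signal rather than noise and the threshold inflates several-fold. The
default instead estimates the pixel noise once from the finest plane —
$\sigma_0 = \mathrm{MAD}(W_1)/0.67449/c_1$ — and propagates it as
$\sigma_j = \sigma_0 c_j$, where $c_j$ is the exact per-scale noise
attenuation (the $L_2$ norm of plane $j$'s equivalent filter, computed
from the kernel's impulse response, not hardcoded). The finest plane is the
least signal-contaminated because diffraction-limited spots put only a
minority of their energy there.

**Mask rule.** A pixel enters the mask where every selected thresholded
plane is strictly *positive*. Requiring positivity (rather than merely a
positive product of planes) matters: every bright spot is surrounded by a
ring of negative coefficients in each plane, and two negative planes would
multiply to a positive product, detecting the dark "moat" around spots as
spurious objects.

**Scale choice.** Detection defaults to scale 2 alone. Scale 1 is
noise-dominated; a diffraction-limited punctum ($\sigma \approx 1.5$ px)
puts its peak response at scale 2. Also demanding significance at scale 3
was tried and rejected: the scale-3 response of a spot a few pixels from a
neighbour is cancelled by that neighbour's negative surround, so joint
{2,3} detection misses close pairs that are plainly resolvable at scale 2.
Larger structures (swollen vacuoles) are better served by
`scales = c(2, 3)`, which remains available.

**Edge handling.** The intensity step at the cell boundary excites large
wavelet coefficients at all scales, which would be detected as a ring of
"compartment" hugging the ROI edge. When an ROI is supplied, the mask is
therefore intersected with the ROI eroded by `edge_margin` pixels
(default: the coarsest analysis scale's half-span, $2 \cdot 2^{j_{max}-1}$).
Correspondingly, the simulator places spots with a default 10 px
`edge_clearance` — organelles do not inhabit the optically thin cell
margin, so this models reality rather than evading it.

Cleanup removes 8-connected components smaller than `min_size = 4` px
(single-pixel noise survivors). Masks are boolean and pixel-aligned; no
sub-pixel contours, and no tracking of objects across frames — vesicles
split, merge and leave the focal plane, so per-frame masks are regenerated
independently at each time point.

## Normalized intensity time-courses

Each probe frame is divided by its ROI mean, recomputed per frame and per
cell, so the ROI mean of every normalized image is exactly 1 and slow
drifts (photobleaching, focus) cancel. The per-frame readout is the mean
normalized probe intensity over the marker mask: 1 means no enrichment,
values above 1 mean the probe concentrates at the compartments. Frames
whose mask is empty yield `NA` with a warning (not an error), and cohort
aggregates — mean ± s.e.m. across cells, with `sem = sd/sqrt(n)` — use
only non-missing cells, reporting `n` per point. Traces are *not* rescaled
to their $t=0$ value; the raw normalized trace is what is plotted. The
convenience `percent_change()` summary uses the mean of all pre-event
frames as baseline and the mean of the last few frames (default 3) as
plateau. For cohort plots of per-cell scores a 95% CI, where used, is the
normal approximation $\pm 1.96 \cdot$ s.e.m. — the choice is labelled, as a
$t$-based interval is equally defensible at cohort sizes around 12-30
cells.

Representative cells are selected nearest the cohort median score, with
ties to the smallest cell id. With order-statistic percentiles (type 2)
the selected score provably lies within the 25th-75th percentile band, so
the selection can never showcase an outlier; interpolated percentile
definitions do not carry that guarantee for very small cohorts, which is
why the order-statistic form is used.

## Cohort statistics

Group comparisons are classical one-way fixed-effects ANOVA followed by
Tukey's honestly-significant-difference procedure on all pairs,
Tukey-Kramer form for unequal group sizes. The implementation wraps base
R's `aov()`/`TukeyHSD()` (studentized-range tail probabilities via
`ptukey`), with the degenerate zero-variance cases pinned explicitly:
all-identical data give $F = 0,\ p = 1$; separated constants give
$F = \infty,\ p = 0$. The tests verify the two-group reduction to the
pooled-variance $t$-test, location/scale invariance, and the family-wise
error rate under the null (2000 simulated cohorts of 3 × 30 cells; the
observed rate is required to fall in $[0.04, 0.06]$ at $\alpha = 0.05$).
Significance stars follow `***` $p < 10^{-4}$, `**` $p < 10^{-3}$,
`*` $p < 0.05$.

## The synthetic-scene generator

The simulator is a first-class, tested module, and its defaults *are* the
study conditions used throughout the test-suite:

* **Geometry.** The cell is an irregular star-convex blob (low-order
  Fourier perturbation of a disc) occupying 20-60% of the frame; spots are
  isotropic 2-D Gaussians with $\sigma = 1.5$ px — diffraction-limited
  puncta at ~0.1 µm/px — whose *integrated* amplitude is specified in
  photons. Spots may overlap freely by default; a minimum separation
  (used at 6 px in the detection oracles) gives clean object-level ground
  truth.
* **Overlap.** With overlap fraction $f$ and $N$ spots, exactly
  $\mathrm{round}(fN)$ spots carry amplitude in both of the first two
  channels and the rest in exactly one (alternating); channels beyond the
  second mark every spot, as a compartment marker would.
* **Kinetics.** Per-channel multipliers per frame: constant, exponential
  decay $3 \to 1$ after an event frame (time constant 2.5 frames, i.e.
  converged within ten post-event frames), or a flat program with +5%
  linear drift. With `conserve_probe = TRUE` the flux a channel loses from
  its spots is redistributed uniformly into its cytosolic background — a
  dissociating GFP fusion relocates to the cytosol, it does not vanish.
  Conservation is off by default (so the expectation image is exactly
  background + multiplier × spots) and on in the dissociation/persistence
  scenarios, where ignoring it would overstate the apparent drop.
* **Noise.** Poisson shot noise on expected photons, then gain (counts per
  photon), offset, additive Gaussian read noise, and quantization to
  integer counts clipped to 16 bits. The default gain places the brightest
  expected pixel near a quarter of the 16-bit range. The peak-SNR
  convention used by `amplitude_for_snr()` is peak signal above background
  divided by the background noise s.d.
* **Scenario brightness.** The dissociation/persistence scenarios use 12
  probe puncta of 30000 photons (peak ≈ 20× the 100 photon/px cytosol) and
  a modest 2500-photon marker. The probe:cytosol contrast is what an
  overexpressed, strongly membrane-bound biosensor shows; the modest
  marker keeps masks compact. These values were fixed from the physics of
  the readout — the normalized compartment mean is bounded below by 1, so
  a 3×→1× enrichment decay can only register as a large fractional drop
  when the puncta dominate the local signal.

What the generator does **not** emulate: vesicle motility, splitting and
merging; z-sectioning, bleaching and stage drift; PSF structure beyond the
Gaussian spot model; heterogeneous per-spot kinetics; autofluorescence
outside the cell. Passing tests therefore demonstrate correctness of the
*analysis* under a controlled forward model, not robustness to every
property of real microscope data — in particular, real data adds motion
blur and focal loss that the per-frame masking handles only implicitly
(masks are regenerated each frame).

## Problem sizes and determinism

The test-suite runs scenes of 64-128 px squared with 10-50 spots, 10-seed
replicates for detection and monotonicity properties, and 2000-replicate
null calibration for the statistics — sizes chosen so the full suite
completes in well under a minute on one CPU while leaving each property
with clear statistical headroom. All randomness flows from explicit
integer seeds through one RNG-scoping helper; rendering a scene twice from
the same configuration is bitwise identical, and the end-to-end pipeline
writes byte-identical CSVs when re-run with the same configuration and
seed (verified by checksum in the tests).
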