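---
title: "Methods: intensity-based optical redox ratio imaging with orrpipe"
author: "orrpipe maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intensity-based optical redox ratio imaging with orrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orrpipe)
```

## The measurement model

NAD(P)H and FAD autofluorescence intensities, collected in the
440 ± 20 nm and 520 ± 20 nm bands, report on the cellular redox state
through the bounded ratio

$$\mathrm{ORR} \;=\; \frac{cFAD}{I^{NAD(P)H} + cFAD},
\qquad cFAD = I^{FAD} - \alpha\, I^{NAD(P)H},$$

computed pixel by pixel on background-subtracted summed images. The chain
of estimators the package implements, and the assumptions each one makes:

* **Z-stack summation.** The 30 planes (15 for ex vivo slices) span only
  3 µm at 0.1-µm steps and are treated as repeated scans of the same
  optical section: no inter-plane registration is attempted. Summation is
  exact integer arithmetic in a wide accumulator — 30 planes of the 16-bit
  maximum reach 1,966,050 without clipping. Because all downstream
  absolute quantities (background, validity floor) live on the summed
  scale, the number of planes is carried in the `SummedImage` metadata and
  never hard-coded.
* **Segmentation.** Objects are detected in the summed bright-field image
  only; the fluorescence channels never influence the mask, which keeps the
  redox statistics free of selection effects. A pixel is foreground iff it
  deviates from a Gaussian-weighted local mean by more than a relative
  offset, which cancels any smooth illumination field exactly (a ramp
  multiplies both the pixel and its neighbourhood mean).
* **Background.** The median over the inverse mask is insensitive to
  stray bright debris and, by construction, to anything inside objects.
  Subtraction clamps at zero: negative intensities are physically
  meaningless and would break the [0, 1] bound of the ratio.
* **Crosstalk.** The NAD(P)H → FAD-band bleed-through coefficient defaults
  to 0.39, the value calibrated on NADH-only standards over the
  physiological 0.05–0.2 mM range; `estimateCrosstalk` refits it from
  standard-curve images as a zero-intercept regression (zero fluorophore
  ⇒ zero background-subtracted signal), restricted to that range by
  default. The reverse coefficient is fixed at zero because FAD emission
  is not detectable in the 440-nm band; no symmetric unmixing exists. The
  coefficient is treated as concentration-independent within the
  restricted range — no extrapolation outside it is attempted.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `windowPx` | image width / 8, odd | px | neighbourhood of the adaptive threshold; larger than any object cross-section at 10× so the local mean tracks illumination, not objects |
| `offset` | 0.05 | fraction of local mean | rejects noise-level deviations; bright-field object contrast is far stronger |
| `polarity` | `"auto"` | — | see below |
| `minAreaUm2` | 500 | µm² | debris rejection; more than an order of magnitude below the smallest reported microtumors (~3.3 × 10⁴ µm²) |
| `connectivity` | 8 | — | diagonal adjacency joins objects, matching visual continuity of spheroid outlines |
| `keepBorderObjects` | TRUE | — | ex vivo mosaics clip many objects; exclusion is a per-analysis choice, so clipped objects are only flagged (`touches_border`) |
| `alpha` | 0.39 | fraction | reference calibration; replaced by a calibration file when supplied, and always recorded in the run log |
| `minSignal` | 1% of the 99th-percentile object-pixel total intensity | summed counts | a validity floor must exist (zero-denominator pixels); this rule rejects only essentially signal-free pixels and is provenance-logged per field |

**Auto polarity.** Bright-field contrast direction depends on focus, so the
package must guess whether objects are darker or brighter than background.
The candidate masks for both polarities are computed and the one with the
larger relative difference between foreground and background mean intensity
wins. An earlier candidate rule — pick the smaller foreground fraction —
proved fragile: adaptive thresholding surrounds every strong object with a
faint opposite-polarity halo (the local mean is pulled toward the object),
and the halo's area can rival the objects' own, letting noise decide the
comparison. Contrast separates the two candidates by an order of magnitude
and is stable across the tested cohorts.

## Redox statistics

Two per-object summaries are reported because they genuinely differ and
both are in use: the **median of pixel ORRs** (primary; robust to rim
gradients and noise) and the **overall ORR**, the ratio of object-mean
intensities $\overline{cFAD} / (\overline{I^{NAD(P)H}} +
\overline{cFAD})$. For a two-pixel object with NAD(P)H = {1, 3} and
cFAD = {1, 1}, the overall ORR is 1/3 while the mean of pixel ratios is
0.375 — the averaging order matters. For ex vivo slices, where tissue
fills the tile and no object mask exists, the per-image median over valid
pixels is the primary output, and tiles are stitched abutting (no
blending or registration) so every mosaic pixel equals its source-tile
pixel.

## Group comparison

Each group is screened with the D'Agostino–Pearson omnibus test
(implemented from the published skewness and kurtosis transforms; it
requires n ≥ 8). If **any** group fails at α = 0.05 the nonparametric
branch is taken — the parametric omnibus assumes all groups approximately
normal, so per-group gating with an any-fail rule is the conservative
reading of a per-dataset gate. The parametric branch is one-way ANOVA with
Bonferroni-adjusted pooled-SD pairwise t-tests; the nonparametric branch is
Kruskal–Wallis with Dunn's pairwise z-tests on joint ranks (tie-corrected),
Bonferroni-adjusted to mirror the parametric branch, since the post hoc
procedure is named without an adjustment. Stars map adjusted p-values as
`*` ≤ 0.05, `**` ≤ 0.01, `***` ≤ 0.005, `****` ≤ 0.001. The
ORR-versus-size regression is reported descriptively (slope, intercept,
Pearson r) with no p-value attached: it serves as a qualitative indication
of the size–ORR relation, not a hypothesis test.

## The synthetic acquisition generator

The generator is the package's ground-truth instrument: every test that
claims the pipeline "recovers" something is a closed loop against it.

What it emulates:

* the acquisition geometry — 1272.32-µm field of view, 30-plane stacks
  (15 for slices), 16-bit quantization;
* anti-aliased disk-shaped objects on darker-object bright-field contrast;
* a programmed per-pixel true ORR: the total fluorescence intensity at
  each pixel is split between the channels so that
  $cFAD/(I^{NAD(P)H}+cFAD)$ equals the programmed value exactly before
  background, crosstalk and noise are layered on — which is why, with
  noise disabled, the full pipeline inverts background + crosstalk to
  machine precision;
* per-channel additive background on the summed scale, injected NAD(P)H →
  FAD crosstalk at a known coefficient, and Poisson shot noise plus
  Gaussian read noise applied per plane **before** summation, so summation
  genuinely improves SNR as in the instrument;
* a rim of elevated ORR with a fixed physical depth (12 µm default),
  mimicking the characteristic scale of oxygen/nutrient gradients: the
  periphery of spheroids reads more oxidized than the core, and because
  the rim depth is physical rather than proportional, small objects carry
  a larger oxidized area fraction and cohorts with varying radii show the
  negative size–ORR trend.

Phenotype presets program population medians 0.21 (AsPC-1-like, spread
0.06), 0.12 (PANC-1-like, 0.12) and 0.05 (MIA PaCa-2-like, 0.02),
mirroring the reported spheroid phenotypes of the three pancreatic cancer
lines. Per-object core ORRs are drawn by stratified (jittered-quantile)
normal sampling: each simulated cohort realizes the programmed population
quantiles accurately while keeping object-to-object spread at the
programmed level, so "recovered median vs programmed median" checks test
the pipeline rather than the sampling noise of the draw. Objects are
placed with at least 10 px edge-to-edge separation, the condition under
which segmentation is expected to recover programmed counts exactly
(touching-object splitting is out of scope). At the preset radii
(≥ 50 µm) the rim is a minority of each object's area, leaving the
per-object median at the programmed core value.

What it does **not** emulate — and what passing tests therefore do not
show about real data: point-spread blur and scattering, depth-dependent
attenuation, photobleaching over the stack, saturated pixels, non-disk
morphologies, touching or overlapping objects, and autofluorescence from
debris. The simulator's noise-free path is an algebraic identity check,
not an instrument model.

## Numerical choices

* Negative intensities after background subtraction or crosstalk
  correction clamp to 0 (never negative signal).
* Pixels with total signal at or below the validity floor are invalid and
  excluded from every statistic; objects with no valid pixels carry NA
  statistics, written as empty CSV cells.
* Connected components are labelled 1..K in raster-scan order (row-major,
  origin top-left) of the first-encountered pixel, making label maps
  bit-reproducible across runs; 8-connectivity is derived from the
  4-connected labelling by merging diagonally adjacent labels.
* Heatmaps use a fixed 256-step perceptually ordered ramp over [0, 1]
  (never per-image autoscaled) with a reserved mid-grey for invalid
  pixels, so images are comparable across fields.
* The crosstalk fit is closed-form zero-intercept least squares; wells at
  concentration 0 (blanks), when present, define the per-band background
  and are excluded from the fit.
* Degenerate inputs fail loudly: empty stacks, masks covering the whole
  field (no background pixels), fewer than 3 calibration wells in range,
  zero-variance sizes in the regression, and groups smaller than the
  normality test's minimum (which instead forces the nonparametric path
  with a warning).

## Problem sizes used in the test suite

Simulated fields are 256 × 256 px (4.97 µm/px at the reference field of
view) with 8 objects per field; cohort-level checks use 9 fields per
phenotype (72 objects), calibration checks use 8 concentrations × 3
replicates, and the null-calibration of the omnibus test uses 2000
simulated three-group datasets of n = 30. These sizes were chosen so that
the closed-loop tolerances (±0.02 on recovered medians and on the refitted
crosstalk coefficient) are dominated by the pipeline's behaviour, not by
sampling noise.

## Known limitations

* Touching spheroids are not split (no watershed); the segmentation
  reports them as one object.
* The crosstalk coefficient is a single scalar per acquisition; spectral
  unmixing and concentration-dependent bleed-through are out of scope.
* Stitching is abutting placement from a layout file; there is no
  feature-based registration or overlap blending.
* ORR maps are 2D; no 3D-resolved redox volumes.
* Fluorescence-lifetime readouts are out of scope.
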