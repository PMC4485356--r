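---
title: "Quantitative MRI of disc degeneration: models, phantom and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative MRI of disc degeneration: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdqmri)
```

## The problem

Early intervertebral disc degeneration changes the biochemistry of the disc
— water and proteoglycan loss, collagen remodeling — before any structural
change is visible on conventional MRI, and the cartilage endplate zone
(CEPZ: the cartilaginous surface, bony endplate and growth plate between
disc and vertebra) is the hardest compartment to assess. Two quantitative
measures are sensitive to those changes:

* the **T2 relaxation time**, estimated per pixel from a multi-echo
  spin-echo series under the mono-exponential model
  $SI(TE) = S_0\, e^{-TE/T_2}$, which tracks water and proteoglycan
  content; and
* the **magnetization transfer ratio**,
  $\mathrm{MTR} = (M_o - M_s)/M_o$, the fractional signal drop caused by an
  off-resonance saturation pulse, which tracks macromolecular (collagen)
  content.

`ivdqmri` implements the full analysis chain for the canine annular
stab-injury degeneration model — phantom simulation, pixel-wise mapping,
a continuous-rectangle ROI profiling method for the CEPZ, and the
degeneration statistics — so that every step is reproducible and testable
against known ground truth.

## The synthetic phantom

No image data from the in-vivo study are available; what is available are
the published per-tissue summary tables. The phantom generator therefore
*defines the study conditions*: a 2D mid-sagittal slice (row 1 cephalic) of
alternating vertebral bodies and discs, each disc wrapped
anteriorly/posteriorly by the annulus fibrosus (AF) and bounded above and
below by a three-layer CEPZ band. At the default 0.25 mm isotropic spacing
the disc is 3 mm tall and the CEPZ band 0.75 mm, matching canine lumbar
proportions. `assign_ground_truth()` stamps each tissue with the published
mean T2 (ms) and MTR at one of seven timepoints (pre-operation, 1–4, 8 and
12 weeks post-injury); `jitter_sd` adds inter-subject spread as a fraction
of the published SDs.

Acquisitions follow the published protocol: 8 echoes evenly spaced over
8.5–67.9 ms (the only defensible reading of a printed range plus an echo
count), TR 1500 ms, MT offset 1100 Hz. Noise is **Rician** — two Gaussian
channels of SD $\sigma$, magnitude taken — because magnitude
reconstruction makes that the physically correct model; a plain Gaussian
option exists for oracle tests whose sampling distributions must be exact.
The default $\sigma = 20$ at a tissue $S_0$ of 1000 (SNR 50) is a
realistic 3 T spin-echo operating point; the source study does not state
its noise level, so this is the package's own choice, made once.

Two parameters are not published at all and are stated here as package
defaults, not inferences: vertebral marrow (T2 = 100 ms, MTR = 0.45) and
background (near-zero signal). The marrow T2 was chosen on two grounds:
it is a reasonable fatty-marrow value at 3 T, and it must exceed the CEPZ
T2 at every timepoint (45.6–78.5 ms) for the CEPZ to present as a profile
*trough* between vertebra and disc — which is how the curve analysis
discriminates it. A marrow T2 inside the CEPZ range would make the
trough/peak reading ill-posed in the model as well as in practice.

### Co-simulated biochemistry

Water content, uronic acid (proteoglycan assay) and hydroxyproline
(collagen assay) are drawn jointly with the tissue T2/MTR values from a
multivariate Gaussian whose means and SDs are the published per-timepoint
values and whose biochemistry-vs-qMRI cross-correlations are the published
correlation table. Two numerical points deserve note:

* **PSD structure.** With the biochemistry–biochemistry block left at
  zero, the published cross-correlations make the joint correlation matrix
  indefinite (the NP cross block alone has largest singular value ≈ 1.46).
  Rather than distorting the published couplings by projection, the
  default biochemistry block is the one *induced by a two-factor model*:
  each biochemical variable loads on the standardized (T2, MTR) pair plus
  independent noise. That matrix is positive semi-definite by construction
  and reproduces every published cross-correlation exactly. Nearest-PSD
  projection (`Matrix::nearPD`) remains as a repair path for user-supplied
  specs, with a hard error when the repair moves any entry beyond
  `repair_tol`.
* **Truncation.** Values are kept physical (water in (0, 100], assays and
  T2 non-negative, MTR in [0, 100)) by *resampling*, not clipping, so no
  point masses appear at the bounds. One published cell — AF
  hydroxyproline at 12 weeks, 1.05 ± 0.94 (an SD an order of magnitude
  larger than every neighboring cell, taken as printed) — sits only 1.1 SD
  from the zero bound, where naive resampling would inflate the mean by
  ≈ 0.23. The generator therefore solves for the latent (pre-truncation)
  mean whose truncated mean equals the target, and propagates the exact
  single-constraint conditional-mean correction to the correlated
  coordinates, so all published means are still recovered. The same
  correction is applied to the endplate scores (4-week mean 3.94 ± 2.19 is
  1.8 SD from zero). Truncation mildly attenuates correlations involving
  the corrected margin; means are exact.

Endplate scores are zero pre-operatively and truncated normals at the
dissection timepoints. They are drawn independently of the qMRI values;
the published score–T2 correlation is an observed result, not a
generator target.

## Relaxometry

The default T2 estimator is log-linear weighted least squares: regress
$\ln SI$ on $TE$ with weights $SI^2$ (the delta-method variance weighting
for log-transformed magnitude data), giving a closed-form, exactly
testable fit; `method = "nonlinear"` refines it by Levenberg–Marquardt on
the raw signal. With exactly two echoes both reduce to
$T_2 = \Delta TE / \ln(SI_1/SI_2)$. Degenerate pixels — fewer than two
positive echoes, non-decaying signal, non-finite estimates — are marked
invalid rather than raising, because in a map a bad pixel is data, not an
exception. Pixels whose first-echo signal falls below
$\max(3\hat\sigma, 1)$ are excluded; $\hat\sigma$ comes from the image
corners with the Rayleigh correction, and the absolute floor of one
signal unit catches the noise-free case where $\hat\sigma = 0$. No
spatial smoothing is applied. An `exclude_first_echo` switch exists for
reconstructions that discard the first echo of a multi-spin-echo train;
it defaults off. MTR needs no fitting: $100(M_o-M_s)/M_o$ wherever
$M_o$ clears the floor.

On Rician-noisy data the log-linear estimator is biased; the bias falls
monotonically with SNR (a property the test suite checks across a
three-point noise ladder), which is why noisy-recovery tolerances in the
tests are a few percent while noise-free recovery is exact to 1e-6.

## The continuous-rectangle ROI profiler

The measurement method chains small rectangles (1-based, half-open
`[top, bottom) x [left, right)` bounds) down the spine axis, each sharing
its bottom edge with the next rectangle's top edge, so every axial row is
covered exactly once — no tissue information is omitted or double-counted.
Default region widths at 2-px rectangle height give per-rectangle areas of
1.00, 2.375 and 0.75 mm² for the anterior, middle and posterior chains,
matching the reported ROI areas. Chains extend a few rows (`vertebra_pad`,
default 4) into the adjacent vertebrae: extrema are only defined with a
two-sided neighborhood, so the CEPZ can only register as a trough if the
chain sees vertebra on its far side — the original measurement included
the vertebrae for the same reason.

The profile value at each row is the mean of valid pixels across the
rectangle width. Tissue discrimination is *curve analysis*: plateaus of
equal value are merged; interior plateaus higher (lower) than both
neighbors are peaks (troughs); the `k` most prominent are kept, ties
broken toward the cephalic side, plateau centers reported. Boundary
plateaus are never extrema. Segmentation grows each extremum's plateau
while values stay on the extremum's side of the midpoint to the nearest
*distinct-valued* row — on noise-free phantoms this recovers the
ground-truth tissue rows exactly; on noisy profiles it degrades to a tight
neighborhood of the extremum, the "three or four values from the peak or
trough" reading. Role assignment is anatomical: on the mid-disc chain the
most prominent peak is NP and the flanking troughs are CEPZ; on the
AF chains the single most prominent trough is AF. Both maps exist for the
same slice, and assignment always uses the T2 profile (NP ordering on T2
is monotone across all timepoints; on MTR it is not), mirroring the
copy-and-paste ROI transfer between co-acquired maps.

Within each tissue's pixel pool the **subtraction threshold** removes
values below `mean − 2·SD` (sample SD, one-sided: the method subtracts
*low* outliers from surrounding tissue). The threshold is computed per
chain set by default; a per-ROI variant was considered and rejected
because single rectangles at the default sizes hold too few pixels for a
stable SD. Measurements are repeated three times with ±1 px placement
jitter (the package's stand-in for manual re-drawing, which is out of
scope) and the repeat means averaged. Summaries carry both the
across-repeat SD (placement variability; zero at zero jitter) and the
pooled within-tissue pixel SD, which is what the downstream ANOVA uses
as within-group spread.

The elliptical disc outline drawn in the original workflow is a display
aid for locating the disc and is not implemented.

## Statistics

Percent change versus pre-operation is `100·|pre − post|/pre`, rounded to
two decimals: the published changes are magnitudes whether the measure
fell (T2) or rose (MTR in NP/AF), and this definition reproduces the
published NP/AF figures exactly from the published means. One-way ANOVA
uses the classical equal-variance decomposition; pairwise pooled-t markers
are emitted only when the omnibus test is significant at α = 0.05, and are
uncorrected by default (matching plain `P < 0.05` reporting) with a
Bonferroni option. Correlations default to `auto`: Pearson when both
margins pass Shapiro–Wilk at α = 0.05, Spearman otherwise. Strength bands
on |r| are half-open — [0.80, 1.00] very strong, [0.60, 0.80) strong,
[0.40, 0.60) moderate, [0.20, 0.40) weak, [0, 0.20) none — so values such
as 0.795 that fall between printed band edges are still classified.

A caveat the package replicates rather than fixes: the study design is
repeated imaging of the same animals, but the published analysis (and
therefore `build_report()`) uses plain one-way ANOVA across timepoints,
not a mixed model.

## What the phantom does and does not show

Passing recovery tests on this phantom demonstrates that the measurement
chain is unbiased and self-consistent under its own generative model:
mono-exponential decay, a fixed per-tissue saturation fraction, piecewise
constant tissue parameters, perfect inter-map alignment and Rician noise.
Real data add partial-volume mixing at tissue boundaries, B0/B1
inhomogeneity, motion, multi-component relaxation and registration error
between acquisitions — none of which are simulated, so phantom recovery
bounds method error from below, not scanner error. Multi-slice/3D
imaging, sequence-level (Bloch) simulation, T2*, T1ρ, diffusion and
ultrashort-echo-time techniques are out of scope.

## Problem sizes and numerical choices

The default grid (110 × 50 px, three discs) keeps the full 7-timepoint
pipeline under a couple of seconds while leaving every tissue tens of
pixels wide. Test problem sizes were chosen the same way: Monte-Carlo
checks use 10⁴–10⁵ draws where a 3-standard-error bound is asserted,
correlation recovery uses n = 5000 (sampling error ≈ 0.007 for r ≈ 0.7),
the Rician-bias ladder uses 200 replicates per noise level, and the
extrema oracle enumerates all profiles over {0, 1, 2} up to length 8
(≈ 10⁴ cases) plus seeded samples of lengths 9–12. All stochastic steps
take explicit seeds; `run_pipeline()` writes a checksum manifest and
identical configs give identical checksums (images are written as
uncompressed NIfTI for exactly this reason).
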