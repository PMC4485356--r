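# ivdqmri

Quantitative MRI analysis of intervertebral disc degeneration, built around
the canine annular stab-injury model: pixel-wise T2 relaxometry and
magnetization transfer ratio (MTR) mapping, a continuous-rectangle ROI
profiling method for the cartilage endplate zone (CEPZ), and the
degeneration statistics layer — exercised end to end on a synthetic
mid-sagittal lumbar phantom whose ground truth is the published per-tissue
table values.

**Who it is for:** researchers working with quantitative MR measures of
disc and cartilage degeneration who need a reproducible, testable
implementation of the measurement chain — from raw multi-echo magnitude
stacks to percent-change / ANOVA / correlation tables — with known ground
truth to validate against.

## The models

* **T2 mapping** — per pixel, the multi-echo spin-echo signal follows the
  mono-exponential decay `SI(TE) = S0 · exp(−TE/T2)`. The default
  estimator is log-linear least squares on `ln SI` vs `TE`, weighted by
  `SI²`, with an optional Levenberg–Marquardt refinement on the raw
  signal. Eight echoes evenly spaced over 8.5–67.9 ms.
* **MTR mapping** — `MTR(%) = 100 · (Mo − Ms)/Mo`, where `Mo`/`Ms` are the
  images without/with a 1100 Hz off-resonance saturation pulse.
* **ROI profiling** — edge-sharing rectangles chained from the cephalic to
  the caudal CEPZ (through the adjacent vertebrae) yield a per-row profile
  curve; tissues are discriminated by peak/trough curve analysis (NP =
  peak, CEPZ = flanking troughs on the mid-disc chain; AF = trough on the
  anterior/posterior chains), pixels below the slice `mean − 2·SD`
  subtraction threshold are removed, and triplicate placements are
  averaged.
* **Statistics** — absolute percent change vs the pre-operative baseline,
  one-way ANOVA across timepoints with pairwise markers at α = 0.05, and
  Pearson/Spearman correlations (auto-selected by normality) classified
  into the conventional strength bands on |r|.

## Worked example

```r
library(ivdqmri)

# phantom at pre-operation, noise-free acquisition, T2 map
ph <- assign_ground_truth(build_label_map(seed = 0), "PO")
t2 <- fit_t2_map(simulate_echo_series(ph))

# continuous-rectangle chains over the central disc
chains <- sapply(c("anterior", "middle", "posterior"), function(reg)
  build_roi_chain(t2, disc_roi_spec(ph, 2, reg), reg),
  simplify = FALSE)

summarize_tissue(t2, chains, seg_map = t2, n_repeats = 3,
                 jitter_px = 1, seed = 5, timepoint = "PO")
#>   tissue timepoint kind   mean sd pixel_sd n_pixels n_repeats
#> 1     NP        PO   T2 150.78  0        0      228         3
#> 2     AF        PO   T2  28.93  0        0      168         3
#> 3   CEPZ        PO   T2  67.09  0        0      114         3
```

The three tissue means recover the generating ground truth (NP 150.78 ms,
AF 28.93 ms, CEPZ 67.09 ms) exactly: the fit is exact on noise-free decays
and the peak/trough segmentation finds the ground-truth tissue rows. The
`sd` column is the across-repeat (placement) variability — zero here
because a noise-free map is insensitive to ±1 px jitter.

Percent change against the pre-operative baseline reproduces the published
degeneration figures from the published means, e.g. the nucleus pulposus
T2 drop at 4 weeks:

```r
ref <- qmri_reference_values()
percent_change(150.78, 102.42)   # NP T2, PO -> 4W
#> [1] 32.07
percent_change(18.72, 31.27)     # NP MTR, PO -> 8W
#> [1] 67.04
```

The full workflow is scripted under `analysis/` (simulate → fit →
profile → stats), writing its tables under `results/run/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_fit_maps.R
Rscript analysis/03_profile_rois.R
Rscript analysis/04_degeneration_stats.R
```

With the default noisy conditions (Rician, SNR 50) the last stage prints,
among others, the T2 percent-change table — NP 32.74 % at 4 weeks and
50.84 % at 8 weeks in a representative run, within a few percent of the
noise-free arithmetic — and the ANOVA across timepoints (all tissues and
both maps significant). `run_pipeline()` performs the same four stages in
one call and writes a checksum manifest; identical configurations give
identical checksums.

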