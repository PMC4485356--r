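# Published tissue calibration values for the canine annular stab-injury
# degeneration model. These tables are the ground-truth targets of the
# synthetic phantom generator and the baselines of the degeneration
# statistics; they are the study conditions, not tuning knobs.

QMRI_TIMEPOINTS <- c("PO", "1W", "2W", "3W", "4W", "8W", "12W")
BIOCHEM_TIMEPOINTS <- c("PO", "4W", "8W", "12W")
QMRI_TISSUES <- c("NP", "AF", "CEPZ")

#' Reference tissue T2 and MTR values
#'
#' Mean and standard deviation of the T2 relaxation time (ms) and the
#' magnetization transfer ratio (%) of the nucleus pulposus (NP), annulus
#' fibrosus (AF) and cartilage endplate zone (CEPZ), measured at 3.0 T in the
#' canine annular stab-injury model at seven timepoints: pre-operation (PO)
#' and 1, 2, 3, 4, 8 and 12 weeks post-surgery.
#'
#' @return A data.frame with columns `tissue`, `timepoint`, `t2_mean`,
#'   `t2_sd` (ms), `mtr_mean`, `mtr_sd` (%).
#' @export
qmri_reference_values <- function() {
  tp <- QMRI_TIMEPOINTS
  build <- function(tissue, t2m, t2s, mtm, mts) {
    data.frame(tissue = tissue, timepoint = tp,
               t2_mean = t2m, t2_sd = t2s,
               mtr_mean = mtm, mtr_sd = mts,
               stringsAsFactors = FALSE)
  }
  rbind(
    build("NP",
          c(150.78, 143.44, 120.20, 131.42, 102.42, 75.58, 52.08),
          c(26.47, 19.38, 28.10, 20.93, 16.20, 14.77, 10.31),
          c(18.72, 15.66, 16.14, 16.82, 25.07, 31.27, 35.67),
          c(5.65, 6.00, 7.08, 5.44, 7.25, 7.21, 5.02)),
    build("AF",
          c(28.93, 25.22, 23.93, 25.19, 21.65, 18.65, 14.75),
          c(9.00, 3.72, 5.58, 4.63, 7.25, 4.76, 2.43),
          c(39.69, 35.13, 35.48, 37.61, 43.99, 50.37, 56.47),
          c(5.99, 5.18, 4.15, 5.90, 6.74, 8.73, 7.04)),
    build("CEPZ",
          c(67.09, 67.07, 61.39, 66.45, 78.50, 54.36, 45.61),
          c(10.59, 7.02, 9.79, 12.09, 10.40, 6.33, 6.20),
          c(31.77, 30.22, 29.23, 32.91, 31.72, 28.34, 24.27),
          c(9.62, 8.79, 9.50, 8.73, 7.40, 7.57, 7.35))
  )
}

#' Reference disc biochemistry
#'
#' Water content (% of wet/dry ratio), uronic acid (a proteoglycan assay) and
#' hydroxyproline (a collagen assay), both in ug/mg dry weight, for NP, AF and
#' CEPZ at pre-operation and 4, 8 and 12 weeks after annular stab injury.
#'
#' @return A data.frame with columns `tissue`, `timepoint`, `water_mean`,
#'   `water_sd`, `uronic_mean`, `uronic_sd`, `hyp_mean`, `hyp_sd`.
#' @export
biochem_reference_values <- function() {
  tp <- BIOCHEM_TIMEPOINTS
  build <- function(tissue, wm, ws, um, us, hm, hs) {
    data.frame(tissue = tissue, timepoint = tp,
               water_mean = wm, water_sd = ws,
               uronic_mean = um, uronic_sd = us,
               hyp_mean = hm, hyp_sd = hs,
               stringsAsFactors = FALSE)
  }
  rbind(
    build("NP",
          c(82.62, 80.83, 76.04, 71.43), c(4.70, 3.11, 3.85, 2.98),
          c(1.59, 1.49, 1.17, 0.94), c(0.12, 0.13, 0.14, 0.11),
          c(0.41, 0.47, 0.51, 0.57), c(0.06, 0.05, 0.05, 0.03)),
    build("AF",
          c(75.46, 72.95, 67.17, 62.29), c(4.07, 3.96, 4.56, 3.24),
          c(0.52, 0.48, 0.41, 0.34), c(0.06, 0.04, 0.07, 0.03),
          c(0.80, 0.89, 0.97, 1.05), c(0.08, 0.08, 0.09, 0.94)),
    build("CEPZ",
          c(79.75, 78.48, 73.72, 69.07), c(4.23, 3.18, 3.72, 3.59),
          c(0.72, 0.69, 0.62, 0.56), c(0.08, 0.05, 0.06, 0.07),
          c(0.55, 0.51, 0.45, 0.40), c(0.08, 0.06, 0.05, 0.05))
  )
}

#' Reference semiquantitative endplate degeneration scores
#'
#' Total histological endplate score (sclerosis + fibrosis + cellularity) in
#' the stab-injury model: 0 pre-operatively, rising through 12 weeks.
#'
#' @return data.frame with `timepoint`, `score_mean`, `score_sd`.
#' @export
endplate_score_reference <- function() {
  data.frame(timepoint = BIOCHEM_TIMEPOINTS,
             score_mean = c(0, 3.94, 5.79, 8.23),
             score_sd = c(0, 2.19, 1.77, 1.49),
             stringsAsFactors = FALSE)
}

#' Reference qMRI-biochemistry correlations
#'
#' Target correlations between tissue biochemistry (water, uronic acid,
#' hydroxyproline) and quantitative MR measures (T2, MTR) used as the coupling
#' of the joint phantom generator. These are the default `correlation_spec` of
#' [simulate_biochem()].
#'
#' @return data.frame with columns `tissue`, `variable`, `r_t2`, `r_mtr`.
#' @export
qmri_biochem_correlations <- function() {
  vars <- c("water_pct", "uronic_acid", "hydroxyproline")
  rbind(
    data.frame(tissue = "AF", variable = vars,
               r_t2 = c(0.369, 0.562, -0.54),
               r_mtr = c(-0.127, -0.55, 0.42), stringsAsFactors = FALSE),
    data.frame(tissue = "NP", variable = vars,
               r_t2 = c(0.697, 0.577, -0.701),
               r_mtr = c(-0.631, -0.352, 0.559), stringsAsFactors = FALSE),
    data.frame(tissue = "CEPZ", variable = vars,
               r_t2 = c(0.599, 0.439, 0.454),
               r_mtr = c(0.426, 0.392, 0.216), stringsAsFactors = FALSE)
  )
}
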