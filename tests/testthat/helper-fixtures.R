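# fixtures shared across test files; everything is generated in code

ref_qmri <- qmri_reference_values()

ref_value <- function(tissue, timepoint, kind = c("t2", "mtr")) {
  kind <- match.arg(kind)
  ref_qmri[ref_qmri$tissue == tissue & ref_qmri$timepoint == timepoint,
           paste0(kind, "_mean")]
}

# standard noise-free phantom with ground truth at a timepoint
make_phantom <- function(timepoint = "PO", seed = 1) {
  assign_ground_truth(build_label_map(seed = seed), timepoint)
}

# small single-disc geometry for Monte-Carlo-heavy tests
small_geometry <- function() {
  utils::modifyList(default_geometry(),
                    list(n_discs = 1L, vertebra_height = 8L, np_width = 10L,
                         af_width = 4L, margin = 4L))
}

# noise-free T2 + MTR maps and the standard three-chain set for one disc
make_maps_and_chains <- function(timepoint = "PO", noise_sigma = 0,
                                 seed = 1) {
  ph <- make_phantom(timepoint)
  es <- simulate_echo_series(ph, noise_sigma = noise_sigma, seed = seed)
  mt <- simulate_mt_pair(ph, noise_sigma = noise_sigma, seed = seed + 1)
  t2 <- fit_t2_map(es)
  mtr <- compute_mtr_map(mt)
  chains <- lapply(c(anterior = "anterior", middle = "middle",
                     posterior = "posterior"), function(reg) {
    build_roi_chain(t2, disc_roi_spec(ph, disc_index = 2, region = reg), reg)
  })
  list(phantom = ph, t2 = t2, mtr = mtr, chains = chains)
}

# exhaustive neighborhood-scan oracle for extrema detection: for each
# position find the nearest differing values on each side; interior
# plateaus only (independent of the run-length implementation under test)
extrema_oracle <- function(vals) {
  n <- length(vals)
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && vals[j + 1] == vals[i]) j <- j + 1
    if (i > 1 && j < n) {
      left <- vals[i - 1]; right <- vals[j + 1]
      type <- if (left < vals[i] && right < vals[i]) "peak"
              else if (left > vals[i] && right > vals[i]) "trough"
              else NA
      if (!is.na(type)) {
        out <- rbind(out, data.frame(position = mean(i:j), type = type,
                                     stringsAsFactors = FALSE))
      }
    }
    i <- j + 1
  }
  out
}

# uniform quantitative map for profile tests
uniform_map <- function(value, nr = 20, nc = 12, kind = "T2") {
  quantitative_map(kind, matrix(value, nr, nc),
                   matrix(1, nr, nc), matrix(TRUE, nr, nc),
                   pixel_spacing = 0.25)
}
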