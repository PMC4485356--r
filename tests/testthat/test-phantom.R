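# phantom generator: geometry, ground truth, simulated acquisitions

# flood-fill connected-component count (4-neighborhood), used as an
# independent oracle for the disc count
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j] > 0) next
    comp <- comp + 1L
    queue <- list(c(i, j))
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- p[1]; c <- p[2]
      if (r < 1 || c < 1 || r > nrow(mask) || c > ncol(mask)) next
      if (!mask[r, c] || lab[r, c] > 0) next
      lab[r, c] <- comp
      queue <- c(queue, list(c(r - 1, c), c(r + 1, c), c(r, c - 1),
                             c(r, c + 1)))
    }
  }
  comp
}

test_that("label map satisfies the anatomy invariants and is deterministic", {
  ph <- build_label_map(seed = 0)
  expect_setequal(unique(as.vector(ph$labels)), unname(PHANTOM_LABELS))

  # same config + seed twice -> identical grids
  expect_identical(ph$labels, build_label_map(seed = 0)$labels)

  # NP enclosed by AF along the anterior/posterior disc margins
  np_rows <- which(apply(ph$labels == PHANTOM_LABELS[["NP"]], 1, any))
  for (r in np_rows) {
    cols <- which(ph$labels[r, ] == PHANTOM_LABELS[["NP"]])
    expect_equal(ph$labels[r, min(cols) - 1], PHANTOM_LABELS[["AF"]])
    expect_equal(ph$labels[r, max(cols) + 1], PHANTOM_LABELS[["AF"]])
  }

  # each disc bounded cephalically and caudally by a CEPZ band
  cepz_codes <- PHANTOM_LABELS[CEPZ_SUBLABELS]
  for (d in seq_len(nrow(ph$discs))) {
    info <- ph$discs[d, ]
    expect_true(all(ph$labels[info$disc_first - 1,
                              ph$labels[info$disc_first, ] %in%
                                PHANTOM_LABELS[c("NP", "AF")]] %in% cepz_codes))
    expect_true(all(ph$labels[info$disc_last + 1,
                              ph$labels[info$disc_last, ] %in%
                                PHANTOM_LABELS[c("NP", "AF")]] %in% cepz_codes))
  }
})

test_that("NP component count equals the configured disc count (flood fill)", {
  for (nd in c(2L, 3L)) {
    ph <- build_label_map(utils::modifyList(default_geometry(),
                                            list(n_discs = nd)), seed = 0)
    expect_equal(count_components(ph$labels == PHANTOM_LABELS[["NP"]]), nd)
  }
})

test_that("impossible band thicknesses raise a geometry error", {
  expect_error(build_label_map(utils::modifyList(default_geometry(),
                                                 list(n_rows = 20))),
               "geometry error")
  expect_error(build_label_map(utils::modifyList(default_geometry(),
                                                 list(vertebra_height = 0))),
               "geometry error")
})

test_that("edge jitter keeps invariants and stays seed-deterministic", {
  g <- utils::modifyList(default_geometry(), list(edge_jitter_px = 2L))
  ph1 <- build_label_map(g, seed = 9)
  ph2 <- build_label_map(g, seed = 9)
  expect_identical(ph1$labels, ph2$labels)
  expect_setequal(unique(as.vector(ph1$labels)), unname(PHANTOM_LABELS))
  expect_equal(count_components(ph1$labels == PHANTOM_LABELS[["NP"]]), 3)
})

test_that("ground truth carries the reference values and honors jitter", {
  ph <- make_phantom("PO")
  p <- ph$params
  expect_equal(p$t2_true[p$name == "NP"], 150.78)
  expect_equal(p$mtr_true[p$name == "NP"], 0.1872)
  ph12 <- make_phantom("12W")
  expect_equal(ph12$params$t2_true[ph12$params$name == "bony_endplate"],
               45.61)

  # zero jitter is seed-independent
  a <- assign_ground_truth(build_label_map(seed = 0), "4W", 0, seed = 1)
  b <- assign_ground_truth(build_label_map(seed = 0), "4W", 0, seed = 2)
  expect_identical(a$params, b$params)

  # jittered values stay physical and are seed-deterministic
  j1 <- assign_ground_truth(build_label_map(seed = 0), "4W", 1, seed = 3)
  j2 <- assign_ground_truth(build_label_map(seed = 0), "4W", 1, seed = 3)
  expect_identical(j1$params, j2$params)
  expect_true(all(j1$params$t2_true > 0))
  expect_true(all(j1$params$mtr_true >= 0 & j1$params$mtr_true < 1))

  expect_error(assign_ground_truth(ph, "6W"), "unknown timepoint")
})

test_that("noise-free echo series equals the closed-form decay everywhere", {
  ph <- make_phantom("PO")
  es <- simulate_echo_series(ph)
  t2g <- matrix(ph$params$t2_true[match(ph$labels, ph$params$label)],
                nrow(ph$labels))
  s0g <- matrix(ph$params$s0_true[match(ph$labels, ph$params$label)],
                nrow(ph$labels))
  for (e in seq_along(es$protocol$te_list)) {
    expect_equal(es$data[, , e], s0g * exp(-es$protocol$te_list[e] / t2g),
                 tolerance = 1e-12)
  }
  # spot value: s0 = 1000, t2 = 50, TE = 50 -> 1000 * exp(-1)
  proto <- acquisition_protocol(tr = 1500, te_list = c(10, 50))
  ph2 <- ph
  ph2$params$t2_true[] <- 50
  es2 <- simulate_echo_series(ph2, proto)
  np_px <- which(ph$labels == PHANTOM_LABELS[["NP"]], arr.ind = TRUE)[1, ]
  expect_equal(es2$data[np_px[1], np_px[2], 2], 1000 * exp(-1),
               tolerance = 1e-12)

  # strictly decreasing in TE; deep decay limit for short T2
  expect_true(all(apply(es$data, c(1, 2), function(v) all(diff(v) < 0))))
  ph5 <- ph
  ph5$params$t2_true[] <- 5
  es5 <- simulate_echo_series(ph5)
  expect_lt(max(es5$data[, , 8] / 1000), 1e-3)
})

test_that("Rician noise reproduces the high-SNR Rician mean", {
  # Monte-Carlo oracle: nu + sigma^2 / (2 nu) at high SNR
  nu <- 1000 * exp(-8.5 / 50)
  sigma <- 20
  n <- 1e5
  x <- withr::with_seed(11,
    apply_magnitude_noise(rep(nu, n), sigma, "rician"))
  expected <- nu + sigma^2 / (2 * nu)
  se <- sigma / sqrt(n)
  expect_lt(abs(mean(x) - expected), 4 * se)
  expect_gt(mean(x), nu) # magnitude bias is positive

  # seeded simulation is reproducible at the series level
  ph <- make_phantom("PO")
  a <- simulate_echo_series(ph, noise_sigma = 20, seed = 3)
  b <- simulate_echo_series(ph, noise_sigma = 20, seed = 3)
  expect_identical(a$data, b$data)
})

test_that("MT pair matches the saturation model and MTR is consistent", {
  ph <- make_phantom("PO")
  mt <- simulate_mt_pair(ph)
  cep_px <- which(ph$labels == PHANTOM_LABELS[["bony_endplate"]],
                  arr.ind = TRUE)[1, ]
  expect_equal(mt$mo[cep_px[1], cep_px[2]], 1000)
  expect_equal(mt$ms[cep_px[1], cep_px[2]], 682.3)
  expect_true(all(mt$ms <= mt$mo))

  # recomputed MTR equals the ground truth at every non-background pixel
  mtr_true <- matrix(ph$params$mtr_true[match(ph$labels, ph$params$label)],
                     nrow(ph$labels))
  body <- ph$labels != PHANTOM_LABELS[["background"]]
  rec <- 100 * (mt$mo - mt$ms) / mt$mo
  expect_equal(rec[body], 100 * mtr_true[body], tolerance = 1e-12)

  # no MT effect -> identical images
  ph0 <- ph
  ph0$params$mtr_true[] <- 0
  mt0 <- simulate_mt_pair(ph0)
  expect_identical(mt0$mo, mt0$ms)
})
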