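# continuous-rectangle ROI chains, profiles, threshold subtraction,
# extrema detection and tissue summaries

test_that("chains partition the span into edge-sharing rectangles", {
  map <- uniform_map(10, nr = 60, nc = 30)
  ch <- build_roi_chain(map, list(row_start = 11, row_end = 41, left = 5,
                                  width = 10, rect_height = 5))
  expect_equal(nrow(ch$rects), 6)
  expect_true(all(ch$rects$bottom[-6] == ch$rects$top[-1]))

  # single-rectangle chain
  one <- build_roi_chain(map, list(row_start = 11, row_end = 16, left = 5,
                                   width = 10, rect_height = 5))
  expect_equal(nrow(one$rects), 1)

  # remainder shortens the final rectangle (logged), never drops it
  expect_message(
    short <- build_roi_chain(map, list(row_start = 1, row_end = 8, left = 5,
                                       width = 10, rect_height = 2)),
    "shortened")
  expect_equal(nrow(short$rects), 4)
  expect_equal(short$rects$bottom[4] - short$rects$top[4], 1)

  # chain coverage: every row covered exactly once
  rows <- unlist(Map(function(t, b) t:(b - 1), short$rects$top,
                     short$rects$bottom))
  expect_identical(sort(rows), 1:7)
  expect_equal(anyDuplicated(rows), 0)

  expect_error(build_roi_chain(map, list(row_start = 50, row_end = 80,
                                         left = 5, width = 10,
                                         rect_height = 5)), "input error")
})

test_that("default region geometry reproduces the reported ROI areas", {
  x <- make_maps_and_chains("PO")
  areas <- vapply(x$chains, function(ch) ch$rects$area_mm2[1], numeric(1))
  # anterior 1.00 +/- 0.13, middle 2.35 +/- 0.12, posterior 0.70 +/- 0.14
  expect_lt(abs(areas[["anterior"]] - 1.00), 0.13)
  expect_lt(abs(areas[["middle"]] - 2.35), 0.12)
  expect_lt(abs(areas[["posterior"]] - 0.70), 0.14)
})

test_that("profiles average valid pixels across each rectangle row", {
  expect_equal(unique(extract_profile(uniform_map(10),
    build_roi_chain(uniform_map(10), list(row_start = 3, row_end = 9,
                                          left = 2, width = 4,
                                          rect_height = 2)))$values), 10)

  # two-column rectangle with values {4, 6} -> row mean 5
  vals <- matrix(4, 6, 6); vals[, 4] <- 6
  m <- quantitative_map("T2", vals, matrix(1, 6, 6), matrix(TRUE, 6, 6))
  ch <- build_roi_chain(m, list(row_start = 1, row_end = 3, left = 3,
                                width = 2, rect_height = 2))
  expect_equal(extract_profile(m, ch)$values, c(5, 5))

  # rows with no valid pixel are missing
  m2 <- m; m2$valid[2, ] <- FALSE; m2$values[2, ] <- NA
  expect_true(is.na(extract_profile(m2, ch)$values[2]))

  # kind mismatch is an input error
  mtr <- uniform_map(30, kind = "MTR")
  expect_error(extract_profile(mtr, ch), "input error")
})

test_that("profile of the noise-free phantom peaks at the NP value", {
  x <- make_maps_and_chains("PO")
  prof <- extract_profile(x$t2, x$chains$middle, phantom = x$phantom)
  expect_equal(max(prof$values), 150.78, tolerance = 1e-9)
  np_rows <- prof$labels == PHANTOM_LABELS[["NP"]]
  expect_true(all(prof$values[np_rows] > 100))
})

test_that("subtract_threshold implements mean - 2 SD one-sided removal", {
  v <- c(rep(100, 9), 0)
  st <- subtract_threshold(v)
  expect_equal(st$threshold, mean(v) - 2 * sd(v))
  expect_equal(st$threshold, 26.754, tolerance = 1e-3)
  expect_equal(st$values, rep(100, 9))
  expect_equal(st$n_removed, 1)

  # constant input: threshold = mean, nothing removed
  stc <- subtract_threshold(rep(7, 5))
  expect_equal(stc$threshold, 7)
  expect_equal(length(stc$values), 5)

  st3 <- subtract_threshold(c(50, 60, 70))
  expect_equal(st3$threshold, 40)
  expect_equal(st3$n_removed, 0)

  expect_error(subtract_threshold(c(1, NA, Inf)), "input error")

  # brute-force property: never removes values >= mean - 2 SD
  withr::with_seed(7, {
    for (i in 1:30) {
      v <- rnorm(50, 100, 25)
      st <- suppressWarnings(subtract_threshold(v))
      thr <- mean(v) - 2 * sd(v)
      expect_setequal(st$values, v[v >= thr])
    }
  })
})

test_that("extrema detection merges plateaus and excludes boundaries", {
  prof <- c(60, 60, 30, 30, 150, 150, 30, 30, 60)
  ex <- detect_extrema(prof, k = 3)
  expect_equal(nrow(ex), 3)
  expect_equal(ex$value[ex$type == "peak"], 150)
  expect_equal(sort(ex$value[ex$type == "trough"]), c(30, 30))
  expect_equal(ex$position[ex$type == "peak"], 5.5)

  expect_message(mono <- detect_extrema(c(1, 2, 3, 4, 5), k = 3),
                 "no interior extrema")
  expect_equal(nrow(mono), 0)
  expect_error(detect_extrema(c(1, 2)), "input error")
})

test_that("extrema detection agrees with the exhaustive-scan oracle", {
  check <- function(vals) {
    got <- suppressMessages(detect_extrema(vals))
    want <- extrema_oracle(vals)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$position), c("position", "type")]
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want[order(want$position), ])
    }
  }
  # all profiles over {0,1,2} up to length 8
  for (len in 3:8) {
    grid <- as.matrix(expand.grid(rep(list(0:2), len)))
    for (r in seq_len(nrow(grid))) check(as.numeric(grid[r, ]))
  }
  # seeded samples of longer profiles
  withr::with_seed(99, {
    for (i in 1:400) {
      check(sample(0:2, sample(9:12, 1), replace = TRUE))
    }
  })
})

test_that("phantom T2 profile extrema are NP peak and CEPZ troughs", {
  x <- make_maps_and_chains("PO")
  prof <- extract_profile(x$t2, x$chains$middle)
  ex <- detect_extrema(prof, k = 3)
  expect_equal(ex$value[ex$type == "peak"], 150.78, tolerance = 1e-9)
  expect_equal(unique(round(ex$value[ex$type == "trough"], 2)),
               67.09)
})

test_that("label-based summaries recover ground truth exactly", {
  x <- make_maps_and_chains("PO")
  s <- summarize_tissue(x$t2, x$chains, phantom = x$phantom,
                        n_repeats = 3, jitter_px = 0, timepoint = "PO")
  expect_equal(s$mean[s$tissue == "NP"], 150.78, tolerance = 1e-9)
  expect_equal(s$mean[s$tissue == "CEPZ"], 67.09, tolerance = 1e-9)
  expect_equal(s$mean[s$tissue == "AF"], 28.93, tolerance = 1e-9)
  expect_true(all(s$sd == 0))       # identical repeats at zero jitter
  expect_true(all(s$n_repeats == 3))
})

test_that("segmentation-based summaries match reference values within 1%", {
  for (tp in QMRI_TIMEPOINTS) {
    x <- make_maps_and_chains(tp)
    for (kind in c("t2", "mtr")) {
      map <- if (kind == "t2") x$t2 else x$mtr
      s <- summarize_tissue(map, x$chains, seg_map = x$t2,
                            n_repeats = 3, jitter_px = 1, seed = 4,
                            timepoint = tp)
      for (tis in c("NP", "AF", "CEPZ")) {
        want <- ref_value(tis, tp, kind)
        expect_lt(abs(s$mean[s$tissue == tis] - want) / want, 0.01,
                  label = paste(tp, kind, tis, "relative error"))
      }
    }
  }
})

test_that("jittered placement changes noise-free summaries by < 2%", {
  x <- make_maps_and_chains("8W")
  s0 <- summarize_tissue(x$t2, x$chains, seg_map = x$t2, n_repeats = 3,
                         jitter_px = 0, timepoint = "8W")
  s1 <- summarize_tissue(x$t2, x$chains, seg_map = x$t2, n_repeats = 3,
                         jitter_px = 1, seed = 2, timepoint = "8W")
  m <- merge(s0, s1, by = "tissue")
  expect_true(all(abs(m$mean.x - m$mean.y) / m$mean.x < 0.02))
})

test_that("noisy 12W NP summaries stay within 5% of 52.08", {
  errs <- vapply(1:2, function(s) {
    x <- make_maps_and_chains("12W", noise_sigma = 20, seed = 10 + s)
    su <- summarize_tissue(x$t2, x$chains, seg_map = x$t2, n_repeats = 3,
                           jitter_px = 1, seed = s, timepoint = "12W")
    abs(su$mean[su$tissue == "NP"] - 52.08) / 52.08
  }, numeric(1))
  expect_true(all(errs < 0.05))
})
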