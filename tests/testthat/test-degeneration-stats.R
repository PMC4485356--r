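# percent change, one-way ANOVA, correlations, report assembly

test_that("percent change is absolute, scale invariant and validated", {
  expect_equal(percent_change(150.78, 102.42), 32.07)
  expect_equal(percent_change(18.72, 31.27), 67.04)
  expect_equal(percent_change(42, 42), 0)
  # direction-blind: rises and falls give the same magnitude
  expect_equal(percent_change(100, 80), percent_change(100, 120))
  withr::with_seed(1, {
    for (i in 1:20) {
      pre <- runif(1, 1, 100); post <- runif(1, 1, 100)
      ct <- runif(1, 0.1, 10)
      expect_equal(percent_change(pre, post), percent_change(ct * pre, ct * post))
    }
  })
  expect_error(percent_change(0, 5), "input error")
  expect_error(percent_change(-3, 5), "input error")
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  a <- anova_oneway(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3)
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 6L)

  same <- anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p_value, 1)

  expect_error(anova_oneway(list(c(1, 2), c(3))), "input error")
  expect_error(anova_oneway(list(c(1, 2))), "input error")
})

test_that("ANOVA conserves SS_total and equals t^2 with two groups", {
  withr::with_seed(12, {
    for (i in 1:20) {
      k <- sample(2:5, 1)
      groups <- lapply(seq_len(k), function(j) rnorm(sample(3:9, 1), j, 2))
      a <- anova_oneway(groups)
      # independent decomposition by brute force
      all_v <- unlist(groups)
      grand <- mean(all_v)
      ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                        numeric(1)))
      ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
      sst <- sum((all_v - grand)^2)
      expect_equal(ssb + ssw, sst, tolerance = 1e-10)
      expect_equal(a$F, (ssb / a$df_between) / (ssw / a$df_within),
                   tolerance = 1e-10)
    }
    # F = t^2 identity for two groups
    g1 <- rnorm(8, 0, 1); g2 <- rnorm(11, 0.7, 1)
    a2 <- anova_oneway(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(a2$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a2$p_value, tt$p.value, tolerance = 1e-10)
  })
})

test_that("strength bands partition [0, 1] with half-open edges", {
  expect_equal(classify_strength(-0.686), "strong")
  expect_equal(classify_strength(0.80), "very strong")
  expect_equal(classify_strength(0.795), "strong")
  expect_equal(classify_strength(0.19), "none")
  expect_equal(classify_strength(0), "none")
  expect_error(classify_strength(1.2), "input error")
  # every |r| maps to exactly one band
  grid <- seq(0, 1, by = 0.001)
  labs <- classify_strength(grid)
  expect_false(any(is.na(labs)))
  expect_setequal(unique(labs),
                  c("none", "weak", "moderate", "strong", "very strong"))
})

test_that("correlate handles methods, invariances and degenerate input", {
  x <- c(1, 5, 3, 9, 7, 2, 8)
  self <- correlate(x, x, method = "pearson")
  expect_equal(self$r, 1)
  expect_equal(self$strength, "very strong")

  cr <- correlate(c(1, 2, 3), c(6, 4, 5), method = "pearson")
  expect_equal(cr$r, -0.5, tolerance = 1e-12)
  expect_equal(cr$strength, "moderate")

  # Pearson invariant under positive affine maps; Spearman under monotone
  withr::with_seed(8, {
    a <- rnorm(40); b <- 0.6 * a + rnorm(40, 0, 0.5)
    p1 <- correlate(a, b, method = "pearson")
    p2 <- correlate(3 * a + 7, 0.2 * b - 1, method = "pearson")
    expect_equal(p1$r, p2$r, tolerance = 1e-12)
    s1 <- correlate(a, b, method = "spearman")
    s2 <- correlate(exp(a), b^3, method = "spearman")
    expect_equal(s1$r, s2$r, tolerance = 1e-12)
  })

  expect_warning(z <- correlate(rep(1, 5), c(1, 2, 3, 4, 5)),
                 "zero variance")
  expect_true(is.na(z$r))
  expect_error(correlate(1:2, 2:3), "input error")
})

test_that("auto method picks Pearson for normal and Spearman for skewed", {
  withr::with_seed(30, {
    a <- rnorm(200); b <- 0.5 * a + rnorm(200, 0, 0.8)
    expect_equal(correlate(a, b, method = "auto")$method, "pearson")
    sk <- exp(rnorm(200, 0, 1.5))
    expect_equal(correlate(sk, 0.5 * sk + exp(rnorm(200)),
                           method = "auto")$method, "spearman")
  })
})

test_that("report percent-change rows reproduce the reference arithmetic", {
  ref <- qmri_reference_values()
  summaries <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    data.frame(tissue = ref$tissue[i], timepoint = ref$timepoint[i],
               kind = c("T2", "MTR"),
               mean = c(ref$t2_mean[i], ref$mtr_mean[i]),
               sd = c(ref$t2_sd[i], ref$mtr_sd[i]),
               n_pixels = 50L, n_repeats = 3L, stringsAsFactors = FALSE)
  }))
  rep <- build_report(summaries)
  pc <- rep$percent_change
  g <- function(tis, kd, tp) pc$change_pct[pc$tissue == tis & pc$kind == kd &
                                           pc$timepoint == tp]
  expect_equal(g("NP", "T2", "PO"), 0)
  expect_equal(g("NP", "T2", "4W"), 32.07)
  expect_equal(g("AF", "T2", "12W"), 49.01)
  expect_equal(g("NP", "MTR", "12W"), 90.54)
  expect_true(all(pc$change_pct >= 0))
  # ANOVA across timepoints is significant for these group differences
  expect_true(all(rep$anova$significant))
  expect_false(is.null(rep$pairwise))
})

test_that("single-timepoint input degrades to summaries with a warning", {
  s <- data.frame(tissue = "NP", timepoint = "PO", kind = "T2",
                  mean = 150, sd = 20, n_pixels = 40L, n_repeats = 3L)
  expect_warning(rep <- build_report(s), "fewer than 2 timepoints")
  expect_null(rep$percent_change)
  expect_identical(rep$summaries, s)
})

test_that("missing baseline omits percent change but keeps ANOVA", {
  s <- data.frame(tissue = "NP", timepoint = c("4W", "8W"), kind = "T2",
                  mean = c(102.42, 75.58), sd = c(16.2, 14.8),
                  n_pixels = 40L, n_repeats = 3L)
  expect_warning(rep <- build_report(s), "baseline")
  expect_null(rep$percent_change)
  expect_false(is.null(rep$anova))
})

test_that("no pairwise markers are emitted when the omnibus test fails", {
  s <- data.frame(tissue = "NP", timepoint = c("PO", "4W", "8W"), kind = "T2",
                  mean = c(100, 100.1, 99.9), sd = 30, n_pixels = 10L,
                  n_repeats = 3L)
  rep <- build_report(s)
  expect_false(rep$anova$significant)
  expect_null(rep$pairwise)
})

test_that("report correlations recover the configured couplings", {
  b <- simulate_biochem("PO", n = 5000, tissues = "NP", seed = 77)
  rep <- build_report(
    data.frame(tissue = "NP", timepoint = c("PO", "4W"), kind = "T2",
               mean = c(150.78, 102.42), sd = c(26, 16), n_pixels = 40L,
               n_repeats = 3L),
    biochem = b)
  cors <- rep$correlations
  want <- qmri_biochem_correlations()
  want <- want[want$tissue == "NP", ]
  for (i in seq_len(nrow(want))) {
    got_t2 <- cors$r[cors$variable == want$variable[i] &
                     cors$map_kind == "T2"]
    got_mtr <- cors$r[cors$variable == want$variable[i] &
                      cors$map_kind == "MTR"]
    expect_lt(abs(got_t2 - want$r_t2[i]), 0.03)
    expect_lt(abs(got_mtr - want$r_mtr[i]), 0.03)
  }
  expect_equal(cors$strength[cors$variable == "water_pct" &
                             cors$map_kind == "T2"],
               classify_strength(cors$r[cors$variable == "water_pct" &
                                        cors$map_kind == "T2"]))
})
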