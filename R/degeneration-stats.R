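# Degeneration statistics: percent change vs pre-operation, one-way ANOVA
# across timepoints, Pearson/Spearman correlations with strength
# classification, and the joined summary report.

#' Absolute percent change versus baseline
#'
#' `100 * |pre - post| / pre`, rounded to 2 decimals for reporting. The
#' magnitude convention matches how degeneration changes are quoted whether
#' the measure fell (T2) or rose (MTR in NP/AF).
#'
#' @param pre baseline mean (> 0).
#' @param post follow-up mean.
#' @param digits decimals for reporting (default 2).
#' @return percent change, `>= 0`. Vectorized.
#' @export
percent_change <- function(pre, post, digits = 2) {
  if (any(!is.finite(pre)) || any(pre <= 0)) {
    stop("input error: baseline value must be positive")
  }
  round(100 * abs(pre - post) / pre, digits)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition with equal-variance pooling; the
#' p-value comes from the F distribution.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return an `anova_result`: list(F, df_between, df_within, p_value).
#' @export
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    stop("input error: need >= 2 groups")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("input error: every group needs >= 2 values")
  }
  values <- unlist(groups)
  fac <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  k <- length(groups)
  n <- length(values)
  if (stats::var(values) == 0) {
    res <- list(F = 0, df_between = k - 1L, df_within = n - k, p_value = 1)
  } else {
    ft <- stats::oneway.test(values ~ fac, var.equal = TRUE)
    res <- list(F = unname(ft$statistic),
                df_between = as.integer(ft$parameter[["num df"]]),
                df_within = as.integer(ft$parameter[["denom df"]]),
                p_value = unname(ft$p.value))
  }
  structure(res, class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p_value))
  invisible(x)
}

# one-way ANOVA from per-group summary statistics (means, SDs, sizes)
anova_from_summary <- function(means, sds, ns) {
  stopifnot(length(means) == length(sds), length(means) == length(ns))
  k <- length(means)
  n <- sum(ns)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  dfb <- k - 1L
  dfw <- as.integer(n - k)
  if (ssw == 0) {
    if (ssb == 0) return(structure(list(F = 0, df_between = dfb,
                                        df_within = dfw, p_value = 1),
                                   class = "anova_result"))
    return(structure(list(F = Inf, df_between = dfb, df_within = dfw,
                          p_value = 0), class = "anova_result"))
  }
  f <- (ssb / dfb) / (ssw / dfw)
  structure(list(F = f, df_between = dfb, df_within = dfw,
                 p_value = stats::pf(f, dfb, dfw, lower.tail = FALSE)),
            class = "anova_result")
}

# pooled-variance two-sample t test from summary statistics
pooled_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 == 0) return(list(t = if (m1 == m2) 0 else Inf,
                            p = if (m1 == m2) 1 else 0))
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
}

#' Classify correlation strength
#'
#' Bands on `|r|`: `[0.80, 1.00]` very strong, `[0.60, 0.80)` strong,
#' `[0.40, 0.60)` moderate, `[0.20, 0.40)` weak, `[0, 0.20)` none. The
#' half-open implementation partitions `[0, 1]` completely.
#'
#' @param r correlation coefficient(s) in `[-1, 1]`.
#' @return character vector of strength labels (`NA` for `NA` input).
#' @export
classify_strength <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("input error: |r| must be <= 1")
  }
  a <- abs(r)
  ifelse(is.na(a), NA_character_,
    ifelse(a >= 0.80, "very strong",
      ifelse(a >= 0.60, "strong",
        ifelse(a >= 0.40, "moderate",
          ifelse(a >= 0.20, "weak", "none")))))
}

#' Correlation with automatic method choice and strength classification
#'
#' `method = "auto"` uses Pearson when both margins pass a Shapiro-Wilk
#' normality test at alpha = 0.05 and Spearman otherwise (the conventional
#' "as appropriate for the distribution" rule). Missing values are removed
#' pairwise; zero variance in a margin yields an undefined (NA) result with
#' a warning rather than an error.
#'
#' @param x,y paired numeric vectors (>= 3 complete pairs).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @return a `correlation_result`: list(method, r, p_value, strength, n).
#' @export
correlate <- function(x, y, method = c("auto", "pearson", "spearman")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("input error: need >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in a margin; correlation undefined")
    return(structure(list(method = method, r = NA_real_, p_value = NA_real_,
                          strength = NA_character_, n = n),
                     class = "correlation_result"))
  }
  if (method == "auto") {
    normal <- function(v) {
      v <- if (length(v) > 5000) v[seq_len(5000)] else v
      stats::shapiro.test(v)$p.value >= 0.05
    }
    method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  r <- unname(ct$estimate)
  structure(list(method = method, r = r, p_value = unname(ct$p.value),
                 strength = classify_strength(r), n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s r = %.3f (p = %.3g, n = %d): %s correlation\n",
              x$method, x$r, x$p_value, x$n,
              if (x$strength == "none") "no" else x$strength))
  invisible(x)
}

#' Build the degeneration summary report
#'
#' Joins tissue summaries across timepoints with the co-simulated (or
#' measured) biochemistry into: a percent-change table versus the
#' pre-operative baseline, per tissue/map-kind one-way ANOVA across
#' timepoints with pairwise significance markers at `alpha` (pairwise
#' pooled-variance t tests, run only when the omnibus ANOVA is significant),
#' and the biochemistry-vs-qMRI correlation matrix with strength labels.
#'
#' @param summaries data.frame from [summarize_tissue()] rows across
#'   timepoints (columns tissue, timepoint, kind, mean, sd, n_pixels).
#' @param biochem optional data.frame from [simulate_biochem()] (or measured
#'   records with the same columns).
#' @param alpha significance level (default 0.05).
#' @param correlation_method passed to [correlate()] (default `"auto"`).
#' @param pairwise_adjust `"none"` (plain P < alpha, default) or
#'   `"bonferroni"`.
#' @return a `degeneration_report`: list(percent_change, anova, pairwise,
#'   correlations, summaries).
#' @export
build_report <- function(summaries, biochem = NULL, alpha = 0.05,
                         correlation_method = "auto",
                         pairwise_adjust = c("none", "bonferroni")) {
  pairwise_adjust <- match.arg(pairwise_adjust)
  need <- c("tissue", "timepoint", "kind", "mean", "sd", "n_pixels")
  if (!all(need %in% names(summaries))) {
    stop("input error: summaries must have columns ",
         paste(need, collapse = ", "))
  }
  tps <- unique(summaries$timepoint)
  if (length(tps) < 2) {
    warning("fewer than 2 timepoints; report contains summaries only")
    return(structure(list(percent_change = NULL, anova = NULL,
                          pairwise = NULL, correlations = NULL,
                          summaries = summaries),
                     class = "degeneration_report"))
  }
  tp_order <- intersect(QMRI_TIMEPOINTS, tps)

  pct <- NULL
  if (!"PO" %in% tps) {
    warning("no pre-operative (PO) baseline; percent-change section omitted")
  } else {
    for (tis in unique(summaries$tissue)) {
      for (kd in unique(summaries$kind)) {
        s <- summaries[summaries$tissue == tis & summaries$kind == kd, ]
        base <- s$mean[s$timepoint == "PO"]
        if (!length(base)) next
        for (tp in tp_order) {
          m <- s$mean[s$timepoint == tp]
          if (!length(m)) next
          pct <- rbind(pct, data.frame(
            tissue = tis, kind = kd, timepoint = tp,
            change_pct = percent_change(base, m), stringsAsFactors = FALSE))
        }
      }
    }
  }

  anova_tab <- NULL
  pairwise <- NULL
  for (tis in unique(summaries$tissue)) {
    for (kd in unique(summaries$kind)) {
      s <- summaries[summaries$tissue == tis & summaries$kind == kd, ]
      s <- s[match(tp_order, s$timepoint), ]
      s <- s[!is.na(s$mean), ]
      if (nrow(s) < 2 || any(s$n_pixels < 2)) next
      # within-group spread: the per-pixel SD when the summaries carry it,
      # the across-repeat SD otherwise
      s$group_sd <- if ("pixel_sd" %in% names(s)) s$pixel_sd else s$sd
      a <- anova_from_summary(s$mean, s$group_sd, s$n_pixels)
      anova_tab <- rbind(anova_tab, data.frame(
        tissue = tis, kind = kd, F = a$F, df_between = a$df_between,
        df_within = a$df_within, p_value = a$p_value,
        significant = a$p_value < alpha, stringsAsFactors = FALSE))
      if (a$p_value < alpha) {
        prs <- utils::combn(nrow(s), 2)
        pv <- apply(prs, 2, function(ij) {
          i <- ij[1]; j <- ij[2]
          pooled_t_from_summary(s$mean[i], s$group_sd[i], s$n_pixels[i],
                                s$mean[j], s$group_sd[j], s$n_pixels[j])$p
        })
        if (pairwise_adjust == "bonferroni") {
          pv <- stats::p.adjust(pv, method = "bonferroni")
        }
        pairwise <- rbind(pairwise, data.frame(
          tissue = tis, kind = kd,
          timepoint_a = s$timepoint[prs[1, ]],
          timepoint_b = s$timepoint[prs[2, ]],
          p_value = pv, significant = pv < alpha, stringsAsFactors = FALSE))
      }
    }
  }

  cors <- NULL
  if (!is.null(biochem)) {
    for (tis in unique(biochem$tissue)) {
      b <- biochem[biochem$tissue == tis, ]
      for (var in intersect(BIOCHEM_VARS, names(b))) {
        for (qv in QMRI_VARS) {
          if (sum(is.finite(b[[var]]) & is.finite(b[[qv]])) < 3) next
          cr <- correlate(b[[var]], b[[qv]], method = correlation_method)
          cors <- rbind(cors, data.frame(
            tissue = tis, variable = var,
            map_kind = if (qv == "t2_value") "T2" else "MTR",
            method = cr$method, r = cr$r, p_value = cr$p_value,
            strength = cr$strength, n = cr$n, stringsAsFactors = FALSE))
        }
      }
    }
  }

  structure(list(percent_change = pct, anova = anova_tab,
                 pairwise = pairwise, correlations = cors,
                 summaries = summaries),
            class = "degeneration_report")
}

#' @export
print.degeneration_report <- function(x, ...) {
  cat("<degeneration_report>\n")
  if (!is.null(x$percent_change)) {
    cat(" percent change vs PO:", nrow(x$percent_change), "rows\n")
  }
  if (!is.null(x$anova)) {
    cat(" ANOVA:", nrow(x$anova), "tissue x kind tests;",
        sum(x$anova$significant), "significant\n")
  }
  if (!is.null(x$correlations)) {
    cat(" correlations:", nrow(x$correlations), "pairs\n")
  }
  invisible(x)
}
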