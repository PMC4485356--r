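# Pixel-wise T2 relaxometry and magnetization transfer ratio mapping.
#
# The T2 fit is the mono-exponential decay SI = S0 * exp(-TE / T2). The
# default estimator is log-linear least squares on ln(SI) vs TE, weighted by
# SI^2 (the delta-method variance weighting for log-transformed magnitude
# data); the nonlinear option refines that estimate by Levenberg-Marquardt
# least squares on the raw signal.

#' Fit the mono-exponential T2 decay of one pixel
#'
#' @param signal magnitudes at each echo, ordered as `te_list`.
#' @param te_list strictly increasing echo times (ms).
#' @param method `"loglinear"` (weighted least squares on the log signal,
#'   default) or `"nonlinear"` (Levenberg-Marquardt on the raw signal,
#'   initialized from the log-linear estimate).
#' @param exclude_first_echo drop the first echo before fitting (off by
#'   default; some multi-spin-echo reconstructions discard it because of
#'   stimulated-echo contamination).
#' @return list with `t2` (ms), `s0`, `quality` (coefficient of
#'   determination in `[0, 1]`) and `valid`. Degenerate inputs (fewer than
#'   two usable echoes, non-decaying signal, non-finite estimates) yield an
#'   invalid result rather than an error.
#' @export
fit_t2_pixel <- function(signal, te_list,
                         method = c("loglinear", "nonlinear"),
                         exclude_first_echo = FALSE) {
  method <- match.arg(method)
  if (length(signal) != length(te_list) || any(diff(te_list) <= 0)) {
    stop("signal and strictly increasing te_list of equal length required")
  }
  if (exclude_first_echo && length(signal) > 2) {
    signal <- signal[-1]
    te_list <- te_list[-1]
  }
  invalid <- list(t2 = NA_real_, s0 = NA_real_, quality = NA_real_,
                  valid = FALSE)
  use <- is.finite(signal) & signal > 0
  if (sum(use) < 2) return(invalid)
  s <- signal[use]
  te <- te_list[use]
  w <- s^2
  y <- log(s)
  sw <- sum(w); swx <- sum(w * te); swy <- sum(w * y)
  swxx <- sum(w * te^2); swxy <- sum(w * te * y)
  denom <- sw * swxx - swx^2
  if (denom <= 0) return(invalid)
  slope <- (sw * swxy - swx * swy) / denom
  icept <- (swy - slope * swx) / sw
  t2 <- -1 / slope
  s0 <- exp(icept)
  if (!is.finite(t2) || t2 <= 0 || !is.finite(s0)) return(invalid)
  if (method == "nonlinear") {
    fit <- tryCatch(
      minpack.lm::nlsLM(s ~ a * exp(-te / b),
                        start = list(a = s0, b = t2),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) return(invalid)
    cf <- stats::coef(fit)
    s0 <- unname(cf[["a"]])
    t2 <- unname(cf[["b"]])
    if (!is.finite(t2) || t2 <= 0) return(invalid)
    res <- s - s0 * exp(-te / t2)
    sst <- sum((s - mean(s))^2)
    quality <- if (sst > 0) max(0, min(1, 1 - sum(res^2) / sst)) else 1
  } else {
    yhat <- icept + slope * te
    sst <- sum(w * (y - swy / sw)^2)
    quality <- if (sst > 0) {
      max(0, min(1, 1 - sum(w * (y - yhat)^2) / sst))
    } else 1
  }
  list(t2 = t2, s0 = s0, quality = quality, valid = TRUE)
}

# background noise SD estimate from the four image corners (Rayleigh
# correction: the SD of a noise-only magnitude pixel is sigma * sqrt(2-pi/2))
estimate_background_sigma <- function(img, patch = 6L) {
  nr <- nrow(img); nc <- ncol(img)
  p <- min(patch, floor(nr / 4), floor(nc / 4))
  if (p < 2) return(0)
  vals <- c(img[1:p, 1:p], img[1:p, (nc - p + 1):nc],
            (img[(nr - p + 1):nr, 1:p]), img[(nr - p + 1):nr, (nc - p + 1):nc])
  stats::sd(vals) / sqrt(2 - pi / 2)
}

#' Fit a pixel-wise T2 map
#'
#' Applies the mono-exponential fit to every masked pixel of a multi-echo
#' series. Pixels whose first-echo signal falls below the noise floor
#' (`max(floor_k * sigma_hat, abs_floor)`, with `sigma_hat` estimated from
#' the background corners unless `noise_floor` is given) are marked invalid,
#' as are pixels with degenerate fits.
#'
#' @param series an `echo_series`.
#' @param mask optional logical matrix matching the image dimensions.
#' @param method passed to [fit_t2_pixel()].
#' @param noise_floor explicit signal floor (overrides the estimate).
#' @param floor_k multiplier on the estimated background noise SD.
#' @param abs_floor absolute minimum floor in signal units.
#' @param exclude_first_echo passed to [fit_t2_pixel()].
#' @return a `quantitative_map` of kind `"T2"` (values in ms; `NA` where
#'   invalid) with per-pixel `quality` and `valid` mask.
#' @export
fit_t2_map <- function(series, mask = NULL,
                       method = c("loglinear", "nonlinear"),
                       noise_floor = NULL, floor_k = 3, abs_floor = 1,
                       exclude_first_echo = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(series, "echo_series"))
  d <- series$data
  dm <- dim(d)
  if (is.null(mask)) mask <- matrix(TRUE, dm[1], dm[2])
  if (!all(dim(mask) == dm[1:2])) {
    stop("input error: mask dimensions do not match the image")
  }
  te <- series$protocol$te_list
  if (exclude_first_echo && length(te) > 2) {
    d <- d[, , -1, drop = FALSE]
    te <- te[-1]
    dm <- dim(d)
  }
  first <- d[, , 1]
  floor_val <- noise_floor %||%
    max(floor_k * estimate_background_sigma(first), abs_floor)

  npix <- dm[1] * dm[2]
  ne <- dm[3]
  S <- matrix(d, npix, ne)
  ok <- is.finite(S) & S > 0
  W <- matrix(0, npix, ne); W[ok] <- S[ok]^2
  Y <- matrix(0, npix, ne); Y[ok] <- log(S[ok])
  X <- matrix(te, npix, ne, byrow = TRUE)
  sw <- rowSums(W); swx <- rowSums(W * X); swy <- rowSums(W * Y)
  swxx <- rowSums(W * X^2); swxy <- rowSums(W * X * Y)
  denom <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / denom
  icept <- (swy - slope * swx) / sw
  t2 <- -1 / slope
  s0 <- exp(icept)
  ssr <- rowSums(W * (Y - icept - slope * X)^2)
  sst <- rowSums(W * (Y - swy / sw)^2)
  quality <- ifelse(sst > 0, pmin(pmax(1 - ssr / sst, 0), 1), 1)

  valid <- as.vector(mask) & as.vector(first) >= floor_val &
    rowSums(ok) >= 2 & is.finite(t2) & t2 > 0 & is.finite(denom) & denom > 0

  if (method == "nonlinear") {
    for (i in which(valid)) {
      f <- fit_t2_pixel(S[i, ], te, method = "nonlinear")
      valid[i] <- f$valid
      t2[i] <- f$t2; s0[i] <- f$s0; quality[i] <- f$quality %||% NA_real_
    }
  }

  vals <- matrix(ifelse(valid, t2, NA_real_), dm[1], dm[2])
  qual <- matrix(ifelse(valid, quality, NA_real_), dm[1], dm[2])
  quantitative_map("T2", vals, qual, matrix(valid, dm[1], dm[2]),
                   pixel_spacing = series$protocol$pixel_spacing,
                   method = method, noise_floor = floor_val)
}

#' Compute a magnetization transfer ratio map
#'
#' `MTR(%) = 100 * (Mo - Ms) / Mo` per pixel; pixels whose unsaturated
#' signal Mo is below the noise floor are invalid.
#'
#' @param pair an `mt_pair` (images `mo`, `ms` of identical size).
#' @param mask optional logical matrix.
#' @inheritParams fit_t2_map
#' @return a `quantitative_map` of kind `"MTR"` (values in %, quality 1
#'   where valid).
#' @export
compute_mtr_map <- function(pair, mask = NULL, noise_floor = NULL,
                            floor_k = 3, abs_floor = 1) {
  stopifnot(inherits(pair, "mt_pair"))
  mo <- pair$mo; ms <- pair$ms
  if (!all(dim(mo) == dim(ms))) {
    stop("input error: Mo and Ms dimensions differ")
  }
  if (is.null(mask)) mask <- matrix(TRUE, nrow(mo), ncol(mo))
  if (!all(dim(mask) == dim(mo))) {
    stop("input error: mask dimensions do not match the image")
  }
  floor_val <- noise_floor %||%
    max(floor_k * estimate_background_sigma(mo), abs_floor)
  valid <- mask & is.finite(mo) & is.finite(ms) & mo >= floor_val
  vals <- ifelse(valid, 100 * (mo - ms) / mo, NA_real_)
  qual <- ifelse(valid, 1, NA_real_)
  quantitative_map("MTR", vals, qual, valid,
                   pixel_spacing = pair$protocol$pixel_spacing,
                   method = "ratio", noise_floor = floor_val)
}

#' Construct a quantitative map object
#'
#' @param kind `"T2"` (ms) or `"MTR"` (%).
#' @param values numeric matrix, `NA` where invalid.
#' @param quality per-pixel goodness of fit in `[0, 1]`.
#' @param valid logical matrix.
#' @param pixel_spacing mm per pixel.
#' @param method fit method used.
#' @param noise_floor signal floor applied.
#' @export
quantitative_map <- function(kind = c("T2", "MTR"), values, quality, valid,
                             pixel_spacing = 0.25, method = "loglinear",
                             noise_floor = 0) {
  kind <- match.arg(kind)
  stopifnot(all(dim(values) == dim(valid)))
  structure(list(kind = kind, values = values, quality = quality,
                 valid = valid, pixel_spacing = pixel_spacing,
                 method = method, noise_floor = noise_floor),
            class = "quantitative_map")
}

#' @export
print.quantitative_map <- function(x, ...) {
  cat("<quantitative_map> ", x$kind, " ", nrow(x$values), "x", ncol(x$values),
      " px, ", sum(x$valid), " valid (floor ", signif(x$noise_floor, 3),
      ", method ", x$method, ")\n", sep = "")
  invisible(x)
}
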