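# Joint simulation of tissue biochemistry, qMRI values and endplate scores.
#
# The coupling between biochemistry (water, uronic acid, hydroxyproline) and
# the qMRI measures (T2, MTR) is a multivariate Gaussian whose cross block is
# the target correlation table. The biochem-biochem block defaults to the
# correlations induced by a two-factor model in which each biochemical
# variable loads on the standardized (T2, MTR) pair plus independent noise:
# that choice reproduces every target cross-correlation exactly and is
# positive semi-definite by construction. Values are kept in physical range
# by resampling (no point masses at the bounds); where a bound is close
# enough to shift a mean, the latent mean is corrected analytically so the
# post-truncation mean still hits the target.

BIOCHEM_VARS <- c("water_pct", "uronic_acid", "hydroxyproline")
QMRI_VARS <- c("t2_value", "mtr_value")

# lower/upper physical bounds per column
biochem_bounds <- function() {
  list(lower = c(water_pct = 0, uronic_acid = 0, hydroxyproline = 0,
                 t2_value = 0, mtr_value = 0),
       upper = c(water_pct = 100, uronic_acid = Inf, hydroxyproline = Inf,
                 t2_value = Inf, mtr_value = 100))
}

# Assemble the 5x5 correlation matrix for one tissue from the cross block.
# spec_rows: data.frame(variable, r_t2, r_mtr); rho: corr(T2, MTR).
build_joint_correlation <- function(spec_rows, rho = 0, biochem_cor = NULL,
                                    repair_tol = 0.05) {
  if (any(abs(c(spec_rows$r_t2, spec_rows$r_mtr, rho)) > 1)) {
    stop("parameter error: correlations must lie in [-1, 1]")
  }
  r2 <- matrix(c(1, rho, rho, 1), 2)
  ab <- t(apply(spec_rows[, c("r_t2", "r_mtr")], 1,
                function(r) solve(r2, as.numeric(r))))
  c2 <- 1 - rowSums(ab * spec_rows[, c("r_t2", "r_mtr")])

  sig <- diag(5)
  vars <- c(BIOCHEM_VARS, QMRI_VARS)
  dimnames(sig) <- list(vars, vars)
  sig[4, 5] <- sig[5, 4] <- rho
  for (i in 1:3) {
    sig[i, 4:5] <- sig[4:5, i] <- c(spec_rows$r_t2[i], spec_rows$r_mtr[i])
  }
  if (is.null(biochem_cor)) {
    for (i in 1:2) for (j in (i + 1):3) {
      sig[i, j] <- sig[j, i] <- drop(ab[i, ] %*% r2 %*% ab[j, ])
    }
  } else {
    sig[1:3, 1:3] <- biochem_cor
    diag(sig) <- 1
  }

  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 || any(c2 < -1e-8)) {
    rep <- as.matrix(Matrix::nearPD(sig, corr = TRUE)$mat)
    if (max(abs(rep - sig)) > repair_tol) {
      stop("parameter error: correlation spec is not positive semi-definite ",
           "and nearest-PSD repair moves entries by more than ", repair_tol)
    }
    sig <- rep
  }
  sig
}

#' Simulate joint biochemistry and qMRI records
#'
#' Draws, per tissue, `(water, uronic acid, hydroxyproline, T2, MTR)` from a
#' joint Gaussian with the reference means and SDs at `timepoint` and the
#' cross-correlations of `correlation_spec`; rows falling outside physical
#' ranges are redrawn. CEPZ rows additionally carry a simulated total
#' endplate score.
#'
#' @param timepoint one of `"PO","4W","8W","12W"` (the biochemistry
#'   timepoints).
#' @param n samples per tissue (>= 2).
#' @param tissues subset of `c("NP","AF","CEPZ")`.
#' @param correlation_spec data.frame like [qmri_biochem_correlations()]:
#'   columns `tissue`, `variable`, `r_t2`, `r_mtr`, entries in `[-1, 1]`.
#' @param rho_t2_mtr correlation between the T2 and MTR margins (default 0).
#' @param biochem_cor optional 3x3 override of the biochemistry block; if it
#'   makes the joint matrix non-PSD it is repaired by nearest-PSD projection,
#'   erroring when the repair exceeds `repair_tol`.
#' @param repair_tol maximum entry shift tolerated from PSD repair.
#' @param seed integer seed.
#' @return data.frame with columns `tissue`, `timepoint`, `water_pct`,
#'   `uronic_acid`, `hydroxyproline`, `endplate_score` (NA outside CEPZ),
#'   `t2_value` (ms), `mtr_value` (%).
#' @export
simulate_biochem <- function(timepoint, n, tissues = QMRI_TISSUES,
                             correlation_spec = qmri_biochem_correlations(),
                             rho_t2_mtr = 0, biochem_cor = NULL,
                             repair_tol = 0.05, seed = NULL) {
  bio <- biochem_reference_values()
  qmri <- qmri_reference_values()
  if (!timepoint %in% bio$timepoint) {
    stop("parameter error: unknown biochemistry timepoint '", timepoint, "'")
  }
  if (n < 2) stop("parameter error: n must be >= 2")
  stopifnot(all(tissues %in% QMRI_TISSUES))
  bounds <- biochem_bounds()

  with_seed_if(seed, {
    out <- lapply(tissues, function(tis) {
      b <- bio[bio$tissue == tis & bio$timepoint == timepoint, ]
      q <- qmri[qmri$tissue == tis & qmri$timepoint == timepoint, ]
      mu <- c(water_pct = b$water_mean, uronic_acid = b$uronic_mean,
              hydroxyproline = b$hyp_mean,
              t2_value = q$t2_mean, mtr_value = q$mtr_mean)
      sd <- c(water_pct = b$water_sd, uronic_acid = b$uronic_sd,
              hydroxyproline = b$hyp_sd,
              t2_value = q$t2_sd, mtr_value = q$mtr_sd)
      spec_rows <- correlation_spec[correlation_spec$tissue == tis, ]
      spec_rows <- spec_rows[match(BIOCHEM_VARS, spec_rows$variable), ]
      if (any(is.na(spec_rows$r_t2))) {
        stop("parameter error: correlation_spec incomplete for ", tis)
      }
      sig <- build_joint_correlation(spec_rows, rho_t2_mtr, biochem_cor,
                                     repair_tol)

      # analytic latent-mean correction for truncation: exact when a single
      # coordinate has non-negligible mass outside its bounds
      mu_lat <- mu
      p_low <- stats::pnorm((bounds$lower[names(mu)] - mu) / sd)
      active <- which(sd > 0 & p_low > 1e-6)
      if (length(active) == 1) {
        h <- active
        mu_lat[h] <- latent_mean_for_target(mu[h], sd[h],
                                            bounds$lower[names(mu)[h]],
                                            tol = 0)
        lam <- (mu[h] - mu_lat[h]) / sd[h]
        for (j in setdiff(seq_along(mu), h)) {
          mu_lat[j] <- mu[j] - sig[j, h] * sd[j] * lam
        }
      } else if (length(active) > 1) {
        warning("multiple truncation-active coordinates for ", tis,
                "; applying marginal corrections only")
        for (h in active) {
          mu_lat[h] <- latent_mean_for_target(mu[h], sd[h],
                                              bounds$lower[names(mu)[h]],
                                              tol = 0)
        }
      }

      covm <- diag(sd) %*% sig %*% diag(sd)
      x <- MASS::mvrnorm(n, mu_lat, covm)
      colnames(x) <- names(mu)
      lo <- bounds$lower[colnames(x)]
      hi <- bounds$upper[colnames(x)]
      for (it in 1:200) {
        bad <- which(apply(x, 1, function(r) any(r <= lo | r >= hi)))
        if (!length(bad)) break
        x[bad, ] <- MASS::mvrnorm(length(bad), mu_lat, covm)
      }
      df <- as.data.frame(x)
      df$tissue <- tis
      df$timepoint <- timepoint
      df$endplate_score <- if (tis == "CEPZ") {
        draw_endplate_scores(timepoint, n)
      } else NA_real_
      df[, c("tissue", "timepoint", "water_pct", "uronic_acid",
             "hydroxyproline", "endplate_score", "t2_value", "mtr_value")]
    })
    do.call(rbind, out)
  })
}

# endplate score draw inside an already-seeded context
draw_endplate_scores <- function(timepoint, n) {
  ref <- endplate_score_reference()
  r <- ref[ref$timepoint == timepoint, ]
  if (r$score_sd == 0) return(rep(r$score_mean, n))
  mu_lat <- latent_mean_for_target(r$score_mean, r$score_sd, lower = 0)
  x <- stats::rnorm(n, mu_lat, r$score_sd)
  for (it in 1:200) {
    bad <- which(x < 0)
    if (!length(bad)) break
    x[bad] <- stats::rnorm(length(bad), mu_lat, r$score_sd)
  }
  x
}

#' Simulate total histological endplate scores
#'
#' Pre-operatively every score is 0; at 4, 8 and 12 weeks scores are drawn
#' from a normal with the reference mean/SD, kept non-negative by resampling
#' (the latent mean is corrected so the truncated mean matches the target).
#'
#' @param timepoint one of `"PO","4W","8W","12W"`.
#' @param n number of scores (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `n`, all >= 0.
#' @export
simulate_endplate_scores <- function(timepoint, n, seed = NULL) {
  ref <- endplate_score_reference()
  if (!timepoint %in% ref$timepoint) {
    stop("parameter error: unknown timepoint '", timepoint, "'")
  }
  if (n < 1) stop("parameter error: n must be >= 1")
  with_seed_if(seed, draw_endplate_scores(timepoint, n))
}
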