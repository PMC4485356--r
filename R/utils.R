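# shared internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG seed when one is supplied, leaving the
# caller's RNG state untouched. seed = NULL uses (and advances) the global RNG.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

#' Apply magnitude noise to a noise-free signal array
#'
#' Rician noise is the physical model for magnitude-reconstructed MR images:
#' independent Gaussian noise of standard deviation `sigma` is added to the
#' real and imaginary channels and the magnitude taken. A plain additive
#' Gaussian model is available for oracle tests where the exact sampling
#' distribution of the mean matters.
#'
#' @param x numeric vector/array of noise-free magnitudes (>= 0).
#' @param sigma per-channel noise standard deviation, in signal units.
#' @param model "rician" (default) or "gaussian".
#' @return array of the same shape as `x`.
#' @export
apply_magnitude_noise <- function(x, sigma, model = c("rician", "gaussian")) {
  model <- match.arg(model)
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  if (sigma == 0) return(x)
  n <- length(x)
  y <- if (model == "gaussian") {
    x + stats::rnorm(n, 0, sigma)
  } else {
    sqrt((x + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
  dim(y) <- dim(x)
  y
}

# Mean of a normal N(mu, sd^2) truncated to [lower, Inf).
truncnorm_mean <- function(mu, sd, lower = 0) {
  a <- (lower - mu) / sd
  mu + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
}

# Latent (pre-truncation) mean such that a normal with standard deviation `sd`
# truncated at `lower` has mean `target`. Only corrects when the naive shift
# exceeds `tol` (a fraction of the target), so distributions far from the bound
# keep their printed means as latent means.
latent_mean_for_target <- function(target, sd, lower = 0, tol = 0.005) {
  if (sd <= 0) return(target)
  shift <- truncnorm_mean(target, sd, lower) - target
  if (abs(shift) <= tol * max(abs(target), .Machine$double.eps)) return(target)
  f <- function(mu) truncnorm_mean(mu, sd, lower) - target
  stats::uniroot(f, lower = target - 10 * sd, upper = target + 2 * sd,
                 tol = 1e-12)$root
}

# md5 checksums for a set of files, named by path relative to `root`
file_checksums <- function(paths, root = NULL) {
  sums <- tools::md5sum(paths)
  if (!is.null(root)) {
    names(sums) <- sub(paste0("^", root, "/?"), "", names(sums))
  }
  as.list(sums)
}
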