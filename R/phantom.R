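# Synthetic mid-sagittal lumbar spine phantom: labeled geometry, per-tissue
# ground-truth MR parameters, and simulated acquisitions.

#' Phantom tissue labels
#'
#' Integer codes of the label grid. The cartilage endplate zone (CEPZ) is the
#' union of the cartilaginous surface, bony endplate and growth plate bands.
#' @export
PHANTOM_LABELS <- c(background = 0L, vertebra = 1L, bony_endplate = 2L,
                    growth_plate = 3L, cartilage_surface = 4L,
                    NP = 5L, AF = 6L)

#' @rdname PHANTOM_LABELS
#' @export
CEPZ_SUBLABELS <- c("bony_endplate", "growth_plate", "cartilage_surface")

#' Default phantom geometry
#'
#' A single 2D mid-sagittal slice: a column of vertebral bodies separated by
#' discs, each disc bounded cephalically and caudally by a three-layer CEPZ
#' band (bony endplate, growth plate, cartilaginous surface) and enclosed
#' anteriorly/posteriorly by the annulus fibrosus. Sizes are in pixels at the
#' default 0.25 mm isotropic spacing, scaled to canine lumbar anatomy
#' (disc height 3 mm, CEPZ band 0.75 mm).
#'
#' @return named list of geometry parameters; pass to [build_label_map()].
#' @export
default_geometry <- function() {
  list(
    n_discs = 3L,
    pixel_spacing = 0.25,      # mm, isotropic
    vertebra_height = 14L,     # px
    cepz_layer_px = 1L,        # px per CEPZ sub-band
    disc_height = 12L,         # px
    np_width = 22L,            # px
    af_width = 8L,             # px, each side
    margin = 6L,               # background columns each side
    n_rows = NULL,             # optional fixed grid size (>= required)
    n_cols = NULL,
    edge_jitter_px = 0L,       # per-disc endplate tilt, in px
    vertebra = list(t2 = 100, mtr = 0.45, s0 = 1000),
    background = list(t2 = 1, mtr = 0, s0 = 0.01),
    tissue_s0 = 1000
  )
}

#' Build the labeled phantom grid
#'
#' Deterministic for a fixed `(geometry, seed)`. Row 1 is the most cephalic
#' row. With `edge_jitter_px > 0` each disc's CEPZ-disc-CEPZ sandwich is given
#' a small random linear tilt across columns, emulating the non-parallel
#' ventral/dorsal endplate anatomy; the default is perfectly rectangular.
#'
#' @param geometry list as returned by [default_geometry()].
#' @param seed integer seed for the (optional) edge jitter.
#' @return An object of class `tissue_phantom` with elements `labels`
#'   (integer matrix), `pixel_spacing`, `geometry`, `discs` (per-disc row
#'   bookkeeping), and empty `params`/`timepoint` until
#'   [assign_ground_truth()] is called.
#' @export
build_label_map <- function(geometry = default_geometry(), seed = 0) {
  g <- utils::modifyList(default_geometry(), geometry)
  ints <- c("n_discs", "vertebra_height", "cepz_layer_px", "disc_height",
            "np_width", "af_width", "margin")
  for (k in ints) {
    if (!is.numeric(g[[k]]) || g[[k]] < 1) {
      stop("geometry error: '", k, "' must be a positive integer")
    }
    g[[k]] <- as.integer(g[[k]])
  }
  lp <- g$cepz_layer_px
  band <- 3L * lp
  unit <- g$vertebra_height + band + g$disc_height + band
  req_rows <- g$n_discs * unit + g$vertebra_height
  req_cols <- 2L * g$margin + 2L * g$af_width + g$np_width
  n_rows <- as.integer(g$n_rows %||% req_rows)
  n_cols <- as.integer(g$n_cols %||% req_cols)
  if (n_rows < req_rows || n_cols < req_cols) {
    stop("geometry error: band thicknesses exceed the grid (need ",
         req_rows, "x", req_cols, ", have ", n_rows, "x", n_cols, ")")
  }

  lab <- matrix(PHANTOM_LABELS[["background"]], n_rows, n_cols)
  body_cols <- (g$margin + 1L):(g$margin + 2L * g$af_width + g$np_width)
  np_cols <- (g$margin + g$af_width + 1L):(g$margin + g$af_width + g$np_width)
  af_cols <- setdiff(body_cols, np_cols)

  discs <- data.frame(disc = integer(), cepz_top_first = integer(),
                      disc_first = integer(), disc_last = integer(),
                      cepz_bottom_last = integer())
  tilts <- with_seed_if(seed, {
    if (g$edge_jitter_px > 0) {
      stats::runif(g$n_discs, -g$edge_jitter_px, g$edge_jitter_px)
    } else rep(0, g$n_discs)
  })

  # per-column vertical offset realizing the endplate tilt of disc d
  col_offset <- function(d) {
    ctr <- mean(body_cols)
    off <- tilts[d] * (seq_len(n_cols) - ctr) / (max(body_cols) - ctr)
    as.integer(round(off))
  }

  # fill the whole spinal column with vertebra, then carve each disc's
  # CEPZ-disc-CEPZ sandwich (possibly tilted) out of it: tilt can never leave
  # background gaps or unbounded discs this way
  lab[seq_len(req_rows), body_cols] <- PHANTOM_LABELS[["vertebra"]]
  layer_codes <- PHANTOM_LABELS[c("bony_endplate", "growth_plate",
                                  "cartilage_surface")]
  for (d in seq_len(g$n_discs)) {
    base <- (d - 1L) * unit
    cepz_top <- base + g$vertebra_height
    disc_first <- cepz_top + band
    disc_last <- disc_first + g$disc_height
    off <- pmax(pmin(col_offset(d), g$vertebra_height - 1L),
                -(g$vertebra_height - 1L))
    for (cc in body_cols) {
      sh <- off[cc]
      for (i in 1:3) {
        rows <- (cepz_top + sh + (i - 1L) * lp + 1L):(cepz_top + sh + i * lp)
        lab[rows, cc] <- layer_codes[[i]]
      }
      disc_rows <- (disc_first + sh + 1L):(disc_last + sh)
      lab[disc_rows, cc] <- if (cc %in% np_cols) {
        PHANTOM_LABELS[["NP"]]
      } else PHANTOM_LABELS[["AF"]]
      for (i in 1:3) {
        rows <- (disc_last + sh + (i - 1L) * lp + 1L):(disc_last + sh + i * lp)
        lab[rows, cc] <- layer_codes[[4L - i]]
      }
    }
    discs <- rbind(discs, data.frame(
      disc = d, cepz_top_first = cepz_top + 1L,
      disc_first = disc_first + 1L, disc_last = disc_last,
      cepz_bottom_last = disc_last + band))
  }

  structure(list(labels = lab, pixel_spacing = g$pixel_spacing,
                 geometry = g, discs = discs, params = NULL,
                 timepoint = NULL),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", nrow(x$labels), "x", ncol(x$labels),
      " px @ ", x$pixel_spacing, " mm, ", x$geometry$n_discs, " discs",
      if (!is.null(x$timepoint)) paste0(", timepoint ", x$timepoint) else
        " (no ground truth assigned)",
      "\n", sep = "")
  invisible(x)
}

#' Assign per-tissue ground-truth MR parameters
#'
#' Looks up the reference T2 (ms) and MTR for NP, AF and the three CEPZ
#' sub-labels at the requested timepoint; `jitter_sd` adds inter-subject
#' variation as a fraction of the reference standard deviations (values are
#' redrawn until physical: T2 > 0, 0 <= MTR < 1). Vertebra and background use
#' the geometry defaults.
#'
#' @param phantom a `tissue_phantom`.
#' @param timepoint one of `"PO","1W","2W","3W","4W","8W","12W"`.
#' @param jitter_sd non-negative fraction of the reference SDs.
#' @param seed integer seed (only matters when `jitter_sd > 0`).
#' @return the phantom with `params` (one row per label) and `timepoint` set.
#' @export
assign_ground_truth <- function(phantom, timepoint, jitter_sd = 0,
                                seed = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  ref <- qmri_reference_values()
  if (!timepoint %in% ref$timepoint) {
    stop("parameter error: unknown timepoint '", timepoint, "'")
  }
  if (jitter_sd < 0) stop("parameter error: jitter_sd must be >= 0")
  g <- phantom$geometry

  draw_pos <- function(mean, sd, lower = 0, upper = Inf) {
    if (sd == 0) return(mean)
    for (i in 1:1000) {
      x <- stats::rnorm(1, mean, sd)
      if (x > lower && x < upper) return(x)
    }
    stop("parameter error: could not draw a physical value near ", mean)
  }

  params <- with_seed_if(seed, {
    rows <- lapply(c("NP", "AF", "CEPZ"), function(tis) {
      r <- ref[ref$tissue == tis & ref$timepoint == timepoint, ]
      t2 <- draw_pos(r$t2_mean, jitter_sd * r$t2_sd)
      mtr <- draw_pos(r$mtr_mean / 100, jitter_sd * r$mtr_sd / 100,
                      lower = 0, upper = 1)
      data.frame(tissue = tis, t2_true = t2, mtr_true = mtr)
    })
    do.call(rbind, rows)
  })
  get <- function(tis, col) params[params$tissue == tis, col]

  tab <- data.frame(
    label = unname(PHANTOM_LABELS),
    name = names(PHANTOM_LABELS),
    t2_true = c(g$background$t2, g$vertebra$t2,
                rep(get("CEPZ", "t2_true"), 3),
                get("NP", "t2_true"), get("AF", "t2_true")),
    s0_true = c(g$background$s0, g$vertebra$s0, rep(g$tissue_s0, 5)),
    mtr_true = c(g$background$mtr, g$vertebra$mtr,
                 rep(get("CEPZ", "mtr_true"), 3),
                 get("NP", "mtr_true"), get("AF", "mtr_true")),
    stringsAsFactors = FALSE)
  stopifnot(all(tab$t2_true > 0), all(tab$s0_true > 0),
            all(tab$mtr_true >= 0 & tab$mtr_true < 1))
  phantom$params <- tab
  phantom$timepoint <- timepoint
  phantom
}

# per-pixel grid of a ground-truth parameter
param_grid <- function(phantom, field) {
  if (is.null(phantom$params)) {
    stop("phantom has no ground truth; call assign_ground_truth() first")
  }
  idx <- match(phantom$labels, phantom$params$label)
  matrix(phantom$params[[field]][idx], nrow(phantom$labels),
         ncol(phantom$labels))
}

#' Default acquisition protocol
#'
#' Multi-spin-echo T2 mapping protocol: TR 1500 ms, 8 echoes evenly spaced
#' over 8.5-67.9 ms; MT off-resonance offset 1100 Hz; 3 mm slice.
#'
#' @param phantom optional `tissue_phantom`; sets `matrix_size` and
#'   `pixel_spacing` from its grid.
#' @return an `acquisition_protocol` object.
#' @export
default_protocol <- function(phantom = NULL) {
  acquisition_protocol(
    tr = 1500,
    te_list = seq(8.5, 67.9, length.out = 8),
    mt_offset_hz = 1100,
    matrix_size = if (is.null(phantom)) c(256L, 160L) else dim(phantom$labels),
    slice_thickness = 3,
    pixel_spacing = if (is.null(phantom)) 0.25 else phantom$pixel_spacing)
}

#' Construct an acquisition protocol
#'
#' @param tr repetition time (ms).
#' @param te_list strictly increasing echo times (ms).
#' @param mt_offset_hz off-resonance frequency of the MT saturation pulse.
#' @param matrix_size image rows x cols.
#' @param slice_thickness mm.
#' @param pixel_spacing in-plane mm per pixel.
#' @export
acquisition_protocol <- function(tr, te_list, mt_offset_hz = 1100,
                                 matrix_size = c(256L, 160L),
                                 slice_thickness = 3, pixel_spacing = 0.25) {
  te_list <- as.numeric(te_list)
  if (length(te_list) < 1 || any(te_list <= 0) ||
      any(diff(te_list) <= 0)) {
    stop("te_list must be positive and strictly increasing")
  }
  stopifnot(tr > 0, slice_thickness > 0, pixel_spacing > 0)
  structure(list(tr = tr, te_list = te_list, n_echoes = length(te_list),
                 mt_offset_hz = mt_offset_hz,
                 matrix_size = as.integer(matrix_size),
                 slice_thickness = slice_thickness,
                 pixel_spacing = pixel_spacing),
            class = "acquisition_protocol")
}

#' Simulate a multi-echo spin-echo magnitude series
#'
#' The noise-free signal at echo time TE is the mono-exponential decay
#' `S0 * exp(-TE / T2)` of each pixel's ground-truth parameters; with
#' `noise_sigma > 0` magnitude noise is applied per echo (Rician by default).
#'
#' @param phantom a `tissue_phantom` with ground truth assigned.
#' @param protocol an `acquisition_protocol`.
#' @param noise_sigma per-channel noise SD in signal units (>= 0).
#' @param seed integer seed for the noise draw.
#' @param noise_model "rician" or "gaussian".
#' @return An `echo_series`: list(data = rows x cols x n_echoes array,
#'   protocol).
#' @export
simulate_echo_series <- function(phantom, protocol = default_protocol(phantom),
                                 noise_sigma = 0, seed = NULL,
                                 noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  t2 <- param_grid(phantom, "t2_true")
  s0 <- param_grid(phantom, "s0_true")
  dm <- dim(phantom$labels)
  dat <- array(0, c(dm, protocol$n_echoes))
  for (e in seq_len(protocol$n_echoes)) {
    dat[, , e] <- s0 * exp(-protocol$te_list[e] / t2)
  }
  if (noise_sigma > 0) {
    dat <- with_seed_if(seed,
      apply_magnitude_noise(dat, noise_sigma, noise_model))
  }
  structure(list(data = dat, protocol = protocol), class = "echo_series")
}

#' Simulate an MT-on/MT-off magnitude pair
#'
#' Noise-free, the image without the off-resonance saturation pulse (Mo) is
#' the pixel's S0 and the saturated image (Ms) is `S0 * (1 - MTR_true)`, a
#' fixed saturation fraction per tissue; magnitude noise as in
#' [simulate_echo_series()].
#'
#' @inheritParams simulate_echo_series
#' @return an `mt_pair`: list(mo, ms matrices, protocol).
#' @export
simulate_mt_pair <- function(phantom, protocol = default_protocol(phantom),
                             noise_sigma = 0, seed = NULL,
                             noise_model = c("rician", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  s0 <- param_grid(phantom, "s0_true")
  mtr <- param_grid(phantom, "mtr_true")
  mo <- s0
  ms <- s0 * (1 - mtr)
  if (noise_sigma > 0) {
    noisy <- with_seed_if(seed, {
      list(mo = apply_magnitude_noise(mo, noise_sigma, noise_model),
           ms = apply_magnitude_noise(ms, noise_sigma, noise_model))
    })
    mo <- noisy$mo
    ms <- noisy$ms
  }
  structure(list(mo = mo, ms = ms, protocol = protocol), class = "mt_pair")
}
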