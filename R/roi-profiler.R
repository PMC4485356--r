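# Continuous-rectangle ROI profiling: chained edge-sharing rectangles spanning
# a disc from the cephalic to the caudal CEPZ (through a few vertebral rows on
# each side), the per-row profile curve, the mean - 2 SD subtraction
# threshold, peak/trough tissue discrimination, and triplicate-averaged
# tissue summaries.
#
# Coordinates are 1-based half-open pixel bounds: a rectangle covers rows
# [top, bottom) and columns [left, right); consecutive rectangles in a chain
# share an edge (rect i's bottom == rect i+1's top). Row 1 is cephalic.

#' Construct a single rectangular ROI
#'
#' @param top,bottom,left,right 1-based half-open pixel bounds.
#' @param region_tag `"anterior"`, `"middle"` or `"posterior"`.
#' @param pixel_spacing mm per pixel (isotropic); sets `area_mm2`.
#' @export
rectangle_roi <- function(top, bottom, left, right,
                          region_tag = c("middle", "anterior", "posterior"),
                          pixel_spacing = 0.25) {
  region_tag <- match.arg(region_tag)
  if (!(top < bottom && left < right)) {
    stop("input error: need top < bottom and left < right")
  }
  data.frame(top = as.integer(top), bottom = as.integer(bottom),
             left = as.integer(left), right = as.integer(right),
             region_tag = region_tag,
             area_mm2 = (bottom - top) * (right - left) * pixel_spacing^2,
             stringsAsFactors = FALSE)
}

#' Axis specification for a disc's ROI chain
#'
#' Computes where to place a continuous-rectangle chain on a phantom-derived
#' map: the row span runs from `vertebra_pad` rows above the disc's cephalic
#' CEPZ to `vertebra_pad` rows below its caudal CEPZ (the chain includes the
#' adjacent vertebrae, as in the original measurement, so the CEPZ has a
#' two-sided neighborhood in the profile), and the columns cover the
#' anterior AF band, the central NP, or the posterior AF band. Default
#' widths with 2-px-tall rectangles at 0.25 mm spacing give per-rectangle
#' areas of 1.00, 2.375 and 0.75 mm^2 for the anterior, middle and posterior
#' regions.
#'
#' @param phantom a `tissue_phantom`.
#' @param disc_index which disc (1-based).
#' @param region `"middle"`, `"anterior"` or `"posterior"`.
#' @param rect_height rectangle height in px.
#' @param width rectangle width in px (region default if `NULL`).
#' @param vertebra_pad rows of vertebra included on each end.
#' @return list(row_start, row_end, left, width, rect_height) with half-open
#'   `[row_start, row_end)` rows; pass to [build_roi_chain()].
#' @export
disc_roi_spec <- function(phantom, disc_index = 2,
                          region = c("middle", "anterior", "posterior"),
                          rect_height = 2, width = NULL, vertebra_pad = 4) {
  region <- match.arg(region)
  stopifnot(inherits(phantom, "tissue_phantom"))
  g <- phantom$geometry
  d <- phantom$discs[phantom$discs$disc == disc_index, ]
  if (nrow(d) != 1) stop("input error: no disc ", disc_index)
  width <- width %||% switch(region, anterior = 8L, middle = 19L,
                             posterior = 6L)
  left <- switch(region,
    anterior = g$margin + 1L,
    middle = g$margin + g$af_width + 1L +
      max(0L, (g$np_width - as.integer(width)) %/% 2L),
    posterior = g$margin + g$af_width + g$np_width + 1L +
      max(0L, (g$af_width - as.integer(width)) %/% 2L))
  list(row_start = d$cepz_top_first - as.integer(vertebra_pad),
       row_end = d$cepz_bottom_last + as.integer(vertebra_pad) + 1L,
       left = as.integer(left), width = as.integer(width),
       rect_height = as.integer(rect_height))
}

#' Build a continuous chain of edge-sharing rectangles
#'
#' Partitions the axial span `[row_start, row_end)` into rectangles of
#' `rect_height` rows, each sharing its bottom edge with the next
#' rectangle's top edge so no tissue row is omitted or double counted. A
#' span not divisible by the rectangle height shortens the final rectangle
#' (logged via `message()`), never drops it.
#'
#' @param map a `quantitative_map` (provides bounds, kind and spacing).
#' @param axis_spec list as from [disc_roi_spec()].
#' @param region_tag region label applied to every rectangle.
#' @return an `roi_chain`: list(rects data.frame, kind, pixel_spacing).
#' @export
build_roi_chain <- function(map, axis_spec,
                            region_tag = c("middle", "anterior",
                                           "posterior")) {
  region_tag <- match.arg(region_tag)
  stopifnot(inherits(map, "quantitative_map"))
  a <- axis_spec
  h <- as.integer(a$rect_height)
  if (h < 1) stop("input error: rect height must be >= 1 px")
  if (a$row_start < 1 || a$row_end > nrow(map$values) + 1 ||
      a$row_end <= a$row_start) {
    stop("input error: axis span outside map bounds")
  }
  if (a$left < 1 || a$left + a$width > ncol(map$values) + 1) {
    stop("input error: column span outside map bounds")
  }
  tops <- seq(a$row_start, a$row_end - 1L, by = h)
  bottoms <- pmin(tops + h, a$row_end)
  if (bottoms[length(bottoms)] - tops[length(tops)] < h) {
    message("final rectangle shortened to ",
            bottoms[length(bottoms)] - tops[length(tops)], " rows")
  }
  rects <- do.call(rbind, Map(function(t, b) {
    rectangle_roi(t, b, a$left, a$left + a$width, region_tag,
                  map$pixel_spacing)
  }, tops, bottoms))
  structure(list(rects = rects, kind = map$kind,
                 pixel_spacing = map$pixel_spacing),
            class = "roi_chain")
}

# shift a chain along the spine axis (triplicate placement jitter)
shift_chain <- function(chain, d) {
  chain$rects$top <- chain$rects$top + as.integer(d)
  chain$rects$bottom <- chain$rects$bottom + as.integer(d)
  chain
}

#' Extract the profile curve of a chain
#'
#' One value per axial row of the chain: the mean of the valid map pixels
#' across the rectangle's width at that row. Rows with no valid pixel are
#' `NA` (missing).
#'
#' @param map a `quantitative_map` of the same kind the chain was built on.
#' @param chain an `roi_chain`.
#' @param phantom optional `tissue_phantom`; attaches the ground-truth label
#'   (majority across the width) per row for validation.
#' @return a `profile_curve`: list(positions, values, labels).
#' @export
extract_profile <- function(map, chain, phantom = NULL) {
  stopifnot(inherits(map, "quantitative_map"), inherits(chain, "roi_chain"))
  if (!identical(chain$kind, map$kind)) {
    stop("input error: chain was built for a ", chain$kind,
         " map, got ", map$kind)
  }
  r <- chain$rects
  if (min(r$top) < 1 || max(r$bottom) > nrow(map$values) + 1) {
    stop("input error: chain outside map bounds")
  }
  rows <- integer(); vals <- numeric(); labs <- integer()
  for (i in seq_len(nrow(r))) {
    for (row in r$top[i]:(r$bottom[i] - 1L)) {
      px <- map$values[row, r$left[i]:(r$right[i] - 1L)]
      rows <- c(rows, row)
      vals <- c(vals, if (all(is.na(px))) NA_real_ else mean(px, na.rm = TRUE))
      if (!is.null(phantom)) {
        lb <- phantom$labels[row, r$left[i]:(r$right[i] - 1L)]
        labs <- c(labs, as.integer(names(which.max(table(lb)))))
      }
    }
  }
  o <- order(rows)
  structure(list(positions = rows[o], values = vals[o],
                 labels = if (is.null(phantom)) NULL else labs[o]),
            class = "profile_curve")
}

#' Mean - 2 SD subtraction threshold
#'
#' Computes the slice threshold `mean - 2 * SD` (sample SD) over all measured
#' values and removes values strictly below it, mirroring the pixel
#' subtraction used to filter surrounding tissue out of tissue means.
#'
#' @param values numeric vector with >= 2 finite values.
#' @return list(values = kept values, threshold, n_removed). Removal of more
#'   than half the input is flagged with a warning.
#' @export
subtract_threshold <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) stop("input error: need at least 2 finite values")
  thr <- mean(v) - 2 * stats::sd(v)
  kept <- v[v >= thr]
  if (length(kept) < length(v) / 2) {
    warning("subtraction threshold removed more than half the values")
  }
  list(values = kept, threshold = thr, n_removed = length(v) - length(kept))
}

#' Detect peak/trough extrema of a profile curve
#'
#' Consecutive equal values are merged into plateaus; an interior plateau is
#' a peak (trough) when both neighboring plateaus are lower (higher).
#' Boundary plateaus have no two-sided neighborhood and are never extrema.
#' The `k` extrema of largest topographic prominence are returned, ties
#' broken toward the smaller position; plateau positions are reported at the
#' plateau center. A monotone profile yields an empty result (signaled via a
#' message, not an error).
#'
#' @param profile a `profile_curve` (or plain numeric vector) with >= 3
#'   non-missing points.
#' @param k number of extrema to keep (`NULL` keeps all).
#' @return data.frame(position, value, type, prominence, run_start, run_end)
#'   ordered by decreasing prominence; `run_start`/`run_end` are the plateau
#'   bounds in profile positions.
#' @export
detect_extrema <- function(profile, k = NULL) {
  if (inherits(profile, "profile_curve")) {
    pos <- profile$positions
    vals <- profile$values
  } else {
    vals <- as.numeric(profile)
    pos <- seq_along(vals)
  }
  keep <- !is.na(vals)
  pos <- pos[keep]; vals <- vals[keep]
  if (length(vals) < 3) stop("input error: need >= 3 non-missing points")

  runs <- rle(vals)
  nr <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  empty <- data.frame(position = numeric(), value = numeric(),
                      type = character(), prominence = numeric(),
                      run_start = numeric(), run_end = numeric(),
                      stringsAsFactors = FALSE)
  if (nr < 3) {
    message("no interior extrema found")
    return(empty)
  }
  rv <- runs$values
  out <- empty
  for (i in 2:(nr - 1)) {
    type <- if (rv[i] > rv[i - 1] && rv[i] > rv[i + 1]) "peak"
            else if (rv[i] < rv[i - 1] && rv[i] < rv[i + 1]) "trough"
            else next
    v <- if (type == "peak") rv else -rv
    # topographic prominence on the run-level series: on each side walk to
    # the nearest strictly higher point (or the boundary) tracking the
    # minimum; prominence is the drop to the higher of the two side minima
    side_min <- function(idx) {
      m <- Inf
      for (j in idx) {
        if (v[j] > v[i]) return(m)
        m <- min(m, v[j])
      }
      m
    }
    base <- max(side_min(rev(seq_len(i - 1))), side_min((i + 1):nr))
    out <- rbind(out, data.frame(
      position = mean(pos[starts[i]:ends[i]]),
      value = rv[i], type = type, prominence = v[i] - base,
      run_start = pos[starts[i]], run_end = pos[ends[i]],
      stringsAsFactors = FALSE))
  }
  if (nrow(out) == 0) {
    message("no interior extrema found")
    return(empty)
  }
  out <- out[order(-out$prominence, out$position), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(k)) out <- utils::head(out, k)
  out
}

#' Segment a profile into extremum neighborhoods
#'
#' Assigns profile rows to the peak or trough they belong to. Each selected
#' extremum claims its plateau; the plateau is then grown in each direction
#' while row values stay on the extremum's side of the midpoint between the
#' extremum value and the nearest distinct-valued row in that direction.
#' On noise-free phantoms, where adjacent tissues form distinct plateaus,
#' this reproduces the ground-truth tissue rows exactly; on noisy profiles
#' it degrades gracefully to a tight neighborhood of the extremum (the "three
#' or four values from the peak or trough" reading of curve analysis).
#'
#' @param profile a `profile_curve`.
#' @param extrema data.frame from [detect_extrema()]; computed with
#'   `k = k` when omitted.
#' @param k passed to [detect_extrema()] when `extrema` is `NULL`.
#' @return character vector along `profile$positions`: `"peak"`, `"trough"`
#'   or `NA` (unassigned).
#' @export
segment_profile <- function(profile, extrema = NULL, k = 3) {
  stopifnot(inherits(profile, "profile_curve"))
  if (is.null(extrema)) extrema <- detect_extrema(profile, k = k)
  n <- length(profile$positions)
  cls <- rep(NA_character_, n)
  if (nrow(extrema) == 0) return(cls)
  vals <- profile$values
  ex <- extrema[order(extrema$position), , drop = FALSE]
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    i0 <- match(e$run_start, profile$positions)
    i1 <- match(e$run_end, profile$positions)
    # nearest row with a value distinct from the extremum, per direction
    distinct_ref <- function(idx) {
      for (j in idx) {
        if (!is.na(vals[j]) && vals[j] != e$value) return(vals[j])
      }
      NA_real_
    }
    grow <- function(start, step, ref) {
      j <- start
      if (is.na(ref)) { # flat to the boundary
        lim <- if (step < 0) 1 else n
        return(lim)
      }
      thr <- (e$value + ref) / 2
      inside <- function(x) {
        !is.na(x) && if (e$type == "peak") x >= thr else x <= thr
      }
      while (j + step >= 1 && j + step <= n && inside(vals[j + step])) {
        j <- j + step
      }
      j
    }
    j0 <- grow(i0, -1L, distinct_ref(rev(seq_len(max(i0 - 1, 0)))))
    j1 <- grow(i1, 1L,
               distinct_ref(if (i1 < n) (i1 + 1):n else integer()))
    cls[j0:j1] <- e$type
  }
  cls
}

#' Triplicate-averaged tissue summaries from ROI chains
#'
#' Reproduces the measurement protocol: the chain set is placed
#' `n_repeats` times (re-placement jitter of up to `jitter_px` rows along
#' the spine axis emulates manual re-drawing), pixels are assigned to NP,
#' AF and CEPZ, the mean - 2 SD subtraction threshold is applied within each
#' tissue's pixel set, and per-repeat tissue means are averaged.
#'
#' Tissue assignment uses the ground-truth labels when `phantom` is given
#' (validation mode); otherwise it uses peak/trough segmentation of the T2
#' profile (`seg_map`, defaulting to `map`): on the mid-disc (middle) chain
#' the peak neighborhood is NP and trough neighborhoods are CEPZ; on
#' anterior/posterior chains the deepest trough neighborhood is AF.
#'
#' @param map the `quantitative_map` to summarize (T2 or MTR).
#' @param chains named list of `roi_chain`s; needs `middle` and at least one
#'   of `anterior`/`posterior` for AF.
#' @param phantom optional `tissue_phantom` for label-based assignment.
#' @param seg_map map used for segmentation (default `map`; pass the T2 map
#'   when summarizing MTR, since tissue ordering is defined on T2).
#' @param n_repeats number of placements averaged (default 3).
#' @param jitter_px maximum per-repeat axial shift in px.
#' @param seed integer seed for the placement jitter.
#' @param timepoint optional label copied into the output.
#' @return data.frame(tissue, timepoint, kind, mean, sd, pixel_sd,
#'   n_pixels, n_repeats); `sd` is the placement variability across repeats
#'   and `pixel_sd` the pooled within-tissue pixel SD (what downstream ANOVA
#'   across timepoints uses). Tissues with no assigned pixels in any repeat
#'   are absent (logged via `message()`).
#' @export
summarize_tissue <- function(map, chains, phantom = NULL, seg_map = NULL,
                             n_repeats = 3, jitter_px = 1, seed = NULL,
                             timepoint = NULL) {
  stopifnot(inherits(map, "quantitative_map"), is.list(chains))
  if (n_repeats < 1) stop("input error: n_repeats must be >= 1")
  seg_map <- seg_map %||% map
  timepoint <- timepoint %||% NA_character_

  tissue_values_one_repeat <- function(d) {
    sets <- list(NP = numeric(), AF = numeric(), CEPZ = numeric())
    for (nm in names(chains)) {
      ch <- shift_chain(chains[[nm]], d)
      if (!is.null(phantom)) {
        r <- ch$rects
        for (i in seq_len(nrow(r))) {
          rows <- r$top[i]:(r$bottom[i] - 1L)
          cols <- r$left[i]:(r$right[i] - 1L)
          lb <- phantom$labels[rows, cols, drop = FALSE]
          vv <- map$values[rows, cols, drop = FALSE]
          sets$NP <- c(sets$NP, vv[lb == PHANTOM_LABELS[["NP"]]])
          sets$AF <- c(sets$AF, vv[lb == PHANTOM_LABELS[["AF"]]])
          cep <- lb %in% PHANTOM_LABELS[CEPZ_SUBLABELS]
          sets$CEPZ <- c(sets$CEPZ, vv[cep])
        }
      } else {
        seg_chain <- ch
        seg_chain$kind <- seg_map$kind
        prof <- extract_profile(seg_map, seg_chain)
        ex <- suppressMessages(detect_extrema(prof, k = 4))
        mprof_rows <- prof$positions
        row_vals <- function(row) {
          r <- ch$rects
          i <- which(r$top <= row & row < r$bottom)[1]
          map$values[row, r$left[i]:(r$right[i] - 1L)]
        }
        take <- function(cls, type) {
          unlist(lapply(which(!is.na(cls) & cls == type),
                        function(jj) row_vals(mprof_rows[jj])))
        }
        if (nm == "middle") {
          # the mid-disc chain crosses CEPZ - NP - CEPZ: NP is the most
          # prominent peak, CEPZ the best trough on each side of it
          pks <- ex[ex$type == "peak", , drop = FALSE]
          trs <- ex[ex$type == "trough", , drop = FALSE]
          if (nrow(pks)) {
            sel <- pks[1, , drop = FALSE]
            above <- trs[trs$position < pks$position[1], , drop = FALSE]
            below <- trs[trs$position > pks$position[1], , drop = FALSE]
            if (nrow(above)) sel <- rbind(sel, above[1, ])
            if (nrow(below)) sel <- rbind(sel, below[1, ])
            cls <- segment_profile(prof, extrema = sel)
            sets$NP <- c(sets$NP, take(cls, "peak"))
            sets$CEPZ <- c(sets$CEPZ, take(cls, "trough"))
          }
        } else {
          # anterior/posterior chains cross CEPZ - AF - CEPZ: AF is the
          # single most prominent trough
          trs <- ex[ex$type == "trough", , drop = FALSE]
          if (nrow(trs)) {
            cls <- segment_profile(prof, extrema = trs[1, , drop = FALSE])
            sets$AF <- c(sets$AF, take(cls, "trough"))
          }
        }
      }
    }
    lapply(sets, function(v) v[is.finite(v)])
  }

  offsets <- with_seed_if(seed, {
    if (jitter_px > 0) {
      sample(seq(-jitter_px, jitter_px), n_repeats, replace = TRUE)
    } else rep(0L, n_repeats)
  })

  per_repeat <- lapply(offsets, function(d) {
    sets <- tissue_values_one_repeat(d)
    lapply(sets, function(v) {
      if (length(v) >= 2) {
        st <- subtract_threshold(v)
        list(mean = mean(st$values), sd = stats::sd(st$values),
             n = length(st$values))
      } else if (length(v) == 1) {
        list(mean = v, sd = 0, n = 1L)
      } else {
        list(mean = NA_real_, sd = NA_real_, n = 0L)
      }
    })
  })

  out <- NULL
  for (tis in c("NP", "AF", "CEPZ")) {
    means <- vapply(per_repeat, function(r) r[[tis]]$mean, numeric(1))
    sds <- vapply(per_repeat, function(r) r[[tis]]$sd, numeric(1))
    ns <- vapply(per_repeat, function(r) r[[tis]]$n, integer(1))
    if (all(is.na(means))) {
      message("tissue ", tis, " had no assigned pixels in any repeat")
      next
    }
    out <- rbind(out, data.frame(
      tissue = tis, timepoint = timepoint, kind = map$kind,
      mean = mean(means, na.rm = TRUE),
      sd = if (sum(!is.na(means)) > 1) stats::sd(means, na.rm = TRUE) else 0,
      pixel_sd = sqrt(mean(sds^2, na.rm = TRUE)),
      n_pixels = as.integer(round(mean(ns[ns > 0]))),
      n_repeats = n_repeats, stringsAsFactors = FALSE))
  }
  out
}
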