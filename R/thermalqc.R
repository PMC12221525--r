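#' Thermal frame series
#'
#' A time-stamped sequence of 2D temperature grids covering the arena.
#' Rows index y (downward), columns index x (rightward); pixel centres span
#' the full arena.
#'
#' @param frames list of numeric matrices (degC), all the same shape.
#' @param timestamps seconds from assay start, strictly increasing.
#' @param arena_mm arena side lengths in mm.
#' @return An object of class `thermal_frames`.
#' @export
thermal_frames <- function(frames, timestamps, arena_mm = c(170, 170)) {
  stopifnot(is.list(frames), length(frames) == length(timestamps),
            length(frames) >= 1)
  shp <- dim(frames[[1]])
  for (f in frames) {
    if (!is.matrix(f) || !identical(dim(f), shp))
      stop("all frames must be matrices of the same shape")
    if (!all(is.finite(f))) stop("temperatures must be finite")
  }
  if (is.unsorted(timestamps, strictly = TRUE))
    stop("timestamps must be strictly increasing")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 shape = as.integer(shp), arena_mm = as.numeric(arena_mm)),
            class = "thermal_frames")
}

# Internal: stack frames into a rows x cols x nframes array and back.
frames_array <- function(series) {
  array(unlist(series$frames), dim = c(series$shape, length(series$frames)))
}

#' Smooth single-frame thermal-camera spikes
#'
#' A pixel whose value differs from both of its temporal neighbours by more
#' than `jump_C` is replaced by the mean of the neighbours (linear temporal
#' interpolation); in the first and last frame the single neighbour is
#' substituted instead. The pass is repeated until no pixel changes (or
#' `max_iter`), which makes the operation idempotent on its own output.
#'
#' @param series a [thermal_frames()] object.
#' @param jump_C spike detection threshold, degC (default reuses the 3 degC
#'   fluctuation bound of the gradient QC).
#' @param max_iter safety cap on smoothing passes.
#' @return The smoothed series; if a single frame is supplied it is
#'   returned unchanged with a warning.
#' @export
smooth_spikes <- function(series, jump_C = 3, max_iter = 20) {
  stopifnot(inherits(series, "thermal_frames"))
  nf <- length(series$frames)
  if (nf < 2) {
    warning("fewer than 2 frames: returned unchanged")
    return(series)
  }
  a <- frames_array(series)
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    if (nf >= 3) {
      prev <- a[, , 1:(nf - 2), drop = FALSE]
      nxt <- a[, , 3:nf, drop = FALSE]
      mid <- a[, , 2:(nf - 1), drop = FALSE]
      bad <- abs(mid - prev) > jump_C & abs(mid - nxt) > jump_C
      if (any(bad)) {
        mid[bad] <- ((prev + nxt) / 2)[bad]
        a[, , 2:(nf - 1)] <- mid
        changed <- TRUE
      }
    }
    b1 <- abs(a[, , 1] - a[, , 2]) > jump_C
    if (any(b1)) { f <- a[, , 1]; f[b1] <- a[, , 2][b1]; a[, , 1] <- f; changed <- TRUE }
    bn <- abs(a[, , nf] - a[, , nf - 1]) > jump_C
    if (any(bn)) { f <- a[, , nf]; f[bn] <- a[, , nf - 1][bn]; a[, , nf] <- f; changed <- TRUE }
    if (!changed) break
  }
  series$frames <- lapply(seq_len(nf), function(i) a[, , i])
  series
}

#' Gradient quality control
#'
#' Applies the three arena QC rules: (a) in more than 90% of frames at
#' least 5% of pixels must be below 17.5 degC, (b) likewise at least 5% of
#' pixels above 24.5 degC, and (c) no pixel may span more than 3 degC
#' between its minimum and maximum over the whole run. Intended to run on
#' spike-smoothed series.
#'
#' @param series a [thermal_frames()] object.
#' @param cold_C,warm_C tail temperature thresholds, degC.
#' @param tail_frac minimum pixel fraction in each tail.
#' @param frame_frac minimum fraction of frames satisfying each tail rule.
#' @param max_range_C per-pixel max-min bound over the run, degC.
#' @return A list of class `qc_report` with `passed`,
#'   `frac_frames_cold_ok`, `frac_frames_warm_ok`, `max_pixel_range_C` and
#'   `failing_rules`.
#' @export
qc_gradient <- function(series, cold_C = 17.5, warm_C = 24.5,
                        tail_frac = 0.05, frame_frac = 0.90,
                        max_range_C = 3) {
  stopifnot(inherits(series, "thermal_frames"))
  if (length(series$frames) == 0) stop("empty frame series")
  cold_ok <- vapply(series$frames, function(f) mean(f < cold_C) >= tail_frac,
                    logical(1))
  warm_ok <- vapply(series$frames, function(f) mean(f > warm_C) >= tail_frac,
                    logical(1))
  a <- frames_array(series)
  rng <- apply(a, c(1, 2), max) - apply(a, c(1, 2), min)
  failing <- character(0)
  if (!(mean(cold_ok) > frame_frac)) failing <- c(failing, "cold_tail")
  if (!(mean(warm_ok) > frame_frac)) failing <- c(failing, "warm_tail")
  if (!(max(rng) <= max_range_C)) failing <- c(failing, "pixel_range")
  structure(list(passed = length(failing) == 0,
                 frac_frames_cold_ok = mean(cold_ok),
                 frac_frames_warm_ok = mean(warm_ok),
                 max_pixel_range_C = max(rng),
                 failing_rules = failing),
            class = "qc_report")
}

#' Remove the assay burn-in period
#'
#' Drops all samples with `t < burnin_s`: the first two minutes of every
#' assay, during which larvae acclimatise, are excluded from analysis.
#' Works on a [thermal_frames()] series or a track table with a `t` column.
#'
#' @param x a `thermal_frames` object or a track data.frame.
#' @param burnin_s burn-in duration, s.
#' @return The same type with early samples removed (possibly empty).
#' @export
remove_burnin <- function(x, burnin_s = 120) {
  if (inherits(x, "thermal_frames")) {
    keep <- x$timestamps >= burnin_s
    x$frames <- x$frames[keep]
    x$timestamps <- x$timestamps[keep]
    x
  } else if (is.data.frame(x)) {
    stopifnot("t" %in% names(x))
    x[x$t >= burnin_s, , drop = FALSE]
  } else stop("unsupported type")
}
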