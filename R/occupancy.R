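# Temperature binning shared across the preference and ABC modules.
#
# Occupancy is first accumulated in fine 0.1 degC bins spanning 14-28 degC
# (the thermoscape's full range); the analysis windows are 1 degC wide with
# 0.1 degC steps and starts 17.0, 17.1, ..., 24.0 (71 windows spanning
# 17-25 degC). Every window is an exact union of 10 adjacent fine bins, so
# window occupancy is a rolling sum over the fine histogram.

fine_bin_lo <- function() 14
fine_bin_width <- function() 0.1
fine_bin_count <- function() 140L

#' Temperature-window grid
#'
#' Start temperatures of the 1 degC analysis windows: 17.0 to 24.0 degC in
#' 0.1 degC steps (71 windows, covering 17-25 degC).
#'
#' @return Numeric vector of window start temperatures, degC.
#' @export
tp_windows <- function() seq.int(170L, 240L) / 10

#' Occupancy histogram from a temperature series
#'
#' Accumulates `dt` seconds per sample into the fine 0.1 degC bins;
#' temperatures outside 14-28 degC are clamped to the edge bins.
#'
#' @param temp_C temperatures, degC.
#' @param dt seconds represented by each sample.
#' @return Numeric vector of length 140 (seconds per fine bin).
#' @export
occupancy_from_temps <- function(temp_C, dt = 0.1) {
  idx <- floor((temp_C - fine_bin_lo()) / fine_bin_width()) + 1
  idx <- pmin(pmax(idx, 1), fine_bin_count())
  occ <- numeric(fine_bin_count())
  tb <- tabulate(idx, nbins = fine_bin_count())
  occ + tb * dt
}

#' Window occupancy from fine-bin occupancy
#'
#' Sums each 1 degC window's 10 constituent fine bins. Accepts a vector
#' (one histogram) or a matrix (rows = agents/larvae).
#'
#' @param occ_fine length-140 vector or n x 140 matrix of fine-bin seconds.
#' @return Length-71 vector or n x 71 matrix of seconds per window.
#' @export
window_occupancy <- function(occ_fine) {
  one <- function(v) {
    cs <- c(0, cumsum(v))
    i0 <- 30 + seq_len(71)        # first fine bin of window w is 30 + w
    cs[i0 + 10] - cs[i0]
  }
  if (is.matrix(occ_fine)) {
    stopifnot(ncol(occ_fine) == fine_bin_count())
    out <- t(apply(occ_fine, 1, one))
    colnames(out) <- NULL
    out
  } else {
    stopifnot(length(occ_fine) == fine_bin_count())
    one(occ_fine)
  }
}
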