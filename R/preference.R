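# Temperature preference: electivity-style index against a
# random-movement null, Tp_opt / Tp_breadth summaries, and cross-species
# window-wise comparisons.

#' Simulate the random-movement null cohort for a run
#'
#' Temperature-blind agents parameterized by the run's average larval
#' speed and turn rate: uniform start in the centred square covering 33%
#' of the arena side, uniform heading, constant speed, Poisson turning at
#' the given rate with wrapped-normal heading changes, reflective walls.
#' The burn-in is discarded as for real runs.
#'
#' @param run_speed_mm_s average larval crawl speed of the run, mm/s.
#' @param run_turn_rate_hz average larval reorientation rate of the run,
#'   Hz (accepted head-sweep events per second).
#' @param field a [thermal_frames()] series (QC-passed) or a
#'   [thermoscape_config()].
#' @param n number of null agents.
#' @param duration_s,burnin_s assay timing, s.
#' @param seed RNG seed.
#' @param turn_sigma_deg SD of the heading-change distribution, degrees.
#' @return A list of class `null_occupancy` with `window_s` (expected
#'   seconds per temperature window, per agent), `occ` (per-agent window
#'   occupancy matrix) and `n`.
#' @export
simulate_null_agents <- function(run_speed_mm_s, run_turn_rate_hz, field,
                                 n = 1000, duration_s = 1200,
                                 burnin_s = 120, seed = NULL,
                                 turn_sigma_deg = 60) {
  if (n < 1) stop("at least one null agent is required")
  stopifnot(run_speed_mm_s > 0, run_turn_rate_hz > 0)
  model <- agent_model(T_hsp = 21, s = 0, speed_mm_s = run_speed_mm_s,
                       base_turn_rate_hz = run_turn_rate_hz,
                       turn_sigma_deg = turn_sigma_deg)
  cohort <- simulate_cohort(model, field, n, duration_s = duration_s,
                            burnin_s = burnin_s, seed = seed)
  occ <- window_occupancy(cohort$occ_fine)
  structure(list(window_s = colMeans(occ), occ = occ, n = n),
            class = "null_occupancy")
}

#' Per-larva observed window occupancy
#'
#' Seconds spent per 1 degC temperature window for each larva, from the
#' assigned per-sample temperatures (after burn-in removal).
#'
#' @param tracks track data.frame with a `temp_C` column.
#' @param dt seconds per sample.
#' @return A matrix (larvae x 71 windows) with rownames the larva ids.
#' @export
observed_occupancy <- function(tracks, dt = 0.1) {
  stopifnot("temp_C" %in% names(tracks))
  sp <- split(tracks$temp_C, tracks$id)
  occ <- t(vapply(sp, function(tc)
    window_occupancy(occupancy_from_temps(tc, dt = dt)), numeric(71)))
  rownames(occ) <- names(sp)
  occ
}

#' Temperature-preference profile
#'
#' The electivity-style index per window:
#' `tp = (obs - exp) / (obs + exp)`, bounded in \[-1, 1\]; windows with
#' `obs = exp = 0` are set to 0 (no evidence either way). `obs` may be a
#' vector (one larva) or a matrix (larvae x windows); `exp` is the null
#' expected seconds per window.
#'
#' @param observed_window_s observed seconds per window (vector or matrix).
#' @param null_window_s expected seconds per window under random movement.
#' @return Preference values with the same shape as `observed_window_s`.
#' @export
tp_profile <- function(observed_window_s, null_window_s) {
  if (is.matrix(observed_window_s)) {
    if (ncol(observed_window_s) != length(null_window_s))
      stop("window grids do not match")
    ex <- matrix(null_window_s, nrow = nrow(observed_window_s),
                 ncol = length(null_window_s), byrow = TRUE)
  } else {
    if (length(observed_window_s) != length(null_window_s))
      stop("window grids do not match")
    ex <- null_window_s
  }
  tot <- observed_window_s + ex
  tp <- (observed_window_s - ex) / tot
  tp[tot == 0] <- 0
  tp
}

#' Peak temperature preference (Tp_opt)
#'
#' The window start whose across-larvae mean preference is maximal; ties
#' go to the coolest window.
#'
#' @param profiles matrix of per-larva preference profiles (larvae x 71).
#' @return A list with `tp_opt_C` and `tp_opt_mean`.
#' @export
tp_opt <- function(profiles) {
  if (is.vector(profiles)) profiles <- matrix(profiles, nrow = 1)
  stopifnot(nrow(profiles) >= 1, ncol(profiles) == 71)
  m <- colMeans(profiles)
  i <- which.max(m)  # first maximum = coolest window on ties
  list(tp_opt_C = tp_windows()[i], tp_opt_mean = m[i])
}

#' Preference breadth (Tp_breadth) via exact sign tests
#'
#' Per window, an exact two-sided sign test (binomial test on the signs of
#' the nonzero preference values) against a median of zero, with
#' Benjamini-Hochberg correction across the 71 windows. Significant
#' positive windows are strong preferences, significant negative windows
#' aversive; the breadth is the contiguous run of non-aversive windows
#' containing Tp_opt.
#'
#' @param profiles matrix of per-larva preference profiles (larvae x 71).
#' @param alpha significance level after correction.
#' @return A list of class `tp_summary`: `tp_opt_C`, `tp_opt_mean`,
#'   `breadth_low_C`, `breadth_high_C`, `strong_windows`,
#'   `aversive_windows`, `p_adj`.
#' @export
tp_breadth <- function(profiles, alpha = 0.05) {
  if (is.vector(profiles)) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) < 6)
    warning("fewer than 6 larvae: sign tests have very little power")
  ws <- tp_windows()
  p <- apply(profiles, 2, function(x) {
    nz <- x[x != 0]
    if (length(nz) == 0) return(1)
    binom.test(sum(nz > 0), length(nz))$p.value
  })
  p_adj <- p.adjust(p, method = "BH")
  direction <- apply(profiles, 2, function(x) sign(sum(x > 0) - sum(x < 0)))
  strong <- p_adj < alpha & direction > 0
  aversive <- p_adj < alpha & direction < 0
  opt <- tp_opt(profiles)
  iopt <- which(abs(ws - opt$tp_opt_C) < 1e-9)
  runs <- rle(!aversive)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  lo <- hi <- NA_real_
  if (!aversive[iopt]) {
    k <- which(starts <= iopt & ends >= iopt & runs$values)
    lo <- ws[starts[k]]; hi <- ws[ends[k]]
  }
  structure(list(tp_opt_C = opt$tp_opt_C, tp_opt_mean = opt$tp_opt_mean,
                 breadth_low_C = lo, breadth_high_C = hi,
                 strong_windows = ws[strong],
                 aversive_windows = ws[aversive],
                 p_adj = p_adj),
            class = "tp_summary")
}

#' Window-wise rank-sum comparison of two groups of profiles
#'
#' Mann-Whitney U test per temperature window (preference values are not
#' normally distributed), Benjamini-Hochberg corrected across windows.
#'
#' @param profiles_A,profiles_B preference matrices (larvae x 71).
#' @param alternative passed to [stats::wilcox.test()].
#' @return data.frame with `window_C`, `p`, `p_adj`.
#' @export
compare_profiles_mwu <- function(profiles_A, profiles_B,
                                 alternative = "two.sided") {
  stopifnot(nrow(profiles_A) >= 1, nrow(profiles_B) >= 1,
            ncol(profiles_A) == ncol(profiles_B))
  p <- vapply(seq_len(ncol(profiles_A)), function(w) {
    a <- profiles_A[, w]; b <- profiles_B[, w]
    if (all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) return(1)
    suppressWarnings(wilcox.test(a, b, alternative = alternative)$p.value)
  }, numeric(1))
  data.frame(window_C = tp_windows(), p = p,
             p_adj = p.adjust(p, method = "BH"))
}
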