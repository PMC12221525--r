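# Fine-scale navigation metrics: windowed velocity, multi-window
# tortuosity, head-sweep detection, temperature-zone resampling contrasts
# and linear temperature trends.

#' Temperature zone definitions
#'
#' The arena's range split into equal thirds: cool \[17.00, 19.67), mid
#' \[19.67, 22.33), warm \[22.33, 25.00\] degC.
#'
#' @return Named list of `c(low, high)` zone bounds, degC.
#' @export
zone_def <- function() {
  list(cool = c(17, 19 + 2 / 3), mid = c(19 + 2 / 3, 22 + 1 / 3),
       warm = c(22 + 1 / 3, 25))
}

#' Assign temperatures to zones
#'
#' @param temp_C temperatures, degC.
#' @return Factor with levels cool/mid/warm (NA outside 17-25 degC).
#' @export
assign_zone <- function(temp_C) {
  z <- zone_def()
  cut(temp_C, breaks = c(z$cool[1], z$mid[1], z$warm[1], z$warm[2]),
      labels = c("cool", "mid", "warm"), right = FALSE,
      include.lowest = TRUE)
}

# Internal: per-track cumulative path length (mm) at each sample.
cumulative_path <- function(x, y) c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))

#' Windowed crawl velocity
#'
#' Velocity at frame i is the path length over the centred `window_s`
#' window divided by the window's duration; edge windows are truncated and
#' flagged as partial. Body-length-normalized velocity uses twice the
#' per-larva median head-to-centroid distance as the body length.
#'
#' @param track one larva's rows of a track table, frame-ordered.
#' @param window_s window size, s.
#' @return data.frame with `frame`, `t`, `v_mm_s`, `v_bl_s`, `partial`;
#'   empty if the track is shorter than the window.
#' @export
windowed_velocity <- function(track, window_s = 3) {
  n <- nrow(track)
  empty <- data.frame(frame = integer(0), t = numeric(0),
                      v_mm_s = numeric(0), v_bl_s = numeric(0),
                      partial = logical(0))
  if (n < 2 || max(track$t) - min(track$t) < window_s) return(empty)
  track <- track[order(track$frame), , drop = FALSE]
  dt <- median(diff(track$t))
  h <- round(window_s / 2 / dt)
  cum <- cumulative_path(track$x, track$y)
  i <- seq_len(n)
  lo <- pmax(i - h, 1); hi <- pmin(i + h, n)
  v <- (cum[hi] - cum[lo]) / (track$t[hi] - track$t[lo])
  bl <- 2 * median(sqrt((track$head_x - track$x)^2 +
                          (track$head_y - track$y)^2))
  data.frame(frame = track$frame, t = track$t, v_mm_s = v,
             v_bl_s = if (is.finite(bl) && bl > 0) v / bl else NA_real_,
             partial = lo > i - h | hi < i + h)
}

#' Windowed path tortuosity
#'
#' For each window size, tortuosity at frame i is
#' `1 - net displacement / accumulated path` over the centred window
#' (0 = straight, -> 1 = returns on itself); windows with zero accumulated
#' path are undefined and excluded. The final value is the mean over the
#' available window sizes.
#'
#' @param track one larva's rows of a track table, frame-ordered.
#' @param windows_s window sizes, s.
#' @return data.frame with `frame`, `t`, `tortuosity`, `partial`.
#' @export
windowed_tortuosity <- function(track, windows_s = c(2, 5, 10, 20, 30)) {
  n <- nrow(track)
  if (n < 2) return(data.frame(frame = integer(0), t = numeric(0),
                               tortuosity = numeric(0), partial = logical(0)))
  track <- track[order(track$frame), , drop = FALSE]
  dt <- median(diff(track$t))
  cum <- cumulative_path(track$x, track$y)
  i <- seq_len(n)
  vals <- matrix(NA_real_, n, length(windows_s))
  partial <- rep(FALSE, n)
  for (k in seq_along(windows_s)) {
    h <- round(windows_s[k] / 2 / dt)
    lo <- pmax(i - h, 1); hi <- pmin(i + h, n)
    partial <- partial | lo > i - h | hi < i + h
    path <- cum[hi] - cum[lo]
    net <- sqrt((track$x[hi] - track$x[lo])^2 +
                  (track$y[hi] - track$y[lo])^2)
    v <- 1 - net / path
    v[path == 0] <- NA_real_
    vals[, k] <- v
  }
  data.frame(frame = track$frame, t = track$t,
             tortuosity = rowMeans(vals, na.rm = TRUE), partial = partial)
}

#' Detect head sweeps from a body-bend series
#'
#' A head sweep is a body-bend excursion whose magnitude exceeds
#' `init_deg` and subsequently returns to within `straight_deg` of a
#' straight posture. Peaks closer in time than `buffer_s` are merged,
#' keeping the larger; a sweep is accepted iff its peak exceeds
#' `keep_deg`.
#'
#' @param bend_deg body-bend angles, degrees (sign ignored).
#' @param t sample times, s (default 10 Hz from 0).
#' @param init_deg minimum excursion to qualify as a sweep, degrees.
#' @param straight_deg return-to-straight threshold, degrees.
#' @param buffer_s minimum separation between sweeps, s.
#' @param keep_deg acceptance threshold on the peak, degrees.
#' @return data.frame with `t_peak`, `peak_deg`, `accepted`.
#' @export
detect_head_sweeps <- function(bend_deg, t = NULL, init_deg = 30,
                               straight_deg = 10, buffer_s = 2,
                               keep_deg = 45) {
  b <- abs(bend_deg)
  if (is.null(t)) t <- (seq_along(b) - 1) / 10
  tp <- numeric(0); pk <- numeric(0)
  in_sweep <- FALSE; peak <- -Inf; peak_t <- NA_real_
  for (i in seq_along(b)) {
    if (!in_sweep) {
      if (b[i] > init_deg) { in_sweep <- TRUE; peak <- b[i]; peak_t <- t[i] }
    } else {
      if (b[i] > peak) { peak <- b[i]; peak_t <- t[i] }
      if (b[i] < straight_deg) {  # completed: returned to straight posture
        tp <- c(tp, peak_t); pk <- c(pk, peak)
        in_sweep <- FALSE; peak <- -Inf
      }
    }
  }
  # merge peaks closer than the buffer, keeping the larger
  while (length(tp) > 1 && any(diff(tp) < buffer_s)) {
    j <- which(diff(tp) < buffer_s)[1]
    drop <- if (pk[j] >= pk[j + 1]) j + 1 else j
    tp <- tp[-drop]; pk <- pk[-drop]
  }
  data.frame(t_peak = tp, peak_deg = pk, accepted = pk > keep_deg)
}

#' Resampled between-zone metric differences
#'
#' For each contrast (warm-cool, mid-cool, warm-mid), draws `n_draws`
#' independent pairs (one value from each zone, uniformly with
#' replacement) and records the difference; empty zones skip their
#' contrasts with a warning.
#'
#' @param values metric values (velocity, tortuosity, sweep size, ...).
#' @param zones zone labels aligned with `values` (cool/mid/warm).
#' @param n_draws number of resampled differences per contrast.
#' @param seed RNG seed.
#' @return A list with `draws` (named list of difference vectors) and
#'   `summary` (data.frame of contrast, mean, q25, q75).
#' @export
zone_differences <- function(values, zones, n_draws = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  zones <- as.character(zones)
  pools <- split(values, zones)
  contrasts <- list(warm_cool = c("warm", "cool"),
                    mid_cool = c("mid", "cool"),
                    warm_mid = c("warm", "mid"))
  draws <- list()
  for (nm in names(contrasts)) {
    a <- contrasts[[nm]][1]; bz <- contrasts[[nm]][2]
    if (is.null(pools[[a]]) || is.null(pools[[bz]]) ||
        length(pools[[a]]) == 0 || length(pools[[bz]]) == 0) {
      warning("empty zone: skipping contrast ", nm)
      next
    }
    pa <- pools[[a]]; pb <- pools[[bz]]
    draws[[nm]] <- pa[sample.int(length(pa), n_draws, replace = TRUE)] -
      pb[sample.int(length(pb), n_draws, replace = TRUE)]
  }
  summary <- do.call(rbind, lapply(names(draws), function(nm)
    data.frame(contrast = nm, mean = mean(draws[[nm]]),
               q25 = unname(quantile(draws[[nm]], 0.25)),
               q75 = unname(quantile(draws[[nm]], 0.75)))))
  list(draws = draws, summary = summary)
}

#' Welch t-test between two resampled difference distributions
#'
#' @param draws_a,draws_b difference vectors from [zone_differences()].
#' @return The `htest` result of [stats::t.test()] (Welch).
#' @export
zone_diff_ttest <- function(draws_a, draws_b) t.test(draws_a, draws_b)

#' Per-group linear trends of a metric across temperature
#'
#' Ordinary least squares of the metric on temperature within each group,
#' with t-based 95% confidence intervals for the slope.
#'
#' @param values metric values.
#' @param temp_C temperatures, degC.
#' @param group group labels (species, clade, ...).
#' @return data.frame with one row per group: slope, intercept, CI bounds,
#'   and R squared; groups orderable by slope.
#' @export
fit_temperature_trend <- function(values, temp_C, group) {
  group <- as.character(group)
  out <- lapply(unique(group), function(g) {
    v <- values[group == g]; tc <- temp_C[group == g]
    keep <- is.finite(v) & is.finite(tc)
    v <- v[keep]; tc <- tc[keep]
    if (length(v) < 3) stop("fewer than 3 samples in group ", g)
    if (var(tc) == 0) stop("constant temperature in group ", g)
    fit <- lm(v ~ tc)
    ci <- confint(fit, "tc", level = 0.95)
    data.frame(group = g, slope = unname(coef(fit)[2]),
               intercept = unname(coef(fit)[1]),
               ci_low = ci[1], ci_high = ci[2],
               r_squared = summary(fit)$r.squared)
  })
  res <- do.call(rbind, out)
  res[order(res$slope), , drop = FALSE]
}

#' Pearson correlation between velocity and tortuosity
#'
#' @param v,tort aligned metric vectors.
#' @return Pearson's r.
#' @export
correlate <- function(v, tort) cor(v, tort, use = "complete.obs")

#' Rank-sum clade comparison per temperature zone
#'
#' Wilcoxon rank-sum test of a metric between two clades within each
#' zone, Benjamini-Hochberg corrected across zones.
#'
#' @param values metric values.
#' @param clade two-level clade labels aligned with `values`.
#' @param zone zone labels aligned with `values`.
#' @return data.frame with `zone`, `p`, `p_adj`.
#' @export
clade_compare <- function(values, clade, zone) {
  clade <- as.character(clade); zone <- as.character(zone)
  lv <- unique(clade)
  stopifnot(length(lv) == 2)
  zs <- intersect(c("cool", "mid", "warm"), unique(zone))
  p <- vapply(zs, function(z) {
    a <- values[zone == z & clade == lv[1]]
    b <- values[zone == z & clade == lv[2]]
    suppressWarnings(wilcox.test(a, b)$p.value)
  }, numeric(1))
  data.frame(zone = zs, p = unname(p),
             p_adj = p.adjust(unname(p), method = "BH"))
}
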