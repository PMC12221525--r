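# Synthetic assay generator: thermal frames and larval tracks with known
# ground truth, written in the pipeline's input formats so that every
# downstream stage can be tested without raw video data.

#' Synthetic assay configuration
#'
#' Defines the emulated assay: a 20-minute, 10 Hz recording of larvae on
#' the 170 x 170 mm patchy-gradient arena, with configurable track
#' fragmentation, larva-larva clashes, non-movers and thermal-camera
#' spikes.
#'
#' @param n_larvae number of larvae.
#' @param agent_model an [agent_model()] generating locomotion, or
#'   `"blind"` for temperature-blind larvae.
#' @param px_per_mm camera scale used when writing files.
#' @param frame_rate_hz tracking rate, Hz.
#' @param duration_s assay duration, s.
#' @param clash_rate expected clash events per track.
#' @param fragment_rate expected tracking gaps per track.
#' @param nonmover_frac fraction of larvae that barely move.
#' @param spike_rate thermal-spike probability per pixel-frame.
#' @param noise_sd Gaussian pixel noise SD on thermal frames, degC.
#' @param seed RNG seed; identical seed and config give identical output.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_larvae = 20, agent_model = "blind",
                         px_per_mm = 4, frame_rate_hz = 10,
                         duration_s = 1200, clash_rate = 0,
                         fragment_rate = 0, nonmover_frac = 0,
                         spike_rate = 0, noise_sd = 0, seed = 1) {
  stopifnot(n_larvae >= 0, px_per_mm > 0, frame_rate_hz > 0,
            duration_s > 0, clash_rate >= 0, fragment_rate >= 0,
            nonmover_frac >= 0, nonmover_frac <= 1, spike_rate >= 0,
            noise_sd >= 0)
  if (identical(agent_model, "blind"))
    agent_model <- agent_model(s = 0)
  stopifnot(inherits(agent_model, "agent_model"))
  structure(list(n_larvae = n_larvae, agent_model = agent_model,
                 px_per_mm = px_per_mm, frame_rate_hz = frame_rate_hz,
                 duration_s = duration_s, clash_rate = clash_rate,
                 fragment_rate = fragment_rate,
                 nonmover_frac = nonmover_frac, spike_rate = spike_rate,
                 noise_sd = noise_sd, seed = seed),
            class = "synth_config")
}

#' Generate synthetic thermal frames
#'
#' One frame per 20 s of simulated time (3 frames/min): the analytic
#' thermoscape field plus optional Gaussian pixel noise plus injected
#' single-pixel, single-frame spikes of +8 to +15 degC at `spike_rate`
#' per pixel-frame.
#'
#' @param config a [synth_config()].
#' @param gradient a [thermoscape_config()].
#' @param nrow,ncol thermal-camera resolution.
#' @param frame_period_s seconds between frames.
#' @return A [thermal_frames()] series with a `spikes` attribute recording
#'   the injected spike coordinates (frame, row, col, delta_C).
#' @export
make_thermal_frames <- function(config, gradient, nrow = 120, ncol = 160,
                                frame_period_s = 20) {
  nf <- floor(config$duration_s / frame_period_s)
  if (nf <= 0) stop("configuration yields no frames")
  set.seed(config$seed + 101)
  base <- thermoscape_grid(gradient, nrow = nrow, ncol = ncol)
  spikes <- data.frame(frame = integer(0), row = integer(0),
                       col = integer(0), delta_C = numeric(0))
  frames <- vector("list", nf)
  for (i in seq_len(nf)) {
    f <- base
    if (config$noise_sd > 0)
      f <- f + matrix(rnorm(nrow * ncol, sd = config$noise_sd), nrow, ncol)
    if (config$spike_rate > 0) {
      hit <- which(runif(nrow * ncol) < config$spike_rate)
      if (length(hit)) {
        delta <- runif(length(hit), 8, 15)
        f[hit] <- f[hit] + delta
        spikes <- rbind(spikes, data.frame(
          frame = i, row = (hit - 1) %% nrow + 1,
          col = (hit - 1) %/% nrow + 1, delta_C = delta))
      }
    }
    frames[[i]] <- f
  }
  out <- thermal_frames(frames, (seq_len(nf) - 1) * frame_period_s,
                        arena_mm = gradient$arena_mm)
  attr(out, "spikes") <- spikes
  out
}

# Internal: split one output track: samples with frame >= at get new_id;
# samples with frame in [at, resume) are dropped (resume = at for clashes).
split_track <- function(tracks, id, at, resume, new_id) {
  rows <- tracks$id == id
  drop <- rows & tracks$frame >= at & tracks$frame < resume
  tracks$id[rows & tracks$frame >= resume] <- new_id
  tracks[!drop, , drop = FALSE]
}

#' Generate synthetic larval tracks with ground truth
#'
#' Movers follow the configured thermotaxis agent model; a `nonmover_frac`
#' fraction instead jitter in place below the movement thresholds
#' (cumulative path < 0.5 mm and net displacement < 0.3 mm). Clash events
#' terminate two tracks on the same frame and restart both under new ids
#' one frame later; fragmentation drops a 2-10 s window of samples and
#' restarts the remainder under a new id.
#'
#' @param config a [synth_config()].
#' @param gradient a [thermoscape_config()].
#' @return A list with `tracks` (raw FIMtrack-style table, mm/seconds),
#'   `truth_tracks` (the unbroken ground-truth table), `larvae`
#'   (per-larva generating parameters) and `id_map` (raw id -> true id
#'   with the breakage cause).
#' @export
make_tracks <- function(config, gradient) {
  empty <- data.frame(id = integer(0), frame = integer(0), t = numeric(0),
                      x = numeric(0), y = numeric(0), head_x = numeric(0),
                      head_y = numeric(0), bend_deg = numeric(0))
  if (config$n_larvae == 0) {
    return(list(tracks = empty, truth_tracks = empty,
                larvae = data.frame(true_id = integer(0),
                                    nonmover = logical(0)),
                id_map = data.frame(raw_id = integer(0),
                                    true_id = integer(0),
                                    cause = character(0))))
  }
  set.seed(config$seed + 202)
  n <- config$n_larvae
  n_non <- round(config$nonmover_frac * n)
  n_mov <- n - n_non
  dt <- 1 / config$frame_rate_hz
  n_frames <- round(config$duration_s / dt)
  W <- gradient$arena_mm[1]; H <- gradient$arena_mm[2]

  truth <- empty
  if (n_mov > 0) {
    cohort <- simulate_cohort(config$agent_model, gradient, n_mov,
                              duration_s = config$duration_s,
                              burnin_s = 0, record_tracks = TRUE)
    truth <- cohort_tracks(cohort)
  }
  if (n_non > 0) {
    for (j in seq_len(n_non)) {
      x0 <- W / 2 + (runif(1) - 0.5) * 0.33 * W
      y0 <- H / 2 + (runif(1) - 0.5) * 0.33 * H
      th <- runif(1, 0, 2 * pi)
      # a few sub-threshold twitches; cumulative path stays below 0.5 mm
      xs <- rep(x0, n_frames + 1); ys <- rep(y0, n_frames + 1)
      twitch_at <- sort(sample(seq_len(n_frames), 3))
      for (ti in twitch_at) {
        a <- runif(1, 0, 2 * pi)
        xs[(ti + 1):(n_frames + 1)] <- xs[(ti + 1):(n_frames + 1)] +
          0.05 * cos(a)
        ys[(ti + 1):(n_frames + 1)] <- ys[(ti + 1):(n_frames + 1)] +
          0.05 * sin(a)
      }
      truth <- rbind(truth, data.frame(
        id = as.integer(n_mov + j), frame = 0:n_frames,
        t = (0:n_frames) * dt,
        x = xs, y = ys, head_x = xs + 2 * cos(th), head_y = ys + 2 * sin(th),
        bend_deg = abs(rnorm(n_frames + 1, 0, 2))))
    }
  }
  larvae <- data.frame(true_id = seq_len(n),
                       nonmover = c(rep(FALSE, n_mov), rep(TRUE, n_non)),
                       T_hsp = config$agent_model$T_hsp,
                       s = ifelse(c(rep(FALSE, n_mov), rep(TRUE, n_non)),
                                  NA_real_, config$agent_model$s))

  raw <- truth
  id_map <- data.frame(raw_id = seq_len(n), true_id = seq_len(n),
                       cause = "original")
  next_id <- n + 1L

  # clash events: two live tracks end on the same frame, restart +1 frame
  n_clash <- if (config$clash_rate > 0)
    stats::rpois(1, config$clash_rate * n / 2) else 0
  for (e in seq_len(n_clash)) {
    ids <- unique(raw$id)
    if (length(ids) < 2) break
    pair <- sample(ids, 2)
    f_rng <- range(raw$frame[raw$id %in% pair])
    lo <- max(tapply(raw$frame, raw$id, min)[as.character(pair)]) + 20
    hi <- min(tapply(raw$frame, raw$id, max)[as.character(pair)]) - 20
    if (!is.finite(lo) || !is.finite(hi) || hi <= lo) next
    f <- sample(seq(lo, hi), 1)
    for (id in pair) {
      tid <- id_map$true_id[id_map$raw_id == id]
      raw <- split_track(raw, id, f + 1, f + 1, next_id)
      id_map <- rbind(id_map, data.frame(raw_id = next_id, true_id = tid,
                                         cause = "clash"))
      next_id <- next_id + 1L
    }
  }

  # fragmentation: drop a 2-10 s gap, rest of the track gets a new id
  for (id in unique(raw$id)) {
    n_gaps <- if (config$fragment_rate > 0)
      stats::rpois(1, config$fragment_rate) else 0
    cur <- id
    for (gi in seq_len(n_gaps)) {
      fr <- raw$frame[raw$id == cur]
      if (length(fr) < 3 * config$frame_rate_hz * 10) break
      gap_len <- round(runif(1, 2, 10) * config$frame_rate_hz)
      at <- sample(seq(min(fr) + 10, max(fr) - gap_len - 10), 1)
      tid <- id_map$true_id[id_map$raw_id == cur]
      raw <- split_track(raw, cur, at, at + gap_len, next_id)
      id_map <- rbind(id_map, data.frame(raw_id = next_id, true_id = tid,
                                         cause = "fragment"))
      cur <- next_id
      next_id <- next_id + 1L
    }
  }
  raw <- raw[order(raw$id, raw$frame), , drop = FALSE]
  rownames(raw) <- NULL
  list(tracks = raw, truth_tracks = truth, larvae = larvae,
       id_map = id_map)
}
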