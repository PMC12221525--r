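# Shared fixture builders; everything is generated in code.

# A minimal track table from coordinate vectors (10 Hz by default).
fix_track <- function(id, x, y, t0 = 0, dt = 0.1, head_x = x, head_y = y,
                      bend = 0) {
  n <- length(x)
  data.frame(id = as.integer(id), frame = round(t0 / dt) + seq_len(n) - 1L,
             t = t0 + (seq_len(n) - 1) * dt,
             x = x, y = y, head_x = head_x, head_y = head_y,
             bend_deg = rep_len(bend, n))
}

# A uniform-temperature frame series.
fix_uniform_frames <- function(temps, timestamps = NULL, nrow = 6,
                               ncol = 8, arena_mm = c(170, 170)) {
  if (is.null(timestamps)) timestamps <- (seq_along(temps) - 1) * 20
  thermal_frames(lapply(temps, function(v) matrix(v, nrow, ncol)),
                 timestamps, arena_mm = arena_mm)
}

# Frame series from a single pixel's time series (all pixels equal).
fix_pixel_series <- function(values, ...) fix_uniform_frames(values, ...)

# Pure-R cohort simulator with the same RNG draw order as the compiled
# stepper; used for exact-equality cross-checks on tiny cases.
ref_simulate <- function(model, field, n, n_steps, seed) {
  set.seed(seed)
  W <- field$arena_mm[1]; H <- field$arena_mm[2]
  x0 <- W / 2 + (runif(n) - 0.5) * 0.33 * W
  y0 <- H / 2 + (runif(n) - 0.5) * 0.33 * H
  th0 <- runif(n, 0, 2 * pi)
  state <- list(x = x0, y = y0, theta = th0, A_O = rep(0, n),
                T_prev = thermoscape_at(x0, y0, field),
                p_turn = rep(min(max(model$dt * model$base_turn_rate_hz, 0),
                                 1), n))
  xs <- matrix(NA_real_, n, n_steps + 1)
  ys <- matrix(NA_real_, n, n_steps + 1)
  xs[, 1] <- x0; ys[, 1] <- y0
  for (m in seq_len(n_steps)) {
    state <- step_agents(state, model, field)
    xs[, m + 1] <- state$x; ys[, m + 1] <- state$y
  }
  list(x = xs, y = ys)
}

# An 8-tip dated-style tree (fixed topology, branch lengths in Myr).
fix_tree8 <- function() {
  ape::read.tree(text = paste0(
    "(((t1:1,t2:1):2,(t3:1.5,t4:1.5):1.5):3,",
    "((t5:2,t6:2):2,(t7:1,t8:1):3):2);"))
}
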