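#' Cross-inhibition thermotaxis agent model
#'
#' Parameters of the run-and-turn virtual larva. The thermosensory side is
#' the cross-inhibition model: cool- and warm-avoidance circuit weights are
#' linear and symmetric in temperature around the homeostatic set point
#' `T_hsp` with sensitivity slope `s` (see [sensor_weights()]); their
#' difference is the gain `G(T) = 2 s (T_hsp - T)` feeding a Weber-Fechner
#' perception signal `A_O` with decay `c_O` (see [update_perception()]).
#' Locomotion is a constant-speed run-and-turn walk whose turning
#' probability per step is `clip(dt * base_turn_rate_hz * (1 - turn_gain *
#' A_O), 0, 1)`: negative `A_O` (aversive context) raises turning, positive
#' suppresses it. `s = 0` gives a temperature-blind agent.
#'
#' `turn_gain` converts the dimensionless perception signal (order 1e-5 to
#' 1e-3 on this arena for the slope ranges explored) into an order-one
#' modulation of the turning rate; the default 20000 yields clear
#' klinokinetic bias across the default slope grid while `s = 0` remains
#' an unbiased walk.
#'
#' @param T_hsp homeostatic set point, degC.
#' @param s sensitivity slope, 1/degC; `s = 0` is temperature-blind.
#' @param c_O perception decay coefficient (1/s).
#' @param dt integration step, s (matches the 10 Hz tracking).
#' @param speed_mm_s constant crawl speed, mm/s.
#' @param base_turn_rate_hz baseline turning-event rate, Hz.
#' @param turn_gain coupling of `A_O` to the turning probability.
#' @param turn_sigma_deg SD of the wrapped-normal heading change, degrees.
#' @return An object of class `agent_model`.
#' @export
agent_model <- function(T_hsp = 21, s = 0.003, c_O = 1, dt = 0.1,
                        speed_mm_s = 0.8, base_turn_rate_hz = 0.3,
                        turn_gain = 20000, turn_sigma_deg = 60) {
  stopifnot(s >= 0, c_O >= 0, dt > 0, speed_mm_s >= 0,
            base_turn_rate_hz >= 0, turn_sigma_deg >= 0)
  structure(list(T_hsp = T_hsp, s = s, c_O = c_O, dt = dt,
                 speed_mm_s = speed_mm_s,
                 base_turn_rate_hz = base_turn_rate_hz,
                 turn_gain = turn_gain, turn_sigma_deg = turn_sigma_deg),
            class = "agent_model")
}

#' Cool- and warm-circuit sensor weights
#'
#' `w_cool = 0.5 + s (T - T_hsp)` and `w_warm = 0.5 + s (T_hsp - T)`, both
#' clamped to \[0, 1\]. The two weights are equal (0.5) exactly at the set
#' point; where unclamped they sum to 1.
#'
#' @param T temperature, degC (vectorized).
#' @param s sensitivity slope, 1/degC.
#' @param T_hsp homeostatic set point, degC.
#' @return A list with components `w_cool` and `w_warm`.
#' @export
sensor_weights <- function(T, s, T_hsp) {
  stopifnot(s >= 0)
  clamp01 <- function(w) pmin(pmax(w, 0), 1)
  list(w_cool = clamp01(0.5 + s * (T - T_hsp)),
       w_warm = clamp01(0.5 + s * (T_hsp - T)))
}

#' Thermosensory gain
#'
#' `G(T) = w_warm - w_cool = 2 s (T_hsp - T)` (unclamped form); odd
#' symmetric about the set point.
#'
#' @inheritParams sensor_weights
#' @return Gain values (dimensionless).
#' @export
gain <- function(T, s, T_hsp) 2 * s * (T_hsp - T)

#' One forward-Euler update of the perception signal
#'
#' The perception dynamics follow a Weber-Fechner law with decay:
#' `dA_O/dt = -c_O A_O + G(T) * (dT/dt) / T`, temperature in degC as
#' printed. Discretized as
#' `A_O' = A_O + dt * (-c_O * A_O + G(T_curr) * (T_curr - T_prev) / (dt * T_curr))`.
#'
#' @param A_O current perception signal.
#' @param T_prev,T_curr sensed temperatures at the previous and current
#'   step, degC (must be positive).
#' @param dt time step, s.
#' @param c_O decay coefficient.
#' @param s sensitivity slope.
#' @param T_hsp homeostatic set point, degC.
#' @return Updated `A_O`.
#' @export
update_perception <- function(A_O, T_prev, T_curr, dt, c_O, s, T_hsp) {
  if (dt <= 0) stop("dt must be positive")
  stopifnot(all(T_prev > 0), all(T_curr > 0))
  A_O + dt * (-c_O * A_O +
                gain(T_curr, s, T_hsp) * (T_curr - T_prev) / (dt * T_curr))
}

# Internal: nearest-in-time frame index for each query time (ties broken
# toward the earlier frame). Timestamps must be sorted increasing.
nearest_frame_index <- function(t, timestamps) {
  n <- length(timestamps)
  if (n == 1) return(rep(1L, length(t)))
  i <- findInterval(t, timestamps)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, n)
  as.integer(ifelse(abs(timestamps[hi] - t) < abs(t - timestamps[lo]),
                    hi, lo))
}

# Internal: assemble the field arguments for the C++ stepper.
field_args <- function(field, dt, n_steps) {
  if (inherits(field, "thermoscape_config")) {
    list(field_type = 0L,
         src_x = field$sources$x, src_y = field$sources$y,
         src_C = field$sources$temp_C, plate = field$plate_C,
         spread_mm = field$spread_mm,
         frame_vals = matrix(0, 1, 1), frame_of_step = 1L,
         nrow_f = 1L, ncol_f = 1L,
         arena_w = field$arena_mm[1], arena_h = field$arena_mm[2])
  } else if (inherits(field, "thermal_frames")) {
    fv <- vapply(field$frames, as.vector,
                 numeric(field$shape[1] * field$shape[2]))
    list(field_type = 1L,
         src_x = numeric(0), src_y = numeric(0), src_C = numeric(0),
         plate = 0, spread_mm = 1,
         frame_vals = fv,
         frame_of_step = as.integer(
           nearest_frame_index(seq_len(n_steps) * dt, field$timestamps)),
         nrow_f = field$shape[1], ncol_f = field$shape[2],
         arena_w = field$arena_mm[1], arena_h = field$arena_mm[2])
  } else stop("field must be a thermoscape_config or thermal_frames")
}

#' Advance a cohort of agent states by one step (reference stepper)
#'
#' Pure-R single-step update used for small-scale work and as the reference
#' semantics for the compiled cohort simulator: turning decision (using the
#' turning probability carried in the state), constant-speed advance with
#' reflective walls, temperature sensing, perception update, and refresh of
#' the turning probability.
#'
#' @param state list with numeric vectors `x`, `y`, `theta`, `A_O`,
#'   `T_prev`, `p_turn` (one entry per agent).
#' @param model an [agent_model()].
#' @param field a [thermoscape_config()] (analytic sensing).
#' @return The updated state list, plus `T_curr`.
#' @export
step_agents <- function(state, model, field) {
  dt <- model$dt
  sigma <- model$turn_sigma_deg * pi / 180
  n <- length(state$x)
  W <- field$arena_mm[1]; H <- field$arena_mm[2]
  for (i in seq_len(n)) {  # per-agent draws, same order as the C++ path
    u <- runif(1)
    if (u < state$p_turn[i]) state$theta[i] <- state$theta[i] + rnorm(1) * sigma
    nx <- state$x[i] + model$speed_mm_s * dt * cos(state$theta[i])
    ny <- state$y[i] + model$speed_mm_s * dt * sin(state$theta[i])
    if (nx < 0) { nx <- -nx; state$theta[i] <- pi - state$theta[i] }
    else if (nx > W) { nx <- 2 * W - nx; state$theta[i] <- pi - state$theta[i] }
    if (ny < 0) { ny <- -ny; state$theta[i] <- -state$theta[i] }
    else if (ny > H) { ny <- 2 * H - ny; state$theta[i] <- -state$theta[i] }
    state$x[i] <- nx; state$y[i] <- ny
  }
  T_curr <- thermoscape_at(state$x, state$y, field)
  state$A_O <- update_perception(state$A_O, state$T_prev, T_curr, dt,
                                 model$c_O, model$s, model$T_hsp)
  state$T_prev <- T_curr
  state$p_turn <- pmin(pmax(dt * model$base_turn_rate_hz *
                              (1 - model$turn_gain * state$A_O), 0), 1)
  state$T_curr <- T_curr
  state
}

#' Simulate a cohort of thermotaxis agents
#'
#' Runs `n` independent agents for `duration_s` seconds at the model's
#' `dt`, starting uniformly inside the centred square covering
#' `start_frac` of the arena side with uniform random headings. Occupancy
#' is accumulated in 0.1 degC fine temperature bins after discarding the
#' burn-in, matching the empirical analysis.
#'
#' @param model an [agent_model()].
#' @param field a [thermoscape_config()] or [thermal_frames()] object.
#' @param n number of agents.
#' @param duration_s simulated assay duration, s.
#' @param burnin_s initial period excluded from occupancy, s.
#' @param seed RNG seed (set once for the whole cohort).
#' @param record_tracks if TRUE, full trajectories are returned as a track
#'   table (see [cohort_tracks()]).
#' @param start_frac side fraction of the centred start square.
#' @return A list of class `agent_cohort` with `occ_fine` (n x 140 matrix
#'   of seconds per 0.1 degC bin over 14-28 degC), `model`, `duration_s`,
#'   `burnin_s`, and (if recorded) `x`, `y`, `theta` matrices plus `t`.
#' @export
simulate_cohort <- function(model, field, n, duration_s = 1200,
                            burnin_s = 120, seed = NULL,
                            record_tracks = FALSE, start_frac = 0.33) {
  stopifnot(inherits(model, "agent_model"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dt <- model$dt
  n_steps <- round(duration_s / dt)
  burn_steps <- round(burnin_s / dt)
  fa <- field_args(field, dt, n_steps)
  W <- fa$arena_w; H <- fa$arena_h
  x0 <- W / 2 + (runif(n) - 0.5) * start_frac * W
  y0 <- H / 2 + (runif(n) - 0.5) * start_frac * H
  th0 <- runif(n, 0, 2 * pi)
  res <- cpp_sim_agents(
    n = as.integer(n), dt = dt, n_steps = as.integer(n_steps),
    burn_steps = as.integer(burn_steps),
    speed = model$speed_mm_s, r0 = model$base_turn_rate_hz,
    k = model$turn_gain, sigma = model$turn_sigma_deg * pi / 180,
    c_o = model$c_O, s = model$s, thsp = model$T_hsp,
    arena_w = W, arena_h = H,
    field_type = fa$field_type, src_x = fa$src_x, src_y = fa$src_y,
    src_C = fa$src_C, plate = fa$plate, spread_mm = fa$spread_mm,
    frame_vals = fa$frame_vals,
    frame_of_step = as.integer(fa$frame_of_step),
    nrow_f = as.integer(fa$nrow_f), ncol_f = as.integer(fa$ncol_f),
    x0 = x0, y0 = y0, th0 = th0,
    bin_lo = fine_bin_lo(), bin_w = fine_bin_width(),
    nbins = fine_bin_count(), record = record_tracks)
  out <- list(occ_fine = res$occ, model = model, n = n,
              duration_s = duration_s, burnin_s = burnin_s,
              arena_mm = c(W, H))
  if (record_tracks) {
    out$x <- res$x; out$y <- res$y; out$theta <- res$theta
    out$t <- seq(0, n_steps) * dt
  }
  class(out) <- "agent_cohort"
  out
}

#' Convert a recorded cohort to a track table
#'
#' Produces the same long-format track table used for empirical data
#' (columns `id`, `frame`, `t`, `x`, `y`, `head_x`, `head_y`, `bend_deg`).
#' The head is placed half a body length ahead of the centroid along the
#' heading; the body-bend angle is the wrapped frame-to-frame heading
#' change in degrees (magnitude).
#'
#' @param cohort an `agent_cohort` simulated with `record_tracks = TRUE`.
#' @param body_length_mm nominal larval body length, mm.
#' @return A data.frame, one row per agent-frame.
#' @export
cohort_tracks <- function(cohort, body_length_mm = 4) {
  stopifnot(inherits(cohort, "agent_cohort"), !is.null(cohort$x))
  n <- nrow(cohort$x); m <- ncol(cohort$x)
  dth <- cbind(0, cohort$theta[, -1, drop = FALSE] -
                    cohort$theta[, -m, drop = FALSE])
  dth <- abs(atan2(sin(dth), cos(dth))) * 180 / pi
  data.frame(
    id = rep(seq_len(n), each = m),
    frame = rep(seq_len(m) - 1L, n),
    t = rep(cohort$t, n),
    x = as.vector(t(cohort$x)),
    y = as.vector(t(cohort$y)),
    head_x = as.vector(t(cohort$x + body_length_mm / 2 * cos(cohort$theta))),
    head_y = as.vector(t(cohort$y + body_length_mm / 2 * sin(cohort$theta))),
    bend_deg = as.vector(t(dth))
  )
}
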