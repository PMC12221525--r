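test_that("sensor weights balance at the set point and follow the linear form", {
  for (s in c(0.0005, 0.003, 0.05, 0.3)) {
    w <- sensor_weights(20, s, 20)
    expect_identical(w$w_cool, 0.5)
    expect_identical(w$w_warm, 0.5)
  }
  w <- sensor_weights(22, 0.005, 20)
  expect_equal(w$w_cool, 0.51)
  expect_equal(w$w_warm, 0.49)
  w <- sensor_weights(25, 0.05, 17)
  expect_equal(w$w_cool, 0.9)
  expect_equal(w$w_warm, 0.1)
  # clamped to [0, 1] over the full parameter grids
  grid <- expand.grid(T = seq(17, 25, 0.5), s = seq(0.0025, 0.05, 0.0025),
                      Thsp = seq(17, 25, 0.5))
  w <- sensor_weights(grid$T, grid$s, grid$Thsp)
  expect_true(all(w$w_cool >= 0 & w$w_cool <= 1))
  expect_true(all(w$w_warm >= 0 & w$w_warm <= 1))
})

test_that("gain equals the weight difference and is odd about the set point", {
  expect_equal(gain(20, 0.01, 20), 0)
  expect_equal(gain(18, 0.003, 20), 0.012)
  set.seed(1)
  T <- runif(200, 17, 25); s <- runif(200, 0, 0.06); Th <- runif(200, 17, 25)
  w <- sensor_weights(T, s, Th)
  unclamped <- abs(s * (T - Th)) <= 0.5
  expect_equal(gain(T, s, Th)[unclamped],
               (w$w_warm - w$w_cool)[unclamped], tolerance = 1e-12)
  d <- runif(50, 0, 3)
  expect_equal(gain(20 + d, 0.004, 20), -gain(20 - d, 0.004, 20))
})

test_that("perception updates follow forward Euler and decay exponentially", {
  expect_equal(update_perception(1, 21, 21, 0.1, 1, 0.003, 20), 0.9)
  # constant temperature at the set point: pure geometric decay
  A <- 1; dt <- 0.01
  for (i in 1:100) A <- update_perception(A, 19, 19, dt, 1, 0.01, 19)
  expect_equal(A, (1 - dt)^100)
  expect_lt(abs(A - exp(-1)) / exp(-1), 0.01)
  # warming above the set point contributes negatively (aversive)
  up <- update_perception(0, 22, 22.1, 0.1, 1, 0.003, 20)
  expect_lt(up, 0)
  expect_error(update_perception(0, 21, 21, 0, 1, 0.003, 20), "dt")
})

test_that("compiled cohort stepper matches the R reference stepper exactly", {
  ts <- thermoscape_config()
  m <- agent_model(T_hsp = 19, s = 0.01, turn_gain = 5000)
  co <- simulate_cohort(m, ts, n = 4, duration_s = 6, burnin_s = 0,
                        seed = 123, record_tracks = TRUE)
  ref <- ref_simulate(m, ts, n = 4, n_steps = 60, seed = 123)
  expect_equal(co$x, ref$x, tolerance = 1e-12)
  expect_equal(co$y, ref$y, tolerance = 1e-12)
})

test_that("cohort simulation is reproducible and conserves occupancy time", {
  ts <- thermoscape_config()
  m <- agent_model(T_hsp = 21, s = 0.002)
  a <- simulate_cohort(m, ts, n = 20, duration_s = 300, burnin_s = 60,
                       seed = 5)
  b <- simulate_cohort(m, ts, n = 20, duration_s = 300, burnin_s = 60,
                       seed = 5)
  expect_identical(a$occ_fine, b$occ_fine)
  # every agent accounts for exactly duration - burnin seconds
  expect_equal(unname(rowSums(a$occ_fine)), rep(240, 20), tolerance = 1e-9)
})

test_that("blind agents walk unbiased and a wall-facing agent is reflected", {
  ts <- thermoscape_config()
  blind <- agent_model(s = 0)
  st <- list(x = 0.01, y = 85, theta = pi, A_O = 0, T_prev = 21,
             p_turn = 0)  # at the left wall, heading outward
  st2 <- step_agents(st, blind, ts)
  expect_gte(st2$x, 0)
  expect_true(abs(st2$x) <= 170)
  # with s = 0 the perception decays and p_turn approaches dt * r0
  st <- list(x = 85, y = 85, theta = 0, A_O = 0.5, T_prev = 21,
             p_turn = 0.03)
  for (i in 1:200) st <- step_agents(st, blind, ts)
  expect_equal(st$p_turn, blind$dt * blind$base_turn_rate_hz,
               tolerance = 1e-4)
  # turning-probability form: frozen A_O = -1 with unit gain doubles p
  m1 <- agent_model(s = 0, turn_gain = 1)
  p <- pmin(pmax(m1$dt * m1$base_turn_rate_hz * (1 - m1$turn_gain * -1), 0), 1)
  expect_equal(p, 2 * m1$dt * m1$base_turn_rate_hz)
})

test_that("occupancy concentrates near the set point as slope increases", {
  ts <- thermoscape_config()
  wmid <- tp_windows() + 0.5
  conc <- vapply(c(0, 0.001, 0.003, 0.007), function(s) {
    co <- simulate_cohort(agent_model(T_hsp = 19, s = s), ts, n = 150,
                          duration_s = 600, seed = 31 + round(s * 1e4))
    o <- colMeans(window_occupancy(co$occ_fine))
    sum(abs(wmid - 19) * o) / sum(o)
  }, numeric(1))
  expect_true(all(diff(conc) < 0))
})

test_that("a cool-set-point cohort occupies cooler temperatures than a blind one", {
  ts <- thermoscape_config()
  wmid <- tp_windows() + 0.5
  cool <- simulate_cohort(agent_model(T_hsp = 19, s = 0.005), ts, n = 150,
                          duration_s = 600, seed = 3)
  blind <- simulate_cohort(agent_model(s = 0), ts, n = 150,
                           duration_s = 600, seed = 4)
  med_T <- function(co) {
    o <- colMeans(window_occupancy(co$occ_fine))
    wmid[which(cumsum(o) >= sum(o) / 2)[1]]
  }
  expect_lt(med_T(cool), med_T(blind))
})
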