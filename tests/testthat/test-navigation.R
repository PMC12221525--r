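test_that("windowed velocity is exact on straight paths and rigid-motion invariant", {
  n <- 101
  tr <- fix_track(1, x = seq(0, 10, length.out = n), y = rep(0, n))
  v <- windowed_velocity(tr)
  expect_equal(v$v_mm_s, rep(1, n), tolerance = 1e-9)
  expect_true(any(v$partial) && !all(v$partial))
  still <- fix_track(2, x = rep(3, n), y = rep(4, n))
  expect_equal(windowed_velocity(still)$v_mm_s, rep(0, n))
  # rotation + translation leave speed unchanged
  a <- 0.7
  rot <- fix_track(3, x = 5 + cos(a) * tr$x, y = -2 + sin(a) * tr$x)
  expect_equal(windowed_velocity(rot)$v_mm_s, v$v_mm_s, tolerance = 1e-9)
  # too-short track -> empty result
  expect_identical(nrow(windowed_velocity(tr[1:10, ])), 0L)
})

test_that("sawtooth velocity equals hand-computed path over the window", {
  # vertex spacing 0.5 mm per 0.5 s: speed 1 mm/s along the teeth
  n <- 201
  tt <- (seq_len(n) - 1) * 0.1
  y <- 0.5 * abs((tt %% 1) - 0.5) * 2
  tr <- fix_track(1, x = tt * 0.0, y = y)
  v <- windowed_velocity(tr)
  mid <- !v$partial
  expect_equal(v$v_mm_s[mid], rep(1, sum(mid)), tolerance = 1e-9)
})

test_that("tortuosity is 0 on straight paths, ~1 on returns, 1 - 2/pi on semicircles", {
  n <- 101
  straight <- fix_track(1, x = seq(0, 10, length.out = n), y = rep(0, n))
  tor <- windowed_tortuosity(straight)
  expect_equal(tor$tortuosity, rep(0, n), tolerance = 1e-9)
  # back-and-forth path returning to the start within every window
  zig <- fix_track(2, x = rep(c(0, 0.05), length.out = n), y = rep(0, n))
  tz <- windowed_tortuosity(zig, windows_s = c(2, 5))
  expect_true(all(tz$tortuosity[!tz$partial] > 0.9))
  # semicircle traversed within a single window
  th <- seq(0, pi, length.out = n)
  semi <- fix_track(3, x = 10 * cos(th), y = 10 * sin(th))
  ts_ <- windowed_tortuosity(semi, windows_s = 10)
  centre <- which(semi$frame == 50)
  expect_equal(ts_$tortuosity[centre], 1 - 2 / pi, tolerance = 1e-3)
  expect_true(all(ts_$tortuosity >= 0 & ts_$tortuosity <= 1, na.rm = TRUE))
})

test_that("head-sweep detection applies the 30/10/45 degree and 2 s rules", {
  flat <- rep(2, 50)
  tri <- function(peak, len = 21) {
    up <- seq(2, peak, length.out = (len + 1) / 2)
    c(up, rev(up)[-1])
  }
  # single 50 degree excursion returning to 5: one accepted sweep
  b <- c(flat, tri(50), flat)
  hs <- detect_head_sweeps(b)
  expect_identical(nrow(hs), 1L)
  expect_true(hs$accepted)
  expect_equal(hs$peak_deg, 50)
  # 40 degree excursion: detected but not accepted
  hs40 <- detect_head_sweeps(c(flat, tri(40), flat))
  expect_identical(nrow(hs40), 1L)
  expect_false(hs40$accepted)
  # two 50 degree peaks 1 s apart merge under the 2 s buffer
  b2 <- c(flat, tri(50, 9), rep(2, 6), tri(52, 9), flat)
  hs2 <- detect_head_sweeps(b2)
  expect_identical(nrow(hs2), 1L)
  expect_equal(hs2$peak_deg, 52)
  # an excursion that never returns below 10 degrees is not a sweep
  expect_identical(nrow(detect_head_sweeps(c(flat, seq(2, 80, 2)))), 0L)
  # planted count recovery: K compliant excursions, spaced > 2 s
  K <- 7
  bk <- rep(2, 30)
  for (i in seq_len(K)) bk <- c(bk, tri(46 + i), rep(2, 30))
  hsk <- detect_head_sweeps(bk)
  expect_equal(sum(hsk$accepted), K)
})

test_that("zone resampling differences obey linear-expectation structure", {
  # point masses: differences are exact
  z <- zone_differences(c(1, 2, 3), c("cool", "mid", "warm"), n_draws = 50,
                        seed = 1)
  expect_equal(unique(z$draws$warm_cool), 2)
  expect_equal(unique(z$draws$mid_cool), 1)
  expect_equal(unique(z$draws$warm_mid), 1)
  # identical zone distributions: mean difference within 2 SE of zero
  set.seed(5)
  vals <- rnorm(300)
  zones <- rep(c("cool", "mid", "warm"), each = 100)
  zz <- zone_differences(vals, zones, n_draws = 2000, seed = 2)
  for (d in zz$draws)
    expect_lt(abs(mean(d)), 2 * sd(d) / sqrt(length(d)))
  # E[warm-cool] = E[warm-mid] + E[mid-cool] under independent draws
  m <- zz$summary$mean
  names(m) <- zz$summary$contrast
  se <- 3 * sd(vals) / sqrt(2000)
  expect_lt(abs(m["warm_cool"] - (m["warm_mid"] + m["mid_cool"])), 3 * se)
  w <- capture_warnings(zone_differences(1:3, rep("cool", 3), n_draws = 10))
  expect_true(any(grepl("empty zone", w)))
})

test_that("temperature trends recover exact and noisy linear structure", {
  tc <- runif(100, 17, 25)
  exact <- suppressWarnings(fit_temperature_trend(2 * tc, tc, rep("a", 100)))
  expect_equal(exact$slope, 2, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)
  # slope equals cov/var computed independently
  set.seed(8)
  y <- 0.5 * tc + rnorm(100)
  fit <- fit_temperature_trend(y, tc, rep("a", 100))
  expect_equal(fit$slope, cov(y, tc) / var(tc), tolerance = 1e-9)
  # pure noise: the slope CI contains zero (n = 1000)
  tc2 <- runif(1000, 17, 25)
  noise <- fit_temperature_trend(rnorm(1000), tc2, rep("a", 1000))
  expect_true(noise$ci_low < 0 && noise$ci_high > 0)
  expect_error(fit_temperature_trend(1:5, rep(20, 5), rep("a", 5)),
               "constant")
})

test_that("correlation and clade rank-sum comparisons behave canonically", {
  v <- runif(200)
  expect_equal(correlate(v, -v), -1)
  set.seed(12)
  expect_lt(abs(correlate(rnorm(1e4), rnorm(1e4))), 0.05)
  vals <- c(rnorm(60), rnorm(60) + 2)
  clade <- rep(c("A", "B"), each = 60)
  zone <- rep(rep(c("cool", "mid", "warm"), each = 20), 2)
  cc <- clade_compare(vals, clade, zone)
  expect_true(all(cc$p_adj < 0.01))
  expect_identical(cc$zone, c("cool", "mid", "warm"))
})

test_that("zone assignment uses the equal-thirds boundaries", {
  z <- assign_zone(c(17, 19.66, 19.67, 22.32, 22.34, 25, 16.9, 25.1))
  expect_equal(as.character(z)[1:6],
               c("cool", "cool", "mid", "mid", "warm", "warm"))
  expect_true(all(is.na(z[7:8])))
})
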