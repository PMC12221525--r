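test_that("thermal-frame generation matches the 3 frames/min schedule", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 0, duration_s = 1200, seed = 3)
  fr <- make_thermal_frames(cfg, ts, nrow = 30, ncol = 40)
  expect_length(fr$frames, 60)
  expect_equal(fr$timestamps, (0:59) * 20)
  # no perturbation: every frame equals the analytic field
  base <- thermoscape_grid(ts, nrow = 30, ncol = 40)
  for (f in fr$frames) expect_equal(f, base)
  expect_error(make_thermal_frames(synth_config(duration_s = 5, seed = 1),
                                   ts, frame_period_s = 20), "frames")
})

test_that("spike injection is reproducible and detected by the smoother", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 0, duration_s = 600, spike_rate = 5e-4,
                      seed = 11)
  a <- make_thermal_frames(cfg, ts, nrow = 40, ncol = 40)
  b <- make_thermal_frames(cfg, ts, nrow = 40, ncol = 40)
  expect_identical(attr(a, "spikes"), attr(b, "spikes"))
  sp <- attr(a, "spikes")
  expect_gt(nrow(sp), 0)
  expect_true(all(sp$delta_C >= 8 & sp$delta_C <= 15))
  # smoothing restores the analytic field at all spiked interior pixels
  sm <- smooth_spikes(a)
  base <- thermoscape_grid(ts, nrow = 40, ncol = 40)
  interior <- sp$frame > 1 & sp$frame < length(a$frames)
  for (i in which(interior)) {
    expect_equal(sm$frames[[sp$frame[i]]][sp$row[i], sp$col[i]],
                 base[sp$row[i], sp$col[i]], tolerance = 1e-9)
  }
})

test_that("track generation honours counts, non-movers and determinism", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 10, nonmover_frac = 0.2,
                      duration_s = 200, seed = 9)
  a <- make_tracks(cfg, ts)
  b <- make_tracks(cfg, ts)
  expect_identical(a$tracks, b$tracks)
  # no fragmentation/clashes: one output track per larva, equal to truth
  expect_identical(sort(unique(a$tracks$id)), 1:10)
  expect_equal(a$tracks, a$truth_tracks[order(a$truth_tracks$id,
                                              a$truth_tracks$frame), ],
               ignore_attr = TRUE)
  # exactly 2 planted non-movers below both movement thresholds
  paths <- vapply(split(a$tracks, a$tracks$id), function(tr) {
    c(cum = sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2)),
      net = max(sqrt((tr$x - tr$x[1])^2 + (tr$y - tr$y[1])^2)))
  }, numeric(2))
  expect_equal(sum(paths["cum", ] < 0.5 & paths["net", ] < 0.3), 2)
  expect_equal(sum(a$larvae$nonmover), 2)
  # n_larvae = 0 gives an empty table, not an error
  e <- make_tracks(synth_config(n_larvae = 0, seed = 1), ts)
  expect_identical(nrow(e$tracks), 0L)
})

test_that("clash events end two tracks on one frame and restart them after", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 6, duration_s = 300, clash_rate = 1,
                      seed = 14)
  synth <- make_tracks(cfg, ts)
  clashes <- synth$id_map[synth$id_map$cause == "clash", ]
  expect_gt(nrow(clashes), 0)
  ep <- do.call(rbind, lapply(split(synth$tracks, synth$tracks$id),
                              function(tr) data.frame(
                                id = tr$id[1], f0 = min(tr$frame),
                                f1 = max(tr$frame))))
  # clash-born tracks start one frame after a pair of simultaneous ends
  for (rid in clashes$raw_id) {
    f0 <- ep$f0[ep$id == rid]
    expect_gte(sum(ep$f1 == f0 - 1), 2)
  }
  # the clash joiner reassembles the original larvae
  joined <- join_clashes(synth$tracks)
  expect_equal(length(unique(joined$id)), 6)
})

test_that("FIMtrack CSV writing round-trips losslessly", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 5, duration_s = 60, seed = 4)
  tr <- make_tracks(cfg, ts)$tracks
  f <- withr::local_tempfile(fileext = ".csv")
  write_fimtrack_csv(tr, f)
  back <- read_fimtrack_csv(f)
  rownames(tr) <- rownames(back) <- NULL
  expect_equal(back, tr, tolerance = 0)
  # empty set -> header-only file
  write_fimtrack_csv(tr[0, ], f)
  expect_length(readLines(f), 1)
  expect_identical(nrow(read_fimtrack_csv(f)), 0L)
  # malformed rows are reported with their line number
  writeLines(c("frame,id,mom_x,mom_y,head_x,head_y,bending",
               "0,1,1,2,3,4,5", "0,2,oops"), f)
  expect_error(read_fimtrack_csv(f), "line 3")
})

test_that("thermal frame directories round-trip through the manifest", {
  ts <- thermoscape_config()
  cfg <- synth_config(n_larvae = 0, duration_s = 100, noise_sd = 0.05,
                      seed = 8)
  fr <- make_thermal_frames(cfg, ts, nrow = 12, ncol = 16)
  d <- withr::local_tempdir()
  write_thermal_frames(fr, d)
  back <- read_thermal_frames(d)
  expect_equal(back$timestamps, fr$timestamps)
  expect_equal(back$frames, fr$frames, tolerance = 1e-12)
})
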