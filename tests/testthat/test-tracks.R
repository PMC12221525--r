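test_that("duration filter is strict at the 10 s boundary", {
  short <- fix_track(1, x = seq(0, 1, length.out = 100), y = rep(0, 100))
  exact <- fix_track(2, x = seq(0, 1, length.out = 101), y = rep(0, 101))
  both <- rbind(short, exact)  # 9.9 s and 10.0 s
  kept <- filter_short(both)
  expect_identical(unique(kept$id), 2L)
  expect_identical(nrow(filter_short(both[0, ])), 0L)
})

test_that("non-mover filter requires both criteria (AND rule)", {
  # cum 0.4 mm, net 0.2 mm -> removed
  a <- fix_track(1, x = c(0, 0.1, 0.2, 0.1, 0.2), y = rep(0, 5))
  # cum 0.4 mm straight, net 0.4 mm -> kept (net criterion not met)
  b <- fix_track(2, x = seq(0, 0.4, 0.1), y = rep(0, 5))
  # clearly moving
  c_ <- fix_track(3, x = seq(0, 10, length.out = 5), y = rep(0, 5))
  kept <- filter_nonmoving(rbind(a, b, c_))
  expect_setequal(unique(kept$id), c(2L, 3L))
  # order independence
  perm <- rbind(c_, a, b)
  expect_setequal(unique(filter_nonmoving(perm)$id), c(2L, 3L))
})

test_that("clash joining pairs reciprocally closest tracks at shared end frames", {
  mkseg <- function(id, f0, n, x0, y0, dx = 0.1) {
    data.frame(id = as.integer(id), frame = f0 + seq_len(n) - 1L,
               t = (f0 + seq_len(n) - 1) / 10,
               x = x0 + (seq_len(n) - 1) * dx, y = y0,
               head_x = x0, head_y = y0, bend_deg = 0)
  }
  A <- mkseg(1, 0, 1001, 0, 10)     # ends frame 1000 at x = 100
  B <- mkseg(2, 0, 1001, 0, 50)
  C <- mkseg(3, 1001, 200, 100.1, 10)
  D <- mkseg(4, 1001, 200, 100.1, 50)
  joined <- join_clashes(rbind(A, B, C, D))
  expect_setequal(unique(joined$id), c(1L, 2L))
  expect_true(all(joined$y[joined$id == 1] == 10))
  expect_true(all(joined$y[joined$id == 2] == 50))
  # no simultaneous endings: output == input
  solo <- rbind(mkseg(1, 0, 500, 0, 10), mkseg(2, 100, 500, 0, 50))
  out <- join_clashes(solo)
  expect_equal(out$id, solo$id)
  # two end together but only one successor exists nearby
  out2 <- join_clashes(rbind(A, B, C))
  expect_setequal(unique(out2$id), c(1L, 2L))
  expect_true(all(out2$y[out2$id == 1] == 10))
  expect_equal(sum(out2$id == 2), 1001)
})

test_that("fragment joining honours the staged distance/time/speed limits", {
  mkseg <- function(id, f0, n, x0, y0 = 0) {
    data.frame(id = as.integer(id), frame = f0 + seq_len(n) - 1L,
               t = (f0 + seq_len(n) - 1) / 10,
               x = x0 + (seq_len(n) - 1) * 0.05, y = y0,
               head_x = x0, head_y = y0, bend_deg = 0)
  }
  # gap 100 px (25 mm) / 10 s -> 10 px/s: joined in round 1
  r1 <- rbind(mkseg(1, 0, 200, 0), mkseg(2, 300, 200, 0.05 * 199 + 25))
  j1 <- join_fragments(r1)
  expect_identical(unique(j1$id), 1L)
  expect_equal(attr(j1, "joins")$round, 1)
  # gap 300 px / 50 s (6 px/s): distance blocks round 1, joined round 2
  r2 <- rbind(mkseg(1, 0, 200, 0), mkseg(2, 700, 200, 0.05 * 199 + 75))
  j2 <- join_fragments(r2)
  expect_identical(unique(j2$id), 1L)
  expect_equal(attr(j2, "joins")$round, 2)
  # gap 100 px / 5 s (20 px/s): speed blocks round 1, joined round 2
  r3 <- rbind(mkseg(1, 0, 200, 0), mkseg(2, 250, 200, 0.05 * 199 + 25))
  j3 <- join_fragments(r3)
  expect_identical(unique(j3$id), 1L)
  expect_equal(attr(j3, "joins")$round, 2)
  # joining never creates time overlaps within a track
  for (j in list(j1, j2, j3)) {
    expect_false(any(duplicated(j[, c("id", "frame")])))
    expect_true(all(tapply(j$t, j$id, function(t) all(diff(t) > 0))))
  }
})

test_that("temperature assignment uses the nearest-in-time frame, earlier on ties", {
  s <- fix_uniform_frames(c(1, 2, 3), timestamps = c(0, 20, 40))
  tr <- data.frame(id = 1, frame = c(100, 290, 350), t = c(10, 29, 35),
                   x = c(50, 50, 50), y = c(50, 50, 50),
                   head_x = c(50, 50, 50), head_y = c(50, 50, 50),
                   bend_deg = 0)
  out <- assign_temperature(tr, s)
  expect_equal(out$temp_C, c(1, 2, 3))  # t=10 ties to the earlier frame
  expect_false(any(out$temp_clamped))
  # uniform frames give the uniform temperature everywhere
  s21 <- fix_uniform_frames(c(21, 21), timestamps = c(0, 20))
  out21 <- assign_temperature(tr, s21)
  expect_equal(out21$temp_C, rep(21, 3))
  # positions outside the grid are clamped and flagged
  tr$head_x[1] <- 500
  out_cl <- assign_temperature(tr, s)
  expect_true(out_cl$temp_clamped[1])
})

test_that("synthetic fragmentation within round-1 limits is fully recovered", {
  cfg <- synth_config(n_larvae = 12, agent_model = agent_model(s = 0),
                      duration_s = 400, fragment_rate = 1.5, seed = 21)
  ts <- thermoscape_config()
  synth <- make_tracks(cfg, ts)
  expect_gt(length(unique(synth$tracks$id)), 12)
  raw <- synth$tracks
  raw$orig <- raw$id
  joined <- join_fragments(raw)
  true_of <- setNames(synth$id_map$true_id, synth$id_map$raw_id)
  grp <- split(true_of[as.character(joined$orig)], joined$id)
  # every reassembled track is pure and all larvae are recovered
  purity <- vapply(grp, function(g) max(table(g)) / length(g), numeric(1))
  expect_gte(mean(purity), 0.99)
  expect_equal(length(grp), 12)
})
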