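# behaviour derivation for a toy session built from random_toy_behavior
toy_bd <- function(tb, env_label = "familiar") {
  segs <- suppressMessages(segment_laps(length(tb$pos), tb$teleports))
  n <- length(tb$pos)
  structure(list(velocity_cm_s = tb$v, lap_index = segs$lap_index,
                 lap_table = segs$lap_table, env = rep(env_label, n),
                 immobile_5 = tb$v < 5, stationary_02 = tb$v <= 0.2),
            class = "axonav_behavior_derived")
}

test_that("position binning agrees exactly with the brute-force oracle", {
  for (seed in 1:25) {
    tb <- random_toy_behavior(n = 900, track = 100, seed = seed)
    if (length(tb$teleports) < 2) next
    bd <- toy_bd(tb)
    set.seed(seed + 1000)
    vals <- runif(900)
    cv <- bin_by_position(vals, tb$pos, bd, "familiar", 100, bin_cm = 10)
    laps <- cv$laps
    edges <- seq(0, 100, by = 10)
    expect_equal(cv$per_lap, oracle_bin(vals, tb$pos, bd$lap_index, laps, edges),
                 label = paste("seed", seed))
  }
})

test_that("velocity binning agrees with the oracle and excludes out-of-range frames", {
  for (seed in 1:25) {
    tb <- random_toy_behavior(n = 900, track = 100, seed = seed)
    if (length(tb$teleports) < 2) next
    bd <- toy_bd(tb)
    set.seed(seed + 2000)
    vals <- runif(900)
    cv <- tryCatch(bin_by_velocity(vals, bd, "familiar", bin_cm_s = 2,
                                   range = c(1, 29)),
                   error = function(e) NULL)
    if (is.null(cv)) next
    cov <- bd$velocity_cm_s
    cov[cov < 1 | cov > 29] <- NA
    expect_equal(cv$per_lap,
                 oracle_bin(vals, cov, bd$lap_index, cv$laps, seq(1, 29, 2)),
                 label = paste("seed", seed))
  }
})

test_that("tuning-curve identities: linear signal, constant trace, NaN bins", {
  # norm_q == position/track: curve mean per bin = bin centre / track
  fs <- 30
  pos <- c(rep(seq(0.5, 199.5, by = 1), times = 3), rep(0.5, 10))  # 3 laps + stub
  n <- length(pos)
  tp <- c(200L, 400L, 600L)
  bd <- structure(list(velocity_cm_s = rep(10, n),
                       lap_index = segment_laps(n, tp)$lap_index,
                       lap_table = segment_laps(n, tp)$lap_table,
                       env = rep("familiar", n)),
                  class = "axonav_behavior_derived")
  cv <- bin_by_position(pos / 200, pos, bd, "familiar", 200, bin_cm = 5)
  expect_equal(cv$mean, cv$bin_centers / 200, tolerance = 1e-12)
  expect_equal(cv$bin_centers_norm, cv$bin_centers / 200)

  # constant trace: flat curve, sem 0
  cv2 <- bin_by_position(rep(0.7, n), pos, bd, "familiar", 200, bin_cm = 5)
  expect_true(all(abs(cv2$mean - 0.7) < 1e-12))
  expect_true(all(cv2$sem == 0))

  # a lap missing one bin: NaN cell excluded from the across-lap mean
  pos3 <- pos; sel <- bd$lap_index == 1 & pos >= 50 & pos < 55
  pos3[sel] <- 57  # lap 1 never visits bin [50,55)
  cv3 <- bin_by_position(rep(1, n), pos3, bd, "familiar", 200, bin_cm = 5)
  b <- which(cv3$bin_edges == 50)
  expect_true(is.nan(cv3$per_lap[2, b]))
  expect_equal(cv3$n_laps_per_bin[b], 2)
  expect_equal(cv3$mean[b], 1)

  expect_error(bin_by_position(rep(1, n), pos, bd, "novel", 200), "no completed laps")
})

test_that("velocity curve flags bins above the population-complete cutoff", {
  tb <- random_toy_behavior(n = 500, track = 100, seed = 3)
  bd <- toy_bd(tb)
  cv <- bin_by_velocity(runif(500), bd, "familiar")
  expect_identical(cv$population_complete, cv$bin_centers <= 14)
  # all frames below range -> error
  bd0 <- bd; bd0$velocity_cm_s <- rep(0.5, 500)
  expect_error(bin_by_velocity(runif(500), bd0, "familiar"), "velocity range")
})

test_that("reward-proximity curves: distance is mirrored position, time peaks at reward", {
  tb <- random_toy_behavior(n = 900, track = 100, seed = 9)
  bd <- toy_bd(tb)
  vals <- tb$pos / 100
  cvd <- bin_by_reward_proximity(vals, tb$pos, bd, "familiar", 100, "distance")
  # activity proportional to position must decrease with distance-to-reward
  f <- fit_linear(cvd$bin_centers, cvd$mean)
  expect_lt(f$slope, 0)

  # time mode: value jumps to 1 at the reward frame -> hottest bin is [0, 0.5)
  rewards <- tb$teleports - 1L  # toy: reward on the frame before teleport
  v2 <- numeric(900); v2[rewards + 1L] <- 1
  cvt <- bin_by_reward_proximity(v2, tb$pos, bd, "familiar", 100, "time",
                                 reward_frames = rewards, frame_rate_hz = 30)
  expect_identical(which.max(cvt$mean), 1L)

  expect_error(bin_by_reward_proximity(vals, tb$pos, bd, "familiar", 100, "nope"))
})

test_that("motion-onset alignment extracts the stated windows", {
  fs <- 30
  n <- 900
  vals <- rep(0.2, n)
  onsets <- data.frame(onset_frame = c(200L, 500L))
  # linear ramp to 1 over the 2 s before each onset
  for (o in onsets$onset_frame) {
    idx <- (o - 60):(o - 1)
    vals[idx + 1] <- seq(0, 1, length.out = 60)
  }
  al <- align_to_motion_onset(vals, onsets, fs, window_s = c(-2, 3))
  expect_identical(dim(al$matrix), c(2L, 151L))
  expect_equal(al$time_s[61], 0)
  pre <- al$mean[1:60]
  expect_gt(cor(pre, seq_along(pre)), 0.999)   # rises linearly to t=0

  # constant trace: flat aligned mean
  al2 <- align_to_motion_onset(rep(0.5, n), onsets, fs)
  expect_true(all(al2$mean == 0.5))

  # event too close to the trace edge is excluded
  al3 <- align_to_motion_onset(vals, data.frame(onset_frame = c(10L, 500L)), fs)
  expect_identical(al3$event_frames, 500L)
  expect_error(align_to_motion_onset(vals, data.frame(onset_frame = 10L), fs),
               "complete window")
})

test_that("transition alignment: identity, step, and mask behaviour", {
  tr <- matrix(1, nrow = 4, ncol = 300)
  al <- align_to_transition(tr, 150L, 30)
  expect_true(all(al$matrix == 1))
  expect_equal(al$time_s[151], 0)

  tr2 <- tr; tr2[1, 151:300] <- 2           # one ROI steps by +1 at the event
  al2 <- align_to_transition(tr2, 150L, 30)
  post <- al2$population_mean[al2$time_s >= 0]
  pre <- al2$population_mean[al2$time_s < 0]
  expect_equal(unique(post) - unique(pre), 1 / 4)

  # mask concatenation: alignment lands on first retained frame >= event
  keep <- c(0:99, 200:299)
  al3 <- align_to_transition(tr2, 150L, 30, frame_index = keep)
  expect_identical(ncol(al3$matrix), 200L)
  expect_equal(al3$matrix[1, al3$time_s >= 0], rep(2, 100))

  expect_error(align_to_transition(tr, 150L, 30, frame_index = 200:299),
               "no pre-event")
})

test_that("aligned binning: 50-frame tiling and lap bins", {
  tr <- matrix(rep(1:500, each = 2), nrow = 2)   # value = column index
  al <- align_to_transition(tr, 250L, 30)
  b <- bin_aligned(al, "frames", 50L)
  expect_identical(ncol(b$matrix), 10L)          # 500 frames -> 10 full bins
  # bin starting at offset d covers columns 251+d .. 300+d: mean 275.5+d
  expect_equal(b$matrix[1, ], 275.5 + b$bin_label)

  # remainder frames are dropped: 520 frames -> still full bins only
  tr2 <- matrix(1, nrow = 2, ncol = 520)
  al2 <- align_to_transition(tr2, 250L, 30)
  b2 <- bin_aligned(al2, "frames", 50L)
  expect_true(all(table(b2$bin_label) == 1))
  expect_lte(ncol(b2$matrix), 10L)

  # lap mode: one bin per lap, 3 laps after the switch
  lap_index <- rep(0:4, each = 100)
  al3 <- align_to_transition(matrix(lap_index, nrow = 1, byrow = TRUE), 200L, 30)
  b3 <- bin_aligned(al3, "lap", lap_index = lap_index)
  expect_identical(b3$bin_label, c(-2L, -1L, 0L, 1L, 2L))
  expect_equal(b3$matrix[1, ], 0:4)              # lap means recover lap ids
})
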