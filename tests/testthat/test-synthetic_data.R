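test_that("behaviour simulation is a pure function of (cfg, seed)", {
  cfg <- quick_cfg()
  b1 <- simulate_behavior(cfg)
  b2 <- simulate_behavior(cfg)
  expect_identical(b1, b2)
})

test_that("deterministic locomotion gives closed-form lap arithmetic", {
  # no pauses, constant 10 cm/s on a 200 cm track at 30 Hz:
  # lap duration = 200/10 + 1.5 = 21.5 s = 645 frames
  cfg <- sim_config(track_length_cm = 200, frame_rate_hz = 30,
                    familiar_duration_s = 600, novel_duration_s = 0,
                    run_speed_cm_s = 10, run_speed_sd = 0,
                    speed_jitter_sd = 0,
                    pause_rate_hz = 0, pause_after_teleport_prob = 0,
                    seed = 5)
  b <- simulate_behavior(cfg)
  rw <- b$behavior$reward_frames
  expect_identical(diff(rw), rep(645L, length(rw) - 1L))
  expect_identical(length(rw), 27L)         # floor(600 s / 21.5 s per lap)
  # teleport follows each reward by the 1.5 s pause (45 frames)
  tp <- b$behavior$teleport_frames
  expect_identical(tp - rw[seq_along(tp)], rep(45L, length(tp)))
})

test_that("too-short sessions are rejected", {
  expect_error(simulate_behavior(sim_config(familiar_duration_s = 5,
                                            novel_duration_s = 0)),
               "too short")
})

test_that("novelty velocity dip scales the first novel lap by the configured fraction", {
  ratios <- vapply(1:20, function(sd0) {
    cfg <- sim_config(novelty_dip_frac = 0.5, familiar_duration_s = 300,
                      novel_duration_s = 300, pause_rate_hz = 0.02,
                      seed = 100 + sd0)
    b <- simulate_behavior(cfg)
    bd <- segment_laps(b$n_frames, b$behavior$teleport_frames)
    cv <- compute_velocity(b$behavior$position_cm, b$behavior$teleport_frames,
                           cfg$frame_rate_hz)
    env <- rep("familiar", b$n_frames)
    sw <- b$env_schedule$start_frame[b$env_schedule$env_label == "novel"]
    env[(sw + 1):b$n_frames] <- "novel"
    lm <- lap_metrics(cv$velocity_cm_s, bd$lap_index, env)
    fam <- lm$mean_moving_velocity_cm_s[lm$env == "familiar"]
    first_novel <- lm$mean_moving_velocity_cm_s[lm$env == "novel"][1]
    first_novel / mean(fam, na.rm = TRUE)
  }, numeric(1))
  expect_gt(mean(ratios, na.rm = TRUE), 0.35)
  expect_lt(mean(ratios, na.rm = TRUE), 0.65)
})

test_that("latent rate identities hold by construction", {
  cfg <- sim_config(track_length_cm = 200, run_speed_cm_s = 10,
                    run_speed_sd = 0, speed_jitter_sd = 0, pause_rate_hz = 0,
                    pause_after_teleport_prob = 0,
                    familiar_duration_s = 120, novel_duration_s = 0, seed = 2)
  beh <- simulate_behavior(cfg)

  # velocity-only coding at constant speed: rate = base + g_v * v
  r_v <- simulate_axon_rates(beh, cfg, velocity_gain = 0.1, base = 1)
  run_frames <- which(beh$speed_cm_s == 10)
  expect_equal(unique(r_v[run_frames]), 1 + 0.1 * 10)

  # ramp coding: at the track end immediately before reward, rate = base + g_r
  r_r <- simulate_axon_rates(beh, cfg, ramp_gain = 2, base = 1)
  rw <- beh$behavior$reward_frames[1]
  expect_equal(r_r[rw + 1], 1 + 2, tolerance = 0.01)

  # novelty transient half-life: rate(t_switch + tau*ln 2) = base + A/2
  cfg2 <- sim_config(familiar_duration_s = 60, novel_duration_s = 120,
                     novelty_tau_s = 20, pause_rate_hz = 0,
                     run_speed_sd = 0, speed_jitter_sd = 0,
                     pause_after_teleport_prob = 0, seed = 2)
  beh2 <- simulate_behavior(cfg2)
  r_n <- simulate_axon_rates(beh2, cfg2, novelty_amp = 4, base = 1,
                             novelty_tau_s = 20)
  sw <- beh2$env_schedule$start_frame[beh2$env_schedule$env_label == "novel"]
  half_frame <- sw + round(20 * log(2) * cfg2$frame_rate_hz)
  expect_equal(r_n[half_frame + 1], 1 + 2, tolerance = 0.02)
})

test_that("fluorescence forward model matches its stated moments", {
  cfg <- quick_cfg(noise_sd = 0.5, baseline_f0 = 50, bleach_per_frame = 0)
  n <- 20000
  f <- render_fluorescence(numeric(n), cfg, seed = 4)
  expect_equal(mean(f), 50, tolerance = 0.05)
  expect_equal(sd(f), 0.5, tolerance = 0.02)

  # unit impulse: kernel area 1 so summed response is 1, peak after t=0
  cfg0 <- quick_cfg(noise_sd = 0, baseline_f0 = 10)
  rate <- numeric(600); rate[100] <- 1
  f0 <- render_fluorescence(rate, cfg0, seed = 1)
  resp <- f0 - 10
  expect_equal(sum(resp), 1, tolerance = 1e-6)
  expect_gt(which.max(resp), 100)
  # decay tail follows tau_decay (ratio over one tau ~ 1/e)
  pk <- which.max(resp)
  tau_frames <- round(cfg0$tau_decay_s * cfg0$frame_rate_hz)
  expect_equal(resp[pk + 2 * tau_frames] / resp[pk + tau_frames], exp(-1),
               tolerance = 0.05)

  # sustained step shifts the post-step mean by its magnitude
  cfgs <- quick_cfg(noise_sd = 0.2, baseline_f0 = 50)
  fs <- render_fluorescence(numeric(6000), cfgs,
                            unhealthy_step = list(frame = 3000, magnitude = 1),
                            seed = 9)
  expect_equal(mean(fs[3001:6000]) - mean(fs[1:3000]), 1, tolerance = 0.05)

  expect_error(render_fluorescence(c(-1, 0, 1), cfg), "non-negative")
})

test_that("make_cohort bookkeeping, determinism, unhealthy fraction", {
  cfg <- sim_config(n_sessions = 2, axons_per_session = 4, blebs_per_session = 3,
                    familiar_duration_s = 90, novel_duration_s = 0,
                    unhealthy_fraction = 0, seed = 21)
  coh <- make_cohort(cfg)
  expect_length(coh$sessions, 2)
  expect_identical(vapply(coh$sessions, function(s) length(s$rois), integer(1)),
                   c(7L, 7L))
  expect_identical(nrow(coh$ground_truth), 14L)
  expect_identical(sum(coh$ground_truth$is_bleb), 6L)
  expect_true(all(is.na(coh$ground_truth$unhealthy_frame)))
  # all-axon rows have one GroundTruth record per emitted ROI
  ids_gt <- coh$ground_truth$roi_id
  ids_roi <- unlist(lapply(coh$sessions, function(s)
    vapply(s$rois, function(r) r$roi_id, character(1))))
  expect_setequal(ids_gt, ids_roi)

  coh2 <- make_cohort(cfg)
  expect_identical(coh$sessions[[1]]$rois[[1]]$raw_f,
                   coh2$sessions[[1]]$rois[[1]]$raw_f)
  expect_identical(coh$ground_truth, coh2$ground_truth)

  cfg_u <- sim_config(n_sessions = 1, axons_per_session = 10,
                      blebs_per_session = 2, familiar_duration_s = 90,
                      novel_duration_s = 0, unhealthy_fraction = 1, seed = 3)
  coh_u <- make_cohort(cfg_u)
  gt_ax <- coh_u$ground_truth[!coh_u$ground_truth$is_bleb, ]
  expect_true(all(is.finite(gt_ax$unhealthy_frame)))
})

test_that("simulated rates are non-negative and fluorescence finite", {
  cfg <- quick_cfg(seed = 31)
  coh <- make_cohort(cfg)
  for (r in coh$sessions[[1]]$rois) expect_true(all(is.finite(r$raw_f)))
  beh <- simulate_behavior(cfg)
  rate <- simulate_axon_rates(beh, cfg, ramp_gain = 1, velocity_gain = 0.05,
                              premotion_gain = 1, novelty_amp = 1)
  expect_true(all(rate >= 0))
})

test_that("generator honesty: freezing ratio responds to the pause process", {
  # high pause rate vs no pauses separates freezing ratios as configured
  fr <- function(pr, seed) {
    cfg <- sim_config(pause_rate_hz = pr, familiar_duration_s = 120,
                      novel_duration_s = 0, seed = seed)
    b <- simulate_behavior(cfg)
    bd <- segment_laps(b$n_frames, b$behavior$teleport_frames)
    cv <- compute_velocity(b$behavior$position_cm, b$behavior$teleport_frames, 30)
    mean(lap_metrics(cv$velocity_cm_s, bd$lap_index)$freezing_ratio)
  }
  hi <- mean(vapply(1:8, function(s) fr(0.2, s), numeric(1)))
  lo <- mean(vapply(1:8, function(s) fr(0.005, s), numeric(1)))
  expect_gt(hi, lo + 0.1)
})
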