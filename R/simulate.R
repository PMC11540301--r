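#' Simulation configuration
#'
#' Describes a cohort of synthetic sessions emulating the behavioural
#' protocol: a head-fixed mouse runs laps on a 2 m or 3 m virtual linear
#' track, receives a 4 ul reward at the track end followed by a 1.5 s VR
#' pause and teleport to the start, and is switched from a familiar to a
#' novel environment mid-session (optionally preceded by darkness before VR
#' onset).  Axon encodings follow the two phenotypes described for
#' dopaminergic (ramp-to-reward with post-reward decay) and noradrenergic
#' (velocity, pre-motion and novelty) inputs.
#'
#' @param n_sessions number of sessions in the cohort.
#' @param axons_per_session,blebs_per_session ROI counts per session.
#' @param source `"VTA"` or `"LC"`; selects the default encoding phenotype.
#' @param track_length_cm track length (default 200 for VTA, 300 for LC).
#' @param frame_rate_hz imaging/behaviour rate, default 30.
#' @param familiar_duration_s,novel_duration_s time in each environment
#'   (defaults 600 s each, matching the 10 min per environment protocol).
#' @param dark_lead_s darkness before VR onset (0 disables the dark epoch).
#' @param run_speed_cm_s,run_speed_sd mean/sd of per-run target speed draws.
#' @param speed_jitter_sd,speed_jitter_tau_s within-run speed fluctuation: an
#'   Ornstein-Uhlenbeck wobble around the run's target speed (sd in cm/s,
#'   time constant in s); 0 disables it.  Real locomotion varies smoothly
#'   within a run, which is what makes velocity tuning identifiable.
#' @param pause_rate_hz hazard of ending a run (per second).
#' @param pause_duration_s mean pause duration (exponential).
#' @param pause_after_teleport_prob probability a pause is inserted right
#'   after teleport, emulating immobility concentrated between reward and
#'   the next lap's start.
#' @param novelty_dip_frac multiplicative velocity factor on the first novel
#'   lap (0.5 halves running speed); recovery is exponential afterwards.
#' @param novelty_dip_recovery_s time constant of the post-dip recovery.
#' @param novelty_freeze_reduction fractional reduction of the pause rate in
#'   the novel environment (persistently reduced immobility).
#' @param reward_pause_s VR pause after reward, default 1.5 s.
#' @param rewarded logical; when `FALSE` the ramp-to-reward term is removed
#'   from all axons (unrewarded-environment manipulation).
#' @param ramp_gain,velocity_gain,premotion_gain central encoding gains
#'   (fluorescence units per normalised position, per cm/s, per unit ramp).
#' @param novelty_amp,novelty_tau_s amplitude and decay time of the
#'   environment-switch transient; `vr_onset_scale` scales the same transient
#'   applied at darkness-to-VR onset.
#' @param post_reward_tau_s decay time of the ramp term after reward.
#' @param gain_jitter per-axon gains are multiplied by
#'   `runif(1 - gain_jitter, 1 + gain_jitter)`.
#' @param private_rate_sd stationary sd of each axon's private
#'   Ornstein-Uhlenbeck rate component (spontaneous transients uncorrelated
#'   across axons); keeps identically tuned axons from merging and gives
#'   axons their in-band spectral signal.  `private_tau_s` its time
#'   constant.
#' @param tau_rise_s,tau_decay_s GCaMP kernel time constants (GCaMP6s-like
#'   defaults 0.2 s and 1.5 s).
#' @param noise_sd,baseline_f0,bleach_per_frame imaging noise sd, baseline
#'   fluorescence and per-frame multiplicative bleaching.
#' @param unhealthy_fraction fraction of axons given a sustained fluorescence
#'   step ("filling" artifact); `unhealthy_step_sd` its magnitude in noise
#'   sds.
#' @param seed root seed; every session derives its own stream from it.
#' @return list of class `"axonav_sim_config"`.
#' @export
sim_config <- function(n_sessions = 1, axons_per_session = 10,
                       blebs_per_session = 5, source = "LC",
                       track_length_cm = if (source == "VTA") 200 else 300,
                       frame_rate_hz = 30,
                       familiar_duration_s = 600, novel_duration_s = 600,
                       dark_lead_s = 0,
                       run_speed_cm_s = 15, run_speed_sd = 3,
                       speed_jitter_sd = 4, speed_jitter_tau_s = 2,
                       pause_rate_hz = 0.05, pause_duration_s = 4,
                       pause_after_teleport_prob = 0.6,
                       novelty_dip_frac = 0.5, novelty_dip_recovery_s = 30,
                       novelty_freeze_reduction = 0.5,
                       reward_pause_s = 1.5, rewarded = TRUE,
                       ramp_gain = if (source == "VTA") 1 else 0,
                       velocity_gain = if (source == "VTA") 0 else 0.04,
                       premotion_gain = if (source == "VTA") 0 else 0.5,
                       novelty_amp = if (source == "VTA") 0 else 0.5,
                       novelty_tau_s = 30, vr_onset_scale = 1,
                       post_reward_tau_s = 2,
                       gain_jitter = 0.3,
                       private_rate_sd = 0.3, private_tau_s = 0.5,
                       tau_rise_s = 0.2, tau_decay_s = 1.5,
                       noise_sd = 0.03, baseline_f0 = 100,
                       bleach_per_frame = 0, unhealthy_fraction = 0,
                       unhealthy_step_sd = 5, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(source %in% c("VTA", "LC"),
            track_length_cm > 0, frame_rate_hz > 0,
            familiar_duration_s > 0, novel_duration_s >= 0, dark_lead_s >= 0,
            run_speed_cm_s > 0, pause_duration_s > 0, reward_pause_s > 0,
            speed_jitter_sd >= 0, speed_jitter_tau_s > 0,
            novelty_dip_frac >= 0, novelty_dip_frac <= 1,
            novelty_freeze_reduction >= 0, novelty_freeze_reduction <= 1,
            unhealthy_fraction >= 0, unhealthy_fraction <= 1,
            private_rate_sd >= 0, private_tau_s > 0,
            tau_rise_s > 0, tau_decay_s > 0, post_reward_tau_s > 0,
            novelty_tau_s > 0, noise_sd >= 0, baseline_f0 > 0)
  class(cfg) <- "axonav_sim_config"
  cfg
}

#' Simulate run/pause lap behaviour
#'
#' A two-state semi-Markov locomotion process: runs at a per-run speed drawn
#' from `N(run_speed_cm_s, run_speed_sd)` (floored at 1 cm/s) end with
#' hazard `pause_rate_hz`; pauses last `Exp(pause_duration_s)` and are also
#' inserted after teleports with probability `pause_after_teleport_prob`.
#' Completing the track emits a reward frame, freezes position at the track
#' end for `reward_pause_s`, then emits a teleport frame resetting position
#' to 0.  The environment switch forces a teleport; running speed on the
#' first novel lap is multiplied by `novelty_dip_frac`, recovering
#' exponentially afterwards, and the novel pause rate is reduced by
#' `novelty_freeze_reduction`.
#'
#' @param cfg a [sim_config()].
#' @param seed integer; defaults to `cfg$seed`.
#' @return list with `behavior` ([behavior_raw()]), `env_schedule`,
#'   `speed_cm_s` (latent per-frame speed) and `n_frames`.
#' @export
simulate_behavior <- function(cfg, seed = cfg$seed) {
  fs <- cfg$frame_rate_hz
  dt <- 1 / fs
  n_dark <- round(cfg$dark_lead_s * fs)
  n_fam <- round(cfg$familiar_duration_s * fs)
  n_nov <- round(cfg$novel_duration_s * fs)
  n <- n_dark + n_fam + n_nov
  L <- cfg$track_length_cm
  min_lap_s <- L / max(cfg$run_speed_cm_s, 1) + cfg$reward_pause_s
  if (cfg$familiar_duration_s < min_lap_s)
    stopf("familiar_duration_s (%g s) too short for one lap (~%g s)",
          cfg$familiar_duration_s, min_lap_s)

  with_seed(seed, {
    pos <- numeric(n)
    speed <- numeric(n)
    reward <- integer(0)
    teleport <- integer(0)

    switch_frame <- n_dark + n_fam        # first novel frame (0-based)
    draw_run_frames <- function(pr) {
      if (pr > 0) max(1L, round(stats::rexp(1, pr) * fs)) else n
    }
    draw_pause_frames <- function() {
      max(1L, round(stats::rexp(1, 1 / cfg$pause_duration_s) * fs))
    }
    draw_speed <- function() max(1, stats::rnorm(1, cfg$run_speed_cm_s,
                                                 cfg$run_speed_sd))
    # within-run speed wobble (OU around the run's target speed)
    ou_a <- exp(-1 / (fs * cfg$speed_jitter_tau_s))
    ou_s <- cfg$speed_jitter_sd * sqrt(1 - ou_a^2)
    wobble <- 0
    if (cfg$pause_rate_hz > 0) {
      state <- "pause"                     # enter VR paused briefly
      state_left <- draw_pause_frames()
      cur_speed <- 0
    } else {
      state <- "run"
      state_left <- n
      cur_speed <- draw_speed()
    }
    p <- 0
    pause_left <- 0L                       # reward-pause frames remaining
    first_novel_lap_done <- FALSE
    novel_recovery_t0 <- NA_real_

    for (i in seq_len(n)) {
      f0 <- i - 1L                         # 0-based frame index
      in_dark <- f0 < n_dark
      in_novel <- f0 >= switch_frame
      if (f0 == switch_frame && n_nov > 0L) {
        # forced teleport into the novel environment
        p <- 0
        teleport <- c(teleport, f0)
        pause_left <- 0L
        first_novel_lap_done <- FALSE
        state <- "run"
        cur_speed <- draw_speed()
        state_left <- draw_run_frames(cfg$pause_rate_hz)
      }

      if (in_dark) {
        pos[i] <- 0
        speed[i] <- 0
        next
      }

      if (pause_left > 0L) {               # reward pause: position frozen
        pause_left <- pause_left - 1L
        pos[i] <- p
        speed[i] <- 0
        if (pause_left == 0L) {
          teleport <- c(teleport, f0)      # teleport on last pause frame
          pos[i] <- 0
          p <- 0
          if (in_novel && !first_novel_lap_done) {
            first_novel_lap_done <- TRUE
            novel_recovery_t0 <- f0 * dt
          }
          if (stats::runif(1) < cfg$pause_after_teleport_prob) {
            state <- "pause"
            state_left <- draw_pause_frames()
          } else {
            state <- "run"
            cur_speed <- draw_speed()
            state_left <- draw_run_frames(cfg$pause_rate_hz)
          }
        }
        next
      }

      # run/pause state machine
      if (state_left <= 0L) {
        pr <- cfg$pause_rate_hz
        if (in_novel) pr <- pr * (1 - cfg$novelty_freeze_reduction)
        if (state == "run" && pr > 0) {
          state <- "pause"
          state_left <- draw_pause_frames()
        } else {
          state <- "run"
          cur_speed <- draw_speed()
          state_left <- draw_run_frames(pr)
        }
      }
      state_left <- state_left - 1L

      if (cfg$speed_jitter_sd > 0)
        wobble <- ou_a * wobble + stats::rnorm(1, 0, ou_s)
      v <- if (state == "run") max(1, cur_speed + wobble) else 0
      if (in_novel && v > 0) {
        if (!first_novel_lap_done) {
          v <- v * cfg$novelty_dip_frac
        } else if (is.finite(novel_recovery_t0)) {
          tt <- f0 * dt - novel_recovery_t0
          v <- v * (1 - (1 - cfg$novelty_dip_frac) * exp(-tt / cfg$novelty_dip_recovery_s))
        }
      }
      p <- p + v * dt
      if (p >= L) {
        p <- L
        reward <- c(reward, f0)
        pause_left <- round(cfg$reward_pause_s * fs)
        v <- 0
      }
      pos[i] <- p
      speed[i] <- v
    }

    sched <- data.frame(env_label = character(), start_frame = integer(),
                        stringsAsFactors = FALSE)
    if (n_dark > 0L) sched <- rbind(sched, data.frame(env_label = "dark", start_frame = 0L))
    sched <- rbind(sched, data.frame(env_label = "familiar", start_frame = n_dark))
    if (n_nov > 0L) sched <- rbind(sched, data.frame(env_label = "novel", start_frame = switch_frame))

    list(behavior = behavior_raw(pos, reward, teleport),
         env_schedule = sched,
         speed_cm_s = speed,
         n_frames = n)
  })
}

#' Latent activity rate of one synthetic axon
#'
#' Composes the encoding phenotypes additively on top of a unit base rate:
#' a reward-expectation ramp `ramp_gain * position/track_length` active in
#' rewarded environments, replaced after each reward by exponential decay
#' from the ramp peak (`post_reward_tau_s`); a velocity term
#' `velocity_gain * speed`; a linear ramp `premotion_gain * (0..1)` over the
#' 2 s preceding each motion onset; and a novelty transient
#' `A * exp(-(t - t_switch)/tau)` after the environment switch (and, scaled
#' by `vr_onset_scale`, after darkness-to-VR onset).  The result is clipped
#' at zero.
#'
#' @param beh output of [simulate_behavior()].
#' @param cfg a [sim_config()] supplying track length, frame rate and event
#'   conventions.
#' @param ramp_gain,velocity_gain,premotion_gain,novelty_amp per-axon gains.
#' @param novelty_tau_s,post_reward_tau_s,vr_onset_scale time constants.
#' @param base base rate (fluorescence units), default 0.
#' @return numeric per-frame latent rate, non-negative.
#' @export
simulate_axon_rates <- function(beh, cfg, ramp_gain = 0, velocity_gain = 0,
                                premotion_gain = 0, novelty_amp = 0,
                                novelty_tau_s = cfg$novelty_tau_s,
                                post_reward_tau_s = cfg$post_reward_tau_s,
                                vr_onset_scale = cfg$vr_onset_scale,
                                base = 0) {
  fs <- cfg$frame_rate_hz
  n <- beh$n_frames
  pos <- beh$behavior$position_cm
  speed <- beh$speed_cm_s
  t <- (seq_len(n) - 1L) / fs
  rate <- rep(base, n)

  if (ramp_gain != 0 && isTRUE(cfg$rewarded)) {
    ramp <- ramp_gain * pos / cfg$track_length_cm
    # after each reward, decay from the ramp value at reward until teleport
    rw <- beh$behavior$reward_frames
    tp <- beh$behavior$teleport_frames
    for (r in rw) {
      nxt <- tp[tp > r]
      end <- if (length(nxt)) nxt[1] else (n - 1L)
      idx <- (r + 1L):(end + 1L)           # 1-based frames r..end
      ramp[idx] <- ramp[r + 1L] * exp(-(t[idx] - t[r + 1L]) / post_reward_tau_s)
    }
    rate <- rate + ramp
  }

  if (velocity_gain != 0) rate <- rate + velocity_gain * speed

  if (premotion_gain != 0) {
    onsets <- detect_motion_onsets(speed, fs)$onset_frame
    w <- round(2 * fs)
    for (o in onsets) {
      idx0 <- max(0L, o - w):(o - 1L)
      ramp_vals <- 1 - (o - idx0) / w
      rate[idx0 + 1L] <- rate[idx0 + 1L] + premotion_gain * ramp_vals
    }
  }

  if (novelty_amp != 0) {
    sched <- beh$env_schedule
    for (i in seq_len(nrow(sched))) {
      lab <- sched$env_label[i]
      amp <- if (lab == "novel") novelty_amp
             else if (lab == "familiar" && i > 1L && sched$env_label[i - 1L] == "dark")
               novelty_amp * vr_onset_scale
             else 0
      if (amp != 0) {
        sf <- sched$start_frame[i]
        idx <- (sf + 1L):n
        rate[idx] <- rate[idx] + amp * exp(-(t[idx] - t[sf + 1L]) / novelty_tau_s)
      }
    }
  }
  pmax(rate, 0)
}

# stationary Ornstein-Uhlenbeck path: sd `sigma`, time constant `tau_s`
ou_process <- function(n, fs, sigma, tau_s) {
  if (sigma == 0) return(numeric(n))
  a <- exp(-1 / (fs * tau_s))
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - a^2))
  x1 <- stats::rnorm(1, 0, sigma)
  c(x1, as.numeric(stats::filter(innov[-1L], a, "recursive", init = x1)))
}

#' Render a latent rate into a raw fluorescence trace
#'
#' Forward model: `raw_f = baseline_f0 * (1 - bleach)^frame +
#' conv(rate, kernel) + N(0, noise_sd)` plus an optional sustained step.
#' The kernel is a discrete double exponential
#' `exp(-t/tau_decay) - exp(-t/tau_rise)` normalised to unit sum, so a unit
#' impulse of rate contributes unit summed fluorescence and a constant rate
#' passes through with unchanged steady-state amplitude.
#'
#' @param rate non-negative per-frame latent rate.
#' @param cfg a [sim_config()] (kernel taus, noise, baseline, bleach).
#' @param unhealthy_step `NULL` or `list(frame=, magnitude=)` for a sustained
#'   shift starting at `frame` (0-based).
#' @param seed RNG seed for the noise draw.
#' @return numeric raw fluorescence trace.
#' @export
render_fluorescence <- function(rate, cfg, unhealthy_step = NULL, seed = NULL) {
  if (cfg$tau_rise_s <= 0 || cfg$tau_decay_s <= 0)
    stopf("kernel taus must be > 0")
  if (any(rate < 0)) stopf("rate must be non-negative")
  fs <- cfg$frame_rate_hz
  n <- length(rate)
  kt <- seq(0, 8 * cfg$tau_decay_s, by = 1 / fs)
  k <- exp(-kt / cfg$tau_decay_s) - exp(-kt / cfg$tau_rise_s)
  k <- k / sum(k)
  sig <- stats::convolve(c(rate, numeric(length(k))), rev(k), type = "open")
  sig <- sig[seq_len(n)]
  f <- cfg$baseline_f0 * (1 - cfg$bleach_per_frame)^(seq_len(n) - 1L) + sig
  if (!is.null(unhealthy_step))
    f[(unhealthy_step$frame + 1L):n] <- f[(unhealthy_step$frame + 1L):n] +
      unhealthy_step$magnitude
  with_seed(seed, f + stats::rnorm(n, 0, cfg$noise_sd))
}

#' Generate a cohort of synthetic sessions with ground truth
#'
#' Each session gets its own derived seed.  Axons draw gains from the
#' config's central values jittered by `gain_jitter`; blebs are rendered
#' from a zero rate; a configured fraction of axons receives a sustained
#' fluorescence step at a random mid-session frame.
#'
#' @param cfg a [sim_config()].
#' @return list with `sessions` (list of [session()]) and `ground_truth`
#'   (data.frame, one row per ROI: gains, transient parameters, bleb flag,
#'   unhealthy step frame/magnitude).
#' @export
make_cohort <- function(cfg) {
  sessions <- vector("list", cfg$n_sessions)
  gt <- list()
  for (si in seq_len(cfg$n_sessions)) {
    sseed <- derive_seed(cfg$seed, si)
    beh <- simulate_behavior(cfg, seed = sseed)
    n <- beh$n_frames
    rois <- list()
    jit <- function(x, j) if (x == 0) 0 else x * stats::runif(1, 1 - j, 1 + j)
    with_seed(derive_seed(cfg$seed, 10000 + si), {
      unhealthy <- stats::runif(cfg$axons_per_session) < cfg$unhealthy_fraction
      for (ai in seq_len(cfg$axons_per_session)) {
        g_r <- jit(cfg$ramp_gain, cfg$gain_jitter)
        g_v <- jit(cfg$velocity_gain, cfg$gain_jitter)
        g_m <- jit(cfg$premotion_gain, cfg$gain_jitter)
        A <- jit(cfg$novelty_amp, cfg$gain_jitter)
        rate <- simulate_axon_rates(beh, cfg, ramp_gain = g_r,
                                    velocity_gain = g_v, premotion_gain = g_m,
                                    novelty_amp = A)
        rate <- pmax(rate + ou_process(n, cfg$frame_rate_hz,
                                       cfg$private_rate_sd, cfg$private_tau_s), 0)
        step <- NULL
        if (unhealthy[ai]) {
          step <- list(frame = floor(stats::runif(1, 0.3, 0.8) * n),
                       magnitude = cfg$unhealthy_step_sd * cfg$noise_sd)
        }
        id <- sprintf("s%d_axon%02d", si, ai)
        raw <- render_fluorescence(rate, cfg, unhealthy_step = step,
                                   seed = derive_seed(sseed, 100 + ai))
        rois[[length(rois) + 1L]] <- roi_trace(id, "axon", raw)
        gt[[length(gt) + 1L]] <- data.frame(
          session_id = sprintf("sim%03d", si), roi_id = id, is_bleb = FALSE,
          g_r = g_r, g_v = g_v, g_m = g_m, A = A,
          novelty_tau_s = cfg$novelty_tau_s,
          post_reward_tau_s = cfg$post_reward_tau_s,
          unhealthy_frame = if (is.null(step)) NA_integer_ else step$frame,
          unhealthy_magnitude = if (is.null(step)) NA_real_ else step$magnitude,
          stringsAsFactors = FALSE)
      }
      for (bi in seq_len(cfg$blebs_per_session)) {
        id <- sprintf("s%d_bleb%02d", si, bi)
        raw <- render_fluorescence(numeric(n), cfg,
                                   seed = derive_seed(sseed, 500 + bi))
        rois[[length(rois) + 1L]] <- roi_trace(id, "bleb", raw)
        gt[[length(gt) + 1L]] <- data.frame(
          session_id = sprintf("sim%03d", si), roi_id = id, is_bleb = TRUE,
          g_r = 0, g_v = 0, g_m = 0, A = 0,
          novelty_tau_s = NA_real_, post_reward_tau_s = NA_real_,
          unhealthy_frame = NA_integer_, unhealthy_magnitude = NA_real_,
          stringsAsFactors = FALSE)
      }
    })
    sessions[[si]] <- session(
      session_id = sprintf("sim%03d", si), source = cfg$source,
      frame_rate_hz = cfg$frame_rate_hz, track_length_cm = cfg$track_length_cm,
      env_schedule = beh$env_schedule, behavior = beh$behavior, rois = rois,
      meta = list(simulated = TRUE, seed = sseed))
  }
  list(sessions = sessions, ground_truth = do.call(rbind, gt))
}
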