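# Synthetic arm plant: paired EMG/kinematics trials with known ground
# truth, emulating ~3-minute self-paced horizontal-plane reaching.
#
# The plant is deliberately simple so ground truth stays analytically
# checkable: minimum-jerk point-to-point reaches with randomized targets
# and hold periods produce smooth joint trajectories (range ~90 deg,
# speed < 70 deg/s); muscle activations follow a reciprocal
# velocity-proportional drive that LEADS motion by the electromechanical
# delay; raw EMG is a band-limited Gaussian carrier amplitude-modulated
# by the activation. Envelope extraction on the output recovers the
# activation up to scale, so a decoder with a prediction interval near
# the electromechanical delay has the information it needs.

#' Synthetic arm-plant configuration
#'
#' @param duration_s trial length in seconds (default 180, i.e. the
#'   ~3-minute single-trial protocol; minimum 30).
#' @param fs_raw acquisition rate in Hz (default 1000).
#' @param joint_range_deg movement range per joint in degrees (default 90
#'   for all three joints).
#' @param max_speed_dps exclusive joint-speed bound in deg/s (default
#'   70); reaches are planned at a design speed of 55 deg/s, comfortably
#'   inside the bound.
#' @param emd_ms electromechanical delay from activation to motion in
#'   milliseconds (default 100; two steps on the 20 Hz decoding grid).
#' @param carrier_band_hz EMG carrier pass band in Hz (default 20-450).
#' @param noise_floor baseline carrier amplitude as a fraction of the
#'   activation-driven amplitude (default 0.02).
#' @param tonic tonic baseline activation (default 0.05).
#' @param hold_range_s range of the randomized inter-reach hold periods
#'   in seconds (default 0.5-2).
#' @param seed integer seed; all generators are pure functions of
#'   (config, seed).
#' @return An object of class `"arm_plant_config"`.
#' @export
arm_plant_config <- function(duration_s = 180, fs_raw = 1000,
                             joint_range_deg = c(90, 90, 90),
                             max_speed_dps = 70, emd_ms = 100,
                             carrier_band_hz = c(20, 450),
                             noise_floor = 0.02, tonic = 0.05,
                             hold_range_s = c(0.5, 2), seed = 7) {
  if (duration_s < 30)
    stop_emg("duration_s must be at least 30", "emgnarx_parameter_error")
  if (max_speed_dps <= 0)
    stop_emg("max_speed_dps must be positive", "emgnarx_parameter_error")
  if (length(joint_range_deg) == 1L) joint_range_deg <- rep(joint_range_deg, 3)
  structure(list(duration_s = duration_s, fs_raw = fs_raw,
                 joint_range_deg = joint_range_deg,
                 max_speed_dps = max_speed_dps, emd_ms = emd_ms,
                 carrier_band_hz = carrier_band_hz,
                 noise_floor = noise_floor, tonic = tonic,
                 hold_range_s = hold_range_s,
                 design_speed_dps = 55,
                 min_reach_s = 0.6,
                 seed = as.integer(seed)),
            class = "arm_plant_config")
}

# minimum-jerk position profile from 0 to 1 over n samples
min_jerk_profile <- function(n) {
  s <- seq(0, 1, length.out = n)
  s^3 * (10 - 15 * s + 6 * s^2)
}

#' Generate smooth multi-joint reaching kinematics
#'
#' Concatenated minimum-jerk point-to-point reaches with randomized
#' targets inside each joint's range and randomized hold periods. All
#' joints share the reach clock (reach onsets and durations) but draw
#' independent targets. The minimum-jerk peak speed is `1.875 D / T`; the
#' reach duration is chosen from the largest per-joint amplitude so the
#' fastest joint moves at the design speed and every joint stays strictly
#' below `max_speed_dps`.
#'
#' @param cfg an [arm_plant_config()].
#' @return Matrix `(duration_s * fs_raw) x 3` of joint angles in degrees.
#' @export
generate_kinematics <- function(cfg) {
  stopifnot(inherits(cfg, "arm_plant_config"))
  fs <- cfg$fs_raw
  n <- round(cfg$duration_s * fs)
  nj <- length(cfg$joint_range_deg)
  with_seed(cfg$seed, {
    ang <- matrix(0, n, nj)
    pos <- cfg$joint_range_deg / 2
    ang[1, ] <- pos
    i <- 1L
    while (i < n) {
      hold <- round(stats::runif(1, cfg$hold_range_s[1], cfg$hold_range_s[2]) * fs)
      i2 <- min(i + hold, n)
      ang[i:i2, ] <- matrix(pos, i2 - i + 1L, nj, byrow = TRUE)
      i <- i2
      if (i >= n) break
      tgt <- stats::runif(nj, 0, cfg$joint_range_deg)
      D <- max(abs(tgt - pos))
      Tr <- max(cfg$min_reach_s, 1.875 * D / cfg$design_speed_dps)
      nr <- round(Tr * fs)
      i2 <- min(i + nr, n)
      prof <- min_jerk_profile(nr + 1L)[seq_len(i2 - i + 1L)]
      for (j in seq_len(nj))
        ang[i:i2, j] <- pos[j] + (tgt[j] - pos[j]) * prof
      pos <- ang[i2, ]
      i <- i2
    }
    colnames(ang) <- JOINTS[seq_len(nj)]
    ang
  })
}

#' Muscle activations from kinematics (reciprocal drive)
#'
#' For each joint the agonist activation is proportional to the positive
#' part of the joint velocity and the antagonist to the negative part,
#' advanced so the muscle drive leads the motion, plus a small tonic
#' baseline; activations saturate at 1. Velocities are scaled by
#' `max_speed_dps`, so the activation range is roughly
#' `[tonic, tonic + design_speed/max_speed]`. Channel order is the six
#' arm muscles as agonist/antagonist pairs per joint (shoulder:
#' adelt/pdelt, elbow: bic/tri, wrist: fcr/ecr).
#'
#' The plant defines its electromechanical delay at the *linear-envelope*
#' level — the signal the decoder actually sees. The causal envelope
#' filter delays the EMG amplitude by its low-frequency group delay
#' (about 160 ms for the default 6th-order 4 Hz filter), so the raw
#' activation is advanced by `emd_ms` *plus* that group delay; the
#' extracted envelope then leads joint velocity by exactly `emd_ms`,
#' which is what makes a decoder with a matching prediction interval
#' information-sufficient.
#'
#' @param angles matrix `n x 3` of joint angles at `cfg$fs_raw`.
#' @param cfg an [arm_plant_config()].
#' @return Matrix `n x 6` of activations in `[0, 1]`.
#' @export
activations_from_kinematics <- function(angles, cfg) {
  stopifnot(inherits(cfg, "arm_plant_config"))
  angles <- as_matrix(angles)
  n <- nrow(angles); nj <- ncol(angles)
  fs <- cfg$fs_raw
  gd <- envelope_group_delay(fs)
  d <- round((cfg$emd_ms / 1000 + gd) * fs)
  vel <- apply(angles, 2, function(a) c(diff(a), 0) * fs)
  adv <- if (d > 0)
    rbind(vel[(d + 1L):n, , drop = FALSE], matrix(0, d, nj))
  else vel
  act <- matrix(0, n, 2L * nj)
  for (j in seq_len(nj)) {
    act[, 2L * j - 1L] <- cfg$tonic + pmax(adv[, j], 0) / cfg$max_speed_dps
    act[, 2L * j] <- cfg$tonic + pmax(-adv[, j], 0) / cfg$max_speed_dps
  }
  act <- pmin(act, 1)
  colnames(act) <- EMG_CHANNELS[seq_len(2L * nj)]
  act
}

#' Synthesize raw surface EMG from activations
#'
#' Per channel, a zero-mean Gaussian carrier is band-pass filtered to the
#' configured carrier band, normalized to unit RMS, and amplitude
#' modulated by `noise_floor + activation`.
#'
#' @param activations matrix `n x 6` in `[0, 1]`.
#' @param cfg an [arm_plant_config()].
#' @return Matrix `n x 6` of raw EMG (arbitrary millivolt-scale units).
#' @export
synthesize_emg <- function(activations, cfg) {
  stopifnot(inherits(cfg, "arm_plant_config"))
  act <- as_matrix(activations)
  if (any(act < 0) || any(act > 1))
    stop_emg("activations must lie in [0, 1]", "emgnarx_input_error")
  n <- nrow(act)
  bp <- signal::butter(4, cfg$carrier_band_hz / (cfg$fs_raw / 2),
                       type = "pass")
  with_seed(cfg$seed + 104729L, {   # independent stream from kinematics
    emg <- matrix(0, n, ncol(act))
    for (ch in seq_len(ncol(act))) {
      w <- as.numeric(signal::filter(bp, stats::rnorm(n)))
      w <- w / sqrt(mean(w^2))
      emg[, ch] <- w * (cfg$noise_floor + act[, ch])
    }
    colnames(emg) <- colnames(act)
    emg
  })
}

#' Generate a complete synthetic trial
#'
#' Composes [generate_kinematics()], [activations_from_kinematics()] and
#' [synthesize_emg()] into a synchronized [trial_record()] (trigger at
#' the first sample).
#'
#' @param cfg an [arm_plant_config()].
#' @return A [trial_record()] at `cfg$fs_raw`.
#' @export
generate_trial <- function(cfg = arm_plant_config()) {
  ang <- generate_kinematics(cfg)
  act <- activations_from_kinematics(ang, cfg)
  emg <- synthesize_emg(act, cfg)
  trial_record(emg = emg, angles = ang, fs = cfg$fs_raw,
               trigger_index = 1L)
}
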