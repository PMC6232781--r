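# Synthetic recording sessions: self-paced left/right head rotations with a
# planted pre-movement EEG signature, ground-truth events, and an IMU yaw
# velocity trace. Every downstream stage of the pipeline is testable against
# sessions produced here.

#' Configuration for the synthetic session generator
#'
#' Parameters describing one recording block of self-paced head rotations.
#' Defaults emulate the study conditions: two 20-minute blocks per
#' participant, 32 EEG channels, 128 Hz IMU output, at least 2 s between
#' rotations started from center, and a slow lateralized pre-movement
#' potential beginning several hundred ms before movement onset.
#'
#' @param n_channels Number of EEG channels (32-channel 10-20 montage).
#' @param raw_eeg_rate Raw EEG sampling rate in Hz. The generator simulates at
#'   512 Hz so downsampling to 128 Hz is a real pipeline step.
#' @param imu_rate IMU sampling rate in Hz.
#' @param block_duration Block length in seconds (default 1200 s = 20 min).
#' @param min_inter_rotation_gap Minimum gap in seconds between consecutive
#'   center-outward rotation onsets.
#' @param rotation_rate Mean rotation rate in rotations per minute.
#' @param rp_lead Seconds before onset at which the planted slow ramp begins.
#' @param rp_amplitude Peak magnitude (recorded units) of the planted
#'   negativity reached at movement onset.
#' @param lateralization_fraction Fraction of `rp_amplitude` carried by the
#'   direction-dependent (hemispherically antisymmetric) component, in [0, 1].
#' @param noise_sd Standard deviation of the background EEG noise
#'   (recorded units) per channel.
#' @param artifact_rate Rate of high-amplitude artifact bursts, events/min.
#' @param artifact_amplitude Peak magnitude of artifact bursts (recorded
#'   units); should exceed the preprocessing rejection threshold.
#' @param velocity_peak Peak yaw velocity of a rotation in deg/s.
#' @param rotation_duration Duration of one out (or return) movement, seconds.
#' @param imu_noise_sd Standard deviation of IMU velocity noise in deg/s while
#'   the head is still.
#' @param hold_range Range (seconds) of the uniformly drawn hold at the side
#'   before the head returns to center.
#' @param seed Integer seed; the same seed and configuration reproduce the
#'   session bit-identically.
#' @return An object of class `synth_config` (a validated list).
#' @export
#' @examples
#' cfg <- synth_config(block_duration = 60, seed = 7)
#' cfg$rotation_rate
synth_config <- function(n_channels = 32,
                         raw_eeg_rate = 512,
                         imu_rate = 128,
                         block_duration = 1200,
                         min_inter_rotation_gap = 2.0,
                         rotation_rate = 6,
                         rp_lead = 0.45,
                         rp_amplitude = 6,
                         lateralization_fraction = 0.5,
                         noise_sd = 10,
                         artifact_rate = 0.5,
                         artifact_amplitude = 200,
                         velocity_peak = 250,
                         rotation_duration = 0.5,
                         imu_noise_sd = 0.1,
                         hold_range = c(0.3, 0.8),
                         seed = 1L) {
  cfg <- list(n_channels = n_channels, raw_eeg_rate = raw_eeg_rate,
              imu_rate = imu_rate, block_duration = block_duration,
              min_inter_rotation_gap = min_inter_rotation_gap,
              rotation_rate = rotation_rate, rp_lead = rp_lead,
              rp_amplitude = rp_amplitude,
              lateralization_fraction = lateralization_fraction,
              noise_sd = noise_sd, artifact_rate = artifact_rate,
              artifact_amplitude = artifact_amplitude,
              velocity_peak = velocity_peak,
              rotation_duration = rotation_duration,
              imu_noise_sd = imu_noise_sd, hold_range = hold_range,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(cfg$n_channels >= 1,
            cfg$raw_eeg_rate > 0, cfg$imu_rate > 0,
            cfg$raw_eeg_rate >= cfg$imu_rate,
            cfg$rotation_rate > 0, cfg$block_duration > 0,
            cfg$min_inter_rotation_gap > 0,
            cfg$rp_lead > 0, cfg$rp_amplitude >= 0,
            cfg$lateralization_fraction >= 0,
            cfg$lateralization_fraction <= 1,
            cfg$noise_sd >= 0, cfg$artifact_rate >= 0,
            cfg$velocity_peak > 0, cfg$rotation_duration > 0,
            cfg$imu_noise_sd >= 0,
            length(cfg$hold_range) == 2, diff(cfg$hold_range) >= 0)
  if (cfg$rp_lead >= cfg$min_inter_rotation_gap)
    stop("rp_lead must be smaller than min_inter_rotation_gap")
  if (cfg$block_duration <= 10 * cfg$min_inter_rotation_gap)
    stop("block_duration must exceed 10 x min_inter_rotation_gap")
  invisible(cfg)
}

# derived sub-seeds so schedule, IMU and EEG rendering are independently
# reproducible from one configuration seed
synth_subseed <- function(cfg, what) {
  offset <- c(schedule = 101L, imu = 211L, eeg = 307L, artifact = 401L)[[what]]
  as.integer((as.numeric(cfg$seed) * 7919 + offset) %% 2147483647)
}

#' Generate the ground-truth rotation schedule for one block
#'
#' Draws self-paced center-outward rotation onsets with inter-onset gaps of at
#' least `min_inter_rotation_gap`, assigns each a direction by a seeded fair
#' coin, and plans the return-to-center movement after a short hold at the
#' side, so that every scored rotation begins with the head facing center.
#' High-amplitude artifact intervals are drawn as a Poisson process.
#'
#' @param cfg A [synth_config()].
#' @return An object of class `ground_truth`: a list with `events` (data frame
#'   `onset`, `direction`, `offset`, `from_center` for the scored
#'   center-outward rotations), `returns` (the unscored return-to-center
#'   movements present in the velocity trace), `artifact_intervals` (data
#'   frame `start`, `end` in seconds) and `block_duration`. If the block is
#'   too short to fit a single rotation, `events` has zero rows and the
#'   `empty` flag is set.
#' @export
#' @examples
#' gt <- generate_schedule(synth_config(block_duration = 120, seed = 1))
#' head(gt$events)
generate_schedule <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(synth_subseed(cfg, "schedule"))
  dur <- cfg$rotation_duration
  mean_gap <- 60 / cfg$rotation_rate
  first_margin <- 3.0           # room for pre-onset epochs before first event
  end_margin <- dur + cfg$hold_range[2] + dur + 0.5

  onsets <- numeric(0); holds <- numeric(0)
  t <- first_margin
  repeat {
    hold <- runif(1, cfg$hold_range[1], cfg$hold_range[2])
    # the out-hold-return excursion must complete before the next onset
    g0 <- max(cfg$min_inter_rotation_gap, 2 * dur + hold + 0.25)
    extra <- max(mean_gap - g0, 0.05)
    t <- t + if (length(onsets) == 0) rexp(1, 1 / mean_gap) else
      g0 + rexp(1, 1 / extra)
    if (t > cfg$block_duration - end_margin) break
    onsets <- c(onsets, t); holds <- c(holds, hold)
  }

  n <- length(onsets)
  empty <- n == 0
  if (empty)
    message("generate_schedule: block too short (or rate too low) to fit a ",
            "single rotation; returning an empty schedule")
  dirs <- if (n) sample(c("left", "right"), n, replace = TRUE) else character(0)
  events <- data.frame(onset = onsets, direction = dirs,
                       offset = onsets + dur,
                       from_center = rep(TRUE, n),
                       stringsAsFactors = FALSE)
  returns <- data.frame(onset = onsets + dur + holds,
                        direction = ifelse(dirs == "left", "right", "left"),
                        offset = onsets + 2 * dur + holds,
                        stringsAsFactors = FALSE)

  set.seed(synth_subseed(cfg, "artifact"))
  n_art <- rpois(1, cfg$artifact_rate * cfg$block_duration / 60)
  if (n_art > 0) {
    a_start <- sort(runif(n_art, 1, cfg$block_duration - 1))
    a_len <- runif(n_art, 0.2, 0.6)
    artifacts <- data.frame(start = a_start,
                            end = pmin(a_start + a_len, cfg$block_duration))
  } else {
    artifacts <- data.frame(start = numeric(0), end = numeric(0))
  }

  structure(list(events = events, returns = returns,
                 artifact_intervals = artifacts,
                 block_duration = cfg$block_duration, empty = empty),
            class = "ground_truth")
}

# raised-cosine velocity pulse, compact support [0, dur], peak at dur/2
raised_cosine_pulse <- function(t_rel, dur, peak) {
  v <- numeric(length(t_rel))
  inside <- t_rel >= 0 & t_rel <= dur
  v[inside] <- peak * 0.5 * (1 - cos(2 * pi * t_rel[inside] / dur))
  v
}

#' Render the IMU yaw-velocity trace for a schedule
#'
#' Produces the head-yaw angular-velocity signal at `cfg$imu_rate`:
#' near-zero Gaussian sensor noise while the head is still, and one smooth
#' raised-cosine velocity pulse per movement. Rightward rotation is positive
#' by convention. Each scored event contributes an outward pulse starting at
#' its onset; the planned return movements contribute opposite-sign pulses so
#' that the integrated position comes back to center.
#'
#' @param gt A `ground_truth` from [generate_schedule()].
#' @param cfg The same [synth_config()].
#' @return A data frame with columns `time_s` and `yaw_velocity` (deg/s),
#'   `round(block_duration * imu_rate)` rows.
#' @export
render_imu <- function(gt, cfg) {
  stopifnot(inherits(gt, "ground_truth"))
  set.seed(synth_subseed(cfg, "imu"))
  n <- round(cfg$block_duration * cfg$imu_rate)
  t <- (seq_len(n) - 1) / cfg$imu_rate
  v <- rnorm(n, 0, cfg$imu_noise_sd)
  add_pulse <- function(onset, direction) {
    sgn <- if (direction == "right") 1 else -1
    i0 <- max(1L, floor(onset * cfg$imu_rate) + 1L)
    i1 <- min(n, ceiling((onset + cfg$rotation_duration) * cfg$imu_rate) + 1L)
    idx <- i0:i1
    v[idx] <<- v[idx] +
      raised_cosine_pulse(t[idx] - onset, cfg$rotation_duration,
                          sgn * cfg$velocity_peak)
  }
  for (i in seq_len(nrow(gt$events)))
    add_pulse(gt$events$onset[i], gt$events$direction[i])
  for (i in seq_len(nrow(gt$returns)))
    add_pulse(gt$returns$onset[i], gt$returns$direction[i])
  data.frame(time_s = t, yaw_velocity = v)
}

# pink-ish background noise: white noise spectrally shaped toward 1/f,
# standardized to unit sd. FFT shaping keeps generation seeded and fast.
pinkish_noise <- function(n, rate) {
  x <- rnorm(n)
  f <- seq(0, rate, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, rate - f)                     # two-sided frequency magnitude
  shape <- 1 / sqrt(pmax(f, 0.25))           # flatten below 0.25 Hz
  y <- Re(fft(fft(x) * shape, inverse = TRUE)) / n
  y / sd(y)
}

#' Render multichannel EEG with the planted pre-movement signature
#'
#' Background activity is pink-ish noise of standard deviation
#' `cfg$noise_sd` per channel. For every scored rotation a slow linear ramp
#' is added over central/frontal channels, rising from zero at
#' `onset - rp_lead` to a negativity of magnitude `rp_amplitude` at onset
#' (weighted per electrode by the montage's `rp_weight`), plus a lateralized
#' component of magnitude `lateralization_fraction * rp_amplitude` whose sign
#' is antisymmetric across the midline and flips with rotation direction
#' (contralateral hemisphere more negative). Artifact intervals receive a
#' high-amplitude raised-cosine burst on all channels.
#'
#' @inheritParams render_imu
#' @return A matrix of `round(block_duration * raw_eeg_rate)` rows (samples)
#'   by `n_channels` columns, with electrode labels as column names.
#' @export
render_eeg <- function(gt, cfg) {
  stopifnot(inherits(gt, "ground_truth"))
  mont <- montage_32()[seq_len(cfg$n_channels), ]
  set.seed(synth_subseed(cfg, "eeg"))
  n <- round(cfg$block_duration * cfg$raw_eeg_rate)
  t <- (seq_len(n) - 1) / cfg$raw_eeg_rate
  eeg <- matrix(0, n, cfg$n_channels, dimnames = list(NULL, mont$label))
  for (ch in seq_len(cfg$n_channels))
    eeg[, ch] <- pinkish_noise(n, cfg$raw_eeg_rate) * cfg$noise_sd

  if (cfg$rp_amplitude > 0 && nrow(gt$events) > 0) {
    A <- cfg$rp_amplitude
    lat <- cfg$lateralization_fraction
    for (i in seq_len(nrow(gt$events))) {
      onset <- gt$events$onset[i]
      sgn <- if (gt$events$direction[i] == "right") 1 else -1
      i0 <- max(1L, floor((onset - cfg$rp_lead) * cfg$raw_eeg_rate) + 1L)
      i1 <- min(n, floor(onset * cfg$raw_eeg_rate) + 1L)
      ramp <- (t[i0:i1] - (onset - cfg$rp_lead)) / cfg$rp_lead
      ramp <- pmin(pmax(ramp, 0), 1)
      # per-channel amplitude: shared negativity + lateralized part whose sign
      # follows hemisphere x direction (lat_weight > 0 on the left hemisphere)
      amp <- -A * mont$rp_weight - sgn * lat * A * mont$lat_weight
      eeg[i0:i1, ] <- eeg[i0:i1, ] + outer(ramp, amp)
    }
  }

  if (nrow(gt$artifact_intervals) > 0) {
    for (i in seq_len(nrow(gt$artifact_intervals))) {
      a0 <- gt$artifact_intervals$start[i]; a1 <- gt$artifact_intervals$end[i]
      i0 <- max(1L, floor(a0 * cfg$raw_eeg_rate) + 1L)
      i1 <- min(n, floor(a1 * cfg$raw_eeg_rate) + 1L)
      burst <- raised_cosine_pulse(t[i0:i1] - a0, a1 - a0,
                                   cfg$artifact_amplitude)
      eeg[i0:i1, ] <- eeg[i0:i1, ] + burst
    }
  }
  eeg
}

#' Generate one complete synthetic recording block
#'
#' Convenience wrapper running [generate_schedule()], [render_imu()] and
#' [render_eeg()] for one block.
#'
#' @param cfg A [synth_config()].
#' @param block Integer block index (1 or 2); blocks of one participant use
#'   sub-seeds derived from `cfg$seed` and the block index.
#' @return An object of class `recording_session`: list with `eeg` (samples x
#'   channels matrix at `raw_eeg_rate`), `eeg_rate`, `channels`, `imu` (data
#'   frame `time_s`, `yaw_velocity`), `imu_rate`, `ground_truth`, `cfg`,
#'   `block`.
#' @export
#' @examples
#' s <- synth_session(synth_config(block_duration = 60, seed = 3))
#' dim(s$eeg)
#' nrow(s$ground_truth$events)
synth_session <- function(cfg, block = 1L) {
  bcfg <- cfg
  bcfg$seed <- as.integer((as.numeric(cfg$seed) * 131 + block) %% 2147483647)
  gt <- generate_schedule(bcfg)
  imu <- render_imu(gt, bcfg)
  eeg <- render_eeg(gt, bcfg)
  structure(list(eeg = eeg, eeg_rate = cfg$raw_eeg_rate,
                 channels = colnames(eeg), imu = imu,
                 imu_rate = cfg$imu_rate, ground_truth = gt,
                 cfg = bcfg, block = block),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat("<recording_session> block", x$block, "\n")
  cat("  EEG:", nrow(x$eeg), "samples x", ncol(x$eeg), "channels @",
      x$eeg_rate, "Hz\n")
  cat("  IMU:", nrow(x$imu), "frames @", x$imu_rate, "Hz\n")
  cat("  events:", nrow(x$ground_truth$events), "scored rotations,",
      nrow(x$ground_truth$artifact_intervals), "artifact intervals\n")
  invisible(x)
}
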