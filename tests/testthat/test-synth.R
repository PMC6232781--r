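# Synthetic-session generator: schedule constraints, IMU rendering, planted
# EEG signature.

test_that("same seed and config reproduce the session bit-identically", {
  cfg <- synth_config(block_duration = 30, seed = 9)
  s1 <- synth_session(cfg)
  s2 <- synth_session(cfg)
  expect_identical(s1$eeg, s2$eeg)
  expect_identical(s1$imu, s2$imu)
  expect_identical(s1$ground_truth, s2$ground_truth)
})

test_that("a block too short for one rotation yields an explicit empty schedule", {
  cfg <- synth_config(block_duration = 30, rotation_rate = 0.001, seed = 3)
  expect_message(gt <- generate_schedule(cfg), "empty schedule")
  expect_true(gt$empty)
  expect_equal(nrow(gt$events), 0)
  imu <- render_imu(gt, cfg)
  expect_equal(nrow(imu), round(30 * 128))
  # pure sensor noise: mean near zero, sd near the configured level
  expect_lt(abs(mean(imu$yaw_velocity)), cfg$imu_noise_sd)
  expect_equal(sd(imu$yaw_velocity), cfg$imu_noise_sd, tolerance = 0.05)
})

test_that("inter-onset gaps respect the 2-s minimum across many seeds", {
  min_gap <- Inf
  for (seed in 1:200) {
    gt <- generate_schedule(synth_config(block_duration = 1200,
                                         rotation_rate = 6, seed = seed))
    if (nrow(gt$events) > 1)
      min_gap <- min(min_gap, min(diff(gt$events$onset)))
    expect_false(is.unsorted(gt$events$onset, strictly = TRUE))
    expect_true(all(gt$events$direction %in% c("left", "right")))
  }
  expect_gte(min_gap, 2.0)
})

test_that("rotation counts and directions are balanced in distribution", {
  dirs <- unlist(lapply(1:30, function(seed) {
    generate_schedule(synth_config(block_duration = 300, seed = seed))$events$direction
  }))
  n <- length(dirs)
  expect_gt(n, 300)   # ~6/min x 5 min x 30 seeds, minus margins
  p_right <- mean(dirs == "right")
  expect_lt(abs(p_right - 0.5), 3 * sqrt(0.25 / n))
})

test_that("IMU pulse peaks at the planted time with the planted sign", {
  cfg <- synth_config(block_duration = 30, rotation_rate = 2, seed = 11)
  gt <- generate_schedule(cfg)
  gt$events <- data.frame(onset = 10, direction = "right", offset = 10.5,
                          from_center = TRUE)
  gt$returns <- gt$returns[0, ]
  imu <- render_imu(gt, cfg)
  expect_equal(nrow(imu), round(30 * 128))
  in_pulse <- imu$time_s >= 10 & imu$time_s <= 10 + cfg$rotation_duration
  peak_t <- imu$time_s[in_pulse][which.max(imu$yaw_velocity[in_pulse])]
  # raised cosine peaks mid-movement
  expect_equal(peak_t, 10 + cfg$rotation_duration / 2, tolerance = 2 / 128)
  expect_gt(max(imu$yaw_velocity[in_pulse]), 0.9 * cfg$velocity_peak)
})

test_that("signal-free EEG is noise with the configured channel sd", {
  cfg <- synth_config(block_duration = 30, rp_amplitude = 0,
                      artifact_rate = 0, noise_sd = 10, seed = 13)
  gt <- generate_schedule(cfg)
  eeg <- render_eeg(gt, cfg)
  expect_equal(dim(eeg), c(round(30 * 512), 32))
  sds <- apply(eeg, 2, sd)
  expect_equal(unname(sds), rep(10, 32), tolerance = 0.02)
  expect_lt(max(abs(eeg)), 80)   # no artifact excursions when rate = 0
})

test_that("onset-locked averaging recovers the planted ramp amplitude", {
  # many events, moderate noise: mean over (-lead, 0) minus mean over
  # (-2 lead, -lead) approaches -A/2 x channel weight at a central electrode
  cfg <- synth_config(block_duration = 600, rotation_rate = 10,
                      rp_amplitude = 8, lateralization_fraction = 0,
                      noise_sd = 5, artifact_rate = 0, seed = 17)
  gt <- generate_schedule(cfg)
  expect_gte(nrow(gt$events), 90)
  eeg <- render_eeg(gt, cfg)
  rate <- cfg$raw_eeg_rate
  cz <- which(colnames(eeg) == "Cz")   # rp_weight 1, lat_weight 0
  lead_n <- round(cfg$rp_lead * rate)
  late <- early <- numeric(0)
  for (on in gt$events$onset) {
    i_on <- floor(on * rate)
    late <- c(late, mean(eeg[(i_on - lead_n + 1):i_on, cz]))
    early <- c(early, mean(eeg[(i_on - 2 * lead_n + 1):(i_on - lead_n), cz]))
  }
  # expected difference: mean of a 0 -> -A linear ramp is -A/2
  expect_equal(mean(late) - mean(early), -cfg$rp_amplitude / 2,
               tolerance = 0.12 * cfg$rp_amplitude)
})

test_that("zero lateralization leaves left and right pre-onset EEG symmetric", {
  cfg <- synth_config(block_duration = 600, rotation_rate = 10,
                      rp_amplitude = 8, lateralization_fraction = 0,
                      noise_sd = 5, artifact_rate = 0, seed = 19)
  gt <- generate_schedule(cfg)
  eeg <- render_eeg(gt, cfg)
  rate <- cfg$raw_eeg_rate
  lead_n <- round(cfg$rp_lead * rate)
  side_means <- function(dir, ch) {
    ons <- gt$events$onset[gt$events$direction == dir]
    vapply(ons, function(on) {
      i_on <- floor(on * rate)
      mean(eeg[(i_on - lead_n + 1):i_on, ch])
    }, numeric(1))
  }
  for (ch in c("C3", "C4")) {
    tt <- t.test(side_means("left", ch), side_means("right", ch))
    expect_gt(tt$p.value, 1e-4)   # no systematic left/right asymmetry
  }
})

test_that("planted artifacts exceed the rejection threshold after preprocessing", {
  cfg <- synth_config(block_duration = 60, artifact_rate = 3,
                      rp_amplitude = 0, seed = 23)
  gt <- generate_schedule(cfg)
  expect_gt(nrow(gt$artifact_intervals), 0)
  eeg <- render_eeg(gt, cfg)
  pcfg <- preproc_config()
  filt <- eeg_resample(bandpass(eeg, cfg$raw_eeg_rate, pcfg),
                       cfg$raw_eeg_rate, 128)
  for (i in seq_len(nrow(gt$artifact_intervals))) {
    i0 <- max(1, floor(gt$artifact_intervals$start[i] * 128))
    i1 <- min(nrow(filt), ceiling(gt$artifact_intervals$end[i] * 128))
    expect_gt(max(abs(filt[i0:i1, ])), pcfg$artifact_threshold)
  }
})

test_that("every planted event is recoverable by the detector within 2 frames", {
  cfg <- synth_config(block_duration = 600, seed = 29)
  gt <- generate_schedule(cfg)
  expect_gte(nrow(gt$events), 50)
  imu <- render_imu(gt, cfg)
  det <- onset_detector_config()
  thr <- estimate_noise_threshold(imu, det, cfg$imu_rate)
  lf <- label_and_filter(detect_onsets(imu, thr, det, cfg$imu_rate), imu,
                         det, cfg$imu_rate)
  err_frames <- vapply(gt$events$onset, function(on)
    min(abs(lf$scored_events$onset - on)) * cfg$imu_rate, numeric(1))
  expect_gte(mean(err_frames <= 2), 0.95)
})
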