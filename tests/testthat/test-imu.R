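# Onset detection from the yaw-velocity trace: noise threshold, sustained
# threshold crossing, frame labeling, center-outward filtering.

test_that("noise threshold is multiplier x stationary sd and scales linearly", {
  set.seed(1)
  v <- rnorm(1e4, 0, 1.0)
  cfg <- onset_detector_config(stationary_segment = c(0, 1e4 / 128))
  thr <- estimate_noise_threshold(v, cfg, rate = 128)
  expect_equal(thr, 3.0, tolerance = 0.05)
  cfg6 <- onset_detector_config(threshold_multiplier = 6,
                                stationary_segment = c(0, 1e4 / 128))
  expect_equal(estimate_noise_threshold(v, cfg6, rate = 128), 2 * thr)
})

test_that("degenerate or too-short stationary segments are refused", {
  expect_error(estimate_noise_threshold(rep(0, 1000),
                                        onset_detector_config(), 128),
               "degenerate")
  cfg <- onset_detector_config(stationary_segment = c(0, 0.05))
  expect_error(estimate_noise_threshold(rnorm(1000), cfg, 128), "shorter")
})

test_that("sustained step crossings are detected at the crossing frame", {
  rate <- 128
  v <- rep(0, 10 * rate)
  v[(2 * rate + 1):(3 * rate)] <- 2.0      # 1-s step at t = 2.0 s
  ev <- detect_onsets(v, threshold = 1.0, rate = rate)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 2.0, tolerance = 1 / rate)
  expect_equal(ev$direction, "right")
  expect_equal(ev$offset, 3.0, tolerance = 1 / rate)
})

test_that("spikes shorter than the 125-ms window are rejected", {
  rate <- 128
  v <- rep(0, 5 * rate)
  v[257:262] <- 5.0                        # ~50 ms spike
  expect_equal(nrow(detect_onsets(v, 1.0, rate = rate)), 0)
  expect_equal(nrow(detect_onsets(rep(0, 5 * rate), 1.0, rate = rate)), 0)
  expect_equal(nrow(detect_onsets(numeric(0), 1.0, rate = rate)), 0)
})

test_that("sub-window dips do not split one movement", {
  rate <- 128
  v <- rep(0, 5 * rate)
  v[129:384] <- 3.0
  v[250:255] <- 0.0                        # 6-frame dip inside the movement
  ev <- detect_onsets(v, 1.0, rate = rate)
  expect_equal(nrow(ev), 1)
})

test_that("sign flip swaps all directions and nothing else", {
  s <- test_session()
  thr <- estimate_noise_threshold(s$imu, rate = s$imu_rate)
  ev1 <- detect_onsets(s$imu, thr, rate = s$imu_rate)
  flipped <- s$imu
  flipped$yaw_velocity <- -flipped$yaw_velocity
  ev2 <- detect_onsets(flipped, thr, rate = s$imu_rate)
  expect_equal(ev1$onset, ev2$onset)
  expect_equal(ev1$offset, ev2$offset)
  expect_true(all(ev1$direction != ev2$direction))
})

test_that("raising the threshold never increases the event count", {
  s <- test_session()
  thr <- estimate_noise_threshold(s$imu, rate = s$imu_rate)
  counts <- vapply(thr * c(1, 2, 5, 20, 100, 1000), function(th)
    nrow(detect_onsets(s$imu, th, rate = s$imu_rate)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("frame labels cover exactly the detected spans", {
  rate <- 128
  v <- rep(0, 20 * rate)
  v[(2 * rate + 1):(2.5 * rate)] <- 2      # right
  v[(6 * rate + 1):(6.5 * rate)] <- -2     # left
  ev <- detect_onsets(v, 1.0, rate = rate)
  expect_equal(ev$direction, c("right", "left"))
  lf <- label_and_filter(ev, v, rate = rate)
  expected <- sum(round((ev$offset - ev$onset) * rate))
  expect_equal(sum(lf$labels != "none"), expected)
  expect_equal(as.vector(table(lf$labels)[c("left", "right")]),
               rep(round(0.5 * rate), 2))
})

test_that("rotations launched away from center are excluded", {
  rate <- 128
  dur <- 0.5
  pulse <- function(sign) sign * 100 * 0.5 *
    (1 - cos(2 * pi * seq(0, dur, by = 1 / rate) / dur))
  v <- rep(0, 30 * rate)
  put <- function(t0, p) {
    idx <- round(t0 * rate) + seq_along(p)
    v[idx] <<- p
    v
  }
  # out-and-back pair: center -> left -> center, then center -> right
  v <- put(2, pulse(-1)); v <- put(4, pulse(+1))      # returns to center
  v <- put(8, pulse(+1)); v <- put(10, pulse(-1))
  # a leftward rotation launched while still displaced right
  v <- put(14, pulse(+1))                             # go right, no return
  v <- put(17, pulse(-0.3))                           # small left, off-center
  ev <- detect_onsets(v, 1.0, rate = rate)
  lf <- label_and_filter(ev, v, rate = rate)
  sc <- lf$scored_events
  # first movement of each out-and-back pair is scored
  expect_true(any(abs(sc$onset - 2) < 0.1 & sc$direction == "left"))
  expect_true(any(abs(sc$onset - 8) < 0.1 & sc$direction == "right"))
  expect_true(any(abs(sc$onset - 14) < 0.1))
  # the off-center launch at t = 17 is excluded
  expect_false(any(abs(sc$onset - 17) < 0.2))
})

test_that("a single event in a session counts as center-outward", {
  rate <- 128
  v <- rep(0, 10 * rate)
  v[(3 * rate):(3.5 * rate)] <- 50
  ev <- detect_onsets(v, 1.0, rate = rate)
  lf <- label_and_filter(ev, v, rate = rate)
  expect_equal(nrow(lf$scored_events), 1)
  expect_true(lf$scored_events$from_center)
})
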