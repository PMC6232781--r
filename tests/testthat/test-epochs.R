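# Window geometry, no-rotation clearance, balancing, and the 72/18/10 split.

test_that("jittered window geometry matches the printed parameters", {
  for (onset in c(10, 37.5, 600.123)) {
    w <- rotation_windows(onset)
    expect_equal(nrow(w), 7)
    # closest window ends 188 ms, furthest starts 488 ms before onset
    expect_equal(max(w$end), onset - 0.188)
    expect_equal(min(w$start), onset - 0.488)
    # middle window center 338 ms before onset
    expect_equal(w$start[4] + 0.125, onset - 0.338)
    expect_equal(w$t_center[4], -0.338)
    # geometry identity: the union spans exactly 300 ms
    expect_equal(max(w$end) - min(w$start), 0.300)
    # evenly spaced starts, overlapping neighbours
    expect_equal(diff(w$start), rep(0.050 / 6, 6))
  }
  w <- rotation_windows(10)
  expect_equal(c(w$start[4], w$end[4]), c(9.537, 9.787))
})

test_that("onsets too early in the recording are skipped with a message", {
  expect_message(w <- rotation_windows(0.1), "skipped")
  expect_null(w)
})

test_that("sampled no-rotation windows respect clearance and spans", {
  rate <- 128
  labels <- factor(rep("none", 20 * rate), levels = c("none", "left", "right"))
  ev <- data.frame(onset = 5.0, offset = 5.5, direction = "right")
  labels[(5 * rate):(5.5 * rate)] <- "right"
  nr <- no_rotation_windows(ev, labels, n_required = 200, seed = 7)
  # never ends in the second before the onset, never overlaps the span
  expect_true(all(nr$end <= 4.0 | nr$start >= 5.5))
  expect_true(all(nr$end <= 20))
  # determinism
  nr2 <- no_rotation_windows(ev, labels, n_required = 200, seed = 7)
  expect_identical(nr, nr2)
  # no events: anywhere in bounds
  nr3 <- no_rotation_windows(ev[0, ], factor(rep("none", 5 * rate),
                                             levels = levels(labels)),
                             n_required = 50, seed = 1)
  expect_equal(nrow(nr3), 50)
  expect_error(no_rotation_windows(ev, labels[1:700], n_required = 1e5,
                                   seed = 1),
               "eligible")
})

test_that("feature vectors have length channels x samples and fixed order", {
  s <- test_session()
  dp <- detect_and_preprocess(s)
  ds <- build_epoch_dataset(dp$session, dp$scored, dp$labels,
                            all_events = dp$events, seed = 1)
  expect_equal(ncol(ds$features), 32 * 32)
  expect_equal(ncol(ds$features), 1024)
  # channel-major order: first 32 entries are channel 1's samples
  i0 <- round(ds$window_start[1] * 128) + 1
  expect_equal(ds$features[1, 1:32], unname(dp$session$eeg[i0:(i0 + 31), 1]))
  expect_equal(ds$features[1, 33:64], unname(dp$session$eeg[i0:(i0 + 31), 2]))
  # every scored rotation contributes 7 windows (no artifacts at defaults)
  rot <- ds$label != "none"
  expect_equal(sum(rot) %% 7, 0)
})

test_that("class balancing undersamples to min(left, right)", {
  set.seed(5)
  n <- c(none = 500, left = 70, right = 84)
  ds <- structure(list(
    features = matrix(rnorm(sum(n) * 8), sum(n), 8),
    label = factor(rep(names(n), n), levels = c("none", "left", "right")),
    t_center = rep(NA_real_, sum(n)), event_id = rep(NA_integer_, sum(n)),
    window_start = seq_len(sum(n)), block = 1L, n_rejected = 0L,
    rate = 128, n_channels = 1), class = "epoch_dataset")
  bal <- balance_classes(ds, seed = 3)
  expect_equal(as.vector(table(bal$label)), c(70, 70, 70))
  # already balanced: unchanged contents
  bal2 <- balance_classes(bal, seed = 9)
  expect_equal(table(bal2$label), table(bal$label))
  expect_setequal(bal2$window_start, bal$window_start)
  ds$label[ds$label == "left"] <- "none"
  ds$label <- droplevels(ds$label)
  ds$label <- factor(as.character(ds$label), levels = c("none", "left", "right"))
  expect_error(balance_classes(ds, 1), "empty class")
})

test_that("split yields a contiguous test stream and a leak-free partition", {
  s1 <- test_session("split1", block_duration = 200, seed = 51)
  s2 <- synth_session(s1$cfg, block = 2)
  dp1 <- detect_and_preprocess(s1)
  dp2 <- detect_and_preprocess(s2)
  ds1 <- build_epoch_dataset(dp1$session, dp1$scored, dp1$labels,
                             all_events = dp1$events, seed = 1)
  ds2 <- build_epoch_dataset(dp2$session, dp2$scored, dp2$labels,
                             all_events = dp2$events, seed = 2)
  comb <- combine_epochs(ds1, ds2)
  sp <- split_dataset(comb, c(200, 200), seed = 11)

  # test stream: one contiguous 10% (40 s) segment at the end of block 2
  expect_equal(sp$test_stream$end - sp$test_stream$start, 40)
  expect_equal(sp$test_stream$end, 200)
  expect_equal(sp$test_stream$block, 2)

  # partition: each epoch in exactly one set
  key <- function(d) paste(d$block, round(d$window_start * 128))
  k <- c(key(sp$train), key(sp$val), key(sp$test))
  expect_equal(length(k) + sp$n_dropped, length(comb$label))
  expect_equal(anyDuplicated(k), 0)

  # all test epochs lie wholly inside the stream
  expect_true(all(sp$test$window_start >= sp$test_stream$start &
                    sp$test$window_start + 0.25 <= sp$test_stream$end))

  # train : val epoch ratio approximates 72 : 18 = 4 : 1 (group-granular)
  r <- length(sp$train$label) / length(sp$val$label)
  expect_gt(r, 3.0)
  expect_lt(r, 5.3)

  # leakage: no rotation's windows span partitions
  for (d in list(sp$train, sp$val, sp$test)) {
    ids <- stats::na.omit(unique(paste(d$block, d$event_id)[!is.na(d$event_id)]))
    for (o in list(sp$train, sp$val, sp$test)) {
      if (identical(d, o)) next
      ids_o <- unique(paste(o$block, o$event_id)[!is.na(o$event_id)])
      expect_length(intersect(ids, ids_o), 0)
    }
  }
})
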