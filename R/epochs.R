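# Labeled-epoch construction: seven jittered pre-onset windows per scored
# rotation, clearance-checked no-rotation windows, class balancing by
# undersampling, and the 72/18/10 split with a contiguous test stream.

#' Pre-onset window geometry
#'
#' Each scored rotation contributes `n_windows` partially overlapping 250-ms
#' windows. The window closest to onset ends 188 ms before it, the furthest
#' starts 488 ms before it; with seven windows the start offsets are evenly
#' spaced over \[-488, -438\] ms and the middle window is centered 338 ms
#' before onset. No-rotation windows must end at least
#' `no_rotation_clearance` seconds before the next rotation onset.
#'
#' @param width Window width in seconds (0.250 s = 32 samples at 128 Hz).
#' @param closest_end Seconds before onset at which the closest window ends.
#' @param furthest_start Seconds before onset at which the furthest window
#'   starts.
#' @param n_windows Number of jittered windows per rotation (odd).
#' @param no_rotation_clearance Minimum gap in seconds between the end of a
#'   no-rotation window and the next rotation onset.
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(width = 0.250,
                        closest_end = 0.188,
                        furthest_start = 0.488,
                        n_windows = 7,
                        no_rotation_clearance = 1.000) {
  stopifnot(width > 0, closest_end > 0, furthest_start > closest_end,
            n_windows >= 1, n_windows %% 2 == 1,
            no_rotation_clearance >= 0,
            furthest_start - width < closest_end + width)  # windows overlap
  structure(list(width = width, closest_end = closest_end,
                 furthest_start = furthest_start, n_windows = n_windows,
                 no_rotation_clearance = no_rotation_clearance),
            class = "window_spec")
}

#' Jittered pre-onset windows for one rotation
#'
#' @param onset Rotation onset time in seconds.
#' @param spec A [window_spec()].
#' @return Data frame of `n_windows` rows: `start`, `end`, `t_center`
#'   (window center relative to onset, negative), ordered from furthest to
#'   closest; or `NULL` (with a message) when the recording does not cover
#'   the furthest window.
#' @export
#' @examples
#' rotation_windows(10)           # middle window [9.537, 9.787], center 9.662
rotation_windows <- function(onset, spec = window_spec()) {
  if (onset - spec$furthest_start < 0) {
    message(sprintf("rotation at %.3f s too early for pre-onset windows; skipped",
                    onset))
    return(NULL)
  }
  starts <- seq(onset - spec$furthest_start,
                onset - spec$closest_end - spec$width,
                length.out = spec$n_windows)
  data.frame(start = starts, end = starts + spec$width,
             t_center = starts + spec$width / 2 - onset)
}

#' Sample no-rotation windows with clearance
#'
#' Draws window start times uniformly (seeded) over all eligible frames of
#' the 128 Hz timeline. A window is eligible when it overlaps no detected
#' rotation span (any frame labeled non-`none`) and ends at least
#' `spec$no_rotation_clearance` seconds before the next rotation onset.
#'
#' @param events Data frame of all detected events (onset/offset in seconds);
#'   clearance is enforced against every onset, scored or not.
#' @param frame_labels Factor of per-frame labels from [label_and_filter()].
#' @param spec A [window_spec()].
#' @param n_required Number of windows to sample.
#' @param seed Integer seed for the draw.
#' @param rate Frame rate of `frame_labels` in Hz.
#' @return Data frame with `start`, `end` times (seconds) of the sampled
#'   windows.
#' @export
no_rotation_windows <- function(events, frame_labels, spec = window_spec(),
                                n_required = 100, seed = 1, rate = 128) {
  n <- length(frame_labels)
  w <- round(spec$width * rate)
  if (n < w) stop("trace shorter than one window")
  busy <- as.integer(frame_labels != "none")
  cbusy <- c(0, cumsum(busy))
  starts <- seq_len(n - w + 1)
  clean <- (cbusy[starts + w] - cbusy[starts]) == 0

  end_time <- (starts - 1) / rate + spec$width
  onsets <- sort(events$onset)
  if (length(onsets) > 0) {
    # next onset strictly after each window end
    nxt <- findInterval(end_time, onsets) + 1
    gap <- ifelse(nxt <= length(onsets), onsets[nxt] - end_time, Inf)
    clear <- gap >= spec$no_rotation_clearance
  } else {
    clear <- rep(TRUE, length(starts))
  }
  eligible <- starts[clean & clear]
  if (length(eligible) < n_required)
    stop(sprintf("only %d eligible no-rotation frames for %d requested windows",
                 length(eligible), n_required))
  set.seed(as.integer(seed))
  picked <- sort(sample(eligible, n_required))
  data.frame(start = (picked - 1) / rate,
             end = (picked - 1) / rate + spec$width)
}

# cut one window from the 128 Hz EEG and flatten channel-major
# (channel outer, time inner): feature length = n_channels * width * rate
cut_epoch_features <- function(eeg, start_time, width, rate) {
  i0 <- round(start_time * rate) + 1L
  i1 <- i0 + round(width * rate) - 1L
  if (i0 < 1 || i1 > nrow(eeg)) return(NULL)
  as.vector(eeg[i0:i1, ])    # columns are channels: channel-major flatten
}

#' Build the labeled epoch dataset for one block
#'
#' Cuts the seven jittered pre-onset windows for every scored (center-outward)
#' rotation and the requested number of clearance-checked no-rotation windows
#' from the preprocessed 128 Hz EEG, applies amplitude rejection
#' ([reject_interval()]) to every window, and assembles the feature matrix
#' (one flattened channel x sample vector per epoch).
#'
#' @param session A preprocessed `recording_session` (128 Hz EEG).
#' @param scored_events Center-outward events (from [label_and_filter()]).
#' @param frame_labels Per-frame labels aligned to the 128 Hz timeline.
#' @param all_events All detected events, for no-rotation clearance.
#' @param spec A [window_spec()].
#' @param n_none Number of no-rotation windows to sample before rejection;
#'   default `2 *` the number of rotation windows.
#' @param seed Seed for the no-rotation draw.
#' @param preproc A [preproc_config()] supplying the rejection threshold.
#' @return An object of class `epoch_dataset`: list with `features` (epochs x
#'   1024 matrix), `label` (factor none/left/right), `t_center` (window
#'   center relative to onset; `NA` for none), `event_id` (grouping key; `NA`
#'   for none), `window_start` (seconds), `block`, `n_rejected`.
#' @export
build_epoch_dataset <- function(session, scored_events, frame_labels,
                                all_events = scored_events,
                                spec = window_spec(),
                                n_none = NULL, seed = 1,
                                preproc = preproc_config()) {
  stopifnot(isTRUE(session$preprocessed))
  eeg <- session$eeg
  rate <- session$eeg_rate
  rows <- list(); lab <- character(0); tc <- numeric(0)
  eid <- integer(0); ws <- numeric(0)
  n_rejected <- 0L

  for (k in seq_len(nrow(scored_events))) {
    wnd <- rotation_windows(scored_events$onset[k], spec)
    if (is.null(wnd)) next
    for (j in seq_len(nrow(wnd))) {
      f <- cut_epoch_features(eeg, wnd$start[j], spec$width, rate)
      if (is.null(f)) next
      if (!reject_interval(matrix(f, ncol = ncol(eeg)), preproc)) {
        n_rejected <- n_rejected + 1L
        next
      }
      rows[[length(rows) + 1L]] <- f
      lab <- c(lab, scored_events$direction[k])
      tc <- c(tc, wnd$t_center[j])
      eid <- c(eid, k)
      ws <- c(ws, wnd$start[j])
    }
  }
  n_rot <- length(rows)
  if (is.null(n_none)) n_none <- max(2L * n_rot, 14L)

  nr <- no_rotation_windows(all_events, frame_labels, spec,
                            n_required = n_none, seed = seed, rate = rate)
  for (j in seq_len(nrow(nr))) {
    f <- cut_epoch_features(eeg, nr$start[j], spec$width, rate)
    if (is.null(f)) next
    if (!reject_interval(matrix(f, ncol = ncol(eeg)), preproc)) {
      n_rejected <- n_rejected + 1L
      next
    }
    rows[[length(rows) + 1L]] <- f
    lab <- c(lab, "none")
    tc <- c(tc, NA_real_)
    eid <- c(eid, NA_integer_)
    ws <- c(ws, nr$start[j])
  }

  features <- do.call(rbind, rows)
  structure(list(features = features,
                 label = factor(lab, levels = c("none", "left", "right")),
                 t_center = tc, event_id = eid, window_start = ws,
                 block = session$block, n_rejected = n_rejected,
                 rate = rate, n_channels = ncol(eeg)),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat("<epoch_dataset>", nrow(x$features), "epochs x", ncol(x$features),
      "features\n")
  print(table(x$label))
  invisible(x)
}

subset_epochs <- function(ds, idx) {
  structure(list(features = ds$features[idx, , drop = FALSE],
                 label = droplevels_keep3(ds$label[idx]),
                 t_center = ds$t_center[idx], event_id = ds$event_id[idx],
                 window_start = ds$window_start[idx],
                 block = if (length(ds$block) > 1) ds$block[idx] else ds$block,
                 n_rejected = ds$n_rejected, rate = ds$rate,
                 n_channels = ds$n_channels),
            class = "epoch_dataset")
}

droplevels_keep3 <- function(f) factor(f, levels = c("none", "left", "right"))

#' Concatenate epoch datasets (e.g., the two blocks of one participant)
#'
#' @param ... `epoch_dataset` objects.
#' @return One combined `epoch_dataset`; `block` becomes a per-epoch vector
#'   and `event_id` values are made unique across inputs.
#' @export
combine_epochs <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "epoch_dataset")) parts <- parts[[1]]
  off <- 0L
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    p$event_id <- ifelse(is.na(p$event_id), NA_integer_, p$event_id + off)
    off <- off + max(c(0L, p$event_id), na.rm = TRUE)
    p$block <- rep(p$block, length(p$label))
    parts[[i]] <- p
  }
  structure(list(features = do.call(rbind, lapply(parts, `[[`, "features")),
                 label = droplevels_keep3(factor(unlist(lapply(parts, function(p) as.character(p$label))),
                                levels = c("none", "left", "right"))),
                 t_center = unlist(lapply(parts, `[[`, "t_center")),
                 event_id = unlist(lapply(parts, `[[`, "event_id")),
                 window_start = unlist(lapply(parts, `[[`, "window_start")),
                 block = unlist(lapply(parts, `[[`, "block")),
                 n_rejected = sum(vapply(parts, `[[`, integer(1), "n_rejected")),
                 rate = parts[[1]]$rate, n_channels = parts[[1]]$n_channels),
            class = "epoch_dataset")
}

#' Balance classes by seeded undersampling
#'
#' All three classes are reduced to the size of the smaller rotation class,
#' `min(n_left, n_right)`; surplus epochs of the other classes are dropped
#' uniformly at random (seeded).
#'
#' @param ds An `epoch_dataset`.
#' @param seed Integer seed for the draw.
#' @return The balanced `epoch_dataset`.
#' @export
balance_classes <- function(ds, seed = 1) {
  counts <- table(ds$label)
  if (any(counts == 0))
    stop("cannot balance: empty class(es): ",
         paste(names(counts)[counts == 0], collapse = ", "))
  target <- min(counts[["left"]], counts[["right"]])
  if (counts[["none"]] < target)
    stop(sprintf("cannot balance: only %d 'none' epochs for target %d",
                 counts[["none"]], target))
  set.seed(as.integer(seed))
  keep <- unlist(lapply(levels(ds$label), function(lv) {
    idx <- which(ds$label == lv)
    if (length(idx) > target) sort(sample(idx, target)) else idx
  }))
  subset_epochs(ds, sort(keep))
}

#' Split configuration
#'
#' @param train_frac,val_frac,test_frac Fractions of the session assigned to
#'   training, validation and test; must sum to 1. The test fraction is one
#'   contiguous stream of data (4 min of 40 at defaults).
#' @param n_repetitions Training repetitions per participant.
#' @param test_position `"end"` places the test stream at the end of the last
#'   block; `"random"` draws a seeded position inside one block.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_frac = 0.72, val_frac = 0.18, test_frac = 0.10,
                       n_repetitions = 3, test_position = "end") {
  stopifnot(abs(train_frac + val_frac + test_frac - 1) < 1e-9,
            train_frac > 0, val_frac > 0, test_frac > 0,
            n_repetitions >= 1, test_position %in% c("end", "random"))
  structure(list(train_frac = train_frac, val_frac = val_frac,
                 test_frac = test_frac, n_repetitions = n_repetitions,
                 test_position = test_position),
            class = "split_spec")
}

#' Split epochs into train / validation / test with a contiguous test stream
#'
#' Reserves one contiguous segment of `test_frac` of the total session
#' duration (default: the end of the last block) as the test stream. Epochs
#' lying wholly inside it form the test set; epochs overlapping its boundary
#' are dropped; the remainder is split `train_frac : val_frac` within each
#' block, keeping all jittered windows of one rotation in the same partition
#' to avoid leakage.
#'
#' @param ds A combined `epoch_dataset` with per-epoch `block`.
#' @param block_durations Named or ordered numeric vector of block durations
#'   in seconds.
#' @param spec A [split_spec()].
#' @param seed Integer seed for the group shuffle (and test position when
#'   `test_position = "random"`).
#' @return A list: `train`, `val`, `test` (epoch datasets), `test_stream`
#'   (`block`, `start`, `end` of the reserved segment), `n_dropped` (epochs
#'   straddling the test boundary).
#' @export
split_dataset <- function(ds, block_durations, spec = split_spec(), seed = 1) {
  if (length(unique(ds$block)) < 1) stop("no blocks present")
  total <- sum(block_durations)
  test_len <- spec$test_frac * total
  blocks <- sort(unique(ds$block))
  set.seed(as.integer(seed))
  if (spec$test_position == "end") {
    tb <- blocks[length(blocks)]
    t1 <- block_durations[length(block_durations)]
    t0 <- t1 - test_len
  } else {
    tb <- sample(blocks, 1)
    bd <- block_durations[match(tb, blocks)]
    t0 <- runif(1, 0, bd - test_len)
    t1 <- t0 + test_len
  }
  if (t0 < 0) stop("test stream longer than its block")

  ep_start <- ds$window_start
  ep_end <- ds$window_start + ncol(ds$features) / ds$n_channels / ds$rate
  in_block <- ds$block == tb
  wholly_in <- in_block & ep_start >= t0 & ep_end <= t1
  straddle <- in_block & !wholly_in & ep_end > t0 & ep_start < t1

  # group key: all 7 windows of one rotation move together
  grp <- paste0(ds$block, ":", ifelse(is.na(ds$event_id), paste0("n", seq_along(ds$event_id)), ds$event_id))
  test_groups <- unique(grp[wholly_in])
  # a rotation with any window in/straddling the test stream contributes
  # nothing to train/val
  tainted <- unique(grp[straddle | wholly_in])
  test_idx <- which(wholly_in & !(grp %in% unique(grp[straddle])))
  drop_idx <- which((grp %in% tainted) &
                      !(seq_along(grp) %in% test_idx))

  if (sum(ds$label[test_idx] %in% c("left", "right")) == 0)
    stop("test stream contains no rotation events; choose another position")

  rest <- setdiff(seq_along(grp), c(test_idx, drop_idx))
  train_idx <- integer(0); val_idx <- integer(0)
  p_train <- spec$train_frac / (spec$train_frac + spec$val_frac)
  for (b in blocks) {
    rb <- rest[ds$block[rest] == b]
    gb <- unique(grp[rb])
    gb <- sample(gb)
    sizes <- vapply(gb, function(g) sum(grp[rb] == g), numeric(1))
    csum <- cumsum(sizes)
    n_train_groups <- sum(csum <= p_train * sum(sizes) + 1e-9)
    tr_g <- gb[seq_len(n_train_groups)]
    train_idx <- c(train_idx, rb[grp[rb] %in% tr_g])
    val_idx <- c(val_idx, rb[!(grp[rb] %in% tr_g)])
  }

  list(train = subset_epochs(ds, sort(train_idx)),
       val = subset_epochs(ds, sort(val_idx)),
       test = subset_epochs(ds, sort(test_idx)),
       test_stream = list(block = tb, start = t0, end = t1),
       n_dropped = length(drop_idx))
}
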