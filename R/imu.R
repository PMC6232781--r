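# Head-rotation extraction from the yaw angular-velocity trace: noise
# threshold from a stationary segment, sustained-threshold onset detection,
# per-frame labeling, and the center-outward filter.

#' Onset detector configuration
#'
#' @param window Sliding-window length in seconds over which the velocity must
#'   stay above threshold for an onset to be declared (default 0.125 s).
#' @param threshold_multiplier Threshold = multiplier x sd of the velocity
#'   over a stationary segment (default 3).
#' @param stationary_segment Either `"auto"` (pick the quietest 2-s chunk of
#'   the trace) or a numeric `c(start, end)` in seconds.
#' @param center_tolerance Maximum integrated yaw displacement (deg) at onset
#'   for a rotation to count as starting from center.
#' @return An object of class `onset_detector_config`.
#' @export
onset_detector_config <- function(window = 0.125,
                                  threshold_multiplier = 3.0,
                                  stationary_segment = "auto",
                                  center_tolerance = 5) {
  stopifnot(window > 0, threshold_multiplier > 0, center_tolerance > 0)
  structure(list(window = window,
                 threshold_multiplier = threshold_multiplier,
                 stationary_segment = stationary_segment,
                 center_tolerance = center_tolerance),
            class = "onset_detector_config")
}

#' Estimate the motion noise threshold from a stationary segment
#'
#' The detection threshold is `threshold_multiplier` times the standard
#' deviation of the yaw velocity while the head is held steady. With
#' `stationary_segment = "auto"` the quietest 2-second chunk of the trace is
#' used as the steady reference.
#'
#' @param velocity Numeric yaw-velocity trace (deg/s) or a data frame with a
#'   `yaw_velocity` column.
#' @param cfg An [onset_detector_config()].
#' @param rate IMU sampling rate in Hz.
#' @return Threshold in deg/s (strictly positive).
#' @export
#' @examples
#' set.seed(1)
#' estimate_noise_threshold(rnorm(1e4), onset_detector_config(), rate = 128)
estimate_noise_threshold <- function(velocity, cfg = onset_detector_config(),
                                     rate = 128) {
  v <- if (is.data.frame(velocity)) velocity$yaw_velocity else velocity
  if (identical(cfg$stationary_segment, "auto")) {
    chunk <- max(round(2 * rate), 2L)
    n_chunks <- floor(length(v) / chunk)
    if (n_chunks < 1) stop("trace too short for automatic stationary segment")
    sds <- vapply(seq_len(n_chunks), function(i)
      sd(v[((i - 1) * chunk + 1):(i * chunk)]), numeric(1))
    seg_sd <- min(sds)
  } else {
    i0 <- floor(cfg$stationary_segment[1] * rate) + 1
    i1 <- floor(cfg$stationary_segment[2] * rate)
    if ((i1 - i0 + 1) / rate < cfg$window)
      stop("stationary segment shorter than the detector window")
    seg_sd <- sd(v[i0:i1])
  }
  thr <- cfg$threshold_multiplier * seg_sd
  if (!is.finite(thr) || thr <= 0)
    stop("degenerate stationary segment: velocity sd is zero")
  thr
}

#' Detect rotation onsets by sustained threshold crossing
#'
#' An onset is declared at the first frame where the absolute velocity
#' exceeds the threshold and stays above it for the full detector window
#' (125 ms by default); brief spikes shorter than the window are rejected.
#' The event ends at the first subsequent return below threshold that is
#' itself sustained for a full window, so short dips inside a movement do not
#' split it. Direction is the sign of the velocity over the event (rightward
#' positive).
#'
#' @inheritParams estimate_noise_threshold
#' @param threshold Detection threshold in deg/s (> 0), from
#'   [estimate_noise_threshold()].
#' @return A data frame of events: `onset`, `direction` (`"left"`/`"right"`),
#'   `offset` (seconds), `from_center` (`NA` until [label_and_filter()] is
#'   applied), time-ordered and non-overlapping. Zero rows for an empty or
#'   quiet trace.
#' @export
detect_onsets <- function(velocity, threshold, cfg = onset_detector_config(),
                          rate = 128) {
  stopifnot(threshold > 0)
  v <- if (is.data.frame(velocity)) velocity$yaw_velocity else velocity
  empty <- data.frame(onset = numeric(0), direction = character(0),
                      offset = numeric(0), from_center = logical(0),
                      stringsAsFactors = FALSE)
  n <- length(v)
  w <- max(1L, round(cfg$window * rate))
  if (n < w) return(empty)

  above <- abs(v) > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  onsets <- integer(0); offsets <- integer(0)
  i <- 1L; nr <- length(r$lengths)
  while (i <= nr) {
    if (r$values[i] && r$lengths[i] >= w) {
      on <- starts[i]
      # absorb sub-window dips followed by more supra-threshold activity
      j <- i
      while (j + 2L <= nr && !r$values[j + 1L] && r$lengths[j + 1L] < w)
        j <- j + 2L
      off <- ends[j]
      onsets <- c(onsets, on); offsets <- c(offsets, off)
      i <- j + 1L
    }
    i <- i + 1L
  }
  if (length(onsets) == 0) return(empty)

  dir_sign <- vapply(seq_along(onsets), function(k)
    sign(mean(v[onsets[k]:offsets[k]])), numeric(1))
  data.frame(onset = (onsets - 1) / rate,
             direction = ifelse(dir_sign >= 0, "right", "left"),
             offset = (offsets - 1) / rate + 1 / rate,
             from_center = NA,
             stringsAsFactors = FALSE)
}

#' Label IMU frames and keep center-outward rotations
#'
#' Assigns each IMU frame a class (`none`, `left`, `right`): frames inside a
#' detected event span take the event's direction, all others are `none`.
#' The head position is recovered by integrating the velocity; an event is
#' scored as center-outward (`from_center`) when the integrated yaw
#' displacement at its onset is within `center_tolerance` of center. Only
#' center-outward rotations are used for training and evaluation, since only
#' for those is the upcoming direction unknown.
#'
#' @param events Event data frame from [detect_onsets()], time-ordered.
#' @param velocity The same yaw-velocity trace the events were detected on.
#' @param cfg An [onset_detector_config()].
#' @param rate IMU sampling rate in Hz.
#' @return A list: `labels` (factor of length `length(velocity)` with levels
#'   `none`, `left`, `right`), `events` (input events with `from_center`
#'   filled), `scored_events` (the center-outward subset).
#' @export
label_and_filter <- function(events, velocity, cfg = onset_detector_config(),
                             rate = 128) {
  v <- if (is.data.frame(velocity)) velocity$yaw_velocity else velocity
  n <- length(v)
  labels <- factor(rep("none", n), levels = c("none", "left", "right"))
  position <- cumsum(v) / rate        # integrated yaw displacement, deg
  if (nrow(events) > 0) {
    stopifnot(!is.unsorted(events$onset))
    for (k in seq_len(nrow(events))) {
      i0 <- round(events$onset[k] * rate) + 1L
      len <- round((events$offset[k] - events$onset[k]) * rate)
      idx <- i0:(i0 + len - 1L)
      idx <- idx[idx >= 1 & idx <= n]
      labels[idx] <- events$direction[k]
    }
    pos_at_onset <- vapply(events$onset, function(on) {
      i <- max(1L, round(on * rate))  # displacement just before the onset
      position[i]
    }, numeric(1))
    events$from_center <- abs(pos_at_onset) <= cfg$center_tolerance
  }
  list(labels = labels, events = events,
       scored_events = events[which(events$from_center), , drop = FALSE])
}
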