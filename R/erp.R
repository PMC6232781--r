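# Pre-onset ERP and lateralization topography: per-electrode mean voltage
# over the second preceding rotation onset, baselined at -1000 ms, and the
# left-minus-right difference with per-participant equal-count averaging.

#' Pre-onset event-related potential
#'
#' Cuts the window `[-window, 0)` seconds before each onset from the 128 Hz
#' EEG, baselines every epoch by subtracting the mean of the first
#' `baseline_frames` frames (a short segment at -1000 ms; a single-sample
#' baseline would be needlessly noise-sensitive), and averages across
#' epochs.
#'
#' @param eeg Samples x channels matrix at `rate` Hz.
#' @param onsets Onset times in seconds (use one direction's center-outward
#'   events).
#' @param rate Sampling rate in Hz.
#' @param window Pre-onset window length in seconds.
#' @param baseline_frames Number of frames at the epoch start averaged into
#'   the baseline.
#' @return An object of class `pre_onset_erp`: `time` (relative seconds),
#'   `erp` (time x channels mean time-course), `electrode_means` (named
#'   per-electrode mean over the whole window), `n_events`.
#' @export
pre_onset_erp <- function(eeg, onsets, rate = 128, window = 1.0,
                          baseline_frames = 3) {
  eeg <- as.matrix(eeg)
  n <- nrow(eeg)
  w <- round(window * rate)
  epochs <- list()
  for (on in onsets) {
    i1 <- round(on * rate)          # last frame before onset
    i0 <- i1 - w + 1
    if (i0 < 1 || i1 > n) {
      message(sprintf("onset at %.3f s lacks full pre-onset coverage; skipped",
                      on))
      next
    }
    ep <- eeg[i0:i1, , drop = FALSE]
    base <- colMeans(ep[seq_len(min(baseline_frames, w)), , drop = FALSE])
    epochs[[length(epochs) + 1]] <- sweep(ep, 2, base)
  }
  if (length(epochs) == 0) stop("no onset with full pre-onset coverage")
  arr <- simplify2array(epochs)     # time x channel x epoch
  erp <- apply(arr, c(1, 2), mean)
  colnames(erp) <- colnames(eeg)
  means <- colMeans(erp)
  structure(list(time = seq(-w, -1) / rate, erp = erp,
                 electrode_means = means, n_events = length(epochs)),
            class = "pre_onset_erp")
}

#' @export
print.pre_onset_erp <- function(x, ...) {
  cat("<pre_onset_erp>", x$n_events, "events,", ncol(x$erp), "electrodes\n")
  invisible(x)
}

#' Left-minus-right lateralization map for one participant
#'
#' Subsamples (seeded) the more numerous direction so both sides contribute
#' equal event counts, computes the pre-onset ERP window mean per electrode
#' for each side, and returns the left-minus-right difference.
#'
#' @param eeg Samples x channels matrix at `rate` Hz (one participant's
#'   data, typically both blocks concatenated or one block).
#' @param events Data frame of center-outward events (`onset`, `direction`).
#' @param rate Sampling rate in Hz.
#' @param window Pre-onset window length in seconds.
#' @param seed Seed for the equal-count subsample.
#' @param baseline_frames Passed to [pre_onset_erp()].
#' @return An object of class `topography_map`: data frame `electrode`,
#'   `value` plus attributes `n_per_side`.
#' @export
lateralization_map <- function(eeg, events, rate = 128, window = 1.0,
                               seed = 1, baseline_frames = 3) {
  left <- events$onset[events$direction == "left"]
  right <- events$onset[events$direction == "right"]
  if (length(left) == 0 || length(right) == 0)
    stop("participant lacks events on one side; excluded")
  n_eq <- min(length(left), length(right))
  set.seed(as.integer(seed))
  if (length(left) > n_eq) left <- sort(sample(left, n_eq))
  if (length(right) > n_eq) right <- sort(sample(right, n_eq))
  erp_l <- pre_onset_erp(eeg, left, rate, window, baseline_frames)
  erp_r <- pre_onset_erp(eeg, right, rate, window, baseline_frames)
  out <- data.frame(electrode = names(erp_l$electrode_means),
                    value = unname(erp_l$electrode_means -
                                     erp_r$electrode_means),
                    stringsAsFactors = FALSE)
  attr(out, "n_per_side") <- c(left = erp_l$n_events, right = erp_r$n_events)
  class(out) <- c("topography_map", "data.frame")
  out
}

#' Grand-average topography across participants
#'
#' Unweighted mean of per-participant maps, so each participant is
#' represented equally strongly.
#'
#' @param maps List of `topography_map` objects with identical electrodes.
#' @return A `topography_map` of the grand average.
#' @export
grand_topography <- function(maps) {
  stopifnot(length(maps) >= 1)
  el <- maps[[1]]$electrode
  vals <- vapply(maps, function(m) {
    stopifnot(identical(m$electrode, el))
    m$value
  }, numeric(length(el)))
  out <- data.frame(electrode = el,
                    value = rowMeans(as.matrix(vals)),
                    stringsAsFactors = FALSE)
  attr(out, "n_participants") <- length(maps)
  class(out) <- c("topography_map", "data.frame")
  out
}

#' Write a topography map as TSV keyed by 10-20 electrode labels
#'
#' @param map A `topography_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_topography_tsv <- function(map, path) {
  write.table(as.data.frame(map), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}
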