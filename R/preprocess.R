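# EEG preprocessing: amplitude-based interval rejection, 0.75-8 Hz band-pass
# (zero-phase), and downsampling to the 128 Hz analysis rate.

#' Preprocessing configuration
#'
#' @param artifact_threshold Absolute-amplitude rejection threshold in
#'   recorded units (default 80). An epoch is discarded when any sample on
#'   any channel exceeds it (strictly).
#' @param band Band-pass edges in Hz, default `c(0.75, 8)`: the pipeline uses
#'   slow time-series components only.
#' @param target_rate Analysis sampling rate in Hz (default 128).
#' @param hp_order,lp_order Butterworth orders of the high-pass and low-pass
#'   stages of the zero-phase band-pass cascade.
#' @return An object of class `preproc_config`.
#' @export
preproc_config <- function(artifact_threshold = 80,
                           band = c(0.75, 8),
                           target_rate = 128,
                           hp_order = 2,
                           lp_order = 4) {
  stopifnot(artifact_threshold > 0, length(band) == 2,
            band[1] > 0, band[1] < band[2], band[2] < target_rate / 2,
            hp_order >= 1, lp_order >= 1)
  structure(list(artifact_threshold = artifact_threshold, band = band,
                 target_rate = target_rate, hp_order = hp_order,
                 lp_order = lp_order),
            class = "preproc_config")
}

#' Zero-phase band-pass filter
#'
#' Filters every channel between `cfg$band[1]` and `cfg$band[2]` Hz with a
#' forward-backward (zero-phase) Butterworth cascade: a high-pass stage
#' followed by a low-pass stage. Zero-phase filtering introduces no group
#' delay, so onset-locked features keep their timing.
#'
#' @param eeg Numeric matrix, samples x channels (a vector is treated as one
#'   channel).
#' @param rate Sampling rate of `eeg` in Hz.
#' @param cfg A [preproc_config()].
#' @return Filtered matrix with the same dimensions.
#' @export
bandpass <- function(eeg, rate, cfg = preproc_config()) {
  if (rate < 2 * cfg$band[2])
    stop("sampling rate too low for the requested band")
  x <- as.matrix(eeg)
  hp <- signal::butter(cfg$hp_order, cfg$band[1] / (rate / 2), type = "high")
  lp <- signal::butter(cfg$lp_order, cfg$band[2] / (rate / 2), type = "low")
  out <- x
  for (ch in seq_len(ncol(x)))
    out[, ch] <- signal::filtfilt(lp, signal::filtfilt(hp, x[, ch]))
  dimnames(out) <- dimnames(x)
  if (is.null(dim(eeg))) drop(out) else out
}

#' Downsample EEG to the analysis rate
#'
#' Decimates each channel from `from_rate` to `to_rate`. For integer ratios a
#' zero-phase FIR anti-aliasing low-pass is applied before subsampling; for
#' rational ratios polyphase resampling is used. Upsampling is refused.
#'
#' @param eeg Samples x channels matrix (or vector).
#' @param from_rate,to_rate Sampling rates in Hz; `from_rate >= to_rate` and
#'   the ratio must be rational.
#' @return Matrix of `round(n * to_rate / from_rate)` samples.
#' @export
eeg_resample <- function(eeg, from_rate, to_rate = 128) {
  if (from_rate < to_rate) stop("upsampling is not supported")
  x <- as.matrix(eeg)
  if (from_rate == to_rate)
    return(if (is.null(dim(eeg))) drop(x) else x)
  n_out <- round(nrow(x) * to_rate / from_rate)
  ratio <- from_rate / to_rate
  if (abs(ratio - round(ratio)) < 1e-9) {
    k <- round(ratio)
    # zero-phase FIR anti-alias at 80% of the new Nyquist
    fir <- as.numeric(signal::fir1(64, 0.8 * (to_rate / 2) / (from_rate / 2)))
    out <- matrix(0, n_out, ncol(x))
    for (ch in seq_len(ncol(x))) {
      y <- signal::filtfilt(fir, 1, x[, ch])
      out[, ch] <- y[seq(1, by = k, length.out = n_out)]
    }
  } else {
    frac <- as.integer(c(to_rate, from_rate) /
                         gcd_int(as.integer(to_rate), as.integer(from_rate)))
    out <- matrix(0, n_out, ncol(x))
    for (ch in seq_len(ncol(x))) {
      y <- signal::resample(x[, ch], frac[1], frac[2])
      out[, ch] <- y[seq_len(min(n_out, length(y)))]
    }
  }
  colnames(out) <- colnames(x)
  if (is.null(dim(eeg))) drop(out) else out
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

#' Amplitude-based epoch rejection
#'
#' An epoch is discarded when the raw absolute amplitude of any sample on any
#' channel is strictly greater than the threshold; a sample exactly at the
#' threshold is kept. Rejection is applied when selecting epochs for training
#' and evaluation; the continuous record is left untouched for streaming.
#'
#' @param epoch Samples x channels matrix (or vector) of one epoch.
#' @param cfg A [preproc_config()].
#' @return `TRUE` to keep the epoch, `FALSE` to discard it.
#' @export
#' @examples
#' reject_interval(matrix(0, 32, 32))          # TRUE: keep
#' reject_interval(matrix(81, 32, 32))         # FALSE: discard
reject_interval <- function(epoch, cfg = preproc_config()) {
  stopifnot(length(epoch) > 0)
  max(abs(epoch)) <= cfg$artifact_threshold
}

#' Preprocess a recording session
#'
#' Runs the full preprocessing chain on a session's EEG: band-pass at the
#' native rate (which doubles as the anti-alias stage for the band of
#' interest), then downsample to `cfg$target_rate`. Returns the session with
#' `eeg` replaced and `eeg_rate` updated; amplitude rejection is applied
#' later, at epoch-selection time.
#'
#' @param session A `recording_session` from [synth_session()] or
#'   [read_session()].
#' @param cfg A [preproc_config()].
#' @return The session with filtered, downsampled EEG and a `preprocessed`
#'   flag.
#' @export
preprocess_session <- function(session, cfg = preproc_config()) {
  stopifnot(inherits(session, "recording_session"))
  eeg <- bandpass(session$eeg, session$eeg_rate, cfg)
  eeg <- eeg_resample(eeg, session$eeg_rate, cfg$target_rate)
  session$eeg <- eeg
  session$eeg_rate <- cfg$target_rate
  session$preprocessed <- TRUE
  session$preproc_cfg <- cfg
  session
}
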