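# Pseudo-online evaluation: slide the trained classifier over a continuous
# 128 Hz EEG stream one frame at a time and build onset-locked probability
# traces.

#' Classify a continuous EEG stream frame by frame
#'
#' Presents the stream to the model as subsequent 250-ms windows shifted by
#' one frame (7.8 ms at 128 Hz). Each window's probability triple is indexed
#' at the *center* of its window; because a window must have elapsed before
#' its classification exists, the information is really available half a
#' window (125 ms) after the plotted time — this availability delay is
#' carried in the result so consumers can shift honestly. No window extends
#' past the end of the stream.
#'
#' @param model A fitted `rotation_model`.
#' @param eeg Continuous preprocessed EEG, samples x channels, at `rate` Hz.
#' @param rate Sampling rate of the stream (Hz).
#' @param width Window width in seconds.
#' @param chunk Number of window positions classified per internal batch.
#' @return An object of class `probability_trace`: list with `time` (window-
#'   center times, seconds), `prob` (positions x 3 matrix, columns `none`,
#'   `left`, `right`), `rate`, `convention = "window-center"`,
#'   `availability_delay` (seconds).
#' @export
stream_classify <- function(model, eeg, rate = 128, width = 0.250,
                            chunk = 4096) {
  eeg <- as.matrix(eeg)
  w <- round(width * rate)
  n <- nrow(eeg)
  if (n < w) stop("stream shorter than one window")
  n_pos <- n - w + 1
  n_ch <- ncol(eeg)
  prob <- matrix(NA_real_, n_pos, 3,
                 dimnames = list(NULL, c("none", "left", "right")))
  for (p0 in seq(1, n_pos, by = chunk)) {
    p1 <- min(p0 + chunk - 1, n_pos)
    m <- p1 - p0 + 1
    feats <- matrix(0, m, n_ch * w)
    for (ch in seq_len(n_ch)) {
      block <- vapply(seq_len(w), function(s)
        eeg[(p0 + s - 2) + seq_len(m), ch], numeric(m))
      feats[, (ch - 1) * w + seq_len(w)] <- block
    }
    prob[p0:p1, ] <- predict(model, feats, type = "prob")
  }
  stopifnot(n_pos + w - 1 <= n)   # causality: last window ends at stream end
  structure(list(time = (seq_len(n_pos) - 1) / rate + width / 2,
                 prob = prob, rate = rate,
                 convention = "window-center",
                 availability_delay = width / 2),
            class = "probability_trace")
}

#' @export
print.probability_trace <- function(x, ...) {
  cat("<probability_trace>", nrow(x$prob), "positions @", x$rate,
      "Hz, window-center convention (+", x$availability_delay * 1000,
      "ms availability delay)\n")
  invisible(x)
}

#' Onset-locked average of a probability trace
#'
#' Aligns the per-frame probability triples to rotation onsets (time 0) and
#' averages across events, giving the mean and standard deviation of each
#' class probability at every time point before onset. Events whose window
#' is not fully covered by the trace are skipped with a message.
#'
#' @param trace A `probability_trace` from [stream_classify()].
#' @param onsets Numeric vector of rotation onset times (seconds, on the
#'   stream's clock); use the center-outward filtered events.
#' @param window Relative time range `c(from, to)` in seconds around onset.
#' @param normalize Divide each probability triple by its sum before
#'   averaging. The three outputs are independent sigmoids whose absolute
#'   scale is not anchored by the loss; normalized triples express the
#'   relative evidence for the classes and are the right scale for comparing
#'   class curves over time.
#' @return An object of class `onset_locked_average`: `time` (relative
#'   seconds), `mean` and `sd` (time x 3 matrices), `n_events`.
#' @export
lock_to_onsets <- function(trace, onsets, window = c(-1, 0),
                           normalize = FALSE) {
  stopifnot(inherits(trace, "probability_trace"), window[1] < window[2])
  if (normalize) trace$prob <- trace$prob / rowSums(trace$prob)
  rate <- trace$rate
  rel <- seq(round(window[1] * rate), round(window[2] * rate)) / rate
  n_pos <- nrow(trace$prob)
  t0 <- trace$time[1]
  used <- list()
  for (on in onsets) {
    idx <- round((on + rel - t0) * rate) + 1
    if (any(idx < 1 | idx > n_pos)) {
      message(sprintf("onset at %.3f s lacks full coverage; skipped", on))
      next
    }
    used[[length(used) + 1]] <- trace$prob[idx, , drop = FALSE]
  }
  if (length(used) == 0) stop("no onset with full trace coverage")
  arr <- simplify2array(used)              # time x class x event
  mean_mat <- apply(arr, c(1, 2), mean)
  sd_mat <- if (length(used) > 1) apply(arr, c(1, 2), sd) else
    mean_mat * 0
  dimnames(mean_mat) <- dimnames(sd_mat) <-
    list(NULL, c("none", "left", "right"))
  structure(list(time = rel, mean = mean_mat, sd = sd_mat,
                 n_events = length(used)),
            class = "onset_locked_average")
}

#' @export
print.onset_locked_average <- function(x, ...) {
  cat("<onset_locked_average>", x$n_events, "events,",
      length(x$time), "time points in [",
      min(x$time), ",", max(x$time), "] s\n")
  invisible(x)
}

#' Plot an onset-locked probability average
#'
#' Mean class probabilities against time before onset, with +/- 1 sd shading.
#'
#' @param x An `onset_locked_average`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.onset_locked_average <- function(x, ...) {
  cols <- c(none = "firebrick", left = "forestgreen", right = "royalblue")
  graphics::matplot(x$time, x$mean, type = "l", lty = 1, col = cols,
                    xlab = "time to onset (s)", ylab = "probability",
                    ylim = c(0, 1), ...)
  for (k in 1:3) {
    graphics::polygon(c(x$time, rev(x$time)),
                      c(x$mean[, k] + x$sd[, k],
                        rev(x$mean[, k] - x$sd[, k])),
                      col = grDevices::adjustcolor(cols[k], alpha.f = 0.15),
                      border = NA)
  }
  graphics::legend("topleft", colnames(x$mean), lty = 1, col = cols, bty = "n")
  invisible(x)
}

#' Serialize a probability trace or onset-locked average to TSV
#'
#' @param x A `probability_trace` or `onset_locked_average`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_tsv <- function(x, path) {
  if (inherits(x, "probability_trace")) {
    df <- data.frame(time_s = x$time, p_none = x$prob[, 1],
                     p_left = x$prob[, 2], p_right = x$prob[, 3])
  } else if (inherits(x, "onset_locked_average")) {
    df <- data.frame(time_s = x$time,
                     p_none = x$mean[, 1], p_left = x$mean[, 2],
                     p_right = x$mean[, 3],
                     sd_none = x$sd[, 1], sd_left = x$sd[, 2],
                     sd_right = x$sd[, 3])
  } else stop("unsupported object")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
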