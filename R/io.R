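# On-disk interchange: EDF for EEG, CSV for the IMU trace, TSV for events,
# JSON for ground truth, RDS containers (with rate/channel metadata) for
# preprocessed arrays and epoch datasets.

pad_field <- function(x, width) {
  s <- substr(format(x, trim = TRUE), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write EEG to an EDF file
#'
#' Writes a continuous multichannel recording as a standard European Data
#' Format (EDF, 16-bit) file with one data record per second. Physical
#' scaling is chosen from the data range per channel, so round-trips are
#' exact up to 16-bit quantization of that range.
#'
#' @param eeg Samples x channels numeric matrix; column names become signal
#'   labels.
#' @param rate Sampling rate in Hz (samples per record).
#' @param path Output file path.
#' @param physical_dim Physical dimension string stored per signal.
#' @return `path`, invisibly.
#' @export
write_edf <- function(eeg, rate, path, physical_dim = "uV") {
  eeg <- as.matrix(eeg)
  ns <- ncol(eeg)
  spr <- as.integer(round(rate))
  n_rec <- floor(nrow(eeg) / spr)
  stopifnot(n_rec >= 1)
  labels <- colnames(eeg)
  if (is.null(labels)) labels <- paste0("ch", seq_len(ns))

  pmin_ <- apply(eeg, 2, min); pmax_ <- apply(eeg, 2, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),                       # version
    pad_field("X X X X", 80),                # patient id (anonymous)
    pad_field("Startdate X X X X", 80),      # recording id
    pad_field("01.01.20", 8), pad_field("00.00.00", 8),
    pad_field(256 + ns * 256, 8),
    pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8),  # record duration 1 s
    pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(pad_field(labels, 16), collapse = ""),
    paste(pad_field(rep("EEG", ns), 80), collapse = ""),
    paste(pad_field(rep(physical_dim, ns), 8), collapse = ""),
    paste(pad_field(sprintf("%.6g", pmin_), 8), collapse = ""),
    paste(pad_field(sprintf("%.6g", pmax_), 8), collapse = ""),
    paste(pad_field(rep(dmin, ns), 8), collapse = ""),
    paste(pad_field(rep(dmax, ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 80), collapse = ""),
    paste(pad_field(rep(spr, ns), 8), collapse = ""),
    paste(pad_field(rep("", ns), 32), collapse = ""))
  writeChar(sig_hdr, con, eos = NULL)

  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    rows <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((eeg[rows, ch] - pmin_[ch]) * gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports continuous EDF recordings with a common sampling rate across
#' signals and integer-second record duration.
#'
#' @param path EDF file path.
#' @return List with `eeg` (samples x channels matrix, labeled columns),
#'   `rate` (Hz), `n_records`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  rd(80 * ns); rd(8 * ns)
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), character(1)))
  rd(32 * ns)
  stopifnot(length(unique(spr)) == 1)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  eeg <- matrix(0, n_rec * spr[1], ns, dimnames = list(NULL, labels))
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[ch], size = 2,
                     endian = "little", signed = TRUE)
      eeg[((r - 1) * spr[1] + 1):(r * spr[1]), ch] <-
        (dig - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  list(eeg = eeg, rate = spr[1] / rec_dur, n_records = n_rec)
}

#' Write / read the IMU trace as CSV
#'
#' Columns `time_s,yaw_velocity`; rightward rotation is positive yaw
#' velocity by convention.
#'
#' @param imu Data frame with `time_s` and `yaw_velocity`.
#' @param path File path.
#' @return `path` invisibly (writer); the data frame (reader).
#' @export
write_imu_csv <- function(imu, path) {
  stopifnot(all(c("time_s", "yaw_velocity") %in% names(imu)))
  write.csv(imu[, c("time_s", "yaw_velocity")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "yaw_velocity") %in% names(df)))
  df
}

#' Write / read detected events as TSV
#'
#' Columns `onset_s,direction,offset_s,from_center`.
#'
#' @param events Event data frame (`onset`, `direction`, `offset`,
#'   `from_center`).
#' @param path File path.
#' @return `path` invisibly (writer); the event data frame (reader).
#' @export
write_events_tsv <- function(events, path) {
  df <- data.frame(onset_s = events$onset, direction = events$direction,
                   offset_s = events$offset, from_center = events$from_center)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  df <- read.delim(path)
  data.frame(onset = df$onset_s, direction = df$direction,
             offset = df$offset_s, from_center = df$from_center,
             stringsAsFactors = FALSE)
}

#' Write / read ground truth as a JSON sidecar
#'
#' @param gt A `ground_truth` object.
#' @param path File path.
#' @return `path` invisibly (writer); the `ground_truth` (reader).
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_ground_truth_json
#' @export
read_ground_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(l, proto) {
    if (length(l) == 0 || length(l[[1]]) == 0)
      return(as.data.frame(proto))          # typed zero-row frame
    as.data.frame(l, stringsAsFactors = FALSE)
  }
  structure(list(events = as_df(x$events,
                                list(onset = numeric(0),
                                     direction = character(0),
                                     offset = numeric(0),
                                     from_center = logical(0))),
                 returns = as_df(x$returns,
                                 list(onset = numeric(0),
                                      direction = character(0),
                                      offset = numeric(0))),
                 artifact_intervals = as_df(x$artifact_intervals,
                                            list(start = numeric(0),
                                                 end = numeric(0))),
                 block_duration = x$block_duration,
                 empty = isTRUE(x$empty)),
            class = "ground_truth")
}

#' Write a recording session to a directory
#'
#' EEG as EDF, IMU as CSV, ground truth as JSON sidecar; [read_session()]
#' round-trips all three.
#'
#' @param session A `recording_session`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_edf(session$eeg, session$eeg_rate, file.path(dir, "eeg.edf"))
  write_imu_csv(session$imu, file.path(dir, "imu.csv"))
  write_ground_truth_json(session$ground_truth,
                          file.path(dir, "ground_truth.json"))
  meta <- list(eeg_rate = session$eeg_rate, imu_rate = session$imu_rate,
               channels = session$channels, block = session$block)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a recording session written by [write_session()]
#'
#' @param dir Session directory.
#' @return A `recording_session`.
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  edf <- read_edf(file.path(dir, "eeg.edf"))
  structure(list(eeg = edf$eeg, eeg_rate = meta$eeg_rate,
                 channels = meta$channels,
                 imu = read_imu_csv(file.path(dir, "imu.csv")),
                 imu_rate = meta$imu_rate,
                 ground_truth = read_ground_truth_json(
                   file.path(dir, "ground_truth.json")),
                 cfg = NULL, block = meta$block),
            class = "recording_session")
}

#' Save / load an epoch dataset container
#'
#' Serializes the dataset (features, labels, timing, split provenance) with
#' its rate and channel metadata in one RDS container.
#'
#' @param ds An `epoch_dataset`.
#' @param path File path (`.rds`).
#' @param provenance Optional list (seed, config hash, ...) stored alongside.
#' @return `path` invisibly (writer); the dataset (reader).
#' @export
write_epoch_dataset <- function(ds, path, provenance = NULL) {
  saveRDS(list(dataset = ds, provenance = provenance), path)
  invisible(path)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(path) {
  x <- readRDS(path)
  structure(x$dataset, provenance = x$provenance)
}
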