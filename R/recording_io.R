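# Recording serialization: EEG/EOG as 16-bit EDF, events and eye streams
# as companion TSVs, remaining metadata as JSON. A session directory
# round-trips through write_recording()/read_recording() with voltages
# preserved to within one EDF quantization step.

.pad_ascii <- function(s, width) {
  s <- substr(s, 1, width)
  sprintf(paste0("%-", width, "s"), s)
}

# Format a number into <= 8 ASCII chars and return the exactly
# representable value actually written (used for scaling).
.edf_num8 <- function(x) {
  for (digits in 7:1) {
    s <- formatC(x, digits = digits, format = "g", width = 1)
    if (nchar(s) <= 8) return(list(s = s, v = as.numeric(s)))
  }
  stop("cannot format ", x, " into 8 characters")
}

#' Write EEG/EOG channels to a 16-bit EDF file
#'
#' Classic continuous EDF: one data record per second, samples as
#' little-endian 16-bit integers scaled channel-wise between the physical
#' minimum/maximum. The last partial record is padded with the final
#' sample value; the true sample count is stored by the caller
#' ([write_recording()]) in the session metadata.
#'
#' @param data channels x samples matrix (rownames = channel labels).
#' @param fs sampling rate, Hz (samples per record).
#' @param path output file.
#' @return invisibly, the per-channel quantization step (microvolts).
#' @export
write_edf <- function(data, fs, path) {
  stopifnot(is.matrix(data), !is.null(rownames(data)))
  ns <- nrow(data)
  n <- ncol(data)
  n_rec <- ceiling(n / fs)
  n_pad <- n_rec * fs
  dmin <- -32768; dmax <- 32767
  pmin <- pv <- numeric(ns); pmax <- numeric(ns)
  pmin_s <- pmax_s <- character(ns)
  for (i in seq_len(ns)) {
    lo <- min(data[i, ]); hi <- max(data[i, ])
    if (hi <= lo) hi <- lo + 1
    span <- hi - lo
    lo8 <- .edf_num8(lo - 0.01 * span)
    hi8 <- .edf_num8(hi + 0.01 * span)
    if (lo8$v > lo) lo8 <- .edf_num8(lo - 0.1 * span)
    if (hi8$v < hi) hi8 <- .edf_num8(hi + 0.1 * span)
    pmin[i] <- lo8$v; pmax[i] <- hi8$v
    pmin_s[i] <- lo8$s; pmax_s[i] <- hi8$s
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(.pad_ascii(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)
  wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(as.character(256 * (ns + 1)), 8)
  wr("", 44)
  wr(as.character(n_rec), 8)
  wr("1", 8)
  wr(as.character(ns), 4)
  labels <- rownames(data)
  for (l in labels) wr(l, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin_s[i], 8)
  for (i in seq_len(ns)) wr(pmax_s[i], 8)
  for (i in seq_len(ns)) wr(as.character(dmin), 8)
  for (i in seq_len(ns)) wr(as.character(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(as.character(fs), 8)
  for (i in seq_len(ns)) wr("", 32)
  # digitize with padding
  dig <- matrix(0L, ns, n_pad)
  step <- (pmax - pmin) / (dmax - dmin)
  for (i in seq_len(ns)) {
    x <- c(data[i, ], rep(data[i, n], n_pad - n))
    d <- round((x - pmin[i]) / step[i]) + dmin
    dig[i, ] <- as.integer(pmin(pmax(d, dmin), dmax))
  }
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns))
      writeBin(dig[i, cols], con, size = 2, endian = "little")
  }
  invisible(step)
}

#' Read a 16-bit EDF file written by [write_edf()]
#'
#' @param path EDF file.
#' @return list with `data` (channels x samples matrix, labels as
#'   rownames), `fs` (samples per one-second record).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) {
    s <- readChar(con, w, useBytes = TRUE)
    if (nchar(s, type = "bytes") < w) stop("truncated EDF header in ", path)
    trimws(s)
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop("malformed EDF header in ", path)
  if (header_bytes != 256 * (ns + 1)) stop("inconsistent EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  data <- matrix(NA_real_, ns, n_rec * spr[1],
                 dimnames = list(labels, NULL))
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[i], size = 2, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[i]) stop("truncated EDF data in ", path)
      phys <- (raw - dmin[i]) * (pmax[i] - pmin[i]) / (dmax[i] - dmin[i]) +
        pmin[i]
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  list(data = data, fs = spr[1] / rec_dur)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
.read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a session recording to a directory
#'
#' Produces `recording.edf` (EEG + HEOG/VEOG, 16-bit), `events.tsv` (one
#' row per stimulus event), `eye.tsv` (`time_s`, `x_px`, `y_px`,
#' `pupil_mm`, `valid`), ground-truth tables (`truth_saccades.tsv`,
#' `truth_blinks.tsv`) and `meta.json`.
#'
#' @param rec an `srp_recording`.
#' @param path directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "srp_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  data <- rbind(rec$eeg, HEOG = rec$heog, VEOG = rec$veog)
  write_edf(data, rec$fs, file.path(path, "recording.edf"))
  .write_tsv(rec$events, file.path(path, "events.tsv"))
  .write_tsv(rec$eye, file.path(path, "eye.tsv"))
  .write_tsv(rec$truth$saccades, file.path(path, "truth_saccades.tsv"))
  .write_tsv(rec$truth$blinks, file.path(path, "truth_blinks.tsv"))
  meta <- list(fs = rec$fs, eye_fs = rec$eye_fs, load = rec$load,
               n_samples = ncol(rec$eeg), duration_s = rec$duration_s,
               channels = rec$channels,
               gaze_cal = rec$truth$gaze_cal)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a session recording written by [write_recording()]
#'
#' @param path session directory.
#' @param require_channels channel labels that must be present (error names
#'   the missing ones).
#' @return an `srp_recording` (without the synthesis parameter objects;
#'   `config` is rebuilt from the events table spacing where possible).
#' @export
read_recording <- function(path, require_channels = c("HEOG", "VEOG")) {
  need <- file.path(path, c("recording.edf", "events.tsv", "eye.tsv",
                            "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("not a session directory; missing: ",
         paste(basename(missing), collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  edf <- read_edf(file.path(path, "recording.edf"))
  data <- edf$data[, seq_len(meta$n_samples), drop = FALSE]
  absent <- setdiff(require_channels, rownames(data))
  if (length(absent))
    stop("required channel(s) missing from EDF: ",
         paste(absent, collapse = ", "))
  eeg_ch <- setdiff(rownames(data), c("HEOG", "VEOG"))
  events <- .read_tsv(file.path(path, "events.tsv"))
  truth <- list(
    saccades = if (file.exists(file.path(path, "truth_saccades.tsv")))
      .read_tsv(file.path(path, "truth_saccades.tsv")) else NULL,
    blinks = if (file.exists(file.path(path, "truth_blinks.tsv")))
      .read_tsv(file.path(path, "truth_blinks.tsv")) else NULL,
    gaze_cal = meta$gaze_cal)
  structure(list(
    eeg = data[eeg_ch, , drop = FALSE], channels = eeg_ch, fs = meta$fs,
    heog = as.numeric(data["HEOG", ]), veog = as.numeric(data["VEOG", ]),
    eye = .read_tsv(file.path(path, "eye.tsv")), eye_fs = meta$eye_fs,
    events = events, truth = truth, load = meta$load,
    geometry = screen_geometry(), params = NULL,
    duration_s = meta$duration_s
  ), class = "srp_recording")
}
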