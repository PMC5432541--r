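# EEG conditioning and saccade-locked epoch extraction. Fixed chain:
# resample -> bad-channel detection -> interpolation (unfiltered) ->
# average re-reference (unfiltered) -> bandpass -> epoch -> baseline ->
# outlier rejection.

#' Resample a recording's EEG/EOG channels
#'
#' Polyphase anti-aliased resampling of all EEG-rate streams to
#' `target_fs`. Eye streams and event times (seconds-based) are untouched.
#' Upsampling is rejected.
#'
#' @param rec an `srp_recording`.
#' @param target_fs Hz, must divide into the native rate as a rational
#'   p/q <= 1.
#' @return the recording with `eeg`, `heog`, `veog` resampled and `fs`
#'   updated.
#' @export
resample_recording <- function(rec, target_fs = 256) {
  stopifnot(inherits(rec, "srp_recording"))
  if (target_fs > rec$fs) stop("upsampling not supported (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  g <- .gcd(target_fs, rec$fs)
  p <- target_fs / g; q <- rec$fs / g
  rs <- if (p == 1) {
    # integer decimation: symmetric FIR anti-aliasing (zero phase in a
    # single centred pass), reflected edges, then subsample
    h <- as.numeric(signal::fir1(60, 1 / q))
    half <- (length(h) - 1) / 2
    function(x) {
      n_x <- length(x)
      padded <- c(x[(half + 1):2], x, x[(n_x - 1):(n_x - half)])
      y <- stats::filter(padded, h, sides = 2)
      as.numeric(y[seq(half + 1, half + n_x, by = q)])
    }
  } else function(x) as.numeric(signal::resample(x, p, q))
  new_eeg <- t(apply(rec$eeg, 1, rs))
  dimnames(new_eeg) <- list(rec$channels, NULL)
  rec$eeg <- new_eeg
  rec$heog <- rs(rec$heog)
  rec$veog <- rs(rec$veog)
  rec$fs <- target_fs
  rec
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Detect bad EEG channels
#'
#' A channel is flagged when the SD of its band-passed (0.5-32 Hz) copy
#' exceeds `k` times the median SD over all channels. The data itself is
#' not modified.
#'
#' @param eeg channels x samples matrix with channel-name rownames.
#' @param fs Hz.
#' @param k multiplier on the median SD (default 5).
#' @param band Hz, the band used for the SD estimate.
#' @return character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(eeg, fs, k = 5, band = c(0.5, 32)) {
  stopifnot(nrow(eeg) >= 3)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  sds <- apply(eeg, 1, function(x) sd(signal::filtfilt(bf, x)))
  rownames(eeg)[sds > k * median(sds)]
}

#' Interpolate bad channels from their neighbours
#'
#' Each bad channel is replaced, sample-wise, by the inverse-distance
#' weighted average of its `k` nearest good channels on the 2D montage.
#' Operates on unfiltered data.
#'
#' @param eeg channels x samples matrix (rownames = channel names).
#' @param bads channel names to replace.
#' @param montage data.frame `channel`, `x`, `y` ([montage_1020()]).
#' @param k number of neighbours (default 4).
#' @return the matrix with bad channels replaced.
#' @export
interpolate_bad_channels <- function(eeg, bads, montage = montage_1020(),
                                     k = 4) {
  if (length(bads) == 0) return(eeg)
  good <- setdiff(rownames(eeg), bads)
  if (length(good) == 0) stop("all channels bad; cannot interpolate")
  k <- min(k, length(good))
  pos <- montage[match(rownames(eeg), montage$channel), ]
  for (b in bads) {
    bi <- match(b, rownames(eeg))
    d <- sqrt((pos$x[bi] - pos$x[match(good, rownames(eeg))])^2 +
              (pos$y[bi] - pos$y[match(good, rownames(eeg))])^2)
    nn <- order(d)[seq_len(k)]
    w <- 1 / pmax(d[nn], 1e-6)
    w <- w / sum(w)
    eeg[bi, ] <- as.numeric(w %*% eeg[match(good, rownames(eeg))[nn], ,
                                      drop = FALSE])
  }
  eeg
}

#' Re-reference to the average of good channels
#'
#' Subtracts, at every sample, the mean over the good channels from every
#' channel. Afterwards the good-channel mean is zero everywhere.
#'
#' @param eeg channels x samples matrix.
#' @param bads channel names excluded from the reference.
#' @return the re-referenced matrix.
#' @export
rereference_average <- function(eeg, bads = character(0)) {
  good <- setdiff(rownames(eeg), bads)
  if (length(good) < 2) stop("need >= 2 good channels for an average reference")
  ref <- colMeans(eeg[good, , drop = FALSE])
  sweep(eeg, 2, ref)
}

#' Zero-phase Butterworth bandpass
#'
#' 4th-order Butterworth applied forward and backward (zero phase) to every
#' channel.
#'
#' @param eeg channels x samples matrix (or a plain vector).
#' @param fs Hz.
#' @param band c(low, high) Hz with `0 < low < high < fs/2`.
#' @return filtered data, same shape.
#' @export
bandpass_eeg <- function(eeg, fs, band = c(0.5, 32)) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  if (is.matrix(eeg)) {
    out <- t(apply(eeg, 1, function(x) signal::filtfilt(bf, x)))
    dimnames(out) <- dimnames(eeg)
    out
  } else signal::filtfilt(bf, eeg)
}

#' Extract saccade-locked epochs
#'
#' Per selected saccade, the window \[t0, t0 + span) starting at the
#' velocity peak is cut from every channel and baselined by subtracting the
#' mean of the first `baseline_span` seconds (25 samples at 256 Hz).
#' Saccades whose epoch would run past the end of the recording are skipped
#' with a warning and counted.
#'
#' @param data channels x samples matrix (typically EEG plus HEOG/VEOG).
#' @param fs Hz.
#' @param saccades [detect_saccades_of_interest()] output; only matched
#'   rows are epoched.
#' @param labels data.frame with one row per event (e.g. the behavior
#'   events table) carried into the epoch labels.
#' @param span seconds relative to the velocity peak, default \[0, 1).
#' @param baseline_span seconds, baseline window at the epoch start.
#' @return object of class `srp_epochs`: `data` (epochs x channels x
#'   samples array), `times` (s), `channels`, `fs`, `labels` (one row per
#'   epoch), `rejected` (ids removed later), `n_skipped`.
#' @export
extract_epochs <- function(data, fs, saccades, labels,
                           span = c(0, 1), baseline_span = 0.1) {
  stopifnot(is.matrix(data), nrow(labels) == nrow(saccades))
  n_samp <- round((span[2] - span[1]) * fs)
  n_base <- floor(baseline_span * fs)
  keep <- which(saccades$matched)
  n_total <- ncol(data)
  epochs <- list(); lab_rows <- list(); skipped <- 0L
  for (i in keep) {
    i0 <- floor((saccades$peak_time[i] + span[1]) * fs) + 1L
    i1 <- i0 + n_samp - 1L
    if (i0 < 1L || i1 > n_total) { skipped <- skipped + 1L; next }
    seg <- data[, i0:i1, drop = FALSE]
    base <- rowMeans(seg[, seq_len(n_base), drop = FALSE])
    epochs[[length(epochs) + 1L]] <- seg - base
    lr <- labels[i, , drop = FALSE]
    lr$event <- i
    lr$peak_time <- saccades$peak_time[i]
    lr$latency_ms <- saccades$latency_ms[i]
    lab_rows[[length(lab_rows) + 1L]] <- lr
  }
  if (skipped > 0)
    warning(skipped, " saccade(s) too close to the recording end; skipped")
  if (length(epochs) == 0) stop("no epochs could be extracted")
  arr <- array(NA_real_, dim = c(length(epochs), nrow(data), n_samp),
               dimnames = list(NULL, rownames(data), NULL))
  for (e in seq_along(epochs)) arr[e, , ] <- epochs[[e]]
  lab <- do.call(rbind, lab_rows)
  rownames(lab) <- NULL
  structure(list(data = arr, times = span[1] + (seq_len(n_samp) - 1) / fs,
                 channels = rownames(data), fs = fs, labels = lab,
                 rejected = integer(0), n_skipped = skipped),
            class = "srp_epochs")
}

#' Reject high-variance outlier epochs
#'
#' An epoch is discarded when, on any of the reference channels, its
#' within-epoch SD exceeds `k` times that channel's median within-epoch SD
#' across epochs.
#'
#' @param epochs an `srp_epochs`.
#' @param k multiplier (default 50).
#' @param channels channels entering the criterion (default: all EEG
#'   channels, i.e. everything except HEOG/VEOG).
#' @return the epoch set with outliers removed; removed epoch ids (row
#'   numbers in the original set) accumulate in `$rejected`.
#' @export
reject_outlier_epochs <- function(epochs, k = 50, channels = NULL) {
  stopifnot(inherits(epochs, "srp_epochs"), dim(epochs$data)[1] >= 2)
  if (is.null(channels))
    channels <- setdiff(epochs$channels, c("HEOG", "VEOG"))
  ci <- match(channels, epochs$channels)
  sds <- apply(epochs$data[, ci, , drop = FALSE], c(1, 2), sd)
  med <- apply(sds, 2, median)
  bad <- which(apply(sds, 1, function(s) any(s > k * med)))
  if (length(bad)) {
    epochs$rejected <- c(epochs$rejected, bad)
    epochs$data <- epochs$data[-bad, , , drop = FALSE]
    epochs$labels <- epochs$labels[-bad, , drop = FALSE]
    rownames(epochs$labels) <- NULL
  }
  epochs
}

#' @export
print.srp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<srp_epochs> ", d[1], " epochs x ", d[2], " channels x ", d[3],
      " samples @ ", x$fs, " Hz; ", length(x$rejected), " rejected, ",
      x$n_skipped, " skipped\n", sep = "")
  invisible(x)
}
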