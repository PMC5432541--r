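# EOG conditioning: despiking, blink removal, derivative-of-Gaussian
# velocity estimation. Thresholds are multiples of the channel's global SD.

# Merge [start, end] integer intervals whose gaps are < merge_gap samples,
# given as a 2-column matrix; returns the same representation.
.merge_intervals <- function(iv, merge_gap = 0L) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    if (iv[k, 1] - out[nrow(out), 2] - 1L < merge_gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[k, 2])
    } else out <- rbind(out, iv[k, , drop = FALSE])
  }
  out
}

# Runs of TRUE as a 2-column [start, end] matrix (1-based, inclusive).
.runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(starts[r$values], ends[r$values])
}

# Cut [start, end] sample intervals out of x and linearly interpolate
# between flanking clean samples; endpoints held at the nearest clean value.
.cut_and_interpolate <- function(x, iv) {
  if (nrow(iv) == 0) return(x)
  bad <- logical(length(x))
  for (k in seq_len(nrow(iv))) bad[iv[k, 1]:iv[k, 2]] <- TRUE
  if (all(bad)) stop("entire signal flagged; nothing to interpolate from")
  good_idx <- which(!bad)
  x[bad] <- approx(good_idx, x[good_idx], xout = which(bad), rule = 2)$y
  x
}

#' Remove amplitude spikes from an EOG channel
#'
#' Samples whose deviation from the channel mean exceeds `k` times the
#' channel's global SD are flagged; flagged runs are padded, cut out and
#' linearly interpolated from the flanking clean samples.
#'
#' @param signal voltage vector (finite, length >= 3).
#' @param k SD multiplier (default 5).
#' @param fs sampling rate, Hz (for the padding).
#' @param pad_ms padding added on each side of a flagged run.
#' @return list with `signal` (cleaned) and `intervals` (2-column matrix of
#'   \[start, end\] sample indices that were replaced).
#' @export
despike <- function(signal, k = 5, fs = 256, pad_ms = 50) {
  stopifnot(length(signal) >= 3, all(is.finite(signal)), k > 0)
  thr <- k * sd(signal)
  flag <- abs(signal - mean(signal)) > thr
  if (!any(flag))
    return(list(signal = signal, intervals = matrix(0L, 0, 2)))
  pad <- round(pad_ms / 1000 * fs)
  iv <- .runs_of(flag)
  iv[, 1] <- pmax(1L, iv[, 1] - pad)
  iv[, 2] <- pmin(length(signal), iv[, 2] + pad)
  iv <- .merge_intervals(iv, 1L)
  list(signal = .cut_and_interpolate(signal, iv), intervals = iv)
}

#' Detect and remove blinks from vertical EOG
#'
#' Detection runs on a band-passed (default 2-100 Hz) copy: samples with
#' positive peaks exceeding `k` times the SD of the filtered copy are
#' blink candidates (blinks are positive VEOG deflections); candidate runs
#' closer than `merge_ms` are merged, padded by `pad_ms`, then cut out of
#' the *original* signal and linearly interpolated.
#'
#' @param veog voltage vector.
#' @param fs sampling rate, Hz (must exceed twice the band's upper edge).
#' @param k SD multiplier on the filtered copy (default 3).
#' @param band Hz, detection band.
#' @param merge_ms,pad_ms run merging and padding.
#' @return list with `signal` (cleaned VEOG) and `intervals` (\[start, end\]
#'   sample matrix).
#' @export
detect_and_remove_blinks <- function(veog, fs, k = 3, band = c(2, 100),
                                     merge_ms = 100, pad_ms = 100) {
  stopifnot(all(is.finite(veog)), fs > 2 * band[2], k > 0)
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, veog)
  thr <- k * sd(filt)
  flag <- filt > thr
  if (!any(flag))
    return(list(signal = veog, intervals = matrix(0L, 0, 2)))
  iv <- .merge_intervals(.runs_of(flag), round(merge_ms / 1000 * fs))
  pad <- round(pad_ms / 1000 * fs)
  iv[, 1] <- pmax(1L, iv[, 1] - pad)
  iv[, 2] <- pmin(length(veog), iv[, 2] + pad)
  iv <- .merge_intervals(iv, 1L)
  list(signal = .cut_and_interpolate(veog, iv), intervals = iv)
}

#' Derivative-of-Gaussian velocity filter
#'
#' Convolves the signal with the first derivative of a Gaussian kernel
#' (truncated at +-4 sigma), normalized so a unit-slope ramp maps to a
#' constant 1 (slope per sample). Positive output for a rising signal.
#' Edges use reflected padding.
#'
#' @param signal voltage vector, length > 8 sigma.
#' @param sigma kernel SD in samples (default 8; about 31 ms at 256 Hz).
#' @return velocity vector, same length as the input.
#' @export
gaussian_derivative_filter <- function(signal, sigma = 8) {
  stopifnot(sigma >= 1)
  half <- ceiling(4 * sigma)
  if (length(signal) <= 2 * half)
    stop("signal too short for the velocity kernel (need > 8 sigma samples)")
  j <- seq(-half, half)
  kern <- -j * exp(-j^2 / (2 * sigma^2))
  kern <- kern / sum(j^2 * exp(-j^2 / (2 * sigma^2)))   # unit ramp -> slope 1
  n <- length(signal)
  padded <- c(signal[(half + 1):2], signal, signal[(n - 1):(n - half)])
  out <- stats::filter(padded, kern, sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Clean both EOG channels and compute velocity traces
#'
#' Convenience wrapper running [despike()] on HEOG and VEOG, blink removal
#' on VEOG, and the velocity filter on both cleaned channels (the order of
#' the analysis chain: despike, deblink, differentiate).
#'
#' @param heog,veog voltage vectors at `fs`.
#' @param fs Hz.
#' @param params a [pipeline_params()].
#' @return list of class `srp_clean_eog`: `heog`, `veog` (cleaned),
#'   `vel_h`, `vel_v` (velocity traces), `spike_intervals_h/v`,
#'   `blink_intervals`, `fs`.
#' @export
clean_eog <- function(heog, veog, fs, params = pipeline_params()) {
  dh <- despike(heog, params$spike_k, fs, params$spike_pad_ms)
  dv <- despike(veog, params$spike_k, fs, params$spike_pad_ms)
  bl <- detect_and_remove_blinks(dv$signal, fs, params$blink_k,
                                 params$blink_band, params$blink_merge_ms,
                                 params$blink_pad_ms)
  structure(list(
    heog = dh$signal, veog = bl$signal,
    vel_h = gaussian_derivative_filter(dh$signal, params$velocity_sigma),
    vel_v = gaussian_derivative_filter(bl$signal, params$velocity_sigma),
    spike_intervals_h = dh$intervals, spike_intervals_v = dv$intervals,
    blink_intervals = bl$intervals, fs = fs
  ), class = "srp_clean_eog")
}
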