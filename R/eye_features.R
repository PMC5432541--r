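# Gaze recalibration against the known stimulus positions and per-event
# fixation-duration / pupil-size feature extraction.

#' Recalibrate gaze using the displayed stimulus positions
#'
#' For every highlight, the median valid gaze position over
#' \[onset + 0.3 s, onset + 1.0 s\] is paired with the true stimulus centre;
#' a global 2D affine transform (least squares) mapping measured medians to
#' true centres is then applied to the whole stream. With degenerate
#' geometry (collinear medians) the fit falls back to translation only,
#' with a warning.
#'
#' @param eye data.frame `time_s`, `x_px`, `y_px`, `pupil_mm`, `valid`.
#' @param schedule the session's `srp_schedule`.
#' @param geometry a [screen_geometry()].
#' @param sample_window seconds after onset used for the per-event median.
#' @param min_events minimum usable events required for the affine fit.
#' @return list with `eye` (recalibrated stream), `transform` (2 x 3
#'   matrix `[A | b]` so that `corrected = A %*% measured + b`),
#'   `n_events_used`, `fit` (`"affine"` or `"translation"`).
#' @export
recalibrate_gaze <- function(eye, schedule, geometry = screen_geometry(),
                             sample_window = c(0.3, 1.0), min_events = 3) {
  centers <- stimulus_centers(attr(schedule, "config"), geometry)
  med <- matrix(NA_real_, nrow(schedule), 2)
  tru <- matrix(NA_real_, nrow(schedule), 2)
  for (i in seq_len(nrow(schedule))) {
    on <- schedule$onset_time[i]
    sel <- eye$valid & eye$time_s >= on + sample_window[1] &
      eye$time_s <= on + sample_window[2]
    if (sum(sel) < 5) next
    med[i, ] <- c(median(eye$x_px[sel]), median(eye$y_px[sel]))
    ci <- which(centers$row == schedule$row[i] &
                centers$col == schedule$col[i])
    tru[i, ] <- c(centers$x_px[ci], centers$y_px[ci])
  }
  ok <- complete.cases(med)
  if (sum(ok) < min_events)
    stop("too few events with valid gaze for recalibration")
  # distinct measured positions must span the plane for an affine fit
  X <- cbind(med[ok, , drop = FALSE], 1)
  degenerate <- qr(X)$rank < 3
  if (degenerate) {
    warning("degenerate gaze geometry; translation-only recalibration")
    b <- colMeans(tru[ok, , drop = FALSE]) - colMeans(med[ok, , drop = FALSE])
    A <- diag(2)
  } else {
    beta <- qr.solve(X, tru[ok, , drop = FALSE])   # 3 x 2
    A <- t(beta[1:2, ]); b <- beta[3, ]
  }
  xy <- cbind(eye$x_px, eye$y_px) %*% t(A)
  eye$x_px <- xy[, 1] + b[1]
  eye$y_px <- xy[, 2] + b[2]
  list(eye = eye, transform = cbind(A, b), n_events_used = sum(ok),
       fit = if (degenerate) "translation" else "affine")
}

#' Fixation-duration and pupil features per stimulus event
#'
#' Within \[onset, onset + window) only valid eye samples are considered; a
#' sample is on-stimulus when its Euclidean distance to the current
#' stimulus centre is at most `radius_px`. Fixation duration is the
#' on-stimulus valid sample count divided by the eye sampling rate; pupil
#' size is the mean (or median) of the pupil values over those same
#' samples. Events with no valid sample yield `NA` features.
#'
#' @param eye (recalibrated) eye data.frame.
#' @param schedule the session's `srp_schedule`.
#' @param geometry a [screen_geometry()].
#' @param eye_fs eye sampling rate, Hz.
#' @param radius_px on-stimulus radius (150 px: 4.4 cm on the study
#'   display).
#' @param window seconds after onset (default 2).
#' @param pupil_stat `"mean"` (default) or `"median"`.
#' @return data.frame per event: `event`, `fixation_duration_ms`,
#'   `pupil_mm`, `valid_fraction`.
#' @export
fixation_features <- function(eye, schedule, geometry = screen_geometry(),
                              eye_fs = 60, radius_px = 150, window = 2,
                              pupil_stat = c("mean", "median")) {
  pupil_stat <- match.arg(pupil_stat)
  pfun <- if (pupil_stat == "mean") mean else median
  centers <- stimulus_centers(attr(schedule, "config"), geometry)
  n_ev <- nrow(schedule)
  out <- data.frame(event = seq_len(n_ev),
                    fixation_duration_ms = NA_real_,
                    pupil_mm = NA_real_, valid_fraction = NA_real_)
  for (i in seq_len(n_ev)) {
    on <- schedule$onset_time[i]
    win <- eye$time_s >= on & eye$time_s < on + window
    if (!any(win)) next
    out$valid_fraction[i] <- mean(eye$valid[win])
    sel <- win & eye$valid
    if (!any(sel)) next
    ci <- which(centers$row == schedule$row[i] &
                centers$col == schedule$col[i])
    d <- sqrt((eye$x_px[sel] - centers$x_px[ci])^2 +
              (eye$y_px[sel] - centers$y_px[ci])^2)
    on_stim <- d <= radius_px
    out$fixation_duration_ms[i] <- sum(on_stim) / eye_fs * 1000
    if (any(on_stim)) out$pupil_mm[i] <- pfun(eye$pupil_mm[sel][on_stim])
  }
  out
}
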