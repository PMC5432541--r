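# Synthetic co-registered EEG/EOG + gaze/pupil rendering.
#
# The generator turns a trial schedule plus simulated report behavior into
# continuous signals carrying the statistical structure the analysis
# assumes: sigmoidal EOG/gaze steps per stimulus-to-stimulus saccade with
# per-condition latency distributions, a parieto-central positive EEG bump
# peaking 0.5 s after the saccade velocity peak (larger for targets),
# condition-dependent fixation dwells, load- and miss-dependent pupil size,
# and Poisson blinks. Ground-truth annotations are always returned.
#
# Timing structure: saccades toward stimuli are fast (40 ms rise); the
# post-dwell disengagement and the return to screen centre during the
# reporting pause are rendered as slow drifts (no saccadic velocity peak),
# since reporting-phase kinematics are not modeled.

# 1/f^alpha noise via spectral shaping, unit variance. Computed at the
# next 2-3-5-smooth length (fast FFT) and truncated.
.pink_noise <- function(n, alpha = 1) {
  if (n < 4) return(rnorm(n))
  m <- stats::nextn(n, c(2, 3, 5))
  white <- rnorm(m)
  spec <- fft(white)
  f <- c(1, seq_len(m - 1))                    # avoid DC blowup
  f <- pmin(f, m - f + 1)                      # two-sided frequency index
  scale <- f^(-alpha / 2)
  scale[1] <- 0                                # remove DC
  x <- Re(fft(spec * scale, inverse = TRUE))[seq_len(n)] / m
  x / sd(x)
}

# Normal draw redrawn into [lo, hi].
.rtrunc_norm <- function(n, mean, sd, lo, hi, max_iter = 200L) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(max_iter)) {
    bad <- which(x < lo | x > hi)
    if (!length(bad)) return(x)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  pmin(pmax(x, lo), hi)
}

# Evaluate x0 + sum_k delta_k * sigmoid((t - t_k)/tau_k) on a regular grid,
# touching only a +-6 tau window per transition (tails handled by cumsum).
.apply_transitions <- function(n, fs, x0, t_mid, delta, tau) {
  contrib <- numeric(n)
  steps <- numeric(n)
  for (k in seq_along(t_mid)) {
    w <- 6 * tau[k]
    i0 <- max(1L, floor((t_mid[k] - w) * fs) + 1L)
    i1 <- min(n, ceiling((t_mid[k] + w) * fs) + 1L)
    if (i0 > n) next
    tt <- (seq(i0, i1) - 1) / fs
    contrib[i0:i1] <- contrib[i0:i1] +
      delta[k] * plogis((tt - t_mid[k]) / tau[k])
    if (i1 < n) steps[i1 + 1L] <- steps[i1 + 1L] + delta[k]
  }
  x0 + contrib + cumsum(steps)
}

# Hann bump sample indices and waveform (NULL when outside the signal).
.hann_window <- function(n, fs, center, width) {
  i0 <- max(1L, floor((center - width / 2) * fs) + 1L)
  i1 <- min(n, ceiling((center + width / 2) * fs) + 1L)
  if (i0 > n || i1 < 1L || i0 > i1) return(NULL)
  tt <- (seq(i0, i1) - 1) / fs
  u <- (tt - center) / width
  list(idx = i0:i1, b = ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0))
}

#' Inject blinks into a vertical EOG trace
#'
#' Adds positive Hann-shaped deflections at Poisson-distributed times and
#' returns the ground-truth intervals. Blink amplitude is intended to be
#' much larger than saccade steps so blink removal is testable.
#'
#' @param veog voltage vector.
#' @param fs sampling rate, Hz.
#' @param rate_per_min expected blinks per minute (>= 0).
#' @param amplitude peak deflection, microvolts.
#' @param width_range seconds, blink full width drawn uniformly.
#' @param seed optional integer; if `NULL` the current RNG stream is used.
#' @return list with `veog` (with blinks) and `intervals`
#'   (data.frame `start_s`, `end_s`).
#' @export
inject_blinks <- function(veog, fs, rate_per_min, amplitude = 400,
                          width_range = c(0.15, 0.4), seed = NULL) {
  stopifnot(rate_per_min >= 0)
  if (!is.null(seed)) {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
  }
  dur <- length(veog) / fs
  n_blinks <- rpois(1, rate_per_min * dur / 60)
  if (n_blinks == 0)
    return(list(veog = veog,
                intervals = data.frame(start_s = numeric(0),
                                       end_s = numeric(0))))
  centers <- sort(runif(n_blinks, 0, dur))
  widths <- runif(n_blinks, width_range[1], width_range[2])
  for (k in seq_len(n_blinks)) {
    hw <- .hann_window(length(veog), fs, centers[k], widths[k])
    if (!is.null(hw)) veog[hw$idx] <- veog[hw$idx] + amplitude * hw$b
  }
  list(veog = veog,
       intervals = data.frame(start_s = pmax(0, centers - widths / 2),
                              end_s = pmin(dur, centers + widths / 2)))
}

# Pixel offset -> degrees of gaze rotation from straight ahead.
.px_to_deg <- function(px_offset, cm_per_px, eye_distance_cm) {
  (180 / pi) * atan(px_offset * cm_per_px / eye_distance_cm)
}

# Disengagement point: ~offset_px away from the current stimulus, on
# screen, clear of both the current and the next stimulus.
.departure_point <- function(cur, nxt, geometry, offset_px = 170,
                             min_clear = 160) {
  d <- nxt - cur
  nd <- sqrt(sum(d^2))
  u <- if (nd > 1e-9) d / nd else c(1, 0)
  perp <- c(-u[2], u[1])
  cand <- list(-u, perp, -perp,
               (-u + perp) / sqrt(2), (-u - perp) / sqrt(2), u)
  for (v in cand) {
    p <- cur + offset_px * v
    if (p[1] < 10 || p[1] > geometry$width_px - 10 ||
        p[2] < 10 || p[2] > geometry$height_px - 10) next
    if (sqrt(sum((p - cur)^2)) < min_clear * 0.9) next
    if (sqrt(sum((p - nxt)^2)) < min_clear * 0.9) next
    return(p)
  }
  pmin(pmax(cur + offset_px * perp, 10),
       c(geometry$width_px, geometry$height_px) - 10)
}

#' Synthesize a continuous recording for one session
#'
#' Renders schedule + behavior into synchronized EEG (32 channels, 10-20
#' labels), HEOG/VEOG, and 60 Hz gaze/pupil streams sharing t = 0, plus
#' ground-truth annotations (true saccade peak-velocity times, blink
#' intervals, injected response amplitudes, dwell times).
#'
#' Per stimulus event a saccade is rendered as a logistic-sigmoid gaze step
#' whose midpoint (the velocity peak) lies at onset + latency, latency
#' drawn per condition. After a condition-dependent dwell the gaze drifts
#' slowly off the stimulus; during the inter-trial reporting pause it
#' drifts back to screen centre. Gaze is measured through a configurable
#' affine miscalibration (recovered later by [recalibrate_gaze()]).
#'
#' @param schedule an `srp_schedule`.
#' @param behavior the matching [simulate_behavior()] output.
#' @param params a [signal_params()].
#' @param geometry a [screen_geometry()].
#' @param seed integer seed; synthesis is deterministic given
#'   (inputs, params, seed).
#' @param gaze_cal_offset_px,gaze_cal_scale affine miscalibration applied
#'   to the measured gaze: `measured = scale * (true - centre) + centre +
#'   offset`.
#' @return Object of class `srp_recording`: `eeg` (channels x samples
#'   matrix, microvolts), `channels`, `fs`, `heog`, `veog`, `eye`
#'   (data.frame `time_s`, `x_px`, `y_px`, `pupil_mm`, `valid`), `eye_fs`,
#'   `events` (behavior events table), `truth` (list: `saccades` with
#'   `t_peak`/`latency_ms`/`dwell_ms`/`amp` per event, `blinks`,
#'   `gaze_cal`), `load`, `config`, `geometry`, `params`.
#' @export
synthesize_recording <- function(schedule, behavior,
                                 params = signal_params(),
                                 geometry = screen_geometry(),
                                 seed = 1L,
                                 gaze_cal_offset_px = c(15, -10),
                                 gaze_cal_scale = 1.03) {
  stopifnot(inherits(schedule, "srp_schedule"),
            inherits(behavior, "srp_behavior"))
  ev <- behavior$events
  if (nrow(ev) != nrow(schedule))
    stop("schedule and behavior do not describe the same events")
  load <- behavior$load
  cfg <- attr(schedule, "config")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))

  fs <- params$eeg_fs
  eye_fs <- params$eye_fs
  duration <- max(ev$onset_time) + cfg$highlight_duration + 2.5
  n <- ceiling(duration * fs)
  n_eye <- ceiling(duration * eye_fs)
  centers <- stimulus_centers(cfg, geometry)
  loc_key <- paste(centers$row, centers$col)
  cx <- geometry$width_px / 2; cy <- geometry$height_px / 2
  rise_to_tau <- function(rise_ms) (rise_ms / 1000) / (2 * log(9))
  tau_drift <- rise_to_tau(params$departure_rise_ms)
  tau_return <- rise_to_tau(params$return_rise_ms)
  cmx <- geometry$width_cm / geometry$width_px
  cmy <- geometry$height_cm / geometry$height_px
  lat_mu <- params$saccade_latency_means[[load]]
  lat_sd <- params$saccade_latency_sds[[load]]
  lb <- params$latency_bounds

  # --- event timeline: transitions shared by gaze and EOG -----------------
  n_ev <- nrow(ev)
  ev_sp <- ev$serial_position; ev_trial <- ev$trial_id
  ev_onset <- ev$onset_time; ev_label <- ev$label
  ci_all <- match(paste(ev$row, ev$col), loc_key)
  t_mid <- numeric(0); dx <- numeric(0); dy <- numeric(0); tau <- numeric(0)
  cur <- c(cx, cy)
  truth_lat <- rep(NA_real_, n_ev); truth_peak <- rep(NA_real_, n_ev)
  truth_dwell <- rep(NA_real_, n_ev); truth_amp <- rep(NA_real_, n_ev)
  truth_dx <- rep(NA_real_, n_ev); truth_dy <- rep(NA_real_, n_ev)
  add_tr <- function(tm, d, tw) {
    t_mid[length(t_mid) + 1L] <<- tm
    dx[length(dx) + 1L] <<- d[1]; dy[length(dy) + 1L] <<- d[2]
    tau[length(tau) + 1L] <<- tw
  }
  for (i in seq_len(n_ev)) {
    if (ev_sp[i] == 1L && i > 1L) {
      # drift back to centre during the reporting pause (after the last
      # event's feature window has closed)
      t_ret <- ev_onset[i] - cfg$intertrial_gap + 3.5
      add_tr(t_ret, c(cx, cy) - cur, tau_return)
      cur <- c(cx, cy)
    }
    dest <- c(centers$x_px[ci_all[i]], centers$y_px[ci_all[i]]) +
      rnorm(2, 0, params$gaze_jitter_px)
    disp <- dest - cur
    cond <- ev_label[i]  # nontarget / hit / miss
    if (sqrt(sum(disp^2)) >= 20) {
      lat <- .rtrunc_norm(1, lat_mu[[cond]], lat_sd[[cond]], lb[1], lb[2])
      t_peak <- ev_onset[i] + lat / 1000
      amp_deg <- sqrt(.px_to_deg(disp[1], cmx, geometry$eye_distance_cm)^2 +
                      .px_to_deg(disp[2], cmy, geometry$eye_distance_cm)^2)
      tau_sacc <- rise_to_tau(params$saccade_rise_ms +
                                params$rise_ms_per_deg * amp_deg)
      if (amp_deg > params$undershoot_min_deg && params$undershoot_frac > 0) {
        # main-sequence undershoot: main saccade + corrective 150 ms later
        add_tr(t_peak, disp * (1 - params$undershoot_frac), tau_sacc)
        add_tr(t_peak + 0.15, disp * params$undershoot_frac,
               rise_to_tau(30))
      } else {
        add_tr(t_peak, disp, tau_sacc)
      }
      truth_lat[i] <- lat; truth_peak[i] <- t_peak
      truth_dx[i] <- disp[1]; truth_dy[i] <- disp[2]
      cur <- dest
      arrive <- t_peak
    } else {
      arrive <- ev_onset[i]   # gaze already on the stimulus
    }
    # condition-dependent dwell, then slow disengagement drift
    dwell <- .rtrunc_norm(1, params$fixation_dwell_means[[cond]],
                          params$fixation_dwell_sd, 100, 1500)
    t_dep_max <- ev_onset[i] + cfg$highlight_duration + 0.09
    t_dep <- min(arrive + dwell / 1000, t_dep_max)
    truth_dwell[i] <- (t_dep - arrive) * 1000
    nxt_dest <- if (i < n_ev && ev_trial[i + 1L] == ev_trial[i]) {
      c(centers$x_px[ci_all[i + 1L]], centers$y_px[ci_all[i + 1L]])
    } else c(cx, cy)
    dep <- .departure_point(cur, nxt_dest, geometry)
    add_tr(t_dep + 0.125, dep - cur, tau_drift)  # drift midpoint after dwell
    cur <- dep
  }

  # --- true gaze paths on both clocks ------------------------------------
  gx_hi <- .apply_transitions(n, fs, cx, t_mid, dx, tau)
  gy_hi <- .apply_transitions(n, fs, cy, t_mid, dy, tau)
  gx_lo <- .apply_transitions(n_eye, eye_fs, cx, t_mid, dx, tau)
  gy_lo <- .apply_transitions(n_eye, eye_fs, cy, t_mid, dy, tau)

  # --- EOG: gain x gaze angle + noise + blinks ---------------------------
  heog <- params$eog_gain *
    .px_to_deg(gx_hi - cx, cmx, geometry$eye_distance_cm) +
    rnorm(n, 0, params$eog_noise_sd)
  veog <- params$eog_gain *
    .px_to_deg(cy - gy_hi, cmy, geometry$eye_distance_cm) +
    rnorm(n, 0, params$eog_noise_sd)
  bl <- inject_blinks(veog, fs, params$blink_rate_per_min,
                      params$blink_amplitude, params$blink_width_range)
  veog <- bl$veog

  # --- EEG: 1/f + white background, parieto-central bump per saccade -----
  channels <- montage_1020()$channel
  topo <- p300_topography(channels, params$p300_topo_sigma)
  active_ch <- which(topo >= 0.01)
  eeg <- matrix(0, nrow = length(channels), ncol = n,
                dimnames = list(channels, NULL))
  for (c_i in seq_along(channels)) {
    eeg[c_i, ] <- params$eeg_pink_sd * .pink_noise(n, params$pink_exponent) +
      rnorm(n, 0, params$eeg_white_sd)
  }
  amp_of <- c(hit = params$p300_amplitude_target,
              miss = params$p300_amplitude_miss,
              nontarget = params$p300_amplitude_nontarget)
  bump_t <- rep(NA_real_, n_ev)
  for (i in seq_len(n_ev)) {
    if (is.na(truth_peak[i])) next
    amp <- amp_of[[ev_label[i]]]
    truth_amp[i] <- amp
    if (amp == 0) next
    center <- truth_peak[i] + params$p300_latency
    bump_t[i] <- center
    hw <- .hann_window(n, fs, center, params$p300_width)
    if (is.null(hw)) next
    eeg[active_ch, hw$idx] <- eeg[active_ch, hw$idx] +
      (amp * topo[active_ch]) %o% hw$b
  }

  # --- eye streams: miscalibrated gaze, pupil, validity ------------------
  t_eye <- (seq_len(n_eye) - 1) / eye_fs
  meas_x <- gaze_cal_scale * (gx_lo - cx) + cx + gaze_cal_offset_px[1] +
    rnorm(n_eye, 0, 2)
  meas_y <- gaze_cal_scale * (gy_lo - cy) + cy + gaze_cal_offset_px[2] +
    rnorm(n_eye, 0, 2)
  drift <- stats::filter(rnorm(n_eye), rep(1 / (eye_fs * 5), eye_fs * 5),
                         sides = 2, circular = TRUE)
  drift <- as.numeric(drift)
  if (sd(drift) > 0) drift <- drift / sd(drift) * params$pupil_drift_sd
  pupil <- params$pupil_baseline[[load]] + drift +
    rnorm(n_eye, 0, params$pupil_noise_sd)
  if (params$pupil_miss_increment != 0) {
    for (i in which(ev_label == "miss")) {
      on <- ev_onset[i]
      t_end <- if (is.na(truth_peak[i])) on + 1 else
        truth_peak[i] + truth_dwell[i] / 1000
      pupil <- pupil + params$pupil_miss_increment *
        (plogis((t_eye - (on + 0.1)) / 0.1) - plogis((t_eye - t_end) / 0.2))
    }
  }
  valid <- runif(n_eye) >= params$invalid_sample_prob
  if (nrow(bl$intervals) > 0) {
    for (k in seq_len(nrow(bl$intervals)))
      valid[t_eye >= bl$intervals$start_s[k] &
            t_eye <= bl$intervals$end_s[k]] <- FALSE
  }

  truth <- list(
    saccades = data.frame(event = seq_len(n_ev),
                          trial_id = ev_trial,
                          serial_position = ev_sp,
                          onset_time = ev_onset,
                          label = ev_label,
                          latency_ms = truth_lat, t_peak = truth_peak,
                          dx_px = truth_dx, dy_px = truth_dy,
                          dwell_ms = truth_dwell, amp = truth_amp,
                          bump_center = bump_t),
    blinks = bl$intervals,
    gaze_cal = list(offset_px = gaze_cal_offset_px, scale = gaze_cal_scale)
  )
  structure(list(
    eeg = eeg, channels = channels, fs = fs,
    heog = heog, veog = veog,
    eye = data.frame(time_s = t_eye, x_px = meas_x, y_px = meas_y,
                     pupil_mm = pupil, valid = valid),
    eye_fs = eye_fs,
    events = ev, truth = truth, load = load, config = cfg,
    geometry = geometry, params = params, duration_s = duration
  ), class = "srp_recording")
}

#' @export
print.srp_recording <- function(x, ...) {
  cat("<srp_recording> ", length(x$channels), " EEG channels + HEOG/VEOG @ ",
      x$fs, " Hz, ", round(x$duration_s, 1), " s, ",
      nrow(x$events), " stimulus events (", x$load, " load), eye @ ",
      x$eye_fs, " Hz\n", sep = "")
  invisible(x)
}
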