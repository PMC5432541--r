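#' Experiment configuration
#'
#' Parameters of the structured search task: a 3 x 5 grid of "system"
#' locations highlighted one after another for about one second each, with a
#' concurrent aurally presented arithmetic task. Defaults reproduce the
#' study design; every field can be overridden.
#'
#' @param n_rows,n_cols grid dimensions (3 x 5).
#' @param highlight_duration seconds each location stays highlighted (1.027).
#' @param n_targets_choices per-trial target counts drawn uniformly (2, 3, 4).
#' @param n_blocks_per_load,n_trials_per_block session structure
#'   (8 blocks of 11 trials per load condition).
#' @param math_first_onset seconds from trial start to the first spoken
#'   number (1.0).
#' @param math_interval seconds between spoken numbers (2.66).
#' @param math_n_numbers numbers per sum (6).
#' @param intertrial_gap seconds of inter-trial pause standing in for the
#'   reporting phase (clicking target boxes and typing the math answer);
#'   gaze drifts back to screen centre and the signals are otherwise quiet.
#' @param session_start_pad seconds of recording before the first trial.
#' @return An object of class `srp_config` (a list); `n_positions_per_trial`
#'   is derived as `n_rows * n_cols`.
#' @export
experiment_config <- function(n_rows = 3L, n_cols = 5L,
                              highlight_duration = 1.027,
                              n_targets_choices = c(2L, 3L, 4L),
                              n_blocks_per_load = 8L,
                              n_trials_per_block = 11L,
                              math_first_onset = 1.0,
                              math_interval = 2.66,
                              math_n_numbers = 6L,
                              intertrial_gap = 18.0,
                              session_start_pad = 2.0) {
  cfg <- list(
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    n_positions_per_trial = as.integer(n_rows) * as.integer(n_cols),
    highlight_duration = highlight_duration,
    n_targets_choices = as.integer(n_targets_choices),
    n_blocks_per_load = as.integer(n_blocks_per_load),
    n_trials_per_block = as.integer(n_trials_per_block),
    math_first_onset = math_first_onset,
    math_interval = math_interval,
    math_n_numbers = as.integer(math_n_numbers),
    intertrial_gap = intertrial_gap,
    session_start_pad = session_start_pad
  )
  counts <- c(cfg$n_rows, cfg$n_cols, cfg$n_blocks_per_load,
              cfg$n_trials_per_block, cfg$math_n_numbers,
              cfg$n_targets_choices)
  if (any(counts <= 0)) stop("all configured counts must be positive")
  if (any(cfg$n_targets_choices >= cfg$n_positions_per_trial))
    stop("more targets than grid locations")
  structure(cfg, class = "srp_config")
}

#' Behavioral model parameters
#'
#' Stochastic hit/miss model: each presented target is missed independently
#' with probability `base_miss_prob(load) * serial_position_curve[pos]`
#' (clipped to \[0, 1\]). The serial-position curve is U-shaped in hit rate
#' (so the miss multiplier is low at the ends and high in the middle),
#' reflecting primacy and recency. A miss spawns a false alarm at a random
#' non-target location with probability `false_alarm_prob_per_miss`.
#'
#' Default base rates give expected hit rates of 0.73 (high load) and 0.96
#' (low load); the curve is normalized to mean 1 so the expectation is exact
#' when target positions are uniform.
#'
#' @param base_miss_prob_low,base_miss_prob_high mean miss probability per
#'   load condition.
#' @param serial_position_curve multiplicative modifier per serial position
#'   (length must match the grid size; normalized mean need not be 1 but the
#'   default is).
#' @param false_alarm_prob_per_miss probability that a missed target produces
#'   a report at some non-target location (default 42/72, the ratio of the
#'   average false-alarm and miss counts in high load).
#' @param n_positions serial positions per trial.
#' @return Object of class `srp_behavior_params`.
#' @export
behavior_params <- function(base_miss_prob_low = 0.04,
                            base_miss_prob_high = 0.27,
                            serial_position_curve = NULL,
                            false_alarm_prob_per_miss = 42 / 72,
                            n_positions = 15L) {
  if (is.null(serial_position_curve)) {
    pos <- seq_len(n_positions)
    raw <- 1 - 0.45 * cos(2 * pi * (pos - 1) / (n_positions - 1))
    serial_position_curve <- raw / mean(raw)
  }
  p <- list(base_miss_prob_low = base_miss_prob_low,
            base_miss_prob_high = base_miss_prob_high,
            serial_position_curve = serial_position_curve,
            false_alarm_prob_per_miss = false_alarm_prob_per_miss)
  probs <- c(base_miss_prob_low, base_miss_prob_high, false_alarm_prob_per_miss)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (any(serial_position_curve < 0)) stop("curve modifiers must be >= 0")
  n <- length(serial_position_curve)
  ends <- serial_position_curve[c(1L, n)]
  if (any(ends > max(serial_position_curve[-c(1L, n)])))
    stop("serial_position_curve must be U-shaped: ends <= middle")
  structure(p, class = "srp_behavior_params")
}

#' Screen geometry of the stimulus display
#'
#' @param width_px,height_px display resolution (1280 x 1024).
#' @param width_cm,height_cm physical display size (37.5 x 30 cm).
#' @param eye_distance_cm viewing distance (40 cm).
#' @return Object of class `srp_geometry`.
#' @export
screen_geometry <- function(width_px = 1280, height_px = 1024,
                            width_cm = 37.5, height_cm = 30,
                            eye_distance_cm = 40) {
  g <- list(width_px = width_px, height_px = height_px,
            width_cm = width_cm, height_cm = height_cm,
            eye_distance_cm = eye_distance_cm)
  if (any(unlist(g) <= 0)) stop("geometry dimensions must be positive")
  structure(g, class = "srp_geometry")
}

#' Convert a pixel extent to physical units
#'
#' Uses the horizontal pixel pitch; degrees of visual angle use the exact
#' formula `2 atan(cm / (2 d))`.
#'
#' @param pixels length in pixels.
#' @param geometry a [screen_geometry()].
#' @return list with `cm` and `degrees`.
#' @export
px_to_physical <- function(pixels, geometry = screen_geometry()) {
  stopifnot(inherits(geometry, "srp_geometry"))
  cm <- pixels * geometry$width_cm / geometry$width_px
  degrees <- (180 / pi) * 2 * atan(cm / (2 * geometry$eye_distance_cm))
  list(cm = cm, degrees = degrees)
}

#' Pixel centres of the stimulus grid locations
#'
#' @param config an [experiment_config()].
#' @param geometry a [screen_geometry()].
#' @return data.frame with `row`, `col` (0-based, row 0 at top) and pixel
#'   centre coordinates `x_px`, `y_px` (y grows downward).
#' @export
stimulus_centers <- function(config = experiment_config(),
                             geometry = screen_geometry()) {
  grid <- expand.grid(row = seq_len(config$n_rows) - 1L,
                      col = seq_len(config$n_cols) - 1L)
  grid$x_px <- (grid$col + 0.5) * geometry$width_px / config$n_cols
  grid$y_px <- (grid$row + 0.5) * geometry$height_px / config$n_rows
  grid[order(grid$row, grid$col), , drop = FALSE]
}

#' Analysis pipeline thresholds
#'
#' All numeric thresholds of the preprocessing/analysis chain in one place.
#' Defaults follow the study's analysis: 5 SD despiking, 3 SD blink
#' detection on a 2-100 Hz band, velocity sigma of 8 samples, 4 SD saccade
#' candidates in a 100-800 ms window, 5x-median-SD bad channels, 0.5-32 Hz
#' EEG band, 1 s epochs baselined on their first 100 ms, 50x-median-SD epoch
#' rejection, 250-1000 ms SVM features, 150 px fixation radius with a 2 s
#' window, 5-fold cross-validation, alpha 0.05.
#'
#' @param spike_k,blink_k,candidate_k,badchan_k,outlier_k SD multipliers.
#' @param blink_band,eeg_band Hz.
#' @param velocity_sigma samples.
#' @param saccade_window seconds after highlight onset.
#' @param epoch_span,baseline_span seconds from the saccade velocity peak.
#' @param svm_interval seconds within the epoch used as SVM features.
#' @param fixation_radius_px,fixation_window on-stimulus criterion.
#' @param spike_pad_ms,blink_pad_ms padding cut around detected artifacts.
#' @param blink_merge_ms,candidate_merge_ms run-merging gaps.
#' @param interp_k good channels used to interpolate a bad one.
#' @param cv_folds,alpha statistics settings.
#' @param target_fs Hz the recording is resampled to before analysis.
#' @param pupil_stat `"mean"` (default) or `"median"` pupil summary.
#' @param min_miss_count misses required before a hit/miss contrast is run.
#' @return Object of class `srp_pipeline_params`.
#' @export
pipeline_params <- function(spike_k = 5, blink_k = 3, blink_band = c(2, 100),
                            velocity_sigma = 8, candidate_k = 4,
                            saccade_window = c(0.1, 0.8),
                            badchan_k = 5, eeg_band = c(0.5, 32),
                            epoch_span = c(0, 1), baseline_span = 0.1,
                            outlier_k = 50, svm_interval = c(0.25, 1.0),
                            fixation_radius_px = 150, fixation_window = 2,
                            spike_pad_ms = 50, blink_pad_ms = 100,
                            blink_merge_ms = 100, candidate_merge_ms = 20,
                            interp_k = 4, cv_folds = 5, alpha = 0.05,
                            target_fs = 256, pupil_stat = c("mean", "median"),
                            min_miss_count = 10) {
  ks <- c(spike_k, blink_k, candidate_k, badchan_k, outlier_k)
  if (any(ks <= 0)) stop("SD multipliers must be positive")
  stopifnot(saccade_window[1] < saccade_window[2],
            eeg_band[1] < eeg_band[2], blink_band[1] < blink_band[2],
            epoch_span[1] < epoch_span[2],
            svm_interval[1] < svm_interval[2])
  structure(list(
    spike_k = spike_k, blink_k = blink_k, blink_band = blink_band,
    velocity_sigma = velocity_sigma, candidate_k = candidate_k,
    saccade_window = saccade_window, badchan_k = badchan_k,
    eeg_band = eeg_band, epoch_span = epoch_span,
    baseline_span = baseline_span, outlier_k = outlier_k,
    svm_interval = svm_interval, fixation_radius_px = fixation_radius_px,
    fixation_window = fixation_window, spike_pad_ms = spike_pad_ms,
    blink_pad_ms = blink_pad_ms, blink_merge_ms = blink_merge_ms,
    candidate_merge_ms = candidate_merge_ms, interp_k = interp_k,
    cv_folds = cv_folds, alpha = alpha, target_fs = target_fs,
    pupil_stat = match.arg(pupil_stat), min_miss_count = min_miss_count
  ), class = "srp_pipeline_params")
}

#' 2D montage of the 32-channel 10-20 layout
#'
#' Approximate top-view projected coordinates (unit head radius, nose up)
#' for the standard 32-electrode cap, used for bad-channel interpolation and
#' the parieto-central response topography.
#'
#' @return data.frame with `channel`, `x` (left negative), `y` (front
#'   positive).
#' @export
montage_1020 <- function() {
  m <- rbind(
    c("Fp1", -0.25,  0.76), c("Fp2",  0.25,  0.76),
    c("AF3", -0.21,  0.60), c("AF4",  0.21,  0.60),
    c("F7",  -0.76,  0.25), c("F3",  -0.40,  0.42),
    c("Fz",   0.00,  0.40), c("F4",   0.40,  0.42), c("F8",  0.76,  0.25),
    c("FC5", -0.60,  0.21), c("FC1", -0.21,  0.21),
    c("FC2",  0.21,  0.21), c("FC6",  0.60,  0.21),
    c("T7",  -0.80,  0.00), c("C3",  -0.40,  0.00),
    c("Cz",   0.00,  0.00), c("C4",   0.40,  0.00), c("T8",  0.80,  0.00),
    c("CP5", -0.60, -0.21), c("CP1", -0.21, -0.21),
    c("CP2",  0.21, -0.21), c("CP6",  0.60, -0.21),
    c("P7",  -0.76, -0.25), c("P3",  -0.40, -0.42),
    c("Pz",   0.00, -0.40), c("P4",   0.40, -0.42), c("P8",  0.76, -0.25),
    c("PO3", -0.25, -0.62), c("PO4",  0.25, -0.62),
    c("O1",  -0.25, -0.76), c("Oz",   0.00, -0.80), c("O2",  0.25, -0.76)
  )
  data.frame(channel = m[, 1], x = as.numeric(m[, 2]),
             y = as.numeric(m[, 3]), stringsAsFactors = FALSE)
}

#' Channels entering the parieto-central average
#' @return character vector of the seven channels around Pz.
#' @export
srp_channel_set <- function() c("CP1", "P3", "Pz", "PO3", "PO4", "P4", "CP2")

#' Signal-synthesis parameters
#'
#' Controls the synthetic recording: native sampling rates, background noise,
#' the parieto-central target response, per-condition saccade latencies and
#' fixation dwells, pupil baselines, blink and dropout rates, and the
#' EOG gain. Latency means/SDs default to the study's saccade-latency table;
#' the target response is a Hann-shaped positive bump peaking 0.5 s after
#' the saccade velocity peak, larger for targets than non-targets, with hit
#' and miss amplitudes equal. Fixation dwells are longer for targets than
#' non-targets and for hits than misses; pupil baseline is larger under high
#' load, with an extra increment while a to-be-missed target is fixated.
#'
#' @param eeg_fs,eye_fs native sampling rates (Hz).
#' @param eeg_pink_sd,eeg_white_sd,pink_exponent EEG background noise:
#'   1/f^alpha component SD, white component SD (microvolts), and alpha.
#' @param p300_amplitude_target,p300_amplitude_nontarget bump amplitude
#'   (microvolts) at the topography maximum.
#' @param p300_amplitude_miss amplitude for missed targets; `NULL` means
#'   equal to `p300_amplitude_target`.
#' @param p300_latency,p300_width seconds (peak delay after the saccade
#'   velocity peak; full bump width).
#' @param p300_topo_sigma spatial Gaussian falloff (montage units) of the
#'   parieto-central topography.
#' @param saccade_latency_means,saccade_latency_sds per load x condition
#'   (`hit`, `miss`, `nontarget`) latency distributions, ms.
#' @param latency_bounds ms; latency draws are redrawn into these bounds.
#' @param fixation_dwell_means,fixation_dwell_sd per condition dwell on the
#'   stimulus, ms.
#' @param pupil_baseline mm per load condition.
#' @param pupil_miss_increment mm added while fixating a to-be-missed target.
#' @param pupil_drift_sd,pupil_noise_sd mm (slow drift; per-sample noise).
#' @param blink_rate_per_min,blink_amplitude,blink_width_range blink model
#'   (Poisson rate; microvolts; seconds).
#' @param eog_gain microvolts per degree of gaze rotation.
#' @param eog_noise_sd microvolts.
#' @param saccade_rise_ms,rise_ms_per_deg saccade 10-90% rise time:
#'   `saccade_rise_ms + rise_ms_per_deg * amplitude_deg` (main-sequence
#'   duration scaling).
#' @param departure_rise_ms,return_rise_ms rise times of the slow
#'   post-dwell disengagement drift and the inter-trial recentering drift
#'   (rendered as drifts, not saccades: reporting-phase kinematics are not
#'   modeled).
#' @param undershoot_frac,undershoot_min_deg saccades larger than
#'   `undershoot_min_deg` undershoot by `undershoot_frac` and complete
#'   with a corrective saccade 150 ms later (saccadic main sequence).
#' @param gaze_jitter_px fixation-position jitter SD.
#' @param invalid_sample_prob probability an eye sample is flagged invalid
#'   outside blinks.
#' @return Object of class `srp_signal_params`.
#' @export
signal_params <- function(eeg_fs = 512, eye_fs = 60,
                          eeg_pink_sd = 8, eeg_white_sd = 2,
                          pink_exponent = 1,
                          p300_amplitude_target = 5,
                          p300_amplitude_nontarget = 1,
                          p300_amplitude_miss = NULL,
                          p300_latency = 0.5, p300_width = 0.3,
                          p300_topo_sigma = 0.35,
                          saccade_latency_means = list(
                            low  = c(hit = 154, miss = 267, nontarget = 165),
                            high = c(hit = 199, miss = 284, nontarget = 229)),
                          saccade_latency_sds = list(
                            low  = c(hit = 38, miss = 245, nontarget = 45),
                            high = c(hit = 43, miss = 97, nontarget = 53)),
                          latency_bounds = c(110, 780),
                          fixation_dwell_means = c(hit = 750, miss = 600,
                                                   nontarget = 500),
                          fixation_dwell_sd = 150,
                          pupil_baseline = c(low = 4.3, high = 4.7),
                          pupil_miss_increment = 0.25,
                          pupil_drift_sd = 0.1, pupil_noise_sd = 0.05,
                          blink_rate_per_min = 10, blink_amplitude = 400,
                          blink_width_range = c(0.1, 0.25),
                          eog_gain = 12, eog_noise_sd = 5,
                          saccade_rise_ms = 25, rise_ms_per_deg = 2.5,
                          departure_rise_ms = 400, return_rise_ms = 2500,
                          undershoot_frac = 0.12, undershoot_min_deg = 15,
                          gaze_jitter_px = 6,
                          invalid_sample_prob = 0.02) {
  if (is.null(p300_amplitude_miss)) p300_amplitude_miss <- p300_amplitude_target
  p <- list(eeg_fs = eeg_fs, eye_fs = eye_fs,
            eeg_pink_sd = eeg_pink_sd, eeg_white_sd = eeg_white_sd,
            pink_exponent = pink_exponent,
            p300_amplitude_target = p300_amplitude_target,
            p300_amplitude_nontarget = p300_amplitude_nontarget,
            p300_amplitude_miss = p300_amplitude_miss,
            p300_latency = p300_latency, p300_width = p300_width,
            p300_topo_sigma = p300_topo_sigma,
            saccade_latency_means = saccade_latency_means,
            saccade_latency_sds = saccade_latency_sds,
            latency_bounds = latency_bounds,
            fixation_dwell_means = fixation_dwell_means,
            fixation_dwell_sd = fixation_dwell_sd,
            pupil_baseline = pupil_baseline,
            pupil_miss_increment = pupil_miss_increment,
            pupil_drift_sd = pupil_drift_sd, pupil_noise_sd = pupil_noise_sd,
            blink_rate_per_min = blink_rate_per_min,
            blink_amplitude = blink_amplitude,
            blink_width_range = blink_width_range,
            eog_gain = eog_gain, eog_noise_sd = eog_noise_sd,
            saccade_rise_ms = saccade_rise_ms,
            rise_ms_per_deg = rise_ms_per_deg,
            departure_rise_ms = departure_rise_ms,
            return_rise_ms = return_rise_ms,
            undershoot_frac = undershoot_frac,
            undershoot_min_deg = undershoot_min_deg,
            gaze_jitter_px = gaze_jitter_px,
            invalid_sample_prob = invalid_sample_prob)
  nonneg <- c(eeg_pink_sd, eeg_white_sd, pupil_drift_sd, pupil_noise_sd,
              blink_rate_per_min, eog_noise_sd, gaze_jitter_px,
              invalid_sample_prob, fixation_dwell_sd)
  if (any(nonneg < 0)) stop("rates and SDs must be non-negative")
  structure(p, class = "srp_signal_params")
}

#' Null-condition signal parameters
#'
#' A [signal_params()] variant with every condition effect removed: equal
#' target/non-target/miss response amplitudes, identical saccade-latency
#' and fixation-dwell distributions across conditions, equal pupil
#' baselines and no miss-related pupil increment. Used for calibration:
#' under these parameters condition-wise summaries differ only by sampling
#' error, pointwise tests should be significant at about the alpha rate,
#' and classifiers should sit at chance.
#'
#' @param amplitude common response amplitude (microvolts).
#' @param ... further overrides passed to [signal_params()].
#' @return an `srp_signal_params` object.
#' @export
null_signal_params <- function(amplitude = 2, ...) {
  signal_params(
    p300_amplitude_target = amplitude,
    p300_amplitude_nontarget = amplitude,
    p300_amplitude_miss = amplitude,
    saccade_latency_means = list(
      low  = c(hit = 165, miss = 165, nontarget = 165),
      high = c(hit = 229, miss = 229, nontarget = 229)),
    saccade_latency_sds = list(
      low  = c(hit = 45, miss = 45, nontarget = 45),
      high = c(hit = 53, miss = 53, nontarget = 53)),
    fixation_dwell_means = c(hit = 600, miss = 600, nontarget = 600),
    pupil_baseline = c(low = 4.5, high = 4.5),
    pupil_miss_increment = 0,
    ...
  )
}

#' Parieto-central topography weights for the synthetic target response
#'
#' Gaussian falloff on the 2D montage from the centroid of the
#' parieto-central channel set, scaled to a maximum of 1 within that set.
#'
#' @param channels channel names to weight.
#' @param sigma spatial falloff (montage units).
#' @return named numeric vector of weights in \[0, 1\].
#' @export
p300_topography <- function(channels = montage_1020()$channel, sigma = 0.35) {
  mon <- montage_1020()
  core <- mon[mon$channel %in% srp_channel_set(), ]
  cx <- mean(core$x); cy <- mean(core$y)
  idx <- match(channels, mon$channel)
  if (anyNA(idx)) stop("unknown channel(s): ",
                       paste(channels[is.na(idx)], collapse = ", "))
  d2 <- (mon$x[idx] - cx)^2 + (mon$y[idx] - cy)^2
  w <- exp(-d2 / (2 * sigma^2))
  names(w) <- channels
  w / max(exp(-((core$x - cx)^2 + (core$y - cy)^2) / (2 * sigma^2)))
}
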