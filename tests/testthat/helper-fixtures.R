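# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# A processed high-load session (6 trials) with ground truth, reused by
# several files.
shared_session <- function() {
  if (!is.null(.fixture_cache$session)) return(.fixture_cache$session)
  cfg <- experiment_config()
  sched <- generate_schedule(cfg, "high", seed = 301, n_trials = 6)
  beh <- simulate_behavior(sched, params = behavior_params(), seed = 302)
  rec <- synthesize_recording(sched, beh, seed = 303)
  ses <- process_session(rec)
  .fixture_cache$session <- list(schedule = sched, behavior = beh,
                                 recording = rec, session = ses)
  .fixture_cache$session
}

# Hand-built schedule skeleton (no adjacency guarantees) for behavioral
# tests that need many trials cheaply.
make_flat_schedule <- function(n_trials, config = experiment_config(),
                               target_positions = c(3, 8, 13)) {
  n_pos <- config$n_positions_per_trial
  grid <- expand.grid(row = seq_len(config$n_rows) - 1L,
                      col = seq_len(config$n_cols) - 1L)
  trial_len <- n_pos * config$highlight_duration + config$intertrial_gap
  sched <- do.call(rbind, lapply(seq_len(n_trials), function(t) {
    data.frame(trial_id = t,
               block = ((t - 1L) %/% config$n_trials_per_block) + 1L,
               serial_position = seq_len(n_pos),
               row = grid$row, col = grid$col,
               onset_time = config$session_start_pad + (t - 1) * trial_len +
                 (seq_len(n_pos) - 1) * config$highlight_duration,
               is_target = seq_len(n_pos) %in% target_positions)
  }))
  structure(sched, class = c("srp_schedule", "data.frame"),
            load_condition = "high", config = config, seed = NA)
}

# Noise-free signal parameters for exact-recovery tests.
quiet_signal_params <- function(...) {
  signal_params(eeg_pink_sd = 0, eeg_white_sd = 0, eog_noise_sd = 0,
                blink_rate_per_min = 0, gaze_jitter_px = 0,
                pupil_drift_sd = 0, pupil_noise_sd = 0,
                invalid_sample_prob = 0, ...)
}
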