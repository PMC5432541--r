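# End-to-end study orchestration: simulate participants, run the full
# processing chain, aggregate group statistics and the classification grid.

# Deterministic sub-seed derivation, kept below 2^31 (exact in doubles).
.derive_seed <- function(seed, ...) {
  k <- c(...)
  v <- (as.numeric(seed) * 48271 + sum(k * 7919^seq_along(k))) %%
    2147483629
  as.integer(v %% 2147483629 + 1)
}

#' Simulate one participant's sessions
#'
#' Generates a schedule, report behavior and a synthetic recording per load
#' condition.
#'
#' @param participant integer id.
#' @param seed study seed; per-session seeds are derived deterministically.
#' @param n_trials_per_load trials per load condition; either a single
#'   count or a named vector like `c(low = 10, high = 16)`.
#' @param config an [experiment_config()].
#' @param bparams a [behavior_params()].
#' @param sparams a [signal_params()].
#' @param geometry a [screen_geometry()].
#' @param loads load conditions to simulate.
#' @return named list per load: `schedule`, `behavior`, `recording`.
#' @export
simulate_participant <- function(participant, seed = 1L,
                                 n_trials_per_load = 16L,
                                 config = experiment_config(),
                                 bparams = behavior_params(),
                                 sparams = signal_params(),
                                 geometry = screen_geometry(),
                                 loads = c("low", "high")) {
  out <- list()
  for (load in loads) {
    li <- match(load, c("low", "high"))
    n_tr <- if (length(n_trials_per_load) > 1) n_trials_per_load[[load]]
    else n_trials_per_load
    sched <- generate_schedule(config, load,
                               seed = .derive_seed(seed, participant, li, 1),
                               n_trials = n_tr)
    beh <- simulate_behavior(sched, load, bparams,
                             seed = .derive_seed(seed, participant, li, 2))
    rec <- synthesize_recording(sched, beh, sparams, geometry,
                                seed = .derive_seed(seed, participant, li, 3))
    out[[load]] <- list(schedule = sched, behavior = beh, recording = rec)
  }
  out
}

#' Run the full processing chain on one recording
#'
#' Fixed order: resample; EOG despike + deblink + velocity; saccade
#' detection and selection; EEG bad-channel detection, interpolation
#' (unfiltered), average re-reference (unfiltered), 0.5-32 Hz bandpass;
#' saccade-locked epochs (EEG + cleaned EOG channels) with first-100-ms
#' baseline; outlier-epoch rejection; gaze recalibration; fixation/pupil
#' features.
#'
#' @param rec an `srp_recording`.
#' @param params a [pipeline_params()].
#' @return list of class `srp_session`: `epochs`, `saccades`,
#'   `eye_features`, `cleaned_eog`, `bad_channels`, `recalibration`,
#'   `unmatched_fraction`, `events`, `load`.
#' @export
process_session <- function(rec, params = pipeline_params()) {
  stopifnot(inherits(rec, "srp_recording"))
  rec <- resample_recording(rec, params$target_fs)
  fs <- rec$fs
  sched <- structure(rec$events, class = c("srp_schedule", "data.frame"),
                     config = rec$config, load_condition = rec$load)
  cleaned <- clean_eog(rec$heog, rec$veog, fs, params)
  saccades <- detect_saccades_of_interest(cleaned, sched, rec$geometry,
                                          params)
  bads <- detect_bad_channels(rec$eeg, fs, params$badchan_k,
                              params$eeg_band)
  eeg <- interpolate_bad_channels(rec$eeg, bads, montage_1020(),
                                  params$interp_k)
  eeg <- rereference_average(eeg, bads)
  eeg <- bandpass_eeg(eeg, fs, params$eeg_band)
  data <- rbind(eeg, HEOG = cleaned$heog, VEOG = cleaned$veog)
  labels <- rec$events[, c("trial_id", "serial_position", "is_target",
                           "hit", "label")]
  epochs <- extract_epochs(data, fs, saccades, labels,
                           params$epoch_span, params$baseline_span)
  epochs <- reject_outlier_epochs(epochs, params$outlier_k,
                                  setdiff(rec$channels, c("HEOG", "VEOG")))
  recal <- tryCatch(
    recalibrate_gaze(rec$eye, sched, rec$geometry),
    error = function(e) list(eye = rec$eye, transform = NULL,
                             fit = "none", n_events_used = 0))
  eyef <- fixation_features(recal$eye, sched, rec$geometry, rec$eye_fs,
                            params$fixation_radius_px,
                            params$fixation_window, params$pupil_stat)
  structure(list(epochs = epochs, saccades = saccades, eye_features = eyef,
                 cleaned_eog = cleaned, bad_channels = bads,
                 recalibration = recal[c("transform", "fit",
                                         "n_events_used")],
                 unmatched_fraction = attr(saccades, "unmatched_fraction"),
                 events = rec$events, load = rec$load),
            class = "srp_session")
}

# Per-participant condition means of a scalar eye feature.
.feature_means <- function(session, column) {
  f <- session$eye_features[[column]]
  lab <- session$events$label
  c(target = mean(f[lab != "nontarget"], na.rm = TRUE),
    nontarget = mean(f[lab == "nontarget"], na.rm = TRUE),
    hit = mean(f[lab == "hit"], na.rm = TRUE),
    miss = if (any(lab == "miss")) mean(f[lab == "miss"], na.rm = TRUE)
    else NA_real_)
}

#' Simulate and analyze a complete study
#'
#' Simulates `n_participants`, runs [process_session()] on every session,
#' and aggregates: behavioral summaries, the condition-wise saccade-latency
#' table, parieto-central SRP traces with pointwise paired t-tests
#' (target vs non-target per load, hit vs miss in high load),
#' paired tests on fixation duration and pupil size, a math-vs-monitoring
#' performance correlation, and the single-trial classification grid.
#'
#' @param n_participants simulated participants.
#' @param seed study seed; everything derives from it.
#' @param n_trials_per_load trials per load condition per participant.
#' @param config,bparams,sparams,pparams,geometry component parameter
#'   objects.
#' @param feature_ids classifier feature sets to evaluate.
#' @param math_correct_prob probability a math answer is correct (62%).
#' @param out_dir optional directory; result tables are written as TSVs.
#' @return object of class `srp_study` (see elements described above).
#' @export
run_study <- function(n_participants = 20, seed = 1L,
                      n_trials_per_load = 16L,
                      config = experiment_config(),
                      bparams = behavior_params(),
                      sparams = signal_params(),
                      pparams = pipeline_params(),
                      geometry = screen_geometry(),
                      feature_ids = c("SRP", "FIXDUR", "PUPIL", "EYE",
                                      "ALL"),
                      math_correct_prob = 0.62,
                      out_dir = NULL) {
  loads <- c("low", "high")
  conds <- c("target", "nontarget", "hit", "miss")
  n_samp <- round((pparams$epoch_span[2] - pparams$epoch_span[1]) *
                  pparams$target_fs)
  traces <- list()
  for (ld in loads) for (cn in conds)
    traces[[paste(ld, cn, sep = ".")]] <-
      matrix(NA_real_, n_participants, n_samp)
  behavioral <- list(); latency <- list(); fixdur <- list(); pupil <- list()
  grids <- list(); unmatched <- c(); math_scores <- numeric(n_participants)

  for (p in seq_len(n_participants)) {
    sim <- simulate_participant(p, seed, n_trials_per_load, config,
                                bparams, sparams, geometry, loads)
    sessions <- list()
    for (ld in loads) {
      ses <- process_session(sim[[ld]]$recording, pparams)
      sessions[[ld]] <- ses
      bm <- behavioral_metrics(sim[[ld]]$schedule, sim[[ld]]$behavior)
      behavioral[[length(behavioral) + 1L]] <- data.frame(
        participant = p, load = ld, hit_rate = bm$hit_rate,
        n_targets = bm$n_targets, n_misses = bm$n_misses,
        n_false_alarms = bm$n_false_alarms,
        under_report = bm$under_report)
      lt <- compute_saccade_latencies(ses$saccades, ses$events$label)
      lt$participant <- p; lt$load <- ld
      latency[[length(latency) + 1L]] <- lt
      unmatched <- c(unmatched, ses$unmatched_fraction)
      lab <- ses$epochs$labels
      for (cn in conds) {
        mask <- switch(cn,
                       target = lab$is_target,
                       nontarget = !lab$is_target,
                       hit = lab$label == "hit",
                       miss = lab$label == "miss")
        tr <- participant_srp(ses$epochs, mask)
        if (!is.null(tr)) traces[[paste(ld, cn, sep = ".")]][p, ] <- tr
      }
      fixdur[[length(fixdur) + 1L]] <- data.frame(
        participant = p, load = ld,
        t(.feature_means(ses, "fixation_duration_ms")))
      pupil[[length(pupil) + 1L]] <- data.frame(
        participant = p, load = ld, t(.feature_means(ses, "pupil_mm")))
    }
    grid <- comparison_grid(
      list(low = list(epochs = sessions$low$epochs,
                      eye_features = sessions$low$eye_features),
           high = list(epochs = sessions$high$epochs,
                       eye_features = sessions$high$eye_features)),
      feature_ids = feature_ids, folds = pparams$cv_folds,
      alpha = pparams$alpha, min_miss = pparams$min_miss_count,
      seed = .derive_seed(seed, p, 9))
    grid$participant <- p
    grids[[p]] <- grid
    # math-task score, independent of the monitoring model
    old <- .Random.seed_save()
    set.seed(.derive_seed(seed, p, 11))
    n_tr_high <- if (length(n_trials_per_load) > 1)
      n_trials_per_load[["high"]] else n_trials_per_load
    math_scores[p] <- mean(rbinom(n_tr_high, 1, math_correct_prob))
    .Random.seed_restore(old)
  }

  behavioral <- do.call(rbind, behavioral)
  latency <- do.call(rbind, latency)
  fixdur <- do.call(rbind, fixdur)
  pupil <- do.call(rbind, pupil)
  grid <- do.call(rbind, grids)
  times <- pparams$epoch_span[1] + (seq_len(n_samp) - 1) / pparams$target_fs

  pw_try <- function(a, b) tryCatch(
    pointwise_paired_ttest(a, b, times, pparams$alpha),
    error = function(e) NULL)   # too few participants: reported as NULL
  pointwise <- list(
    tnt_low = pw_try(traces$low.target, traces$low.nontarget),
    tnt_high = pw_try(traces$high.target, traces$high.nontarget),
    hm_high = pw_try(traces$high.hit, traces$high.miss))

  fd_h <- fixdur[fixdur$load == "high", ]
  pp_h <- pupil[pupil$load == "high", ]
  pp_l <- pupil[pupil$load == "low", ]
  ft_try <- function(a, b) tryCatch(paired_feature_test(a, b),
                                    error = function(e) NULL)
  feature_tests <- list(
    fixdur_target_nontarget_high = ft_try(fd_h$target, fd_h$nontarget),
    fixdur_hit_miss_high = ft_try(fd_h$hit, fd_h$miss),
    pupil_hit_miss_high = ft_try(pp_h$miss, pp_h$hit),
    pupil_load = ft_try(pp_h$target, pp_l$target))

  hr_high <- behavioral$hit_rate[behavioral$load == "high"]
  correlation <- tryCatch(correlate_performance(math_scores, hr_high),
                          error = function(e) NULL)

  # group latency table: mean over participant means per condition x load
  lat_group <- do.call(rbind, lapply(loads, function(ld) {
    sub <- latency[latency$load == ld & latency$n > 0, ]
    agg <- aggregate(cbind(mean_ms, sd_ms) ~ condition, sub, mean)
    agg$load <- ld
    agg
  }))

  # classification summary per cell
  av <- grid[grid$available %in% TRUE, ]
  class_summary <- if (nrow(av)) {
    s <- aggregate(accuracy ~ load + contrast + feature_set, av, mean)
    s$sem <- aggregate(accuracy ~ load + contrast + feature_set, av,
                       function(a) sd(a) / sqrt(length(a)))$accuracy
    s$n_above_chance <- aggregate(above_chance ~ load + contrast +
                                    feature_set, av, sum)$above_chance
    s$n_participants <- aggregate(accuracy ~ load + contrast + feature_set,
                                  av, length)$accuracy
    s
  } else NULL

  study <- structure(list(
    behavioral = behavioral, latency = latency, latency_group = lat_group,
    traces = traces, times = times, pointwise = pointwise,
    fixation_duration = fixdur, pupil = pupil,
    feature_tests = feature_tests, correlation = correlation,
    classification = grid, classification_summary = class_summary,
    unmatched_fraction = mean(unmatched), math_scores = math_scores,
    n_participants = n_participants, seed = seed,
    n_trials_per_load = n_trials_per_load
  ), class = "srp_study")
  if (!is.null(out_dir)) write_study_tables(study, out_dir)
  study
}

#' Write a study's result tables
#'
#' Deterministic TSV dumps of the aggregate tables (byte-identical for
#' identical studies): behavioral, latency (per participant and group),
#' grand-average traces with SEM, pointwise test results, feature tests,
#' classification grid and summary.
#'
#' @param study an `srp_study`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_study_tables <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(study$behavioral, file.path(out_dir, "behavioral.tsv"))
  .write_tsv(study$latency, file.path(out_dir, "latency.tsv"))
  .write_tsv(study$latency_group, file.path(out_dir, "latency_group.tsv"))
  tr_rows <- list()
  for (nm in names(study$traces)) {
    ga <- average_srp(study$traces[[nm]])
    if (ga$n == 0) next
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    tr_rows[[nm]] <- data.frame(time_s = study$times, load = parts[1],
                                condition = parts[2], mean = ga$grand,
                                sem = ga$sem, n = ga$n)
  }
  .write_tsv(do.call(rbind, tr_rows), file.path(out_dir, "traces.tsv"))
  pw_rows <- list()
  for (nm in names(study$pointwise)) {
    pw <- study$pointwise[[nm]]
    if (is.null(pw)) next
    pw_rows[[nm]] <- data.frame(contrast = nm, time_s = pw$times,
                                t = pw$t, p = pw$p,
                                sig_uncorrected = pw$sig_uncorrected,
                                sig_bh = pw$sig_bh)
  }
  if (length(pw_rows))
    .write_tsv(do.call(rbind, pw_rows), file.path(out_dir, "pointwise.tsv"))
  ft <- do.call(rbind, lapply(names(study$feature_tests), function(nm) {
    x <- study$feature_tests[[nm]]
    if (is.null(x)) return(NULL)
    data.frame(test = nm, t = x$t, df = x$df, p = x$p,
               mean_diff = x$mean_diff, n = x$n)
  }))
  if (!is.null(ft)) .write_tsv(ft, file.path(out_dir, "feature_tests.tsv"))
  .write_tsv(study$classification, file.path(out_dir, "classification.tsv"))
  if (!is.null(study$classification_summary))
    .write_tsv(study$classification_summary,
               file.path(out_dir, "classification_summary.tsv"))
  invisible(out_dir)
}

#' @export
print.srp_study <- function(x, ...) {
  cat("<srp_study> ", x$n_participants, " participants, ",
      x$n_trials_per_load, " trials/load, seed ", x$seed, "\n", sep = "")
  hr <- aggregate(hit_rate ~ load, x$behavioral, mean)
  for (i in seq_len(nrow(hr)))
    cat("  hit rate (", hr$load[i], " load): ",
        sprintf("%.3f", hr$hit_rate[i]), "\n", sep = "")
  cat("  unmatched saccade fraction: ",
      sprintf("%.3f", x$unmatched_fraction), "\n", sep = "")
  invisible(x)
}
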