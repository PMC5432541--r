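# Gaze recalibration and fixation/pupil features.

# Eye stream glued to each highlighted stimulus centre.
make_glued_eye <- function(schedule, geometry = screen_geometry(),
                           eye_fs = 60, jitter = 0) {
  centers <- stimulus_centers(attr(schedule, "config"), geometry)
  dur <- max(schedule$onset_time) + 3
  t <- seq(0, dur, by = 1 / eye_fs)
  x <- rep(geometry$width_px / 2, length(t))
  y <- rep(geometry$height_px / 2, length(t))
  for (i in seq_len(nrow(schedule))) {
    ci <- which(centers$row == schedule$row[i] &
                centers$col == schedule$col[i])
    sel <- t >= schedule$onset_time[i] &
      t < schedule$onset_time[i] + 1.027
    x[sel] <- centers$x_px[ci]
    y[sel] <- centers$y_px[ci]
  }
  if (jitter > 0) {
    x <- x + rnorm(length(t), 0, jitter)
    y <- y + rnorm(length(t), 0, jitter)
  }
  data.frame(time_s = t, x_px = x, y_px = y, pupil_mm = 4.5, valid = TRUE)
}

test_that("recalibration recovers identity and known affine distortions", {
  sched <- generate_schedule(experiment_config(), "high", seed = 91,
                             n_trials = 2)
  eye <- make_glued_eye(sched)
  out <- recalibrate_gaze(eye, sched)
  expect_equal(out$fit, "affine")
  expect_equal(unname(out$transform[, 1:2]), diag(2), tolerance = 1e-6)
  expect_equal(unname(out$transform[, 3]), c(0, 0), tolerance = 1e-4)

  # known distortion: scale 1.05 + offset 30 px
  eye_d <- eye
  eye_d$x_px <- eye$x_px * 1.05 + 30
  eye_d$y_px <- eye$y_px * 1.05 + 30
  out_d <- recalibrate_gaze(eye_d, sched)
  expect_equal(unname(out_d$transform[1, 1]), 1 / 1.05, tolerance = 0.01)
  expect_equal(unname(out_d$transform[2, 2]), 1 / 1.05, tolerance = 0.01)
  expect_lt(max(abs(out_d$eye$x_px - eye$x_px)), 1)
  expect_lt(max(abs(out_d$eye$y_px - eye$y_px)), 1)

  # translation-only distortion: residual error below the jitter scale
  set.seed(12)
  eye_t <- make_glued_eye(sched, jitter = 3)
  eye_t$x_px <- eye_t$x_px + 25
  eye_t$y_px <- eye_t$y_px - 40
  out_t <- recalibrate_gaze(eye_t, sched)
  ref <- make_glued_eye(sched)
  on_stim <- rep(FALSE, nrow(ref))
  for (i in seq_len(nrow(sched)))
    on_stim <- on_stim | (ref$time_s >= sched$onset_time[i] + 0.3 &
                          ref$time_s <= sched$onset_time[i] + 1)
  expect_lt(median(abs(out_t$eye$x_px[on_stim] - ref$x_px[on_stim])), 3)
})

test_that("fixation features count on-stimulus valid samples", {
  cfg <- experiment_config()
  sched <- generate_schedule(cfg, "high", seed = 92, n_trials = 1)
  eye <- make_glued_eye(sched)
  # gaze remains glued for 2 s windows that stay within the trial; take
  # event 1 and extend its dwell artificially
  centers <- stimulus_centers(cfg, screen_geometry())
  ci <- which(centers$row == sched$row[1] & centers$col == sched$col[1])
  sel <- eye$time_s >= sched$onset_time[1] &
    eye$time_s < sched$onset_time[1] + 2
  eye$x_px[sel] <- centers$x_px[ci]
  eye$y_px[sel] <- centers$y_px[ci]
  f <- fixation_features(eye, sched, eye_fs = 60)
  expect_equal(f$fixation_duration_ms[1], 2000, tolerance = 20)
  expect_equal(f$pupil_mm[1], 4.5)
  expect_equal(f$valid_fraction[1], 1)

  # arrival 500 ms after onset: duration 1500 ms within one sample
  eye2 <- eye
  late <- eye2$time_s >= sched$onset_time[2] &
    eye2$time_s < sched$onset_time[2] + 0.5
  eye2$x_px[late] <- 0; eye2$y_px[late] <- 0
  ci2 <- which(centers$row == sched$row[2] & centers$col == sched$col[2])
  rest <- eye2$time_s >= sched$onset_time[2] + 0.5 &
    eye2$time_s < sched$onset_time[2] + 2
  eye2$x_px[rest] <- centers$x_px[ci2]; eye2$y_px[rest] <- centers$y_px[ci2]
  f2 <- fixation_features(eye2, sched, eye_fs = 60)
  expect_equal(f2$fixation_duration_ms[2], 1500, tolerance = 2 * 1000 / 60)

  # all samples invalid in a window: feature missing, not zero
  eye3 <- eye
  win3 <- eye3$time_s >= sched$onset_time[3] &
    eye3$time_s < sched$onset_time[3] + 2
  eye3$valid[win3] <- FALSE
  f3 <- fixation_features(eye3, sched, eye_fs = 60)
  expect_true(is.na(f3$fixation_duration_ms[3]))
  expect_true(is.na(f3$pupil_mm[3]))
})

test_that("duration is monotone in the radius and linear in pupil scaling", {
  fx <- shared_session()
  sched <- structure(fx$recording$events,
                     class = c("srp_schedule", "data.frame"),
                     config = fx$recording$config, load_condition = "high")
  eye <- fx$recording$eye
  f_tight <- fixation_features(eye, sched, eye_fs = 60, radius_px = 80)
  f_wide <- fixation_features(eye, sched, eye_fs = 60, radius_px = 150)
  ok <- !is.na(f_tight$fixation_duration_ms) &
    !is.na(f_wide$fixation_duration_ms)
  expect_true(all(f_tight$fixation_duration_ms[ok] <=
                  f_wide$fixation_duration_ms[ok]))
  # pupil scaling linearity
  eye_s <- eye; eye_s$pupil_mm <- eye$pupil_mm * 2
  f1 <- fixation_features(eye, sched, eye_fs = 60)
  f2 <- fixation_features(eye_s, sched, eye_fs = 60)
  ok2 <- !is.na(f1$pupil_mm)
  expect_equal(f2$pupil_mm[ok2], 2 * f1$pupil_mm[ok2], tolerance = 1e-12)
})
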