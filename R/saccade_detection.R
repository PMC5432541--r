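# EOG-velocity saccade detection and direction-matched selection of the
# stimulus-to-stimulus saccade of interest per highlight event.

#' Find candidate saccades in a velocity trace
#'
#' Contiguous runs where `|v|` exceeds `k` times the trace's global SD are
#' candidate saccades; runs separated by less than `merge_ms` are merged.
#' Each run contributes one candidate at its sample of maximum magnitude.
#'
#' @param velocity velocity trace (finite).
#' @param fs Hz.
#' @param k SD multiplier (default 4).
#' @param merge_ms merging gap, ms.
#' @return data.frame with `peak_time` (s, sample times start at 0),
#'   `peak_velocity` (signed) and `sign`.
#' @export
find_candidate_saccades <- function(velocity, fs, k = 4, merge_ms = 20) {
  stopifnot(all(is.finite(velocity)), k > 0)
  thr <- k * sd(velocity)
  flag <- abs(velocity) > thr
  if (!any(flag))
    return(data.frame(peak_time = numeric(0), peak_velocity = numeric(0),
                      sign = numeric(0)))
  iv <- .merge_intervals(.runs_of(flag), round(merge_ms / 1000 * fs))
  peaks <- apply(iv, 1, function(r) {
    idx <- r[1]:r[2]
    idx[which.max(abs(velocity[idx]))]
  })
  data.frame(peak_time = (peaks - 1) / fs,
             peak_velocity = velocity[peaks],
             sign = sign(velocity[peaks]))
}

#' Select the saccade of interest for one stimulus event
#'
#' Among candidates with latency inside the window (default 100-800 ms,
#' endpoints inclusive) after the highlight onset, the first horizontal
#' candidate whose sign matches the horizontal direction of the
#' stimulus-to-stimulus transition is selected. If the transition has no
#' horizontal component, or no matching horizontal candidate exists, the
#' first vertical candidate matching the vertical direction is used.
#' Returns `NULL` when no candidate matches (a valid outcome whose
#' frequency is reported upstream).
#'
#' Directions are in screen coordinates: positive HEOG for rightward gaze
#' (increasing x), positive VEOG for upward gaze (decreasing screen y).
#'
#' @param candidates_h,candidates_v [find_candidate_saccades()] outputs for
#'   the horizontal and vertical velocity traces (time-sorted).
#' @param onset_time highlight onset, s.
#' @param prev_xy,curr_xy previous and current gaze-target positions in
#'   screen pixels (the previous stimulus centre, or the screen centre for
#'   the first highlight of a trial).
#' @param window latency window in seconds.
#' @return list with `peak_time`, `latency_ms`, `channel` (`"H"`/`"V"`),
#'   `sign`, or `NULL`.
#' @export
select_saccade_of_interest <- function(candidates_h, candidates_v,
                                       onset_time, prev_xy, curr_xy,
                                       window = c(0.1, 0.8)) {
  dx <- curr_xy[1] - prev_xy[1]
  dy_up <- prev_xy[2] - curr_xy[2]       # screen y grows downward
  pick <- function(cand, want_sign) {
    if (nrow(cand) == 0 || want_sign == 0) return(NULL)
    lat <- cand$peak_time - onset_time
    ok <- lat >= window[1] - 1e-9 & lat <= window[2] + 1e-9 &
      cand$sign == want_sign
    if (!any(ok)) return(NULL)
    i <- which(ok)[1]
    list(peak_time = cand$peak_time[i], latency_ms = lat[i] * 1000,
         sign = cand$sign[i])
  }
  if (dx != 0) {
    h <- pick(candidates_h, sign(dx))
    if (!is.null(h)) return(c(h, channel = "H"))
  }
  v <- pick(candidates_v, sign(dy_up))
  if (!is.null(v)) return(c(v, channel = "V"))
  NULL
}

#' Detect saccades of interest for a whole session
#'
#' Runs [find_candidate_saccades()] on the cleaned EOG velocity traces and
#' [select_saccade_of_interest()] for every stimulus event. The previous
#' position for the first highlight of each trial is the screen centre
#' (gaze rests there between trials).
#'
#' @param cleaned a [clean_eog()] result.
#' @param schedule the session's `srp_schedule`.
#' @param geometry a [screen_geometry()].
#' @param params a [pipeline_params()].
#' @return data.frame with one row per event: `event`, `trial_id`,
#'   `serial_position`, `onset_time`, `matched`, `peak_time`, `latency_ms`,
#'   `channel`, `sign`. The unmatched fraction is attached as attribute
#'   `unmatched_fraction`.
#' @export
detect_saccades_of_interest <- function(cleaned, schedule,
                                        geometry = screen_geometry(),
                                        params = pipeline_params()) {
  stopifnot(inherits(cleaned, "srp_clean_eog"))
  cfg <- attr(schedule, "config")
  cand_h <- find_candidate_saccades(cleaned$vel_h, cleaned$fs,
                                    params$candidate_k,
                                    params$candidate_merge_ms)
  cand_v <- find_candidate_saccades(cleaned$vel_v, cleaned$fs,
                                    params$candidate_k,
                                    params$candidate_merge_ms)
  centers <- stimulus_centers(cfg, geometry)
  cx <- geometry$width_px / 2; cy <- geometry$height_px / 2
  n_ev <- nrow(schedule)
  out <- data.frame(event = seq_len(n_ev),
                    trial_id = schedule$trial_id,
                    serial_position = schedule$serial_position,
                    onset_time = schedule$onset_time,
                    matched = FALSE, peak_time = NA_real_,
                    latency_ms = NA_real_, channel = NA_character_,
                    sign = NA_real_)
  loc_xy <- function(i) {
    ci <- which(centers$row == schedule$row[i] &
                centers$col == schedule$col[i])
    c(centers$x_px[ci], centers$y_px[ci])
  }
  for (i in seq_len(n_ev)) {
    prev <- if (schedule$serial_position[i] == 1L) c(cx, cy) else
      loc_xy(i - 1L)
    sel <- select_saccade_of_interest(cand_h, cand_v,
                                      schedule$onset_time[i],
                                      prev, loc_xy(i),
                                      params$saccade_window)
    if (!is.null(sel)) {
      out$matched[i] <- TRUE
      out$peak_time[i] <- sel$peak_time
      out$latency_ms[i] <- sel$latency_ms
      out$channel[i] <- sel$channel
      out$sign[i] <- sel$sign
    }
  }
  attr(out, "unmatched_fraction") <- mean(!out$matched)
  out
}

#' Condition-wise saccade-latency table
#'
#' Mean and SD of the saccade-of-interest latency per condition (target,
#' non-target, hit, miss; targets are hits plus misses). With multiple
#' participants, per-participant statistics are computed first and the
#' group table averages the participant means.
#'
#' @param saccades a [detect_saccades_of_interest()] result (or several
#'   row-bound ones) with a `participant` column when grouping; must carry
#'   `latency_ms` and `matched`.
#' @param labels character vector per event: `nontarget`, `hit`, `miss`.
#' @return data.frame `condition`, `mean_ms`, `sd_ms`, `n`; conditions with
#'   zero observations are reported with `NA` means and `n = 0`.
#' @export
compute_saccade_latencies <- function(saccades, labels) {
  stopifnot(nrow(saccades) == length(labels))
  lat <- saccades$latency_ms[saccades$matched]
  lab <- labels[saccades$matched]
  groups <- list(target = lat[lab %in% c("hit", "miss")],
                 nontarget = lat[lab == "nontarget"],
                 hit = lat[lab == "hit"],
                 miss = lat[lab == "miss"])
  do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(condition = g,
               mean_ms = if (length(x)) mean(x) else NA_real_,
               sd_ms = if (length(x) > 1) sd(x) else NA_real_,
               n = length(x))
  }))
}
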