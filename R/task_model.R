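#' Adjacency predicate for consecutive highlight locations
#'
#' Two successively highlighted locations are never further apart than two
#' steps horizontally combined with one vertically, or two vertically
#' combined with one horizontally.
#'
#' @param sequence a 2-column matrix or data.frame of 0-based (row, col)
#'   grid locations in presentation order.
#' @param n_rows,n_cols grid dimensions (coordinates outside the grid are
#'   rejected).
#' @return `TRUE` iff every consecutive pair satisfies the constraint.
#' @examples
#' validate_adjacency(rbind(c(0, 0), c(1, 2)))  # TRUE
#' validate_adjacency(rbind(c(0, 0), c(2, 2)))  # FALSE
#' @export
validate_adjacency <- function(sequence, n_rows = 3L, n_cols = 5L) {
  m <- as.matrix(sequence)
  if (ncol(m) != 2) stop("sequence must have two columns (row, col)")
  storage.mode(m) <- "double"
  if (any(m != floor(m)) || any(m[, 1] < 0) || any(m[, 1] >= n_rows) ||
      any(m[, 2] < 0) || any(m[, 2] >= n_cols))
    stop("locations must be 0-based integer grid coordinates")
  if (nrow(m) < 2) return(TRUE)
  dr <- abs(diff(m[, 1])); dc <- abs(diff(m[, 2]))
  all((dc <= 2 & dr <= 1) | (dr <= 2 & dc <= 1))
}

.adjacency_ok <- function(r1, c1, r2, c2) {
  dr <- abs(r1 - r2); dc <- abs(c1 - c2)
  (dc <= 2 & dr <= 1) | (dr <= 2 & dc <= 1)
}

# One random highlight order: greedy random walk over unvisited locations,
# restarting on dead ends.
.sample_trial_order <- function(config, max_attempts = 1000L) {
  grid <- expand.grid(row = seq_len(config$n_rows) - 1L,
                      col = seq_len(config$n_cols) - 1L)
  n <- nrow(grid)
  for (attempt in seq_len(max_attempts)) {
    order <- integer(n)
    order[1] <- sample.int(n, 1L)
    visited <- logical(n); visited[order[1]] <- TRUE
    ok <- TRUE
    for (k in 2:n) {
      cur <- order[k - 1L]
      cand <- which(!visited &
                    .adjacency_ok(grid$row[cur], grid$col[cur],
                                  grid$row, grid$col))
      if (length(cand) == 0L) { ok <- FALSE; break }
      nxt <- cand[sample.int(length(cand), 1L)]
      order[k] <- nxt; visited[nxt] <- TRUE
    }
    if (ok) return(grid[order, , drop = FALSE])
  }
  stop("no valid highlight order found after ", max_attempts, " attempts; ",
       "the adjacency constraint admits no permutation for this grid")
}

#' Generate a trial schedule for one load condition
#'
#' Each trial highlights every grid location exactly once, in a random order
#' constrained so consecutive locations satisfy [validate_adjacency()]. The
#' number of targets per trial is drawn uniformly from
#' `config$n_targets_choices` and target locations are uniform without
#' replacement.
#'
#' @param config an [experiment_config()].
#' @param load_condition `"low"` or `"high"`.
#' @param seed integer seed; the schedule is reproducible bit-for-bit.
#' @param n_trials number of trials (default: blocks x trials per block).
#' @return data.frame of class `srp_schedule` with one row per stimulus
#'   event: `trial_id`, `block`, `serial_position` (1-based), `row`, `col`
#'   (0-based), `onset_time` (s from session start), `is_target`. The load
#'   condition and config are attached as attributes.
#' @export
generate_schedule <- function(config = experiment_config(),
                              load_condition = c("high", "low"),
                              seed = 1L,
                              n_trials = config$n_blocks_per_load *
                                config$n_trials_per_block) {
  load_condition <- match.arg(load_condition)
  stopifnot(n_trials >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  n_pos <- config$n_positions_per_trial
  trial_len <- n_pos * config$highlight_duration + config$intertrial_gap
  rows <- vector("list", n_trials)
  for (t in seq_len(n_trials)) {
    locs <- .sample_trial_order(config)
    n_targ <- config$n_targets_choices[
      sample.int(length(config$n_targets_choices), 1L)]
    targ_pos <- sample.int(n_pos, n_targ)
    t0 <- config$session_start_pad + (t - 1) * trial_len
    rows[[t]] <- data.frame(
      trial_id = t,
      block = ((t - 1L) %/% config$n_trials_per_block) + 1L,
      serial_position = seq_len(n_pos),
      row = locs$row, col = locs$col,
      onset_time = t0 + (seq_len(n_pos) - 1) * config$highlight_duration,
      is_target = seq_len(n_pos) %in% targ_pos
    )
  }
  sched <- do.call(rbind, rows)
  rownames(sched) <- NULL
  structure(sched, class = c("srp_schedule", "data.frame"),
            load_condition = load_condition, config = config, seed = seed)
}

#' Simulate report behavior for a schedule
#'
#' Applies the stochastic miss model of [behavior_params()]: each target is
#' missed with probability `base_miss_prob(load) * curve[serial_position]`;
#' each miss spawns, with probability `false_alarm_prob_per_miss`, a false
#' alarm at a uniformly random location that held no target in that trial.
#'
#' @param schedule an [generate_schedule()] output.
#' @param load `"low"` or `"high"` (defaults to the schedule's own).
#' @param params a [behavior_params()].
#' @param seed integer seed.
#' @return list of class `srp_behavior` with `events` (the schedule plus
#'   `hit` — `NA` for non-targets — and a `label` in
#'   `nontarget`/`hit`/`miss`), `false_alarms` (trial_id, row, col) and
#'   `reported` (all clicked locations per trial).
#' @export
simulate_behavior <- function(schedule, load = NULL,
                              params = behavior_params(), seed = 1L) {
  stopifnot(inherits(schedule, "srp_schedule"))
  if (is.null(load)) load <- attr(schedule, "load_condition")
  load <- match.arg(load, c("low", "high"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  base <- if (load == "high") params$base_miss_prob_high else
    params$base_miss_prob_low
  curve <- params$serial_position_curve
  ev <- as.data.frame(schedule)
  ev$hit <- NA
  p_miss <- pmin(pmax(base * curve[ev$serial_position], 0), 1)
  is_t <- ev$is_target
  ev$hit[is_t] <- runif(sum(is_t)) >= p_miss[is_t]
  ev$label <- ifelse(!is_t, "nontarget", ifelse(ev$hit, "hit", "miss"))

  fa <- list(); rep_rows <- list()
  for (t in unique(ev$trial_id)) {
    tr <- ev[ev$trial_id == t, ]
    hits <- tr[tr$is_target & tr$hit %in% TRUE, c("row", "col")]
    n_miss <- sum(tr$label == "miss")
    fa_t <- NULL
    if (n_miss > 0 && params$false_alarm_prob_per_miss > 0) {
      n_fa <- sum(runif(n_miss) < params$false_alarm_prob_per_miss)
      if (n_fa > 0) {
        nt <- tr[!tr$is_target, c("row", "col")]
        pick <- sample.int(nrow(nt), min(n_fa, nrow(nt)))
        fa_t <- cbind(trial_id = t, nt[pick, , drop = FALSE])
        fa[[length(fa) + 1L]] <- fa_t
      }
    }
    rep_t <- rbind(if (nrow(hits)) cbind(trial_id = t, hits),
                   fa_t)
    if (!is.null(rep_t)) rep_rows[[length(rep_rows) + 1L]] <- rep_t
  }
  false_alarms <- if (length(fa)) do.call(rbind, fa) else
    data.frame(trial_id = integer(0), row = integer(0), col = integer(0))
  reported <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(trial_id = integer(0), row = integer(0), col = integer(0))
  rownames(false_alarms) <- rownames(reported) <- NULL
  structure(list(events = ev, false_alarms = false_alarms,
                 reported = reported, load = load, seed = seed),
            class = "srp_behavior")
}

#' Math-task number onsets for one trial
#'
#' @param config an [experiment_config()].
#' @return numeric vector of onsets (s from trial start):
#'   `math_first_onset + k * math_interval`, k = 0 .. n-1. With defaults the
#'   sixth number lands at 14.3 s.
#' @export
math_task_schedule <- function(config = experiment_config()) {
  config$math_first_onset +
    (seq_len(config$math_n_numbers) - 1) * config$math_interval
}

#' Behavioral summary of a simulated (or scored) session
#'
#' @param schedule an `srp_schedule`.
#' @param behavior the matching [simulate_behavior()] output.
#' @return list with `hit_rate` (overall), `hit_rate_by_block`,
#'   `hit_rate_by_position` (per serial position), `n_targets`, `n_hits`,
#'   `n_misses`, `n_false_alarms` and `under_report`
#'   (targets presented minus locations reported; can be negative).
#' @export
behavioral_metrics <- function(schedule, behavior) {
  stopifnot(inherits(behavior, "srp_behavior"))
  ev <- behavior$events
  if (nrow(ev) == 0) stop("empty schedule")
  tg <- ev[ev$is_target, ]
  if (nrow(tg) == 0) stop("schedule contains no targets")
  by_block <- tapply(tg$hit, tg$block, mean)
  by_pos <- tapply(tg$hit, factor(tg$serial_position,
                                  levels = sort(unique(ev$serial_position))),
                   mean)
  list(
    hit_rate = mean(tg$hit),
    hit_rate_by_block = by_block,
    hit_rate_by_position = by_pos,
    n_targets = nrow(tg),
    n_hits = sum(tg$hit),
    n_misses = sum(!tg$hit),
    n_false_alarms = nrow(behavior$false_alarms),
    under_report = nrow(tg) - nrow(behavior$reported)
  )
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
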