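# Task structure: adjacency-constrained highlight orders, target
# assignment, behavioral miss model, math-task timing.

test_that("adjacency predicate matches brute-force enumeration", {
  expect_true(validate_adjacency(rbind(c(0, 0), c(1, 2))))
  expect_true(validate_adjacency(rbind(c(0, 0), c(0, 0))))
  expect_false(validate_adjacency(rbind(c(0, 0), c(2, 2))))
  expect_error(validate_adjacency(rbind(c(0, 0), c(3, 0))), "grid")
  # brute force over all location pairs
  grid <- expand.grid(r = 0:2, c = 0:4)
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    dr <- abs(grid$r[i] - grid$r[j]); dc <- abs(grid$c[i] - grid$c[j])
    expect_identical(
      validate_adjacency(rbind(c(grid$r[i], grid$c[i]),
                               c(grid$r[j], grid$c[j]))),
      (dc <= 2 && dr <= 1) || (dr <= 2 && dc <= 1))
  }
})

test_that("generated schedules are valid permutations obeying adjacency", {
  cfg <- experiment_config()
  for (seed in 1:5) {
    sched <- generate_schedule(cfg, "high", seed = seed, n_trials = 6)
    for (t in unique(sched$trial_id)) {
      tr <- sched[sched$trial_id == t, ]
      # every location exactly once
      expect_equal(nrow(unique(tr[, c("row", "col")])), 15)
      expect_true(validate_adjacency(as.matrix(tr[, c("row", "col")])))
      # onsets strictly increasing with highlight spacing
      expect_equal(diff(tr$onset_time),
                   rep(cfg$highlight_duration, 14))
    }
    expect_true(all(sched$serial_position %in% 1:15))
  }
  # determinism
  a <- generate_schedule(cfg, "high", seed = 9, n_trials = 4)
  b <- generate_schedule(cfg, "high", seed = 9, n_trials = 4)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("per-trial target counts are uniform over {2,3,4}", {
  cfg <- experiment_config()
  sched <- generate_schedule(cfg, "high", seed = 77, n_trials = 1500)
  counts <- tapply(sched$is_target, sched$trial_id, sum)
  tab <- table(factor(counts, levels = 2:4))
  expect_equal(sum(tab), 1500)
  # chi-square against the uniform multinomial
  expect_gt(stats::chisq.test(tab, p = rep(1 / 3, 3))$p.value, 1e-3)
})

test_that("miss model reproduces configured rates and serial-position curve", {
  # base miss probability zero: every target hit, no false alarms
  sched <- make_flat_schedule(20)
  bp0 <- behavior_params(base_miss_prob_low = 0, base_miss_prob_high = 0)
  beh0 <- simulate_behavior(sched, "high", bp0, seed = 1)
  expect_true(all(beh0$events$hit[beh0$events$is_target]))
  expect_equal(nrow(beh0$false_alarms), 0)

  # default high-load parameters: hit rate within 0.02 of 0.73 over >=5000
  # targets (target serial positions cover the curve uniformly here)
  sched_u <- make_flat_schedule(400, target_positions = c(1, 6, 11))
  sched_u2 <- make_flat_schedule(400, target_positions = c(2, 7, 12))
  sched_u3 <- make_flat_schedule(400, target_positions = c(3, 8, 13))
  sched_u4 <- make_flat_schedule(400, target_positions = c(4, 9, 14))
  sched_u5 <- make_flat_schedule(400, target_positions = c(5, 10, 15))
  hits <- unlist(lapply(list(sched_u, sched_u2, sched_u3, sched_u4,
                             sched_u5), function(s) {
    b <- simulate_behavior(s, "high", behavior_params(), seed = nrow(s))
    b$events$hit[b$events$is_target]
  }))
  expect_gte(length(hits), 5000)
  expect_lt(abs(mean(hits) - 0.73), 0.02)

  # flat curve: per-position hit rates equal within sampling error
  bp_flat <- behavior_params(serial_position_curve = rep(1, 15))
  beh_f <- simulate_behavior(make_flat_schedule(660), "high", bp_flat,
                             seed = 5)
  tg <- beh_f$events[beh_f$events$is_target, ]
  tab <- table(tg$serial_position, tg$hit)
  expect_gt(stats::chisq.test(tab)$p.value, 1e-3)
})

test_that("behavioral metrics aggregate hand-computable counts", {
  sched <- make_flat_schedule(1)
  beh <- simulate_behavior(sched, "high",
                           behavior_params(base_miss_prob_high = 0),
                           seed = 1)
  # doctor one miss + one false alarm by hand
  beh$events$hit[beh$events$serial_position == 3] <- FALSE
  beh$events$label[beh$events$serial_position == 3] <- "miss"
  beh$false_alarms <- data.frame(trial_id = 1, row = 0, col = 1)
  beh$reported <- rbind(
    beh$events[beh$events$is_target & beh$events$hit %in% TRUE,
               c("trial_id", "row", "col")],
    beh$false_alarms)
  m <- behavioral_metrics(sched, beh)
  expect_equal(m$hit_rate, 2 / 3)
  expect_equal(m$n_false_alarms, 1)
  expect_equal(m$under_report, 0)

  # per-block hit rates weighted by block target counts equal the overall
  sched20 <- make_flat_schedule(20)
  beh20 <- simulate_behavior(sched20, "high", behavior_params(), seed = 2)
  m20 <- behavioral_metrics(sched20, beh20)
  tg <- beh20$events[beh20$events$is_target, ]
  w <- as.numeric(table(tg$block))
  expect_equal(sum(m20$hit_rate_by_block * w) / sum(w), m20$hit_rate)
})

test_that("math-task onsets follow the fixed spacing", {
  cfg <- experiment_config()
  onsets <- math_task_schedule(cfg)
  expect_equal(onsets[1], 1.0)
  expect_equal(onsets[6], 14.3)
  expect_equal(length(onsets), 6)
  one <- math_task_schedule(experiment_config(math_n_numbers = 1))
  expect_equal(one, cfg$math_first_onset)
})
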