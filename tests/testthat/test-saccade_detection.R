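# Candidate detection, direction-matched selection, latency tables.

test_that("candidate detection thresholds, merges and localizes runs", {
  expect_equal(nrow(find_candidate_saccades(numeric(1000), 256)), 0)

  # two supra-threshold runs 10 ms apart merge into one candidate
  set.seed(4)
  v <- rnorm(2000, 0, 0.1)
  thr <- 4 * sd(v)   # approximate; bumps below raise it slightly
  v[1000:1003] <- 10
  v[1006:1009] <- 8   # 10 ms gap at 256 Hz is ~2.5 samples
  out <- find_candidate_saccades(v, 256, k = 4, merge_ms = 20)
  expect_equal(nrow(out), 1)
  expect_equal(out$peak_time, (1000 - 1) / 256)
  expect_equal(out$sign, 1)

  # two runs far apart stay separate
  v2 <- numeric(4000)
  v2[1000] <- 5; v2[3000] <- -5
  out2 <- find_candidate_saccades(v2, 256, k = 4)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$sign, c(1, -1))
})

test_that("saccade-of-interest selection follows the H-then-V sign rule", {
  mk <- function(times, signs)
    data.frame(peak_time = times, peak_velocity = signs * 5, sign = signs)
  onset <- 10
  right <- c(300, 100)   # current stimulus right of previous
  left0 <- c(100, 100)
  # single H candidate with correct sign
  sel <- select_saccade_of_interest(mk(10.2, 1), mk(numeric(0), numeric(0)),
                                    onset, left0, right)
  expect_equal(sel$channel, "H")
  expect_equal(sel$latency_ms, 200)
  # wrong-sign H at 150 ms, correct V at 300 ms, vertical component present
  below <- c(300, 300)   # down-right: H sign +1, V sign -1 (screen y down)
  sel2 <- select_saccade_of_interest(mk(10.15, -1), mk(10.3, -1),
                                     onset, left0, below)
  expect_equal(sel2$channel, "V")
  expect_equal(sel2$latency_ms, 300)
  # window endpoints inclusive
  sel3 <- select_saccade_of_interest(mk(10.8, 1), mk(numeric(0), numeric(0)),
                                     onset, left0, right)
  expect_equal(sel3$latency_ms, 800)
  sel4 <- select_saccade_of_interest(mk(10.85, 1), mk(numeric(0), numeric(0)),
                                     onset, left0, right)
  expect_null(sel4)
  # purely vertical transition skips H entirely
  up <- c(100, 50)
  sel5 <- select_saccade_of_interest(mk(10.2, 1), mk(10.4, 1),
                                     onset, left0, up)
  expect_equal(sel5$channel, "V")
  # earliest matching candidate wins
  sel6 <- select_saccade_of_interest(mk(c(10.2, 10.4), c(1, 1)),
                                     mk(numeric(0), numeric(0)),
                                     onset, left0, right)
  expect_equal(sel6$latency_ms, 200)
})

test_that("selected saccades satisfy the window and sign invariants", {
  fx <- shared_session()
  sac <- fx$session$saccades
  m <- sac[sac$matched, ]
  expect_true(all(m$latency_ms >= 100 & m$latency_ms <= 800))
  expect_true(all(m$channel %in% c("H", "V")))
  expect_true(all(m$sign %in% c(-1, 1)))
  expect_lte(attr(sac, "unmatched_fraction"), 0.15)
})

test_that("latency table computes per-condition means and SDs", {
  sac <- data.frame(matched = rep(TRUE, 5),
                    latency_ms = c(200, 200, 200, 200, 200))
  lt <- compute_saccade_latencies(sac, rep("nontarget", 5))
  row <- lt[lt$condition == "nontarget", ]
  expect_equal(row$mean_ms, 200)
  expect_equal(row$sd_ms, 0)
  expect_equal(row$n, 5)
  # hand-computed 5-value example across conditions
  sac2 <- data.frame(matched = c(TRUE, TRUE, TRUE, TRUE, FALSE),
                     latency_ms = c(150, 250, 300, 500, 999))
  lab2 <- c("hit", "hit", "miss", "nontarget", "nontarget")
  lt2 <- compute_saccade_latencies(sac2, lab2)
  expect_equal(lt2$mean_ms[lt2$condition == "hit"], 200)
  expect_equal(lt2$sd_ms[lt2$condition == "hit"], sd(c(150, 250)))
  expect_equal(lt2$mean_ms[lt2$condition == "target"], mean(c(150, 250, 300)))
  expect_equal(lt2$n[lt2$condition == "nontarget"], 1)
  # empty condition flagged missing, not zero
  lt3 <- compute_saccade_latencies(sac, rep("hit", 5))
  expect_true(is.na(lt3$mean_ms[lt3$condition == "miss"]))
  expect_equal(lt3$n[lt3$condition == "miss"], 0)
})

test_that("detection degrades monotonically with EOG noise", {
  cfg <- experiment_config()
  unmatched <- vapply(c(5, 60, 150), function(noise) {
    u <- vapply(1:2, function(s) {
      sched <- generate_schedule(cfg, "high", seed = 60 + s, n_trials = 3)
      beh <- simulate_behavior(sched, params = behavior_params(),
                               seed = 70 + s)
      rec <- synthesize_recording(sched, beh,
                                  signal_params(eog_noise_sd = noise),
                                  seed = 80 + s)
      ses <- process_session(rec)
      ses$unmatched_fraction
    }, 0)
    mean(u)
  }, 0)
  expect_true(all(diff(unmatched) >= -0.02))
  expect_gt(unmatched[3], unmatched[1])
})
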