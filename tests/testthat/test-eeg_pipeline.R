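# EEG conditioning chain and epoch extraction.

make_rec <- function(eeg, fs = 512, channels = rownames(eeg)) {
  structure(list(eeg = eeg, channels = channels, fs = fs,
                 heog = eeg[1, ], veog = eeg[1, ], eye = NULL, eye_fs = 60,
                 events = NULL, truth = NULL, load = "high", config = NULL,
                 geometry = screen_geometry(), params = NULL,
                 duration_s = ncol(eeg) / fs),
            class = "srp_recording")
}

test_that("resampling preserves amplitude and rejects upsampling", {
  n <- 512 * 60
  x <- sin(2 * pi * 10 * (0:(n - 1)) / 512)
  rec <- make_rec(matrix(x, 1, n, dimnames = list("Pz", NULL)))
  out <- resample_recording(rec, 256)
  expect_equal(out$fs, 256)
  expect_equal(ncol(out$eeg), ceiling(n / 2))
  mid <- 2000:13000
  expect_lt(abs(max(abs(out$eeg[1, mid])) - 1), 0.01)
  # identity when target equals native rate
  expect_identical(resample_recording(rec, 512)$eeg, rec$eeg)
  expect_error(resample_recording(rec, 1024), "upsampling")
})

test_that("bad channels are flagged against the median SD", {
  set.seed(7)
  n <- 256 * 20
  eeg <- matrix(rnorm(8 * n), 8, n,
                dimnames = list(paste0("C", 1:8), NULL))
  expect_equal(length(detect_bad_channels(eeg, 256)), 0)
  eeg["C5", ] <- eeg["C5", ] * 10
  expect_equal(detect_bad_channels(eeg, 256), "C5")
})

test_that("bad-channel interpolation averages the nearest good channels", {
  mon <- montage_1020()
  n <- 1000
  set.seed(8)
  base <- rnorm(n)
  eeg <- matrix(rep(base, each = nrow(mon)), nrow(mon), n,
                dimnames = list(mon$channel, NULL))
  out <- interpolate_bad_channels(eeg, "Pz", mon)
  # identical neighbours: replacement equals the neighbour signal
  expect_equal(out["Pz", ], base, tolerance = 1e-12)
  # convexity: interpolated values stay within the neighbours' range
  eeg2 <- eeg
  for (i in seq_len(nrow(mon))) eeg2[i, ] <- rnorm(n)
  out2 <- interpolate_bad_channels(eeg2, "Cz", mon)
  good <- eeg2[setdiff(rownames(eeg2), "Cz"), ]
  expect_true(all(out2["Cz", ] <= apply(good, 2, max) + 1e-12))
  expect_true(all(out2["Cz", ] >= apply(good, 2, min) - 1e-12))
  expect_error(interpolate_bad_channels(eeg, mon$channel, mon), "all")
})

test_that("average reference zeroes the good-channel mean", {
  set.seed(9)
  eeg <- matrix(rnorm(5 * 100), 5, 100,
                dimnames = list(paste0("C", 1:5), NULL))
  out <- rereference_average(eeg)
  expect_lt(max(abs(colMeans(out))), 1e-12)
  # two equal channels become zero
  two <- matrix(rep(rnorm(50), each = 2), 2, 50,
                dimnames = list(c("A", "B"), NULL))
  expect_lt(max(abs(rereference_average(two))), 1e-12)
  # hand 3-channel, 2-sample example
  h <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(unname(rereference_average(h)),
               unname(h - rep(colMeans(h), each = 3)))
  # bad channels excluded from the reference
  out_b <- rereference_average(h, bads = "C")
  expect_equal(unname(colMeans(out_b[c("A", "B"), ])), c(0, 0))
})

test_that("bandpass attenuates out-of-band and passes in-band components", {
  fs <- 256; n <- fs * 20
  t <- (0:(n - 1)) / fs
  hi <- sin(2 * pi * 60 * t)
  lo <- sin(2 * pi * 10 * t)
  mid <- 2000:3000
  out_hi <- bandpass_eeg(hi, fs)
  out_lo <- bandpass_eeg(lo, fs)
  expect_lt(max(abs(out_hi[mid])), 10^(-20 / 20))   # >= 20 dB down
  expect_lt(abs(max(abs(out_lo[mid])) - 1), 0.05)
  dc <- bandpass_eeg(rep(5, n), fs)
  expect_lt(abs(mean(dc[mid])), 0.05)
  expect_error(bandpass_eeg(lo, fs, band = c(10, 200)), "band")
})

test_that("epoch extraction windows, baselines and labels correctly", {
  fs <- 256
  n <- fs * 10
  ramp <- seq_len(n) * 0.5
  const <- rep(4, n)
  data <- rbind(R = ramp, K = const)
  sac <- data.frame(matched = c(TRUE, TRUE, TRUE),
                    peak_time = c(2.0, 5.0, 9.9),
                    latency_ms = c(200, 250, 300))
  labels <- data.frame(trial_id = 1:3, serial_position = 1:3,
                       is_target = c(TRUE, FALSE, TRUE),
                       hit = c(TRUE, NA, FALSE),
                       label = c("hit", "nontarget", "miss"))
  expect_warning(ep <- extract_epochs(data, fs, sac, labels), "skipped")
  expect_equal(dim(ep$data), c(2, 2, 256))
  expect_equal(ep$n_skipped, 1)
  # constant channel: all-zero after baseline
  expect_equal(max(abs(ep$data[, "K", ])), 0)
  # ramp channel: ramp minus the mean of its first 25 samples
  i0 <- floor(2.0 * fs) + 1
  seg <- ramp[i0:(i0 + 255)]
  expect_equal(ep$data[1, "R", ], seg - mean(seg[1:25]), tolerance = 1e-12)
  # baseline window mean is exactly zero
  expect_lt(abs(mean(ep$data[1, "R", 1:25])), 1e-9)
  expect_equal(ep$labels$label, c("hit", "nontarget"))
})

test_that("outlier epochs are rejected by the median-SD rule", {
  set.seed(10)
  n_ep <- 8
  arr <- array(rnorm(n_ep * 3 * 256), dim = c(n_ep, 3, 256),
               dimnames = list(NULL, c("A", "B", "C"), NULL))
  ep <- structure(list(data = arr, times = (0:255) / 256,
                       channels = c("A", "B", "C"), fs = 256,
                       labels = data.frame(event = 1:n_ep),
                       rejected = integer(0), n_skipped = 0L),
                  class = "srp_epochs")
  expect_equal(length(reject_outlier_epochs(ep, 50, c("A", "B", "C"))$rejected), 0)
  ep$data[3, , ] <- ep$data[3, , ] * 100
  out <- reject_outlier_epochs(ep, 50, c("A", "B", "C"))
  expect_equal(out$rejected, 3L)
  expect_equal(dim(out$data)[1], n_ep - 1)
  # invariant to channel ordering
  ep_perm <- ep
  ep_perm$data <- ep$data[, c(3, 1, 2), ]
  ep_perm$channels <- c("C", "A", "B")
  out_p <- reject_outlier_epochs(ep_perm, 50, c("C", "A", "B"))
  expect_equal(out_p$rejected, 3L)
})
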