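fs <- 1250

test_that("bandpass keeps the passband and rejects the stopband", {
  t <- seq_len(10 * fs) / fs
  tone150 <- sin(2 * pi * 150 * t)
  out <- bandpass(tone150, 80, 250, fs)
  mid <- seq(fs, 9 * fs)
  expect_lt(abs(sd(out[mid]) / sd(tone150[mid]) - 1), 0.05)
  tone10 <- sin(2 * pi * 10 * t)
  out10 <- bandpass(tone10, 80, 250, fs)
  expect_lt(20 * log10(sd(out10[mid]) / sd(tone10[mid])), -20)
  set.seed(1)
  noise <- rnorm(fs * 5)
  expect_lt(var(bandpass(noise, 80, 250, fs)), var(noise))
  expect_error(bandpass(noise, 80, 700, fs), "fs/2")
})

test_that("a planted high-SNR burst is detected once with its frequency", {
  set.seed(2)
  n <- 60 * fs
  noise_sd <- 10
  x <- rnorm(n, sd = noise_sd)
  tt <- seq(-0.03, 0.03, by = 1 / fs)
  burst <- 8 * noise_sd * exp(-tt^2 / (2 * 0.015^2)) * cos(2 * pi * 150 * tt)
  at <- 30 * fs
  x[at + seq_along(tt)] <- x[at + seq_along(tt)] + burst
  centre_s <- at / fs + 0.03  # burst centre sits mid-window
  ref <- rnorm(n, sd = noise_sd)
  rt <- detect_ripples(x, ref, fs)
  valid <- rt[rt$valid, ]
  expect_equal(nrow(valid), 1L)
  expect_lt(abs(valid$mean_freq_hz - 150), 5)
  expect_lt(abs(valid$peak_time_s - centre_s), 0.01)
  expect_true(valid$onset_s <= valid$peak_time_s)
  expect_true(valid$offset_s >= valid$peak_time_s)
})

test_that("a three-cycle burst is detected but invalidated by the cycle rule", {
  set.seed(3)
  n <- 60 * fs
  x <- rnorm(n, sd = 10)
  # 3 cycles at 150 Hz = 20 ms; narrow envelope clips the cycle count
  tt <- seq(-0.010, 0.010, by = 1 / fs)
  burst <- 120 * exp(-tt^2 / (2 * 0.004^2)) * cos(2 * pi * 150 * tt)
  x[30 * fs + seq_along(tt)] <- x[30 * fs + seq_along(tt)] + burst
  rt <- detect_ripples(x, rnorm(n, sd = 10), fs)
  expect_gte(nrow(rt), 1L)
  hit <- which.min(abs(rt$peak_time_s - 30))
  expect_false(rt$ok_cycles[hit])
  expect_false(rt$valid[hit])
})

test_that("sub-threshold input yields an empty table", {
  set.seed(4)
  rt <- detect_ripples(rnorm(10 * fs), rnorm(10 * fs), fs)
  expect_equal(nrow(rt[rt$valid, ]), 0L)
})

test_that("detected events are non-overlapping and bracket their peaks", {
  sim <- fixture_lfp()
  rec <- sim$recording
  pyr <- round(median(layer_channels(rec$layer_map, "pyramidale")))
  ref <- layer_channels(rec$layer_map, "granule")[1L]
  rt <- detect_ripples(rec$data[pyr, ], rec$data[ref, ], rec$fs_hz)
  v <- rt[rt$valid, ]
  expect_gt(nrow(v), 10L)
  expect_true(all(diff(v$peak_time_s) > 0.02))
  expect_true(all(v$onset_s <= v$peak_time_s & v$peak_time_s <= v$offset_s))
  expect_true(all(v$offset_s[-nrow(v)] <= v$onset_s[-1L]))
  expect_true(all(v$mean_freq_hz > 80))
  expect_true(all(v$n_cycles >= 4))
})

test_that("reference channel selection finds planted ripple content", {
  set.seed(5)
  m <- matrix(rnorm(8 * 30 * fs, sd = 10), nrow = 8)
  tt <- seq(-0.03, 0.03, by = 1 / fs)
  for (at in seq(2, 28, by = 1) * fs) {
    m[5, at + seq_along(tt)] <- m[5, at + seq_along(tt)] +
      100 * exp(-tt^2 / (2 * 0.012^2)) * cos(2 * pi * 150 * tt)
  }
  best <- select_reference_channel(m, fs = fs)
  expect_equal(as.integer(best), 5L)
  scores <- attr(best, "scores")
  expect_true(all(scores > 0 & scores < 1))  # band nesting
  # identical channels tie-break to the lowest index
  m2 <- matrix(rep(rnorm(10 * fs), 3), nrow = 3, byrow = TRUE)
  expect_equal(as.integer(select_reference_channel(m2, fs = fs)), 1L)
})

test_that("theta cycle segmentation counts and validates cycles", {
  t <- seq_len(10 * fs) / fs
  x8 <- sin(2 * pi * 8 * (t - 0.01))
  cyc <- segment_theta_cycles(x8, 0, fs)
  expect_gte(nrow(cyc), 78L)
  expect_lte(nrow(cyc), 80L)
  # 13 Hz: half-period 38 ms, peak-to-peak 77 ms -> retained
  x13 <- sin(2 * pi * 13 * t)
  expect_gt(nrow(segment_theta_cycles(x13, 0, fs)), 0L)
  # 16 Hz: half-period passes but peak-to-peak 62.5 ms < 71 ms -> rejected
  x16 <- sin(2 * pi * 16 * t)
  expect_equal(nrow(segment_theta_cycles(x16, 0, fs)), 0L)
  # 20 Hz: half-period 25 ms -> rejected
  x20 <- sin(2 * pi * 20 * t)
  expect_equal(nrow(segment_theta_cycles(x20, 0, fs)), 0L)
  # 4 Hz: peak-to-peak 250 ms -> rejected
  x4 <- sin(2 * pi * 4 * t)
  expect_equal(nrow(segment_theta_cycles(x4, 0, fs)), 0L)
  # amplitude threshold discards small extrema
  expect_equal(nrow(segment_theta_cycles(0.5 * x8, 1, fs)), 0L)
})

test_that("theta phase follows the control-point convention", {
  t <- seq_len(5 * fs) / fs
  x <- sin(2 * pi * 8 * t)
  cyc <- segment_theta_cycles(x, 0, fs)
  expect_gt(nrow(cyc), 10L)
  # trough maps to pi, peak to 0
  expect_lt(max(abs(theta_phase(cyc, cyc$trough_s) - pi)), 1e-6)
  expect_lt(max(abs(theta_phase(cyc, cyc$peak_s))), 1e-6)
  # midpoint of the peak -> trough span maps to pi/2 for a symmetric cycle
  mid <- (cyc$peak_s[2] + cyc$trough_s[2]) / 2
  expect_lt(abs(theta_phase(cyc, mid) - pi / 2), 0.1)
  # monotone non-decreasing within the cycle's own (non-overlapping) span
  ts <- seq(cyc$zc1_s[3], cyc$zc3_s[3] - 1e-4, length.out = 50)
  ph <- theta_phase(cyc, ts)
  expect_true(all(diff(ph) > -1e-9))
  # outside validated cycles -> NA
  expect_true(is.na(theta_phase(cyc, max(cyc$peak2_s) + 10)))
})

test_that("NREM segmentation recovers planted state boundaries", {
  fs2 <- 250
  mk <- function(dur, theta) {
    n <- dur * fs2
    base <- rnorm(n, sd = 20)
    f <- if (theta) 7 else 1.5
    base + 60 * sin(2 * pi * f * seq_len(n) / fs2)
  }
  set.seed(1)
  lfp <- c(mk(180, FALSE), mk(60, TRUE), mk(150, FALSE), mk(40, TRUE))
  ep <- segment_nrem(lfp, speed = rep(0, 430), fs = fs2)
  expect_setequal(ep$state, c("NREM", "REM"))
  # boundary recovery within 2 s
  nrem <- ep[ep$state == "NREM", ]
  expect_lt(abs(nrem$end_s[1] - 180), 2)
  expect_lt(abs(nrem$start_s[2] - 240), 2)
  # epochs partition time without overlap
  expect_true(all(ep$start_s[-1L] == ep$end_s[-nrow(ep)]))
  # high-theta bout NOT preceded by >= 2 min NREM is not REM
  set.seed(2)
  lfp2 <- c(mk(60, FALSE), mk(60, TRUE), mk(120, FALSE))
  ep2 <- segment_nrem(lfp2, speed = rep(0, 240), fs = fs2)
  expect_false("REM" %in% ep2$state)
})

test_that("isolation predicate flags events within 250 ms", {
  iso <- is_isolated(c(1, 1.2, 2, 3, 3.24))
  expect_equal(iso, c(FALSE, FALSE, TRUE, FALSE, FALSE))
})
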