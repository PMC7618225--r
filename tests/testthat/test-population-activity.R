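test_that("PETH is flat for homogeneous Poisson units and conserves spikes", {
  set.seed(1)
  rate <- 20
  spikes <- data.frame(unit_id = 1L,
                       spike_time_s = sort(runif(rate * 600, 0, 600)))
  events <- seq(10, 590, by = 2)
  p <- compute_peth(spikes, events, smooth_sd_ms = 0)
  expect_true(all(p$rate >= 0))
  se <- sqrt(rate / (length(events) * p$bin_ms / 1000))
  expect_lt(max(abs(p$rate - rate)), 3.5 * se)
  # integral of raw PETH x bin width ~ spikes per event in the window
  expect_lt(abs(sum(p$rate) * p$bin_ms / 1000 - rate * 0.4) / (rate * 0.4), 0.05)
  expect_error(compute_peth(spikes, numeric(0)), "events")
})

test_that("planted in-event rate doubling appears at the peak", {
  set.seed(2)
  events <- seq(10, 990, by = 4)
  base <- sort(runif(5 * 1000, 0, 1000))
  extra <- unlist(lapply(events, function(t0) t0 + runif(rpois(1, 0.25), -0.025, 0.025)))
  spikes <- data.frame(unit_id = 1L, spike_time_s = sort(c(base, extra)))
  p <- compute_peth(spikes, events)
  peak <- peth_peak_rate(p)
  baseline <- mean(p$rate[, abs(p$lags_ms) > 100])
  expect_gt(peak / baseline, 1.6)
  expect_lt(peak / baseline, 2.6)
})

test_that("delta log rate is the base-10 ratio with zero-baseline exclusion", {
  expect_equal(delta_log_rate(5, 5), 0)
  expect_equal(delta_log_rate(50, 5), 1)
  expect_message(out <- delta_log_rate(c(1, 2), c(1, 0)), "zero baseline")
  expect_true(is.na(out[2]))
})

test_that("phase coupling matches circular statistics", {
  pc <- ripple_phase_coupling(rep(pi / 2, 100))
  expect_lt(abs(pc$preferred_phase - pi / 2), 0.14)  # bin-centre resolution
  expect_gt(pc$coherence, 0.99)
  set.seed(3)
  pc_u <- ripple_phase_coupling(runif(20000, 0, 2 * pi))
  expect_lt(pc_u$coherence, 0.05)
  # von Mises kappa = 2: coherence ~ I1(2)/I0(2) = 0.698
  vm <- function(n, mu, k) {
    # rejection sampling against the wrapped uniform envelope
    out <- numeric(0)
    while (length(out) < n) {
      x <- runif(2 * n, 0, 2 * pi)
      keep <- runif(2 * n) < exp(k * (cos(x - mu) - 1))
      out <- c(out, x[keep])
    }
    out[seq_len(n)]
  }
  pc_v <- ripple_phase_coupling(vm(20000, pi, 2))
  expect_lt(abs(pc_v$coherence - besselI(2, 1) / besselI(2, 0)), 0.05)
  expect_true(is.na(ripple_phase_coupling(numeric(0))$coherence))
})

test_that("interneuron-to-principal ratio is a log10 mean ratio", {
  expect_equal(int_to_pyr_ratio(c(4, 6), c(4, 6)), 0)
  expect_equal(int_to_pyr_ratio(c(10, 10), c(5, 5)), log10(2))
  expect_true(is.na(int_to_pyr_ratio(c(0, 0), c(1, 2))))
})

test_that("margin-preserving shuffle conserves margins exactly", {
  set.seed(4)
  for (i in 1:250) {
    m <- matrix(rpois(12 * 30, runif(1, 0.2, 3)), 12, 30)
    s <- margin_preserving_shuffle(m)
    expect_identical(rowSums(s), rowSums(m))
    expect_identical(colSums(s), colSums(m))
  }
  # 2x2 identity: only the two margin-consistent tables are reachable
  seen <- replicate(50, margin_preserving_shuffle(diag(1L, 2)), simplify = FALSE)
  ok <- vapply(seen, function(s) {
    identical(s, diag(1L, 2)) || identical(s, matrix(c(0L, 1L, 1L, 0L), 2))
  }, logical(1))
  expect_true(all(ok))
})

test_that("margin shuffle destroys planted pairwise correlation", {
  set.seed(5)
  n_e <- 400
  on <- rbinom(n_e, 1, 0.5)
  a <- rpois(n_e, 0.5 + 2 * on)
  b <- rpois(n_e, 0.5 + 2 * on)
  m <- rbind(a, b, matrix(rpois(8 * n_e, 1), 8))
  r_true <- cor(m[1, ], m[2, ])
  expect_gt(r_true, 0.3)
  r_sh <- replicate(200, {
    s <- margin_preserving_shuffle(m)
    cor(s[1, ], s[2, ])
  })
  # correlation collapses to the rate-coupling floor, far below planted
  expect_lt(mean(r_sh) + 3 * sd(r_sh) / sqrt(200), r_true / 2)
})

test_that("confusion-table MI is 1 bit for perfect balanced predictions", {
  expect_equal(confusion_mi(matrix(c(50, 0, 0, 50), 2)), 1)
  expect_equal(confusion_mi(matrix(c(25, 25, 25, 25), 2)), 0)
})

test_that("population-vector decoding beats its coactivity-shuffled control", {
  pv <- fixture_pvs()
  counts <- cbind(pv$lm, pv$rad)
  labels <- rep(c("LM", "Rad"), c(ncol(pv$lm), ncol(pv$rad)))
  dec <- decode_ripple_type(counts, labels, n_cells = 15, n_perm = 25,
                            n_cv = 10, min_events_per_class = 100, seed = 6)
  expect_gt(dec$mean_observed, dec$mean_control)
  expect_lt(t.test(dec$mi_observed, dec$mi_control,
                   alternative = "greater")$p.value, 0.05)
  # labels independent of activity: MI within the control band
  set.seed(7)
  dec0 <- decode_ripple_type(counts, sample(labels), n_cells = 15, n_perm = 20,
                             n_cv = 10, min_events_per_class = 100, seed = 8)
  expect_lt(dec0$mean_observed,
            mean(dec0$mi_control) + 3 * sd(dec0$mi_control))
  expect_error(decode_ripple_type(counts[1:5, ], labels, n_cells = 15,
                                  min_events_per_class = 100), "units")
})

test_that("temporal-pattern features have two columns per unit", {
  ss <- fixture_session()
  post <- ss$events[ss$events$epoch == "post-sleep", ]
  iso <- post$peak_time_s[is_isolated(post$peak_time_s)][1:80]
  ids <- ss$units$unit_id[ss$units$cell_class == "principal"][1:8]
  f <- temporal_pattern_features(ss$spikes, iso, unit_ids = ids)
  expect_equal(dim(f), c(80L, 16L))
  # a silent unit yields zero columns and is flagged
  sp2 <- ss$spikes[ss$spikes$unit_id != ids[1], ]
  f2 <- temporal_pattern_features(sp2, iso, unit_ids = ids)
  expect_true(ids[1] %in% attr(f2, "degenerate_units"))
  expect_true(all(f2[, 1:2] == 0))
})

test_that("pre-event CA3 transient separates classes beyond count vectors", {
  ss <- fixture_session()
  post <- ss$events[ss$events$epoch == "post-sleep", ]
  iso <- is_isolated(post$peak_time_s)
  ca3 <- ss$units$unit_id[ss$units$region == "CA3" &
                            ss$units$cell_class == "principal"]
  lm_t <- post$peak_time_s[iso & post$true_class == "LM"]
  rad_t <- post$peak_time_s[iso & post$true_class == "Rad"]
  peth_lm <- compute_peth(ss$spikes, lm_t, unit_ids = ca3)
  peth_rad <- compute_peth(ss$spikes, rad_t, unit_ids = ca3)
  pre_win <- peth_lm$lags_ms > -120 & peth_lm$lags_ms < -80
  expect_gt(mean(peth_lm$rate[, pre_win]), 1.5 * mean(peth_rad$rate[, pre_win]))
})
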