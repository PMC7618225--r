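test_that("second-difference CSD matches the defining formula", {
  expect_equal(as.numeric(compute_csd(matrix(c(1, 2, 3), 3, 1))), 0)
  expect_equal(as.numeric(compute_csd(matrix(c(0, -1, 0), 3, 1))), -2)
  m <- matrix(rnorm(5 * 10), 5, 10)
  expect_equal(compute_csd(m + 7), compute_csd(m))  # offset invariance
  expect_error(compute_csd(matrix(1:2, 2, 1)), "3 channels")
  # linear-in-depth profile has zero CSD at every instant
  depth <- matrix(rep(1:6, 4), 6, 4) * rep(c(1, -2, 0.5, 3), each = 6)
  expect_true(all(abs(compute_csd(depth)) < 1e-12))
})

test_that("laminar smoothing is a normalized, spacing-aware kernel", {
  x <- matrix(rnorm(12), 12, 1)
  expect_equal(smooth_laminar(x, 50, sigma_um = 0), x)
  imp <- matrix(0, 15, 1); imp[8, 1] <- 1
  sm <- smooth_laminar(imp, 50, sigma_um = 50)
  expect_lt(abs(sum(sm) - 1), 1e-6)        # unit mass
  expect_equal(which.max(sm), 8L)
  # two spacings, same underlying profile: agreement after resampling
  f <- function(d_um) exp(-(d_um - 350)^2 / (2 * 80^2))
  d20 <- seq(0, 700, by = 20); d50 <- seq(0, 700, by = 50)
  s20 <- smooth_laminar(matrix(f(d20)), 20, 50)
  s50 <- smooth_laminar(matrix(f(d50)), 50, 50)
  interp <- approx(d20, s20, xout = d50)$y
  expect_lt(max(abs(interp - s50)) / max(abs(s50)), 0.05)
})

test_that("signatures summarize the peak-centred window", {
  fs <- 1000
  csd <- matrix(rnorm(10 * 2000, sd = 1e-6), 10, 2000)
  prof <- seq(-1, 1, length.out = 10)
  csd[, 950:1049] <- csd[, 950:1049] + prof   # constant-in-time profile
  sig <- signature(csd, peak_time_s = 1.0, fs = fs)
  expect_equal(sig, prof, tolerance = 1e-4)
  # zero-mean oscillation -> near-zero signature
  osc <- matrix(rep(sin(2 * pi * 150 * seq_len(2000) / fs), each = 10), 10)
  expect_lt(max(abs(signature(osc, 1.0, fs))), 0.05)
  # event at the record edge is skipped with a warning
  expect_warning(out <- signature(csd, 0.001, fs), "edge")
  expect_null(out)
})

test_that("dominant sink recovers the planted laminar class", {
  sim <- fixture_lfp()
  csd <- fixture_csd()
  rec <- sim$recording
  sigs <- ripple_signatures(csd, sim$truth$events$peak_time_s, rec$fs_hz)
  kept <- attr(sigs, "kept")
  sinks <- apply(sigs, 1L, dominant_sink_layer, layer_map = rec$layer_map)
  truth <- sim$truth$events$true_class[kept]
  pred <- ifelse(sinks == "radiatum", "Rad",
                 ifelse(sinks == "lacunosum-moleculare", "LM", sinks))
  expect_gt(mean(pred == truth), 0.9)
  # all-positive signature -> no sink
  expect_equal(dominant_sink_layer(rep(1, 14), rec$layer_map), "no sink")
})

test_that("LM-type events show the planted temporal sink order", {
  sim <- fixture_lfp()
  csd <- fixture_csd()
  rec <- sim$recording
  fs <- rec$fs_hz
  interior <- rec$layer_map[2:(length(rec$layer_map) - 1L)]
  lm_ch <- which(interior == "lacunosum-moleculare")
  rad_ch <- which(interior == "radiatum")
  lm_ev <- sim$truth$events$peak_time_s[sim$truth$events$true_class == "LM"]
  lead_lag <- vapply(lm_ev, function(t0) {
    idx <- round(t0 * fs) + seq(-round(0.04 * fs), round(0.04 * fs))
    if (min(idx) < 1 || max(idx) > ncol(csd)) return(c(NA, NA))
    lm_tr <- colMeans(csd[lm_ch, idx, drop = FALSE])
    rad_tr <- colMeans(csd[rad_ch, idx, drop = FALSE])
    mid <- (length(idx) + 1) / 2
    c(which.min(lm_tr) - mid, which.min(rad_tr) - mid) / fs
  }, numeric(2))
  # sign test: LM sink trough precedes the peak, radiatum sink follows it
  expect_gt(mean(lead_lag[1, ] < 0, na.rm = TRUE), 0.8)
  expect_gt(mean(lead_lag[2, ] > 0, na.rm = TRUE), 0.8)
})

test_that("signature PCA normalizes variance and fixes the PC1 sign", {
  sim <- fixture_lfp()
  csd <- fixture_csd()
  rec <- sim$recording
  sigs <- ripple_signatures(csd, sim$truth$events$peak_time_s, rec$fs_hz)
  p <- pca_signatures(sigs, rec$layer_map)
  expect_equal(sum(p$variance_explained), 1)
  interior <- rec$layer_map[2:(length(rec$layer_map) - 1L)]
  expect_lte(mean(p$components[interior == "radiatum", 1L]), 0)
  # two planted orthogonal spatial modes are recovered
  set.seed(9)
  m1 <- unit_vec(2:4, 14); m2 <- unit_vec(9:11, 14)
  scores <- cbind(rnorm(300, sd = 3), rnorm(300, sd = 1.5))
  X <- scores %*% rbind(m1, m2) + matrix(rnorm(300 * 14, sd = 0.05), 300)
  pp <- pca_signatures(X, rec$layer_map)
  expect_gt(abs(sum(pp$components[, 1L] * m1)), 0.95)
  expect_gt(abs(sum(pp$components[, 2L] * m2)), 0.95)
  expect_error(pca_signatures(matrix(1, 5, 14), rec$layer_map), "rank")
})

test_that("percentile labels split 30/40/30 with boundary ties intermediate", {
  lab <- label_by_pc1(1:10)
  expect_equal(sum(lab == "Rad"), 3L)
  expect_equal(sum(lab == "LM"), 3L)
  expect_equal(sum(lab == "intermediate"), 4L)
  expect_true(all(label_by_pc1(rep(2, 8)) == "intermediate"))
  # invariance to monotone rescaling
  x <- rnorm(200)
  expect_equal(label_by_pc1(x), label_by_pc1(exp(2 * x + 1)))
})

test_that("LM-CSD labelling agrees with planted classes", {
  sim <- fixture_lfp()
  csd <- fixture_csd()
  rec <- sim$recording
  sigs <- ripple_signatures(csd, sim$truth$events$peak_time_s, rec$fs_hz)
  kept <- attr(sigs, "kept")
  lab <- label_by_lm_csd(sigs, rec$layer_map)
  expect_equal(sd(lab$scores), 1)
  truth <- sim$truth$events$true_class[kept]
  keep <- lab$labels != "intermediate"
  expect_gt(mean(lab$labels[keep] == truth[keep]), 0.9)
  expect_error(label_by_lm_csd(matrix(1, 50, 14), rec$layer_map), "variance")
})
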