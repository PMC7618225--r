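test_that("recent/prior transforms satisfy their algebraic identities", {
  set.seed(1)
  A <- crossprod(matrix(rnorm(36), 6)) / 6
  diag(A) <- 0
  W <- recent_prior_transform(A, A, diag_load = 0)
  expect_equal(W$W_recent, diag(6), tolerance = 1e-8)
  W1 <- recent_prior_transform(A, A, diag_load = 1)
  expect_equal(W1$W_recent, diag(6), tolerance = 1e-8)
  W2 <- recent_prior_transform(A, 2 * A, diag_load = 0)
  expect_equal(W2$W_recent, 2 * diag(6), tolerance = 1e-8)
  # W_recent %*% A_pre = A_theta when no regularization was triggered
  B <- A + 0.05 * {M <- matrix(rnorm(36), 6); (M + t(M)) / 2}
  diag(B) <- 0
  W3 <- recent_prior_transform(A, B, diag_load = 1)
  expect_false(any(W3$regularized))
  expect_equal(W3$W_recent %*% (A + diag(6)), B + diag(6), tolerance = 1e-8)
})

test_that("the transform's top eigenvector aligns with a wake-gained motif", {
  set.seed(2)
  n <- 12
  noise <- function() {
    M <- matrix(rnorm(n * n, sd = 0.02), n)
    (M + t(M)) / 2
  }
  motif_pre <- unit_vec(1:4, n)
  motif_wake <- unit_vec(7:10, n)
  A_pre <- 0.6 * tcrossprod(motif_pre) + noise(); diag(A_pre) <- 0
  A_th <- 0.6 * tcrossprod(motif_wake) + noise(); diag(A_th) <- 0
  W <- recent_prior_transform(A_pre, A_th)
  top <- eigen(W$W_recent)$vectors[, 1L]
  expect_gt(abs(sum(Re(top) * motif_wake)), 0.8)
})

test_that("balance score is the quadratic form with regional masking", {
  set.seed(3)
  W <- matrix(rnorm(25), 5)
  v <- rnorm(5)
  expect_equal(balance_score(diag(5), v), sum(v^2))
  expect_equal(balance_score(W, 2 * v), 4 * balance_score(W, v))
  expect_equal(balance_score(W, v), drop(t(v) %*% W %*% v))
  region <- c("CA1", "CA1", "CA1", "CA3", "CA3")
  masked <- balance_score(W, v, region = region, cross_regions = c("CA3", "CA1"))
  Wm <- W * (outer(region == "CA3", region == "CA1") |
               outer(region == "CA1", region == "CA3"))
  expect_equal(masked, drop(t(v) %*% Wm %*% v))
  expect_error(balance_score(W, rnorm(4)), "mismatch")
})

test_that("drift time course uses six 10-minute windows normalized to zero mean", {
  set.seed(4)
  tt <- runif(4000, 0, 75)
  ds <- drift_timecourse(rep(2.5, 4000), tt)
  expect_equal(sort(unique(ds$t_min)), seq(15, 65, by = 10))
  expect_true(all(abs(ds$value) < 1e-12))  # constant input -> all zero
  # simulated exponential decay -> monotone binned series
  y <- 3 * exp(-tt / 13) + rnorm(4000, sd = 0.01)
  ds2 <- drift_timecourse(y, tt)
  expect_true(all(diff(ds2$value[order(ds2$t_min)]) < 0))
})

test_that("BIC model selection separates flat from exponential dynamics", {
  t_bins <- rep(seq(15, 65, by = 10), times = 8)
  sess <- rep(1:8, each = 6)
  # flat + noise: flat wins in >= 95% of seeds
  flat_wins <- vapply(1:20, function(s) {
    set.seed(s)
    y <- rnorm(length(t_bins), sd = 0.3)
    fit_flat_vs_exponential(t_bins, y, session = sess, n_boot = 0,
                            seed = s)$model == "flat"
  }, logical(1))
  expect_gte(mean(flat_wins), 0.95)
  # planted tau = 13: exponential wins and the bootstrap CI covers 13
  set.seed(99)
  y <- 1 * exp(-t_bins / 13) + rnorm(length(t_bins), sd = 0.05)
  f <- fit_flat_vs_exponential(t_bins, y, session = sess, n_boot = 400, seed = 1)
  expect_equal(f$model, "exponential")
  expect_lt(f$bic_exp, f$bic_flat)
  expect_true(f$tau_ci[1] <= 13 && 13 <= f$tau_ci[2])
  expect_lt(abs(f$pars[["tau"]] - 13) / 13, 0.5)
  # adding a constant is absorbed by the offset, tau unchanged
  f2 <- fit_flat_vs_exponential(t_bins, y + 5, session = sess, n_boot = 0, seed = 1)
  expect_lt(abs(f2$pars[["tau"]] - f$pars[["tau"]]) / f$pars[["tau"]], 0.05)
})

test_that("bootstrap tau CIs cover the planted value across replicate worlds", {
  t_bins <- rep(seq(15, 65, by = 10), times = 10)
  sess <- rep(1:10, each = 6)
  cover <- vapply(1:12, function(s) {
    set.seed(s + 200)
    y <- exp(-t_bins / 13) + rnorm(length(t_bins), sd = 0.08)
    f <- fit_flat_vs_exponential(t_bins, y, session = sess, n_boot = 150,
                                 seed = s)
    f$tau_ci[1] <= 13 && 13 <= f$tau_ci[2]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("GLM peer prediction detects post-sleep re-expression of wake motifs", {
  ss <- fixture_session()
  ev <- ss$events
  pre <- ev[ev$epoch == "pre-sleep", ]
  post <- ev[ev$epoch == "post-sleep", ]
  units_pr <- ss$units[ss$units$cell_class == "principal", ]
  th <- population_vectors(ss, ss$theta_cycles$time_s, window_ms = 125)
  pv_pre <- population_vectors(ss, pre$peak_time_s[pre$true_class == "LM"])
  pv_post <- population_vectors(ss, post$peak_time_s[post$true_class == "LM"])
  gr <- glm_reactivation(th, pv_pre, pv_post, units_pr, n_draws = 20,
                         n_boot = 2000, seed = 5)
  expect_true(all(abs(gr$per_unit$acc_pre) <= 1))
  expect_true(all(abs(gr$per_unit$acc_post) <= 1))
  expect_gt(gr$mean_post, gr$mean_pre)
  expect_lt(gr$p_reactivation, 0.05)
  # null: swap roles, pre ripples cannot contain the wake motif
  gr0 <- glm_reactivation(th, pv_post, pv_pre, units_pr, n_draws = 20,
                          n_boot = 2000, seed = 6)
  expect_gt(gr0$p_reactivation, 0.5)
})

test_that("pre-sleep coactivity reactivation declines for the drifting class", {
  ss <- memo("drift_session", function() {
    simulate_spike_session(sim_config(seed = 17))
  })
  ev <- ss$events
  pre <- ev[ev$epoch == "pre-sleep", ]
  post <- ev[ev$epoch == "post-sleep", ]
  lm_post <- post[post$true_class == "LM", ]
  pv_pre <- population_vectors(ss, pre$peak_time_s[pre$true_class == "LM"])
  pv_post <- population_vectors(ss, lm_post$peak_time_s)
  t_min <- (lm_post$peak_time_s - ss$epochs$start_s[3L]) / 60
  pd <- presleep_reactivation_decay(pv_pre, pv_post, t_min, n_shuffle = 30,
                                    seed = 7)
  expect_true(all(is.finite(pd$strength)))
  # early windows express the prior coactivity more than late windows
  expect_gt(mean(pd$strength[1:2]), mean(pd$strength[(nrow(pd) - 1):nrow(pd)]))
  # chance normalization: shuffled-identity accuracy was subtracted
  expect_lt(mean(pd$strength), 0.6)
})

test_that("wake reactivation survives partialling out pre-sleep cofiring", {
  ss <- fixture_session()
  ev <- ss$events
  pre <- ev[ev$epoch == "pre-sleep", ]
  post <- ev[ev$epoch == "post-sleep", ]
  th <- population_vectors(ss, ss$theta_cycles$time_s, window_ms = 125)
  pv_pre <- population_vectors(ss, pre$peak_time_s)
  pv_post <- population_vectors(ss, post$peak_time_s)
  t_min <- (post$peak_time_s - ss$epochs$start_s[3L]) / 60
  wp <- wake_reactivation_partial(pv_pre, th, pv_post, t_min)
  expect_gt(nrow(wp), 1L)
  expect_true(all(wp$beta_wake > 0))
})

test_that("stability score is 1 minus the accuracy drop", {
  expect_equal(stability_score(0.5, 0.5), 1)
  expect_equal(stability_score(0.8, 0.3), 0.5)
  expect_gt(stability_score(0.8, 0.7), stability_score(0.8, 0.4))
})

test_that("feature attribution assigns drift to log-time only", {
  set.seed(8)
  n <- 48
  t_min <- rep(seq(15, 65, by = 10), times = 8)
  occ <- rnorm(n, 10, 0.5)
  sparse <- rnorm(n, 0.3, 0.01)
  bal <- -exp(-t_min / 13) + rnorm(n, sd = 0.05)
  fa <- feature_attribution(bal, t_min, occ, sparse, n_shuffles = 300, seed = 9)
  expect_lt(fa$p[fa$feature == "log_time"], 0.05)
  expect_gt(fa$p[fa$feature == "occ"], 0.05)
  expect_gt(fa$p[fa$feature == "sparse"], 0.05)
  expect_gt(fa$gain[fa$feature == "log_time"], fa$gain[fa$feature == "occ"])
  # balance shuffled: the full model sits inside its chance band
  fa0 <- feature_attribution(sample(bal), t_min, occ, sparse,
                             n_shuffles = 100, seed = 10)
  ch <- attr(fa0, "chance")
  expect_lt(attr(fa0, "accuracy"), ch[2] + 0.1)
})

test_that("sublayer comparison finds decay planted in deep units only", {
  set.seed(11)
  n_u <- 24
  t_mid <- seq(15, 65, by = 10)
  sub <- rep(c("deep", "superficial"), each = n_u / 2)
  sess <- rep(1:4, length.out = n_u)
  strength <- matrix(NA_real_, n_u, length(t_mid))
  for (u in seq_len(n_u)) {
    base <- if (sub[u] == "deep") 0.5 * exp(-t_mid / 13) else rep(0.25, 6)
    strength[u, ] <- base + rnorm(6, sd = 0.05)
  }
  sc <- sublayer_decay_compare(strength, t_mid, sub, sess, n_boot = 400,
                               seed = 12)
  z_deep <- sc$z[sc$sublayer == "deep"]
  z_sup <- sc$z[sc$sublayer == "superficial"]
  expect_lt(z_deep, z_sup - 2)
  expect_lt(z_deep, -2)
  expect_lt(sc$slope[sc$sublayer == "deep"], 0)
  # superficial slope stays near zero relative to the planted deep decay
  expect_lt(abs(sc$slope[sc$sublayer == "superficial"]),
            abs(sc$slope[sc$sublayer == "deep"]) / 2)
})

test_that("circular shuffling preserves the series autocorrelation spectrum", {
  set.seed(13)
  x <- as.numeric(arima.sim(list(ar = 0.8), 64))
  k <- 17
  xs <- x[((seq_along(x) - 1 + k) %% length(x)) + 1]
  expect_equal(sort(x), sort(xs))
  expect_equal(Mod(fft(xs))^2, Mod(fft(x))^2, tolerance = 1e-8)
})

test_that("session-level balance drift rises toward recent motifs in LM ripples", {
  ss <- fixture_session()
  ds <- session_balance_drift(ss)
  bal <- attr(ds, "balance")
  post <- ss$events[ss$events$epoch == "post-sleep", ]
  lmev <- post$true_class == "LM"
  m_prior <- mean(bal[lmev & post$expressed == "prior"])
  m_recent <- mean(bal[lmev & post$expressed == "recent"])
  expect_gt(m_recent, m_prior)
})
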