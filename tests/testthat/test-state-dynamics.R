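test_that("DG energy is a z-scored 5 Hz series", {
  set.seed(1)
  csd <- matrix(rnorm(5 * 12500), 5, 12500)
  e <- dg_energy(csd, 2:4, fs = 1250)
  expect_length(e, 50L)
  expect_lt(abs(mean(e)), 1e-10)
  expect_equal(sd(e), 1)
  expect_false(attr(e, "degenerate"))
  ec <- dg_energy(matrix(1, 5, 12500), 2:4, fs = 1250)
  expect_true(attr(ec, "degenerate"))
  expect_true(all(ec == 0))
  expect_error(dg_energy(csd, integer(0), 1250), "DG")
})

test_that("planted two-state energy is bimodal beyond a unimodal control", {
  cfg <- sim_config(seed = 8)
  ud <- simulate_updown_energy(cfg, duration_s = 1000, gap_sd = 3)
  bimod <- function(x) {
    # bimodality coefficient (skew^2 + 1) / kurtosis
    n <- length(x); s <- (x - mean(x)) / sd(x)
    (mean(s^3)^2 + 1) / (mean(s^4) + 3 * (n - 1)^2 / ((n - 2) * (n - 3)) - 3)
  }
  set.seed(1)
  expect_gt(bimod(ud$energy), bimod(rnorm(length(ud$energy))))
})

test_that("HMM decoding recovers planted states and is affine-invariant", {
  cfg <- sim_config(seed = 9)
  ud <- simulate_updown_energy(cfg, duration_s = 1200, gap_sd = 3)
  st <- infer_updown(ud$energy, min_epochs = 10L)
  expect_gt(mean(st$states == ud$states), 0.95)
  expect_false(st$low_confidence)
  st2 <- infer_updown(3 * ud$energy - 5, min_epochs = 10L)
  expect_equal(st2$states, st$states)
  # epochs reconstruct the decoded sequence exactly
  rebuilt <- unlist(mapply(function(s, d) rep(s, round(d * 5)),
                           st$epochs$state, st$epochs$duration_s,
                           SIMPLIFY = FALSE), use.names = FALSE)
  expect_equal(rebuilt, st$states)
  # decoded mean dwell within 20% of the semi-Markov targets
  up_d <- mean(st$epochs$duration_s[st$epochs$state == "Up"])
  dn_d <- mean(st$epochs$duration_s[st$epochs$state == "Down"])
  expect_lt(abs(up_d - 5.74) / 5.74, 0.2)
  expect_lt(abs(dn_d - 4.4) / 4.4, 0.2)
})

test_that("degenerate emission separation is flagged", {
  cfg <- sim_config(seed = 10)
  set.seed(1)
  x <- rnorm(600)  # gap = 0: no separable states
  st <- infer_updown(x, min_epochs = 1L)
  expect_true(st$low_confidence)
})

test_that("LM proportion by state recovers a planted state dependence", {
  cfg <- sim_config(seed = 11)
  ud <- simulate_updown_energy(cfg, duration_s = 2000, gap_sd = 3)
  st <- infer_updown(ud$energy, min_epochs = 10L)
  set.seed(2)
  n_ev <- 800
  tt <- sort(runif(n_ev, 0, 2000))
  idx <- pmin(floor(tt * 5) + 1L, length(ud$states))
  p_lm <- ifelse(ud$states[idx] == "Up", 0.45, 0.15)
  lab <- ifelse(runif(n_ev) < p_lm, "LM", "Rad")
  res <- lm_proportion_by_state(tt, lab, st, ud$energy)
  pu <- res$by_state$prop_lm[res$by_state$state == "Up"]
  pd <- res$by_state$prop_lm[res$by_state$state == "Down"]
  expect_gt(pu, pd)
  ok <- !is.na(res$by_energy$prop_lm)
  expect_true(all(res$by_energy$prop_lm[ok] >= 0 & res$by_energy$prop_lm[ok] <= 1))
  # null: equal probability in both states -> CI covers 0
  lab0 <- ifelse(runif(n_ev) < 0.3, "LM", "Rad")
  res0 <- lm_proportion_by_state(tt, lab0, st, ud$energy)
  d0 <- abs(res0$by_state$prop_lm[1] - res0$by_state$prop_lm[2])
  expect_lt(d0, 0.08)
})

test_that("ripple chains follow the 250 ms gap rule", {
  ch <- ripple_chains(c(0, 0.2, 0.39, 1.0))
  expect_equal(sort(ch$lengths, decreasing = TRUE), c(3L, 1L))
  ch2 <- ripple_chains(seq(0, 3, by = 0.3))
  expect_true(all(ch2$lengths == 1L))
  # Poisson trains give monotonically decreasing chain-length counts
  set.seed(3)
  tt <- cumsum(rexp(2000, rate = 1.2))
  h <- ripple_chains(tt)$histogram
  expect_true(all(diff(h$count[1:min(4, nrow(h))]) < 0))
})

test_that("transition matrices are row-stochastic and shuffle-normalized", {
  lab <- rep("Rad", 30)
  tm <- transition_matrix(lab, rep(1L, 30), classes = c("Rad", "LM"),
                          n_shuffle = 50)
  expect_equal(tm$raw["Rad", "Rad"], 1)
  # bursty generator: positive normalized diagonal
  set.seed(4)
  lab2 <- character(400)
  lab2[1] <- "Rad"
  for (i in 2:400) {
    lab2[i] <- if (runif(1) < 0.8) lab2[i - 1] else sample(c("Rad", "LM"), 1)
  }
  tm2 <- transition_matrix(lab2, rep(1L, 400), classes = c("Rad", "LM"),
                           n_shuffle = 200)
  expect_true(all(abs(rowSums(tm2$raw) - 1) < 1e-12))
  expect_gt(tm2$normalized["Rad", "Rad"], 0)
  expect_gt(tm2$normalized["LM", "LM"], 0)
  # exchangeable labels: normalized entries near 0
  lab3 <- sample(rep(c("Rad", "LM"), 200))
  tm3 <- transition_matrix(lab3, rep(1L, 400), classes = c("Rad", "LM"),
                           n_shuffle = 400)
  expect_lt(max(abs(tm3$normalized)), 0.08)
  expect_error(transition_matrix("Rad", 1L), "pairs")
})

test_that("NREM occurrence profiles detect ramped but not uniform placement", {
  set.seed(5)
  bouts <- data.frame(start_s = seq(0, 900, by = 100),
                      end_s = seq(60, 960, by = 100))
  uni <- unlist(lapply(seq_len(nrow(bouts)), function(b) {
    runif(30, bouts$start_s[b], bouts$end_s[b])
  }))
  res_u <- nrem_occurrence_profile(uni, rep("Rad", length(uni)), bouts,
                                   n_shuffle = 500)
  expect_gt(res_u$p, 0.05)
  ramp <- unlist(lapply(seq_len(nrow(bouts)), function(b) {
    bouts$start_s[b] + 60 * sqrt(runif(30))
  }))
  res_r <- nrem_occurrence_profile(ramp, rep("Rad", length(ramp)), bouts,
                                   n_shuffle = 500)
  expect_lt(res_r$p, 0.05)
  expect_gt(res_r$cor, 0)
  profs <- attr(res_r, "profiles")$Rad
  expect_true(all(abs(rowSums(profs) - 1) < 1e-12))
})
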