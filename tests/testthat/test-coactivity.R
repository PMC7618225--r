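test_that("population-conditioned coefficients match the two-regressor OLS oracle", {
  set.seed(1)
  n <- 5000
  shared <- rnorm(n)
  x1 <- shared + 0.3 * rnorm(n)
  x2 <- shared + 0.3 * rnorm(n)
  others <- matrix(rnorm(3 * n), 3)
  counts <- rbind(x1, x2, others)
  g <- population_conditioned_coactivity(counts)
  # oracle: lm() on the same z-scored variables
  z <- t(scale(t(counts)))
  P <- colSums(z) - z[1, ] - z[2, ]
  beta_or <- unname(coef(lm(z[2, ] ~ z[1, ] + P))[2])
  beta_rev <- unname(coef(lm(z[1, ] ~ z[2, ] + P))[2])
  expect_lt(abs(g$adjacency[1, 2] - (beta_or + beta_rev) / 2), 1e-6)
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  # independent units: near-zero couplings
  set.seed(2)
  ind <- matrix(rpois(8 * 10000, 1), 8)
  g0 <- population_conditioned_coactivity(ind)
  expect_lt(max(abs(g0$adjacency)), 0.05)
})

test_that("ridge coactivity has the right shrinkage limits", {
  set.seed(3)
  counts <- matrix(rpois(6 * 800, 1.5), 6)
  z <- t(scale(t(counts)))
  big <- fully_conditioned_coactivity(counts, penalty = 1e9)
  expect_lt(max(abs(big$adjacency)), 1e-5)
  small <- fully_conditioned_coactivity(counts, penalty = 1e-8)
  b_ols <- unname(coef(lm(z[1, ] ~ t(z[-1, ]) - 1)))
  expect_lt(max(abs(small$adjacency[1, -1] - b_ols)), 1e-5)
  expect_false(small$symmetric)
  # planted 3-unit motif: within-motif coefficients exceed between
  set.seed(4)
  on <- rbinom(1500, 1, 0.4)
  motif <- t(sapply(1:3, function(i) rpois(1500, 0.3 + 2 * on)))
  bg <- matrix(rpois(5 * 1500, 1), 5)
  gm <- fully_conditioned_coactivity(rbind(motif, bg), penalty = 1)
  A <- gm$adjacency
  within <- A[1:3, 1:3][upper.tri(diag(3))]
  between <- as.vector(A[1:3, 4:8])
  expect_gt(min(within), max(between))
})

test_that("node strength averages off-diagonal weights", {
  A <- matrix(0.5, 4, 4); diag(A) <- 0
  expect_equal(node_strength(A), rep(0.5, 4))
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- c(1, -1, 1, -1)
  expect_equal(node_strength(star)[1], 0)
})

test_that("within-motif coupling dominates the LM-event graph", {
  pv <- fixture_pvs()
  ss <- pv$session
  A <- population_conditioned_coactivity(pv$lm)$adjacency
  core <- ss$core_motif
  non <- setdiff(seq_len(nrow(pv$lm)), c(core, ss$composite_extra, ss$recent_motif))
  within <- mean(A[core, core][upper.tri(diag(length(core)))])
  background <- mean(A[non, non][upper.tri(diag(length(non)))], na.rm = TRUE)
  expect_gt(within, background + 0.2)
  # the same core block is weaker in Rad events, where the composite is shared
  A_rad <- population_conditioned_coactivity(pv$rad)$adjacency
  extra <- ss$composite_extra
  cross_rad <- mean(A_rad[core, extra])
  cross_lm <- mean(A[core, extra])
  expect_gt(cross_rad, cross_lm)  # extras couple to the core only in Rad events
})

test_that("structural balance equals the exhaustive triad census", {
  expect_equal(structural_balance({A <- matrix(1, 4, 4); diag(A) <- 0; A}), 1)
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- -1
  expect_equal(structural_balance(tri), 0)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    A <- matrix(0, n, n)
    A[upper.tri(A)] <- sample(c(-1, 0, 1), n * (n - 1) / 2, TRUE)
    A <- A + t(A)
    expect_equal(structural_balance(A), balance_brute(A))
  }
  expect_true(is.na(structural_balance(matrix(0, 4, 4))))
})

test_that("Gini sparsity matches the mean-absolute-difference oracle", {
  expect_equal(gini_sparsity(c(1, 1, 1, 1)), 0)
  expect_equal(gini_sparsity(c(0, 0, 0, 8)), 0.75)
  expect_equal(gini_sparsity(c(2, 4, 6)), gini_sparsity(c(6, 2, 4)))
  expect_equal(gini_sparsity(c(1, 2, 3)), gini_sparsity(10 * c(1, 2, 3)))
  set.seed(6)
  for (i in 1:1000) {
    x <- rpois(sample(5:40, 1), runif(1, 0.5, 4))
    if (sum(x) == 0) next
    expect_lt(abs(gini_sparsity(x) - gini_mad(x)), 1e-9)
  }
})

test_that("ABID satisfies its geometric contracts", {
  collinear <- rbind(c(1, 0), c(2, 0), c(3, 0), c(5, 0))
  expect_equal(abid_dimensionality(collinear, k = 3, zscore = FALSE)$per_event[1], 1)
  ortho <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(abid_dimensionality(ortho, k = 2, zscore = FALSE,
                                   center = FALSE)$per_event[1], 2)
  set.seed(7)
  X <- matrix(rnorm(1200 * 3), 1200, 3)
  a <- abid_dimensionality(X, k = 40, zscore = FALSE)
  expect_lt(abs(a$mean_d - 3) / 3, 0.1)
})

test_that("shuffle-normalized dimensionality detects planted low-dim structure", {
  set.seed(8)
  ind <- matrix(rpois(400 * 20, 1), 400, 20)
  r0 <- normalized_dimensionality(ind, k = 30, n_surrogates = 5)
  expect_gt(r0$ratio, 0)
  expect_lt(abs(r0$ratio - 1), 0.12)
  on <- rbinom(400, 1, 0.4)
  motifs <- sapply(1:20, function(j) {
    if (j <= 10) rpois(400, 0.3 + 2.5 * on) else rpois(400, 0.3 + 2.5 * (1 - on))
  })
  r1 <- normalized_dimensionality(motifs, k = 30, n_surrogates = 5)
  expect_lt(r1$ratio, r0$ratio)
  expect_lt(r1$ratio, 0.95)
})

test_that("participation ratio matches direct eigenvalue evaluation", {
  expect_equal(participation_ratio(values = rep(2, 7)), 7)
  expect_equal(participation_ratio(values = c(5, 0, 0)), 1)
  expect_equal(participation_ratio(values = c(2, 1, 1)), 16 / 6)
  set.seed(9)
  X <- matrix(rnorm(500 * 8), 500, 8)
  lam <- eigen(cov(scale(X)), symmetric = TRUE)$values
  expect_equal(participation_ratio(X), participation_ratio(values = lam),
               tolerance = 1e-8)
})

test_that("asymmetric inclusion counts shared active cells directionally", {
  expect_equal(asymmetric_inclusion(c(1, 2, 0), c(2, 1, 0)), 1)
  expect_equal(asymmetric_inclusion(c(1, 0, 0), c(0, 1, 1)), 0)
  m <- c(1, 1, 0); q <- c(1, 1, 1)
  expect_equal(asymmetric_inclusion(m, q), 1)
  expect_equal(asymmetric_inclusion(q, m), 2 / 3)
  expect_true(is.na(asymmetric_inclusion(c(0, 0), c(1, 1))))
})

test_that("resampled inclusion finds core-in-composite containment", {
  pv <- fixture_pvs()
  ident <- inclusion_resampled(t(pv$lm[, 1:50]), t(pv$lm[, 1:50]), n_iter = 10)
  expect_true(all(ident >= 0 & ident <= 1))
  incl <- inclusion_resampled(t(pv$lm), t(pv$rad), n_iter = 100, seed = 10)
  # identity-shuffled control: shuffle unit identities within each LM event
  set.seed(11)
  lm_sh <- t(apply(t(pv$lm), 1L, sample))
  incl_sh <- inclusion_resampled(lm_sh, t(pv$rad), n_iter = 100, seed = 10)
  expect_gt(mean(incl), mean(incl_sh))
})

test_that("PC1-vs-rate control separates excitability from motif structure", {
  set.seed(12)
  # rates-only generator: heterogeneous rates, no coactivity
  rates <- runif(12, 0.3, 3)
  m0 <- t(sapply(rates, function(r) rpois(600, r)))
  r0 <- excitability_control_pc1(m0, n_surrogates = 100, seed = 13)
  expect_true(r0$r_observed >= r0$band[1] - 0.1 & r0$r_observed <= r0$band[2] + 0.1)
  expect_true(all(abs(r0$r_surrogate) <= 1))
  # planted rate-independent motif: observed r below the surrogate band
  on <- rbinom(600, 1, 0.5)
  m1 <- rbind(t(sapply(1:4, function(i) rpois(600, 0.4 + 1.2 * on))),
              t(sapply(1:4, function(i) rpois(600, 1.6 - 1.2 * on))),
              matrix(rpois(4 * 600, 1), 4))
  r1 <- excitability_control_pc1(m1, n_surrogates = 100, seed = 14)
  expect_lt(r1$r_observed, r1$band[1])
})
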