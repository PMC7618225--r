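#' GLM peer-prediction reactivation
#'
#' For each target unit, linear models predict its firing from four peer
#' units recorded on other tetrodes (optionally restricted to the same
#' sublayer), trained on theta-cycle counts from exploration. The
#' cross-validated models are applied to z-scored ripple-nested counts in
#' pre- and post-sleep separately; accuracy is the Pearson correlation of
#' predicted versus actual activity, averaged over `n_draws` random
#' predictor draws. Reactivation is a one-tailed paired bootstrap of
#' post > pre accuracy across units.
#'
#' @param theta_counts units x cycles count matrix (exploration).
#' @param pv_pre,pv_post units x events count matrices (pre/post-sleep
#'   ripples of one class).
#' @param units unit-metadata data frame with `tetrode` and optionally
#'   `sublayer` (rows aligned with the count matrices).
#' @param sublayer_filter `NULL`, or `"deep"`/`"superficial"`: restricts
#'   targets and predictors to one sublayer.
#' @param n_draws predictor draws per target (default 100).
#' @param n_boot bootstrap resamples for the population test (default 5000).
#' @param seed RNG seed.
#' @return list of class `glm_reactivation`: `per_unit` (data frame
#'   unit/acc_pre/acc_post), `p_reactivation`, `mean_pre`, `mean_post`.
#' @export
glm_reactivation <- function(theta_counts, pv_pre, pv_post, units,
                             sublayer_filter = NULL, n_draws = 100,
                             n_boot = 5000, seed = 1L) {
  set.seed(seed)
  zt <- zscore_pvs(theta_counts)
  zpre <- zscore_pvs(pv_pre)
  zpost <- zscore_pvs(pv_post)
  n_u <- nrow(zt)
  eligible <- seq_len(n_u)
  if (!is.null(sublayer_filter)) {
    eligible <- which(!is.na(units$sublayer) & units$sublayer == sublayer_filter)
  }
  res <- list()
  for (u in eligible) {
    pool <- setdiff(eligible[units$tetrode[eligible] != units$tetrode[u]], u)
    if (length(pool) < 5L) next
    ap <- an <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      pred <- sample(pool, 4L)
      X <- t(zt[pred, , drop = FALSE])
      b <- stats::lm.fit(cbind(1, X), zt[u, ])$coefficients
      b[is.na(b)] <- 0
      yhat_pre <- drop(cbind(1, t(zpre[pred, , drop = FALSE])) %*% b)
      yhat_post <- drop(cbind(1, t(zpost[pred, , drop = FALSE])) %*% b)
      ap[d] <- suppressWarnings(stats::cor(yhat_pre, zpre[u, ]))
      an[d] <- suppressWarnings(stats::cor(yhat_post, zpost[u, ]))
    }
    res[[length(res) + 1L]] <- data.frame(
      unit = u, acc_pre = mean(ap, na.rm = TRUE),
      acc_post = mean(an, na.rm = TRUE))
  }
  if (length(res) == 0L) stop("glm_reactivation: no eligible target units")
  per_unit <- do.call(rbind, res)
  d <- per_unit$acc_post - per_unit$acc_pre
  boot <- vapply(seq_len(n_boot), function(i) {
    mean(d[sample.int(length(d), replace = TRUE)])
  }, numeric(1))
  structure(list(per_unit = per_unit,
                 p_reactivation = mean(boot <= 0),
                 mean_pre = mean(per_unit$acc_pre),
                 mean_post = mean(per_unit$acc_post)),
            class = "glm_reactivation")
}

#' Recent and prior coactivity transforms
#'
#' `W_recent = A_theta %*% solve(A_pre)` captures coactivity gained in
#' wakefulness relative to pre-sleep (and `W_prior` the reverse): the
#' inverse acts as a whitening of the pre-sleep patterns, so directions
#' already strong in pre-sleep are de-emphasized and wake-gained directions
#' pass through.
#'
#' Estimated coactivity matrices have zero diagonal, so their spectra
#' straddle zero and a raw inverse is dominated by near-null noise
#' directions. `diag_load` (default 1) restores each unit's unit
#' self-coactivity before inversion, i.e. both matrices are taken as
#' `A + diag_load * I`; with z-scored counts this makes the inverted matrix
#' a positive-definite correlation-like matrix and the transform a proper
#' whitening. `diag_load = 0` reproduces the raw definition (requires
#' well-conditioned input; a minimal ridge is applied and flagged above
#' `max_kappa`).
#'
#' @param A_pre,A_theta square coactivity matrices on the same unit set.
#' @param diag_load diagonal loading added to both matrices (default 1).
#' @param max_kappa condition-number limit for the raw inverse (default 1e8).
#' @return list: `W_recent`, `W_prior`, `regularized` (logical flags).
#' @export
recent_prior_transform <- function(A_pre, A_theta, diag_load = 1,
                                   max_kappa = 1e8) {
  n <- nrow(A_pre)
  Ap <- A_pre + diag(diag_load, n)
  At <- A_theta + diag(diag_load, n)
  safe_inv <- function(M) {
    kap <- kappa(M, exact = FALSE)
    reg <- FALSE
    if (!is.finite(kap) || kap > max_kappa) {
      eps <- 1e-6 * sum(abs(diag(M))) / n
      if (!is.finite(eps) || eps == 0) eps <- 1e-6
      M <- M + diag(eps, n)
      reg <- TRUE
    }
    list(inv = solve(M), reg = reg)
  }
  ip <- safe_inv(Ap)
  it <- safe_inv(At)
  list(W_recent = At %*% ip$inv,
       W_prior = Ap %*% it$inv,
       regularized = c(pre = ip$reg, theta = it$reg))
}

#' Recent-to-prior balance of ripple population vectors
#'
#' Quadratic form `v' W v` per event. The CA3-CA1 variant zeroes all matrix
#' entries except CA3 x CA1 pairs before projecting.
#'
#' @param W transform matrix (units x units).
#' @param pvs z-scored units x events matrix (unit order matching `W`).
#' @param region optional per-unit region labels for the cross-regional
#'   variant.
#' @param cross_regions length-2 character, e.g. `c("CA3","CA1")`: keep only
#'   entries pairing the two regions.
#' @return numeric vector, one balance score per event.
#' @export
balance_score <- function(W, pvs, region = NULL, cross_regions = NULL) {
  if (!is.matrix(pvs)) pvs <- matrix(pvs, ncol = 1L)
  if (nrow(pvs) != nrow(W)) stop("balance_score: dimension mismatch")
  if (!is.null(cross_regions)) {
    if (is.null(region)) stop("balance_score: region labels required")
    keep <- outer(region == cross_regions[1L], region == cross_regions[2L]) |
      outer(region == cross_regions[2L], region == cross_regions[1L])
    W <- W * keep
  }
  colSums(pvs * (W %*% pvs))
}

#' Time-binned drift series
#'
#' Means of per-event values over non-overlapping 10-minute windows spanning
#' (10, 70] minutes of post-sleep (the first 10 minutes are excluded as
#' rest-to-sleep transition), normalized by subtracting the session grand
#' mean across bins and classes.
#'
#' @param values per-event values (balance or reactivation strength).
#' @param times_min event times in minutes into post-sleep.
#' @param classes optional per-event class labels; normalization pools
#'   classes, output is per class.
#' @param bin_min window width (default 10).
#' @param t_start,t_end fitted range in minutes (default 10, 70).
#' @return data frame of class `drift_series`: `class`, `t_min` (bin
#'   centre), `value` (normalized), `value_raw`, `n`.
#' @export
drift_timecourse <- function(values, times_min, classes = NULL, bin_min = 10,
                             t_start = 10, t_end = 70) {
  if (is.null(classes)) classes <- rep("all", length(values))
  edges <- seq(t_start, t_end, by = bin_min)
  bin <- cut(times_min, edges, labels = FALSE)
  keep <- !is.na(bin)
  df <- data.frame(value = values[keep], bin = bin[keep],
                   class = classes[keep])
  agg <- stats::aggregate(value ~ class + bin, df, mean)
  counts <- stats::aggregate(value ~ class + bin, df, length)
  grand <- mean(agg$value)
  out <- data.frame(class = agg$class,
                    t_min = edges[agg$bin] + bin_min / 2,
                    value = agg$value - grand,
                    value_raw = agg$value,
                    n = counts$value)
  class(out) <- c("drift_series", "data.frame")
  out
}

#' Flat versus exponential model comparison with BIC
#'
#' Fits a constant model and `y = a * exp(-t / tau) + c` (grid-searched
#' starting values, Levenberg-Marquardt least squares) to a time series,
#' compares them with `BIC = k * log(n) + n * log(SSE / n)` (k = 1 flat,
#' k = 3 exponential), and bootstraps sessions to give percentile CIs of
#' tau and of the fit correlation r.
#'
#' @param t_min time points (minutes).
#' @param y values.
#' @param session optional session id per point (bootstrap unit; default
#'   each point its own session).
#' @param n_boot bootstrap resamples (default 2000).
#' @param tau_grid starting values for tau (minutes).
#' @param seed RNG seed.
#' @return list of class `fit_result`: `model` ("flat"/"exponential"),
#'   `bic_flat`, `bic_exp`, `pars` (a, tau, c), `tau_ci`, `r`, `r_ci`,
#'   `tau_boot`.
#' @export
fit_flat_vs_exponential <- function(t_min, y, session = NULL, n_boot = 2000,
                                    tau_grid = c(2, 5, 10, 13, 20, 40, 80),
                                    seed = 1L) {
  n <- length(y)
  stopifnot(length(t_min) == n)
  if (is.null(session)) session <- seq_len(n)
  # Given tau the model is linear in (a, c): profile over a tau grid by
  # ordinary least squares (always solvable), then refine the best grid
  # point with Levenberg-Marquardt when it converges.
  profile_grid <- exp(seq(log(0.5), log(300), length.out = 80))
  fit_exp <- function(t, yy) {
    best <- NULL
    for (tau0 in unique(c(profile_grid, tau_grid))) {
      X <- cbind(1, exp(-t / tau0))
      cf <- stats::lm.fit(X, yy)$coefficients
      cf[is.na(cf)] <- 0
      pred <- drop(X %*% cf)
      sse <- sum((yy - pred)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(pars = c(a = unname(cf[2L]), tau = tau0,
                              c0 = unname(cf[1L])),
                     sse = sse, pred = pred)
      }
    }
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ a * exp(-t / tau) + c0,
                        start = as.list(best$pars),
                        lower = c(-Inf, 1e-3, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(stats::residuals(fit)^2)
      if (sse < best$sse) {
        best <- list(pars = stats::coef(fit), sse = sse,
                     pred = stats::fitted(fit))
      }
    }
    best
  }
  bic <- function(k, sse, nn) k * log(nn) + nn * log(sse / nn)
  sse_flat <- sum((y - mean(y))^2)
  ex <- fit_exp(t_min, y)
  if (is.null(ex)) stop("fit_flat_vs_exponential: exponential fit did not converge")
  bic_f <- bic(1, sse_flat, n)
  bic_e <- bic(3, ex$sse, n)
  r_obs <- suppressWarnings(stats::cor(y, ex$pred))
  set.seed(seed)
  us <- unique(session)
  tau_b <- r_b <- rep(NA_real_, n_boot)
  for (b in seq_len(n_boot)) {
    ss <- sample(us, length(us), replace = TRUE)
    idx <- unlist(lapply(ss, function(s) which(session == s)))
    eb <- fit_exp(t_min[idx], y[idx])
    if (is.null(eb)) next
    tau_b[b] <- eb$pars[["tau"]]
    r_b[b] <- suppressWarnings(stats::cor(y[idx], eb$pred))
  }
  structure(list(
    model = if (bic_e < bic_f) "exponential" else "flat",
    bic_flat = bic_f, bic_exp = bic_e,
    pars = ex$pars,
    tau_ci = stats::quantile(tau_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    r = r_obs,
    r_ci = stats::quantile(r_b, c(0.025, 0.975), na.rm = TRUE, names = FALSE),
    tau_boot = tau_b
  ), class = "fit_result")
}

#' Reactivation strength of pre-sleep coactivity across post-sleep windows
#'
#' Per target unit, a linear model trained on pre-sleep z-scored ripple
#' population vectors predicts the unit from all other units; the model is
#' applied to ripples in successive 10-minute post-sleep windows and the
#' mean prediction accuracy (Pearson r) across units per window is the
#' reactivation strength. Chance is estimated by cell-identity shuffles of
#' the pre-sleep vectors prior to training and subtracted.
#'
#' @param pv_pre units x events pre-sleep count matrix (one ripple class).
#' @param pv_post units x events post-sleep count matrix (same class).
#' @param post_times_min post-event times (minutes into post-sleep).
#' @param n_shuffle chance shuffles (default 100; 500 in full runs).
#' @param bin_min window (default 10), fitted range (10, 70].
#' @param per_unit return per-unit series instead of the mean (default
#'   FALSE).
#' @param seed RNG seed.
#' @return data frame `t_min`, `strength` (chance-subtracted), `n`; or with
#'   `per_unit` a units x windows matrix (attribute `t_min`).
#' @export
presleep_reactivation_decay <- function(pv_pre, pv_post, post_times_min,
                                        n_shuffle = 100, bin_min = 10,
                                        per_unit = FALSE, seed = 1L) {
  set.seed(seed)
  zpre <- zscore_pvs(pv_pre)
  zpost <- zscore_pvs(pv_post)
  n_u <- nrow(zpre)
  coefs <- function(z) {
    lapply(seq_len(n_u), function(u) {
      X <- cbind(1, t(z[-u, , drop = FALSE]))
      b <- stats::lm.fit(X, z[u, ])$coefficients
      b[is.na(b)] <- 0
      b
    })
  }
  b_true <- coefs(zpre)
  b_null <- lapply(seq_len(n_shuffle), function(s) {
    coefs(zpre[sample.int(n_u), , drop = FALSE])
  })
  edges <- seq(10, 70, by = bin_min)
  bin <- cut(post_times_min, edges, labels = FALSE)
  wins <- sort(unique(bin[!is.na(bin)]))
  acc_mat <- matrix(NA_real_, n_u, length(wins))
  chance_mat <- matrix(NA_real_, n_u, length(wins))
  for (wi in seq_along(wins)) {
    ev <- which(!is.na(bin) & bin == wins[wi])
    if (length(ev) < 5L) next
    Z <- zpost[, ev, drop = FALSE]
    for (u in seq_len(n_u)) {
      X <- cbind(1, t(Z[-u, , drop = FALSE]))
      acc_mat[u, wi] <- suppressWarnings(stats::cor(drop(X %*% b_true[[u]]), Z[u, ]))
      ch <- vapply(b_null, function(bn) {
        suppressWarnings(stats::cor(drop(X %*% bn[[u]]), Z[u, ]))
      }, numeric(1))
      chance_mat[u, wi] <- mean(ch, na.rm = TRUE)
    }
  }
  strength <- acc_mat - chance_mat
  t_mid <- edges[wins] + bin_min / 2
  if (per_unit) {
    attr(strength, "t_min") <- t_mid
    return(strength)
  }
  data.frame(t_min = t_mid,
             strength = colMeans(strength, na.rm = TRUE),
             n = colSums(!is.na(strength)))
}

#' Wake-coactivity reactivation with pre-sleep regressed out
#'
#' Pairwise cofiring (count correlations over events) is computed for
#' pre-sleep, exploration theta cycles, and each 10-minute post-sleep
#' window; per window, post cofiring is regressed on wake cofiring with
#' pre-sleep cofiring as covariate, and the wake coefficient is the
#' reactivation strength.
#'
#' @param pv_pre,theta_counts units x events / units x cycles matrices.
#' @param pv_post units x events post matrix.
#' @param post_times_min post-event times (minutes into post-sleep).
#' @param bin_min window (default 10).
#' @return data frame `t_min`, `beta_wake`, `n_pairs`.
#' @export
wake_reactivation_partial <- function(pv_pre, theta_counts, pv_post,
                                      post_times_min, bin_min = 10) {
  cof <- function(m) {
    C <- suppressWarnings(stats::cor(t(m)))
    C[upper.tri(C)]
  }
  c_pre <- cof(pv_pre)
  c_wake <- cof(theta_counts)
  edges <- seq(10, 70, by = bin_min)
  bin <- cut(post_times_min, edges, labels = FALSE)
  wins <- sort(unique(bin[!is.na(bin)]))
  res <- lapply(wins, function(w) {
    ev <- which(!is.na(bin) & bin == w)
    if (length(ev) < 5L) return(NULL)
    c_post <- cof(pv_post[, ev, drop = FALSE])
    ok <- is.finite(c_post) & is.finite(c_wake) & is.finite(c_pre)
    if (sum(ok) < 10L) return(NULL)
    fit <- stats::lm(c_post[ok] ~ c_wake[ok] + c_pre[ok])
    data.frame(t_min = edges[w] + bin_min / 2,
               beta_wake = stats::coef(fit)[[2L]],
               n_pairs = sum(ok))
  })
  do.call(rbind, res)
}

#' Recent-to-prior balance drift of one session
#'
#' Convenience wrapper running the full balance pipeline on a simulated (or
#' loaded) spike session: population-conditioned coactivity from pre-sleep
#' ripples and exploration theta cycles, the recent/prior transform,
#' per-event balance of post-sleep ripples (scaled to unit SD within the
#' session so sessions are comparable), and the 10-minute drift time course
#' per ripple class.
#'
#' @param session a `spike_session`.
#' @param ripple_classes optional per-event class labels for the session's
#'   events (default: the session's ground-truth classes, standing in for
#'   detector output).
#' @return `drift_series` data frame with an extra `session` column, plus
#'   attributes `balance` (per post event) and `W` (the transform).
#' @export
session_balance_drift <- function(session, ripple_classes = NULL) {
  ev <- session$events
  if (is.null(ripple_classes)) ripple_classes <- ev$true_class
  post <- ev$epoch == "post-sleep"
  pre <- ev$epoch == "pre-sleep"
  a_pre <- population_conditioned_coactivity(
    population_vectors(session, ev$peak_time_s[pre]))$adjacency
  a_th <- population_conditioned_coactivity(
    population_vectors(session, session$theta_cycles$time_s,
                       window_ms = 125))$adjacency
  W <- recent_prior_transform(a_pre, a_th)
  zpost <- zscore_pvs(population_vectors(session, ev$peak_time_s[post]))
  bal <- balance_score(W$W_recent, zpost)
  bal <- bal / stats::sd(bal)
  t_min <- (ev$peak_time_s[post] - session$epochs$start_s[3L]) / 60
  ds <- drift_timecourse(bal, t_min, classes = ripple_classes[post])
  attr(ds, "balance") <- bal
  attr(ds, "W") <- W
  ds
}

#' Coactivity stability score
#'
#' `1 - (r_pre - r_post)` on chance-normalized accuracies; ~1 means the
#' pre-sleep coactivity model transferred unchanged to post-sleep.
#' @param acc_pre,acc_post chance-normalized accuracies.
#' @return numeric vector.
#' @export
stability_score <- function(acc_pre, acc_post) 1 - (acc_pre - acc_post)

#' Feature attribution for drift time courses
#'
#' Linear model of per-bin balance on log time, ripple occurrence frequency
#' (events/min), and population sparsity (mean active-cell proportion), with
#' 20-fold 80/20 cross-validated Pearson-r accuracy. Per feature, shuffles
#' of that feature's values give the accuracy gain (full-model accuracy
#' minus shuffled-feature accuracy) and p = fraction of shuffles with gain
#' below 0.
#'
#' @param balance per-bin values.
#' @param t_min per-bin times (minutes; > 0, log-transformed internally).
#' @param occurrence_freq per-bin ripples/min.
#' @param sparsity per-bin mean active-cell proportion.
#' @param n_shuffles per-feature shuffles (default 1000; 25000 full-scale).
#' @param n_splits CV splits (default 20).
#' @param seed RNG seed.
#' @return data frame per feature: `feature`, `gain`, `p`; attribute
#'   `accuracy` (full model), `chance` (balance-shuffled accuracy band).
#' @export
feature_attribution <- function(balance, t_min, occurrence_freq, sparsity,
                                n_shuffles = 1000, n_splits = 20, seed = 1L) {
  stopifnot(all(t_min > 0))
  X <- cbind(log_time = log(t_min), occ = occurrence_freq, sparse = sparsity)
  if (qr(scale(X))$rank < ncol(X)) warning("feature_attribution: collinear features")
  n <- length(balance)
  set.seed(seed)
  cv_acc <- function(Xm, y) {
    mean(vapply(seq_len(n_splits), function(s) {
      tr <- sample.int(n, max(2L, round(0.8 * n)))
      te <- setdiff(seq_len(n), tr)
      if (length(te) == 0L) return(NA_real_)
      b <- stats::lm.fit(cbind(1, Xm[tr, , drop = FALSE]), y[tr])$coefficients
      b[is.na(b)] <- 0
      pred <- drop(cbind(1, Xm[te, , drop = FALSE]) %*% b)
      if (stats::sd(pred) == 0 || stats::sd(y[te]) == 0) return(0)
      stats::cor(pred, y[te])
    }, numeric(1)), na.rm = TRUE)
  }
  acc_full <- cv_acc(X, balance)
  chance <- vapply(seq_len(min(n_shuffles, 200L)), function(s) {
    cv_acc(X, sample(balance))
  }, numeric(1))
  res <- lapply(colnames(X), function(f) {
    gains <- vapply(seq_len(n_shuffles), function(s) {
      Xs <- X
      Xs[, f] <- sample(Xs[, f])
      acc_full - cv_acc(Xs, balance)
    }, numeric(1))
    data.frame(feature = f, gain = mean(gains), p = mean(gains < 0))
  })
  out <- do.call(rbind, res)
  attr(out, "accuracy") <- acc_full
  attr(out, "chance") <- stats::quantile(chance, c(0.025, 0.975), names = FALSE)
  out
}

#' Sublayer-specific decay-rate comparison
#'
#' Per sublayer, reactivation strength is regressed on log time over
#' bootstrapped session subsets; per bootstrap a chance slope is obtained by
#' circularly shuffling the time labels within each session series. The
#' z-scored slope (observed mean versus the circular-shuffle distribution)
#' is reported per sublayer.
#'
#' @param strength units x windows matrix of per-unit reactivation series.
#' @param t_min window centres (minutes).
#' @param sublayer per-unit sublayer labels ("deep"/"superficial").
#' @param session per-unit session ids.
#' @param n_boot bootstrap iterations (default 2000).
#' @param min_units minimum units per sublayer (default 5).
#' @param seed RNG seed.
#' @return data frame per sublayer: `sublayer`, `slope`, `z`.
#' @export
sublayer_decay_compare <- function(strength, t_min, sublayer, session,
                                   n_boot = 2000, min_units = 5L, seed = 1L) {
  set.seed(seed)
  lt <- log(t_min)
  res <- lapply(c("deep", "superficial"), function(sl) {
    rows <- which(!is.na(sublayer) & sublayer == sl)
    if (length(rows) < min_units) return(NULL)
    us <- unique(session[rows])
    slope_of <- function(rr, shift = FALSE) {
      Y <- strength[rr, , drop = FALSE]
      if (shift) {
        Y <- t(apply(Y, 1L, function(v) {
          k <- sample.int(length(v), 1L)
          v[((seq_along(v) - 1L + k) %% length(v)) + 1L]
        }))
      }
      y <- as.vector(t(Y))
      x <- rep(lt, length(rr))
      ok <- is.finite(y)
      if (sum(ok) < 4L) return(NA_real_)
      stats::cov(x[ok], y[ok]) / stats::var(x[ok])
    }
    bo <- bn <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      ss <- sample(us, length(us), replace = TRUE)
      rr <- unlist(lapply(ss, function(s) rows[session[rows] == s]))
      bo[b] <- slope_of(rr)
      bn[b] <- slope_of(rr, shift = TRUE)
    }
    data.frame(sublayer = sl, slope = mean(bo, na.rm = TRUE),
               z = (mean(bo, na.rm = TRUE) - mean(bn, na.rm = TRUE)) /
                 stats::sd(bn, na.rm = TRUE))
  })
  do.call(rbind, res)
}
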