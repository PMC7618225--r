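#' Peri-event time histogram
#'
#' Raw firing rate per unit and lag bin around event peaks (default
#' +/-200 ms, 0.8-ms bins), smoothed with a Gaussian kernel (SD 5 ms).
#' Intended for isolated events only.
#'
#' @param spikes data frame `unit_id`, `spike_time_s`.
#' @param event_times_s event peaks (s).
#' @param unit_ids units to include (default: all in `spikes`).
#' @param window_ms half-window (default 200).
#' @param bin_ms bin width (default 0.8).
#' @param smooth_sd_ms Gaussian smoothing SD (default 5; 0 disables).
#' @return list of class `peth`: `rate` (units x bins, Hz), `lags_ms`,
#'   `n_events`, `bin_ms`.
#' @export
compute_peth <- function(spikes, event_times_s, unit_ids = NULL,
                         window_ms = 200, bin_ms = 0.8, smooth_sd_ms = 5) {
  if (length(event_times_s) == 0L) stop("compute_peth: no events")
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  edges <- seq(-window_ms / 1000, window_ms / 1000, by = bin_ms / 1000)
  n_bins <- length(edges) - 1L
  counts <- matrix(0, length(unit_ids), n_bins,
                   dimnames = list(unit_ids, NULL))
  sel <- spikes$unit_id %in% unit_ids
  st <- spikes$spike_time_s[sel]
  su <- match(spikes$unit_id[sel], unit_ids)
  for (t0 in event_times_s) {
    rel <- st - t0
    inw <- which(rel >= edges[1L] & rel < edges[length(edges)])
    if (length(inw) == 0L) next
    b <- findInterval(rel[inw], edges)
    for (k in seq_along(inw)) {
      counts[su[inw[k]], b[k]] <- counts[su[inw[k]], b[k]] + 1
    }
  }
  rate <- counts / (length(event_times_s) * bin_ms / 1000)
  if (smooth_sd_ms > 0) {
    rate <- t(apply(rate, 1L, gauss_smooth, sd_samples = smooth_sd_ms / bin_ms))
  }
  structure(list(rate = rate,
                 lags_ms = (edges[-1L] + edges[-length(edges)]) / 2 * 1000,
                 n_events = length(event_times_s), bin_ms = bin_ms),
            class = "peth")
}

#' Z-score a PETH against a reference PETH
#'
#' Normalizes each unit's rate by its mean and SD in the reference PETH
#' (conventionally the radiatum-sink-event PETH), then smooths again with
#' the same Gaussian kernel.
#' @param peth,ref_peth `peth` objects with matching units/bins.
#' @return `peth` object with z-scored `rate`.
#' @export
zscore_peth <- function(peth, ref_peth, smooth_sd_ms = 5) {
  m <- rowMeans(ref_peth$rate)
  s <- apply(ref_peth$rate, 1L, stats::sd)
  s[s == 0] <- 1
  z <- (peth$rate - m) / s
  if (smooth_sd_ms > 0) {
    z <- t(apply(z, 1L, gauss_smooth, sd_samples = smooth_sd_ms / peth$bin_ms))
  }
  out <- peth
  out$rate <- z
  out
}

#' Peak rate around the event peak
#' @param peth a `peth` object.
#' @param half_ms half-window around lag 0 (default 25 ms).
#' @return per-unit maximum rate within +/-`half_ms`.
#' @export
peth_peak_rate <- function(peth, half_ms = 25) {
  sel <- abs(peth$lags_ms) <= half_ms
  apply(peth$rate[, sel, drop = FALSE], 1L, max)
}

#' Log-ratio firing-rate change from baseline
#'
#' `log10(rate_ripple / rate_baseline)`; the baseline window is -200 to
#' -100 ms before the peak. Units with zero baseline get `NA` (excluded,
#' with a message).
#' @param rate_ripple,rate_baseline per-unit rates (Hz).
#' @return per-unit log10 ratio.
#' @export
delta_log_rate <- function(rate_ripple, rate_baseline) {
  bad <- rate_baseline <= 0
  if (any(bad)) message(sprintf("delta_log_rate: %d unit(s) with zero baseline excluded", sum(bad)))
  out <- rep(NA_real_, length(rate_ripple))
  out[!bad] <- log10(rate_ripple[!bad] / rate_baseline[!bad])
  out
}

#' Ripple-phase coupling of a unit
#'
#' Spike phases are binned into 24 equal bins over [0, 2*pi); the preferred
#' phase is the angular component of the mean resultant vector of the binned
#' distribution and the coherence its magnitude.
#'
#' @param spike_phases spike phases (radians).
#' @param n_bins phase bins (default 24).
#' @return list `preferred_phase` (in [0, 2*pi)), `coherence` in [0, 1];
#'   both `NA` when no spikes.
#' @export
ripple_phase_coupling <- function(spike_phases, n_bins = 24) {
  if (length(spike_phases) == 0L) {
    return(list(preferred_phase = NA_real_, coherence = NA_real_))
  }
  ph <- spike_phases %% (2 * pi)
  edges <- seq(0, 2 * pi, length.out = n_bins + 1L)
  p <- tabulate(findInterval(ph, edges, rightmost.closed = TRUE), n_bins)
  p <- p / sum(p)
  centres <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  v <- sum(p * exp(1i * centres))
  list(preferred_phase = Arg(v) %% (2 * pi), coherence = Mod(v))
}

#' Interneuron-to-principal firing ratio
#'
#' `log10(mean(rates_int) / mean(rates_pyr))`.
#' @param rates_int,rates_pyr per-unit mean event rates (Hz); both groups
#'   non-empty with positive means.
#' @return scalar, `NA` when a mean is non-positive.
#' @export
int_to_pyr_ratio <- function(rates_int, rates_pyr) {
  mi <- mean(rates_int); mp <- mean(rates_pyr)
  if (!is.finite(mi) || !is.finite(mp) || mi <= 0 || mp <= 0) return(NA_real_)
  log10(mi / mp)
}

#' Margin-preserving shuffle of a spike-count matrix
#'
#' Randomizes which unit fired each spike while conserving both every unit's
#' total spike count (row sums) and every event's population count (column
#' sums) exactly: the full list of per-spike unit labels is permuted and
#' reassigned to events in their original per-event counts.
#'
#' @param counts nonnegative integer units x events matrix.
#' @param seed optional RNG seed.
#' @return shuffled matrix with identical row and column sums.
#' @export
margin_preserving_shuffle <- function(counts, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rs <- rowSums(counts)
  cs <- colSums(counts)
  total <- sum(rs)
  if (total == 0L) return(counts)
  units <- rep.int(seq_len(nrow(counts)), rs)
  units <- units[sample.int(total)]
  ev <- rep.int(seq_len(ncol(counts)), cs)
  tab <- table(factor(units, levels = seq_len(nrow(counts))),
               factor(ev, levels = seq_len(ncol(counts))))
  out <- matrix(as.integer(tab), nrow(counts), ncol(counts),
                dimnames = dimnames(counts))
  out
}

#' Plug-in mutual information of a confusion table (bits)
#' @param conf contingency table of true x predicted labels.
#' @return scalar >= 0.
#' @export
confusion_mi <- function(conf) {
  p <- conf / sum(conf)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
  }
  max(0, s)
}

# Ridge-stabilized binary logistic regression (IRLS); weak fixed L2 keeps
# separable folds finite without materially shrinking coefficients.
logistic_fit <- function(X, y, lambda = 1e-3, n_iter = 50) {
  X1 <- cbind(1, X)
  b <- numeric(ncol(X1))
  pen <- diag(c(0, rep(lambda, ncol(X))))
  for (it in seq_len(n_iter)) {
    eta <- drop(X1 %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-8)
    z <- eta + (y - mu) / w
    H <- crossprod(X1 * w, X1) + pen
    b_new <- solve(H, crossprod(X1 * w, z))
    if (max(abs(b_new - b)) < 1e-8) { b <- b_new; break }
    b <- b_new
  }
  drop(b)
}

#' Decode ripple type from population vectors
#'
#' Logistic-regression decoding of the (binary) ripple class from z-scored
#' population vectors. Per permutation a random subset of `n_cells` units is
#' drawn, classes are balanced by downsampling the larger class, and the
#' model is cross-validated over `n_cv` random 80/20 splits; accuracy is the
#' plug-in mutual information (bits) of the pooled test confusion table.
#' The control repeats the procedure on margin-preserving shuffles of the
#' counts, which conserve unit rates and per-event population counts while
#' destroying coactivity.
#'
#' @param counts units x events spike-count matrix.
#' @param labels two-class event labels.
#' @param n_cells units per model (default 15).
#' @param n_perm permutations (default 200).
#' @param n_cv cross-validation splits per permutation (default 20).
#' @param min_events_per_class inclusion rule (default 250; lower it only
#'   for small fixtures).
#' @param seed RNG seed.
#' @return list: `mi_observed`, `mi_control` (per-permutation vectors),
#'   `mean_observed`, `mean_control`.
#' @export
decode_ripple_type <- function(counts, labels, n_cells = 15, n_perm = 200,
                               n_cv = 20, min_events_per_class = 250,
                               seed = 1L) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L) stop("decode_ripple_type: need exactly 2 classes")
  tab <- table(labels)
  if (nrow(counts) < n_cells) stop("decode_ripple_type: fewer units than n_cells")
  if (any(tab < min_events_per_class)) {
    stop(sprintf("decode_ripple_type: need >= %d events per class", min_events_per_class))
  }
  set.seed(seed)
  run_once <- function(cmat) {
    cells <- sample.int(nrow(cmat), n_cells)
    n_min <- min(tab)
    idx <- unlist(lapply(classes, function(cl) sample(which(labels == cl), n_min)))
    y <- as.integer(labels[idx] == classes[2L])
    X <- zscore_pvs(cmat[cells, idx, drop = FALSE])
    X <- t(X)
    n <- length(y)
    conf <- matrix(0, 2, 2)
    for (s in seq_len(n_cv)) {
      tr <- sample.int(n, round(0.8 * n))
      te <- setdiff(seq_len(n), tr)
      b <- logistic_fit(X[tr, , drop = FALSE], y[tr])
      pred <- as.integer(drop(cbind(1, X[te, , drop = FALSE]) %*% b) > 0)
      conf <- conf + table(factor(y[te], levels = 0:1),
                           factor(pred, levels = 0:1))
    }
    confusion_mi(conf)
  }
  mi_obs <- vapply(seq_len(n_perm), function(i) run_once(counts), numeric(1))
  mi_ctl <- vapply(seq_len(n_perm), function(i) {
    run_once(margin_preserving_shuffle(counts))
  }, numeric(1))
  list(mi_observed = mi_obs, mi_control = mi_ctl,
       mean_observed = mean(mi_obs), mean_control = mean(mi_ctl))
}

#' Temporal-pattern decoding features
#'
#' Per unit, the event x lag matrix of its smoothed (SD 3 ms) peri-event
#' spike pattern is reduced to its first two principal components; the
#' per-event component strengths of all units are concatenated and z-scored
#' per column, giving an events x (2 * n_units) feature matrix for the
#' ripple-type decoder.
#'
#' @param spikes data frame `unit_id`, `spike_time_s`.
#' @param event_times_s isolated event peaks (s).
#' @param unit_ids units (default all in `spikes`).
#' @param window_ms half-window (default 200).
#' @param bin_ms bin width (default 4).
#' @param smooth_sd_ms smoothing SD (default 3).
#' @return events x (2 n_units) matrix; attribute `degenerate_units` lists
#'   units whose component strengths had zero variance (columns left 0).
#' @export
temporal_pattern_features <- function(spikes, event_times_s, unit_ids = NULL,
                                      window_ms = 200, bin_ms = 4,
                                      smooth_sd_ms = 3) {
  if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  edges <- seq(-window_ms / 1000, window_ms / 1000, by = bin_ms / 1000)
  n_bins <- length(edges) - 1L
  n_ev <- length(event_times_s)
  feats <- matrix(0, n_ev, 2L * length(unit_ids))
  degen <- integer(0)
  for (u in seq_along(unit_ids)) {
    st <- spikes$spike_time_s[spikes$unit_id == unit_ids[u]]
    M <- matrix(0, n_ev, n_bins)
    for (e in seq_len(n_ev)) {
      rel <- st - event_times_s[e]
      inw <- rel[rel >= edges[1L] & rel < edges[length(edges)]]
      if (length(inw)) M[e, ] <- tabulate(findInterval(inw, edges), n_bins)
    }
    M <- t(apply(M, 1L, gauss_smooth, sd_samples = smooth_sd_ms / bin_ms))
    sds <- apply(M, 2L, stats::sd)
    if (all(sds == 0)) { degen <- c(degen, unit_ids[u]); next }
    p <- stats::prcomp(M, center = TRUE, scale. = FALSE)
    k <- min(2L, ncol(p$x))
    sc <- p$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      s <- stats::sd(sc[, j])
      if (s == 0) { degen <- c(degen, unit_ids[u]); next }
      feats[, 2L * (u - 1L) + j] <- (sc[, j] - mean(sc[, j])) / s
    }
  }
  attr(feats, "degenerate_units") <- unique(degen)
  feats
}

#' Window-mean correlation between population responses
#'
#' Pearson correlation across cells of mean z-scored PETH rates in two
#' +/-`half_ms` windows, with a bootstrap CI over cells. Used to relate the
#' population active before lacunosum-moleculare-sink ripples to that active
#' in radiatum-sink ripples.
#' @param zpeth_a,zpeth_b z-scored `peth` objects over the same units.
#' @param centre_a_ms,centre_b_ms window centres (ms relative to peak).
#' @param half_ms half-window (default 25).
#' @param n_boot bootstrap resamples over cells (default 10000).
#' @param seed RNG seed.
#' @return list `r`, `ci` (2.5/97.5 percentiles).
#' @export
peth_window_correlation <- function(zpeth_a, zpeth_b, centre_a_ms, centre_b_ms,
                                    half_ms = 25, n_boot = 10000, seed = 1L) {
  wa <- abs(zpeth_a$lags_ms - centre_a_ms) <= half_ms
  wb <- abs(zpeth_b$lags_ms - centre_b_ms) <= half_ms
  a <- rowMeans(zpeth_a$rate[, wa, drop = FALSE])
  b <- rowMeans(zpeth_b$rate[, wb, drop = FALSE])
  r <- stats::cor(a, b)
  set.seed(seed)
  n <- length(a)
  boot <- vapply(seq_len(n_boot), function(i) {
    ix <- sample.int(n, n, replace = TRUE)
    suppressWarnings(stats::cor(a[ix], b[ix]))
  }, numeric(1))
  list(r = r, ci = stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE,
                                   names = FALSE))
}
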