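#' Dentate-gyrus molecular-layer CSD energy
#'
#' Mean rectified CSD across the molecular-layer channels, smoothed with a
#' 1-s median filter, downsampled to 5 Hz by block averaging, z-scored.
#'
#' @param csd interior-channel x time CSD matrix.
#' @param dg_channels row indices (into the CSD matrix) of the molecular
#'   layer.
#' @param fs CSD sampling rate (Hz).
#' @param fs_out output rate (default 5 Hz).
#' @return numeric series; attribute `degenerate` set (and values 0) when
#'   the raw energy is constant.
#' @export
dg_energy <- function(csd, dg_channels, fs, fs_out = 5) {
  if (length(dg_channels) == 0L) stop("dg_energy: no DG molecular channels")
  e <- colMeans(abs(csd[dg_channels, , drop = FALSE]))
  k <- round(fs)
  if (k %% 2L == 0L) k <- k + 1L
  e <- stats::runmed(e, k)
  blk <- round(fs / fs_out)
  n_out <- floor(length(e) / blk)
  e5 <- colMeans(matrix(e[seq_len(n_out * blk)], nrow = blk))
  s <- stats::sd(e5)
  if (s == 0 || !is.finite(s)) {
    out <- rep(0, n_out)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- (e5 - mean(e5)) / s
  attr(out, "degenerate") <- FALSE
  out
}

# --- two-state Gaussian HMM ------------------------------------------------
# Baum-Welch with emissions initialized from a two-component GMM; Viterbi
# decoding. Small and self-contained.

hmm_forward_backward <- function(x, mu, sd2, A, p0) {
  n <- length(x); K <- 2L
  B <- cbind(stats::dnorm(x, mu[1], sd2[1]), stats::dnorm(x, mu[2], sd2[2]))
  B[B < 1e-300] <- 1e-300
  alpha <- matrix(0, n, K); cvec <- numeric(n)
  alpha[1, ] <- p0 * B[1, ]; cvec[1] <- sum(alpha[1, ]); alpha[1, ] <- alpha[1, ] / cvec[1]
  for (t in 2:n) {
    alpha[t, ] <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(alpha[t, ]); alpha[t, ] <- alpha[t, ] / cvec[t]
  }
  beta <- matrix(0, n, K); beta[n, ] <- 1
  for (t in (n - 1):1) {
    beta[t, ] <- A %*% (B[t + 1, ] * beta[t + 1, ]) / cvec[t + 1]
  }
  gamma <- alpha * beta; gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, loglik = sum(log(cvec)), B = B, alpha = alpha,
       beta = beta, cvec = cvec)
}

hmm_fit_2state <- function(x, mu0, sd0, n_iter = 50, n_restarts = 10,
                           seed = 1L) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    A <- matrix(stats::runif(4, 0.05, 0.95), 2)
    A <- A / rowSums(A)
    mu <- mu0; sd2 <- sd0; p0 <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(n_iter)) {
      fb <- hmm_forward_backward(x, mu, sd2, A, p0)
      g <- fb$gamma
      # transition expectations
      n <- length(x)
      xi <- matrix(0, 2, 2)
      for (i in 1:2) for (j in 1:2) {
        xi[i, j] <- sum(fb$alpha[1:(n - 1), i] * A[i, j] * fb$B[2:n, j] *
                          fb$beta[2:n, j] / fb$cvec[2:n])
      }
      A <- xi / rowSums(xi)
      p0 <- g[1, ]
      mu <- colSums(g * x) / colSums(g)
      sd2 <- sqrt(colSums(g * (outer(x, mu, "-")^2)) / colSums(g))
      sd2 <- pmax(sd2, 1e-3)
      if (abs(fb$loglik - ll_old) < 1e-6) break
      ll_old <- fb$loglik
    }
    if (is.null(best) || ll_old > best$loglik) {
      best <- list(mu = mu, sd = sd2, A = A, p0 = p0, loglik = ll_old)
    }
  }
  best
}

hmm_viterbi <- function(x, mu, sd2, A, p0) {
  n <- length(x)
  logB <- cbind(stats::dnorm(x, mu[1], sd2[1], log = TRUE),
                stats::dnorm(x, mu[2], sd2[2], log = TRUE))
  lA <- log(A)
  delta <- matrix(-Inf, n, 2); psi <- matrix(0L, n, 2)
  delta[1, ] <- log(p0) + logB[1, ]
  for (t in 2:n) {
    for (j in 1:2) {
      v <- delta[t - 1, ] + lA[, j]
      psi[t, j] <- which.max(v)
      delta[t, j] <- max(v) + logB[t, j]
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  for (t in (n - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Infer Up/Down states from a molecular-layer energy series
#'
#' A two-component Gaussian mixture initializes the emission parameters of a
#' two-state Gaussian HMM (uniform transition initialization, 10 random
#' restarts, best likelihood kept); the state sequence is decoded by
#' Viterbi. The state with the higher emission mean is Up.
#'
#' @param energy z-scored 5-Hz energy series (>= 100 samples).
#' @param fs series sampling rate (default 5 Hz).
#' @param seed RNG seed for the restarts.
#' @param min_epochs sessions with fewer detected Up or Down epochs than
#'   this are flagged as not passing the inclusion rule (default 100).
#' @return list of class `state_sequence`: `states` (per-sample "Up"/"Down"),
#'   `epochs` (data frame state/start_s/end_s/duration_s), `low_confidence`
#'   (emission separation < 0.5 pooled SD), `includable`, `model`.
#' @export
infer_updown <- function(energy, fs = 5, seed = 1L, min_epochs = 100L) {
  x <- as.numeric(energy)
  if (length(x) < 100L) stop("infer_updown: need at least 100 samples")
  gsel <- mclust::Mclust(x, G = 1:2, modelNames = "V", verbose = FALSE)
  unimodal <- gsel$G == 1L
  gmm <- if (gsel$G == 2L) gsel else {
    mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  }
  mu0 <- as.numeric(gmm$parameters$mean)
  sd0 <- sqrt(as.numeric(gmm$parameters$variance$sigmasq))
  if (length(sd0) == 1L) sd0 <- rep(sd0, 2L)
  fit <- hmm_fit_2state(x, mu0, sd0, seed = seed)
  path <- hmm_viterbi(x, fit$mu, fit$sd, fit$A, fit$p0)
  up_state <- which.max(fit$mu)
  states <- ifelse(path == up_state, "Up", "Down")
  sep <- abs(diff(fit$mu)) / mean(fit$sd)
  if (unimodal) sep <- 0  # one-component mixture preferred: no separability
  r <- rle(states)
  ends <- cumsum(r$lengths)
  epochs <- data.frame(state = r$values,
                       start_s = (ends - r$lengths) / fs,
                       end_s = ends / fs,
                       duration_s = r$lengths / fs,
                       stringsAsFactors = FALSE)
  n_up <- sum(epochs$state == "Up"); n_dn <- sum(epochs$state == "Down")
  structure(list(states = states, epochs = epochs,
                 low_confidence = sep < 0.5,
                 includable = n_up >= min_epochs && n_dn >= min_epochs,
                 model = fit, fs_hz = fs),
            class = "state_sequence")
}

#' LM-type ripple proportion by Up/Down state and energy bin
#'
#' Each classified ripple is assigned the state and energy bin at its peak;
#' the proportion of lacunosum-moleculare-sink events among classified
#' (Rad + LM) events is reported per state and per energy bin. Ripples
#' falling in state epochs shorter than `min_epoch_s` are excluded.
#' Intermediate events can optionally enter the denominator.
#'
#' @param peak_times_s ripple peaks (s).
#' @param labels ripple class labels ("Rad"/"intermediate"/"LM").
#' @param state_seq a `state_sequence` from [infer_updown()].
#' @param energy the energy series the states were inferred from.
#' @param n_bins energy bins, equally spaced over [-2.5, 2.5] z (default 10).
#' @param min_epoch_s minimum flanking epoch duration (default 0.5 s).
#' @param include_intermediate include intermediate events in the
#'   denominator (default FALSE: proportion = LM / (LM + Rad)).
#' @return list: `by_state` (data frame state/n/prop_lm), `by_energy`
#'   (bin centre/n/prop_lm; empty bins are `NA`).
#' @export
lm_proportion_by_state <- function(peak_times_s, labels, state_seq, energy,
                                   n_bins = 10, min_epoch_s = 0.5,
                                   include_intermediate = FALSE) {
  fs <- state_seq$fs_hz
  idx <- pmin(pmax(floor(peak_times_s * fs) + 1L, 1L), length(state_seq$states))
  st <- state_seq$states[idx]
  en <- energy[idx]
  ep <- state_seq$epochs
  ep_of <- findInterval(peak_times_s, ep$start_s)
  ok_dur <- ep$duration_s[pmin(pmax(ep_of, 1L), nrow(ep))] >= min_epoch_s
  denom <- if (include_intermediate) rep(TRUE, length(labels)) else labels %in% c("Rad", "LM")
  use <- ok_dur & denom
  by_state <- do.call(rbind, lapply(c("Up", "Down"), function(s) {
    sel <- use & st == s
    data.frame(state = s, n = sum(sel),
               prop_lm = if (sum(sel) > 0) mean(labels[sel] == "LM") else NA_real_)
  }))
  edges <- seq(-2.5, 2.5, length.out = n_bins + 1L)
  bin <- cut(en, edges, include.lowest = TRUE, labels = FALSE)
  by_energy <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- use & !is.na(bin) & bin == b
    data.frame(bin_centre = (edges[b] + edges[b + 1L]) / 2, n = sum(sel),
               prop_lm = if (sum(sel) > 0) mean(labels[sel] == "LM") else NA_real_)
  }))
  list(by_state = by_state, by_energy = by_energy)
}

#' Ripple chains
#'
#' Maximal runs of events whose successive inter-event gaps are below
#' `max_gap_ms`.
#' @param peak_times_s sorted event peaks (s).
#' @param max_gap_ms maximum within-chain gap (default 250 ms).
#' @return list: `chain_id` per event, `lengths` (per chain),
#'   `histogram` (data frame length/count).
#' @export
ripple_chains <- function(peak_times_s, max_gap_ms = 250) {
  n <- length(peak_times_s)
  if (n == 0L) return(list(chain_id = integer(0), lengths = integer(0),
                           histogram = data.frame(length = integer(0),
                                                  count = integer(0))))
  gap <- diff(peak_times_s)
  new_chain <- c(TRUE, gap >= max_gap_ms / 1000)
  chain_id <- cumsum(new_chain)
  lengths <- as.integer(table(chain_id))
  h <- table(lengths)
  list(chain_id = chain_id, lengths = lengths,
       histogram = data.frame(length = as.integer(names(h)),
                              count = as.integer(h)))
}

#' Ripple-type transition matrix with shuffle normalization
#'
#' First-order Markov transition probabilities over within-chain consecutive
#' event pairs, plus a normalized version where each entry has the mean of
#' `n_shuffle` label permutations (class counts preserved) subtracted.
#'
#' @param labels ripple class labels, one per event.
#' @param chain_id chain membership per event (from [ripple_chains()]).
#' @param classes state space (default Rad/intermediate/LM).
#' @param n_shuffle label shuffles (default 1000).
#' @param seed RNG seed.
#' @return list: `raw` (rows sum to 1 where observed), `normalized`,
#'   `n_pairs`.
#' @export
transition_matrix <- function(labels, chain_id,
                              classes = c("Rad", "intermediate", "LM"),
                              n_shuffle = 1000, seed = 1L) {
  count_mat <- function(lab) {
    m <- matrix(0, length(classes), length(classes),
                dimnames = list(classes, classes))
    from <- lab[-length(lab)]; to <- lab[-1L]
    same <- chain_id[-length(chain_id)] == chain_id[-1L]
    for (k in which(same)) m[from[k], to[k]] <- m[from[k], to[k]] + 1
    m
  }
  norm_rows <- function(m) {
    rs <- rowSums(m)
    out <- m
    out[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
    out
  }
  cm <- count_mat(labels)
  if (sum(cm) == 0) stop("transition_matrix: no within-chain pairs")
  raw <- norm_rows(cm)
  set.seed(seed)
  acc <- matrix(0, length(classes), length(classes))
  for (s in seq_len(n_shuffle)) {
    acc <- acc + norm_rows(count_mat(sample(labels)))
  }
  list(raw = raw, normalized = raw - acc / n_shuffle, n_pairs = sum(cm))
}

#' Ripple occurrence profile over normalized NREM time
#'
#' Each NREM bout of at least `min_bout_s` is divided into `n_bins` equal
#' bins of normalized time; per bout and ripple type the proportion of that
#' type's events per bin is computed. The concatenated proportions are
#' correlated with bin centres and tested against bin-label permutations
#' within bouts.
#'
#' @param peak_times_s ripple peaks (s).
#' @param labels class per ripple.
#' @param bouts data frame with `start_s`, `end_s` of NREM bouts.
#' @param n_bins bins per bout (default 5).
#' @param n_shuffle permutations (default 10000).
#' @param min_bout_s minimum bout duration (default 10 s).
#' @param seed RNG seed.
#' @return data frame per type: `type`, `cor`, `p`, plus attribute
#'   `profiles` (type -> bout x bin proportion matrices).
#' @export
nrem_occurrence_profile <- function(peak_times_s, labels, bouts, n_bins = 5,
                                    n_shuffle = 10000, min_bout_s = 10,
                                    seed = 1L) {
  bouts <- bouts[bouts$end_s - bouts$start_s >= min_bout_s, , drop = FALSE]
  types <- setdiff(unique(labels), NA)
  profs <- list()
  for (ty in types) {
    rows <- list()
    for (b in seq_len(nrow(bouts))) {
      sel <- labels == ty & peak_times_s >= bouts$start_s[b] &
        peak_times_s < bouts$end_s[b]
      if (sum(sel) == 0L) next
      u <- (peak_times_s[sel] - bouts$start_s[b]) /
        (bouts$end_s[b] - bouts$start_s[b])
      bin <- pmin(floor(u * n_bins) + 1L, n_bins)
      cnt <- tabulate(bin, n_bins)
      rows[[length(rows) + 1L]] <- cnt / sum(cnt)
    }
    if (length(rows)) profs[[ty]] <- do.call(rbind, rows)
  }
  set.seed(seed)
  centres <- (seq_len(n_bins) - 0.5) / n_bins
  res <- lapply(names(profs), function(ty) {
    P <- profs[[ty]]
    y <- as.vector(t(P))
    x <- rep(centres, nrow(P))
    obs <- stats::cor(x, y)
    null <- vapply(seq_len(n_shuffle), function(i) {
      ys <- as.vector(apply(P, 1L, function(r) r[sample.int(n_bins)]))
      stats::cor(x, ys)
    }, numeric(1))
    p <- mean(abs(null) >= abs(obs))
    data.frame(type = ty, cor = obs, p = p)
  })
  out <- do.call(rbind, res)
  attr(out, "profiles") <- profs
  out
}
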