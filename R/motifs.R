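#' Marcenko-Pastur significance threshold
#'
#' Upper eigenvalue edge `(1 + sqrt(n_units / n_events))^2` of the
#' correlation spectrum expected from uncorrelated data; correlation-matrix
#' eigenvalues above it mark significant coactivity components.
#' @param n_units,n_events matrix dimensions.
#' @return scalar threshold.
#' @export
mp_threshold <- function(n_units, n_events) (1 + sqrt(n_units / n_events))^2

# Symmetric fixed-point FastICA with tanh contrast on whitened data
# (rows = components). Returns the unmixing matrix W (orthonormal rows).
fastica_symm <- function(Y, n_iter = 200, tol = 1e-6) {
  m <- nrow(Y)
  W <- matrix(stats::rnorm(m * m), m)
  orth <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- orth(W)
  for (it in seq_len(n_iter)) {
    WX <- W %*% Y
    G <- tanh(WX)
    Gp <- 1 - G^2
    W_new <- G %*% t(Y) / ncol(Y) - diag(rowMeans(Gp), m) %*% W
    W_new <- orth(W_new)
    if (max(abs(abs(rowSums(W_new * W)) - 1)) < tol) { W <- W_new; break }
    W <- W_new
  }
  W
}

# negentropy proxy used to rank restarts
negentropy_tanh <- function(Y) {
  sum((rowMeans(log(cosh(Y))) - 0.3745672)^2)
}

#' Extract coactivity motifs by PCA/ICA
#'
#' The unit x event count matrix is z-scored per unit; the number of
#' significant motifs is the number of correlation-matrix eigenvalues above
#' the Marcenko-Pastur threshold. Independent component analysis (symmetric
#' FastICA, tanh contrast, 10 restarts keeping the highest negentropy) is
#' run on the data projected onto the significant subspace. Each motif is a
#' unit-length weight vector over units with its sign fixed so the
#' largest-magnitude weight is positive.
#'
#' @param counts units x events spike-count matrix (>= 10 units).
#' @param n_restarts ICA restarts (default 10).
#' @param seed RNG seed.
#' @return list of class `motif_set`: `weights` (units x n_motifs),
#'   `threshold`, `eigenvalues`, `n_motifs`, `activations`
#'   (n_motifs x events), `z` (the z-scored matrix used).
#' @export
extract_motifs <- function(counts, n_restarts = 10, seed = 1L) {
  if (nrow(counts) < 10L) stop("extract_motifs: need >= 10 units")
  if (ncol(counts) <= nrow(counts)) {
    warning("extract_motifs: fewer events than units; threshold unreliable")
  }
  z <- zscore_pvs(counts)
  n_u <- nrow(z); n_e <- ncol(z)
  C <- tcrossprod(z) / (n_e - 1L)
  eig <- eigen(C, symmetric = TRUE)
  thr <- mp_threshold(n_u, n_e)
  n_sig <- sum(eig$values > thr)
  if (n_sig == 0L) {
    return(structure(list(weights = matrix(0, n_u, 0), threshold = thr,
                          eigenvalues = eig$values, n_motifs = 0L,
                          activations = matrix(0, 0, n_e), z = z),
                     class = "motif_set"))
  }
  V <- eig$vectors[, seq_len(n_sig), drop = FALSE]
  Y <- t(V) %*% z                       # projected data, n_sig x events
  Y <- Y / sqrt(pmax(eig$values[seq_len(n_sig)], 1e-12))  # whiten
  set.seed(seed)
  if (n_sig == 1L) {
    W <- matrix(1, 1, 1)
  } else {
    best <- NULL; best_ne <- -Inf
    for (r in seq_len(n_restarts)) {
      W_r <- fastica_symm(Y)
      ne <- negentropy_tanh(W_r %*% Y)
      if (ne > best_ne) { best <- W_r; best_ne <- ne }
    }
    W <- best
  }
  weights <- V %*% t(W)                 # units x n_sig
  weights <- apply(weights, 2L, function(w) {
    w <- w / sqrt(sum(w^2))
    if (w[which.max(abs(w))] < 0) -w else w
  })
  weights <- matrix(weights, n_u)
  activations <- t(weights) %*% z
  structure(list(weights = weights, threshold = thr, eigenvalues = eig$values,
                 n_motifs = n_sig, activations = activations, z = z),
            class = "motif_set")
}

#' Motif activation strength in an event
#'
#' Inner product between the motif weight vector and a z-scored population
#' vector; to remove a neuron's own influence its weight can be zeroed
#' before projecting.
#'
#' @param motif weight vector over units.
#' @param pv z-scored population vector (or units x events matrix).
#' @param exclude_unit optional unit index whose weight is set to 0.
#' @return scalar (or vector over events).
#' @export
motif_activation <- function(motif, pv, exclude_unit = NULL) {
  if (!is.null(exclude_unit)) motif[exclude_unit] <- 0
  if (is.matrix(pv)) {
    if (nrow(pv) != length(motif)) stop("motif_activation: dimension mismatch")
    return(drop(motif %*% pv))
  }
  if (length(pv) != length(motif)) stop("motif_activation: dimension mismatch")
  sum(motif * pv)
}

#' Units significantly contributing to a motif
#'
#' Membership by the assembly-literature convention: |weight| above 2 SD of
#' that motif's weights.
#' @param motifs a `motif_set`.
#' @return list of integer unit-index vectors, one per motif.
#' @export
motif_members <- function(motifs) {
  lapply(seq_len(motifs$n_motifs), function(k) {
    w <- motifs$weights[, k]
    which(abs(w) > 2 * stats::sd(w))
  })
}

#' Contribution gain of units from LM to Rad events
#'
#' For every unit and LM-derived motif: the correlation between the unit's
#' z-scored activity and the leave-that-unit-out motif activation, computed
#' in Rad events minus in LM events. The gain is z-scored against
#' margin-preserving surrogates of each class (preserving per-unit rates and
#' per-event totals); units whose gain exceeds the surrogate 97.5th
#' percentile are flagged as aggregated into the motif.
#'
#' @param motifs `motif_set` extracted from LM-event counts.
#' @param counts_lm,counts_rad units x events count matrices.
#' @param n_surrogates surrogate pairs (default 500).
#' @param seed RNG seed.
#' @return list of class `contribution_gain`: `gain` (units x motifs),
#'   `gain_z`, `surr_hi` (97.5th percentile per unit x motif), `significant`
#'   (logical matrix), `surrogate_gains` (units x motifs x n_surrogates).
#' @export
contribution_gain <- function(motifs, counts_lm, counts_rad,
                              n_surrogates = 500, seed = 1L) {
  if (motifs$n_motifs == 0L) stop("contribution_gain: no motifs")
  n_u <- nrow(counts_lm)
  gains_for <- function(cl, cr) {
    zl <- zscore_pvs(cl); zr <- zscore_pvs(cr)
    sapply(seq_len(motifs$n_motifs), function(k) {
      w <- motifs$weights[, k]
      vapply(seq_len(n_u), function(u) {
        al <- motif_activation(w, zl, exclude_unit = u)
        ar <- motif_activation(w, zr, exclude_unit = u)
        r_lm <- suppressWarnings(stats::cor(zl[u, ], al))
        r_rad <- suppressWarnings(stats::cor(zr[u, ], ar))
        if (!is.finite(r_lm) || !is.finite(r_rad)) return(NA_real_)
        r_rad - r_lm
      }, numeric(1))
    })
  }
  obs <- gains_for(counts_lm, counts_rad)
  set.seed(seed)
  surr <- array(NA_real_, c(n_u, motifs$n_motifs, n_surrogates))
  for (s in seq_len(n_surrogates)) {
    surr[, , s] <- gains_for(margin_preserving_shuffle(counts_lm),
                             margin_preserving_shuffle(counts_rad))
  }
  mu <- apply(surr, c(1, 2), mean, na.rm = TRUE)
  sdv <- apply(surr, c(1, 2), stats::sd, na.rm = TRUE)
  hi <- apply(surr, c(1, 2), stats::quantile, probs = 0.975, na.rm = TRUE)
  structure(list(gain = obs, gain_z = (obs - mu) / sdv, surr_hi = hi,
                 significant = !is.na(obs) & obs > hi,
                 surrogate_gains = surr),
            class = "contribution_gain")
}

#' Aggregated-neuron count versus surrogate expectation
#'
#' Observed number of significant (unit, motif) contribution gains compared
#' with the count distribution obtained by subjecting each surrogate to the
#' same 97.5th-percentile band.
#'
#' @param cg a `contribution_gain`.
#' @return list: `observed`, `expected` (per-surrogate counts), `p`
#'   (fraction of surrogate counts >= observed).
#' @export
aggregated_count <- function(cg) {
  observed <- sum(cg$significant, na.rm = TRUE)
  ns <- dim(cg$surrogate_gains)[3L]
  expected <- vapply(seq_len(ns), function(s) {
    sum(cg$surrogate_gains[, , s] > cg$surr_hi, na.rm = TRUE)
  }, numeric(1))
  list(observed = observed, expected = expected,
       p = mean(expected >= observed))
}
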