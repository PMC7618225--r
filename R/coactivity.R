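#' Population-conditioned coactivity graph
#'
#' For every ordered unit pair (i, j), the coefficient of unit i in a linear
#' regression of unit j's z-scored event counts on unit i plus the summed
#' activity of the remaining N-2 units (controlling for population rate).
#' The adjacency matrix is symmetrized, (A + t(A)) / 2, with zero diagonal.
#'
#' @param counts units x events spike-count matrix (z-scored internally).
#' @param min_units minimum unit count (default 3).
#' @return list of class `coactivity_graph`: `adjacency` (symmetric, zero
#'   diagonal), `estimator = "population-conditioned"`, `constant_units`.
#' @export
population_conditioned_coactivity <- function(counts, min_units = 3L) {
  if (nrow(counts) < min_units) stop("population_conditioned_coactivity: too few units")
  z <- zscore_pvs(counts)
  const <- attr(z, "constant_units")
  n <- nrow(z)
  tot <- colSums(z)
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    xi <- z[i, ]
    for (j in seq_len(n)) {
      if (i == j) next
      P <- tot - xi - z[j, ]
      X <- cbind(xi, P)
      XtX <- crossprod(X)
      if (abs(det(XtX)) < 1e-12) { B[i, j] <- NA_real_; next }
      beta <- solve(XtX, crossprod(X, z[j, ]))
      B[i, j] <- beta[1L]
    }
  }
  if (length(const)) B[const, ] <- B[, const] <- NA_real_
  A <- (B + t(B)) / 2
  diag(A) <- 0
  structure(list(adjacency = A, estimator = "population-conditioned",
                 symmetric = TRUE, constant_units = const),
            class = "coactivity_graph")
}

#' Fully-conditioned coactivity graph (ridge)
#'
#' For each target unit, an L2-penalized regression of its z-scored counts
#' on all other units individually; the coefficient vectors populate the
#' rows of a directed (non-symmetric) adjacency matrix with zero diagonal.
#'
#' @param counts units x events spike-count matrix.
#' @param penalty ridge penalty lambda (>= 0; zero requires a
#'   well-conditioned design).
#' @return `coactivity_graph` with `estimator = "fully-conditioned"`,
#'   `symmetric = FALSE`.
#' @export
fully_conditioned_coactivity <- function(counts, penalty = 1) {
  if (nrow(counts) < 3L) stop("fully_conditioned_coactivity: too few units")
  z <- zscore_pvs(counts)
  n <- nrow(z)
  C <- matrix(0, n, n)
  for (i in seq_len(n)) {
    X <- t(z[-i, , drop = FALSE])
    y <- z[i, ]
    G <- crossprod(X) + penalty * diag(ncol(X))
    if (penalty == 0 && abs(det(G)) < 1e-10) {
      stop("fully_conditioned_coactivity: singular design with zero penalty")
    }
    C[i, -i] <- solve(G, crossprod(X, y))
  }
  structure(list(adjacency = C, estimator = "fully-conditioned",
                 symmetric = FALSE,
                 constant_units = attr(z, "constant_units")),
            class = "coactivity_graph")
}

#' Node strength
#'
#' Mean of each node's off-diagonal edge weights.
#' @param graph a `coactivity_graph` or adjacency matrix.
#' @return per-node numeric vector.
#' @export
node_strength <- function(graph) {
  A <- if (inherits(graph, "coactivity_graph")) graph$adjacency else graph
  n <- nrow(A)
  (rowSums(A, na.rm = TRUE) - diag(A)) / (n - 1L)
}

#' Structural balance of a signed graph
#'
#' Proportion of closed triads that are balanced (zero or two negative
#' edges) among all closed triads; edges with |weight| below `tol` are
#' absent. Triangle counts come from trace identities on the positive- and
#' negative-edge indicator matrices.
#'
#' @param graph `coactivity_graph` or symmetric signed adjacency matrix.
#' @param tol absolute-weight threshold for edge presence (default 1e-12).
#' @return proportion in [0, 1]; `NA` when the graph has no closed triads.
#' @export
structural_balance <- function(graph, tol = 1e-12) {
  A <- if (inherits(graph, "coactivity_graph")) graph$adjacency else graph
  A[is.na(A)] <- 0
  P <- (A > tol) * 1
  N <- (A < -tol) * 1
  diag(P) <- diag(N) <- 0
  tr <- function(M) sum(diag(M))
  n0 <- tr(P %*% P %*% P) / 6          # all-positive triangles
  n3 <- tr(N %*% N %*% N) / 6          # all-negative
  n1 <- tr(N %*% P %*% P) / 2          # exactly one negative edge
  n2 <- tr(P %*% N %*% N) / 2          # exactly two negative edges
  total <- n0 + n1 + n2 + n3
  if (total == 0) return(NA_real_)
  (n0 + n2) / total
}

#' Gini sparsity of a population vector
#'
#' `S = sum_i (2i - N - 1) x_(i) / (N sum_i x_i)` with x sorted ascending;
#' 0 for perfectly even vectors, (N-1)/N when all spikes sit in one unit.
#' @param pv nonnegative counts, not all zero.
#' @return scalar in [0, 1).
#' @export
gini_sparsity <- function(pv) {
  if (any(pv < 0)) stop("gini_sparsity: counts must be nonnegative")
  s <- sum(pv)
  if (s == 0) return(NA_real_)
  x <- sort(pv)
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n * s)
}

#' Angle-based intrinsic dimensionality (ABID)
#'
#' For each query vector, the difference vectors to its k nearest
#' neighbours (Euclidean) are normalized and their pairwise cosine
#' similarities S computed; the per-query dimensionality is
#' k^2 / sum(S^2) (the diagonal contributes k). With `center = TRUE`
#' (default) the neighbourhood mean displacement is subtracted from the
#' difference vectors first: in inhomogeneous samples the neighbours share a
#' drift toward the local density mode, which inflates the similarities and
#' biases the estimate downward; removing it calibrates the mean estimate to
#' the true dimension for isotropic data (E[S_ij^2] = 1/d). The centered
#' variant is degenerate at k = 2 (two centered vectors are always
#' antiparallel); use `center = FALSE` for the raw construction. The session
#' value is the mean over subsamples of `subsample` vectors, repeated
#' `n_perm` times (k is capped at subsample - 1).
#'
#' @param pvs events x units matrix (z-scored internally per unit).
#' @param k neighbours (default 50).
#' @param subsample events per permutation (default NULL: use all events,
#'   single permutation).
#' @param n_perm permutations when subsampling (default 1000).
#' @param zscore z-score columns first (default TRUE).
#' @param center subtract the neighbourhood mean displacement (default
#'   TRUE; see Details).
#' @param seed RNG seed.
#' @return list: `mean_d`, `per_event` (last permutation's per-query values).
#' @export
abid_dimensionality <- function(pvs, k = 50, subsample = NULL, n_perm = 1000,
                                zscore = TRUE, center = TRUE, seed = 1L) {
  X <- as.matrix(pvs)
  if (zscore) {
    X <- scale(X)
    X[!is.finite(X)] <- 0
  }
  n <- nrow(X)
  if (is.null(subsample)) { subsample <- n; n_perm <- 1L }
  if (n < min(subsample, k + 1L)) stop("abid_dimensionality: too few events")
  set.seed(seed)
  one_pass <- function(S) {
    Y <- X[S, , drop = FALSE]
    m <- nrow(Y)
    kk <- min(k, m - 1L)
    D2 <- as.matrix(stats::dist(Y))^2
    vapply(seq_len(m), function(q) {
      nb <- order(D2[q, ])[2:(kk + 1L)]
      V <- Y[nb, , drop = FALSE] - matrix(Y[q, ], kk, ncol(Y), byrow = TRUE)
      if (center) V <- sweep(V, 2L, colMeans(V))
      nv <- sqrt(rowSums(V^2))
      nv[nv == 0] <- 1
      V <- V / nv
      S2 <- tcrossprod(V)^2
      kk^2 / sum(S2)
    }, numeric(1))
  }
  means <- numeric(n_perm)
  per_event <- NULL
  for (p in seq_len(n_perm)) {
    S <- if (subsample < n) sample.int(n, subsample) else seq_len(n)
    per_event <- one_pass(S)
    means[p] <- mean(per_event)
  }
  list(mean_d = mean(means), per_event = per_event)
}

#' Shuffle-normalized intrinsic dimensionality
#'
#' True ABID divided by the ABID of surrogates in which unit identities are
#' shuffled within each event (sparsity preserved, coactivation structure
#' destroyed). Values below 1 indicate structure beyond sparsity.
#'
#' @param counts events x units count matrix.
#' @param k neighbours.
#' @param n_surrogates surrogate datasets (default 10).
#' @param seed RNG seed.
#' @return list: `ratio`, `true_d`, `surrogate_d`.
#' @export
normalized_dimensionality <- function(counts, k = 50, n_surrogates = 10,
                                      seed = 1L) {
  set.seed(seed)
  true_d <- abid_dimensionality(counts, k = k, seed = seed)$mean_d
  surr <- vapply(seq_len(n_surrogates), function(s) {
    sh <- t(apply(counts, 1L, sample))
    abid_dimensionality(sh, k = k, seed = seed + s)$mean_d
  }, numeric(1))
  list(ratio = true_d / mean(surr), true_d = true_d, surrogate_d = mean(surr))
}

#' Participation ratio
#'
#' `P = (sum lambda)^2 / sum lambda^2` over the eigenvalues of the
#' covariance of the z-scored event matrix (equivalently the squared
#' singular values). Pass precomputed eigenvalues via `values`.
#'
#' @param pvs events x units matrix; ignored when `values` given.
#' @param values optional eigenvalue vector.
#' @return scalar >= 1 (or `NA` for rank-0 input).
#' @export
participation_ratio <- function(pvs = NULL, values = NULL) {
  if (is.null(values)) {
    if (nrow(pvs) < 2L) stop("participation_ratio: need >= 2 events")
    Z <- scale(pvs)
    Z[!is.finite(Z)] <- 0
    values <- svd(Z, nu = 0, nv = 0)$d^2 / (nrow(Z) - 1L)
  }
  s <- sum(values)
  if (s == 0) return(NA_real_)
  s^2 / sum(values^2)
}

#' Asymmetric inclusion of one population vector in another
#'
#' `I_{m,q} = |active(m) intersect active(q)| / |active(m)|` on binarized
#' vectors (any spike -> active).
#' @param pv_m,pv_q count vectors of equal length.
#' @return scalar in [0, 1]; `NA` when `pv_m` has no active cells.
#' @export
asymmetric_inclusion <- function(pv_m, pv_q) {
  am <- pv_m > 0; aq <- pv_q > 0
  if (!any(am)) return(NA_real_)
  sum(am & aq) / sum(am)
}

#' Class-balanced resampled inclusion of LM patterns into Rad patterns
#'
#' Per iteration both classes are subsampled to the smaller class size D and
#' the mean pairwise inclusion I_{LM -> Rad} over the D x D cross pairs is
#' recorded.
#'
#' @param pvs_lm,pvs_rad events x units count matrices.
#' @param n_iter iterations (default 1000).
#' @param seed RNG seed.
#' @return numeric vector of per-iteration mean inclusions.
#' @export
inclusion_resampled <- function(pvs_lm, pvs_rad, n_iter = 1000, seed = 1L) {
  if (nrow(pvs_lm) == 0L || nrow(pvs_rad) == 0L) {
    stop("inclusion_resampled: both classes must be non-empty")
  }
  set.seed(seed)
  Bl <- (pvs_lm > 0) * 1
  Br <- (pvs_rad > 0) * 1
  D <- min(nrow(Bl), nrow(Br))
  vapply(seq_len(n_iter), function(i) {
    il <- if (nrow(Bl) > D) sample.int(nrow(Bl), D) else seq_len(D)
    ir <- if (nrow(Br) > D) sample.int(nrow(Br), D) else seq_len(D)
    L <- Bl[il, , drop = FALSE]; R <- Br[ir, , drop = FALSE]
    sz <- rowSums(L)
    ok <- sz > 0
    if (!any(ok)) return(NA_real_)
    inter <- tcrossprod(L[ok, , drop = FALSE], R)  # |m ∩ q|
    mean(inter / sz[ok])
  }, numeric(1))
}

#' Excitability control: PC1 weights versus firing rate
#'
#' Correlation between the leading principal-component weights of the
#' z-scored unit x event matrix and each unit's mean firing rate, compared
#' to margin-preserving surrogates that keep unit rates and event totals.
#' An observed |r| below the surrogate band indicates coactivity structure
#' beyond shared excitability.
#'
#' @param counts units x events count matrix (>= 10 units).
#' @param n_surrogates surrogate count (default 500).
#' @param seed RNG seed.
#' @return list: `r_observed`, `r_surrogate` (vector), `band`
#'   (2.5/97.5 percentiles of the surrogate |r| is not taken; signed r).
#' @export
excitability_control_pc1 <- function(counts, n_surrogates = 500, seed = 1L) {
  if (nrow(counts) < 10L) stop("excitability_control_pc1: need >= 10 units")
  set.seed(seed)
  pc1_rate_cor <- function(cm) {
    z <- zscore_pvs(cm)
    C <- tcrossprod(z) / (ncol(z) - 1L)
    v <- eigen(C, symmetric = TRUE)$vectors[, 1L]
    if (mean(v) < 0) v <- -v
    stats::cor(v, rowMeans(cm))
  }
  obs <- pc1_rate_cor(counts)
  surr <- vapply(seq_len(n_surrogates), function(s) {
    pc1_rate_cor(margin_preserving_shuffle(counts))
  }, numeric(1))
  list(r_observed = obs, r_surrogate = surr,
       band = stats::quantile(surr, c(0.025, 0.975), names = FALSE))
}
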