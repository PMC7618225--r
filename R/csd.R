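#' Current source density by second spatial difference
#'
#' CSD at channel n is -(LFP[n-1] - 2 LFP[n] + LFP[n+1]); negative values are
#' current sinks, positive values sources. Only interior channels carry a
#' CSD, so the output has two rows fewer than the input.
#'
#' @param lfp_window channel x time matrix (uV), channels ordered
#'   dorsal-to-ventral.
#' @return (channels - 2) x time CSD matrix; row i corresponds to input
#'   channel i + 1.
#' @export
compute_csd <- function(lfp_window) {
  if (!is.matrix(lfp_window)) lfp_window <- matrix(lfp_window, ncol = 1L)
  nch <- nrow(lfp_window)
  if (nch < 3L) stop("compute_csd: need at least 3 channels")
  i <- 2:(nch - 1L)
  -(lfp_window[i - 1L, , drop = FALSE] - 2 * lfp_window[i, , drop = FALSE] +
      lfp_window[i + 1L, , drop = FALSE])
}

#' Gaussian smoothing along the laminar (channel) axis
#'
#' Equalizes spatial resolution across probes with different channel
#' spacings: the kernel standard deviation is fixed in micrometres
#' (default 50 um) and expressed in channel units through the spacing.
#' Boundaries are handled by reflection.
#'
#' @param csd channel x time matrix.
#' @param spacing_um inter-channel spacing (um).
#' @param sigma_um kernel SD in um (default 50). `sigma_um = 0` is the
#'   identity.
#' @return smoothed matrix, same dimensions.
#' @export
smooth_laminar <- function(csd, spacing_um, sigma_um = 50) {
  if (!is.matrix(csd)) csd <- matrix(csd, ncol = 1L)
  sigma_ch <- sigma_um / spacing_um
  if (sigma_ch <= 0) return(csd)
  nch <- nrow(csd)
  half <- max(1L, ceiling(4 * sigma_ch))
  k <- stats::dnorm(seq(-half, half), sd = sigma_ch)
  k <- k / sum(k)
  # reflective padding along channels
  top <- csd[rev(seq_len(min(half, nch))), , drop = FALSE]
  bot <- csd[rev(nch + 1L - seq_len(min(half, nch))), , drop = FALSE]
  while (nrow(top) < half) top <- rbind(top[1L, , drop = FALSE], top)
  while (nrow(bot) < half) bot <- rbind(bot, bot[nrow(bot), , drop = FALSE])
  padded <- rbind(top, csd, bot)
  out <- apply(padded, 2L, function(col) {
    as.numeric(stats::filter(col, k, sides = 2))[(half + 1L):(half + nch)]
  })
  matrix(out, nrow = nch)
}

#' Per-ripple CSD signature
#'
#' Time-mean of the CSD per interior channel over the 50-ms window centred
#' on the ripple power peak, `[peak - 25, peak + 25)` ms (half-open).
#'
#' @param csd interior-channel x time CSD matrix for the whole record.
#' @param peak_time_s ripple peak time (s).
#' @param fs sampling rate (Hz).
#' @param window_ms window width (default 50).
#' @return numeric vector (one value per interior channel), or `NULL` with a
#'   warning when the event lies too close to the record edge.
#' @export
signature <- function(csd, peak_time_s, fs, window_ms = 50) {
  half <- round(window_ms / 2000 * fs)
  peak <- round(peak_time_s * fs) + 1L
  lo <- peak - half
  hi <- peak + half - 1L
  if (lo < 1L || hi > ncol(csd)) {
    warning("signature: event too close to record edge; skipped")
    return(NULL)
  }
  rowMeans(csd[, lo:hi, drop = FALSE])
}

#' Signatures for a table of ripples
#'
#' @param csd interior-channel x time CSD matrix.
#' @param peak_times_s event peak times (s).
#' @inheritParams signature
#' @return ripples x channels matrix; skipped edge events are dropped and
#'   recorded in attribute `kept` (indices into `peak_times_s`).
#' @export
ripple_signatures <- function(csd, peak_times_s, fs, window_ms = 50) {
  sigs <- lapply(peak_times_s, function(t) {
    suppressWarnings(signature(csd, t, fs, window_ms))
  })
  kept <- which(!vapply(sigs, is.null, logical(1)))
  if (length(kept) < length(peak_times_s)) {
    warning(sprintf("ripple_signatures: %d event(s) too close to record edge; skipped",
                    length(peak_times_s) - length(kept)))
  }
  out <- do.call(rbind, sigs[kept])
  attr(out, "kept") <- kept
  out
}

#' Dominant-sink layer of a CSD signature
#'
#' The layer of the interior channel attaining the signature minimum,
#' provided that minimum is negative; otherwise `"no sink"`. Layer summaries
#' use the CA1 strata (oriens, pyramidale, radiatum, lacunosum-moleculare).
#'
#' @param sig signature vector over interior channels.
#' @param layer_map full per-channel layer labels (length = n interior
#'   channels + 2); interior channel i maps to `layer_map[i + 1]`.
#' @return layer label, or `"no sink"`.
#' @export
dominant_sink_layer <- function(sig, layer_map) {
  interior <- layer_map[2:(length(layer_map) - 1L)]
  if (length(sig) != length(interior)) {
    stop("dominant_sink_layer: signature/layer_map length mismatch")
  }
  i <- which.min(sig)
  if (sig[i] >= 0) return("no sink")
  interior[i]
}

#' PCA of ripple CSD signatures
#'
#' Principal components of the ripples x channels signature matrix.
#' `variance_explained` is each component's eigenvalue share. PC1's sign is
#' fixed so its mean weight over the stratum radiatum channels is negative
#' (a higher PC1 strength then means a stronger radiatum sink).
#'
#' @param signatures ripples x interior-channels matrix.
#' @param layer_map full per-channel layer labels.
#' @return list: `components` (channels x k loadings), `variance_explained`,
#'   `pc1_strengths` (per-ripple PC1 scores), `center`.
#' @export
pca_signatures <- function(signatures, layer_map) {
  if (nrow(signatures) < 2L) stop("pca_signatures: need at least 2 ripples")
  if (all(apply(signatures, 2L, stats::sd) == 0)) {
    stop("pca_signatures: rank-0 signature matrix")
  }
  p <- stats::prcomp(signatures, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  interior <- layer_map[2:(length(layer_map) - 1L)]
  rad <- which(interior == "radiatum")
  flip <- if (length(rad) > 0 && mean(p$rotation[rad, 1L]) > 0) -1 else 1
  comps <- p$rotation
  comps[, 1L] <- flip * comps[, 1L]
  scores <- p$x
  scores[, 1L] <- flip * scores[, 1L]
  list(components = comps, variance_explained = ve,
       pc1_strengths = scores[, 1L], center = p$center)
}

#' Percentile labelling of ripples by PC1 strength
#'
#' Strengths above the 70th percentile are radiatum-sink ("Rad"), below the
#' 30th percentile lacunosum-moleculare-sink ("LM"), the rest
#' "intermediate". Percentiles use linear interpolation; values tied with a
#' boundary fall in "intermediate" (strict inequalities on both sides).
#'
#' @param pc1_strengths per-ripple scores (finite).
#' @return character vector of labels.
#' @export
label_by_pc1 <- function(pc1_strengths) {
  stopifnot(all(is.finite(pc1_strengths)))
  q <- stats::quantile(pc1_strengths, c(0.3, 0.7), type = 7, names = FALSE)
  ifelse(pc1_strengths > q[2L], "Rad",
         ifelse(pc1_strengths < q[1L], "LM", "intermediate"))
}

#' Labelling by normalized lacunosum-moleculare CSD
#'
#' Per ripple, the LM score is the signature mean over the central
#' lacunosum-moleculare channel and its two neighbours, divided by the SD of
#' that mean across events. Scores in the lowest 30% (strongest LM sink) are
#' "LM", the top 30% "Rad", the rest "intermediate". This is the CSD ground
#' truth used to train the waveform classifier.
#'
#' @param signatures ripples x interior-channels matrix.
#' @param layer_map full per-channel layer labels.
#' @return list: `labels`, `scores` (normalized; SD 1 across events).
#' @export
label_by_lm_csd <- function(signatures, layer_map) {
  interior <- layer_map[2:(length(layer_map) - 1L)]
  lm <- which(interior == "lacunosum-moleculare")
  if (length(lm) == 0L) stop("label_by_lm_csd: no lacunosum-moleculare channel")
  c0 <- round(stats::median(lm))
  chans <- intersect((c0 - 1L):(c0 + 1L), seq_along(interior))
  if (length(chans) < 3L) {
    warning("label_by_lm_csd: lacunosum-moleculare channel at array edge; using available neighbours")
  }
  raw <- rowMeans(signatures[, chans, drop = FALSE])
  s <- stats::sd(raw)
  if (s == 0) stop("label_by_lm_csd: zero variance across events")
  score <- raw / s
  q <- stats::quantile(score, c(0.3, 0.7), type = 7, names = FALSE)
  labels <- ifelse(score < q[1L], "LM",
                   ifelse(score > q[2L], "Rad", "intermediate"))
  list(labels = labels, scores = score)
}
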