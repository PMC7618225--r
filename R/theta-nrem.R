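#' Segment theta cycles from a narrowband theta component
#'
#' Peaks and troughs of the theta component are retained only where their
#' amplitude exceeds the supplied low-frequency envelope threshold. Each
#' peak-trough-peak sequence is a candidate cycle, validated when both
#' half-periods (peak-trough and trough-peak) fall within 31-100 ms and the
#' peak-to-peak distance within 71-200 ms. For each valid cycle six control
#' points are located: the zero-crossing before the first peak, the peak, the
#' zero-crossing after it, the trough, the zero-crossing after the trough,
#' and the closing peak.
#'
#' The narrowband decomposition backend is caller-supplied; see
#' [theta_component()] for the default zero-phase 5-12 Hz band-pass.
#'
#' @param theta_component narrowband theta series.
#' @param low_freq_envelope amplitude threshold per sample (same length);
#'   scalars are recycled. Use 0 to retain all extrema.
#' @param fs sampling rate (Hz).
#' @return data frame of class `theta_cycles`, one row per valid cycle, with
#'   control-point times `zc1_s`, `peak_s`, `zc2_s`, `trough_s`, `zc3_s`,
#'   `peak2_s` and a `valid` flag (all TRUE; invalid candidates are dropped).
#' @export
segment_theta_cycles <- function(theta_component, low_freq_envelope, fs) {
  x <- theta_component
  n <- length(x)
  env <- rep_len(low_freq_envelope, n)
  pk <- local_maxima(x)
  tr <- local_maxima(-x)
  pk <- pk[x[pk] > env[pk]]
  tr <- tr[-x[tr] > env[tr]]
  empty <- data.frame(zc1_s = numeric(0), peak_s = numeric(0), zc2_s = numeric(0),
                      trough_s = numeric(0), zc3_s = numeric(0), peak2_s = numeric(0),
                      valid = logical(0))
  class(empty) <- c("theta_cycles", "data.frame")
  if (length(pk) < 2L || length(tr) < 1L) return(empty)

  zero_cross <- function(i1, i2, rising) {
    # linear-interpolated zero crossing between samples i1 < i2
    seg <- x[i1:i2]
    sgn <- if (rising) which(seg[-length(seg)] < 0 & seg[-1L] >= 0)
           else which(seg[-length(seg)] >= 0 & seg[-1L] < 0)
    if (length(sgn) == 0L) return(NA_real_)
    j <- i1 + sgn[1L] - 1L
    frac <- x[j] / (x[j] - x[j + 1L])
    (j - 1L + frac) / fs
  }

  rows <- list()
  for (k in seq_len(length(pk) - 1L)) {
    p1 <- pk[k]; p2 <- pk[k + 1L]
    tt <- tr[tr > p1 & tr < p2]
    if (length(tt) != 1L) next
    ht1 <- (tt - p1) / fs; ht2 <- (p2 - tt) / fs; pp <- (p2 - p1) / fs
    if (ht1 < 0.031 || ht1 > 0.100 || ht2 < 0.031 || ht2 > 0.100) next
    if (pp < 0.071 || pp > 0.200) next
    zc1 <- zero_cross(max(1L, p1 - round(0.100 * fs)), p1, rising = TRUE)
    zc2 <- zero_cross(p1, tt, rising = FALSE)
    zc3 <- zero_cross(tt, p2, rising = TRUE)
    if (anyNA(c(zc1, zc2, zc3))) next
    rows[[length(rows) + 1L]] <- c(zc1, (p1 - 1L) / fs, zc2, (tt - 1L) / fs,
                                   zc3, (p2 - 1L) / fs)
  }
  if (length(rows) == 0L) return(empty)
  m <- do.call(rbind, rows)
  out <- data.frame(zc1_s = m[, 1], peak_s = m[, 2], zc2_s = m[, 3],
                    trough_s = m[, 4], zc3_s = m[, 5], peak2_s = m[, 6],
                    valid = TRUE)
  ok <- apply(m, 1L, function(v) all(diff(v) > 0))
  out <- out[ok, , drop = FALSE]
  class(out) <- c("theta_cycles", "data.frame")
  out
}

#' Default theta decomposition backend
#'
#' Zero-phase 4th-order 5-12 Hz band-pass standing in for a masked-EMD sift;
#' the cycle validation rules in [segment_theta_cycles()] make downstream
#' results robust to the choice of backend.
#' @param lfp LFP trace.
#' @param fs sampling rate (Hz).
#' @return narrowband theta component.
#' @export
theta_component <- function(lfp, fs) bandpass(lfp, 5, 12, fs)

#' Instantaneous theta phase by control-point interpolation
#'
#' Phase is piecewise-linear between the control points of each validated
#' cycle, with the convention peak = 0 and trough = pi (so the leading
#' zero-crossing maps to -pi/2 and the closing peak to 2*pi). Timestamps
#' outside validated cycles get `NA`.
#'
#' @param cycles a `theta_cycles` data frame.
#' @param timestamps times (s) at which to evaluate the phase.
#' @return numeric phase per timestamp, in (-pi/2, 2*pi), `NA` outside cycles.
#' @export
theta_phase <- function(cycles, timestamps) {
  out <- rep(NA_real_, length(timestamps))
  if (nrow(cycles) == 0L) return(out)
  phases <- c(-pi / 2, 0, pi / 2, pi, 3 * pi / 2, 2 * pi)
  for (i in seq_len(nrow(cycles))) {
    cp <- as.numeric(cycles[i, c("zc1_s", "peak_s", "zc2_s", "trough_s",
                                 "zc3_s", "peak2_s")])
    sel <- timestamps >= cp[1L] & timestamps <= cp[6L]
    if (!any(sel)) next
    out[sel] <- stats::approx(cp, phases, xout = timestamps[sel])$y
  }
  out
}

#' Segment NREM / REM / wake epochs
#'
#' Computes a theta-power ratio (5-10 Hz power over 0.1-10 Hz power) on 2-s
#' spectrogram windows with 90% overlap, downsamples the ratio to 1 Hz, and
#' splits low from high ratio with a two-component Gaussian mixture. NREM
#' requires the low-ratio component and speed below threshold
#' (mean + 1.5 SD of the session speed); low-speed high-ratio epochs
#' following at least 2 minutes of NREM are REM; everything else is wake.
#'
#' @param lfp_pyr pyramidal-layer LFP trace.
#' @param speed aligned speed trace (any sampling; linearly resampled to
#'   1 Hz). An all-zero speed never blocks the NREM criterion.
#' @param fs LFP sampling rate (Hz).
#' @param min_bout_s bouts shorter than this are merged into their
#'   neighbours' flanking state only for occurrence analyses; the epoch table
#'   carries an `ok_duration` flag instead of dropping rows (default 10 s).
#' @return data frame of class `epoch_table`: `state`, `start_s`, `end_s`,
#'   `ok_duration`; attribute `low_confidence` set when the two mixture
#'   components are separated by less than half a pooled SD.
#' @export
segment_nrem <- function(lfp_pyr, speed, fs, min_bout_s = 10) {
  win <- round(2 * fs)
  step <- max(1L, round(0.1 * win))  # 90% overlap
  starts <- seq(1L, length(lfp_pyr) - win + 1L, by = step)
  if (length(starts) < 10L) stop("segment_nrem: record too short")
  w <- 0.5 * (1 - cos(2 * pi * seq_len(win) / (win + 1)))
  ratio <- vapply(starts, function(s) {
    seg <- (lfp_pyr[s:(s + win - 1L)] - mean(lfp_pyr[s:(s + win - 1L)])) * w
    P <- Mod(stats::fft(seg))^2
    f <- (seq_along(P) - 1L) * fs / win
    th <- sum(P[f >= 5 & f <= 10])
    tot <- sum(P[f >= 0.1 & f <= 10])
    if (tot <= 0) 0 else th / tot
  }, numeric(1))
  t_centres <- (starts - 1L + win / 2) / fs
  # downsample to 1 Hz
  dur <- floor(length(lfp_pyr) / fs)
  sec <- floor(t_centres)
  keep <- sec < dur
  ratio1 <- tapply(ratio[keep], factor(sec[keep], levels = 0:(dur - 1L)), mean)
  ratio1[is.na(ratio1)] <- stats::median(ratio, na.rm = TRUE)

  fit <- mclust::Mclust(as.numeric(ratio1), G = 2, modelNames = "V",
                        verbose = FALSE)
  mu <- fit$parameters$mean
  sd2 <- sqrt(fit$parameters$variance$sigmasq)
  low_comp <- which.min(mu)
  low_conf <- abs(diff(mu)) < 0.5 * mean(sd2)
  is_low <- fit$classification == low_comp

  sp <- rep_len(speed, length.out = max(1L, length(speed)))
  sp1 <- if (length(sp) == dur) sp else stats::approx(
    seq(0, dur - 1, length.out = length(sp)), sp, xout = 0:(dur - 1L), rule = 2)$y
  thr_sp <- mean(sp1) + 1.5 * stats::sd(sp1)
  if (!is.finite(thr_sp) || stats::sd(sp1) == 0) thr_sp <- Inf
  low_speed <- sp1 <= thr_sp

  state <- ifelse(is_low & low_speed, "NREM", ifelse(low_speed, "cand_REM", "wake"))
  # collapse runs into epochs
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts_e <- ends - r$lengths + 1L
  st <- r$values
  # REM requires a preceding NREM epoch of >= 2 minutes
  for (i in seq_along(st)) {
    if (st[i] == "cand_REM") {
      prev_nrem <- i > 1L && st[i - 1L] == "NREM" &&
        r$lengths[i - 1L] >= 120
      st[i] <- if (prev_nrem) "REM" else "wake"
    }
  }
  out <- data.frame(state = st, start_s = starts_e - 1, end_s = ends,
                    ok_duration = r$lengths >= min_bout_s,
                    stringsAsFactors = FALSE)
  # merge adjacent epochs that ended up with the same state
  i <- 1L
  while (i < nrow(out)) {
    if (out$state[i] == out$state[i + 1L]) {
      out$end_s[i] <- out$end_s[i + 1L]
      out$ok_duration[i] <- (out$end_s[i] - out$start_s[i]) >= min_bout_s
      out <- out[-(i + 1L), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(out) <- NULL
  class(out) <- c("epoch_table", "data.frame")
  attr(out, "low_confidence") <- low_conf
  if (low_conf) warning("segment_nrem: theta-ratio mixture components poorly separated; low-confidence segmentation")
  out
}
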