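#' Detect sharp-wave ripple events
#'
#' Detection on the pyramidal-layer trace referenced to a no-ripple channel.
#' The differential signal is band-pass filtered in the ripple band
#' (80-250 Hz) and a high-frequency control band (200-500 Hz); envelopes and
#' phases come from the Hilbert transform. Envelope peaks above five times
#' the session median envelope are event candidates; peaks within 20 ms are
#' merged keeping the larger; onset/offset are where the envelope falls below
#' half the threshold. Candidates are validated by four criteria:
#' \enumerate{
#'   \item ripple-band power in the detection channel at least double that of
#'     the reference channel,
#'   \item mean frequency above 80 Hz,
#'   \item at least four complete ripple cycles (unwrapped phase difference
#'     onset to offset over 2*pi),
#'   \item ripple-band power at least double the control-band power.
#' }
#'
#' @param lfp_pyr pyramidal-layer LFP trace (uV).
#' @param lfp_reference aligned reference trace from a channel without
#'   ripples.
#' @param fs sampling rate (Hz).
#' @param threshold_mult envelope threshold as a multiple of the median
#'   (default 5).
#' @return data frame of class `ripple_table`: `peak_time_s`, `onset_s`,
#'   `offset_s`, `n_cycles`, `mean_freq_hz`, `ripple_power`, `valid`, plus
#'   per-criterion flags.
#' @export
detect_ripples <- function(lfp_pyr, lfp_reference, fs, threshold_mult = 5) {
  if (identical(lfp_pyr, lfp_reference)) {
    warning("detect_ripples: reference identical to detection channel; power-ratio criterion degenerate")
  }
  d <- lfp_pyr - lfp_reference
  hi_band <- min(500, 0.95 * fs / 2)
  rip <- bandpass(d, 80, 250, fs)
  ctrl <- bandpass(d, 200, hi_band, fs)
  ref_rip <- bandpass(lfp_reference, 80, 250, fs)
  an <- analytic_signal(rip)
  env <- Mod(an)
  phase <- Arg(an)
  env_ctrl <- Mod(analytic_signal(ctrl))
  env_ref <- Mod(analytic_signal(ref_rip))

  thr <- threshold_mult * stats::median(env)
  pk <- local_maxima(env)
  pk <- pk[env[pk] > thr]
  empty <- data.frame(peak_time_s = numeric(0), onset_s = numeric(0),
                      offset_s = numeric(0), n_cycles = numeric(0),
                      mean_freq_hz = numeric(0), ripple_power = numeric(0),
                      valid = logical(0), ok_ref_power = logical(0),
                      ok_freq = logical(0), ok_cycles = logical(0),
                      ok_ctrl_power = logical(0))
  class(empty) <- c("ripple_table", "data.frame")
  if (length(pk) == 0L) return(empty)

  # merge peaks closer than 20 ms, keeping the larger
  merge_win <- round(0.020 * fs)
  repeat {
    close <- which(diff(pk) < merge_win)
    if (length(close) == 0L) break
    i <- close[1L]
    drop <- if (env[pk[i]] >= env[pk[i + 1L]]) i + 1L else i
    pk <- pk[-drop]
  }

  half_thr <- thr / 2
  below <- env < half_thr
  n <- length(env)
  onset <- offset <- integer(length(pk))
  for (k in seq_along(pk)) {
    b <- which(below[seq_len(pk[k])])
    onset[k] <- if (length(b)) max(b) + 1L else 1L
    a <- which(below[pk[k]:n])
    offset[k] <- if (length(a)) pk[k] + min(a) - 2L else n
  }
  # events sharing onset/offset collapse to the largest peak
  dup <- duplicated(cbind(onset, offset))
  pk <- pk[!dup]; onset <- onset[!dup]; offset <- offset[!dup]

  n_cycles <- mean_freq <- power <- p_ref <- p_ctrl <- numeric(length(pk))
  for (k in seq_along(pk)) {
    seg <- onset[k]:offset[k]
    ph <- unwrap_phase(phase[seg])
    n_cycles[k] <- (ph[length(ph)] - ph[1L]) / (2 * pi)
    dur <- (offset[k] - onset[k]) / fs
    mean_freq[k] <- if (dur > 0) n_cycles[k] / dur else 0
    power[k] <- mean(env[seg]^2)
    p_ref[k] <- mean(env_ref[seg]^2)
    p_ctrl[k] <- mean(env_ctrl[seg]^2)
  }
  ok_ref <- power >= 2 * p_ref
  ok_freq <- mean_freq > 80
  ok_cyc <- n_cycles >= 4
  ok_ctrl <- power >= 2 * p_ctrl
  out <- data.frame(
    peak_time_s = (pk - 1L) / fs, onset_s = (onset - 1L) / fs,
    offset_s = (offset - 1L) / fs, n_cycles = n_cycles,
    mean_freq_hz = mean_freq, ripple_power = power,
    valid = ok_ref & ok_freq & ok_cyc & ok_ctrl,
    ok_ref_power = ok_ref, ok_freq = ok_freq, ok_cycles = ok_cyc,
    ok_ctrl_power = ok_ctrl
  )
  class(out) <- c("ripple_table", "data.frame")
  out
}

#' Mark isolated ripples
#'
#' An event is isolated when no other event peak lies within +/- `gap_s` of
#' its own peak. Triggered-average consumers (PETHs, triggered CSD) require
#' isolated events.
#' @param peak_times_s sorted event peak times.
#' @param gap_s isolation half-window (default 0.25 s).
#' @return logical vector.
#' @export
is_isolated <- function(peak_times_s, gap_s = 0.25) {
  n <- length(peak_times_s)
  if (n == 0L) return(logical(0))
  prev_gap <- c(Inf, diff(peak_times_s))
  next_gap <- c(diff(peak_times_s), Inf)
  prev_gap > gap_s & next_gap > gap_s
}

#' Select the ripple-band reference channel
#'
#' Scores each channel with Welch power (4-s Hann windows, 50% overlap) in
#' the 80-250 Hz band divided by power in the enclosing 70-300 Hz band, and
#' returns the channel maximising the score (ties break to the lowest
#' index).
#'
#' @param recording a `laminar_recording` (or bare channel x time matrix plus
#'   `fs`).
#' @param fs sampling rate; taken from the recording when absent.
#' @return integer channel index; attribute `scores` holds per-channel scores.
#' @export
select_reference_channel <- function(recording, fs = NULL) {
  if (inherits(recording, "laminar_recording")) {
    m <- recording$data; fs <- recording$fs_hz
  } else m <- recording
  if (nrow(m) < 2L) stop("select_reference_channel: need at least 2 channels")
  scores <- apply(m, 1L, function(x) {
    psd <- welch_psd(x, fs, window_s = 4, overlap = 0.5)
    band_power(psd, 80, 250) / band_power(psd, 70, 300)
  })
  best <- which.max(scores)  # which.max returns the first (lowest) maximiser
  attr(best, "scores") <- scores
  best
}
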