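#' Simulate a laminar LFP recording with planted ripples
#'
#' Generates a channel-by-time LFP matrix (uV) containing sharp-wave/ripple
#' events of two laminar types with known ground truth:
#' \itemize{
#'   \item Radiatum-sink events: a negative Gaussian-profile sharp-wave
#'     deflection peaking on the stratum radiatum channels at the ripple peak,
#'     plus a Gaussian-windowed ripple-band oscillation at `cfg$rad_freq_hz`
#'     on the pyramidale channels.
#'   \item Lacunosum-moleculare-sink events: a negative deflection on the
#'     lacunosum-moleculare channels leading the ripple peak by ~17 ms, a
#'     weaker radiatum deflection ~12 ms after the peak, a positive
#'     pyramidale deflection, and a `cfg$lm_freq_hz` oscillation.
#' }
#' Spatial profiles are Gaussian bumps across channels, so the negated second
#' spatial difference (the CSD) attains its most negative value (sink) on the
#' intended layer.
#'
#' @param cfg a [sim_config()].
#' @param duration_s record duration in seconds.
#' @return list with elements `recording` (class `laminar_recording`: `data`
#'   channel x time matrix in uV, `fs_hz`, `layer_map`, `spacing_um`) and
#'   `truth` (class `ground_truth`: `events` data frame with `peak_time_s`,
#'   `true_class` in `{"Rad","LM"}`, amplitudes and durations; `tau_min`,
#'   motif memberships, `duration_s`).
#' @export
simulate_laminar_lfp <- function(cfg, duration_s = 600) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_channels < 4L) stop("simulate_laminar_lfp: n_channels must be >= 4")
  set.seed(cfg$seed)
  fs <- cfg$fs_hz
  n <- round(duration_s * fs)
  nch <- cfg$n_channels
  lfp <- matrix(stats::rnorm(nch * n, sd = cfg$noise_sd), nrow = nch)

  pyr_ch <- layer_channels(cfg$layer_map, "pyramidale")
  rad_ch <- layer_channels(cfg$layer_map, "radiatum")
  lm_ch <- layer_channels(cfg$layer_map, "lacunosum-moleculare")
  pyr_c <- round(stats::median(pyr_ch))
  rad_c <- stats::median(rad_ch)
  lm_c <- stats::median(lm_ch)

  times <- draw_event_times(cfg$ripple_rate_hz, duration_s, min_sep_s = 0.3)
  n_ev <- length(times)
  classes <- ifelse(stats::runif(n_ev) < cfg$p_lm, "LM", "Rad")
  dur_ms <- stats::runif(n_ev, 40, 100)
  sw_amp <- 300 * exp(stats::rnorm(n_ev, 0, 0.25))
  rip_amp <- 160 * exp(stats::rnorm(n_ev, 0, 0.2))

  ch_idx <- seq_len(nch)
  for (e in seq_len(n_ev)) {
    peak <- round(times[e] * fs)
    half <- round(0.150 * fs)  # event support: +/-150 ms
    lo <- max(1L, peak - half); hi <- min(n, peak + half)
    tt <- (lo:hi - peak) / fs  # seconds relative to peak
    freq <- if (classes[e] == "Rad") cfg$rad_freq_hz else cfg$lm_freq_hz
    # ripple burst: Gaussian-windowed sinusoid on pyramidale channels
    rip_sd <- dur_ms[e] / 3 / 1000
    burst <- rip_amp[e] * exp(-tt^2 / (2 * rip_sd^2)) * cos(2 * pi * freq * tt)
    rip_prof <- exp(-(ch_idx - pyr_c)^2 / (2 * 0.7^2))
    lfp[, lo:hi] <- lfp[, lo:hi] + outer(rip_prof, burst)
    if (classes[e] == "Rad") {
      # sharp wave: negative bump on radiatum at the peak
      sw <- -sw_amp[e] * exp(-tt^2 / (2 * 0.012^2))
      prof <- exp(-(ch_idx - rad_c)^2 / (2 * 1.1^2))
      lfp[, lo:hi] <- lfp[, lo:hi] + outer(prof, sw)
    } else {
      # LM deflection leads the peak by ~17 ms
      sw_lm <- -sw_amp[e] * exp(-(tt + 0.017)^2 / (2 * 0.014^2))
      prof_lm <- exp(-(ch_idx - lm_c)^2 / (2 * 1.0^2))
      lfp[, lo:hi] <- lfp[, lo:hi] + outer(prof_lm, sw_lm)
      # weaker, later radiatum deflection ~12 ms after the peak
      sw_rad <- -0.35 * sw_amp[e] * exp(-(tt - 0.012)^2 / (2 * 0.012^2))
      prof_rad <- exp(-(ch_idx - rad_c)^2 / (2 * 1.1^2))
      lfp[, lo:hi] <- lfp[, lo:hi] + outer(prof_rad, sw_rad)
      # positive pyramidale deflection accompanying the LM sink
      sw_pyr <- 0.35 * sw_amp[e] * exp(-(tt + 0.010)^2 / (2 * 0.014^2))
      prof_pyr <- exp(-(ch_idx - pyr_c)^2 / (2 * 1.2^2))
      lfp[, lo:hi] <- lfp[, lo:hi] + outer(prof_pyr, sw_pyr)
    }
  }

  recording <- structure(list(
    data = lfp, fs_hz = fs, layer_map = cfg$layer_map,
    spacing_um = cfg$channel_spacing_um
  ), class = "laminar_recording")
  truth <- structure(list(
    events = data.frame(peak_time_s = times, true_class = classes,
                        sw_amp_uv = sw_amp, ripple_amp_uv = rip_amp,
                        duration_ms = dur_ms, stringsAsFactors = FALSE),
    tau_min = cfg$tau_min, core_motif = cfg$core_motif,
    composite_extra = cfg$composite_extra, duration_s = duration_s
  ), class = "ground_truth")
  list(recording = recording, truth = truth)
}

#' Simulate a bimodal Up/Down molecular-layer energy series
#'
#' Two-state semi-Markov process (gamma-distributed dwell times) with
#' Gaussian emissions separated by a configurable gap, sampled at 5 Hz. The
#' Up state emulates epochs of high dentate-gyrus molecular-layer CSD energy.
#'
#' @param cfg a [sim_config()] (only `seed` is used).
#' @param duration_s series duration (s).
#' @param gap_sd separation between the two emission means, in units of the
#'   emission standard deviation; must be positive.
#' @param mean_dwell_up_s,mean_dwell_down_s mean dwell times (s).
#' @param fs_energy sampling rate of the series (Hz), default 5.
#' @return list with `energy` (numeric series), `states` (character vector
#'   `"Up"`/`"Down"` per sample), `fs_hz`.
#' @export
simulate_updown_energy <- function(cfg, duration_s,
                                   gap_sd = 3,
                                   mean_dwell_up_s = 5.74,
                                   mean_dwell_down_s = 4.4,
                                   fs_energy = 5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (duration_s <= 0) stop("simulate_updown_energy: duration must be positive")
  if (gap_sd <= 0) stop("simulate_updown_energy: emission gap must be positive")
  set.seed(cfg$seed + 104729L)
  n <- round(duration_s * fs_energy)
  states <- character(0)
  cur <- if (stats::runif(1) < 0.5) "Up" else "Down"
  shape <- 4  # gamma dwell, CV = 0.5
  while (length(states) < n) {
    mu <- if (cur == "Up") mean_dwell_up_s else mean_dwell_down_s
    dwell <- max(2L, round(stats::rgamma(1L, shape = shape, scale = mu / shape) * fs_energy))
    states <- c(states, rep(cur, dwell))
    cur <- if (cur == "Up") "Down" else "Up"
  }
  states <- states[seq_len(n)]
  mu <- ifelse(states == "Up", gap_sd, 0)
  energy <- stats::rnorm(n, mean = mu, sd = 1)
  list(energy = energy, states = states, fs_hz = fs_energy)
}
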