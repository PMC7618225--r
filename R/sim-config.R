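#' Simulation configuration
#'
#' Builds the configuration object for the synthetic laminar recording and
#' spike-session generators. Defaults encode the study conditions the pipeline
#' is validated against: a 16-channel laminar probe spanning CA1 stratum
#' oriens to the dentate granule layer at 50 um spacing, ripple-band
#' oscillation frequencies of 147 Hz (radiatum-sink events) and 125 Hz
#' (lacunosum-moleculare-sink events), and a prior-motif expression decay
#' constant of 13 minutes across post-exploration sleep.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param fs_hz LFP sampling rate (samples/s).
#' @param n_channels number of probe channels (>= 4; the second spatial
#'   difference needs interior channels).
#' @param channel_spacing_um inter-channel spacing in micrometres.
#' @param layer_map character vector of per-channel layer labels in
#'   dorsal-to-ventral order; must cover all channels. Recognised labels:
#'   `"oriens"`, `"pyramidale"`, `"radiatum"`, `"lacunosum-moleculare"`,
#'   `"moleculare"`, `"granule"`.
#' @param n_units_ca1_deep,n_units_ca1_sup,n_units_ca3,n_interneurons unit
#'   counts by group.
#' @param ripple_rate_hz ripple occurrence rate in events/s during sleep. The
#'   source recordings report incidence only qualitatively; 0.4 events/s is a
#'   realistic NREM rate and yields the per-class event counts the population
#'   analyses require.
#' @param p_lm probability that a generated event is of the
#'   lacunosum-moleculare-sink type.
#' @param rad_freq_hz,lm_freq_hz ripple oscillation frequency per event type.
#' @param core_motif integer unit indices of the sparse "core" coactivity
#'   motif (deep-biased by default).
#' @param composite_extra integer unit indices joining the motif only in
#'   radiatum-sink events (superficial-biased); disjoint from `core_motif`.
#' @param tau_min ground-truth decay constant (minutes) of prior-motif
#'   expression across post-sleep.
#' @param noise_sd LFP white-noise standard deviation (uV).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       fs_hz = 1250,
                       n_channels = 16L,
                       channel_spacing_um = 50,
                       layer_map = NULL,
                       n_units_ca1_deep = 14L,
                       n_units_ca1_sup = 10L,
                       n_units_ca3 = 10L,
                       n_interneurons = 6L,
                       ripple_rate_hz = 0.4,
                       p_lm = 0.3,
                       rad_freq_hz = 147,
                       lm_freq_hz = 125,
                       core_motif = NULL,
                       composite_extra = NULL,
                       tau_min = 13,
                       noise_sd = 25) {
  if (n_channels < 4L) stop("sim_config: n_channels must be >= 4 (CSD needs interior channels)")
  if (p_lm < 0 || p_lm > 1) stop("sim_config: p_lm must lie in [0, 1]")
  if (tau_min <= 0) stop("sim_config: tau_min must be positive")
  if (is.null(layer_map)) layer_map <- default_layer_map(n_channels)
  if (length(layer_map) != n_channels) stop("sim_config: layer_map must cover all channels")
  n_pr <- n_units_ca1_deep + n_units_ca1_sup + n_units_ca3
  # deep CA1 units come first, then superficial CA1, then CA3, then interneurons
  if (is.null(core_motif)) core_motif <- seq_len(min(6L, n_units_ca1_deep))
  if (is.null(composite_extra)) {
    composite_extra <- n_units_ca1_deep + seq_len(min(6L, n_units_ca1_sup))
  }
  if (length(intersect(core_motif, composite_extra)) > 0L) {
    stop("sim_config: core_motif and composite_extra must be disjoint")
  }
  if (any(c(core_motif, composite_extra) > n_pr)) {
    stop("sim_config: motif indices must refer to principal cells")
  }
  structure(list(
    seed = as.integer(seed), fs_hz = fs_hz, n_channels = as.integer(n_channels),
    channel_spacing_um = channel_spacing_um, layer_map = layer_map,
    n_units_ca1_deep = as.integer(n_units_ca1_deep),
    n_units_ca1_sup = as.integer(n_units_ca1_sup),
    n_units_ca3 = as.integer(n_units_ca3),
    n_interneurons = as.integer(n_interneurons),
    ripple_rate_hz = ripple_rate_hz, p_lm = p_lm,
    rad_freq_hz = rad_freq_hz, lm_freq_hz = lm_freq_hz,
    core_motif = as.integer(core_motif),
    composite_extra = as.integer(composite_extra),
    tau_min = tau_min, noise_sd = noise_sd
  ), class = "sim_config")
}

#' Default laminar layer map
#'
#' Distributes the six strata over the probe in dorsal-to-ventral order with
#' proportions resembling a probe spanning CA1 into the dentate gyrus.
#' @param n_channels number of channels.
#' @return character vector of length `n_channels`.
#' @export
default_layer_map <- function(n_channels) {
  frac <- c(oriens = 0.18, pyramidale = 0.12, radiatum = 0.26,
            `lacunosum-moleculare` = 0.14, moleculare = 0.18, granule = 0.12)
  counts <- round(frac * n_channels)
  counts[counts < 1] <- 1
  while (sum(counts) > n_channels) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < n_channels) counts[which.max(frac)] <- counts[which.max(frac)] + 1L
  rep(names(counts), counts)
}

#' Channels belonging to a layer
#' @param layer_map per-channel layer labels.
#' @param layer layer label.
#' @return integer channel indices (1-based).
#' @export
layer_channels <- function(layer_map, layer) which(layer_map == layer)

# Draw a sorted vector of event times: Poisson count, uniform placement,
# minimum separation enforced by redrawing offenders so the count itself
# stays exactly Poisson.
draw_event_times <- function(rate_hz, duration_s, min_sep_s = 0.25) {
  n <- stats::rpois(1L, rate_hz * duration_s)
  if (n == 0L) return(numeric(0))
  lo <- min_sep_s
  hi <- duration_s - min_sep_s
  t <- sort(stats::runif(n, lo, hi))
  for (iter in seq_len(200L)) {
    bad <- which(diff(t) < min_sep_s)
    if (length(bad) == 0L) break
    t[bad + 1L] <- stats::runif(length(bad), lo, hi)
    t <- sort(t)
  }
  t
}
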