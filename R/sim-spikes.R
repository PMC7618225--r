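#' Simulate a three-epoch spike session with planted coactivity motifs
#'
#' Generates a pre-sleep / exploration / post-sleep session of spike trains
#' with known coactivity structure:
#' \itemize{
#'   \item In lacunosum-moleculare-sink (LM) ripples, the sparse `core_motif`
#'     units co-spike above a low background; in radiatum-sink (Rad) ripples
#'     the composite set `core_motif` plus `composite_extra` co-spikes above a
#'     higher background, so overall rates are higher and population vectors
#'     less sparse in Rad events.
#'   \item Exploration theta cycles stochastically express a "recent"
#'     (wake-gained) motif that overlaps `composite_extra` but also recruits
#'     wake-specific members absent from the sleep composite.
#'   \item In radiatum-sink events the core and composite-extra sub-motifs
#'     are each expressed stochastically per event, giving the across-event
#'     variance the coactivity estimators measure.
#'   \item Across post-sleep, the probability that an LM ripple expresses the
#'     prior (core) motif decays as exp(-t / tau_min), drifting toward the
#'     recent motif; Rad ripples express the composite set throughout, so
#'     occurrence frequency and population sparsity stay constant over time.
#'   \item Deep CA1 units fire more than superficial ones in LM events; CA3
#'     principal cells emit a transient ~100 ms before the LM ripple peak;
#'     CA3 interneurons are relatively enhanced in LM events.
#' }
#' Spike counts per window follow the 1-ms Bernoulli-bin model (drawn as
#' binomial window counts with uniform in-window placement), which gives
#' exact control of the marginals exercised by the shuffle-based controls.
#'
#' @param cfg a [sim_config()].
#' @param truth optional `ground_truth` from [simulate_laminar_lfp()]; when
#'   given, its `tau_min` and motif memberships override those in `cfg`.
#' @param epoch_durations_s named numeric `c(pre=, expl=, post=)` in seconds.
#' @param rates named list overriding any of the default rate parameters
#'   (Hz): `baseline_pr`, `baseline_int`, `rad_member`, `rad_other`,
#'   `lm_member`, `lm_other`, `int_rad`, `int_lm`, `int_ca3_lm`,
#'   `deep_lm_mult`, `ca3_pre_lm`, `theta_member`, `theta_other`.
#' @param participation per-event probability that a motif member joins its
#'   motif's expression (default 0.9).
#' @param excitability_sd SD (log scale) of the per-event multiplicative
#'   excitability gain shared by all units (default 0.3); models the common
#'   drive fluctuation that couples every unit to the population rate.
#' @param theta_express_p probability that a theta cycle expresses the recent
#'   motif (default 0.6).
#' @return object of class `spike_session`: list with `units` (metadata data
#'   frame: unit_id, region, cell_class, sublayer, tetrode), `spikes`
#'   (unit_id, spike_time_s), `epochs` (epoch, start_s, end_s), `events`
#'   (peak_time_s, true_class, epoch, expressed), `theta_cycles`
#'   (time_s, expressed), plus the planted `core_motif`, `composite_extra`,
#'   `recent_motif` index sets and `tau_min`.
#' @export
simulate_spike_session <- function(cfg, truth = NULL,
                                   epoch_durations_s = c(pre = 1200, expl = 600, post = 4200),
                                   rates = list(),
                                   participation = 0.9,
                                   excitability_sd = 0.3,
                                   theta_express_p = 0.6) {
  stopifnot(inherits(cfg, "sim_config"))
  tau <- if (!is.null(truth)) truth$tau_min else cfg$tau_min
  core <- if (!is.null(truth)) truth$core_motif else cfg$core_motif
  extra <- if (!is.null(truth)) truth$composite_extra else cfg$composite_extra
  if (length(core) == 0L || length(extra) == 0L) {
    stop("simulate_spike_session: motif sets must be non-empty")
  }
  r <- utils::modifyList(list(
    baseline_pr = 0.5, baseline_int = 8,
    rad_member = 40, rad_other = 2, lm_member = 40, lm_other = 0.5,
    int_rad = 30, int_lm = 20, int_ca3_lm = 35,
    deep_lm_mult = 1.6, ca3_pre_lm = 20,
    theta_member = 40, theta_other = 1.5
  ), rates)
  set.seed(cfg$seed + 7919L)

  n_deep <- cfg$n_units_ca1_deep; n_sup <- cfg$n_units_ca1_sup
  n_ca3 <- cfg$n_units_ca3; n_int <- cfg$n_interneurons
  n_pr <- n_deep + n_sup + n_ca3
  n_units <- n_pr + n_int
  units <- data.frame(
    unit_id = seq_len(n_units),
    region = c(rep("CA1", n_deep + n_sup), rep("CA3", n_ca3),
               rep(c("CA1", "CA3"), length.out = n_int)),
    cell_class = c(rep("principal", n_pr), rep("interneuron", n_int)),
    sublayer = c(rep("deep", n_deep), rep("superficial", n_sup),
                 rep(NA_character_, n_ca3 + n_int)),
    tetrode = ((seq_len(n_units) - 1L) %% 8L) + 1L,
    stringsAsFactors = FALSE
  )
  is_int <- units$cell_class == "interneuron"
  is_ca3_pr <- units$region == "CA3" & !is_int
  is_ca3_int <- units$region == "CA3" & is_int
  is_deep <- !is.na(units$sublayer) & units$sublayer == "deep"
  # recent (wake-gained) motif: overlaps composite_extra but includes
  # wake-specific members absent from the sleep composite, so that
  # exploration adds coactivity structure not present in pre-sleep
  sup_pool <- which(!is.na(units$sublayer) & units$sublayer == "superficial")
  wake_only <- setdiff(c(sup_pool, which(is_ca3_pr)), c(core, extra))
  n_wake <- min(3L, length(wake_only))
  recent <- c(extra[seq_len(min(3L, length(extra)))], wake_only[seq_len(n_wake)])

  dur <- epoch_durations_s
  t_pre <- c(0, dur[["pre"]])
  t_expl <- c(t_pre[2], t_pre[2] + dur[["expl"]])
  t_post <- c(t_expl[2], t_expl[2] + dur[["post"]])
  epochs <- data.frame(
    epoch = c("pre-sleep", "exploration", "post-sleep"),
    start_s = c(t_pre[1], t_expl[1], t_post[1]),
    end_s = c(t_pre[2], t_expl[2], t_post[2]), stringsAsFactors = FALSE
  )

  # --- sleep ripple events -------------------------------------------------
  make_events <- function(win, epoch) {
    tt <- draw_event_times(cfg$ripple_rate_hz, diff(win)) + win[1]
    cls <- ifelse(stats::runif(length(tt)) < cfg$p_lm, "LM", "Rad")
    data.frame(peak_time_s = tt, true_class = cls, epoch = epoch,
               stringsAsFactors = FALSE)
  }
  ev <- rbind(make_events(t_pre, "pre-sleep"), make_events(t_post, "post-sleep"))
  # motif expressed per event: Rad -> composite (core and composite-extra
  # each expressed stochastically, giving across-event variance that the
  # coactivity estimators need); LM -> prior (core) or recent, with prior
  # probability decaying across post-sleep
  expressed <- rep("union", nrow(ev))
  lm_idx <- which(ev$true_class == "LM")
  for (i in lm_idx) {
    if (ev$epoch[i] == "pre-sleep") {
      expressed[i] <- "prior"
    } else {
      t_min <- (ev$peak_time_s[i] - t_post[1]) / 60
      expressed[i] <- if (stats::runif(1) < exp(-t_min / tau)) "prior" else "recent"
    }
  }
  ev$expressed <- expressed

  # per-event in-window (50 ms) firing probabilities per 1-ms bin.
  # Rad-event composite expression is stochastic and nested (the extra units
  # only join when the core is expressed): the variance lets the coactivity
  # estimators see the motif, the nesting couples the extra units to the
  # core motif's activation.
  n_ev <- nrow(ev)
  p_core_express <- 0.8
  p_extra_express <- 0.6
  p_lm_express <- 0.8  # not every LM ripple expresses its motif
  p_mat <- matrix(0, n_units, n_ev)
  for (i in seq_len(n_ev)) {
    u_expr <- stats::runif(1)
    m <- switch(ev$expressed[i],
                prior = if (u_expr < p_lm_express) core else integer(0),
                recent = if (u_expr < p_lm_express) recent else integer(0),
                union = c(if (u_expr < p_core_express) core,
                          if (u_expr < p_extra_express) extra))
    act <- m[stats::runif(length(m)) < participation]
    if (ev$true_class[i] == "Rad") {
      rate <- rep(r$rad_other, n_units)
      rate[is_int] <- r$int_rad
      rate[act] <- r$rad_member
      full <- c(core, extra)
      target <- length(full) * r$rad_member * participation +
        (n_pr - length(full)) * r$rad_other
    } else {
      rate <- rep(r$lm_other, n_units)
      rate[is_deep] <- r$lm_other * r$deep_lm_mult
      rate[is_int] <- r$int_lm
      rate[is_ca3_int] <- r$int_ca3_lm
      rate[act] <- r$lm_member
      target <- length(core) * r$lm_member * participation +
        (n_pr - length(core)) * r$lm_other
    }
    # compensate: expression redistributes spikes toward members instead of
    # adding them, keeping the expected principal-population total at the
    # class level regardless of the expression state, so the per-event
    # population rate carries no membership information
    pr_idx <- which(!is_int)
    bg_idx <- setdiff(pr_idx, act)
    deficit <- target - sum(rate[pr_idx])
    if (length(bg_idx) > 0L && deficit > 0) {
      rate[bg_idx] <- rate[bg_idx] + deficit / length(bg_idx)
    }
    p_mat[, i] <- rate / 1000
  }
  # shared excitability: per-event multiplicative gain on all units
  gains <- exp(stats::rnorm(n_ev, 0, excitability_sd))
  p_mat <- sweep(p_mat, 2L, gains, "*")
  counts <- matrix(stats::rbinom(n_units * n_ev, 50L, pmin(p_mat, 1)), n_units, n_ev)
  sp_unit <- rep(rep(seq_len(n_units), n_ev), as.vector(counts))
  sp_peak <- rep(rep(ev$peak_time_s, each = n_units), as.vector(counts))
  sp_time <- sp_peak + stats::runif(length(sp_peak), -0.025, 0.025)
  # CA3 transient ~100 ms before LM ripple peaks (24-ms window)
  lm_ev <- which(ev$true_class == "LM")
  if (length(lm_ev) > 0L && sum(is_ca3_pr) > 0L) {
    nc <- sum(is_ca3_pr)
    tc <- matrix(stats::rbinom(nc * length(lm_ev), 24L, r$ca3_pre_lm / 1000),
                 nc, length(lm_ev))
    cu <- rep(rep(which(is_ca3_pr), length(lm_ev)), as.vector(tc))
    cp <- rep(rep(ev$peak_time_s[lm_ev], each = nc), as.vector(tc))
    sp_unit <- c(sp_unit, cu)
    sp_time <- c(sp_time, cp + stats::runif(length(cp), -0.112, -0.088))
  }

  # --- exploration theta cycles -------------------------------------------
  theta_t <- seq(t_expl[1] + 0.0625, t_expl[2] - 0.0625, by = 0.125)
  th_exp <- stats::runif(length(theta_t)) < theta_express_p
  p_th <- matrix(r$theta_other / 1000, n_units, length(theta_t))
  p_th[is_int, ] <- r$baseline_int / 1000
  th_target <- length(recent) * r$theta_member * participation +
    (n_pr - length(recent)) * r$theta_other
  pr_idx <- which(!is_int)
  # same compensation as for ripples: cycle totals carry no expression signal
  p_th[pr_idx, ] <- th_target / n_pr / 1000
  for (j in which(th_exp)) {
    act <- recent[stats::runif(length(recent)) < participation]
    p_th[pr_idx, j] <- r$theta_other / 1000
    p_th[act, j] <- r$theta_member / 1000
    bg <- setdiff(pr_idx, act)
    deficit <- th_target - sum(p_th[pr_idx, j] * 1000)
    if (length(bg) > 0L && deficit > 0) {
      p_th[bg, j] <- p_th[bg, j] + deficit / length(bg) / 1000
    }
  }
  p_th <- sweep(p_th, 2L,
                exp(stats::rnorm(length(theta_t), 0, excitability_sd)), "*")
  cth <- matrix(stats::rbinom(length(p_th), 125L, p_th), n_units, length(theta_t))
  tu <- rep(rep(seq_len(n_units), length(theta_t)), as.vector(cth))
  tp <- rep(rep(theta_t, each = n_units), as.vector(cth))
  sp_unit <- c(sp_unit, tu)
  sp_time <- c(sp_time, tp + stats::runif(length(tp), -0.0625, 0.0625))

  # --- baseline Poisson spikes --------------------------------------------
  total <- t_post[2]
  base_rate <- ifelse(is_int, r$baseline_int, r$baseline_pr)
  nb <- stats::rpois(n_units, base_rate * total)
  bu <- rep(seq_len(n_units), nb)
  bt <- stats::runif(sum(nb), 0, total)
  sp_unit <- c(sp_unit, bu)
  sp_time <- c(sp_time, bt)

  o <- order(sp_time)
  spikes <- data.frame(unit_id = sp_unit[o], spike_time_s = sp_time[o])

  structure(list(
    units = units, spikes = spikes, epochs = epochs, events = ev,
    theta_cycles = data.frame(time_s = theta_t, expressed = th_exp),
    core_motif = core, composite_extra = extra, recent_motif = recent,
    tau_min = tau
  ), class = "spike_session")
}

#' Spike counts in fixed windows around events
#'
#' Builds the unit-by-event matrix of spike counts in a window centred on
#' each event time (default the 50-ms peak-centred population-vector
#' window, `[peak - 25, peak + 25)` ms).
#'
#' @param session a `spike_session`, or a data frame of spikes
#'   (`unit_id`, `spike_time_s`) plus `unit_ids`.
#' @param event_times_s numeric event centres (s).
#' @param window_ms full window width in ms (default 50).
#' @param unit_ids units to include (default: all principal cells when a
#'   session is given, otherwise all units present).
#' @return integer matrix units x events with `unit_ids` as rownames.
#' @export
population_vectors <- function(session, event_times_s, window_ms = 50,
                               unit_ids = NULL) {
  if (inherits(session, "spike_session")) {
    spikes <- session$spikes
    if (is.null(unit_ids)) {
      unit_ids <- session$units$unit_id[session$units$cell_class == "principal"]
    }
  } else {
    spikes <- session
    if (is.null(unit_ids)) unit_ids <- sort(unique(spikes$unit_id))
  }
  half <- window_ms / 2000
  n_u <- length(unit_ids)
  out <- matrix(0L, n_u, length(event_times_s),
                dimnames = list(unit_ids, NULL))
  sel <- spikes$unit_id %in% unit_ids
  st <- spikes$spike_time_s[sel]
  su <- match(spikes$unit_id[sel], unit_ids)
  if (length(event_times_s) == 0L || length(st) == 0L) return(out)
  # assign each spike to the (at most one, given non-overlapping windows) event
  idx <- findInterval(st, c(rbind(event_times_s - half, event_times_s + half)))
  in_win <- idx %% 2L == 1L
  ev_id <- (idx[in_win] + 1L) %/% 2L
  tab <- table(factor(su[in_win], levels = seq_len(n_u)),
               factor(ev_id, levels = seq_along(event_times_s)))
  out[, ] <- as.integer(tab)
  out
}

#' Column-wise z-score of a population-vector matrix
#'
#' Z-scores each unit's counts across events (rows of a units x events
#' matrix). Constant units are flagged with an attribute and set to zero.
#' @param counts units x events matrix.
#' @return z-scored matrix, attribute `constant_units` marking zero-variance rows.
#' @export
zscore_pvs <- function(counts) {
  m <- rowMeans(counts)
  s <- apply(counts, 1L, stats::sd)
  const <- s == 0 | !is.finite(s)
  s[const] <- 1
  z <- (counts - m) / s
  z[const, ] <- 0
  attr(z, "constant_units") <- which(const)
  z
}
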