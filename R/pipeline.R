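#' Run the full analysis pipeline on a synthetic session
#'
#' Orchestrates simulate -> detect -> csd -> states -> population ->
#' coactivity -> motifs -> reactivation on generated data, writing CSV/JSON
#' outputs and a run log to `out_dir`. Per-stage seeds derive
#' deterministically from `cfg$seed`, so a re-run with the same config
#' reproduces the outputs bit for bit.
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param lfp_duration_s duration of the simulated laminar record (default
#'   300 s).
#' @param epoch_durations_s spike-session epochs (see
#'   [simulate_spike_session()]).
#' @param stages character subset of
#'   `c("simulate","detect","csd","states","population","coactivity",
#'   "motifs","reactivation")`; later stages re-use earlier results, so the
#'   subset must be prefix-closed.
#' @return list of stage results (invisible components noted in the log).
#' @export
run_pipeline <- function(cfg, out_dir = NULL,
                         lfp_duration_s = 300,
                         epoch_durations_s = c(pre = 900, expl = 600, post = 4200),
                         stages = c("simulate", "detect", "csd", "states",
                                    "population", "coactivity", "motifs",
                                    "reactivation")) {
  t0 <- Sys.time()
  res <- list(config = cfg)
  log_lines <- c(sprintf("ripplelamina pipeline; seed=%d; R %s",
                         cfg$seed, getRversion()))
  emit <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  want <- function(s) s %in% stages

  if (want("simulate")) {
    sim <- simulate_laminar_lfp(cfg, duration_s = lfp_duration_s)
    session <- simulate_spike_session(cfg, sim$truth,
                                      epoch_durations_s = epoch_durations_s)
    res$recording <- sim$recording
    res$truth <- sim$truth
    res$session <- session
    emit("simulate: %d LFP events, %d spikes",
         nrow(sim$truth$events), nrow(session$spikes))
  }

  if (want("detect")) {
    rec <- res$recording
    pyr <- round(stats::median(layer_channels(rec$layer_map, "pyramidale")))
    ref <- layer_channels(rec$layer_map, "granule")[1L]
    res$ripples <- detect_ripples(rec$data[pyr, ], rec$data[ref, ], rec$fs_hz)
    emit("detect: %d candidates, %d valid", nrow(res$ripples),
         sum(res$ripples$valid))
  }

  if (want("csd")) {
    rec <- res$recording
    csd <- smooth_laminar(compute_csd(rec$data), rec$spacing_um)
    valid <- res$ripples[res$ripples$valid, ]
    sigs <- ripple_signatures(csd, valid$peak_time_s, rec$fs_hz)
    kept <- attr(sigs, "kept")
    pca <- pca_signatures(sigs, rec$layer_map)
    labels <- label_by_pc1(pca$pc1_strengths)
    sinks <- apply(sigs, 1L, dominant_sink_layer, layer_map = rec$layer_map)
    res$csd <- list(matrix = csd, signatures = sigs, pca = pca,
                    labels = labels, sinks = sinks,
                    peak_times = valid$peak_time_s[kept])
    emit("csd: %d signatures; LM fraction (dominant sink) %.3f",
         nrow(sigs), mean(sinks == "lacunosum-moleculare"))
  }

  if (want("states")) {
    rec <- res$recording
    dg <- layer_channels(rec$layer_map, "moleculare") - 1L  # interior rows
    en <- dg_energy(res$csd$matrix, dg, rec$fs_hz)
    ud <- simulate_updown_energy(cfg, duration_s = 600)
    st <- infer_updown(ud$energy, seed = cfg$seed + 11L, min_epochs = 10L)
    ch <- ripple_chains(res$session$events$peak_time_s)
    tm <- transition_matrix(res$session$events$true_class, ch$chain_id,
                            classes = c("Rad", "LM"), n_shuffle = 200,
                            seed = cfg$seed + 12L)
    res$states <- list(dg_energy = en, updown = st,
                       updown_truth = ud$states, chains = ch,
                       transitions = tm)
    emit("states: %d Up epochs, %d Down epochs; %d chains",
         sum(st$epochs$state == "Up"), sum(st$epochs$state == "Down"),
         length(ch$lengths))
  }

  session <- res$session
  ev <- session$events
  pr_units <- session$units$unit_id[session$units$cell_class == "principal"]

  if (want("population")) {
    post <- ev[ev$epoch == "post-sleep", ]
    iso <- is_isolated(post$peak_time_s)
    peth_rad <- compute_peth(session$spikes,
                             post$peak_time_s[iso & post$true_class == "Rad"],
                             unit_ids = pr_units)
    peth_lm <- compute_peth(session$spikes,
                            post$peak_time_s[iso & post$true_class == "LM"],
                            unit_ids = pr_units)
    res$population <- list(peth_rad = peth_rad, peth_lm = peth_lm,
                           peak_rad = peth_peak_rate(peth_rad),
                           peak_lm = peth_peak_rate(peth_lm))
    emit("population: mean peak rate Rad %.2f Hz, LM %.2f Hz",
         mean(res$population$peak_rad), mean(res$population$peak_lm))
  }

  if (want("coactivity")) {
    post <- ev[ev$epoch == "post-sleep", ]
    pv_rad <- population_vectors(session, post$peak_time_s[post$true_class == "Rad"])
    pv_lm <- population_vectors(session, post$peak_time_s[post$true_class == "LM"])
    g_rad <- population_conditioned_coactivity(pv_rad)
    g_lm <- population_conditioned_coactivity(pv_lm)
    res$coactivity <- list(
      pv_rad = pv_rad, pv_lm = pv_lm, graph_rad = g_rad, graph_lm = g_lm,
      balance_rad = structural_balance(g_rad),
      balance_lm = structural_balance(g_lm),
      gini_rad = mean(apply(pv_rad, 2L, gini_sparsity), na.rm = TRUE),
      gini_lm = mean(apply(pv_lm, 2L, gini_sparsity), na.rm = TRUE))
    emit("coactivity: Gini Rad %.3f LM %.3f; balance Rad %.3f LM %.3f",
         res$coactivity$gini_rad, res$coactivity$gini_lm,
         res$coactivity$balance_rad, res$coactivity$balance_lm)
  }

  if (want("motifs")) {
    m <- extract_motifs(res$coactivity$pv_lm, seed = cfg$seed + 21L)
    res$motifs <- m
    emit("motifs: %d significant motifs (threshold %.3f)", m$n_motifs,
         m$threshold)
  }

  if (want("reactivation")) {
    pre <- ev[ev$epoch == "pre-sleep", ]
    post <- ev[ev$epoch == "post-sleep", ]
    pv_pre <- population_vectors(session, pre$peak_time_s)
    pv_theta <- population_vectors(session, session$theta_cycles$time_s,
                                   window_ms = 125)
    a_pre <- population_conditioned_coactivity(pv_pre)$adjacency
    a_theta <- population_conditioned_coactivity(pv_theta)$adjacency
    W <- recent_prior_transform(a_pre, a_theta)
    pv_post <- population_vectors(session, post$peak_time_s)
    zpost <- zscore_pvs(pv_post)
    bal <- balance_score(W$W_recent, zpost)
    t_post_min <- (post$peak_time_s - session$epochs$start_s[3L]) / 60
    ds <- drift_timecourse(bal, t_post_min, classes = post$true_class)
    lm_series <- ds[ds$class == "LM", ]
    fit <- if (nrow(lm_series) >= 4L) {
      fit_flat_vs_exponential(lm_series$t_min, lm_series$value, n_boot = 200,
                              seed = cfg$seed + 31L)
    } else NULL
    res$reactivation <- list(W = W, balance = bal, drift = ds, fit = fit)
    if (!is.null(fit)) {
      emit("reactivation: LM drift model %s (BIC flat %.1f vs exp %.1f)",
           fit$model, fit$bic_flat, fit$bic_exp)
    }
  }

  emit("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(res$ripples)) {
      write_ripple_table(res$ripples, file.path(out_dir, "ripples.csv"))
    }
    if (!is.null(res$csd)) {
      utils::write.csv(data.frame(peak_time_s = res$csd$peak_times,
                                  label = res$csd$labels,
                                  dominant_sink = res$csd$sinks),
                       file.path(out_dir, "ripple_classes.csv"),
                       row.names = FALSE)
    }
    if (!is.null(res$session)) {
      write_spike_session(res$session, file.path(out_dir, "session"))
    }
    if (!is.null(res$reactivation)) {
      utils::write.csv(res$reactivation$drift,
                       file.path(out_dir, "drift_series.csv"),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  res$log <- log_lines
  res
}
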