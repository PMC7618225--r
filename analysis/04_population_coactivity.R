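#!/usr/bin/env Rscript
# Ripple-locked population analyses on the simulated spike session: PETHs
# and peak rates, ripple-type decoding with the margin-preserving shuffle
# control, coactivity graphs, structural balance, sparsity, and intrinsic
# dimensionality. Reads results/data/session*, writes results/.

suppressMessages(library(ripplelamina))

session <- read_spike_session("results/data/session")
ev <- session$events
post <- ev[ev$epoch == "post-sleep", ]
pr_units <- session$units$unit_id[session$units$cell_class == "principal"]

iso <- is_isolated(post$peak_time_s)
peth_rad <- compute_peth(session$spikes,
                         post$peak_time_s[iso & post$true_class == "Rad"],
                         unit_ids = pr_units)
peth_lm <- compute_peth(session$spikes,
                        post$peak_time_s[iso & post$true_class == "LM"],
                        unit_ids = pr_units)
cat(sprintf("peak rates (principal cells): Rad %.1f Hz, LM %.1f Hz\n",
            mean(peth_peak_rate(peth_rad)), mean(peth_peak_rate(peth_lm))))

pv_rad <- population_vectors(session, post$peak_time_s[post$true_class == "Rad"])
pv_lm <- population_vectors(session, post$peak_time_s[post$true_class == "LM"])

dec <- decode_ripple_type(cbind(pv_lm, pv_rad),
                          rep(c("LM", "Rad"), c(ncol(pv_lm), ncol(pv_rad))),
                          n_cells = 15, n_perm = 50, n_cv = 10,
                          min_events_per_class = 100, seed = 8)
cat(sprintf("ripple-type decoding: %.3f bits observed vs %.3f bits after coactivity shuffle\n",
            dec$mean_observed, dec$mean_control))

g_rad <- population_conditioned_coactivity(pv_rad)
g_lm <- population_conditioned_coactivity(pv_lm)
write_coactivity_graph(g_rad, "results/graph_rad")
write_coactivity_graph(g_lm, "results/graph_lm")
cat(sprintf("structural balance: Rad %.3f, LM %.3f\n",
            structural_balance(g_rad), structural_balance(g_lm)))
cat(sprintf("Gini sparsity: Rad %.3f, LM %.3f\n",
            mean(apply(pv_rad, 2, gini_sparsity), na.rm = TRUE),
            mean(apply(pv_lm, 2, gini_sparsity), na.rm = TRUE)))

ab_rad <- abid_dimensionality(t(pv_rad), k = 50, subsample = 100, n_perm = 100,
                              seed = 9)$mean_d
ab_lm <- abid_dimensionality(t(pv_lm), k = 50, subsample = 100, n_perm = 100,
                             seed = 10)$mean_d
cat(sprintf("ABID: Rad %.2f, LM %.2f; participation ratio: Rad %.2f, LM %.2f\n",
            ab_rad, ab_lm, participation_ratio(t(pv_rad)),
            participation_ratio(t(pv_lm))))

incl <- inclusion_resampled(t(pv_lm), t(pv_rad), n_iter = 500, seed = 11)
cat(sprintf("inclusion of LM patterns into Rad patterns: %.3f (mean over resamples)\n",
            mean(incl)))

summary_df <- data.frame(
  measure = c("peak_rate_rad_hz", "peak_rate_lm_hz", "mi_bits", "mi_shuffled_bits",
              "balance_rad", "balance_lm", "gini_rad", "gini_lm",
              "abid_rad", "abid_lm", "inclusion_lm_to_rad"),
  value = c(mean(peth_peak_rate(peth_rad)), mean(peth_peak_rate(peth_lm)),
            dec$mean_observed, dec$mean_control,
            structural_balance(g_rad), structural_balance(g_lm),
            mean(apply(pv_rad, 2, gini_sparsity), na.rm = TRUE),
            mean(apply(pv_lm, 2, gini_sparsity), na.rm = TRUE),
            ab_rad, ab_lm, mean(incl)))
utils::write.csv(summary_df, "results/population_summary.csv", row.names = FALSE)
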