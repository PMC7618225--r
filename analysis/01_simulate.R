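#!/usr/bin/env Rscript
# Simulate the study's synthetic recordings: a laminar LFP session with
# planted radiatum-sink and lacunosum-moleculare-sink ripples, a three-epoch
# spike session with planted coactivity motifs and a prior-motif decay of
# tau = 13 min, and a bimodal molecular-layer energy series.
# Writes the raw data under results/data/.

suppressMessages(library(ripplelamina))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 1, p_lm = 0.16)
write_sim_config(cfg, file.path(out, "config.yaml"))

sim <- simulate_laminar_lfp(cfg, duration_s = 300)
write_laminar_recording(sim$recording, file.path(out, "laminar"))
utils::write.csv(sim$truth$events, file.path(out, "lfp_ground_truth.csv"),
                 row.names = FALSE)
cat(sprintf("laminar LFP: %d channels x %d samples, %d planted events (%.0f%% LM)\n",
            nrow(sim$recording$data), ncol(sim$recording$data),
            nrow(sim$truth$events),
            100 * mean(sim$truth$events$true_class == "LM")))

# spike session uses a balanced class mix so the population analyses have
# enough events per class
cfg_sp <- sim_config(seed = 1)
session <- simulate_spike_session(cfg_sp)
write_spike_session(session, file.path(out, "session"))
cat(sprintf("spike session: %d units, %d spikes, %d ripple events, %d theta cycles\n",
            nrow(session$units), nrow(session$spikes), nrow(session$events),
            nrow(session$theta_cycles)))

ud <- simulate_updown_energy(cfg, duration_s = 1200, gap_sd = 3)
utils::write.csv(data.frame(t_s = seq_along(ud$energy) / ud$fs_hz,
                            energy = ud$energy, true_state = ud$states),
                 file.path(out, "updown_energy.csv"), row.names = FALSE)
cat(sprintf("up/down energy: %d samples at %g Hz\n", length(ud$energy), ud$fs_hz))
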