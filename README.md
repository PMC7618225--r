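# ripplelamina

Laminar profiling of hippocampal sharp-wave ripples and the population
dynamics that distinguish ripple types.

## The problem

Sharp-wave ripples (SWRs) are transient 100–250 Hz oscillations in CA1
*stratum pyramidale* that replay waking activity during sleep. Individual
ripples are not interchangeable: their laminar current-source-density (CSD)
profiles range from events with a dominant current sink in *stratum
radiatum* (Rad<sup>sink</sup>, reflecting CA3 drive) to events with a
dominant sink in *stratum lacunosum-moleculare* (LM<sup>sink</sup>,
reflecting entorhinal-facing drive). The two profiles recruit different
neuronal populations — composite, denser, higher-dimensional patterns in
Rad<sup>sink</sup> events versus sparse, low-dimensional "core" motifs in
LM<sup>sink</sup> events — and show different offline reactivation dynamics,
with LM<sup>sink</sup> content drifting from prior (pre-sleep) toward recent
(wake-gained) coactivity with an exponential time constant of minutes.

This package is an analysis pipeline for that programme, for
electrophysiologists and computational neuroscientists working with laminar
LFP and simultaneously recorded spike trains. It contains:

* ripple detection and validation (5×-median Hilbert-envelope threshold,
  80–250 Hz band, ≥4-cycle rule, power-ratio criteria);
* per-event CSD signatures, `CSD_n = -(LFP_{n-1} - 2 LFP_n + LFP_{n+1})`,
  50-µm laminar smoothing, dominant-sink labelling, and 30/70-percentile
  classes on the PC1 continuum or on the normalized LM CSD;
* a pyramidal-waveform LDA classifier with leave-one-subject-out validation
  and chance-normalized gain;
* Up/Down state inference from dentate molecular-layer CSD energy
  (GMM-initialized two-state HMM), ripple chains and shuffle-normalized
  Markov transitions, NREM occurrence profiles;
* ripple-locked population analyses: PETHs, Δrate = log₁₀(ripple/baseline),
  phase coupling, ripple-type decoding by mutual information with a
  margin-preserving spike shuffle (row and column sums conserved exactly);
* signed coactivity graphs (population-conditioned and ridge
  fully-conditioned), structural balance by triad census, Gini sparsity,
  angle-based intrinsic dimensionality (ABID), participation ratio,
  asymmetric pattern inclusion;
* PCA/ICA coactivity motifs with the Marčenko–Pastur threshold
  `(1 + √(N/B))²`, leave-one-neuron-out activation, and the contribution
  gain of neurons aggregated from LM<sup>sink</sup> into Rad<sup>sink</sup>
  events against margin-preserving surrogates;
* offline reactivation: GLM peer prediction, the recent-to-prior balance
  `vᵀ W v` with `W_recent = A_theta A_pre⁻¹`, 10-minute drift time courses,
  and flat-vs-exponential model selection with
  `BIC = k·log(n) + n·log(SSE/n)` and bootstrap CIs for τ;
* a synthetic-data generator producing laminar LFP, three-epoch spike
  sessions and state sequences with full ground truth, used to validate
  every analysis end to end.

## Worked example

The `analysis/` scripts run the full workflow on synthetic study conditions
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_detect_classify.R
Rscript analysis/03_state_dynamics.R
Rscript analysis/04_population_coactivity.R
Rscript analysis/05_motifs_reactivation.R
```

Output of `02_detect_classify.R` (300-s laminar record, 16 channels,
planted LM fraction 0.16):

```
113 candidates, 113 valid; planted 113 events
dominant sinks: 0.84 radiatum, 0.16 lacunosum-moleculare
PC1 explains 89% of signature variance
dominant-sink agreement with planted classes: 100.0%
LDA: accuracy 0.584 vs null 0.308 -> chance-normalized gain 89.6%
```

Every planted event is detected and its dominant sink recovered; the
waveform classifier beats its label-shuffled null (0.58 vs 0.31 three-class
accuracy). From `04_population_coactivity.R`:

```
peak rates (principal cells): Rad 16.2 Hz, LM 8.3 Hz
ripple-type decoding: 0.432 bits observed vs 0.233 bits after coactivity shuffle
structural balance: Rad 0.995, LM 0.619
Gini sparsity: Rad 0.686, LM 0.831
ABID: Rad 16.68, LM 14.27
```

Rad-sink events engage more neurons at higher rates (lower Gini), carry
more balanced coactivity graphs, and are higher-dimensional; the decoder
exceeds its margin-preserving shuffle control, so class information lives
in coactivity beyond rates. From `05_motifs_reactivation.R`:

```
LM-event motifs: 2 significant (threshold 1.56; top eigenvalue 4.90)
motif 2 matches the planted core (|cos| = 0.92)
aggregated units on the core motif: 11 15 17 18 19 20 (planted composite-extra: 15 16 17 18 19 20)
LM ripples: exponential model (BIC flat -130.2 vs exp -149.8); tau = 5.3 min (95% CI 0.5-23.7)
Rad ripples: flat model (BIC flat -188.1 vs exp -181.3)
LM ripples: theta-model accuracy pre 0.010 vs post 0.201 (reactivation p = 0.0000)
```

The planted core motif is recovered, the superficial composite-extra units
are flagged as aggregated into it during Rad-sink events, the LM-sink
balance drifts exponentially (the single-session τ estimate is noisy; its
bootstrap CI covers the planted 13 min) while Rad-sink stays flat, and
wake (theta) coactivity reactivates in post-sleep but not pre-sleep
ripples.

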