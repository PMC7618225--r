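# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# 120-s laminar recording with planted ripples of both types
fixture_lfp <- function() {
  memo("lfp", function() simulate_laminar_lfp(sim_config(seed = 7), duration_s = 120))
}

# smoothed CSD of the fixture recording
fixture_csd <- function() {
  memo("csd", function() {
    sim <- fixture_lfp()
    smooth_laminar(compute_csd(sim$recording$data), sim$recording$spacing_um)
  })
}

# moderate spike session (pre 1200 / expl 600 / post 1800 s)
fixture_session <- function() {
  memo("session", function() {
    simulate_spike_session(sim_config(seed = 7),
                           epoch_durations_s = c(pre = 1200, expl = 600,
                                                 post = 1800))
  })
}

# event-class population vectors of the fixture session (post-sleep)
fixture_pvs <- function() {
  memo("pvs", function() {
    ss <- fixture_session()
    post <- ss$events[ss$events$epoch == "post-sleep", ]
    list(session = ss,
         post = post,
         lm = population_vectors(ss, post$peak_time_s[post$true_class == "LM"]),
         rad = population_vectors(ss, post$peak_time_s[post$true_class == "Rad"]))
  })
}

# units x events matrix with three planted, independently expressed assemblies
make_assembly_counts <- function(seed, n_units = 30, n_events = 800,
                                 base = 0.3, boost = 2.5, p_expr = 0.2) {
  set.seed(seed)
  assemblies <- list(1:5, 6:10, 11:15)
  counts <- matrix(stats::rpois(n_units * n_events, base), n_units, n_events)
  for (a in assemblies) {
    on <- which(stats::runif(n_events) < p_expr)
    counts[a, on] <- counts[a, on] + stats::rpois(length(a) * length(on), boost)
  }
  list(counts = counts, assemblies = assemblies)
}

# indicator unit vector over n units
unit_vec <- function(idx, n) {
  v <- rep(0, n)
  v[idx] <- 1
  v / sqrt(sum(v^2))
}

# brute-force triad census oracle for structural balance
balance_brute <- function(A, tol = 1e-12) {
  n <- nrow(A)
  if (n < 3L) return(NA_real_)
  tri <- utils::combn(n, 3)
  bal <- tot <- 0
  for (k in seq_len(ncol(tri))) {
    i <- tri[1, k]; j <- tri[2, k]; l <- tri[3, k]
    w <- c(A[i, j], A[i, l], A[j, l])
    if (any(abs(w) <= tol)) next
    tot <- tot + 1
    if (sum(w < 0) %in% c(0, 2)) bal <- bal + 1
  }
  if (tot == 0) NA_real_ else bal / tot
}

# mean-absolute-difference Gini oracle
gini_mad <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# three-subject synthetic waveform set derived from the laminar generator
classifier_fixture <- function() {
  memo("classifier", function() {
    mk_subj <- function(seed) {
      sim <- simulate_laminar_lfp(sim_config(seed = seed), duration_s = 120)
      rec <- sim$recording
      pyr <- round(median(layer_channels(rec$layer_map, "pyramidale")))
      csd <- smooth_laminar(compute_csd(rec$data), rec$spacing_um)
      tt <- sim$truth$events$peak_time_s
      sigs <- ripple_signatures(csd, tt, rec$fs_hz)
      kept <- attr(sigs, "kept")
      lab <- label_by_lm_csd(sigs, rec$layer_map)
      tr <- ripple_traces(rec$data[pyr, ], tt[kept], rec$fs_hz)
      k2 <- attr(tr, "kept")
      list(traces = tr, labels = lab$labels[k2],
           truth = sim$truth$events$true_class[kept][k2],
           subj = rep(seed, nrow(tr)))
    }
    subs <- lapply(c(11, 12, 13), mk_subj)
    list(traces = do.call(rbind, lapply(subs, `[[`, "traces")),
         labels = unlist(lapply(subs, `[[`, "labels")),
         truth = unlist(lapply(subs, `[[`, "truth")),
         subj = unlist(lapply(subs, `[[`, "subj")))
  })
}

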