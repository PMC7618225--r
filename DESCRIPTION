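Package: ripplelamina
Title: Laminar Current-Source-Density Profiling and Population Dynamics of Hippocampal Ripples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for laminar profiling of hippocampal sharp-wave
    ripples. Detects ripples from multi-channel LFP, computes per-event current
    source density (CSD) signatures, classifies events by their dominant sink
    (stratum radiatum vs stratum lacunosum-moleculare), and quantifies the
    downstream population structure of each ripple type: ripple-locked firing,
    population-vector decoding with margin-preserving shuffles, signed coactivity
    graphs with structural balance, intrinsic dimensionality (ABID, participation
    ratio), ICA coactivity motifs with a Marcenko-Pastur significance threshold,
    and the drift of offline reactivation fitted with flat-versus-exponential
    model selection. Includes a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    MASS,
    mclust,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
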