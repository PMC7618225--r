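#' @importFrom mclust Mclust mclustBIC
#' @importFrom MASS lda
#' @importFrom minpack.lm nlsLM nls.lm.control
#' @importFrom signal butter filtfilt
NULL
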