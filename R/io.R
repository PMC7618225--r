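#' Write a laminar recording to flat binary + JSON sidecar
#'
#' Samples are written channel-major as little-endian float32; the sidecar
#' records sampling rate, channel count/order, layer map and spacing so the
#' format stays language-neutral.
#'
#' @param recording a `laminar_recording`.
#' @param path basename; writes `<path>.bin` and `<path>.json`.
#' @return invisibly, the two paths.
#' @export
write_laminar_recording <- function(recording, path) {
  bin_path <- paste0(path, ".bin")
  json_path <- paste0(path, ".json")
  con <- file(bin_path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(recording$data)), con, size = 4L, endian = "little")
  meta <- list(fs_hz = recording$fs_hz,
               n_channels = nrow(recording$data),
               n_samples = ncol(recording$data),
               channel_order = seq_len(nrow(recording$data)),
               layer_map = recording$layer_map,
               spacing_um = recording$spacing_um,
               dtype = "float32", order = "channel-major",
               endianness = "little")
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(bin = bin_path, json = json_path))
}

#' Read a laminar recording written by [write_laminar_recording()]
#' @param path basename used at write time.
#' @return a `laminar_recording`.
#' @export
read_laminar_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = meta$n_channels * meta$n_samples,
               size = 4L, endian = "little")
  structure(list(data = matrix(x, nrow = meta$n_channels, byrow = TRUE),
                 fs_hz = meta$fs_hz, layer_map = meta$layer_map,
                 spacing_um = meta$spacing_um),
            class = "laminar_recording")
}

#' Write a spike session as CSV files
#'
#' `<path>_units.csv`, `<path>_spikes.csv`, `<path>_epochs.csv`,
#' `<path>_events.csv`; times carry 6 decimal places.
#' @param session a `spike_session`.
#' @param path basename.
#' @return invisibly, the paths.
#' @export
write_spike_session <- function(session, path) {
  paths <- c(units = paste0(path, "_units.csv"),
             spikes = paste0(path, "_spikes.csv"),
             epochs = paste0(path, "_epochs.csv"),
             events = paste0(path, "_events.csv"))
  utils::write.csv(session$units, paths["units"], row.names = FALSE)
  sp <- session$spikes
  sp$spike_time_s <- sprintf("%.6f", sp$spike_time_s)
  utils::write.csv(sp, paths["spikes"], row.names = FALSE)
  utils::write.csv(session$epochs, paths["epochs"], row.names = FALSE)
  ev <- session$events
  ev$peak_time_s <- sprintf("%.6f", ev$peak_time_s)
  utils::write.csv(ev, paths["events"], row.names = FALSE)
  invisible(paths)
}

#' Read a spike session written by [write_spike_session()]
#' @param path basename used at write time.
#' @return a `spike_session` (without theta-cycle/motif ground truth).
#' @export
read_spike_session <- function(path) {
  structure(list(
    units = utils::read.csv(paste0(path, "_units.csv")),
    spikes = utils::read.csv(paste0(path, "_spikes.csv")),
    epochs = utils::read.csv(paste0(path, "_epochs.csv")),
    events = utils::read.csv(paste0(path, "_events.csv"))
  ), class = "spike_session")
}

#' Write a ripple table as CSV (times with 6 decimals)
#' @param ripples a `ripple_table`.
#' @param path file path.
#' @export
write_ripple_table <- function(ripples, path) {
  out <- as.data.frame(ripples)
  for (col in c("peak_time_s", "onset_s", "offset_s")) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulation config as YAML
#' @param cfg a `sim_config`.
#' @param path file path.
#' @export
write_sim_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Read a simulation config written by [write_sim_config()]
#' @param path file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write a coactivity graph as edge list + metadata
#' @param graph a `coactivity_graph`.
#' @param path basename; writes `<path>_edges.csv`, `<path>_meta.json`.
#' @export
write_coactivity_graph <- function(graph, path) {
  A <- graph$adjacency
  idx <- which(row(A) != col(A), arr.ind = TRUE)
  edges <- data.frame(i = idx[, 1L], j = idx[, 2L], weight = A[idx])
  utils::write.csv(edges, paste0(path, "_edges.csv"), row.names = FALSE)
  jsonlite::write_json(list(estimator = graph$estimator,
                            symmetric = graph$symmetric,
                            n_units = nrow(A)),
                       paste0(path, "_meta.json"), auto_unbox = TRUE)
  invisible(path)
}
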