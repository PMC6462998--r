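# Text import/export: rasters, connection tables, frame stacks, configs.

#' Write / read spike rasters as two-column delimited text
#'
#' The de-facto raster exchange format: tab-separated neuron_id, time_ms.
#'
#' @param spikes a [SpikeData-class].
#' @param file path.
#' @return invisibly, the path (write) or a [SpikeData-class] (read).
#' @export
writeSpikes <- function(spikes, file) {
  df <- spikes@events[, c("neuron", "time")]
  names(df) <- c("neuron_id", "time_ms")
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeSpikes
#' @param layer,n,duration layer label, neuron count and duration to attach
#'   on read (not stored in the raster file itself).
#' @export
readSpikes <- function(file, layer = "layer", n = NULL, duration = NULL) {
  df <- read.table(file, header = TRUE, sep = "\t")
  names(df) <- c("neuron", "time")
  if (is.null(n)) n <- max(df$neuron, 1L)
  if (is.null(duration)) duration <- max(df$time, 0)
  new("SpikeData", layer = layer, events = df, n = as.integer(n),
      duration = duration)
}

#' Export all rasters of a simulation result
#'
#' One `<layer>.tsv` per layer under `dir`.
#'
#' @param result a [SimulationResult-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
exportRasters <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(result@spikes), function(lbl) {
    p <- file.path(dir, paste0(lbl, ".tsv"))
    writeSpikes(result@spikes[[lbl]], p)
    p
  }, "")
  invisible(paths)
}

#' Export a connection set as delimited text
#'
#' @param cs a [ConnectionSet-class].
#' @param file path; tab-separated pre, post, weight, delay.
#' @return invisibly, the path.
#' @export
writeConnections <- function(cs, file) {
  write.table(cs@synapses, file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Export a frame sequence as numbered PNG files plus a metadata sidecar
#'
#' @param frames a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the PNG paths.
#' @export
exportFrames <- function(frames, dir, prefix = "frame") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nf <- nFrames(frames)
  paths <- character(nf)
  for (f in seq_len(nf)) {
    paths[f] <- file.path(dir, sprintf("%s_%04d.png", prefix, f))
    png::writePNG(frames@frames[f, , ], paths[f])
  }
  md <- frames@metadata
  keep <- vapply(md, function(x) is.atomic(x) && length(x) <= 8, TRUE)
  lines <- c(sprintf("frame_interval_ms: %.6g", frames@frameInterval),
             sprintf("px_per_degree: %.6g", frames@pxPerDegree),
             vapply(names(md)[keep], function(k)
               paste0(k, ": ", paste(format(md[[k]]), collapse = " ")), ""))
  writeLines(lines, file.path(dir, paste0(prefix, "_meta.txt")))
  invisible(paths)
}

#' Read / write a configuration as YAML
#'
#' @param file path.
#' @return [readConfig()]: the configuration list (defaults overridden by
#'   the file's entries); [writeConfig()]: invisibly, the path.
#' @export
readConfig <- function(file) {
  networkConfig(yaml::read_yaml(file))
}

#' @rdname readConfig
#' @param config a configuration list.
#' @export
writeConfig <- function(config, file) {
  yaml::write_yaml(config, file)
  invisible(file)
}
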