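#' Write a recording to a plain-text bundle
#'
#' Serializes an [MEARecording-class] to a directory of portable text files:
#' `layout.csv` (channel grid and positions), `lfp.csv` (channels x samples,
#' values rounded to float32 precision), `meta.json` (sample rate, stimulus
#' times, duration, seed), `spikes.json` (per-channel spike times at full
#' float64 precision) and, when present, `ground_truth.json`.  The round trip
#' through [readRecording()] is lossless for spike times and float32-accurate
#' for the LFP.
#'
#' @param rec an [MEARecording-class].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
writeRecording <- function(rec, path) {
  stopifnot(is(rec, "MEARecording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  lay <- recordingLayout(rec)
  data.table::fwrite(
    data.frame(channel = seq_len(nChannels(rec)),
               x_mm = lay@positions[, 1], y_mm = lay@positions[, 2]),
    file.path(path, "layout.csv"))
  # float32 has ~7.2 significant decimal digits
  data.table::fwrite(
    data.table::as.data.table(signif(lfp(rec), 8)),
    file.path(path, "lfp.csv"), col.names = FALSE)
  meta <- list(sampleRate = sampleRate(rec), stimTimes = stimTimes(rec),
               duration = metadata(rec)$duration,
               nRows = lay@nRows, nCols = lay@nCols, pitch = lay@pitch,
               seed = metadata(rec)$seed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(spikeTimes(rec), file.path(path, "spikes.json"),
                       digits = NA)
  gt <- groundTruth(rec)
  if (!is.null(gt)) {
    gt$cleanLfp <- NULL                 # regenerable; keep the bundle small
    jsonlite::write_json(gt, file.path(path, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording bundle
#'
#' Counterpart of [writeRecording()].  The ground-truth block is optional
#' (recordings of real data may not have one); a missing required file raises
#' an error naming it.
#'
#' @param path directory written by [writeRecording()].
#' @return an [MEARecording-class].
#' @export
readRecording <- function(path) {
  need <- c("layout.csv", "lfp.csv", "meta.json", "spikes.json")
  for (f in need)
    if (!file.exists(file.path(path, f)))
      stop(sprintf("malformed recording bundle: missing '%s'", f))
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  lay <- electrodeLayout(meta$nRows, meta$nCols, meta$pitch)
  lfpMat <- as.matrix(data.table::fread(file.path(path, "lfp.csv"),
                                        header = FALSE))
  dimnames(lfpMat) <- NULL
  spikes <- jsonlite::read_json(file.path(path, "spikes.json"),
                                simplifyVector = FALSE)
  spikes <- lapply(spikes, function(s) as.numeric(unlist(s)))
  gtPath <- file.path(path, "ground_truth.json")
  gt <- if (file.exists(gtPath))
    jsonlite::read_json(gtPath, simplifyVector = TRUE) else NULL
  se <- SummarizedExperiment(
    assays = list(lfp = lfpMat),
    rowData = DataFrame(channel = seq_len(nChannels(lay)),
                        x = lay@positions[, 1], y = lay@positions[, 2]))
  metadata(se) <- list(sampleRate = meta$sampleRate,
                       stimTimes = meta$stimTimes,
                       duration = meta$duration, spikes = spikes,
                       layout = lay, groundTruth = gt, seed = meta$seed)
  as(se, "MEARecording")
}
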