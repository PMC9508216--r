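#' Text-format readers and writers
#'
#' Plain-text interchange used across the pipeline: two-column CSV signals,
#' hypnogram TSV (`epoch_index`, `stage`, `artifact`), summary-statistics
#' TSV (`SNP CHR BP A1 A2 OR|BETA SE P INFO`), spindle-event TSV and JSON
#' sidecars.
#'
#' @name io_text
NULL

#' @rdname io_text
#' @param recording an [eeg_recording()].
#' @param path output path.
#' @export
write_signal_csv <- function(recording, path) {
  n <- length(recording$samples)
  utils::write.csv(data.frame(
    time_s = (seq_len(n) - 1) / recording$sampling_rate,
    amplitude_uv = recording$samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_text
#' @export
read_signal_csv <- function(path) {
  d <- utils::read.csv(path)
  fs <- round(1 / stats::median(diff(d$time_s)))
  eeg_recording(d$amplitude_uv, fs, channel = "CSV")
}

#' @rdname io_text
#' @param hyp a [hypnogram()].
#' @export
write_hypnogram_tsv <- function(hyp, path) {
  utils::write.table(data.frame(
    epoch_index = seq_along(hyp$stages), stage = hyp$stages,
    artifact = as.integer(hyp$artifact_flags)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_text
#' @export
read_hypnogram_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "character", "integer"))
  hypnogram(d$stage, d$artifact == 1)
}

#' @rdname io_text
#' @param stats a summary-statistics data frame.
#' @export
write_sumstats_tsv <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname io_text
#' @export
read_sumstats_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE,
                         colClasses = c(SNP = "character", A1 = "character",
                                        A2 = "character"))
  class(d) <- c("summary_stats", "data.frame")
  d
}

#' @rdname io_text
#' @param events a `spindle_events` data frame.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(
    as.data.frame(events)[, c("onset_s", "duration_s", "amplitude_uv",
                              "epoch_index")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname io_text
#' @param x a list or data frame.
#' @export
write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}
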