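#' Write a single-channel recording as EDF
#'
#' Minimal European Data Format writer: one signal, 1-s data records,
#' 16-bit little-endian samples linearly scaled between the signal's
#' physical extrema. Sufficient for round-tripping simulated EEG; not a
#' general-purpose EDF library (no annotations, one channel only).
#'
#' @param recording an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path) {
  fs <- recording$sampling_rate
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate")
  x <- recording$samples
  n_rec <- floor(length(x) / fs)
  x <- x[seq_len(n_rec * fs)]

  phys_min <- floor(min(x)); phys_max <- ceiling(max(x))
  if (phys_min == phys_max) phys_max <- phys_min + 1
  dig_min <- -32768L; dig_max <- 32767L
  dig <- as.integer(round((x - phys_min) / (phys_max - phys_min) *
                            (dig_max - dig_min) + dig_min))

  pad <- function(s, w) formatC(as.character(s), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X X X X", 80), pad("Startdate X X X X", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(256 + 256, 8), pad("", 44),
    pad(n_rec, 8), pad("1", 8), pad("1", 4)), con, eos = NULL)
  writeChar(paste0(
    pad(recording$channel, 16), pad("AgAgCl electrode", 80), pad("uV", 8),
    pad(phys_min, 8), pad(phys_max, 8), pad(dig_min, 8), pad(dig_max, 8),
    pad("", 80), pad(fs, 8), pad("", 32)), con, eos = NULL)
  writeBin(dig, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a single-channel EDF file
#'
#' Counterpart of [write_edf()]; reads the first signal of an EDF file and
#' rescales to physical units.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256, useBytes = TRUE)
  n_rec <- as.integer(substr(hdr, 237, 244))
  dur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  if (ns != 1) stop("reader supports single-channel EDF only")
  sh <- readChar(con, 256, useBytes = TRUE)
  label <- trimws(substr(sh, 1, 16))
  phys_min <- as.numeric(substr(sh, 105, 112))
  phys_max <- as.numeric(substr(sh, 113, 120))
  dig_min <- as.numeric(substr(sh, 121, 128))
  dig_max <- as.numeric(substr(sh, 129, 136))
  spr <- as.integer(substr(sh, 217, 224))
  dig <- readBin(con, "integer", n = n_rec * spr, size = 2, signed = TRUE,
                 endian = "little")
  x <- (dig - dig_min) / (dig_max - dig_min) * (phys_max - phys_min) + phys_min
  eeg_recording(x, spr / dur, channel = label)
}
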