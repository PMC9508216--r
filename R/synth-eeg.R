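#' Spindle frequency bands
#'
#' Canonical sigma sub-bands: fast spindles 12-15 Hz, slow spindles 9-12 Hz.
#'
#' @param band `"fast"` or `"slow"`.
#' @return numeric length-2 vector `c(low, high)` in Hz.
#' @export
spindle_band <- function(band = c("fast", "slow")) {
  band <- match.arg(band)
  if (band == "fast") c(12, 15) else c(9, 12)
}

#' Simulate single-channel NREM EEG with embedded sleep spindles
#'
#' Generates a 1/f-shaped background (pink + white noise) and inserts
#' Hann-windowed sinusoidal bursts at random non-overlapping onsets,
#' emulating the waxing-waning morphology of sleep spindles. The ground
#' truth event list is returned alongside the signal, so detector recall
#' and density recovery can be scored exactly.
#'
#' @param duration_s recording length in seconds; must be a multiple of the
#'   30-s epoch length.
#' @param sampling_rate_hz sampling rate, default 256 Hz.
#' @param band `"fast"` (12-15 Hz) or `"slow"` (9-12 Hz).
#' @param truth_density target spindle density in events per 30-s epoch;
#'   the realized event count is Poisson with mean `truth_density * n_epochs`.
#' @param amplitude_uv peak amplitude of the burst envelope in microvolts.
#' @param noise_profile named list/vector with elements `pink` and `white`:
#'   RMS amplitude (microvolts) of the 1/f and white background components.
#' @param frequency_hz oscillation frequency of the bursts; default is the
#'   band midpoint. Must lie inside `band`. Small per-event jitter
#'   (`frequency_jitter_hz`, SD) is applied and truncated to the band.
#' @param duration_mean_s,duration_sd_s mean and SD of event durations
#'   (Gaussian, truncated to \[0.5, 3\] s). Defaults 0.82 and 0.05 s match
#'   typical fast-spindle morphology in healthy adults.
#' @param frequency_jitter_hz SD of per-event frequency jitter in Hz.
#' @param stages per-epoch stage labels; default all `"N2"`.
#' @param artifact_flags per-epoch logical artifact flags; default all FALSE.
#' @param refractory_s minimum gap between consecutive events (s).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return list with elements `recording` (class `eeg_recording`: `samples`,
#'   `sampling_rate`, `channel`), `hypnogram` (class `hypnogram`), and
#'   `truth` (class `spindle_ground_truth`: data frame of events with
#'   `onset_s`, `duration_s`, `frequency_hz`, `amplitude_uv`, plus the
#'   `target_density` attribute).
#' @export
simulate_eeg <- function(duration_s, sampling_rate_hz = 256,
                         band = c("fast", "slow"),
                         truth_density = 2.22, amplitude_uv = 27.56,
                         noise_profile = list(pink = 10, white = 2),
                         frequency_hz = NULL,
                         duration_mean_s = 0.82, duration_sd_s = 0.05,
                         frequency_jitter_hz = 0.1,
                         stages = NULL, artifact_flags = NULL,
                         refractory_s = 1, seed = 1L) {
  band <- match.arg(band)
  epoch_s <- 30
  if (!is_pos_scalar(duration_s) || duration_s %% epoch_s != 0)
    stop("duration_s must be a positive multiple of 30 s")
  if (truth_density < 0) stop("truth_density must be >= 0")
  if (!is_pos_scalar(amplitude_uv)) stop("amplitude_uv must be positive")
  lims <- spindle_band(band)
  if (is.null(frequency_hz)) frequency_hz <- mean(lims)
  if (frequency_hz < lims[1] || frequency_hz > lims[2])
    stop("frequency_hz outside the requested band")

  n_epochs <- duration_s / epoch_s
  fs <- sampling_rate_hz
  n <- as.integer(duration_s * fs)

  with_seed(seed, {
    samples <- pink_noise(n, fs, rms = noise_profile$pink) +
      stats::rnorm(n, sd = noise_profile$white)

    n_events <- stats::rpois(1L, truth_density * n_epochs)
    events <- place_events(n_events, duration_s, duration_mean_s,
                           duration_sd_s, refractory_s)
    if (nrow(events) > 0) {
      events$frequency_hz <- pmin(pmax(
        frequency_hz + stats::rnorm(nrow(events), sd = frequency_jitter_hz),
        lims[1]), lims[2])
      events$amplitude_uv <- amplitude_uv
      for (i in seq_len(nrow(events))) {
        i0 <- round(events$onset_s[i] * fs) + 1L
        m <- round(events$duration_s[i] * fs)
        t <- seq_len(m) / fs
        burst <- amplitude_uv * hann(m) *
          sin(2 * pi * events$frequency_hz[i] * t)
        samples[i0:(i0 + m - 1L)] <- samples[i0:(i0 + m - 1L)] + burst
      }
    } else {
      events$frequency_hz <- numeric(0)
      events$amplitude_uv <- numeric(0)
    }

    if (is.null(stages)) stages <- rep("N2", n_epochs)
    if (is.null(artifact_flags)) artifact_flags <- rep(FALSE, n_epochs)

    list(
      recording = eeg_recording(samples, fs, channel = "C3-A2"),
      hypnogram = hypnogram(stages, artifact_flags, epoch_length_s = epoch_s),
      truth = structure(events, class = c("spindle_ground_truth", "data.frame"),
                        target_density = truth_density)
    )
  })
}

#' @rdname simulate_eeg
#' @param samples numeric vector of amplitudes in microvolts.
#' @param sampling_rate sampling rate in Hz.
#' @param channel channel label.
#' @export
eeg_recording <- function(samples, sampling_rate, channel = "EEG") {
  if (!is_pos_scalar(sampling_rate)) stop("sampling_rate must be positive")
  if (any(!is.finite(samples))) stop("samples must be finite")
  structure(list(samples = as.numeric(samples),
                 sampling_rate = sampling_rate, channel = channel),
            class = "eeg_recording")
}

#' Construct a hypnogram
#'
#' @param stages character vector of per-epoch stages in
#'   `{W, N1, N2, N3, REM}`.
#' @param artifact_flags logical vector, TRUE where the epoch is
#'   artifact/arousal contaminated and must be excluded.
#' @param epoch_length_s epoch length in seconds (30).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(stages, artifact_flags = rep(FALSE, length(stages)),
                      epoch_length_s = 30) {
  stages <- as.character(stages)
  if (!all(stages %in% c("W", "N1", "N2", "N3", "REM")))
    stop("stages must be in {W, N1, N2, N3, REM}")
  if (length(artifact_flags) != length(stages))
    stop("artifact_flags length must match stages")
  structure(list(stages = stages, artifact_flags = as.logical(artifact_flags),
                 epoch_length_s = epoch_length_s),
            class = "hypnogram")
}

#' Epochs eligible for spindle analysis
#'
#' N2 or N3 stage and artifact-free.
#'
#' @param hyp a [hypnogram()].
#' @return integer indices (1-based) of included epochs.
#' @export
included_epochs <- function(hyp) {
  which(hyp$stages %in% c("N2", "N3") & !hyp$artifact_flags)
}

# 1/f amplitude-shaped Gaussian noise scaled to a target RMS
pink_noise <- function(n, fs, rms) {
  if (rms <= 0) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))          # avoid division by zero at DC
  f <- pmin(f, n - f)                # two-sided frequency index
  spec <- spec / sqrt(f)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

hann <- function(m) {
  if (m == 1) return(1)
  0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
}

# rejection-sampled non-overlapping onsets with a refractory gap
place_events <- function(n_events, duration_s, dur_mean, dur_sd, gap_s) {
  onsets <- numeric(0)
  durs <- numeric(0)
  attempts <- 0L
  max_attempts <- max(1000L, 200L * n_events)
  while (length(onsets) < n_events) {
    attempts <- attempts + 1L
    if (attempts > max_attempts)
      stop("event density too high: cannot place events without overlap")
    d <- min(3, max(0.5, stats::rnorm(1, dur_mean, dur_sd)))
    o <- stats::runif(1, 0, duration_s - d)
    ok <- all(o + d + gap_s <= onsets | o >= onsets + durs + gap_s)
    if (ok) {
      onsets <- c(onsets, o)
      durs <- c(durs, d)
    }
  }
  idx <- order(onsets)
  data.frame(onset_s = onsets[idx], duration_s = durs[idx])
}
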