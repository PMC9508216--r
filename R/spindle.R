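#' Average NREM power spectrum
#'
#' Computes a Hann-windowed periodogram for every artifact-free N2/N3 epoch
#' and averages them, giving a per-subject NREM spectral density at 1/30 Hz
#' resolution. This is the spectrum in which the subject's individual
#' spindle peak is located before detection.
#'
#' @param recording an [eeg_recording()].
#' @param hypnogram a [hypnogram()].
#' @param fmin,fmax frequency range to return (Hz).
#' @return data frame with columns `frequency` (Hz) and `power`.
#' @export
nrem_power_spectrum <- function(recording, hypnogram, fmin = 2, fmax = 24) {
  fs <- recording$sampling_rate
  epoch_n <- as.integer(hypnogram$epoch_length_s * fs)
  inc <- included_epochs(hypnogram)
  if (length(inc) == 0) stop("no NREM data: no artifact-free N2/N3 epochs")
  w <- hann(epoch_n)
  acc <- NULL
  for (e in inc) {
    seg <- recording$samples[((e - 1L) * epoch_n + 1L):(e * epoch_n)]
    seg <- (seg - mean(seg)) * w
    pxx <- Mod(stats::fft(seg))^2 / (fs * sum(w^2))
    half <- pxx[seq_len(epoch_n %/% 2 + 1L)]
    acc <- if (is.null(acc)) half else acc + half
  }
  acc <- acc / length(inc)
  freq <- (seq_along(acc) - 1) * fs / epoch_n
  keep <- freq >= fmin & freq <= fmax
  data.frame(frequency = freq[keep], power = acc[keep])
}

#' Locate a subject's spindle peak within a sigma sub-band
#'
#' Automated surrogate for visual peak identification: the spectrum is
#' smoothed over about 0.25 Hz, a log-log linear background (the 1/f
#' trend, fitted outside 8.5-16 Hz) is subtracted, and the most prominent
#' in-band local maximum is returned. A peak counts as detectable only
#' when it rises at least `min_prominence`-fold above the fitted
#' background (default 2, i.e. a clear doubling of power -- the automated
#' analogue of a visually obvious bump); otherwise the peak is reported
#' absent — a legal state (subjects without a detectable slow spindle peak
#' are excluded from slow-spindle analysis rather than zero-filled).
#'
#' @param spectrum data frame `frequency, power` from
#'   [nrem_power_spectrum()].
#' @param band `"fast"` or `"slow"`.
#' @param min_prominence minimum power ratio over the fitted background
#'   for a detectable peak.
#' @param smooth_bw half-width (in bins) of the moving-average smoother.
#' @return object of class `spindle_peak`: list with `band`,
#'   `peak_frequency_hz` (NA when absent), `prominence`, `present`.
#' @export
find_spindle_peak <- function(spectrum, band = c("fast", "slow"),
                              min_prominence = 2.0, smooth_bw = 7) {
  band <- match.arg(band)
  lims <- spindle_band(band)
  f <- spectrum$frequency
  if (min(f) > lims[1] - 1 || max(f) < lims[2] + 1)
    stop("spectrum does not cover the requested band plus margins")
  p <- smooth_ma(spectrum$power, smooth_bw)

  bg_idx <- f >= 4 & f <= 20 & (f < 8.5 | f > 16) & p > 0
  fit <- stats::lm(log(p[bg_idx]) ~ log(f[bg_idx]))
  bg <- exp(fit$coefficients[1] + fit$coefficients[2] * log(f))

  in_band <- which(f >= lims[1] & f <= lims[2])
  # strict local maxima of the smoothed spectrum
  is_max <- in_band[in_band > 1 & in_band < length(p)]
  is_max <- is_max[p[is_max] > p[is_max - 1L] & p[is_max] >= p[is_max + 1L]]
  prom <- p[is_max] / bg[is_max]
  keep <- prom >= min_prominence
  if (length(is_max) == 0 || !any(keep)) {
    return(structure(list(band = band, peak_frequency_hz = NA_real_,
                          prominence = if (length(prom)) max(prom) else 0,
                          present = FALSE),
                     class = "spindle_peak"))
  }
  best <- is_max[keep][which.max(prom[keep])]
  structure(list(band = band, peak_frequency_hz = f[best],
                 prominence = max(prom[keep]), present = TRUE),
            class = "spindle_peak")
}

#' Detect spindle events around an individual spectral peak
#'
#' The signal is zero-phase band-pass filtered (4th-order Butterworth,
#' forward-backward) at `peak +/- halfwidth_hz`; the root-mean-square of
#' the filtered signal is computed over consecutive non-overlapping
#' `rms_window_s` windows; a spindle is an uninterrupted run of windows
#' inside artifact-free N2/N3 epochs whose RMS exceeds `threshold_sd`
#' standard deviations of the filtered signal (SD taken over all included
#' epochs), lasting between `min_dur_s` and `max_dur_s`. Duration is the
#' distance between threshold crossings of the step-wise RMS series; runs
#' longer than `max_dur_s` are discarded, not truncated. Amplitude is the
#' maximal absolute filtered voltage within the event. Events are assigned
#' to the epoch containing their onset; an event touching an excluded epoch
#' is discarded.
#'
#' @param recording an [eeg_recording()].
#' @param hypnogram a [hypnogram()].
#' @param peak a present [find_spindle_peak()] result (or a frequency in Hz).
#' @param halfwidth_hz half-width of the band-pass around the peak (Hz).
#' @param rms_window_s RMS window length in seconds.
#' @param threshold_sd detection threshold in SD units of the filtered
#'   signal.
#' @param min_dur_s,max_dur_s duration bounds in seconds.
#' @param threshold_on what the SD is computed over: the filtered signal
#'   (`"filtered"`, default) or the RMS series (`"rms"`).
#' @return data frame of class `spindle_events` with columns `onset_s`,
#'   `duration_s`, `amplitude_uv`, `epoch_index`; the detection threshold
#'   is attached as attribute `threshold`.
#' @export
detect_spindle_events <- function(recording, hypnogram, peak,
                                  halfwidth_hz = 1.5, rms_window_s = 0.2,
                                  threshold_sd = 1.5,
                                  min_dur_s = 0.5, max_dur_s = 3.0,
                                  threshold_on = c("filtered", "rms")) {
  threshold_on <- match.arg(threshold_on)
  if (inherits(peak, "spindle_peak")) {
    if (!isTRUE(peak$present))
      stop("absent spindle peak: subject must be excluded from this band")
    peak <- peak$peak_frequency_hz
  }
  if (min_dur_s >= max_dur_s) stop("min_dur_s must be < max_dur_s")
  fs <- recording$sampling_rate
  epoch_n <- as.integer(hypnogram$epoch_length_s * fs)
  n_epochs <- length(hypnogram$stages)
  if (length(recording$samples) < epoch_n)
    stop("recording shorter than one epoch")
  inc <- included_epochs(hypnogram)
  if (length(inc) == 0) stop("no NREM data: no artifact-free N2/N3 epochs")

  filt <- bandpass(recording$samples, fs, peak - halfwidth_hz,
                   peak + halfwidth_hz)

  # sample mask of included epochs; threshold SD computed on included data
  inc_mask <- rep(FALSE, length(filt))
  for (e in inc) inc_mask[((e - 1L) * epoch_n + 1L):(e * epoch_n)] <- TRUE
  thr <- threshold_sd * if (threshold_on == "filtered") {
    stats::sd(filt[inc_mask])
  } else {
    win_all <- as.integer(round(rms_window_s * fs))
    sqrt(mean(rms_series(filt[inc_mask], win_all)^2))
  }

  # window length in whole samples; onsets/durations reported in true
  # sample time (win/fs), not the nominal window length
  win <- as.integer(round(rms_window_s * fs))
  n_win <- length(filt) %/% win
  rms <- rms_series(filt[seq_len(n_win * win)], win)
  win_onset <- (seq_len(n_win) - 1L) * win / fs
  win_epoch <- ((seq_len(n_win) - 1L) * win) %/% epoch_n + 1L
  win_end_epoch <- (seq_len(n_win) * win - 1L) %/% epoch_n + 1L
  win_ok <- win_epoch %in% inc & win_end_epoch %in% inc

  above <- rms > thr & win_ok
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- which(runs$values)

  out <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                    amplitude_uv = numeric(0), epoch_index = integer(0))
  for (k in ev) {
    len_s <- runs$lengths[k] * win / fs
    if (len_s < min_dur_s || len_s > max_dur_s) next
    w0 <- starts[k]; w1 <- ends[k]
    # epochs touched by the event must all be included
    if (!all(unique(c(win_epoch[w0:w1], win_end_epoch[w0:w1])) %in% inc)) next
    s0 <- (w0 - 1L) * win + 1L
    s1 <- w1 * win
    out <- rbind(out, data.frame(
      onset_s = win_onset[w0], duration_s = len_s,
      amplitude_uv = max(abs(filt[s0:s1])),
      epoch_index = win_epoch[w0]))
  }
  structure(out, class = c("spindle_events", "data.frame"),
            threshold = thr, peak_frequency_hz = peak)
}

#' Summarize detected spindles for one subject
#'
#' Density is the event count per artifact-free N2/N3 30-s epoch. Mean
#' duration and amplitude are reported only when at least one event exists
#' (`NA` otherwise, never silently zeroed).
#'
#' @param events output of [detect_spindle_events()].
#' @param hypnogram the same [hypnogram()] used for detection.
#' @param peak_frequency_hz optional subject peak frequency to carry along.
#' @return list of class `spindle_summary`: `density`, `mean_duration_s`,
#'   `mean_amplitude_uv`, `peak_frequency_hz`, `n_epochs_included`,
#'   `n_events`.
#' @export
summarize_spindles <- function(events, hypnogram, peak_frequency_hz = NULL) {
  n_inc <- length(included_epochs(hypnogram))
  if (n_inc == 0) stop("zero included epochs")
  n_ev <- nrow(events)
  if (is.null(peak_frequency_hz))
    peak_frequency_hz <- attr(events, "peak_frequency_hz")
  structure(list(
    density = n_ev / n_inc,
    mean_duration_s = if (n_ev > 0) mean(events$duration_s) else NA_real_,
    mean_amplitude_uv = if (n_ev > 0) mean(events$amplitude_uv) else NA_real_,
    peak_frequency_hz = peak_frequency_hz,
    n_epochs_included = n_inc, n_events = n_ev),
    class = "spindle_summary")
}

#' Zero-phase Butterworth band-pass
#'
#' 4th-order Butterworth applied forward and backward
#' (`signal::filtfilt`), so event timing is phase-preserved.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param low,high band edges (Hz).
#' @param order filter order per pass.
#' @return filtered signal.
#' @export
bandpass <- function(x, fs, low, high, order = 4) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Sigma-band background SD of a recording
#'
#' SD of the band-pass-filtered signal — the scale on which the detector
#' threshold operates; useful for expressing burst signal-to-noise ratios.
#'
#' @inheritParams detect_spindle_events
#' @param center_hz band center (Hz).
#' @param halfwidth_hz band half-width (Hz).
#' @return numeric SD in microvolts.
#' @export
sigma_band_sd <- function(recording, center_hz, halfwidth_hz = 1.5) {
  stats::sd(bandpass(recording$samples, recording$sampling_rate,
                     center_hz - halfwidth_hz, center_hz + halfwidth_hz))
}

# RMS over consecutive non-overlapping windows of `win` samples
rms_series <- function(x, win) {
  n_win <- length(x) %/% win
  m <- matrix(x[seq_len(n_win * win)]^2, nrow = win)
  sqrt(colMeans(m))
}

smooth_ma <- function(x, bw) {
  if (bw <= 0) return(x)
  k <- 2L * as.integer(bw) + 1L
  s <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  s[is.na(s)] <- x[is.na(s)]
  s
}
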