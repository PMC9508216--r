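# Deterministic construction for threshold-crossing semantics: a steady
# low-amplitude in-band carrier fixes the filtered-signal SD (and hence
# the threshold) exactly, and a burst of known envelope rides on top.
# No random background, so expected event sets are exact.
carrier_burst <- function(onset, dur, A = 20, B = 2, freq = 13.5,
                          flat = FALSE, n_epochs = 2, fs = 256) {
  n <- n_epochs * 30 * fs
  x <- B * sin(2 * pi * freq * seq_len(n) / fs)
  i0 <- round(onset * fs) + 1
  m <- round(dur * fs)
  t <- seq_len(m) / fs
  if (flat) {
    env <- rep(1, m)
    ramp <- round(0.1 * fs)
    env[1:ramp] <- seq(0, 1, length.out = ramp)
    env[(m - ramp + 1):m] <- seq(1, 0, length.out = ramp)
  } else {
    env <- 0.5 * (1 - cos(2 * pi * (seq_len(m) - 1) / (m - 1)))
  }
  x[i0:(i0 + m - 1)] <- x[i0:(i0 + m - 1)] + A * env * sin(2 * pi * freq * t)
  list(recording = eeg_recording(x, fs),
       hypnogram = hypnogram(rep("N2", n_epochs)))
}

test_that("a single strong embedded burst is detected with faithful timing", {
  sim <- carrier_burst(onset = 20, dur = 1.0)
  ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
  expect_equal(nrow(ev), 1)
  # duration is quantized to 51-sample (0.199 s) RMS windows, so a 1.0-s
  # burst reads as 4 or 5 windows: allow the 0.2-s band plus one quantum
  expect_lt(abs(ev$duration_s - 1.0), 0.2 + 51 / 256)
  expect_lt(abs(ev$onset_s - 20), 0.2 + 1e-9)
  expect_equal(ev$epoch_index, 1L)
  expect_gt(ev$amplitude_uv, 10)
})

test_that("bursts shorter than the minimum duration are not events", {
  # burst centered on an RMS-window boundary: it occupies two 200-ms
  # windows (0.4 s of step-function duration), below the 0.5-s minimum
  sim <- carrier_burst(onset = 101 * 51 / 256 - 0.15, dur = 0.3)
  ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
  expect_equal(nrow(ev), 0)
})

test_that("supra-threshold runs longer than the maximum duration are discarded", {
  sim <- carrier_burst(onset = 20, dur = 4.0, flat = TRUE)
  ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
  expect_equal(nrow(ev), 0)
})

test_that("every detected event duration lies inside the 0.5-3 s rule", {
  for (s in 1:3) {
    sim <- simulate_eeg(30 * 30, truth_density = 3, seed = s)
    ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
    expect_true(all(ev$duration_s >= 0.5 & ev$duration_s <= 3.0))
    expect_true(all(ev$amplitude_uv > 0))
  }
})

test_that("raising the threshold never increases the event count", {
  sim <- simulate_eeg(20 * 30, truth_density = 2.5, seed = 31)
  counts <- vapply(c(1.0, 1.5, 2.0, 2.5, 3.0), function(th)
    nrow(detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5,
                               threshold_sd = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("flagging an epoch removes exactly its events and shrinks the denominator", {
  sim <- simulate_eeg(20 * 30, truth_density = 2.5, seed = 17)
  ev_all <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
  victim <- ev_all$epoch_index[1]
  flags <- rep(FALSE, 20)
  flags[victim] <- TRUE
  hyp2 <- hypnogram(sim$hypnogram$stages, flags)
  ev_flt <- detect_spindle_events(sim$recording, hyp2, peak = 13.5)

  kept <- ev_all[ev_all$epoch_index != victim, ]
  boundary <- abs(ev_all$onset_s + ev_all$duration_s - victim * 30) < 0.4 |
    abs(ev_all$onset_s - (victim - 1) * 30) < 0.4
  if (!any(boundary)) {
    # threshold changes slightly (SD over fewer epochs); compare onsets
    expect_setequal(round(ev_flt$onset_s, 1), round(kept$onset_s, 1))
  }
  s_all <- summarize_spindles(ev_all, sim$hypnogram)
  s_flt <- summarize_spindles(ev_flt, hyp2)
  expect_equal(s_flt$n_epochs_included, s_all$n_epochs_included - 1)
})

test_that("event boundaries equal a naive sample-by-sample RMS threshold scan", {
  for (s in 1:4) {
    sim <- simulate_eeg(2 * 30, truth_density = 2.5, seed = 100 + s)
    ev <- detect_spindle_events(sim$recording, sim$hypnogram, peak = 13.5)
    thr <- attr(ev, "threshold")

    filt <- bandpass(sim$recording$samples, 256, 12, 15)
    win <- round(0.2 * 256)
    n_win <- length(filt) %/% win
    rms <- vapply(seq_len(n_win), function(w)
      sqrt(mean(filt[((w - 1) * win + 1):(w * win)]^2)), numeric(1))
    wlen <- win / 256
    runs <- naive_rms_scan(rms, thr)
    if (is.null(runs)) runs <- matrix(numeric(0), ncol = 2)
    ok <- runs[, 2] * wlen >= 0.5 & runs[, 2] * wlen <= 3
    expect_equal(nrow(ev), sum(ok))
    expect_equal(ev$onset_s, (runs[ok, 1] - 1) * wlen)
    expect_equal(ev$duration_s, runs[ok, 2] * wlen)
  }
})

test_that("detected density recovers simulator ground truth at workable SNR", {
  errs <- vapply(c(1, 2, 3), function(dens) {
    sim <- simulate_eeg(40 * 30, truth_density = dens, amplitude_uv = 25,
                        noise_profile = list(pink = 8, white = 2),
                        seed = 50 + dens)
    spec <- nrem_power_spectrum(sim$recording, sim$hypnogram)
    pk <- find_spindle_peak(spec, "fast")
    ev <- detect_spindle_events(sim$recording, sim$hypnogram, pk)
    d_hat <- summarize_spindles(ev, sim$hypnogram)$density
    d_true <- nrow(sim$truth) / 40
    abs(d_hat - d_true) / d_true
  }, numeric(1))
  expect_lte(stats::median(errs), 0.15)
})

test_that("detection refuses an absent peak and degenerate inputs", {
  sim <- simulate_eeg(2 * 30, truth_density = 0, seed = 3)
  absent <- structure(list(band = "slow", peak_frequency_hz = NA_real_,
                           prominence = 0, present = FALSE),
                      class = "spindle_peak")
  expect_error(detect_spindle_events(sim$recording, sim$hypnogram, absent),
               "absent spindle peak")
  short <- eeg_recording(rnorm(100), 256)
  expect_error(detect_spindle_events(short, sim$hypnogram, peak = 13.5),
               "shorter than one epoch")
})

test_that("spindle summaries are plain arithmetic over events and epochs", {
  hyp <- hypnogram(rep("N2", 10))
  ev <- data.frame(onset_s = seq(0, 210, by = 10)[1:22] + 0.5,
                   duration_s = rep(0.82, 22), amplitude_uv = rep(27.5, 22),
                   epoch_index = rep(1:10, length.out = 22))
  s <- summarize_spindles(ev, hyp)
  expect_equal(s$density, 2.2)
  expect_equal(s$mean_duration_s, 0.82)
  expect_equal(s$n_events, 22)

  s0 <- summarize_spindles(ev[0, ], hyp)
  expect_equal(s0$density, 0)
  expect_true(is.na(s0$mean_duration_s))
  expect_true(is.na(s0$mean_amplitude_uv))
})
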