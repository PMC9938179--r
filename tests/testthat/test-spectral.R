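test_that("welch power recovers a sinusoid's frequency and total power", {
  A <- 30
  s <- sine_signal(2, amp = A, duration = 120, fs = 250)
  ps <- welch_power(s)
  expect_equal(ps$freqs[2] - ps$freqs[1], 0.25)
  expect_equal(ps$freqs[which.max(ps$power)], 2)
  total <- sum(ps$power) * 0.25      # integrate the density (Parseval)
  expect_equal(total, A^2 / 2, tolerance = 0.02 * A^2)
})

test_that("welch power of the zero signal is zero and short input errors", {
  z <- continuous_signal(rep(0, 2000), fs = 250)
  ps <- welch_power(z)
  expect_true(all(ps$power == 0))
  expect_error(welch_power(continuous_signal(rnorm(100), fs = 250)), "window")
})

test_that("welch of concatenated equal-length segments is the mean of their spectra", {
  set.seed(8)
  a <- rnorm(250 * 40); b <- rnorm(250 * 40) * 3
  pa <- welch_power(continuous_signal(a, 250))
  pb <- welch_power(continuous_signal(b, 250))
  pc <- welch_power(continuous_signal(c(a, b), 250))
  expect_equal(pc$power, (pa$power + pb$power) / 2, tolerance = 1e-10)
})

test_that("state restriction drops windows that leave the requested state", {
  s <- sine_signal(2, amp = 10, duration = 40, fs = 250)
  h <- hypnogram(c(rep("NREM", 5), rep("wake", 5)))
  ps <- welch_power(s, hypnogram = h, restrict = "NREM")
  expect_equal(ps$n_segments, 5L)
  expect_error(welch_power(s, hypnogram = hypnogram(rep("artifact", 10)),
                           restrict = "NREM"), "eligible")
})

test_that("SWA time course bins correctly and scales with amplitude squared", {
  fs <- 250
  t1 <- seq(0, 300 - 1 / fs, by = 1 / fs)
  x <- c(10 * sin(2 * pi * 2 * t1), 20 * sin(2 * pi * 2 * t1))
  s <- continuous_signal(x, fs)
  tc <- swa_timecourse(s, bin_len = 300)
  expect_equal(nrow(tc), 2L)
  expect_equal(tc$swa[2] / tc$swa[1], 4, tolerance = 0.05)

  flat <- swa_timecourse(sine_signal(2, 10, duration = 600, fs = fs),
                         bin_len = 300)
  expect_equal(flat$swa[1], flat$swa[2], tolerance = 0.02 * flat$swa[1])
})

test_that("modulation index hits its closed forms", {
  set.seed(3)
  ph <- runif(50000, -pi, pi)
  expect_equal(mi_from_phase_amp(ph, rep(2.5, length(ph))), 0)
  bin1 <- ph >= -pi & ph < -pi + 2 * pi / 18
  expect_equal(mi_from_phase_amp(ph, as.numeric(bin1)), 1)
  expect_error(mi_from_phase_amp(ph, rep(0, length(ph))), "zero")
})

test_that("MI matches a sample-by-sample binning oracle to 1e-10", {
  set.seed(4)
  ph <- runif(20000, -pi, pi)
  amp <- (1 + cos(ph)) / 2
  # independent oracle: explicit per-sample accumulation and KL form
  n_bins <- 18
  sums <- counts <- numeric(n_bins)
  for (i in seq_along(ph)) {
    k <- floor((ph[i] + pi) / (2 * pi) * n_bins) %% n_bins + 1
    sums[k] <- sums[k] + amp[i]
    counts[k] <- counts[k] + 1
  }
  m <- sums / counts
  p <- m / sum(m)
  mi_oracle <- (log(n_bins) + sum(p[p > 0] * log(p[p > 0]))) / log(n_bins)
  expect_equal(mi_from_phase_amp(ph, amp), mi_oracle, tolerance = 1e-10)
  expect_gt(mi_oracle, 0)
})

test_that("MI is invariant to amplitude rescaling and constant phase offsets", {
  set.seed(5)
  fs <- 200
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  phase_sig <- sin(2 * pi * 1 * t)
  amp_sig <- (1 + 0.8 * cos(2 * pi * 1 * t)) * sin(2 * pi * 12 * t)
  mi0 <- modulation_index(phase_sig, amp_sig)
  expect_equal(modulation_index(phase_sig, 13.7 * amp_sig), mi0,
               tolerance = 1e-12)
  phase_shifted <- sin(2 * pi * 1 * t + 1.1)
  mi_shift <- modulation_index(phase_shifted, amp_sig)
  expect_equal(mi_shift, mi0, tolerance = 0.05)  # bin-quantisation residual only
  expect_gt(mi0, 0.001)
})

test_that("a single-cell comodulogram equals modulation_index on those bands", {
  s <- simulate_session(quick_params(duration = 200), seed = 12)
  cm <- comodulogram(s$prl, phase_range = c(0.5, 1.5), amp_range = c(10, 16),
                     phase_width = 1, phase_step = 1, amp_width = 6,
                     amp_step = 6, hypnogram = s$hypnogram, fs_pac = 100)
  expect_equal(dim(cm$mi), c(1L, 1L))
  # recompute by hand on the same decimated, NREM-masked series
  dec <- floor(s$prl$fs / 100)
  n_use <- (length(s$prl$samples) %/% dec) * dec
  y <- colMeans(matrix(s$prl$samples[seq_len(n_use)], nrow = dec))
  sig <- continuous_signal(y, s$prl$fs / dec)
  mask <- somnoscope:::pac_mask(length(y), sig$fs, 0, s$hypnogram,
                                min_run = 8, trim = 1 / 0.5)
  mi <- modulation_index(bandpass_zscore(sig, c(0.5, 1.5)),
                         bandpass_zscore(sig, c(10, 16)), mask = mask)
  expect_equal(cm$mi[1L, 1L], mi, tolerance = 1e-12)
})

test_that("uncoupled noise stays within its phase-shuffle surrogate distribution", {
  s <- simulate_session(quick_params(duration = 240,
                                     coupling = list(prob = 0, depth = 0,
                                                     phase_offset = 0.25)),
                        seed = 31)
  cm <- comodulogram(s$prl, phase_range = c(0.5, 2), amp_range = c(10, 16),
                     phase_width = 1.5, phase_step = 1.5, amp_width = 6,
                     amp_step = 6, hypnogram = s$hypnogram)
  # surrogate: circularly shift the amplitude series against the phase series
  dec <- floor(s$prl$fs / 100)
  n_use <- (length(s$prl$samples) %/% dec) * dec
  y <- colMeans(matrix(s$prl$samples[seq_len(n_use)], nrow = dec))
  sig <- continuous_signal(y, s$prl$fs / dec)
  mask <- somnoscope:::pac_mask(length(y), sig$fs, 0, s$hypnogram,
                                min_run = 8, trim = 2)
  ph <- Arg(analytic_signal(bandpass_zscore(sig, c(0.5, 2))$z))[mask]
  am <- Mod(analytic_signal(bandpass_zscore(sig, c(10, 16))$z))[mask]
  set.seed(32)
  surr <- replicate(40, {
    k <- sample.int(length(am) - 1L, 1L)
    mi_from_phase_amp(ph, c(am[-seq_len(k)], am[seq_len(k)]))
  })
  expect_lte(cm$mi[1L, 1L], quantile(surr, 0.95) * 1.5)
})

test_that("pac_windows crops to manifest windows and reports the MI change", {
  s <- simulate_session(quick_params(duration = 240), seed = 33)
  man <- session_manifest("sim", "custom", injection_time = 120,
                          baseline_window = c(0, 120),
                          post_window = c(120, 240))
  pw <- pac_windows(s$prl, s$hypnogram, man)
  expect_equal(pw$change, pw$mi_post - pw$mi_pre)
  expect_true(pw$mi_pre >= 0 && pw$mi_pre <= 1)
  cs <- crop_signal(s$prl, c(100, 140))
  expect_equal(duration(cs), 40, tolerance = 1e-6)
  expect_equal(cs$t0, 100, tolerance = 1e-6)
  expect_error(crop_signal(s$prl, c(500, 600)), "outside")
})

test_that("pac_change is zero for identical grids and tracks a raised cell", {
  s <- simulate_session(quick_params(duration = 200), seed = 13)
  cm <- comodulogram(s$prl, hypnogram = s$hypnogram)
  expect_equal(pac_change(cm, cm), 0)
  cm2 <- cm
  sel <- somnoscope:::comod_window_cells(cm, c(0.5, 1.5), c(10, 16))
  imax <- which(cm$mi[sel$phase, sel$amp] == max(cm$mi[sel$phase, sel$amp]),
                arr.ind = TRUE)[1L, ]
  cm2$mi[sel$phase[imax[1L]], sel$amp[imax[2L]]] <-
    cm$mi[sel$phase[imax[1L]], sel$amp[imax[2L]]] + 0.05
  expect_equal(pac_change(cm, cm2), 0.05, tolerance = 1e-12)
  cm3 <- comodulogram(s$prl, phase_range = c(2, 4), hypnogram = s$hypnogram)
  expect_error(pac_change(cm, cm3), "grid")
  expect_error(pac_max(cm, c(0.1, 0.2), c(10, 16)), "cells")
})
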