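test_that("band-pass keeps in-band sinusoids and rejects out-of-band ones", {
  s <- sine_signal(2, amp = 40, duration = 60, fs = 500)
  zb <- bandpass_zscore(s, c(0.5, 4))
  expect_equal(sd(zb$z), 1, tolerance = 1e-6)
  core <- 2000:28000
  expect_gt(cor(zb$filtered[core], s$samples[core]), 0.999)

  s50 <- sine_signal(50, amp = 40, duration = 60, fs = 500)
  zb50 <- bandpass_zscore(s50, c(0.5, 4))
  atten <- 20 * log10(sd(zb50$filtered[core]) / sd(s50$samples[core]))
  expect_lt(atten, -40)
})

test_that("constant signals z-score to zero and bad bands error", {
  s <- continuous_signal(rep(7, 5000), fs = 100)
  zb <- bandpass_zscore(s, c(0.5, 4))
  expect_true(all(zb$z == 0))
  expect_error(bandpass_zscore(s, c(10, 60)), "fs/2")
})

test_that("spline envelope of a rectified sinusoid is ~1 and tracks slow AM", {
  fs <- 500
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  z <- sin(2 * pi * 12 * t)
  env <- spline_envelope(z)
  inner <- (2 * fs):(18 * fs)
  expect_lt(max(abs(env[inner] - 1)), 0.05)

  a <- 1 + 0.5 * sin(2 * pi * 0.2 * t)
  env_am <- spline_envelope(a * sin(2 * pi * 12 * t))
  expect_lt(max(abs(env_am[inner] - a[inner]) / a[inner]), 0.05)

  expect_error(spline_envelope(rep(1, 100)), "maxima")
})

test_that("slow-waves need a trough negativity beyond 50 uV of filtered trace", {
  fs <- 500
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  base <- 3 * sin(2 * pi * 1.3 * t)    # sub-threshold 1.3 Hz carrier, SD ~2 uV
  add_wave <- function(x, at, trough, dur = 1) {
    idx <- round(at * fs):round((at + dur) * fs)
    u <- seq(0, 1, length.out = length(idx))
    w <- ifelse(u < 0.4, 0.5 * trough * sin(pi * u / 0.4)^2,
                -trough * sin(pi * (u - 0.4) / 0.6)^2)
    x[idx] <- x[idx] + w
    x
  }
  x <- add_wave(base, 30, trough = 40)    # rejected: negativity <= 50 uV
  x <- add_wave(x, 60, trough = 300)      # detected
  sig <- continuous_signal(x, fs = fs)
  ev <- detect_slow_waves(sig)
  expect_equal(nrow(ev), 1L)
  expect_true(abs(ev$peak_time - 60.7) < 0.15)
  expect_gt(ev$amplitude, 100)
})

test_that("slow-wave intrinsic frequency is the reciprocal of the wave period", {
  ev <- event_table(kind = "slow_wave", start = 0, end = 0.8, peak_time = 0.56,
                    amplitude = 120, intrinsic_freq = 1 / 0.8)
  expect_equal(ev$intrinsic_freq, 1.25)
  # and the detector reproduces it on a clean wave
  fs <- 500
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 1.3 * t)
  idx <- round(20 * fs):round(20.8 * fs)
  u <- seq(0, 1, length.out = length(idx))
  x[idx] <- x[idx] + ifelse(u < 0.4, 100 * sin(pi * u / 0.4)^2,
                            -200 * sin(pi * (u - 0.4) / 0.6)^2)
  ev2 <- detect_slow_waves(continuous_signal(x, fs = fs))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$intrinsic_freq, 1 / ev2$duration, tolerance = 1e-9)
  expect_equal(ev2$duration, 0.8, tolerance = 0.2)
})

make_burst_signal <- function(bursts, fs = 500, duration = 60, carrier = 12,
                              amp = 8, noise_sd = 1, seed = 1) {
  set.seed(seed)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  x <- rnorm(length(t), sd = noise_sd)
  for (b in bursts) {
    idx <- round(b[1L] * fs):round(b[2L] * fs)
    tt <- t[idx] - b[1L]
    d <- b[2L] - b[1L]
    x[idx] <- x[idx] + amp * sin(pi * tt / d)^2 * sin(2 * pi * carrier * tt)
  }
  continuous_signal(x, fs = fs)
}

test_that("short spindle candidates are rejected, close ones merged first", {
  # 300 ms burst alone: below the 350 ms minimum even before edge effects
  s_short <- make_burst_signal(list(c(30, 30.3)), amp = 12)
  ev <- detect_band_events(s_short, "spindle")
  expect_equal(nrow(ev), 0L)

  # two 0.6 s bursts whose detected edges sit ~0.4 s apart merge into one
  # event (merge precedes the duration filter, so the merged event survives)
  s_pair <- make_burst_signal(list(c(30, 30.6), c(30.95, 31.55)), amp = 12)
  ev2 <- detect_band_events(s_pair, "spindle")
  expect_equal(nrow(ev2), 1L)
  expect_gt(ev2$duration, 1.2)

  # well-separated bursts stay distinct
  s_far <- make_burst_signal(list(c(20, 20.8), c(40, 40.8)), amp = 12)
  ev3 <- detect_band_events(s_far, "spindle")
  expect_equal(nrow(ev3), 2L)
})

test_that("ripple gaps under 50 ms are treated as one event", {
  s <- make_burst_signal(list(c(30, 30.08), c(30.11, 30.19)), carrier = 160,
                         amp = 10, fs = 1000)
  ev <- detect_band_events(s, "ripple")
  expect_equal(nrow(ev), 1L)
  s2 <- make_burst_signal(list(c(30, 30.08), c(30.3, 30.38)), carrier = 160,
                          amp = 10, fs = 1000)
  ev2 <- detect_band_events(s2, "ripple")
  expect_equal(nrow(ev2), 2L)
})

test_that("an injected 1 s 12 Hz burst yields one spindle with sane features", {
  s <- make_burst_signal(list(c(25, 26)), amp = 6, seed = 3)
  ev <- detect_band_events(s, "spindle")
  expect_equal(nrow(ev), 1L)
  expect_true(ev$duration >= 0.8 && ev$duration <= 1.2)
  # the cycle-count estimator (peaks - 1)/duration reads up to one cycle per
  # event low when the detected extent out-spans the oscillation
  expect_true(ev$intrinsic_freq >= 10.5 && ev$intrinsic_freq <= 13.5)
  expect_true(abs(ev$peak_time - 25.5) < 0.2)
})

test_that("detections are translation-equivariant", {
  s <- make_burst_signal(list(c(20, 20.8), c(35, 35.7)), amp = 10, seed = 9)
  ev <- detect_band_events(s, "spindle")
  shift_n <- 5 * s$fs
  s2 <- continuous_signal(c(rep(0, shift_n), s$samples)[seq_along(s$samples)],
                          fs = s$fs)
  # same noise realisation shifted; compare matched events
  ev2 <- detect_band_events(s2, "spindle")
  shifted <- ev
  shifted$start <- ev$start + 5; shifted$end <- ev$end + 5
  shifted$peak_time <- ev$peak_time + 5
  matched <- match_events(ev2, shifted, tol = 0.1)
  expect_equal(matched$recall, 1)
})

test_that("positive rescaling leaves spindle detections unchanged (z-invariance)", {
  s <- make_burst_signal(list(c(20, 20.8), c(40, 40.6)), amp = 9, seed = 5)
  ev1 <- detect_band_events(s, "spindle")
  s2 <- s; s2$samples <- s$samples * 7.3
  ev2 <- detect_band_events(s2, "spindle")
  expect_equal(nrow(ev1), nrow(ev2))
  expect_equal(ev1$start, ev2$start, tolerance = 1e-9)
  expect_equal(ev2$amplitude, 7.3 * ev1$amplitude, tolerance = 1e-6)
})

test_that("merge-then-filter equals the exhaustive brute-force oracle", {
  set.seed(42)
  for (kind in c("spindle", "ripple")) {
    cfg <- detection_config(kind)
    for (rep in 1:150) {
      n <- sample(1:8, 1)
      starts <- runif(n, 0, 20)
      ends <- starts + runif(n, 0.01, 1.5)
      got <- apply_event_rules(starts, ends, cfg)
      want <- oracle_rules(starts, ends, cfg)
      dimnames(got) <- NULL
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("noise-only false positives stay below 5 events/min per detector", {
  bg_p <- make_background(300, 1000, exponent = 1, rms = 30, seed = 17)
  n_sw <- nrow(detect_slow_waves(bg_p))
  n_sp <- nrow(detect_band_events(bg_p, "spindle"))
  n_ri <- nrow(detect_band_events(bg_p, "ripple"))
  expect_lt(n_sw / 5, 5)
  expect_lt(n_sp / 5, 5)
  expect_lt(n_ri / 5, 5)
})

test_that("state attribution tags events by the epoch containing the peak", {
  h <- hypnogram(c("wake", "wake", "NREM", "REM"))
  ev <- event_table(kind = c("spindle", "spindle", "spindle"),
                    start = c(1, 9, 30), end = c(2, 11, 31),
                    peak_time = c(1.5, 10, 30.5),
                    amplitude = 1, intrinsic_freq = 12)
  out <- attribute_state(ev, h)
  expect_identical(out$state, c("wake", "NREM", "unscored"))
  all_wake <- attribute_state(ev[1:2, ], hypnogram(rep("wake", 5)))
  expect_equal(attr(all_wake, "state_fractions")[["NREM"]], 0)
})
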