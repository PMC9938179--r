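# shared fixtures, built in code

# small, fast session parameters for tests that only need structure
quick_params <- function(duration = 120, fs = 500, ...) {
  gen_params(duration = duration, fs = fs,
             events = list(
               slow_wave = list(density = 6, amp_mean = 170, amp_sd = 20,
                                dur_mean = 1.0, dur_sd = 0.15, carrier = NA),
               spindle = list(density = 2.5, amp_mean = 55, amp_sd = 8,
                              dur_mean = 1.0, dur_sd = 0.2, carrier = 12),
               ripple = list(density = 15, amp_mean = 48, amp_sd = 8,
                             dur_mean = 0.14, dur_sd = 0.02, carrier = 160)),
             ...)
}

# spike-only parameters: trains drawn against a given hypnogram, no signals
spike_params <- function(duration = 600, n_prl = 5, n_ca1 = 5, base_fr = 1.5,
                         burst_frac = 0, suppression = 0, ripple_gain = 0,
                         common_frac = 0, pyr_frac = 1) {
  gen_params(duration = duration,
             spikes = list(n_units = c(PrL = n_prl, CA1 = n_ca1),
                           base_fr = base_fr, burst_frac = burst_frac,
                           suppression = suppression,
                           ripple_gain = ripple_gain,
                           common_frac = common_frac, pyr_frac = pyr_frac))
}

# pure sinusoid as a continuous signal
sine_signal <- function(freq, amp = 1, duration = 30, fs = 500, phase = 0) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  continuous_signal(amp * sin(2 * pi * freq * t + phase), fs = fs)
}

# brute-force oracle for the merge-then-duration rules: repeatedly merge ANY
# pair with gap < g (or overlap) until a fixpoint, then filter by duration
oracle_rules <- function(starts, ends, cfg) {
  iv <- cbind(starts, ends)[order(starts), , drop = FALSE]
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n)) {
      if (merged) break
      for (j in seq_len(n)) {
        if (i == j) next
        gap <- max(iv[i, 1L], iv[j, 1L]) - min(iv[i, 2L], iv[j, 2L])
        if (gap < cfg$merge_gap) {
          new <- c(min(iv[i, 1L], iv[j, 1L]), max(iv[i, 2L], iv[j, 2L]))
          iv <- rbind(iv[-c(i, j), , drop = FALSE], new)
          iv <- iv[order(iv[, 1L]), , drop = FALSE]
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  d <- iv[, 2L] - iv[, 1L]
  out <- iv[d >= cfg$min_dur & d <= cfg$max_dur, , drop = FALSE]
  dimnames(out) <- NULL
  out
}
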