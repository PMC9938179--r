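#' Parameters of the synthetic polysomnography generator
#'
#' Defines a full ground-truth session: 1/f LFP background, an alternating
#' wake/NREM/REM bout schedule, NREM-restricted oscillation events
#' (slow-waves on the cortical channel, spindles optionally phase-locked to
#' slow-waves, ripples on the hippocampal channel), a state-dependent EMG
#' channel, and inhomogeneous-Poisson spike trains with down-state
#' suppression, ripple gain, burstiness and shared-input pairwise
#' correlation.
#'
#' Default event amplitudes are calibrated against the default 1/f
#' background so that slow-wave troughs sit near 8 SD and spindle/ripple
#' peaks near 6 SD of the corresponding band-filtered background -- clearly
#' detectable at the 3.5 SD thresholds, as a well-targeted in-vivo recording
#' would be. Densities (slow-waves 6/min, spindles 2.5/min, ripples 15/min
#' of NREM) and bout means (NREM 90 s, wake 45 s, REM 30 s) are typical of
#' adult rat NREM sleep. A 5% "leak" fraction of events is placed outside
#' NREM, matching the observation that detections are not exclusive to NREM.
#'
#' @param duration session length, s.
#' @param fs sampling rate, Hz.
#' @param state_means named mean bout lengths, s, for wake/NREM/REM.
#' @param background list: `exponent` (1/f slope), `rms` (uV), `theta_rms`
#'   (uV of the 7 Hz theta added during wake and REM), `theta_freq` (Hz).
#' @param events per-kind lists with `density` (events/min of NREM),
#'   `amp_mean`, `amp_sd` (uV), `dur_mean`, `dur_sd` (s) and `carrier` (Hz;
#'   spindles/ripples).
#' @param coupling list: `prob` (probability a spindle is locked to a
#'   slow-wave), `depth` in [0, 1] (1 = exact phase lock), `phase_offset`
#'   (spindle onset as a fraction of the slow-wave period after the trough).
#' @param leak fraction of events placed outside NREM.
#' @param spikes list: `n_units` (named, per region), `base_fr` (Hz),
#'   `burst_frac` (target bursting index), `suppression` in [0, 1] (rate
#'   factor 1 - s inside slow-wave troughs +/- 125 ms), `ripple_gain` (rate
#'   factor 1 + g inside ripples, CA1 units), `common_frac` in [0, 1]
#'   (shared mother-process fraction), `pyr_frac` (fraction of units with
#'   pyramidal waveform widths).
#' @param emg_rms named per-state EMG RMS, uV.
#' @return list of class `gen_params`.
#' @export
gen_params <- function(duration = 600, fs = 1000,
                       state_means = c(wake = 45, NREM = 90, REM = 30),
                       background = list(exponent = 1, rms = 30,
                                         theta_rms = 12, theta_freq = 7),
                       events = list(
                         slow_wave = list(density = 6, amp_mean = 170,
                                          amp_sd = 20, dur_mean = 1.0,
                                          dur_sd = 0.15, carrier = NA),
                         spindle = list(density = 2.5, amp_mean = 55,
                                        amp_sd = 8, dur_mean = 1.0,
                                        dur_sd = 0.2, carrier = 12),
                         ripple = list(density = 15, amp_mean = 48,
                                       amp_sd = 8, dur_mean = 0.14,
                                       dur_sd = 0.02, carrier = 160)),
                       coupling = list(prob = 0.7, depth = 0.5,
                                       phase_offset = 0.25),
                       leak = 0.05,
                       spikes = list(n_units = c(PrL = 10, CA1 = 10),
                                     base_fr = 1.5, burst_frac = 0.2,
                                     suppression = 0.8, ripple_gain = 2,
                                     common_frac = 0.2, pyr_frac = 0.9),
                       emg_rms = c(wake = 40, NREM = 15, REM = 5)) {
  p <- list(duration = duration, fs = fs, state_means = state_means,
            background = background, events = events, coupling = coupling,
            leak = leak, spikes = spikes, emg_rms = emg_rms,
            provenance = character(0))
  validate_gen_params(p)
  structure(p, class = "gen_params")
}

validate_gen_params <- function(p) {
  if (p$duration <= 0 || p$fs <= 0) stopf("duration and fs must be > 0")
  carriers <- vapply(p$events, function(e) e$carrier %||% NA_real_, numeric(1L))
  if (any(!is.na(carriers) & p$fs < 2 * carriers))
    stopf("fs must exceed twice the highest event carrier frequency")
  for (k in names(p$events)) {
    e <- p$events[[k]]
    if (e$density < 0) stopf("%s density must be >= 0", k)
    if (e$dur_mean <= 0) stopf("%s dur_mean must be > 0", k)
  }
  fr <- c(p$coupling$prob, p$coupling$depth, p$leak, p$spikes$burst_frac,
          p$spikes$suppression, p$spikes$common_frac, p$spikes$pyr_frac)
  if (any(fr < 0 | fr > 1)) stopf("fractions must lie in [0, 1]")
  invisible(p)
}

#' 1/f background noise
#'
#' Gaussian noise shaped in the frequency domain so that power falls as
#' f^-exponent (slope -exponent on log-log axes), scaled to an exact target
#' RMS. Exponent 0 gives white noise.
#'
#' @param duration length, s.
#' @param fs sampling rate, Hz.
#' @param exponent spectral slope in [0, 2].
#' @param rms target RMS, uV.
#' @param seed integer RNG seed.
#' @return a [continuous_signal()].
#' @export
make_background <- function(duration, fs, exponent = 1, rms = 30, seed = 1) {
  if (exponent < 0 || exponent > 2) stopf("exponent must be in [0, 2]")
  n <- round(duration * fs)
  if (n < 8L) stopf("fs too low for the requested duration")
  set.seed(seed)
  x <- rnorm(n)
  X <- fft(x)
  f <- c(0, pmin(seq_len(n - 1L), n - seq_len(n - 1L))) * fs / n
  g <- c(0, f[-1L]^(-exponent / 2))
  y <- Re(fft(X * g, inverse = TRUE) / n)
  y <- y / sqrt(mean(y^2)) * rms
  continuous_signal(y, fs = fs, region = "other", label = "background")
}

#' Alternating-bout hypnogram
#'
#' Cycles wake -> NREM -> REM with exponentially distributed bout lengths
#' (means per state), quantised to the epoch grid by the state active at
#' each epoch start.
#'
#' @param duration session length, s.
#' @param epoch_len epoch length, s.
#' @param state_means named means (s) for wake, NREM, REM.
#' @param seed RNG seed.
#' @return a [hypnogram()].
#' @export
make_hypnogram <- function(duration, epoch_len = 4,
                           state_means = c(wake = 45, NREM = 90, REM = 30),
                           seed = 1) {
  set.seed(seed)
  cycle <- c("wake", "NREM", "REM")
  t <- 0; k <- 0L
  bounds <- numeric(0); states <- character(0)
  while (t < duration) {
    st <- cycle[k %% 3L + 1L]
    len <- rexp(1L, 1 / state_means[[st]])
    bounds <- c(bounds, t); states <- c(states, st)
    t <- t + len; k <- k + 1L
  }
  n_ep <- floor(duration / epoch_len)
  ep_start <- (seq_len(n_ep) - 1L) * epoch_len
  lab <- states[findInterval(ep_start, bounds)]
  hypnogram(lab, epoch_len)
}

# draw event intervals (start, dur) for one kind inside the given spans,
# rejecting same-kind overlap; max_tries per event then error
place_events <- function(n, spans, dur_mean, dur_sd, existing = NULL,
                         max_tries = 200L, best_effort = FALSE) {
  if (n == 0L || nrow(spans) == 0L) return(cbind(start = numeric(0), dur = numeric(0)))
  span_len <- spans[, 2L] - spans[, 1L]
  out_s <- out_d <- numeric(0)
  placed <- existing
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      d <- rnorm_trunc(1L, dur_mean, dur_sd, 0.3 * dur_mean)
      fit <- span_len >= d
      if (!any(fit)) next
      sp <- which(fit)[sample.int(sum(fit), 1L, prob = span_len[fit])]
      s <- runif(1L, spans[sp, 1L], spans[sp, 2L] - d)
      if (is.null(placed) ||
          !any(s < placed[, 1L] + placed[, 2L] & s + d > placed[, 1L])) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      if (best_effort) break       # spans saturated: place what fits
      stopf("could not place event %d without overlap after %d tries",
            i, max_tries)
    }
    out_s <- c(out_s, s); out_d <- c(out_d, d)
    placed <- rbind(placed, c(s, d))
  }
  cbind(start = out_s, dur = out_d)
}

#' Sample ground-truth event times for a session
#'
#' Draws Poisson event counts per kind (density per NREM minute, with a
#' `leak` fraction placed outside NREM), places them without same-kind
#' overlap, and applies slow-wave/spindle phase coupling: each spindle is,
#' with probability `coupling$prob`, anchored to a random slow-wave at onset
#' `trough + phase_offset * period` with uniform jitter of half a period
#' scaled by `(1 - depth)` (depth 1 = exact lock).
#'
#' @param hyp a [hypnogram()].
#' @param params a [gen_params()].
#' @param seed RNG seed.
#' @return an [event_table()] of ground-truth events (states filled).
#' @export
sample_events <- function(hyp, params, seed = 1) {
  set.seed(seed)
  nrem <- state_spans(hyp, "NREM")
  other <- state_spans(hyp, c("wake", "REM"))
  nrem_min <- sum(nrem[, 2L] - nrem[, 1L]) / 60
  rows <- list()
  sw_tab <- NULL
  for (kind in c("slow_wave", "ripple", "spindle")) {
    e <- params$events[[kind]]
    n_tot <- rpois(1L, e$density * nrem_min)
    n_leak <- if (nrow(other) && n_tot > 0) rbinom(1L, n_tot, params$leak) else 0L
    pl_in <- place_events(n_tot - n_leak, nrem, e$dur_mean, e$dur_sd)
    # leaked events are best-effort: scarce wake/REM time may not fit them
    # all, so the realised leak fraction can fall slightly below nominal
    pl_out <- place_events(n_leak, other, e$dur_mean, e$dur_sd,
                           existing = pl_in, best_effort = TRUE)
    pl <- rbind(pl_in, pl_out)
    if (!nrow(pl)) next
    if (kind == "spindle" && !is.null(sw_tab) && nrow(sw_tab) > 0 &&
        params$coupling$prob > 0) {
      lock <- runif(nrow(pl)) < params$coupling$prob
      for (i in which(lock)) {
        for (try in seq_len(200L)) {
          j <- sample.int(nrow(sw_tab), 1L)
          period <- sw_tab$dur[j]
          jit <- runif(1L, -0.5, 0.5) * (1 - params$coupling$depth) * period
          s <- sw_tab$trough[j] + params$coupling$phase_offset * period + jit
          if (s < 0 || s + pl[i, 2L] > duration(hyp)) next
          others_idx <- setdiff(seq_len(nrow(pl)), i)
          if (!any(s < pl[others_idx, 1L] + pl[others_idx, 2L] &
                   s + pl[i, 2L] > pl[others_idx, 1L])) {
            pl[i, 1L] <- s; break
          }
        }
      }
    }
    amp <- rnorm_trunc(nrow(pl), e$amp_mean, e$amp_sd, 0.2 * e$amp_mean)
    if (kind == "slow_wave") {
      peak <- pl[, 1L] + 0.7 * pl[, 2L]          # trough centre of the neg lobe
      ifreq <- 1 / pl[, 2L]
      sw_tab <- data.frame(trough = peak, dur = pl[, 2L])
    } else {
      peak <- pl[, 1L] + 0.5 * pl[, 2L]
      ifreq <- rep(e$carrier, nrow(pl))
    }
    rows[[kind]] <- data.frame(kind = kind, start = pl[, 1L],
                               end = pl[, 1L] + pl[, 2L], peak_time = peak,
                               amplitude = amp, intrinsic_freq = ifreq)
  }
  if (!length(rows)) return(event_table())
  d <- do.call(rbind, rows)
  d <- d[order(d$start), , drop = FALSE]
  ev <- event_table(kind = d$kind, start = d$start, end = d$end,
                    peak_time = d$peak_time, amplitude = d$amplitude,
                    intrinsic_freq = d$intrinsic_freq)
  attribute_state(ev, hyp)
}

# add event waveforms onto a sample vector (in place, returned)
render_events <- function(x, fs, events, kinds, pos_ratio = 0.5) {
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    if (!ev$kind %in% kinds) next
    i0 <- floor(ev$start * fs) + 1L
    i1 <- min(length(x), ceiling(ev$end * fs))
    if (i1 <= i0) next
    tt <- ((i0:i1) - 1L) / fs - ev$start
    d <- ev$end - ev$start
    if (ev$kind == "slow_wave") {
      A <- ev$amplitude / (1 + pos_ratio)        # trough depth
      u <- tt / d
      w <- ifelse(u < 0.4,
                  pos_ratio * A * sin(pi * u / 0.4)^2,
                  -A * sin(pi * (u - 0.4) / 0.6)^2)
    } else {
      # hann-windowed sinusoid: full extent = the nominal duration
      carrier <- ev$intrinsic_freq
      c0 <- d / 2
      w <- ev$amplitude * sin(pi * tt / d)^2 *
        sin(2 * pi * carrier * (tt - c0))
    }
    x[i0:i1] <- x[i0:i1] + w
  }
  x
}

#' Inject oscillation events into a signal
#'
#' Renders slow-waves (one-cycle biphasic raised-cosine pulses, positive
#' lobe over the first 40% of the period then the negative trough), spindles
#' and ripples (Gaussian-windowed sinusoids at their carrier) on top of a
#' background signal, and returns the exact ground truth.
#'
#' @param signal a [continuous_signal()] background.
#' @param hyp a [hypnogram()].
#' @param params a [gen_params()].
#' @param seed RNG seed.
#' @param kinds which kinds to render on this channel.
#' @return list: `signal` (with events added), `truth` (an [event_table()]
#'   of the rendered kinds).
#' @export
inject_events <- function(signal, hyp, params, seed = 1,
                          kinds = c("slow_wave", "spindle")) {
  truth <- sample_events(hyp, params, seed)
  truth <- truth[truth$kind %in% kinds, , drop = FALSE]
  out <- signal
  out$samples <- render_events(signal$samples, signal$fs, truth, kinds)
  list(signal = out, truth = truth)
}

#' Generate spike trains locked to the session's events
#'
#' Each unit is an inhomogeneous Poisson process: rate `base_fr`, multiplied
#' by `(1 - suppression)` within +/- 125 ms of slow-wave troughs (both
#' regions) and by `(1 + ripple_gain)` inside ripples (CA1 units), realised
#' by thinning. Pairwise correlation comes from a per-region mother process:
#' a `common_frac` share of each unit's rate is drawn from shared mother
#' spikes (jittered by ~3 ms). Burstiness appends a doublet (ISI 3-15 ms)
#' after a fraction of spikes, with the append probability corrected for
#' chance short ISIs so the realised bursting index converges to
#' `burst_frac`. Waveform widths make a `pyr_frac` share of units classify
#' as pyramidal.
#'
#' @param hyp a [hypnogram()].
#' @param truth_events ground-truth [event_table()] (slow-waves + ripples).
#' @param params a [gen_params()].
#' @param seed RNG seed.
#' @return list of [spike_train()]s.
#' @export
generate_spike_trains <- function(hyp, truth_events, params, seed = 1) {
  if (length(hyp$labels) == 0L) stopf("empty hypnogram")
  set.seed(seed)
  dur <- duration(hyp)
  sp <- params$spikes
  sw <- truth_events[truth_events$kind == "slow_wave", , drop = FALSE]
  rip <- truth_events[truth_events$kind == "ripple", , drop = FALSE]

  rate_factor <- function(t, region) {
    m <- rep(1, length(t))
    if (nrow(sw) && sp$suppression > 0) {
      idx <- findInterval(t, sw$peak_time - 0.125)
      hit <- idx >= 1L & (t - (sw$peak_time[pmax(idx, 1L)] - 0.125)) <= 0.25
      m[hit] <- m[hit] * (1 - sp$suppression)
    }
    if (region == "CA1" && nrow(rip) && sp$ripple_gain > 0) {
      idx <- findInterval(t, rip$start)
      hit <- idx >= 1L & t < rip$end[pmax(idx, 1L)]
      m[hit] <- m[hit] * (1 + sp$ripple_gain)
    }
    m
  }

  trains <- list()
  for (region in names(sp$n_units)) {
    n_units <- sp$n_units[[region]]
    if (n_units == 0L) next
    m_max <- if (region == "CA1") max(1, 1 + sp$ripple_gain) else 1
    lam0 <- sp$base_fr * m_max
    # shared mother process for this region
    n_m <- rpois(1L, lam0 * dur)
    mother <- sort(runif(n_m, 0, dur))
    n_pyr <- round(sp$pyr_frac * n_units)
    for (u in seq_len(n_units)) {
      n_p <- rpois(1L, lam0 * (1 - sp$common_frac) * dur)
      priv <- runif(n_p, 0, dur)
      shar <- mother[runif(length(mother)) < sp$common_frac]
      if (length(shar)) shar <- shar + rnorm(length(shar), 0, 0.003)
      t_all <- sort(c(priv, shar))
      t_all <- t_all[t_all >= 0 & t_all < dur]
      # thin to the modulated rate
      keep <- runif(length(t_all)) < rate_factor(t_all, region) / m_max
      t_all <- t_all[keep]
      # burst doublets, corrected for chance short ISIs
      rate_eff <- length(t_all) / dur
      p0 <- 1 - exp(-rate_eff * 0.02)
      b <- sp$burst_frac
      p_app <- if (b > p0 && b < 1) (b - p0) / (1 - b) else 0
      if (p_app > 0 && length(t_all)) {
        app <- which(runif(length(t_all)) < p_app)
        t_all <- sort(c(t_all, t_all[app] + runif(length(app), 0.003, 0.015)))
      }
      t_all <- t_all[c(TRUE, diff(t_all) > 1e-5)]
      width <- if (u <= n_pyr) rnorm_trunc(1L, 300, 30, 210) else
        min(rnorm_trunc(1L, 150, 20, 80), 195)
      trains[[paste0(region, "_u", u)]] <-
        spike_train(t_all, unit_id = sprintf("%s_u%02d", region, u),
                    region = region, spike_width = width)
    }
  }
  trains
}

#' Apply a drug-effect transform to generator parameters
#'
#' Effects are named lists keyed by dotted parameter paths (e.g.
#' `events.slow_wave.amp_mean`), each a list with `mul` and/or `add`.
#' Fraction-valued parameters (coupling prob/depth, leak, burst/common/pyr
#' fractions, suppression) are clipped into [0, 1] after the transform. The
#' applied transform is recorded in the returned params' `provenance`.
#'
#' @param params a [gen_params()].
#' @param effect named list of transforms.
#' @return new `gen_params`.
#' @export
apply_drug_effect <- function(params, effect) {
  p <- unclass(params)
  clip01 <- c("coupling.prob", "coupling.depth", "leak", "spikes.burst_frac",
              "spikes.suppression", "spikes.common_frac", "spikes.pyr_frac")
  for (path in names(effect)) {
    keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
    node <- p
    for (k in keys) {
      if (is.null(node[[k]])) stopf("unknown parameter '%s' in drug effect", path)
      node <- node[[k]]
    }
    val <- node
    tr <- effect[[path]]
    if (!is.null(tr$mul)) val <- val * tr$mul
    if (!is.null(tr$add)) val <- val + tr$add
    if (path %in% clip01) val <- min(max(val, 0), 1)
    p[[keys]] <- val
    p$provenance <- c(p$provenance,
                      sprintf("%s: mul=%s add=%s -> %g", path,
                              tr$mul %||% 1, tr$add %||% 0, val))
  }
  out <- structure(p, class = "gen_params")
  validate_gen_params(out)
  out
}

#' Simulate a complete ground-truth session
#'
#' Builds the hypnogram, PrL channel (1/f background + wake/REM theta +
#' slow-waves + spindles), CA1 channel (background + theta + ripples), EMG
#' (state-dependent white noise) and spike trains. Fully deterministic given
#' `(params, seed)`.
#'
#' @param params a [gen_params()].
#' @param seed integer seed.
#' @return list of class `synthetic_session`: `prl`, `ca1`, `emg`
#'   ([continuous_signal()]s), `hypnogram`, `truth` (all events),
#'   `spike_trains`, `params`, `seed`.
#' @export
simulate_session <- function(params = gen_params(), seed = 1) {
  hyp <- make_hypnogram(params$duration, 4, params$state_means,
                        derive_seed(seed, 1L))
  bg <- params$background
  prl <- make_background(params$duration, params$fs, bg$exponent, bg$rms,
                         derive_seed(seed, 2L))
  ca1 <- make_background(params$duration, params$fs, bg$exponent, bg$rms,
                         derive_seed(seed, 3L))
  prl$region <- "PrL"; prl$label <- "PrL"
  ca1$region <- "CA1"; ca1$label <- "CA1"

  truth <- sample_events(hyp, params, derive_seed(seed, 4L))
  prl$samples <- render_events(prl$samples, prl$fs, truth,
                               c("slow_wave", "spindle"))
  ca1$samples <- render_events(ca1$samples, ca1$fs, truth, "ripple")

  # wake/REM theta so the theta/SWA ratio discriminates states; the state
  # indicator is smoothed (1 s moving average, applied twice) so that theta
  # ramps on/off without broadband transients at state boundaries
  if ((bg$theta_rms %||% 0) > 0) {
    tvec <- signal_times(prl)
    ind <- as.numeric(state_at(hyp, tvec) %in% c("wake", "REM"))
    w <- max(3L, round(params$fs / 2))
    sm <- roll_mean(roll_mean(ind, w), w)
    th <- sqrt(2) * bg$theta_rms * sin(2 * pi * bg$theta_freq * tvec) * sm
    prl$samples <- prl$samples + th
    ca1$samples <- ca1$samples + th
  }

  set.seed(derive_seed(seed, 5L))
  n <- length(prl$samples)
  st <- state_at(hyp, signal_times(prl))
  rms_map <- c(params$emg_rms, artifact = unname(params$emg_rms["wake"]),
               unscored = unname(params$emg_rms["wake"]))
  emg <- continuous_signal(rnorm(n) * rms_map[st], fs = params$fs,
                           region = "EMG", label = "EMG")

  spikes <- generate_spike_trains(hyp, truth, params, derive_seed(seed, 6L))
  structure(list(prl = prl, ca1 = ca1, emg = emg, hypnogram = hyp,
                 truth = truth, spike_trains = spikes, params = params,
                 seed = seed),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %.0f s @ %g Hz, %d truth events, %d units (seed %d)\n",
              x$params$duration, x$params$fs, nrow(x$truth),
              length(x$spike_trains), x$seed))
  invisible(x)
}

#' Simulate a baseline / post-drug experiment
#'
#' Two independent sessions from the same base parameters, the post session
#' with a drug-effect transform applied; returned with a manifest treating
#' each session as its own analysis window.
#'
#' @param params baseline [gen_params()].
#' @param effect drug-effect list for [apply_drug_effect()] (or `NULL`).
#' @param seed integer seed (baseline and post use derived sub-seeds).
#' @param condition manifest condition label.
#' @return list: `baseline`, `post` (`synthetic_session`s), `manifest`.
#' @export
simulate_experiment <- function(params = gen_params(), effect = NULL,
                                seed = 1, condition = "custom") {
  post_params <- if (is.null(effect)) params else apply_drug_effect(params, effect)
  base <- simulate_session(params, derive_seed(seed, 101L))
  post <- simulate_session(post_params, derive_seed(seed, 202L))
  man <- session_manifest(subject = sprintf("sim%04d", seed),
                          condition = condition,
                          injection_time = params$duration,
                          baseline_window = c(0, params$duration),
                          post_window = params$duration + c(0, post_params$duration))
  list(baseline = base, post = post, manifest = man)
}
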