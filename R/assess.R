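# End-to-end validation harness: every function simulates fresh ground truth
# with the default study conditions, runs the corresponding analysis stage,
# and reports how well the stage recovers what was injected. Used by the
# test suite and by scripts/acceptance.R.

#' Detector fidelity against synthetic ground truth
#'
#' Simulates `n_sessions` default sessions, runs all three detectors, and
#' pools recall/precision per event kind with the given peak-time matching
#' tolerance.
#'
#' @param n_sessions number of sessions (default 20).
#' @param seed base seed; session k uses a derived sub-seed.
#' @param params generator parameters.
#' @param tol matching tolerance, s.
#' @return data.frame: kind, n_truth, n_detected, n_matched, recall,
#'   precision.
#' @export
assess_detection <- function(n_sessions = 20, seed = 1,
                             params = gen_params(), tol = 0.25) {
  acc <- list(slow_wave = c(0, 0, 0), spindle = c(0, 0, 0),
              ripple = c(0, 0, 0))
  for (k in seq_len(n_sessions)) {
    s <- simulate_session(params, seed = derive_seed(seed, k))
    det <- list(slow_wave = detect_slow_waves(s$prl),
                spindle = detect_band_events(s$prl, "spindle"),
                ripple = detect_band_events(s$ca1, "ripple"))
    for (kind in names(det)) {
      tr <- s$truth[s$truth$kind == kind, , drop = FALSE]
      m <- match_events(det[[kind]], tr, tol = tol)
      acc[[kind]] <- acc[[kind]] + c(nrow(tr), nrow(det[[kind]]), m$n_matched)
    }
  }
  do.call(rbind, lapply(names(acc), function(kind) {
    v <- acc[[kind]]
    data.frame(kind = kind, n_truth = v[1L], n_detected = v[2L],
               n_matched = v[3L], recall = v[3L] / v[1L],
               precision = v[3L] / v[2L])
  }))
}

#' Merge/duration rule conformance against a brute-force oracle
#'
#' Generates random small candidate-interval sets and compares the
#' detector's merge-then-duration post-processing with an exhaustive oracle
#' that repeatedly merges any pair closer than the gap until a fixpoint.
#'
#' @param n_sets number of random sets (default 1000).
#' @param seed RNG seed.
#' @return fraction of sets in exact agreement (1 means all).
#' @export
assess_rule_conformance <- function(n_sets = 1000, seed = 1) {
  brute <- function(iv, cfg) {
    repeat {
      n <- nrow(iv); hit <- FALSE
      for (i in seq_len(n)) {
        if (hit) break
        for (j in seq_len(n)) {
          if (i == j) next
          gap <- max(iv[i, 1L], iv[j, 1L]) - min(iv[i, 2L], iv[j, 2L])
          if (gap < cfg$merge_gap) {
            iv <- rbind(iv[-c(i, j), , drop = FALSE],
                        c(min(iv[i, 1L], iv[j, 1L]), max(iv[i, 2L], iv[j, 2L])))
            iv <- iv[order(iv[, 1L]), , drop = FALSE]
            hit <- TRUE; break
          }
        }
      }
      if (!hit) break
    }
    d <- iv[, 2L] - iv[, 1L]
    out <- iv[d >= cfg$min_dur & d <= cfg$max_dur, , drop = FALSE]
    dimnames(out) <- NULL
    out
  }
  set.seed(seed)
  cfgs <- list(detection_config("spindle"), detection_config("ripple"))
  ok <- 0L
  for (r in seq_len(n_sets)) {
    cfg <- cfgs[[r %% 2L + 1L]]
    n <- sample(1:8, 1L)
    starts <- runif(n, 0, 20)
    ends <- starts + runif(n, 0.01, 1.5)
    got <- apply_event_rules(starts, ends, cfg)
    dimnames(got) <- NULL
    want <- brute(cbind(starts, ends)[order(starts), , drop = FALSE], cfg)
    if (isTRUE(all.equal(got, want, tolerance = 1e-12))) ok <- ok + 1L
  }
  ok / n_sets
}

#' Modulation-index closed-form errors
#'
#' Uniform phase-amplitude profile (MI must be 0), single-bin concentration
#' (MI must be 1), and sinusoidal coupling compared with an independent
#' per-sample binning oracle.
#'
#' @param seed RNG seed.
#' @param n samples per case.
#' @return named vector: `err_uniform`, `err_single_bin`, `err_oracle`.
#' @export
assess_mi_closed_forms <- function(seed = 1, n = 20000) {
  set.seed(seed)
  ph <- runif(n, -pi, pi)
  e1 <- abs(mi_from_phase_amp(ph, rep(1, n)) - 0)
  first_bin <- ph >= -pi & ph < -pi + 2 * pi / 18
  e2 <- abs(mi_from_phase_amp(ph, as.numeric(first_bin)) - 1)
  amp <- (1 + cos(ph)) / 2
  sums <- counts <- numeric(18)
  for (i in seq_len(n)) {
    k <- floor((ph[i] + pi) / (2 * pi) * 18) %% 18 + 1
    sums[k] <- sums[k] + amp[i]; counts[k] <- counts[k] + 1
  }
  m <- sums / counts
  p <- m / sum(m)
  oracle <- (log(18) + sum(p[p > 0] * log(p[p > 0]))) / log(18)
  e3 <- abs(mi_from_phase_amp(ph, amp) - oracle)
  c(err_uniform = e1, err_single_bin = e2, err_oracle = e3)
}

#' Recovery of injected slow-wave amplitude transforms
#'
#' For each multiplier, simulates baseline/post session pairs with the
#' post-session slow-wave amplitude scaled, detects slow-waves in both, and
#' reports the mean recovered % change of detected amplitude across seeds.
#'
#' @param multipliers post/baseline amplitude factors.
#' @param n_seeds seeds per multiplier (default 20).
#' @param seed base seed.
#' @param params baseline generator parameters.
#' @return data.frame: multiplier, injected_pct, recovered_pct, error_pp.
#' @export
assess_recovery <- function(multipliers = c(1.10, 1.25, 1.50), n_seeds = 20,
                            seed = 1, params = gen_params()) {
  rec <- matrix(NA_real_, n_seeds, length(multipliers))
  for (k in seq_len(n_seeds)) {
    base <- simulate_session(params, seed = derive_seed(seed, 1000L + k))
    a0 <- mean(detect_slow_waves(base$prl)$amplitude)
    for (j in seq_along(multipliers)) {
      pp <- apply_drug_effect(params, list(
        "events.slow_wave.amp_mean" = list(mul = multipliers[j])))
      post <- simulate_session(pp, seed = derive_seed(seed, 2000L + 100L * j + k))
      a1 <- mean(detect_slow_waves(post$prl)$amplitude)
      rec[k, j] <- (a1 / a0 - 1) * 100
    }
  }
  data.frame(multiplier = multipliers,
             injected_pct = (multipliers - 1) * 100,
             recovered_pct = colMeans(rec),
             error_pp = colMeans(rec) - (multipliers - 1) * 100)
}

#' Slow-wave/spindle coupling recovery
#'
#' Baseline sessions with coupling depth 0 against post sessions with depth
#' raised to `depth_post`: reports the fraction of seeds whose PAC change
#' (max in-window MI, post - pre) is positive, plus whether the
#' comodulogram maximum of a fully coupled session falls inside the
#' 0.5-1.5 Hz x 10-16 Hz window.
#'
#' @param n_seeds number of seeds (default 20).
#' @param seed base seed.
#' @param duration session length for PAC estimation, s (default 1800; MI
#'   stability needs generous NREM).
#' @param depth_post coupling depth of the post sessions.
#' @return list: `changes` (per-seed), `sign_rate`, `comod_max_in_window`.
#' @export
assess_coupling <- function(n_seeds = 20, seed = 1, duration = 1800,
                            depth_post = 0.8) {
  p0 <- gen_params(duration = duration,
                   coupling = list(prob = 0.7, depth = 0, phase_offset = 0.25))
  changes <- vapply(seq_len(n_seeds), function(k) {
    ex <- simulate_experiment(p0,
      effect = list("coupling.depth" = list(add = depth_post)),
      seed = derive_seed(seed, 3000L + k))
    pre <- comodulogram(ex$baseline$prl, hypnogram = ex$baseline$hypnogram)
    post <- comodulogram(ex$post$prl, hypnogram = ex$post$hypnogram)
    pac_change(pre, post)
  }, numeric(1L))

  p1 <- gen_params(duration = duration,
                   coupling = list(prob = 1, depth = 1, phase_offset = 0.25))
  s1 <- simulate_session(p1, seed = derive_seed(seed, 4000L))
  cm <- comodulogram(s1$prl, hypnogram = s1$hypnogram)
  ij <- which(cm$mi == max(cm$mi), arr.ind = TRUE)[1L, ]
  in_win <- cm$phase_bands[ij[1L], 1L] >= 0.5 - 1e-9 &&
    cm$phase_bands[ij[1L], 2L] <= 1.5 + 1e-9 &&
    cm$amp_bands[ij[2L], 1L] >= 10 - 1e-9 &&
    cm$amp_bands[ij[2L], 2L] <= 16 + 1e-9
  list(changes = changes, sign_rate = mean(changes > 0),
       comod_max_in_window = in_win)
}

#' Cellular analytics against generator truth
#'
#' Three checks: (1) with down-state suppression 0.8, the fraction of
#' pyramidal units whose mean PETH z in +/-250 ms around slow-wave troughs
#' is negative; (2) the fraction of simulated pairs where a common-input
#' pair beats an independent pair on the within-region cross-correlogram
#' peak statistic; (3) the absolute error of the bursting index against the
#' configured burst fraction at >= 10,000 spikes.
#'
#' @param seed base seed.
#' @param n_sessions sessions for the PETH check.
#' @param n_pairs pair draws for the cross-correlogram check (default 100).
#' @return list: `peth_neg_frac`, `xcorr_win_rate`, `bi_error`.
#' @export
assess_cellular <- function(seed = 1, n_sessions = 10, n_pairs = 100) {
  # (1) PETH suppression
  stats <- c()
  for (k in seq_len(n_sessions)) {
    p <- gen_params(spikes = list(n_units = c(PrL = 10, CA1 = 0),
                                  base_fr = 1.5, burst_frac = 0.2,
                                  suppression = 0.8, ripple_gain = 0,
                                  common_frac = 0, pyr_frac = 1))
    hyp <- make_hypnogram(p$duration, 4, p$state_means,
                          derive_seed(seed, 5000L + k))
    tr_ev <- sample_events(hyp, p, derive_seed(seed, 5100L + k))
    trains <- generate_spike_trains(hyp, tr_ev, p, derive_seed(seed, 5200L + k))
    anchors <- tr_ev$peak_time[tr_ev$kind == "slow_wave"]
    stats <- c(stats, vapply(trains, function(tr) {
      pe <- peth(tr, anchors, window = 0.5, bin_len = 0.005)
      if (pe$flagged) NA_real_ else peth_stat(pe, c(-0.25, 0.25))
    }, numeric(1L)))
  }
  peth_neg_frac <- mean(stats < 0, na.rm = TRUE)

  # (2) common input vs independent pairs
  hyp12 <- make_hypnogram(1200, 4, seed = derive_seed(seed, 6000L))
  p_com <- gen_params(duration = 1200,
                      spikes = list(n_units = c(PrL = 2, CA1 = 0),
                                    base_fr = 1.5, burst_frac = 0,
                                    suppression = 0, ripple_gain = 0,
                                    common_frac = 0.5, pyr_frac = 1))
  p_ind <- gen_params(duration = 1200,
                      spikes = list(n_units = c(PrL = 2, CA1 = 0),
                                    base_fr = 1.5, burst_frac = 0,
                                    suppression = 0, ripple_gain = 0,
                                    common_frac = 0, pyr_frac = 1))
  wins <- vapply(seq_len(n_pairs), function(k) {
    tc <- generate_spike_trains(hyp12, event_table(), p_com,
                                derive_seed(seed, 6100L + k))
    ti <- generate_spike_trains(hyp12, event_table(), p_ind,
                                derive_seed(seed, 6300L + k))
    sc <- xcorr_stat(cross_correlogram(tc[[1L]], tc[[2L]]), "within_region")
    si <- xcorr_stat(cross_correlogram(ti[[1L]], ti[[2L]]), "within_region")
    sc > si
  }, logical(1L))

  # (3) bursting-index convergence at 10,000+ spikes
  pb <- gen_params(duration = 7000,
                   spikes = list(n_units = c(PrL = 1, CA1 = 0), base_fr = 1.5,
                                 burst_frac = 0.3, suppression = 0,
                                 ripple_gain = 0, common_frac = 0,
                                 pyr_frac = 1))
  hb <- make_hypnogram(7000, 4, seed = derive_seed(seed, 7000L))
  tb <- generate_spike_trains(hb, event_table(), pb,
                              derive_seed(seed, 7001L))[[1L]]
  bi_error <- abs(bursting_index(tb) - 0.3)

  list(peth_neg_frac = peth_neg_frac, xcorr_win_rate = mean(wins),
       bi_error = bi_error, n_spikes_bi = length(tb$times))
}

#' Type-I error of the group-comparison decision tree
#'
#' Simulates null datasets (4 conditions x n per group, identical
#' distributions) under a Gaussian regime (routing mostly to the ANOVA
#' path) and a heavy-tailed regime (t with 2 df, routing mostly to
#' Kruskal-Wallis) and reports the omnibus rejection rate at alpha 0.05.
#'
#' @param n_sim simulated datasets per regime (default 1000).
#' @param seed RNG seed.
#' @param n_per_group values per condition (default 4).
#' @return named vector: `gaussian`, `heavy_tailed`.
#' @export
assess_type1 <- function(n_sim = 1000, seed = 1, n_per_group = 4) {
  conds <- rep(c("saline", "a", "b", "c"), each = n_per_group)
  one <- function(gen) {
    mean(replicate(n_sim, {
      d <- data.frame(condition = conds, value = gen(length(conds)))
      compare_groups(d)$p < 0.05
    }))
  }
  set.seed(seed)
  g <- one(function(n) rnorm(n))
  h <- one(function(n) stats::rt(n, df = 2))
  c(gaussian = g, heavy_tailed = h)
}

#' Vigilance-scorer agreement with generator truth
#'
#' @param n_sessions default sessions to score.
#' @param seed base seed.
#' @return mean epoch-wise agreement across sessions.
#' @export
assess_scorer <- function(n_sessions = 5, seed = 1) {
  mean(vapply(seq_len(n_sessions), function(k) {
    s <- simulate_session(gen_params(), seed = derive_seed(seed, 8000L + k))
    h <- score_vigilance(s$prl, s$emg)
    mean(h$labels == s$hypnogram$labels)
  }, numeric(1L)))
}
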