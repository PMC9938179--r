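#' Rule-based vigilance-state scoring
#'
#' Per 4 s epoch the theta (5-10 Hz) / SWA (0.5-4 Hz) power ratio of the
#' LFP and the EMG RMS are computed, the two features manual scorers rely
#' on (ratio high in wake and REM, low in NREM; EMG high in wake,
#' intermediate in NREM, very low in REM). Scoring is hierarchical, as in
#' standard rodent auto-scorers: wake is split off first by muscle tone
#' (deterministic two-means clustering of the log EMG RMS); among the
#' remaining epochs REM is split off by its very low EMG, falling back to
#' the theta/SWA ratio whenever the EMG clusters are too close to trust
#' (separation under 0.5 log units). All thresholds are per-recording and
#' scale free. `method = "quantile"` instead uses fixed quantile splits of
#' the ratio (`ratio_q`: epochs below are NREM) and of the EMG among
#' high-ratio epochs (`emg_q`: above wake, below REM). Epochs containing
#' clipped samples (|x| >= `clip_uv`) are artifacts. This is an explicit
#' emulation of manual scoring; externally scored hypnograms can always be
#' supplied instead.
#'
#' @param lfp cortical [continuous_signal()].
#' @param emg EMG [continuous_signal()] covering the same span.
#' @param epoch_len s (default 4).
#' @param theta_band,swa_band Hz.
#' @param method `"cluster"` (two-means split, default) or `"quantile"`.
#' @param ratio_q quantile of the theta/SWA ratio splitting NREM from the
#'   rest (quantile method only).
#' @param emg_q quantile of EMG RMS among high-ratio epochs splitting REM
#'   from wake (quantile method only).
#' @param clip_uv saturation threshold, uV.
#' @return a [hypnogram()].
#' @export
score_vigilance <- function(lfp, emg, epoch_len = 4,
                            theta_band = c(5, 10), swa_band = c(0.5, 4),
                            method = c("cluster", "quantile"),
                            ratio_q = 0.5, emg_q = 1 / 3, clip_uv = 5000) {
  method <- match.arg(method)
  if (abs(duration(lfp) - duration(emg)) > epoch_len)
    stopf("LFP and EMG spans differ by more than one epoch")
  fs <- lfp$fs
  nper <- round(epoch_len * fs)
  n_ep <- floor(length(lfp$samples) / nper)
  if (n_ep < 2L) stopf("need at least 2 epochs to score")
  seg <- matrix(lfp$samples[seq_len(n_ep * nper)], nrow = nper)
  clipped <- apply(abs(seg) >= clip_uv, 2L, any)   # on the raw trace
  seg <- sweep(seg, 2L, colMeans(seg))
  P <- Mod(stats::mvfft(seg))^2
  freqs <- (seq_len(nper) - 1L) * fs / nper
  th <- colMeans(P[freqs >= theta_band[1L] & freqs <= theta_band[2L], , drop = FALSE])
  sw <- colMeans(P[freqs >= swa_band[1L] & freqs <= swa_band[2L], , drop = FALSE])
  ratio <- th / pmax(sw, .Machine$double.eps)

  nper_e <- round(epoch_len * emg$fs)
  emg_seg <- matrix(emg$samples[seq_len(min(n_ep * nper_e, length(emg$samples)))],
                    nrow = nper_e)
  emg_rms <- sqrt(colMeans(emg_seg^2))[seq_len(n_ep)]

  # deterministic 1-d two-means: returns the two cluster means
  means2 <- function(x) {
    if (length(unique(x)) < 2L) return(c(min(x), max(x)))
    c1 <- quantile(x, 0.25, names = FALSE); c2 <- quantile(x, 0.75, names = FALSE)
    for (it in seq_len(50L)) {
      a <- abs(x - c1) <= abs(x - c2)
      n1 <- mean(x[a]); n2 <- if (all(a)) c2 else mean(x[!a])
      if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
      c1 <- n1; c2 <- n2
    }
    sort(c(c1, c2))
  }
  # deterministic 1-d three-means initialised at the extreme quantiles so
  # small wake or REM fractions still seed their own cluster
  means3 <- function(x) {
    cs <- quantile(x, c(0.02, 0.5, 0.98), names = FALSE)
    if (length(unique(x)) < 3L) return(sort(cs))
    for (it in seq_len(100L)) {
      a <- apply(abs(outer(x, cs, "-")), 1L, which.min)
      new <- vapply(1:3, function(k) if (any(a == k)) mean(x[a == k]) else cs[k],
                    numeric(1L))
      if (isTRUE(all.equal(new, cs))) break
      cs <- new
    }
    sort(cs)
  }
  labels <- rep("NREM", n_ep)
  if (method == "cluster") {
    lx <- log(emg_rms)
    cm <- means3(lx)
    assign3 <- apply(abs(outer(lx, cm, "-")), 1L, which.min)
    if (cm[3L] - cm[2L] >= 0.5) labels[assign3 == 3L] <- "wake"
    rest <- which(labels != "wake")
    if (cm[2L] - cm[1L] >= 0.5) {
      labels[intersect(rest, which(assign3 == 1L))] <- "REM"
    } else if (length(rest) >= 2L) {       # fall back to the theta/SWA ratio
      rr <- means2(log(ratio[rest]))
      cand <- log(ratio[rest]) > mean(rr)
      # REM needs genuinely theta-dominated epochs, not a split of log-noise
      if (diff(rr) >= 0.5 && any(cand) && median(ratio[rest][cand]) > 0.3)
        labels[rest][cand] <- "REM"
    }
  } else {
    high <- ratio > quantile(ratio, ratio_q, names = FALSE)
    if (any(high)) {
      emg_thr <- quantile(emg_rms[high], emg_q, names = FALSE)
      labels[high & emg_rms > emg_thr] <- "wake"
      labels[high & emg_rms <= emg_thr] <- "REM"
    }
  }
  labels[clipped] <- "artifact"
  hypnogram(labels, epoch_len)
}

#' Sleep-onset latency
#'
#' Start time of the first NREM epoch; `NA` when none is scored.
#'
#' @param hyp a [hypnogram()].
#' @return latency, s, or `NA`.
#' @export
sleep_onset_latency <- function(hyp) {
  i <- match("NREM", hyp$labels)
  if (is.na(i)) return(NA_real_)
  (i - 1L) * hyp$epoch_len
}

#' Per-window event metrics
#'
#' Event density (per minute of window), mean amplitude, intrinsic frequency
#' and duration per event kind, restricted to events whose peak lies in the
#' half-open window. Feature means of an empty window are `NA`, density 0.
#'
#' @param events an [event_table()].
#' @param window `c(start, end)`, s.
#' @return data.frame: kind, n, density, amplitude, intrinsic_freq, duration.
#' @export
event_metrics <- function(events, window) {
  wmin <- diff(window) / 60
  do.call(rbind, lapply(EVENT_KINDS, function(k) {
    e <- events[events$kind == k & events$peak_time >= window[1L] &
                  events$peak_time < window[2L], , drop = FALSE]
    data.frame(kind = k, n = nrow(e), density = nrow(e) / wmin,
               amplitude = if (nrow(e)) mean(e$amplitude) else NA_real_,
               intrinsic_freq = if (nrow(e)) mean(e$intrinsic_freq) else NA_real_,
               duration = if (nrow(e)) mean(e$duration) else NA_real_)
  }))
}

#' Time in each vigilance state within a window
#' @param hyp a [hypnogram()].
#' @param window `c(start, end)`, s.
#' @return named vector of seconds per state.
#' @export
state_amounts <- function(hyp, window) {
  starts <- (seq_along(hyp$labels) - 1L) * hyp$epoch_len
  ends <- starts + hyp$epoch_len
  ov <- pmax(0, pmin(ends, window[2L]) - pmax(starts, window[1L]))
  vapply(setNames(VIGILANCE_STATES, VIGILANCE_STATES),
         function(s) sum(ov[hyp$labels == s]), numeric(1L))
}

#' Baseline vs post change records
#'
#' One row per metric: baseline value, post value and the change, either as
#' a plain difference (post - baseline) or as % of baseline (only defined
#' for nonzero baselines).
#'
#' @param baseline,post named numeric vectors of matching metrics.
#' @param mode `"difference"` or `"percent"`.
#' @param subject,condition identifiers carried into the record.
#' @return data.frame of class `change_record`.
#' @export
change_records <- function(baseline, post, mode = c("difference", "percent"),
                           subject = NA_character_, condition = NA_character_) {
  mode <- match.arg(mode)
  metrics <- intersect(names(baseline), names(post))
  chg <- if (mode == "difference") post[metrics] - baseline[metrics]
  else ifelse(baseline[metrics] != 0,
              (post[metrics] - baseline[metrics]) / baseline[metrics] * 100,
              NA_real_)
  out <- data.frame(subject = subject, condition = condition, metric = metrics,
                    baseline = unname(baseline[metrics]),
                    post = unname(post[metrics]),
                    change = unname(chg), mode = mode)
  class(out) <- c("change_record", "data.frame")
  out
}

#' Full per-window metric set for a session
#'
#' Computes, separately on the baseline and post windows of the manifest:
#' event metrics, state amounts, NREM Welch spectrum and (optionally) unit
#' firing rate / bursting index.
#'
#' @param events detected [event_table()] (whole recording).
#' @param hyp a [hypnogram()].
#' @param manifest a [session_manifest()].
#' @param signal optional [continuous_signal()] for spectra.
#' @param spike_trains optional list of [spike_train()]s.
#' @return list with elements `baseline` and `post`, each containing
#'   `events`, `states`, and optionally `spectrum`, `units`.
#' @export
windowed_metrics <- function(events, hyp, manifest, signal = NULL,
                             spike_trains = NULL) {
  one <- function(window) {
    out <- list(window = window,
                events = event_metrics(events, window),
                states = state_amounts(hyp, window))
    if (!is.null(signal))
      out$spectrum <- welch_power(crop_signal(signal, window), hypnogram = hyp)
    if (!is.null(spike_trains)) {
      out$units <- do.call(rbind, lapply(spike_trains, function(tr)
        data.frame(unit_id = tr$unit_id, region = tr$region,
                   fr = mean_fr(tr, window),
                   bi = suppressWarnings(bursting_index(tr, window)))))
    }
    out
  }
  list(baseline = one(manifest$baseline_window),
       post = one(manifest$post_window))
}

# Dunn's rank-sum post-hoc z tests vs a reference group, tie-corrected,
# Sidak-adjusted (no installed package provides Dunn's test)
dunn_vs_ref <- function(values, groups, ref) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(values)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  lev <- unique(groups)
  others <- setdiff(lev, ref)
  m <- length(others)
  out <- do.call(rbind, lapply(others, function(g) {
    ri <- mean(r[groups == g]); rj <- mean(r[groups == ref])
    ni <- sum(groups == g); nj <- sum(groups == ref)
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ni + 1 / nj))
    z <- (ri - rj) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(condition = g, statistic = z, p_raw = p,
               p_adj = min(1, 1 - (1 - p)^m))
  }))
  rownames(out) <- NULL
  out
}

# pooled-SD pairwise t-tests vs reference, Bonferroni over k-1 comparisons
bonferroni_vs_ref <- function(values, groups, ref) {
  groups <- as.character(groups)
  lev <- unique(groups)
  others <- setdiff(lev, ref)
  m <- length(others)
  k <- length(lev)
  ss <- sum(vapply(lev, function(g) {
    v <- values[groups == g]; sum((v - mean(v))^2)
  }, numeric(1L)))
  df <- length(values) - k
  sp2 <- ss / df
  out <- do.call(rbind, lapply(others, function(g) {
    vi <- values[groups == g]; vj <- values[groups == ref]
    se <- sqrt(sp2 * (1 / length(vi) + 1 / length(vj)))
    tt <- (mean(vi) - mean(vj)) / se
    p <- 2 * pt(-abs(tt), df)
    data.frame(condition = g, statistic = tt, p_raw = p,
               p_adj = min(1, p * m))
  }))
  rownames(out) <- NULL
  out
}

#' Group comparison with the distribution-driven decision tree
#'
#' Normality of every group is tested with Shapiro-Wilk and equality of
#' variances with Bartlett (alpha 0.05 each). When all pass, the omnibus
#' test is a one-way ANOVA with Bonferroni pairwise comparisons against the
#' reference (saline) group; otherwise Kruskal-Wallis with Dunn's post-hoc
#' (Sidak-adjusted). Degenerate all-identical data short-circuit to p = 1
#' with no post-hoc flags.
#'
#' @param data data.frame with columns `condition` and `value` (one row per
#'   subject/unit/pair).
#' @param ref reference condition (default `"saline"`, else the first
#'   level present).
#' @param alpha assumption-test level.
#' @return list of class `group_comparison`: `test` (one of
#'   `"anova_bonferroni"`, `"kruskal_dunn"`), `statistic`, `df`, `p`,
#'   `posthoc` (condition vs ref table), `assumptions`.
#' @export
compare_groups <- function(data, ref = NULL, alpha = 0.05) {
  stopifnot(all(c("condition", "value") %in% names(data)))
  data <- data[complete.cases(data[c("condition", "value")]), , drop = FALSE]
  groups <- as.character(data$condition)
  values <- data$value
  lev <- unique(groups)
  if (length(lev) < 2L) stopf("need at least 2 conditions")
  sizes <- table(groups)
  if (any(sizes < 3L))
    stopf("condition '%s' has fewer than 3 values", names(sizes)[sizes < 3L][1L])
  if (is.null(ref)) ref <- if ("saline" %in% lev) "saline" else lev[1L]

  if (length(unique(values)) == 1L) {
    out <- list(test = "degenerate", statistic = 0, df = NA_real_, p = 1,
                posthoc = data.frame(condition = setdiff(lev, ref),
                                     statistic = 0, p_raw = 1, p_adj = 1),
                assumptions = list(normal = TRUE, equal_var = TRUE))
    class(out) <- "group_comparison"
    return(out)
  }

  sw_ok <- all(vapply(lev, function(g) {
    v <- values[groups == g]
    if (length(unique(v)) == 1L) return(FALSE)   # constant: not testably normal
    shapiro.test(v)$p.value > alpha
  }, logical(1L)))
  bt_ok <- sw_ok && bartlett.test(values, factor(groups))$p.value > alpha

  if (sw_ok && bt_ok) {
    fit <- aov(values ~ factor(groups))
    sm <- summary(fit)[[1L]]
    out <- list(test = "anova_bonferroni",
                statistic = sm[["F value"]][1L],
                df = sm[["Df"]], p = sm[["Pr(>F)"]][1L],
                posthoc = bonferroni_vs_ref(values, groups, ref))
  } else {
    kw <- kruskal.test(values, factor(groups))
    out <- list(test = "kruskal_dunn",
                statistic = unname(kw$statistic),
                df = unname(kw$parameter), p = kw$p.value,
                posthoc = dunn_vs_ref(values, groups, ref))
  }
  out$assumptions <- list(normal = sw_ok, equal_var = bt_ok)
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: stat=%.3f p=%.4g\n", x$test,
              x$statistic, x$p))
  if (nrow(x$posthoc)) print(x$posthoc)
  invisible(x)
}

#' PAC change comparisons (t-test family)
#'
#' PAC change distributions are not of equal variance; each condition's
#' changes are tested against zero with a one-sample t-test (baseline
#' comparison) and against the reference condition with a Welch two-sample
#' t-test.
#'
#' @param data data.frame with `condition` and `value` (per-subject PAC
#'   change).
#' @param ref reference condition (default saline).
#' @return data.frame: condition, n, mean, sem, t_vs0, p_vs0, t_vs_ref,
#'   p_vs_ref.
#' @export
compare_pac <- function(data, ref = "saline") {
  lev <- unique(as.character(data$condition))
  vref <- data$value[data$condition == ref]
  do.call(rbind, lapply(lev, function(g) {
    v <- data$value[data$condition == g]
    t0 <- t.test(v, mu = 0)
    tw <- if (g != ref && length(vref) >= 2L)
      t.test(v, vref, var.equal = FALSE) else NULL
    data.frame(condition = g, n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)),
               t_vs0 = unname(t0$statistic), p_vs0 = t0$p.value,
               t_vs_ref = if (is.null(tw)) NA_real_ else unname(tw$statistic),
               p_vs_ref = if (is.null(tw)) NA_real_ else tw$p.value)
  }))
}

#' Per-frequency-bin spectral comparison
#'
#' Applies [compare_groups()] independently at every frequency bin of
#' power-as-%-of-baseline values and reports raw and Bonferroni-corrected
#' (across bins) p-values plus runs of significant bins.
#'
#' @param data data.frame with columns `freq`, `condition`, `value`
#'   (post/baseline x 100 per subject), all conditions on a common grid.
#' @param ref reference condition.
#' @param alpha significance level.
#' @return data.frame per bin: freq, test, p, p_bonf, sig_raw, sig_bonf;
#'   attribute `sig_runs` lists contiguous significant (raw) frequency runs.
#' @export
per_bin_spectral_comparison <- function(data, ref = NULL, alpha = 0.05) {
  freqs <- sort(unique(data$freq))
  per_cond_grid <- tapply(data$freq, data$condition,
                          function(f) identical(sort(unique(f)), freqs))
  if (!all(unlist(per_cond_grid)))
    stopf("conditions are not on a common frequency grid")
  nb <- length(freqs)
  res <- do.call(rbind, lapply(freqs, function(f) {
    d <- data[data$freq == f, , drop = FALSE]
    cg <- compare_groups(d, ref = ref)
    data.frame(freq = f, test = cg$test, p = cg$p)
  }))
  res$p_bonf <- pmin(1, res$p * nb)
  res$sig_raw <- res$p < alpha
  res$sig_bonf <- res$p_bonf < alpha
  runs <- rle(res$sig_raw)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  sig_runs <- data.frame(from = freqs[starts[runs$values]],
                         to = freqs[ends[runs$values]])
  attr(res, "sig_runs") <- sig_runs
  res
}
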