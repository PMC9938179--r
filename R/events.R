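#' Zero-phase band-pass filtering and z-scoring
#'
#' Band-pass filters an LFP trace with a zero-phase (forward-backward)
#' order-2 Butterworth filter, then z-scores the filtered trace using the
#' mean and SD of the whole submitted trace. With `hypnogram` and
#' `exclude_artifact = TRUE`, samples in artifact epochs are left in the
#' filtered output but excluded from the scaling statistics.
#'
#' @param signal a [continuous_signal()].
#' @param band `c(low, high)` Hz, inside `(0, fs/2)`.
#' @param hypnogram optional [hypnogram()] used only for artifact exclusion.
#' @param exclude_artifact exclude artifact epochs from mean/SD (default FALSE:
#'   the whole signal scales, artifacts included).
#' @return object of class `zscored_band`: `z` (SD units), `filtered` (uV),
#'   `band`, `fs`, `t0`, `mean`, `sd` (the uV scaling used).
#' @export
bandpass_zscore <- function(signal, band, hypnogram = NULL,
                            exclude_artifact = FALSE) {
  fs <- signal$fs
  if (band[1L] <= 0 || band[2L] >= fs / 2 || band[1L] >= band[2L])
    stopf("band [%g, %g] Hz must lie inside (0, fs/2) = (0, %g)",
          band[1L], band[2L], fs / 2)
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  filt <- signal::filtfilt(bf, signal$samples)
  keep <- rep(TRUE, length(filt))
  if (!is.null(hypnogram) && exclude_artifact) {
    st <- state_at(hypnogram, signal_times(signal))
    keep <- st != "artifact"
    if (!any(keep)) stopf("all samples fall in artifact epochs")
  }
  m <- mean(filt[keep]); s <- sd(filt[keep])
  degenerate <- !is.finite(s) || s == 0 || sd(signal$samples) == 0
  z <- if (degenerate) rep(0, length(filt)) else (filt - m) / s
  if (degenerate) s <- 0
  structure(list(z = z, filtered = filt, band = band, fs = fs,
                 t0 = signal$t0, mean = m, sd = if (is.finite(s)) s else 0),
            class = "zscored_band")
}

#' Cubic-spline amplitude envelope
#'
#' Rectifies a z-scored band signal and interpolates a natural cubic spline
#' through the local maxima of the rectified trace, evaluated at every
#' sample. Before the first and after the last maximum the envelope holds
#' those end values.
#'
#' @param zsignal a `zscored_band` (from [bandpass_zscore()]) or numeric
#'   vector in SD units.
#' @return numeric envelope, same length as the input, class `envelope`
#'   attributes preserved from the input where present.
#' @export
spline_envelope <- function(zsignal) {
  z <- if (inherits(zsignal, "zscored_band")) zsignal$z else as.numeric(zsignal)
  r <- abs(z)
  pk <- local_maxima(r)
  if (length(pk) < 4L)
    stopf("only %d rectified maxima: input too short for a spline envelope",
          length(pk))
  env <- spline(pk, r[pk], xout = seq_along(r), method = "fmm")$y
  if (pk[1L] > 1L) env[seq_len(pk[1L] - 1L)] <- r[pk[1L]]
  n <- length(r)
  if (pk[length(pk)] < n) env[(pk[length(pk)] + 1L):n] <- r[pk[length(pk)]]
  env
}

#' Detect slow-waves from a cortical LFP
#'
#' The 0.5-4 Hz zero-phase filtered, z-scored trace is parsed into candidate
#' waves delimited by its zero-crossings (a positive lobe followed by a
#' negative lobe). A wave qualifies when its extremum exceeds the detection
#' threshold (default 3.5 SD) in either direction. Amplitude is the initial
#' positive peak minus the maximal negative trough in microvolts of the
#' filtered trace; waves whose trough negativity does not exceed
#' `min_negativity` (default 50 uV) are rejected. The intrinsic frequency is
#' the reciprocal of the wave period, `1 / (end - start)`; `peak_time` is the
#' trough time.
#'
#' @param signal a [continuous_signal()] (cortical channel).
#' @param cfg a [detection_config()] for `"slow_wave"`.
#' @param hypnogram optional [hypnogram()]; when given, events are state
#'   tagged via [attribute_state()] (detection itself is never restricted to
#'   NREM).
#' @param exclude_artifact passed to [bandpass_zscore()].
#' @return an [event_table()].
#' @export
detect_slow_waves <- function(signal, cfg = detection_config("slow_wave"),
                              hypnogram = NULL, exclude_artifact = FALSE) {
  zb <- bandpass_zscore(signal, cfg$band, hypnogram, exclude_artifact)
  z <- zb$z; filt <- zb$filtered; fs <- zb$fs
  n <- length(z)
  up <- which(z[-n] < 0 & z[-1L] >= 0)   # index just before the up-crossing
  if (length(up) < 2L) return(event_table())

  rows <- vector("list", length(up) - 1L)
  for (k in seq_len(length(up) - 1L)) {
    i0 <- up[k] + 1L; i1 <- up[k + 1L]  # [i0, i1] spans pos lobe then neg lobe
    seg <- z[i0:i1]
    if (max(abs(seg)) < cfg$detect_thresh) next
    tr_rel <- which.min(seg)
    trough_i <- i0 + tr_rel - 1L
    trough_uv <- filt[trough_i]
    if (trough_uv >= 0) next                        # no negative lobe
    if (-trough_uv <= cfg$min_negativity) next      # negativity rule (uV)
    pre <- filt[i0:trough_i]
    flagged <- FALSE
    if (any(pre > 0)) {
      pos_peak_uv <- max(pre)
    } else {                                        # monophasic fallback
      pos_peak_uv <- 0
      flagged <- TRUE
    }
    start <- zb$t0 + (i0 - 1L) / fs
    end <- zb$t0 + (i1 - 1L) / fs
    dur <- end - start
    if (dur < cfg$min_dur || dur > cfg$max_dur) next
    rows[[k]] <- data.frame(
      start = start, end = end,
      peak_time = zb$t0 + (trough_i - 1L) / fs,
      amplitude = pos_peak_uv - trough_uv,
      intrinsic_freq = 1 / dur, flagged = flagged)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (!length(rows)) return(event_table())
  d <- do.call(rbind, rows)
  ev <- event_table(kind = rep("slow_wave", nrow(d)), start = d$start,
                    end = d$end, peak_time = d$peak_time,
                    amplitude = d$amplitude, intrinsic_freq = d$intrinsic_freq)
  ev$flagged <- d$flagged
  if (!is.null(hypnogram)) ev <- attribute_state(ev, hypnogram)
  ev
}

#' Detect spindles or ripples from the spline envelope
#'
#' The band-filtered z-scored trace is rectified and enveloped
#' ([spline_envelope()]). An event is seeded wherever the envelope crosses
#' the detection threshold and extended outward to the edge-threshold
#' crossings. Events separated by less than `merge_gap` are merged first,
#' then the duration bounds are applied. Amplitude is the peak envelope
#' rescaled to microvolts by the scaling SD; intrinsic frequency is
#' `(number of positive filtered-signal peaks - 1) / duration`; `peak_time`
#' is the envelope maximum.
#'
#' Defaults per kind (see [detection_config()]): spindles 8-16 Hz, 3.5 / 1.5
#' SD, 0.35-4 s, merge 0.5 s; ripples 125-220 Hz, 3.5 / 2 SD, 0.05-0.5 s,
#' merge 0.05 s.
#'
#' @inheritParams detect_slow_waves
#' @param kind `"spindle"` or `"ripple"`.
#' @param cfg a [detection_config()]; defaults to the kind's standard rules.
#' @return an [event_table()].
#' @export
detect_band_events <- function(signal, kind = c("spindle", "ripple"),
                               cfg = NULL, hypnogram = NULL,
                               exclude_artifact = FALSE) {
  kind <- match.arg(kind)
  if (is.null(cfg)) cfg <- detection_config(kind)
  zb <- bandpass_zscore(signal, cfg$band, hypnogram, exclude_artifact)
  env <- spline_envelope(zb)
  fs <- zb$fs; n <- length(env)

  above <- env >= cfg$detect_thresh
  if (!any(above)) return(event_table())
  r <- rle(above)
  seed_end <- cumsum(r$lengths)
  seed_start <- seed_end - r$lengths + 1L
  seeds <- cbind(seed_start[r$values], seed_end[r$values])

  below_edge <- env < cfg$edge_thresh
  # for each seed, walk out to the previous/next sub-edge sample
  idx_below <- which(below_edge)
  starts <- ends <- integer(nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    prev <- idx_below[idx_below < seeds[k, 1L]]
    nxt <- idx_below[idx_below > seeds[k, 2L]]
    starts[k] <- if (length(prev)) max(prev) + 1L else 1L
    ends[k] <- if (length(nxt)) min(nxt) - 1L else n
  }
  iv <- unique(cbind(starts, ends))            # overlapping seeds collapse
  t_start <- zb$t0 + (iv[, 1L] - 1L) / fs
  t_end <- zb$t0 + iv[, 2L] / fs               # half-open: one sample past

  merged <- merge_intervals(t_start, t_end, cfg$merge_gap)
  keep_dur <- (merged[, 2L] - merged[, 1L]) >= cfg$min_dur &
              (merged[, 2L] - merged[, 1L]) <= cfg$max_dur
  merged <- merged[keep_dur, , drop = FALSE]
  if (!nrow(merged)) return(event_table())

  m <- nrow(merged)
  peak_t <- amp <- ifreq <- numeric(m)
  # in a band-limited trace local maxima recur at the carrier rate, so the
  # (peaks - 1) / duration cycle count estimates the intrinsic frequency
  pk_pos <- local_maxima(zb$z)
  for (k in seq_len(m)) {
    i0 <- round((merged[k, 1L] - zb$t0) * fs) + 1L
    i1 <- round((merged[k, 2L] - zb$t0) * fs)
    seg <- env[i0:i1]
    pk <- i0 + which.max(seg) - 1L
    peak_t[k] <- zb$t0 + (pk - 1L) / fs
    amp[k] <- max(seg) * zb$sd
    npk <- sum(pk_pos >= i0 & pk_pos <= i1)
    dur <- merged[k, 2L] - merged[k, 1L]
    ifreq[k] <- max(npk - 1L, 1L) / dur
  }
  ev <- event_table(kind = rep(kind, m), start = merged[, 1L],
                    end = merged[, 2L], peak_time = peak_t,
                    amplitude = amp, intrinsic_freq = ifreq)
  if (!is.null(hypnogram)) ev <- attribute_state(ev, hypnogram)
  ev
}

#' Merge intervals separated by less than a gap
#'
#' Chained single-pass merge on sorted half-open intervals: any two
#' consecutive intervals whose gap is strictly less than `gap` (or which
#' overlap) become one.
#'
#' @param starts,ends numeric vectors.
#' @param gap merge threshold, s.
#' @return two-column matrix `start`, `end`.
#' @export
merge_intervals <- function(starts, ends, gap) {
  if (!length(starts)) return(cbind(start = numeric(0), end = numeric(0)))
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  out_s <- starts[1L]; out_e <- ends[1L]
  k <- 1L
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] - out_e[k] < gap) {
      out_e[k] <- max(out_e[k], ends[i])
    } else {
      k <- k + 1L
      out_s[k] <- starts[i]; out_e[k] <- ends[i]
    }
  }
  cbind(start = out_s, end = out_e)
}

#' Apply merge-then-duration rules to candidate intervals
#'
#' The post-processing applied by [detect_band_events()], exposed for
#' rule-level use: merge gaps below `merge_gap` first, then reject intervals
#' outside `[min_dur, max_dur]`.
#'
#' @param starts,ends candidate interval bounds, s.
#' @param cfg a [detection_config()].
#' @return two-column matrix of surviving intervals.
#' @export
apply_event_rules <- function(starts, ends, cfg) {
  m <- merge_intervals(starts, ends, cfg$merge_gap)
  d <- m[, 2L] - m[, 1L]
  m[d >= cfg$min_dur & d <= cfg$max_dur, , drop = FALSE]
}

#' Attribute a vigilance state to each event
#'
#' Each event is tagged with the label of the epoch containing its
#' `peak_time`; events outside the hypnogram are tagged `"unscored"`.
#'
#' @param events an [event_table()].
#' @param hyp a [hypnogram()].
#' @return the event table with `state` filled; attribute
#'   `state_fractions` holds the per-state proportions.
#' @export
attribute_state <- function(events, hyp) {
  if (nrow(events) == 0L) return(events)
  events$state <- state_at(hyp, events$peak_time)
  frac <- prop.table(table(factor(events$state,
                                  levels = c(VIGILANCE_STATES, "unscored"))))
  attr(events, "state_fractions") <- c(frac)
  events
}

#' Match detected events against ground truth
#'
#' Greedy one-to-one matching by peak-time proximity within a tolerance;
#' reports recall, precision and the matched index pairs.
#'
#' @param detected,truth [event_table()]s (or data frames with `peak_time`).
#' @param tol matching tolerance, s (default 0.25).
#' @return list with `recall`, `precision`, `f1`, `n_matched`, `matches`.
#' @export
match_events <- function(detected, truth, tol = 0.25) {
  nd <- nrow(detected); nt <- nrow(truth)
  if (nd == 0L || nt == 0L)
    return(list(recall = if (nt == 0L) NA_real_ else 0,
                precision = if (nd == 0L) NA_real_ else 0,
                f1 = 0, n_matched = 0L,
                matches = cbind(det = integer(0), truth = integer(0))))
  dmat <- abs(outer(detected$peak_time, truth$peak_time, "-"))
  pairs <- which(dmat <= tol, arr.ind = TRUE)
  if (nrow(pairs)) pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
  used_d <- logical(nd); used_t <- logical(nt)
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    di <- pairs[i, 1L]; ti <- pairs[i, 2L]
    if (!used_d[di] && !used_t[ti]) {
      keep[i] <- TRUE; used_d[di] <- TRUE; used_t[ti] <- TRUE
    }
  }
  nm <- sum(keep)
  rec <- nm / nt; prec <- nm / nd
  list(recall = rec, precision = prec,
       f1 = if (rec + prec > 0) 2 * rec * prec / (rec + prec) else 0,
       n_matched = nm,
       matches = cbind(det = pairs[keep, 1L], truth = pairs[keep, 2L]))
}
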