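#' Vigilance state labels
#'
#' The four labels a hypnogram epoch may take.
#' @export
VIGILANCE_STATES <- c("wake", "NREM", "REM", "artifact")

#' Recording regions
#' @export
REGIONS <- c("PrL", "CA1", "EMG", "other")

#' Oscillation event kinds
#' @export
EVENT_KINDS <- c("slow_wave", "spindle", "ripple")

#' Construct a continuous signal
#'
#' A uniformly sampled LFP/EMG channel in microvolts. All somnoscope times are
#' seconds from recording start (`t0` offsets the first sample) and intervals
#' are half-open `[start, end)`.
#'
#' @param samples numeric vector, microvolts.
#' @param fs sampling rate, Hz (> 0).
#' @param region one of `REGIONS`.
#' @param label free-text channel label.
#' @param t0 time of the first sample, s.
#' @return object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, fs, region = "other", label = region, t0 = 0) {
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  region <- match.arg(region, REGIONS)
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stopf("signal must contain at least one sample")
  if (any(!is.finite(samples)))
    stopf("signal contains %d non-finite samples; flag gaps before constructing",
          sum(!is.finite(samples)))
  structure(list(samples = samples, fs = fs, region = region,
                 label = label, t0 = as.numeric(t0)),
            class = "continuous_signal")
}

#' @export
print.continuous_signal <- function(x, ...) {
  cat(sprintf("<continuous_signal> %s [%s]: %d samples @ %g Hz (%.1f s, t0=%g s)\n",
              x$label, x$region, length(x$samples), x$fs,
              length(x$samples) / x$fs, x$t0))
  invisible(x)
}

#' Duration of a signal or hypnogram in seconds
#' @param x a `continuous_signal` or `hypnogram`.
#' @export
duration <- function(x) UseMethod("duration")

#' @export
duration.continuous_signal <- function(x) length(x$samples) / x$fs

#' @export
duration.hypnogram <- function(x) length(x$labels) * x$epoch_len

# sample times of a continuous signal (left edge convention)
signal_times <- function(x) x$t0 + (seq_along(x$samples) - 1L) / x$fs

#' Crop a signal to a half-open time window
#'
#' @param signal a [continuous_signal()].
#' @param window `c(start, end)`, s, in recording time.
#' @return a [continuous_signal()] with `t0` set to the window start.
#' @export
crop_signal <- function(signal, window) {
  i0 <- max(1L, floor((window[1L] - signal$t0) * signal$fs) + 1L)
  i1 <- min(length(signal$samples),
            ceiling((window[2L] - signal$t0) * signal$fs))
  if (i1 < i0) stopf("window [%g, %g] lies outside the signal",
                     window[1L], window[2L])
  continuous_signal(signal$samples[i0:i1], signal$fs, signal$region,
                    signal$label, t0 = signal$t0 + (i0 - 1L) / signal$fs)
}

#' Construct a hypnogram
#'
#' Epoch-wise vigilance labels on a fixed epoch grid starting at time 0.
#'
#' @param labels character vector of states, each one of `VIGILANCE_STATES`.
#' @param epoch_len epoch length, s (default 4).
#' @return object of class `hypnogram`.
#' @export
hypnogram <- function(labels, epoch_len = 4) {
  labels <- as.character(labels)
  if (length(labels) < 1L) stopf("hypnogram needs at least one epoch")
  bad <- which(!labels %in% VIGILANCE_STATES)
  if (length(bad))
    stopf("unknown vigilance label '%s' at epoch %d", labels[bad[1L]], bad[1L])
  if (!is_scalar_num(epoch_len) || epoch_len <= 0) stopf("epoch_len must be > 0")
  structure(list(labels = labels, epoch_len = epoch_len), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  tab <- table(factor(x$labels, levels = VIGILANCE_STATES))
  cat(sprintf("<hypnogram> %d epochs x %g s (%.0f s): %s\n",
              length(x$labels), x$epoch_len, duration(x),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Vigilance state at given times
#'
#' @param hyp a `hypnogram`.
#' @param times numeric vector, s. Times outside the hypnogram span return
#'   `"unscored"`.
#' @return character vector of labels.
#' @export
state_at <- function(hyp, times) {
  idx <- floor(times / hyp$epoch_len) + 1L
  out <- rep("unscored", length(times))
  ok <- idx >= 1L & idx <= length(hyp$labels) & times >= 0
  out[ok] <- hyp$labels[idx[ok]]
  out
}

# half-open [start, end) spans of epochs in a given state
state_spans <- function(hyp, state) {
  in_state <- hyp$labels %in% state
  if (!any(in_state)) return(cbind(start = numeric(0), end = numeric(0)))
  r <- rle(in_state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = (starts[keep] - 1L) * hyp$epoch_len,
        end = ends[keep] * hyp$epoch_len)
}

#' Construct a spike train
#'
#' @param times strictly increasing spike times, s.
#' @param unit_id unit identifier.
#' @param region `"PrL"` or `"CA1"`.
#' @param spike_width waveform width, microseconds (> 0).
#' @param isolation_distance optional cluster-quality metadata; carried but
#'   never used in analysis.
#' @return object of class `spike_train`.
#' @export
spike_train <- function(times, unit_id, region, spike_width,
                        isolation_distance = NA_real_) {
  region <- match.arg(region, c("PrL", "CA1"))
  times <- as.numeric(times)
  if (length(times) && any(diff(times) <= 0))
    stopf("spike times of unit '%s' must be strictly increasing", unit_id)
  if (!is_scalar_num(spike_width) || spike_width <= 0)
    stopf("spike_width must be > 0 (microseconds)")
  structure(list(times = times, unit_id = as.character(unit_id),
                 region = region, spike_width = spike_width,
                 isolation_distance = isolation_distance),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s [%s]: %d spikes, width %g us\n",
              x$unit_id, x$region, length(x$times), x$spike_width))
  invisible(x)
}

#' Mean firing rate of a spike train
#'
#' @param train a `spike_train`.
#' @param window optional `c(start, end)` window, s (half-open); spikes are
#'   counted in the window and divided by its length. When omitted,
#'   `total_duration` must be given.
#' @param total_duration recording duration, s, used when `window` is `NULL`.
#' @return rate in Hz.
#' @export
mean_fr <- function(train, window = NULL, total_duration = NULL) {
  if (is.null(window)) {
    if (is.null(total_duration)) stopf("need a window or total_duration")
    window <- c(0, total_duration)
  }
  sum(train$times >= window[1L] & train$times < window[2L]) / diff(window)
}

#' Construct an empty oscillation-event table
#'
#' Fixed-schema data frame used by every detector: one row per event with
#' columns kind, start, end, peak_time, amplitude, intrinsic_freq, duration,
#' state. Times are seconds from recording start; intervals half-open.
#'
#' @param ... vectors for the schema columns; omitted columns are filled.
#' @return data.frame with class `event_table`.
#' @export
event_table <- function(...) {
  cols <- list(...)
  schema <- c("kind", "start", "end", "peak_time", "amplitude",
              "intrinsic_freq", "duration", "state")
  n <- if (length(cols)) max(lengths(cols)) else 0L
  out <- lapply(schema, function(nm) {
    if (!is.null(cols[[nm]])) cols[[nm]]
    else if (nm %in% c("kind", "state")) rep(NA_character_, n)
    else rep(NA_real_, n)
  })
  names(out) <- schema
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$start >= df$end)) stopf("event start must precede end")
    df$duration <- df$end - df$start
  }
  class(df) <- c("event_table", "data.frame")
  df
}

#' Session manifest: condition and analysis windows
#'
#' Records the drug condition, injection time and the baseline / post-drug
#' analysis windows (defaults: 5-25 min pre-injection baseline expressed from
#' recording start, and 40-60 min post-injection).
#'
#' @param subject subject identifier.
#' @param condition one of saline, zolpidem, diazepam, THIP, custom.
#' @param injection_time s from recording start.
#' @param baseline_window,post_window `c(start, end)` in s; defaults
#'   `c(300, 1500)` and `injection_time + c(2400, 3600)`.
#' @return object of class `session_manifest`.
#' @export
session_manifest <- function(subject, condition = "custom",
                             injection_time = 1800,
                             baseline_window = c(300, 1500),
                             post_window = injection_time + c(2400, 3600)) {
  condition <- match.arg(condition,
                         c("saline", "zolpidem", "diazepam", "THIP", "custom"))
  if (diff(baseline_window) <= 0 || diff(post_window) <= 0)
    stopf("analysis windows must have positive length")
  if (baseline_window[2L] > post_window[1L] &&
      post_window[2L] > baseline_window[1L])
    stopf("baseline and post windows must not overlap")
  structure(list(subject = as.character(subject), condition = condition,
                 injection_time = injection_time,
                 baseline_window = baseline_window,
                 post_window = post_window),
            class = "session_manifest")
}

#' Per-kind detection configuration
#'
#' Default thresholds and rules for each oscillation kind: band (Hz), detect
#' and edge thresholds (SD units), duration bounds (s), merge gap (s) and,
#' for slow-waves, the minimum trough negativity (microvolts).
#'
#' Defaults: slow-waves 0.5-4 Hz at 3.5 SD with a 50 uV negativity floor;
#' spindles 8-16 Hz, 3.5 SD detect / 1.5 SD edges, 0.35-4 s, 0.5 s merge;
#' ripples 125-220 Hz, 3.5 SD detect / 2 SD edges, 0.05-0.5 s, 0.05 s merge.
#'
#' @param kind one of `EVENT_KINDS`.
#' @param ... overrides of any listed field.
#' @return list of class `detection_config`.
#' @export
detection_config <- function(kind = c("slow_wave", "spindle", "ripple"), ...) {
  kind <- match.arg(kind)
  base <- switch(kind,
    slow_wave = list(band = c(0.5, 4), detect_thresh = 3.5, edge_thresh = 3.5,
                     min_dur = 0, max_dur = Inf, merge_gap = 0,
                     min_negativity = 50),
    spindle   = list(band = c(8, 16), detect_thresh = 3.5, edge_thresh = 1.5,
                     min_dur = 0.35, max_dur = 4, merge_gap = 0.5,
                     min_negativity = NA_real_),
    ripple    = list(band = c(125, 220), detect_thresh = 3.5, edge_thresh = 2,
                     min_dur = 0.05, max_dur = 0.5, merge_gap = 0.05,
                     min_negativity = NA_real_))
  over <- list(...)
  unknown <- setdiff(names(over), names(base))
  if (length(unknown)) stopf("unknown detection_config field '%s'", unknown[1L])
  base[names(over)] <- over
  cfg <- c(list(kind = kind), base)
  if (cfg$band[1L] >= cfg$band[2L]) stopf("band low must be < band high")
  if (cfg$edge_thresh > cfg$detect_thresh)
    stopf("edge_thresh must be <= detect_thresh")
  if (cfg$min_dur >= cfg$max_dur) stopf("min_dur must be < max_dur")
  structure(cfg, class = "detection_config")
}
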