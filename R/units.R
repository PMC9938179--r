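#' Classify a unit as putative pyramidal
#'
#' Pyramidal iff spike width > 200 microseconds AND mean firing rate
#' < 5 Hz; everything else is "other". Vectorised.
#'
#' @param spike_width microseconds.
#' @param mean_fr Hz.
#' @return character vector, `"pyramidal"` or `"other"`.
#' @export
classify_unit <- function(spike_width, mean_fr) {
  ifelse(spike_width > 200 & mean_fr < 5, "pyramidal", "other")
}

#' Unit inclusion criteria
#'
#' `rate_analysis`: mean firing rate over the whole recording > 0.15 Hz.
#' `xcorr`: more than 200 spikes within *each* supplied analysis window
#' (the 20 min baseline and 20 min post windows).
#'
#' @param train a [spike_train()].
#' @param windows list of `c(start, end)` windows, s (for `xcorr`, both the
#'   baseline and post windows; for `rate_analysis` a single recording
#'   span).
#' @param purpose `"rate_analysis"` or `"xcorr"`.
#' @return logical.
#' @export
include_unit <- function(train, windows, purpose = c("rate_analysis", "xcorr")) {
  purpose <- match.arg(purpose)
  if (!is.list(windows)) windows <- list(windows)
  if (!length(train$times)) return(FALSE)
  if (purpose == "rate_analysis") {
    w <- windows[[1L]]
    return(mean_fr(train, w) > 0.15)
  }
  all(vapply(windows, function(w)
    sum(train$times >= w[1L] & train$times < w[2L]) > 200, logical(1L)))
}

#' Bursting index
#'
#' Proportion of interspike intervals strictly shorter than 20 ms.
#'
#' @param train a [spike_train()] or numeric spike-time vector.
#' @param window optional `c(start, end)` restriction, s.
#' @return BI in [0, 1]; `NA` (with a warning) below 2 spikes.
#' @export
bursting_index <- function(train, window = NULL) {
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  if (!is.null(window)) t <- t[t >= window[1L] & t < window[2L]]
  if (length(t) < 2L) {
    warning("fewer than 2 spikes: bursting index undefined")
    return(NA_real_)
  }
  isi <- diff(t)
  sum(isi < 0.020) / length(isi)
}

#' Peri-event time histogram
#'
#' Spike counts around event anchors (slow-wave troughs or ripple envelope
#' maxima), converted to rates (count / (n_anchors * bin)) and z-scored
#' across the bins of the unit's own PETH. Stated analysis settings:
#' slow-waves +/- 500 ms with 5 ms bins, ripples +/- 250 ms with 2 ms bins.
#'
#' @param train a [spike_train()].
#' @param anchors event anchor times, s (>= 1).
#' @param window half-window, s (e.g. 0.5).
#' @param bin_len bin length, s.
#' @return object of class `peth`: `bin_centers` (s, relative), `rate`
#'   (Hz), `z`, `n_events`, `window`, `bin_len`, `flagged` (TRUE when the
#'   rate is constant and z undefined).
#' @export
peth <- function(train, anchors, window = 0.5, bin_len = 0.005) {
  if (!length(anchors)) stopf("need at least one anchor")
  edges <- seq(-window, window, by = bin_len)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  t <- if (inherits(train, "spike_train")) train$times else as.numeric(train)
  for (a in anchors) {
    rel <- t[t >= a - window & t < a + window] - a
    if (length(rel))
      counts <- counts + tabulate(floor((rel + window) / bin_len) + 1L, nb)
  }
  rate <- counts / (length(anchors) * bin_len)
  s <- sd(rate)
  flagged <- !is.finite(s) || s == 0
  z <- if (flagged) rep(NA_real_, nb) else (rate - mean(rate)) / s
  structure(list(bin_centers = edges[-length(edges)] + bin_len / 2,
                 rate = rate, z = z, n_events = length(anchors),
                 window = c(-window, window), bin_len = bin_len,
                 flagged = flagged),
            class = "peth")
}

#' Mean PETH z in a statistic window
#'
#' Mean of the z bins whose centres fall in the closed stat window
#' (+/- 250 ms for slow-waves, +/- 40 ms for ripples).
#'
#' @param p a `peth`.
#' @param stat_window `c(lo, hi)`, s.
#' @return scalar mean z (NA when the PETH was flagged).
#' @export
peth_stat <- function(p, stat_window = c(-0.25, 0.25)) {
  sel <- p$bin_centers >= stat_window[1L] & p$bin_centers <= stat_window[2L]
  if (!any(sel)) stopf("stat window contains no PETH bins")
  mean(p$z[sel])
}

# spike-time differences (b - a) within +/- window, both spikes optionally
# restricted to epochs of the given states
xcorr_counts <- function(ta, tb, window, bin_len) {
  edges <- seq(-window, window, by = bin_len)
  nb <- length(edges) - 1L
  counts <- numeric(nb)
  if (!length(ta) || !length(tb)) return(counts)
  lo <- findInterval(ta - window, tb) + 1L
  hi <- findInterval(ta + window, tb)
  for (i in seq_along(ta)) {
    if (hi[i] < lo[i]) next
    d <- tb[lo[i]:hi[i]] - ta[i]
    d <- d[d >= -window & d < window]
    if (length(d))
      counts <- counts + tabulate(floor((d + window) / bin_len) + 1L, nb)
  }
  counts
}

#' Spike-train cross-correlogram
#'
#' Histogram of pairwise spike-time differences (b - a) on a symmetric lag
#' grid (default +/- 500 ms, 2 ms bins), z-scored across lag bins. With a
#' hypnogram and `restrict`, a difference contributes only when both spikes
#' fall in epochs of the chosen state.
#'
#' @param train_a,train_b [spike_train()]s (distinct units).
#' @param window half-window, s.
#' @param bin_len bin length, s (Methods value 2 ms; 5 ms display binning
#'   also accepted).
#' @param hypnogram optional [hypnogram()].
#' @param restrict optional state label (e.g. `"NREM"`).
#' @return object of class `xcorr`: `lags` (s, bin centres), `counts`,
#'   `z`, `bin_len`, `pair`, `regions`.
#' @export
cross_correlogram <- function(train_a, train_b, window = 0.5, bin_len = 0.002,
                              hypnogram = NULL, restrict = NULL) {
  ta <- train_a$times; tb <- train_b$times
  if (!is.null(restrict)) {
    if (is.null(hypnogram)) stopf("state restriction needs a hypnogram")
    ta <- ta[state_at(hypnogram, ta) %in% restrict]
    tb <- tb[state_at(hypnogram, tb) %in% restrict]
  }
  if (!length(ta) || !length(tb))
    stopf("pair %s/%s has no spikes after restriction",
          train_a$unit_id, train_b$unit_id)
  counts <- xcorr_counts(ta, tb, window, bin_len)
  s <- sd(counts)
  z <- if (!is.finite(s) || s == 0) rep(0, length(counts)) else
    (counts - mean(counts)) / s
  edges <- seq(-window, window, by = bin_len)
  structure(list(lags = edges[-length(edges)] + bin_len / 2, counts = counts,
                 z = z, bin_len = bin_len,
                 pair = c(train_a$unit_id, train_b$unit_id),
                 regions = c(train_a$region, train_b$region)),
            class = "xcorr")
}

#' Cross-correlogram peak statistic
#'
#' Mean z around the cross-correlation peak: +/- 100 ms for within-region
#' pairs (CA1-CA1, PrL-PrL), 0 to +200 ms for PrL-to-CA1 pairs.
#'
#' @param xc an `xcorr`.
#' @param pair_kind `"within_region"` or `"prl_to_ca1"`.
#' @return scalar mean z over the stat window.
#' @export
xcorr_stat <- function(xc, pair_kind = c("within_region", "prl_to_ca1")) {
  pair_kind <- match.arg(pair_kind)
  win <- if (pair_kind == "within_region") c(-0.1, 0.1) else c(0, 0.2)
  sel <- xc$lags >= win[1L] & xc$lags <= win[2L]
  mean(xc$z[sel])
}
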