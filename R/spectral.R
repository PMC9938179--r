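#' Welch power spectral density
#'
#' Mean one-sided periodogram over non-overlapping windows (default 4 s,
#' giving 0.25 Hz bins), Hamming tapered with density normalisation, in
#' uV^2/Hz. With a hypnogram and `restrict`, windows intersecting epochs of
#' any other state (or artifact epochs) are dropped.
#'
#' @param signal a [continuous_signal()].
#' @param window_len window length, s (default 4).
#' @param hypnogram optional [hypnogram()].
#' @param restrict optional state (e.g. `"NREM"`): keep only windows fully in
#'   that state.
#' @return object of class `power_spectrum`: `freqs` (Hz), `power`
#'   (uV^2/Hz), `window_len`, `n_segments`.
#' @export
welch_power <- function(signal, window_len = 4, hypnogram = NULL,
                        restrict = NULL) {
  fs <- signal$fs
  nper <- round(window_len * fs)
  if (length(signal$samples) < nper)
    stopf("signal shorter than one %g s window", window_len)
  nseg <- floor(length(signal$samples) / nper)
  seg_start <- (seq_len(nseg) - 1L) * nper + 1L
  keep <- rep(TRUE, nseg)
  if (!is.null(hypnogram)) {
    for (k in seq_len(nseg)) {
      t0 <- signal$t0 + (seg_start[k] - 1L) / fs
      # states of the epochs this window touches (sample at epoch resolution)
      ts <- seq(t0, t0 + window_len - 1e-9, by = hypnogram$epoch_len / 2)
      st <- unique(state_at(hypnogram, c(ts, t0 + window_len - 1e-9)))
      if (!is.null(restrict)) keep[k] <- all(st %in% restrict)
      else keep[k] <- !any(st == "artifact")
    }
  }
  if (!any(keep)) stopf("no eligible %g s segments after state restriction",
                        window_len)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nper) / (nper + 1))
  norm <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  acc <- numeric(nfreq)
  for (k in which(keep)) {
    x <- signal$samples[seg_start[k]:(seg_start[k] + nper - 1L)]
    X <- fft((x - mean(x)) * w)
    p <- Mod(X[seq_len(nfreq)])^2 / norm
    # one-sided: double everything but DC (and Nyquist when nper even)
    sc <- rep(2, nfreq); sc[1L] <- 1
    if (nper %% 2L == 0L) sc[nfreq] <- 1
    acc <- acc + p * sc
  }
  structure(list(freqs = (seq_len(nfreq) - 1L) / window_len,
                 power = acc / sum(keep), window_len = window_len,
                 n_segments = sum(keep)),
            class = "power_spectrum")
}

#' Mean band power from a spectrum
#' @param spec a `power_spectrum`.
#' @param band `c(low, high)` Hz (closed interval on bin centres).
#' @return mean power density over the band's bins, uV^2/Hz.
#' @export
band_power <- function(spec, band) {
  sel <- spec$freqs >= band[1L] & spec$freqs <= band[2L]
  if (!any(sel)) stopf("no frequency bins inside [%g, %g] Hz", band[1L], band[2L])
  mean(spec$power[sel])
}

#' Slow-wave-activity time course
#'
#' Mean 0.5-4 Hz power per 4 s window, averaged across consecutive bins
#' (default 5 min). Bins with no eligible windows are `NA`, never zero.
#'
#' @param signal a [continuous_signal()].
#' @param bin_len bin length, s (default 300).
#' @param band SWA band, Hz.
#' @param window_len power window, s.
#' @param hypnogram optional; windows in artifact epochs are dropped.
#' @param manifest optional [session_manifest()]; when given, a
#'   `pct_baseline` column expresses each bin as % of the mean SWA of
#'   windows inside the baseline window.
#' @return data.frame with `bin_start`, `bin_mid`, `swa` and optionally
#'   `pct_baseline`.
#' @export
swa_timecourse <- function(signal, bin_len = 300, band = c(0.5, 4),
                           window_len = 4, hypnogram = NULL, manifest = NULL) {
  fs <- signal$fs
  nper <- round(window_len * fs)
  nseg <- floor(length(signal$samples) / nper)
  if (nseg < 1L) stopf("signal shorter than one %g s window", window_len)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nper) / (nper + 1))
  norm <- fs * sum(w^2)
  nfreq <- floor(nper / 2) + 1L
  freqs <- (seq_len(nfreq) - 1L) / window_len
  sel <- freqs >= band[1L] & freqs <= band[2L]
  t_seg <- signal$t0 + (seq_len(nseg) - 1L) * window_len
  swa_seg <- numeric(nseg)
  ok <- rep(TRUE, nseg)
  if (!is.null(hypnogram))
    ok <- state_at(hypnogram, t_seg) != "artifact" &
          state_at(hypnogram, t_seg + window_len - 1e-9) != "artifact"
  for (k in seq_len(nseg)) {
    if (!ok[k]) { swa_seg[k] <- NA_real_; next }
    x <- signal$samples[((k - 1L) * nper + 1L):(k * nper)]
    X <- fft((x - mean(x)) * w)
    p <- Mod(X[seq_len(nfreq)])^2 / norm * 2
    p[1L] <- p[1L] / 2
    swa_seg[k] <- mean(p[sel])
  }
  bin_id <- floor((t_seg - signal$t0) / bin_len)
  out <- do.call(rbind, lapply(sort(unique(bin_id)), function(b) {
    v <- swa_seg[bin_id == b]
    data.frame(bin_start = signal$t0 + b * bin_len,
               bin_mid = signal$t0 + (b + 0.5) * bin_len,
               swa = if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }))
  if (!is.null(manifest)) {
    base_sel <- t_seg >= manifest$baseline_window[1L] &
                t_seg + window_len <= manifest$baseline_window[2L]
    base <- mean(swa_seg[base_sel], na.rm = TRUE)
    out$pct_baseline <- out$swa / base * 100
  }
  out
}

#' Modulation index from phase and amplitude samples
#'
#' Tort's normalised-entropy modulation index: the mean amplitude per phase
#' bin is normalised into a distribution P over `n_bins` bins of (-pi, pi];
#' MI = (log N - H(P)) / log N, in [0, 1] (0 when amplitude is independent
#' of phase, 1 when it concentrates in a single bin).
#'
#' @param phase instantaneous phase samples, radians.
#' @param amp amplitude envelope samples (>= 0), same length.
#' @param n_bins number of phase bins (default 18, i.e. 20 degrees).
#' @return scalar MI in [0, 1].
#' @export
mi_from_phase_amp <- function(phase, amp, n_bins = 18) {
  if (length(phase) != length(amp)) stopf("phase and amp lengths differ")
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  if (sum(amp) <= 0) stopf("total amplitude is zero; MI undefined")
  b <- floor((phase + pi) / (2 * pi) * n_bins) %% n_bins + 1L
  cnt <- tabulate(b, n_bins)
  tot <- numeric(n_bins)
  rs <- rowsum(amp, b)
  tot[as.integer(rownames(rs))] <- rs[, 1L]
  mean_amp <- ifelse(cnt > 0, tot / pmax(cnt, 1L), 0)
  p <- mean_amp / sum(mean_amp)
  h <- -sum(ifelse(p > 0, p * log(p), 0))
  (log(n_bins) - h) / log(n_bins)
}

#' Modulation index of two band-filtered signals
#'
#' Instantaneous phase of the low-frequency (modulator) signal and amplitude
#' envelope of the high-frequency (modulated) signal are taken from their
#' analytic signals, then passed to [mi_from_phase_amp()].
#'
#' @param phase_sig,amp_sig `zscored_band` objects or numeric vectors
#'   (already band-filtered), same length and fs.
#' @param n_bins phase bins (default 18).
#' @param mask optional logical vector selecting the samples entering the MI.
#' @return scalar MI in [0, 1].
#' @export
modulation_index <- function(phase_sig, amp_sig, n_bins = 18, mask = NULL) {
  xp <- if (inherits(phase_sig, "zscored_band")) phase_sig$z else as.numeric(phase_sig)
  xa <- if (inherits(amp_sig, "zscored_band")) amp_sig$z else as.numeric(amp_sig)
  if (length(xp) != length(xa)) stopf("signals must share length")
  ph <- Arg(analytic_signal(xp))
  am <- Mod(analytic_signal(xa))
  if (!is.null(mask)) { ph <- ph[mask]; am <- am[mask] }
  mi_from_phase_amp(ph, am, n_bins)
}

# NREM-restriction mask: samples in runs of `state` epochs at least min_run
# long, trimmed by one cycle of the lowest phase frequency at each run edge
pac_mask <- function(n, fs, t0, hypnogram, state = "NREM",
                     min_run = 8, trim = NULL) {
  if (is.null(hypnogram)) return(rep(TRUE, n))
  spans <- state_spans(hypnogram, state)
  keep <- rep(FALSE, n)
  for (i in seq_len(nrow(spans))) {
    len <- spans[i, 2L] - spans[i, 1L]
    if (len < min_run) next
    a <- spans[i, 1L] + (trim %||% 0)
    b <- spans[i, 2L] - (trim %||% 0)
    if (b <= a) next
    i0 <- max(1L, floor((a - t0) * fs) + 1L)
    i1 <- min(n, ceiling((b - t0) * fs))
    if (i1 >= i0) keep[i0:i1] <- TRUE
  }
  keep
}

#' Phase-amplitude comodulogram
#'
#' MI on a grid of (phase band, amplitude band) cells: phase bands 0.5 Hz
#' wide stepped 0.5 Hz across `phase_range`, amplitude bands 2 Hz wide
#' stepped 1 Hz across `amp_range` (all configurable). Coupling is an NREM
#' phenomenon, so with a hypnogram the MI uses only samples inside NREM runs
#' of at least `min_run` s, trimmed by one cycle of the lowest phase
#' frequency at run edges. To keep the grid cheap the trace is decimated
#' (after zero-phase low-pass filtering) to `fs_pac` before phase/amplitude
#' extraction; all grid bands must sit well below `fs_pac / 2`.
#'
#' @param signal a [continuous_signal()].
#' @param phase_range,amp_range `c(low, high)` Hz.
#' @param phase_width,phase_step,amp_width,amp_step grid geometry, Hz.
#' @param n_bins phase bins for the MI.
#' @param hypnogram optional [hypnogram()] for NREM restriction.
#' @param min_run minimum NREM run length, s.
#' @param fs_pac working sampling rate, Hz (default 100).
#' @return object of class `comodulogram`: `phase_bands`, `amp_bands`
#'   (two-column matrices), `mi` (phase x amp matrix).
#' @export
comodulogram <- function(signal, phase_range = c(0.5, 4), amp_range = c(8, 20),
                         phase_width = 0.5, phase_step = 0.5,
                         amp_width = 2, amp_step = 1, n_bins = 18,
                         hypnogram = NULL, min_run = 8, fs_pac = 100) {
  stopifnot(amp_range[2L] < fs_pac / 2)
  dec <- max(1L, floor(signal$fs / fs_pac))
  sig <- signal
  if (dec > 1L) {
    # boxcar-average decimation: the sinc null sits at the new sampling rate
    # and the narrow analysis bands (<= 20 Hz) reject residual alias energy
    n_use <- (length(signal$samples) %/% dec) * dec
    y <- colMeans(matrix(signal$samples[seq_len(n_use)], nrow = dec))
    sig <- continuous_signal(y, fs = signal$fs / dec, region = signal$region,
                             label = signal$label, t0 = signal$t0)
  }
  p_lo <- seq(phase_range[1L], phase_range[2L] - phase_width, by = phase_step)
  a_lo <- seq(amp_range[1L], amp_range[2L] - amp_width, by = amp_step)
  phase_bands <- cbind(low = p_lo, high = p_lo + phase_width)
  amp_bands <- cbind(low = a_lo, high = a_lo + amp_width)

  mask <- pac_mask(length(sig$samples), sig$fs, sig$t0, hypnogram,
                   min_run = min_run, trim = 1 / phase_range[1L])
  if (!any(mask)) stopf("no NREM samples available for PAC")

  phases <- lapply(seq_len(nrow(phase_bands)), function(i)
    Arg(analytic_signal(bandpass_zscore(sig, phase_bands[i, ])$z))[mask])
  amps <- lapply(seq_len(nrow(amp_bands)), function(j)
    Mod(analytic_signal(bandpass_zscore(sig, amp_bands[j, ])$z))[mask])

  mi <- matrix(0, nrow(phase_bands), nrow(amp_bands))
  for (i in seq_len(nrow(phase_bands)))
    for (j in seq_len(nrow(amp_bands)))
      mi[i, j] <- mi_from_phase_amp(phases[[i]], amps[[j]], n_bins)
  structure(list(phase_bands = phase_bands, amp_bands = amp_bands, mi = mi),
            class = "comodulogram")
}

# cells of a comodulogram whose bands are contained in the given windows
comod_window_cells <- function(cm, phase_win, amp_win) {
  pi_sel <- cm$phase_bands[, 1L] >= phase_win[1L] - 1e-9 &
            cm$phase_bands[, 2L] <= phase_win[2L] + 1e-9
  ai_sel <- cm$amp_bands[, 1L] >= amp_win[1L] - 1e-9 &
            cm$amp_bands[, 2L] <= amp_win[2L] + 1e-9
  if (!any(pi_sel) || !any(ai_sel))
    stopf("window [%g,%g] x [%g,%g] Hz contains no comodulogram cells",
          phase_win[1L], phase_win[2L], amp_win[1L], amp_win[2L])
  list(phase = which(pi_sel), amp = which(ai_sel))
}

#' Maximal in-window MI
#' @param cm a `comodulogram`.
#' @param phase_win,amp_win windows, Hz (defaults 0.5-1.5 and 10-16).
#' @return maximum MI over cells whose bands lie inside both windows.
#' @export
pac_max <- function(cm, phase_win = c(0.5, 1.5), amp_win = c(10, 16)) {
  sel <- comod_window_cells(cm, phase_win, amp_win)
  max(cm$mi[sel$phase, sel$amp])
}

#' Pre/post phase-amplitude coupling for one recording
#'
#' Crops the signal to the manifest's baseline and post windows, computes a
#' comodulogram on each (NREM-restricted via the hypnogram) and extracts
#' the maximal in-window MI and its change.
#'
#' @param signal a [continuous_signal()] (cortical channel).
#' @param hypnogram a [hypnogram()].
#' @param manifest a [session_manifest()].
#' @param phase_win,amp_win extraction windows, Hz.
#' @param ... passed to [comodulogram()].
#' @return list: `pre`, `post` (`comodulogram`s), `mi_pre`, `mi_post`,
#'   `change`.
#' @export
pac_windows <- function(signal, hypnogram, manifest,
                        phase_win = c(0.5, 1.5), amp_win = c(10, 16), ...) {
  pre <- comodulogram(crop_signal(signal, manifest$baseline_window),
                      hypnogram = hypnogram, ...)
  post <- comodulogram(crop_signal(signal, manifest$post_window),
                       hypnogram = hypnogram, ...)
  list(pre = pre, post = post,
       mi_pre = pac_max(pre, phase_win, amp_win),
       mi_post = pac_max(post, phase_win, amp_win),
       change = pac_change(pre, post, phase_win, amp_win))
}

#' Change in phase-amplitude coupling
#'
#' The maximal MI inside the slow-wave x spindle window (default 0.5-1.5 Hz
#' phase, 10-16 Hz amplitude) is extracted from the pre- and post-injection
#' comodulograms and their difference (post - pre) returned, in raw MI units.
#'
#' @param pre,post `comodulogram`s on identical grids.
#' @param phase_win,amp_win extraction windows, Hz.
#' @return scalar MI(post) - MI(pre).
#' @export
pac_change <- function(pre, post, phase_win = c(0.5, 1.5),
                       amp_win = c(10, 16)) {
  if (!isTRUE(all.equal(pre$phase_bands, post$phase_bands)) ||
      !isTRUE(all.equal(pre$amp_bands, post$amp_bands)))
    stopf("pre and post comodulograms must share the same grid")
  pac_max(post, phase_win, amp_win) - pac_max(pre, phase_win, amp_win)
}
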