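# Minimal European Data Format (EDF) support: continuous multi-channel
# recordings, 16-bit samples with physical scaling, 1-second data records.
# Covers the plain-EDF subset needed for LFP/EMG exchange; EDF+ annotations
# are not parsed. Physical dimensions uV and mV are accepted (mV scaled by
# 1000 into uV); anything else is a hard error rather than a silent guess.

edf_pad <- function(x, width) {
  x <- substr(x, 1L, width)
  paste0(x, strrep(" ", width - nchar(x)))
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 6, width = 1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 3, width = 1)
  if (nchar(s) > width) stopf("value %g does not fit an EDF %d-char field", x, width)
  edf_pad(s, width)
}

#' Write signals to an EDF file
#'
#' Signals may have different sampling rates but must share the same duration
#' and an integer number of samples per second. Samples are quantised to the
#' 16-bit digital range over each channel's observed physical range, so
#' round-trips are exact only to that quantisation step. If the duration is
#' not a whole number of seconds the last record is padded (the true sample
#' count is recorded and honoured by [read_edf()]).
#'
#' @param signals list of [continuous_signal()]s.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path) {
  if (inherits(signals, "continuous_signal")) signals <- list(signals)
  ns <- length(signals)
  fs <- vapply(signals, `[[`, numeric(1L), "fs")
  if (any(fs != round(fs))) stopf("EDF writer requires integer sampling rates")
  n <- vapply(signals, function(s) length(s$samples), integer(1L))
  n_rec <- max(ceiling(n / fs))

  phys_min <- phys_max <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- signals[[i]]$samples
    lo <- min(x); hi <- max(x)
    if (lo == hi) { lo <- lo - 1; hi <- hi + 1 }
    phys_min[i] <- edf_num(lo, 8L); phys_max[i] <- edf_num(hi, 8L)
    # quantise against the values as written, so read-back is consistent
    plo <- as.numeric(phys_min[i]); phi <- as.numeric(phys_max[i])
    d <- round((x - plo) / (phi - plo) * 65535 - 32768)
    d <- pmin(pmax(d, -32768), 32767)
    pad <- n_rec * fs[i] - n[i]
    if (pad > 0) d <- c(d, rep(d[length(d)], pad))
    dig[[i]] <- as.integer(d)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + ns * 256L
  writeChar(paste0(
    edf_pad("0", 8L), edf_pad("X X X X", 80L),
    edf_pad("Startdate 01-JAN-2000 X X X", 80L),
    "01.01.00", "00.00.00",
    edf_pad(as.character(hdr_bytes), 8L), edf_pad("", 44L),
    edf_pad(as.character(n_rec), 8L), edf_pad("1", 8L),
    edf_pad(as.character(ns), 4L)), con, eos = NULL)
  writeChar(paste0(vapply(signals, function(s) edf_pad(s$label, 16L), character(1L)),
                   collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)                    # transducer
  writeChar(paste0(rep(edf_pad("uV", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(phys_min, collapse = ""), con, eos = NULL)
  writeChar(paste0(phys_max, collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(edf_pad("-32768", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(paste0(rep(edf_pad("32767", 8L), ns), collapse = ""), con, eos = NULL)
  writeChar(strrep(" ", 80L * ns), con, eos = NULL)                    # prefiltering
  writeChar(paste0(vapply(fs, function(f) edf_pad(as.character(f), 8L),
                          character(1L)), collapse = ""), con, eos = NULL)
  # reserved: stash region and true sample count for lossless trimming
  writeChar(paste0(vapply(seq_len(ns), function(i)
    edf_pad(sprintf("R=%s;N=%d", signals[[i]]$region, n[i]), 32L),
    character(1L)), collapse = ""), con, eos = NULL)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * fs[i] + 1L):(r * fs[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path EDF file.
#' @param channel channel index or label.
#' @return a [continuous_signal()] in microvolts.
#' @export
read_edf <- function(path, channel = 1L) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8L); rd(80L); rd(80L); rd(8L); rd(8L)
  rd(8L)                       # header bytes
  rd(44L)
  n_rec <- as.integer(rd(8L))
  rec_dur <- as.numeric(rd(8L))
  ns <- as.integer(rd(4L))

  labels <- vapply(seq_len(ns), function(i) rd(16L), character(1L))
  vapply(seq_len(ns), function(i) rd(80L), character(1L))
  dims <- vapply(seq_len(ns), function(i) rd(8L), character(1L))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  vapply(seq_len(ns), function(i) rd(80L), character(1L))
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8L), character(1L)))
  reserved <- vapply(seq_len(ns), function(i) rd(32L), character(1L))

  if (is.character(channel)) {
    channel <- match(channel, labels)
    if (is.na(channel)) stopf("no EDF channel labelled '%s'", channel)
  }
  ci <- as.integer(channel)
  if (ci < 1L || ci > ns) stopf("EDF channel index out of range")

  raw_all <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, "integer", n = spr[i], size = 2L,
                      signed = TRUE, endian = "little")
      if (i == ci) raw_all[[r]] <- vals
    }
  }
  d <- unlist(raw_all)
  scale <- unit_scale_to_uv(dims[ci])
  x <- (d - dmin_[ci]) / (dmax_[ci] - dmin_[ci]) * (pmax_[ci] - pmin_[ci]) + pmin_[ci]
  x <- x * scale

  region <- "other"; n_true <- length(x)
  if (nzchar(reserved[ci])) {
    m <- regmatches(reserved[ci], regexec("R=([A-Za-z]+);N=([0-9]+)", reserved[ci]))[[1L]]
    if (length(m) == 3L) {
      if (m[2L] %in% REGIONS) region <- m[2L]
      n_true <- as.integer(m[3L])
    }
  }
  fs <- spr[ci] / rec_dur
  continuous_signal(x[seq_len(min(n_true, length(x)))], fs = fs,
                    region = region, label = labels[ci])
}
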