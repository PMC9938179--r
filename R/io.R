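#' Read a continuous signal from file
#'
#' Supported formats: `edf` (16-bit European Data Format), `csv` (one `value`
#' column with `# key=value` header lines carrying fs/unit/region/label/t0),
#' and `bin` (little-endian float64 with a JSON-ish `.meta` sidecar written by
#' [write_continuous()]). Samples are returned in microvolts; files declaring
#' mV are scaled by 1000, any other unit without a scale factor is an error.
#' A missing sampling rate is a hard error, never guessed.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"edf"`, `"csv"`, `"bin"`.
#' @param channel for EDF: channel label or index (default 1).
#' @return a [continuous_signal()].
#' @export
read_continuous <- function(path, format = c("auto", "edf", "csv", "bin"),
                            channel = 1L) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", bin = "bin",
                     stopf("cannot infer format from extension '%s'", ext))
  }
  switch(format,
         edf = read_edf(path, channel = channel),
         csv = read_continuous_csv(path),
         bin = read_continuous_bin(path))
}

#' Write a continuous signal to file
#'
#' @param signal a [continuous_signal()].
#' @param path destination; extension selects the format when `format="auto"`.
#' @param format see [read_continuous()].
#' @return `path`, invisibly.
#' @export
write_continuous <- function(signal, path,
                             format = c("auto", "edf", "csv", "bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, edf = "edf", csv = "csv", bin = "bin",
                     stopf("cannot infer format from extension '%s'", ext))
  }
  switch(format,
         edf = write_edf(list(signal), path),
         csv = write_continuous_csv(signal, path),
         bin = write_continuous_bin(signal, path))
  invisible(path)
}

unit_scale_to_uv <- function(unit) {
  switch(tolower(trimws(unit)),
         "uv" = 1, "µv" = 1, "mv" = 1000,
         stopf("unit '%s' has no known scale to microvolts", unit))
}

read_continuous_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) meta[[trimws(kv[1L])]] <- trimws(kv[2L])
  }
  if (is.null(meta$fs)) stopf("csv signal '%s' declares no fs", path)
  body <- lines[!grepl("^#", lines)]
  dat <- read.csv(text = paste(body, collapse = "\n"))
  scale <- unit_scale_to_uv(meta$unit %||% "uV")
  continuous_signal(dat$value * scale, fs = as.numeric(meta$fs),
                    region = meta$region %||% "other",
                    label = meta$label %||% basename(path),
                    t0 = as.numeric(meta$t0 %||% 0))
}

write_continuous_csv <- function(signal, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs=%.10g", signal$fs),
               "# unit=uV",
               sprintf("# region=%s", signal$region),
               sprintf("# label=%s", signal$label),
               sprintf("# t0=%.10g", signal$t0),
               "value"), con)
  writeLines(formatC(signal$samples, format = "g", digits = 10), con)
}

read_continuous_bin <- function(path) {
  meta_path <- paste0(path, ".meta")
  if (!file.exists(meta_path)) stopf("binary signal '%s' lacks a .meta sidecar", path)
  meta <- yaml::read_yaml(meta_path)
  if (is.null(meta$fs)) stopf("sidecar of '%s' declares no fs", path)
  n <- file.info(path)$size / 8
  x <- readBin(path, "double", n = n, size = 8, endian = "little")
  scale <- unit_scale_to_uv(meta$unit %||% "uV")
  continuous_signal(x * scale, fs = as.numeric(meta$fs),
                    region = meta$region %||% "other",
                    label = meta$label %||% basename(path),
                    t0 = as.numeric(meta$t0 %||% 0))
}

write_continuous_bin <- function(signal, path) {
  writeBin(signal$samples, path, size = 8, endian = "little")
  yaml::write_yaml(list(fs = signal$fs, unit = "uV", region = signal$region,
                        label = signal$label, t0 = signal$t0),
                   paste0(path, ".meta"))
}

#' Read a hypnogram from CSV
#'
#' Expected columns `epoch_index,label` (0-based contiguous indices); an
#' optional `# epoch_len=<s>` header line sets the epoch length (default 4 s).
#' Unknown labels raise an error naming the offending epoch.
#'
#' @param path CSV file.
#' @param epoch_len fallback epoch length, s.
#' @return a [hypnogram()].
#' @export
read_hypnogram <- function(path, epoch_len = 4) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L && trimws(kv[1L]) == "epoch_len")
      epoch_len <- as.numeric(kv[2L])
  }
  dat <- read.csv(text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
                  stringsAsFactors = FALSE)
  dat <- dat[order(dat$epoch_index), , drop = FALSE]
  hypnogram(dat$label, epoch_len = epoch_len)
}

#' @rdname read_hypnogram
#' @param hyp a [hypnogram()] to write.
#' @export
write_hypnogram <- function(hyp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epoch_len=%g", hyp$epoch_len), con)
  write.csv(data.frame(epoch_index = seq_along(hyp$labels) - 1L,
                       label = hyp$labels),
            con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write oscillation-event tables
#'
#' Plain CSV with the fixed schema kind, start, end, peak_time, amplitude,
#' intrinsic_freq, duration, state (times in s, written with 6 decimal
#' places; half-open BED-like intervals).
#'
#' @param path CSV file.
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(kind = "character", state = "character"))
  if (nrow(dat) == 0L) return(event_table())
  do.call(event_table, as.list(dat))
}

#' @rdname read_events
#' @param events an [event_table()].
#' @export
write_events <- function(events, path) {
  out <- as.data.frame(events)
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write spike trains
#'
#' CSV with columns `unit_id,region,spike_width_us,time_s` (one row per
#' spike; width and region repeated within a unit).
#'
#' @param path CSV file.
#' @return list of [spike_train()] objects.
#' @export
read_spike_trains <- function(path) {
  dat <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(dat, dat$unit_id), function(d) {
    spike_train(sort(d$time_s), unit_id = d$unit_id[1L],
                region = d$region[1L], spike_width = d$spike_width_us[1L])
  })
}

#' @rdname read_spike_trains
#' @param trains list of [spike_train()] objects.
#' @export
write_spike_trains <- function(trains, path) {
  rows <- lapply(trains, function(tr) {
    if (!length(tr$times)) return(NULL)
    data.frame(unit_id = tr$unit_id, region = tr$region,
               spike_width_us = tr$spike_width,
               time_s = sprintf("%.6f", tr$times))
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a session manifest (YAML)
#' @param path YAML file.
#' @return a [session_manifest()].
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  session_manifest(subject = m$subject, condition = m$condition,
                   injection_time = m$injection_time,
                   baseline_window = as.numeric(m$baseline_window),
                   post_window = as.numeric(m$post_window))
}

#' @rdname read_manifest
#' @param manifest a [session_manifest()].
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}

#' Read / write detection configuration (YAML)
#'
#' One file carries every threshold for all three detectors so that the
#' numbers in use are auditable in one place.
#'
#' @param path YAML file.
#' @return named list of [detection_config()] objects.
#' @export
read_detection_config <- function(path) {
  y <- yaml::read_yaml(path)
  out <- lapply(names(y), function(kind) {
    args <- y[[kind]]
    args$band <- as.numeric(args$band)
    do.call(detection_config, c(list(kind = kind), args))
  })
  names(out) <- names(y)
  out
}

#' @rdname read_detection_config
#' @param configs named list of [detection_config()]s (default: all defaults).
#' @export
write_detection_config <- function(path, configs = NULL) {
  if (is.null(configs))
    configs <- lapply(setNames(EVENT_KINDS, EVENT_KINDS), detection_config)
  y <- lapply(configs, function(cfg) {
    cfg <- unclass(cfg)
    cfg$kind <- NULL
    cfg$max_dur <- if (is.finite(cfg$max_dur)) cfg$max_dur else 1e9
    cfg
  })
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @importFrom stats setNames
NULL
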