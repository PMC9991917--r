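#' Multichannel recording container
#'
#' A `recording` holds a samples-by-channels matrix of extracellular voltage
#' together with its sampling rate and channel metadata. Amplitudes are kept
#' in microvolts internally; I/O routines convert on the way in and out.
#'
#' @param data Numeric matrix, samples in rows, channels in columns. A plain
#'   vector is treated as a single channel.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_ids Character vector of unique channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param t0 Recording start time in seconds (default 0).
#' @param units Amplitude unit label, default `"uV"`.
#'
#' @return An object of class `recording` with fields `data`, `fs`,
#'   `channel_ids`, `t0`, `units`.
#' @examples
#' rec <- recording(cbind(sin(1:100), cos(1:100)), fs = 100)
#' n_channels(rec)
#' @export
recording <- function(data, fs, channel_ids = NULL, t0 = 0, units = "uV") {
  if (is.vector(data)) data <- matrix(data, ncol = 1)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    stop_neurowire("fs must be a positive finite scalar", "bad_fs")
  }
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(ncol(data)))
  channel_ids <- as.character(channel_ids)
  if (length(channel_ids) != ncol(data)) {
    stop_neurowire("channel_ids length must equal number of channels",
                   "channel_mismatch")
  }
  if (anyDuplicated(channel_ids)) {
    stop_neurowire("channel_ids must be unique", "channel_mismatch")
  }
  colnames(data) <- channel_ids
  structure(
    list(data = data, fs = as.numeric(fs), channel_ids = channel_ids,
         t0 = as.numeric(t0), units = units),
    class = "recording"
  )
}

stop_neurowire <- function(msg, kind, ...) {
  stop(structure(
    class = c(paste0("neurowire_error_", kind), "neurowire_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %d channels x %d samples @ %g Hz (%.3f s), unit %s\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs, x$units))
  invisible(x)
}

#' @rdname recording
#' @param rec,x A `recording`.
#' @export
n_channels <- function(rec) ncol(rec$data)

#' @rdname recording
#' @export
n_samples <- function(rec) nrow(rec$data)

#' @rdname recording
#' @export
duration_s <- function(rec) nrow(rec$data) / rec$fs

#' Sample times of a recording
#' @param rec A `recording`.
#' @return Numeric vector of times in seconds (`t0` + 0-based index / fs).
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(nrow(rec$data)) - 1) / rec$fs

#' @export
as_tibble.recording <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$data))
  out <- tibble::add_column(out, time_s = rec_times(x), .before = 1)
  out
}

#' Tidy a recording into long format
#'
#' @param x A `recording`.
#' @param ... Unused.
#' @return A tibble with columns `time_s`, `channel`, `value`.
#' @export
tidy.recording <- function(x, ...) {
  tidyr::pivot_longer(as_tibble.recording(x), -"time_s",
                      names_to = "channel", values_to = "value")
}

#' Plot a recording as stacked traces
#' @param object A `recording`.
#' @param ... Unused.
#' @export
autoplot.recording <- function(object, ...) {
  df <- tidy.recording(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.25) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time (s)", y = object$units)
}

#' Write a recording as raw float32 plus JSON sidecar
#'
#' Samples are stored channel-interleaved (sample-major) as little-endian
#' IEEE-754 float32. A sidecar `<path>.json` records `fs`, `n_channels`,
#' `channel_ids`, `unit` and `t0`.
#'
#' @param rec A `recording`.
#' @param path Output path for the binary payload.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  # interleaved: sample 1 all channels, sample 2 all channels, ...
  writeBin(as.vector(t(rec$data)), con, size = 4, endian = "little")
  meta <- list(fs = rec$fs, n_channels = ncol(rec$data),
               n_samples = nrow(rec$data),
               channel_ids = rec$channel_ids, unit = rec$units, t0 = rec$t0)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording from disk
#'
#' Supports the package's raw float32 + JSON sidecar container and 16-bit
#' EDF files. raw_f32 round-trips bit-exactly through [write_recording()];
#' EDF is exact to the format's 16-bit quantization.
#'
#' @param path Path to the binary payload (raw_f32) or `.edf` file.
#' @param format `"raw_f32"` or `"edf"`.
#' @return A [recording()].
#' @export
read_recording <- function(path, format = c("raw_f32", "edf")) {
  format <- match.arg(format)
  if (format == "edf") return(read_edf(path))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop_neurowire(sprintf("missing sidecar '%s'", sidecar), "missing_sidecar")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  n_bytes <- file.size(path)
  n_vals <- n_bytes / 4
  nch <- as.integer(meta$n_channels)
  if (n_vals %% nch != 0) {
    stop_neurowire(sprintf(
      "file holds %d values, not divisible by %d declared channels",
      n_vals, nch), "channel_mismatch")
  }
  if (!is.null(meta$n_samples) && n_vals != nch * meta$n_samples) {
    stop_neurowire(sprintf(
      "file holds %d values but sidecar declares %d channels x %d samples",
      n_vals, nch, meta$n_samples), "channel_mismatch")
  }
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- readBin(con, "double", n = n_vals, size = 4, endian = "little")
  if (length(meta$channel_ids) != nch) {
    stop_neurowire("sidecar channel_ids disagree with n_channels",
                   "channel_mismatch")
  }
  recording(matrix(vals, ncol = nch, byrow = TRUE), fs = meta$fs,
            channel_ids = meta$channel_ids, t0 = meta$t0 %||% 0,
            units = meta$unit %||% "uV")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- minimal EDF (16-bit) support -----------------------------------------
# Header: 256 ASCII bytes + 256 per signal; data records of int16 LE samples.
# One data record per second is written; physical scaling per the header's
# physical/digital min/max fields.

pad_field <- function(x, width) {
  s <- substr(format(x, width = width), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording as a 16-bit EDF file
#'
#' Minimal EDF writer used for interchange and fixtures. Values are scaled
#' to the int16 range per channel; the round-trip through [read_recording()]
#' is exact to that quantization.
#'
#' @param rec A [recording()]; `fs` must be a positive integer (EDF stores an
#'   integer number of samples per 1-s data record).
#' @param path Output `.edf` path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "recording"))
  fs <- rec$fs
  if (fs != round(fs)) {
    stop_neurowire("EDF writer needs an integer sampling rate", "format")
  }
  nch <- ncol(rec$data)
  n_rec <- ceiling(nrow(rec$data) / fs)
  n_pad <- n_rec * fs - nrow(rec$data)
  data <- rbind(rec$data, matrix(0, n_pad, nch))
  phys_min <- apply(data, 2, min)
  phys_max <- apply(data, 2, max)
  flat <- phys_max <= phys_min
  phys_max[flat] <- phys_min[flat] + 1
  dig_min <- -32768
  dig_max <- 32767
  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  digital <- round(sweep(sweep(data, 2, phys_min), 2, scale, `*`)) + dig_min
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),                        # version
    pad_field("X X X X", 80),                 # patient id (anonymous)
    pad_field("Startdate X", 80),             # recording id
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + nch), 8),            # header bytes
    pad_field("", 44),
    pad_field(n_rec, 8),
    pad_field("1", 8),                        # record duration (s)
    pad_field(nch, 4)
  )
  writeChar(hdr, con, eos = NULL)
  per_sig <- function(vals, width) {
    writeChar(paste0(vapply(vals, pad_field, "", width = width),
                     collapse = ""), con, eos = NULL)
  }
  per_sig(rec$channel_ids, 16)
  per_sig(rep("", nch), 80)                   # transducer
  per_sig(rep(rec$units, nch), 8)
  per_sig(sprintf("%.8g", phys_min), 8)
  per_sig(sprintf("%.8g", phys_max), 8)
  per_sig(rep(dig_min, nch), 8)
  per_sig(rep(dig_max, nch), 8)
  per_sig(rep("", nch), 80)                   # prefiltering
  per_sig(rep(fs, nch), 8)                    # samples per record
  per_sig(rep("", nch), 32)                   # reserved
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    # EDF records are signal-by-signal (all samples of signal 1, then 2, ...)
    writeBin(as.integer(digital[idx, ]), con, size = 2, endian = "little")
  }
  invisible(path)
}

read_edf <- function(path) {
  if (!file.exists(path)) stop_neurowire("EDF file not found", "format")
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  if (is.na(nch) || nch < 1) stop_neurowire("unreadable EDF header", "format")
  sig <- function(width) {
    vapply(seq_len(nch), function(i) trimws(rd(width)), "")
  }
  labels <- sig(16); sig(80); units <- sig(8)
  phys_min <- as.numeric(sig(8)); phys_max <- as.numeric(sig(8))
  dig_min <- as.numeric(sig(8)); dig_max <- as.numeric(sig(8))
  sig(80)
  spr <- as.integer(sig(8))
  sig(32)
  seek(con, hdr_bytes)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    rec_vals <- lapply(seq_len(nch), function(i) {
      readBin(con, "integer", n = spr[i], size = 2, endian = "little")
    })
    chunks[[r]] <- rec_vals
  }
  phys <- lapply(seq_len(nch), function(i) {
    dig <- unlist(lapply(chunks, `[[`, i))
    phys_min[i] + (dig - dig_min[i]) *
      (phys_max[i] - phys_min[i]) / (dig_max[i] - dig_min[i])
  })
  if (length(unique(vapply(phys, length, 0L))) != 1) {
    stop_neurowire("EDF signals of unequal length unsupported",
                   "channel_mismatch")
  }
  fs <- spr[1] / rec_dur
  recording(do.call(cbind, phys), fs = fs, channel_ids = make.unique(labels),
            units = units[1])
}

# ---- event tables ----------------------------------------------------------

#' Construct or validate an event stream
#'
#' Events are stored as a tibble with columns `time_s`, `kind` (one of
#' `word_onset`, `crossing_start`, `crossing_end`, `trigger`, `led_sync`)
#' and an optional `label` column carrying per-event payload (for word
#' onsets, a logical remembered flag).
#'
#' @param time_s Event times in seconds (non-decreasing).
#' @param kind Character vector of event kinds.
#' @param label Optional payload vector.
#' @return A tibble of class `event_stream`.
#' @export
event_stream <- function(time_s, kind, label = NA) {
  kinds <- c("word_onset", "crossing_start", "crossing_end", "trigger",
             "led_sync")
  if (!all(kind %in% kinds)) {
    stop_neurowire(sprintf("unknown event kind(s): %s",
                           paste(setdiff(kind, kinds), collapse = ", ")),
                   "bad_events")
  }
  if (is.unsorted(time_s)) {
    stop_neurowire("event times must be non-decreasing", "bad_events")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        kind = as.character(kind), label = label)
  class(out) <- c("event_stream", class(out))
  out
}

#' Read / write event tables as CSV
#'
#' @param path CSV path with header columns `time_s`, `kind`, `label`.
#' @return [read_events()] returns an `event_stream` tibble.
#' @export
read_events <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  event_stream(df$time_s, df$kind, if ("label" %in% names(df)) df$label else NA)
}

#' @rdname read_events
#' @param events An `event_stream`.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events, path)
  invisible(path)
}
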