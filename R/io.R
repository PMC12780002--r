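#' @keywords internal
"_PACKAGE"

FORMAT_VERSION <- 1L

#' Construct a multichannel MEA recording
#'
#' A recording holds raw integer sample counts (channels x time) together
#' with the metadata needed to interpret them physically: sampling rate,
#' microvolt scale factor, and electrode geometry. Counts convert to
#' microvolts by a pure scale (`uv_per_count`); the conversion is lossless
#' in both directions.
#'
#' @param samples integer matrix, channels x time, raw ADC counts.
#' @param sampling_rate_hz sampling rate in Hz (default 30000).
#' @param uv_per_count microvolts per ADC count (default 0.195).
#' @param channel_pitch_um center-to-center electrode spacing in um
#'   (default 200).
#' @param channel_positions optional data.frame with columns `channel`
#'   (1-based, unique, contiguous) and `x_um`; defaults to a linear array
#'   at `channel_pitch_um` spacing.
#' @return an object of class `mea_recording`.
#' @export
recording <- function(samples, sampling_rate_hz = 30000, uv_per_count = 0.195,
                      channel_pitch_um = 200, channel_positions = NULL) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1)
  storage.mode(samples) <- "integer"
  if (anyNA(samples)) stop("recording: samples contain NA")
  if (sampling_rate_hz <= 0) stop("recording: sampling_rate_hz must be > 0")
  if (uv_per_count <= 0) stop("recording: uv_per_count must be > 0")
  if (channel_pitch_um <= 0) stop("recording: channel_pitch_um must be > 0")
  n_ch <- nrow(samples)
  if (is.null(channel_positions)) {
    channel_positions <- data.frame(channel = seq_len(n_ch),
                                    x_um = seq_len(n_ch) * channel_pitch_um)
  }
  if (!identical(sort(channel_positions$channel), seq_len(n_ch)))
    stop("recording: channel indices must be unique and contiguous from 1")
  structure(list(samples = samples,
                 sampling_rate_hz = sampling_rate_hz,
                 uv_per_count = uv_per_count,
                 channel_pitch_um = channel_pitch_um,
                 channel_positions = channel_positions),
            class = "mea_recording")
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf("<mea_recording> %d channel(s) x %d samples @ %g Hz (%.3f s), %g uV/count\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate_hz,
              ncol(x$samples) / x$sampling_rate_hz, x$uv_per_count))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `mea_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$sampling_rate_hz

#' Convert recording counts to microvolts
#'
#' @param rec an `mea_recording`.
#' @return numeric matrix (channels x time) in microvolts.
#' @export
as_uv <- function(rec) rec$samples * rec$uv_per_count

#' Write / read a raw recording (.raw + .json sidecar)
#'
#' The binary container is little-endian int16, channel-major interleaved
#' frames (all channels of sample 1, then sample 2, ...). The JSON sidecar
#' carries the metadata and a `format_version` field; unknown versions are
#' rejected. The pair round-trips byte-identically.
#'
#' @param rec an `mea_recording`.
#' @param path base path; `.raw` and `.json` extensions are appended (a
#'   trailing `.raw` is tolerated and stripped).
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `mea_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "mea_recording"))
  base <- sub("\\.raw$", "", path)
  if (any(abs(rec$samples) > 32767))
    stop("write_recording: samples exceed int16 range")
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  writeBin(as.integer(as.vector(rec$samples)), con, size = 2, endian = "little")
  meta <- list(format_version = FORMAT_VERSION,
               sampling_rate_hz = rec$sampling_rate_hz,
               n_channels = nrow(rec$samples),
               n_samples = ncol(rec$samples),
               uv_per_count = rec$uv_per_count,
               channel_pitch_um = rec$channel_pitch_um,
               channel_positions = rec$channel_positions)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  base <- sub("\\.raw$", "", path)
  sidecar <- paste0(base, ".json")
  rawfile <- paste0(base, ".raw")
  if (!file.exists(sidecar)) stop("read_recording: missing sidecar ", sidecar)
  if (!file.exists(rawfile)) stop("read_recording: missing binary ", rawfile)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("format_version", "sampling_rate_hz", "n_channels",
                "n_samples", "uv_per_count")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("read_recording: sidecar schema error, missing field(s): ",
         paste(missing, collapse = ", "))
  if (meta$format_version != FORMAT_VERSION)
    stop("read_recording: unknown format_version ", meta$format_version)
  expect_bytes <- as.numeric(meta$n_channels) * meta$n_samples * 2
  actual <- file.info(rawfile)$size
  if (actual != expect_bytes)
    stop(sprintf("read_recording: corrupt file: sidecar implies %d bytes, binary has %d",
                 expect_bytes, actual))
  con <- file(rawfile, "rb")
  on.exit(close(con))
  v <- readBin(con, "integer", n = meta$n_channels * meta$n_samples,
               size = 2, signed = TRUE, endian = "little")
  samples <- matrix(v, nrow = meta$n_channels)
  pos <- meta$channel_positions
  if (!is.null(pos)) pos <- as.data.frame(pos)
  recording(samples, meta$sampling_rate_hz, meta$uv_per_count,
            meta$channel_pitch_um %||% 200, pos)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct / validate an event table
#'
#' An event table lists detected (or ground-truth) spike events: channel,
#' time in seconds, an optional code id, and signed peak amplitude in uV.
#' Times must be non-decreasing within each channel.
#'
#' @param channel integer channel indices (1-based).
#' @param time_s event times in seconds, non-negative.
#' @param code_id character code labels (`NA` = unassigned).
#' @param amplitude_uv signed peak amplitudes in microvolts.
#' @return a data.frame of class `mea_events`.
#' @export
event_table <- function(channel = integer(), time_s = numeric(),
                        code_id = NA_character_, amplitude_uv = NA_real_) {
  df <- data.frame(channel = as.integer(channel), time_s = as.numeric(time_s),
                   code_id = rep_len(as.character(code_id),
                                     length(channel)),
                   amplitude_uv = rep_len(as.numeric(amplitude_uv),
                                          length(channel)),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$time_s < 0)) stop("event_table: negative time_s")
    if (any(df$channel < 1)) stop("event_table: channel must be >= 1")
    for (ch in unique(df$channel)) {
      t <- df$time_s[df$channel == ch]
      if (is.unsorted(t)) stop("event_table: times must be non-decreasing within channel ", ch)
    }
  }
  class(df) <- c("mea_events", "data.frame")
  df
}

#' Write / read an event table (CSV)
#'
#' Plain comma-separated text with a format-version comment line and a fixed
#' header. Times are written with full precision; the round trip preserves
#' every field.
#'
#' @param events an `mea_events` table.
#' @param path output CSV path.
#' @export
write_event_table <- function(events, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#neurocode,event_table,%d", FORMAT_VERSION), con)
  writeLines("channel,time_s,code_id,amplitude_uv", con)
  if (nrow(events)) {
    lines <- sprintf("%d,%.9g,%s,%.9g", events$channel, events$time_s,
                     ifelse(is.na(events$code_id), "", events$code_id),
                     events$amplitude_uv)
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#neurocode,event_table"))
    stop("read_event_table: not an event table file")
  ver <- as.integer(strsplit(lines[1], ",")[[1]][3])
  if (is.na(ver) || ver != FORMAT_VERSION)
    stop("read_event_table: unknown format_version")
  body <- lines[-1]
  if (!length(body) || body[1] != "channel,time_s,code_id,amplitude_uv")
    stop("read_event_table: bad header")
  rows <- body[-1]
  if (!length(rows)) return(event_table())
  parts <- strsplit(rows, ",", fixed = TRUE)
  parse_num <- function(x, row, what) {
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & nzchar(x))
    if (length(bad))
      stop(sprintf("read_event_table: parse error in row %d: non-numeric %s '%s'",
                   row[bad[1]], what, x[bad[1]]))
    v
  }
  n <- lengths(parts)
  if (any(n != 4))
    stop(sprintf("read_event_table: parse error in row %d: expected 4 fields, got %d",
                 which(n != 4)[1], n[n != 4][1]))
  m <- do.call(rbind, parts)
  idx <- seq_len(nrow(m))
  event_table(channel = parse_num(m[, 1], idx, "channel"),
              time_s = parse_num(m[, 2], idx, "time_s"),
              code_id = ifelse(nzchar(m[, 3]), m[, 3], NA_character_),
              amplitude_uv = parse_num(m[, 4], idx, "amplitude_uv"))
}

#' Read / write a per-day per-electrode cell-count table (CSV)
#'
#' Rows are days, columns electrodes; entries are non-negative integer cell
#' counts near each electrode. See [count_table()] for the in-memory form.
#'
#' @param path CSV path.
#' @param pitch_um electrode pitch recorded in the file header comment;
#'   used when the file lacks one.
#' @export
read_count_table <- function(path, pitch_um = 200) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#neurocode,count_table"))
    stop("read_count_table: not a count table file")
  hdr <- strsplit(lines[1], ",")[[1]]
  if (as.integer(hdr[3]) != FORMAT_VERSION)
    stop("read_count_table: unknown format_version")
  if (length(hdr) >= 4) pitch_um <- as.numeric(hdr[4])
  body <- lines[-(1:2)]  # drop version + header row
  parts <- strsplit(body, ",", fixed = TRUE)
  n <- lengths(parts)
  if (length(unique(n)) > 1)
    stop("read_count_table: ragged rows (validation error)")
  m <- do.call(rbind, lapply(parts, function(p) suppressWarnings(as.numeric(p[-1]))))
  days <- vapply(parts, `[[`, "", 1)
  if (anyNA(m)) stop("read_count_table: non-numeric count")
  if (any(m < 0)) stop("read_count_table: negative count (validation error)")
  count_table(m, days = days, pitch_um = pitch_um)
}

#' @rdname read_count_table
#' @param tab an `mea_counts` table.
#' @export
write_count_table <- function(tab, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#neurocode,count_table,%d,%g", FORMAT_VERSION, tab$pitch_um), con)
  writeLines(paste(c("day", sprintf("e%02d", seq_len(ncol(tab$counts)))),
                   collapse = ","), con)
  for (i in seq_len(nrow(tab$counts)))
    writeLines(paste(c(tab$days[i], tab$counts[i, ]), collapse = ","), con)
  invisible(path)
}

#' Write / read a neural-code library (JSON)
#'
#' Stores, per code, the template samples in uV, the peak alignment index,
#' the member count and the min/max member envelope, plus the library's
#' tolerance and consistency parameters.
#'
#' @param library a `code_library` (see [build_codebook()]).
#' @param path JSON path.
#' @export
write_code_library <- function(library, path) {
  stopifnot(inherits(library, "code_library"))
  obj <- list(format_version = FORMAT_VERSION,
              tolerance = library$tolerance,
              consistency_min = library$consistency_min,
              codes = lapply(library$codes, function(cd) {
                list(code_id = cd$code_id, template_uv = cd$template_uv,
                     alignment_index = cd$alignment_index,
                     n_members = cd$n_members,
                     envelope_min = cd$envelope_min,
                     envelope_max = cd$envelope_max)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_code_library
#' @export
read_code_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (is.null(obj$format_version) || obj$format_version != FORMAT_VERSION)
    stop("read_code_library: unknown format_version")
  codes <- lapply(obj$codes, function(cd) {
    list(code_id = cd$code_id,
         template_uv = as.numeric(cd$template_uv),
         alignment_index = as.integer(cd$alignment_index),
         n_members = as.integer(cd$n_members),
         envelope_min = as.numeric(cd$envelope_min),
         envelope_max = as.numeric(cd$envelope_max))
  })
  new_code_library(codes, tolerance = obj$tolerance,
                   consistency_min = obj$consistency_min)
}
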