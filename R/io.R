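#' Label manifest for multichannel recordings
#'
#' Maps `(file, channel_id)` to a seizure-type label, with an optional
#' onset time in seconds used when clipping EDF channels to the onset
#' window. Stored/read as CSV with columns `file,channel_id,label[,onset_s]`.
#'
#' @param file,channel_id,label Equal-length vectors.
#' @param onset_s Optional onset time per channel in seconds (default 0).
#' @return Data frame of class `label_manifest`.
#' @export
label_manifest <- function(file, channel_id, label, onset_s = 0) {
  df <- data.frame(file = as.character(file),
                   channel_id = as.character(channel_id),
                   label = as.character(label),
                   onset_s = as.numeric(onset_s),
                   stringsAsFactors = FALSE)
  if (!all(df$label %in% SEIZURE_LABELS)) {
    stop_seizr("labels must be TCSZ, CPSZ or EGSZ",
               "seizr_error_invalid_argument")
  }
  if (anyDuplicated(df[, c("file", "channel_id")])) {
    stop_seizr("duplicate (file, channel_id) keys in manifest",
               "seizr_error_invalid_argument")
  }
  class(df) <- c("label_manifest", "data.frame")
  df
}

#' @rdname label_manifest
#' @param path CSV file to read.
#' @export
read_label_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("file", "channel_id", "label")
  if (!all(need %in% names(df))) {
    stop_seizr("manifest must have columns file, channel_id, label",
               "seizr_error_format")
  }
  label_manifest(df$file, df$channel_id, df$label,
                 if ("onset_s" %in% names(df)) df$onset_s else 0)
}

# --------------------------------------------------------------------------
# Minimal EDF (European Data Format) support: 16-bit samples, one data
# record spanning the whole segment, identical rate across channels.

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write channels to an EDF file
#'
#' Minimal EDF writer: all channels must share one sampling rate and
#' length; samples are stored as 16-bit integers scaled to each channel's
#' physical range, which bounds the round-trip error by half a quantization
#' step (range / 65535 / 2).
#'
#' @param segments List of [signal_segment()]s of equal rate and length.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(segments, path) {
  if (length(segments) < 1) {
    stop_seizr("no channels to write", "seizr_error_invalid_argument")
  }
  segments <- lapply(segments, as_signal_segment)
  fs <- unique(vapply(segments, function(s) s$sampling_rate_hz, numeric(1)))
  ns <- unique(vapply(segments, function(s) length(s$samples), integer(1)))
  if (length(fs) != 1 || length(ns) != 1) {
    stop_seizr("all channels must share one sampling rate and length",
               "seizr_error_format")
  }
  dur <- ns / fs
  nchan <- length(segments)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeChar(pad_field(x, width), con, width,
                                     eos = NULL)
  wr("0", 8)                               # version
  wr("synthetic", 80)                      # patient id (synthetic data)
  wr("seizr", 80)                          # recording id
  wr("01.01.26", 8); wr("00.00.00", 8)     # date, time
  wr(256 + 256 * nchan, 8)                 # header bytes
  wr("", 44)                               # reserved
  wr(1, 8)                                 # number of data records
  wr(format(dur, digits = 8), 8)           # record duration (s)
  wr(nchan, 4)
  phys_min <- numeric(nchan); phys_max <- numeric(nchan)
  for (s in segments) wr(s$channel_id, 16)
  for (s in segments) wr("EEG", 80)        # transducer
  for (s in segments) wr("uV", 8)
  for (i in seq_len(nchan)) {
    r <- range(segments[[i]]$samples)
    if (r[1] == r[2]) r <- r + c(-1, 1)
    phys_min[i] <- r[1]; phys_max[i] <- r[2]
  }
  for (v in phys_min) wr(format(v, digits = 7), 8)
  for (v in phys_max) wr(format(v, digits = 7), 8)
  for (i in seq_len(nchan)) wr(-32768, 8)
  for (i in seq_len(nchan)) wr(32767, 8)
  for (i in seq_len(nchan)) wr("", 80)     # prefiltering
  for (i in seq_len(nchan)) wr(ns, 8)      # samples per record
  for (i in seq_len(nchan)) wr("", 32)     # reserved
  for (i in seq_len(nchan)) {
    x <- segments[[i]]$samples
    dig <- round((x - phys_min[i]) / (phys_max[i] - phys_min[i]) * 65535) -
      32768
    writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
             endian = "little")
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file written by [write_edf()] or any single-record,
#'   16-bit EDF whose channels share one sampling rate.
#' @return List with `channels` (named list of numeric sample vectors) and
#'   `sampling_rate_hz`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") {
    stop_seizr("not an EDF file (bad version field)", "seizr_error_format")
  }
  rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  nchan <- as.integer(rd(4))
  labels <- vapply(seq_len(nchan), function(i) rd(16), character(1))
  for (i in seq_len(nchan)) rd(80)
  for (i in seq_len(nchan)) rd(8)
  phys_min <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(nchan), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nchan)) rd(80)
  spr <- vapply(seq_len(nchan), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nchan)) rd(32)
  rates <- spr / recdur
  if (length(unique(rates)) != 1) {
    stop_seizr("channels disagree on sampling rate", "seizr_error_format")
  }
  channels <- stats::setNames(
    lapply(seq_len(nchan), function(i) numeric(0)), labels)
  for (r in seq_len(nrec)) {
    for (i in seq_len(nchan)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      phys <- phys_min[i] + (dig - dig_min[i]) /
        (dig_max[i] - dig_min[i]) * (phys_max[i] - phys_min[i])
      channels[[i]] <- c(channels[[i]], phys)
    }
  }
  list(channels = channels, sampling_rate_hz = rates[1])
}

# --------------------------------------------------------------------------

#' Read labeled EEG segments from EDF or delimited text
#'
#' Reads every manifest-listed channel of `path` and clips it to the onset
#' window. For EDF the sampling rate comes from the header and the onset
#' sample from the manifest's optional `onset_s`; for CSV (columns =
#' channels, rows = samples) the rate must be given and the onset is the
#' series start.
#'
#' @param path EDF or CSV file.
#' @param manifest A [label_manifest()]; rows whose `file` matches
#'   `basename(path)` (or the full path) select and label the channels. If
#'   `NULL`, all channels are read unlabeled from onset 0.
#' @param onset_window_s Window kept from the onset, in seconds (default 4).
#' @param sampling_rate_hz Required for CSV input; ignored for EDF.
#' @return List of [signal_segment()]s of exactly
#'   `onset_window_s * rate` samples each.
#' @export
read_signals <- function(path, manifest = NULL, onset_window_s = 4,
                         sampling_rate_hz = NULL) {
  if (!file.exists(path)) {
    stop_seizr(sprintf("file not found: %s", path), "seizr_error_io")
  }
  is_edf <- grepl("\\.edf$", path, ignore.case = TRUE)
  if (is_edf) {
    rec <- read_edf(path)
    fs <- rec$sampling_rate_hz
    channels <- rec$channels
  } else {
    if (is.null(sampling_rate_hz)) {
      stop_seizr("'sampling_rate_hz' is required for delimited-text input",
                 "seizr_error_invalid_argument")
    }
    fs <- sampling_rate_hz
    df <- utils::read.csv(path)
    channels <- as.list(df)
  }
  rows <- NULL
  if (!is.null(manifest)) {
    rows <- manifest[manifest$file %in% c(basename(path), path), ,
                     drop = FALSE]
    if (nrow(rows) == 0) {
      stop_seizr(sprintf("manifest has no rows for file '%s'",
                         basename(path)), "seizr_error_missing_channel")
    }
    missing <- setdiff(rows$channel_id, names(channels))
    if (length(missing)) {
      stop_seizr(sprintf("channel(s) not present in %s: %s", basename(path),
                         paste(missing, collapse = ", ")),
                 "seizr_error_missing_channel")
    }
  }
  want <- as.integer(round(onset_window_s * fs))
  ids <- if (is.null(rows)) names(channels) else rows$channel_id
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    onset <- if (is.null(rows) || !is_edf) 0 else rows$onset_s[i]
    start <- as.integer(round(onset * fs)) + 1L
    x <- channels[[id]]
    if (length(x) - start + 1L < want) {
      stop_seizr(sprintf(
        "channel '%s': %d samples from onset, need %d for a %g s window",
        id, max(0L, length(x) - start + 1L), want, onset_window_s),
        "seizr_error_short_segment")
    }
    out[[i]] <- signal_segment(x[start:(start + want - 1L)], fs,
                               channel_id = id,
                               label = if (is.null(rows)) NULL else
                                 rows$label[i])
  }
  out
}

# --------------------------------------------------------------------------

#' Persist and reload feature tables
#'
#' CSV with columns `channel_id,label,<features...>`. Values are written
#' with 17 significant digits so the numeric round trip is lossless.
#'
#' @param table Feature table from [extract_feature_table()].
#' @param path CSV path.
#' @return `write_feature_table`: `path` invisibly. `read_feature_table`:
#'   the table.
#' @export
write_feature_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    stop_seizr("feature table must be a non-empty data frame",
               "seizr_error_invalid_argument")
  }
  num <- vapply(table, is.numeric, logical(1))
  out <- table
  out[num] <- lapply(table[num], function(x) sprintf("%.17g", x))
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel_id", "label") %in% names(df))) {
    stop_seizr("malformed feature table: need channel_id and label columns",
               "seizr_error_format")
  }
  df$channel_id <- as.character(df$channel_id)
  df$label <- as.character(df$label)
  df
}
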