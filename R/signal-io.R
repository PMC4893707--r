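#' Multi-channel recording container
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param fs sampling rate, Hz (> 0).
#' @param channels data.frame with one row per channel: `label`,
#'   `hemisphere`, `ap_mm`, `ml_mm`. Labels must be unique.
#' @return object of class `swd_recording`.
#' @export
swd_recording <- function(samples, fs, channels) {
  if (!is.matrix(samples)) stop("samples must be a channels x time matrix",
                                call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (nrow(samples) != nrow(channels))
    stop("channel metadata rows must match sample rows", call. = FALSE)
  if (anyDuplicated(channels$label))
    stop("duplicate channel labels: ",
         paste(unique(channels$label[duplicated(channels$label)]),
               collapse = ", "), call. = FALSE)
  structure(list(samples = samples, fs = fs, channels = channels),
            class = "swd_recording")
}

#' @export
print.swd_recording <- function(x, ...) {
  cat(sprintf("LFP recording: %d channels x %.1f s @ %g Hz\n",
              nrow(x$samples), ncol(x$samples) / x$fs, x$fs))
  cat("  channels:", paste(x$channels$label, collapse = " "), "\n")
  invisible(x)
}

#' Extract one channel's trace
#'
#' @param rec a [swd_recording()].
#' @param channel channel label or index.
#' @param from,to optional time range in seconds (half-open, from start).
#' @return numeric vector.
#' @export
channel_trace <- function(rec, channel, from = NULL, to = NULL) {
  stopifnot(inherits(rec, "swd_recording"))
  i <- if (is.character(channel)) match(channel, rec$channels$label)
       else as.integer(channel)
  if (is.na(i) || i < 1 || i > nrow(rec$samples))
    stop("unknown channel: ", channel, call. = FALSE)
  x <- rec$samples[i, ]
  if (!is.null(from) || !is.null(to)) {
    a <- if (is.null(from)) 1L else round(from * rec$fs) + 1L
    b <- if (is.null(to)) length(x) else round(to * rec$fs)
    if (a < 1L || b > length(x) || a > b)
      stop("requested range outside the recording", call. = FALSE)
    x <- x[a:b]
  }
  x
}

pad_ascii <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a European Data Format (EDF) file
#'
#' Standard EDF: fixed 256-byte header, 256 bytes per signal, then 1 s data
#' records of 16-bit little-endian integers scaled per channel between the
#' stored physical min/max. Channel hemisphere and coordinates are packed in
#' the transducer field so they round-trip. The trailing partial second, if
#' any, is zero-padded into the final record.
#'
#' @param rec a [swd_recording()] (fs must be a whole number for EDF's 1 s
#'   records).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path) {
  stopifnot(inherits(rec, "swd_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- nrow(rec$samples)
  n <- ncol(rec$samples)
  n_rec <- ceiling(n / fs)
  x <- rec$samples
  if (n < n_rec * fs) x <- cbind(x, matrix(0, ns, n_rec * fs - n))

  phys_max <- apply(abs(x), 1, max)
  phys_max[phys_max == 0] <- 1
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(pad_ascii(s, width), con,
                                     nchars = width, eos = NULL)
  wr("0", 8)
  wr("X X X X", 80)                       # patient id
  wr("Startdate X X X X", 80)             # recording id
  wr("01.01.01", 8); wr("00.00.00", 8)
  wr(256 * (ns + 1), 8)
  wr("", 44)
  wr(n_rec, 8)
  wr(1, 8)                                # record duration (s)
  wr(ns, 4)
  meta <- sprintf("%s %s %g %g", rec$channels$label, rec$channels$hemisphere,
                  rec$channels$ap_mm, rec$channels$ml_mm)
  for (v in rec$channels$label) wr(v, 16)
  for (v in meta) wr(v, 80)               # transducer: metadata round-trip
  for (v in rep("uV", ns)) wr(v, 8)
  for (v in sprintf("%.6g", -phys_max)) wr(v, 8)
  for (v in sprintf("%.6g", phys_max)) wr(v, 8)
  for (v in rep(-dig_max, ns)) wr(v, 8)
  for (v in rep(dig_max, ns)) wr(v, 8)
  for (v in rep("", ns)) wr(v, 80)
  for (v in rep(fs, ns)) wr(v, 8)
  for (v in rep("", ns)) wr(v, 32)

  scale <- dig_max / phys_max
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    block <- round(x[, idx, drop = FALSE] * scale)   # ns x fs
    writeBin(as.integer(t(block)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a recording from an EDF file
#'
#' @param path EDF file written by [write_recording_edf()] or any plain
#'   (uncompressed, non-EDF+) EDF with equal sampling rates across signals.
#' @return a [swd_recording()]; values in the file's physical units.
#' @export
read_recording_edf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (version != "0")
    stop("EDF header field 'version' is '", version, "', expected '0'",
         call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  rd(8)                                    # header bytes
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (is.na(ns) || ns < 1)
    stop("EDF header field 'number of signals' is invalid", call. = FALSE)
  if (is.na(n_rec) || is.na(rec_dur) || rec_dur <= 0)
    stop("EDF header field 'data records' or 'record duration' is invalid",
         call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  transducer <- vapply(seq_len(ns), function(i) rd(80), "")
  rd(8 * ns)                               # physical dimension
  phys_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(80 * ns)
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  rd(32 * ns)
  if (anyDuplicated(labels))
    stop("duplicate channel labels in EDF header: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  if (length(unique(spr)) != 1L)
    stop("EDF signals have unequal sampling rates; not supported",
         call. = FALSE)
  if (any(is.na(phys_min) | is.na(phys_max) | is.na(dig_min) | is.na(dig_max)))
    stop("EDF header scaling fields are invalid", call. = FALSE)
  fs <- spr[1] / rec_dur
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  samples <- matrix(0, nrow = ns, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = ns * spr[1], size = 2,
                   endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = ns)   # samples x signals
    idx <- ((r - 1) * spr[1] + 1):(r * spr[1])
    samples[, idx] <- t(block) * gain + offset
  }
  meta <- strsplit(transducer, " +")
  parse_meta <- function(m, lab) {
    if (length(m) >= 4 && !is.na(suppressWarnings(as.numeric(m[3]))))
      data.frame(label = lab, hemisphere = m[2],
                 ap_mm = as.numeric(m[3]), ml_mm = as.numeric(m[4]),
                 stringsAsFactors = FALSE)
    else data.frame(label = lab, hemisphere = NA_character_,
                    ap_mm = NA_real_, ml_mm = NA_real_,
                    stringsAsFactors = FALSE)
  }
  channels <- do.call(rbind, Map(parse_meta, meta, labels))
  rownames(channels) <- NULL
  swd_recording(samples, fs, channels)
}

#' Read a recording
#'
#' @param path input file.
#' @param format `"edf"` or `"auto"` (by extension).
#' @return a [swd_recording()].
#' @export
read_recording <- function(path, format = c("auto", "edf")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (ext != "edf")
      stop("unsupported recording format: .", ext, call. = FALSE)
  }
  read_recording_edf(path)
}

#' Read / write SWD event lists
#'
#' Event lists are CSV files with header `onset_s,offset_s`, times in seconds
#' from recording start, half-open intervals. Values are written as decimal
#' text at full double precision so round-trips are exact.
#'
#' @param path CSV file.
#' @return `read_events`: data.frame with `onset_s`, `offset_s` (sorted).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df)[1:2], c("onset_s", "offset_s")))
    stop("event CSV must have header onset_s,offset_s", call. = FALSE)
  validate_events(df)
  df
}

#' @rdname read_events
#' @param events data.frame with columns `onset_s`, `offset_s`.
#' @export
write_events <- function(events, path) {
  validate_events(events)
  out <- data.frame(onset_s = formatC(events$onset_s, digits = 17,
                                      format = "g"),
                    offset_s = formatC(events$offset_s, digits = 17,
                                       format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_events <- function(events) {
  if (nrow(events) == 0) return(invisible(events))
  bad <- which(events$offset_s <= events$onset_s)
  if (length(bad))
    stop("event offset <= onset at row ", bad[1], call. = FALSE)
  ord <- order(events$onset_s)
  ev <- events[ord, ]
  if (nrow(ev) > 1 && any(ev$onset_s[-1] < ev$offset_s[-nrow(ev)]))
    stop("events overlap", call. = FALSE)
  invisible(events)
}

#' Read an analysis configuration file
#'
#' JSON (`.json`) or YAML (`.yml`/`.yaml`) key-value file.
#'
#' @param path config file.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else stop("unsupported config format: .", ext, call. = FALSE)
}
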