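#' @section AEDAT dialect:
#' The binary format is the jAER "AER-DAT2.0" dialect: an ASCII header of
#' comment lines starting with `#` (the first being `#!AER-DAT2.0`),
#' followed by one record per event of two 32-bit big-endian words: the
#' address word, then the timestamp in microseconds.
#' @name aedat-format
#' @keywords internal
NULL

AEDAT_MAGIC <- "#!AER-DAT2.0"

#' Pack DVS128 events into 32-bit AER address words
#'
#' Address word layout (DVS128 profile used by this package): bit 0 is the
#' polarity (1 = ON, 0 = OFF), bits 1-7 the x address, bits 8-14 the y
#' address, all higher bits zero. Coordinates are 0-based with the origin at
#' the lower-left pixel; y is stored unflipped. The packing is bijective
#' over the 128 x 128 x 2 address space.
#'
#' @param x,y Integer pixel addresses (vectorized).
#' @param polarity `"ON"`/`"OFF"` (vectorized, recycled).
#' @param geometry A [sensor_geometry()]; must fit in 7-bit addresses
#'   (width, height <= 128).
#' @return Integer vector of address words.
#' @seealso [decode_address()]
#' @examples
#' encode_address(0, 0, "OFF")   # 0
#' encode_address(5, 3, "ON")    # bitwAnd layout: 3*256 + 5*2 + 1
#' @export
encode_address <- function(x, y, polarity, geometry = sensor_geometry()) {
  if (geometry$width > 128L || geometry$height > 128L) {
    stop("the AER address word layout supports at most 128 x 128 sensors")
  }
  x <- as.integer(x)
  y <- as.integer(y)
  pol <- as.integer(as_polarity(polarity) == "ON")
  if (any(x < 0L | x >= geometry$width) || any(y < 0L | y >= geometry$height)) {
    stop("coordinates overflow the sensor geometry; cannot encode")
  }
  bitwOr(bitwOr(bitwShiftL(y, 8L), bitwShiftL(x, 1L)), pol)
}

#' Unpack 32-bit AER address words into DVS128 addresses
#'
#' Inverse of [encode_address()]. Words with any bit above bit 14 set, or
#' with an address outside the geometry, are reported as invalid.
#'
#' @param word Integer vector of address words.
#' @param geometry A [sensor_geometry()].
#' @return A data.frame with columns `x`, `y`, `polarity`.
#' @export
decode_address <- function(word, geometry = sensor_geometry()) {
  word <- as.integer(word)
  if (any(is.na(word)) || any(word < 0L) || any(bitwShiftR(word, 15L) != 0L)) {
    stop("invalid address word: bits above the DVS128 layout are set")
  }
  x <- bitwAnd(bitwShiftR(word, 1L), 127L)
  y <- bitwAnd(bitwShiftR(word, 8L), 127L)
  pol <- EVENT_POLARITIES[bitwAnd(word, 1L) + 1L]
  if (any(x >= geometry$width) || any(y >= geometry$height)) {
    stop("decoded address outside the sensor geometry")
  }
  data.frame(x = x, y = y, polarity = pol, stringsAsFactors = FALSE)
}

infer_format <- function(path, format = c("auto", "aedat", "csv")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "aedat"
}

#' Read an AER event stream from disk
#'
#' Reads either the jAER-style AEDAT 2.0 binary dialect (see
#' [write_events()] for the byte layout) or the package's CSV dialect with
#' header `t_us,x,y,polarity`. Events with addresses outside the sensor
#' geometry raise an error naming the offending byte offset (AEDAT) or row
#' (CSV); they are never silently dropped.
#'
#' @param path File to read.
#' @param format `"aedat"`, `"csv"`, or `"auto"` (default: by file
#'   extension, `.csv` means CSV, anything else AEDAT).
#' @param geometry Expected [sensor_geometry()] (default DVS128).
#' @return An [event_stream()].
#' @export
read_events <- function(path, format = c("auto", "aedat", "csv"),
                        geometry = sensor_geometry()) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- infer_format(path, format)
  if (format == "csv") read_events_csv(path, geometry)
  else read_events_aedat(path, geometry)
}

read_events_aedat <- function(path, geometry) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  nl <- as.raw(0x0a)
  pos <- 1L
  header <- character()
  while (pos <= length(raw) && raw[pos] == as.raw(0x23)) {  # '#'
    eol <- pos
    while (eol <= length(raw) && raw[eol] != nl) eol <- eol + 1L
    if (eol > length(raw)) stop("AEDAT format error: unterminated header line")
    header <- c(header, rawToChar(raw[pos:(eol - 1L)]))
    pos <- eol + 1L
  }
  if (length(header) == 0 || !startsWith(sub("\r$", "", header[1]), AEDAT_MAGIC)) {
    stop("AEDAT format error: missing '", AEDAT_MAGIC, "' header magic")
  }
  body <- raw[seq.int(pos, length.out = length(raw) - pos + 1L)]
  if (length(body) %% 8L != 0L) {
    stop("AEDAT format error: body length ", length(body),
         " is not a multiple of 8 bytes")
  }
  n <- length(body) %/% 8L
  if (n == 0L) return(event_stream(geometry = geometry))
  words <- readBin(body, what = "integer", n = 2L * n, size = 4L,
                   endian = "big")
  addr <- words[seq(1L, 2L * n, by = 2L)]
  ts <- words[seq(2L, 2L * n, by = 2L)]
  dec <- tryCatch(decode_address(addr, geometry), error = function(e) e)
  if (inherits(dec, "error")) {
    # locate the first offending record for the error message
    ok <- addr >= 0L & bitwShiftR(addr, 15L) == 0L &
      bitwAnd(bitwShiftR(addr, 1L), 127L) < geometry$width &
      bitwAnd(bitwShiftR(addr, 8L), 127L) < geometry$height
    bad <- which(!ok)[1]
    stop(sprintf(
      "AEDAT validation error: out-of-range address word at byte offset %d",
      (pos - 1L) + (bad - 1L) * 8L))
  }
  if (any(ts < 0L)) stop("AEDAT validation error: negative timestamp")
  event_stream(data.frame(t = as.numeric(ts), x = dec$x, y = dec$y,
                          polarity = dec$polarity,
                          stringsAsFactors = FALSE),
               geometry)
}

read_events_csv <- function(path, geometry) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("t_us", "x", "y", "polarity")
  if (!all(req %in% names(df))) {
    stop("CSV format error: expected header 't_us,x,y,polarity'")
  }
  if (nrow(df) == 0) return(event_stream(geometry = geometry))
  bad <- which(df$x < 0 | df$x >= geometry$width |
                 df$y < 0 | df$y >= geometry$height)
  if (length(bad)) {
    stop(sprintf("CSV validation error: out-of-range address at data row %d",
                 bad[1]))
  }
  event_stream(data.frame(t = as.numeric(df$t_us), x = df$x, y = df$y,
                          polarity = df$polarity, stringsAsFactors = FALSE),
               geometry)
}

#' Write an AER event stream to disk
#'
#' AEDAT output starts with the `#!AER-DAT2.0` magic line and `#` comment
#' lines, then one record per event: a 32-bit big-endian address word (see
#' [encode_address()]) followed by the 32-bit big-endian timestamp in
#' microseconds. CSV output has header `t_us,x,y,polarity` with polarity
#' spelled `ON`/`OFF`. Both round-trip exactly through [read_events()].
#'
#' @param stream A valid [event_stream()] (non-decreasing timestamps).
#' @param path Output file.
#' @param format `"aedat"`, `"csv"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_events <- function(stream, path, format = c("auto", "aedat", "csv")) {
  validate_event_stream(stream)
  format <- infer_format(path, format)
  ev <- stream$events
  if (format == "csv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines("t_us,x,y,polarity", con)
    if (nrow(ev) > 0) {
      utils::write.table(
        data.frame(t_us = format(ev$t, scientific = FALSE, trim = TRUE),
                   x = ev$x, y = ev$y, polarity = ev$polarity),
        con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  } else {
    if (nrow(ev) > 0 && max(ev$t) >= 2^31) {
      stop("timestamps overflow the 32-bit AEDAT timestamp field")
    }
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeChar(paste0(AEDAT_MAGIC, "\r\n",
                     "# acsim DVS event stream\r\n",
                     "# one 32-bit big-endian address word + 32-bit ",
                     "big-endian timestamp (us) per event\r\n"),
              con, eos = NULL)
    if (nrow(ev) > 0) {
      addr <- encode_address(ev$x, ev$y, ev$polarity, stream$geometry)
      inter <- integer(2L * nrow(ev))
      inter[seq(1L, length(inter), by = 2L)] <- addr
      inter[seq(2L, length(inter), by = 2L)] <- as.integer(ev$t)
      writeBin(inter, con, size = 4L, endian = "big")
    }
  }
  invisible(path)
}
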