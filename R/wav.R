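# Minimal RIFF/WAVE reader and writer: 16/24-bit integer PCM and 32-bit IEEE
# float, mono or two-channel. Float round-trips are bit-exact.

#' Read a WAV file
#'
#' Supports 16- and 24-bit integer PCM and 32-bit float encodings, mono and
#' two-channel. Integer samples are scaled to [-1, 1); float samples are
#' returned unchanged.
#'
#' @param path Path to a `.wav` file.
#' @return For mono, an `audio` object; for two channels, a list of two
#'   `audio` objects (`mic1`, `mic2`).
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, integer(), 1, 4, endian = "little")        # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE")) {
    stop("not a WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, raw(), sz)
      fmt <- list(
        format = rawToUint(raw[1:2]),
        channels = rawToUint(raw[3:4]),
        fs = rawToUint(raw[5:8]),
        bits = rawToUint(raw[15:16]))
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, raw(), sz)
    } else {
      readBin(con, raw(), sz + (sz %% 2))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) stop("malformed WAV: missing fmt or data chunk")
  samples <- decode_wav_samples(data_raw, fmt)
  if (fmt$channels == 1) {
    audio(samples[, 1], fmt$fs)
  } else if (fmt$channels == 2) {
    list(mic1 = audio(samples[, 1], fmt$fs), mic2 = audio(samples[, 2], fmt$fs))
  } else {
    stop("unsupported channel count: ", fmt$channels)
  }
}

rawToUint <- function(r) sum(as.integer(r) * 256^(seq_along(r) - 1))

decode_wav_samples <- function(data_raw, fmt) {
  if (fmt$format == 3 && fmt$bits == 32) {
    x <- readBin(data_raw, numeric(), length(data_raw) / 4, 4, endian = "little")
  } else if (fmt$format == 1 && fmt$bits == 16) {
    x <- readBin(data_raw, integer(), length(data_raw) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$format == 1 && fmt$bits == 24) {
    n <- length(data_raw) / 3
    m <- matrix(as.integer(data_raw), 3, n)
    v <- m[1, ] + m[2, ] * 256L + m[3, ] * 65536L
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / 2^23
  } else {
    stop(sprintf("unsupported WAV encoding: format %d, %d-bit",
                 fmt$format, fmt$bits))
  }
  matrix(x, ncol = fmt$channels, byrow = TRUE)
}

#' Write a WAV file
#'
#' @param path Output path.
#' @param x An `audio` object (mono) or a list of two equal-length `audio`
#'   objects (two-channel).
#' @param bits 16, 24 (integer PCM, clipped to [-1, 1]) or 32 (IEEE float,
#'   bit-exact round trip).
#' @return The path, invisibly.
#' @export
write_wav <- function(path, x, bits = 32) {
  if (inherits(x, "audio")) {
    chans <- list(x)
  } else if (is.list(x) && length(x) == 2 &&
             all(vapply(x, inherits, logical(1), "audio"))) {
    if (length(x[[1]]) != length(x[[2]])) stop("channels must have equal length")
    chans <- x
  } else {
    stop("'x' must be an audio object or a list of two audio objects")
  }
  if (!bits %in% c(16, 24, 32)) stop("bits must be 16, 24 or 32")
  fs <- chans[[1]]$fs
  nch <- length(chans)
  interleaved <- as.numeric(t(do.call(cbind, lapply(chans, `[[`, "samples"))))
  fmt_code <- if (bits == 32) 3L else 1L
  bytes_per <- bits / 8
  data_size <- length(interleaved) * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(as.integer(nch), con, 2, endian = "little")
  writeBin(as.integer(fs), con, 4, endian = "little")
  writeBin(as.integer(fs * nch * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(nch * bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bits), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bits == 32) {
    writeBin(interleaved, con, 4, endian = "little")
  } else if (bits == 16) {
    v <- as.integer(round(pmax(-1, pmin(1 - 1 / 32768, interleaved)) * 32768))
    writeBin(v, con, 2, endian = "little")
  } else {
    v <- round(pmax(-1, pmin(1 - 1 / 2^23, interleaved)) * 2^23)
    v <- ifelse(v < 0, v + 2^24, v)
    b <- rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256)
    writeBin(as.raw(as.integer(b)), con)
  }
  invisible(path)
}
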