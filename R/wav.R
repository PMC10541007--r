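# Minimal mono RIFF/WAVE I/O. Ultrasonic recordings are single-channel and
# either 16-bit PCM or IEEE float32; nothing more is needed here.

#' Write a mono waveform to a WAV file
#'
#' @param x numeric vector of samples. For `format = "pcm16"` values are
#'   clipped to \[-1, 1\] and scaled to 16-bit integers; for `"float32"`
#'   they are stored as-is.
#' @param fs sampling rate in Hz (stored in the header).
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(x, fs, path, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot_scalar_num(fs, "fs", lo = 1)
  con <- file(path, "wb")
  on.exit(close(con))
  if (format == "pcm16") {
    bits <- 16L; fmt <- 1L; bytes <- 2L
    data <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
  } else {
    bits <- 32L; fmt <- 3L; bytes <- 4L
    data <- x
  }
  n <- length(x) * bytes
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs) * bytes, con, size = 4, endian = "little")
  writeBin(bytes, con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n), con, size = 4, endian = "little")
  if (format == "pcm16") {
    writeBin(data, con, size = 2, endian = "little")
  } else {
    writeBin(data, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Supports the 16-bit PCM and IEEE float32 files written by [write_wav()]
#' (and by common recording software, provided the file is single-channel).
#'
#' @param path file path.
#' @return list with `x` (numeric samples; PCM scaled to \[-1, 1\]) and
#'   `fs` (sampling rate in Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, integer(), size = 4, endian = "little")
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file: ", path)
  fmt <- NULL; fs <- NULL; bits <- NULL; nch <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk found in ", path)
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), size = 2, endian = "little")
      nch <- readBin(con, integer(), size = 2, endian = "little")
      fs <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (sz > 16L) readBin(con, raw(), n = sz - 16L)
    } else if (id == "data") {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      if (nch != 1L) stop("only mono WAV files are supported")
      if (fmt == 1L && bits == 16L) {
        x <- readBin(con, integer(), n = sz / 2L, size = 2,
                     signed = TRUE, endian = "little") / 32767
      } else if (fmt == 3L && bits == 32L) {
        x <- readBin(con, numeric(), n = sz / 4L, size = 4, endian = "little")
      } else {
        stop("unsupported WAV encoding (fmt ", fmt, ", ", bits, " bit)")
      }
      return(list(x = x, fs = fs))
    } else {
      readBin(con, raw(), n = sz + (sz %% 2L))
    }
  }
}
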