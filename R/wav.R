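# Minimal mono RIFF/WAVE I/O. Supports PCM 16/24-bit integer and IEEE
# float32; that covers every recorder export the pipeline consumes.

#' Read a mono WAV file
#'
#' Reads a RIFF/WAVE file into an [audio_recording()]. Only mono files are
#' accepted; 16- and 24-bit integer PCM and 32-bit IEEE float encodings are
#' supported. Samples are returned as doubles in nominal `[-1, 1]`.
#'
#' @param path Path to a `.wav` file.
#' @return An `audio_recording` object.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file", path), class = "bcgsleep_format_error")
  }
  readBin(con, "integer", 1, size = 4, endian = "little") # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) {
    abort(sprintf("'%s' is not a RIFF/WAVE file", path), class = "bcgsleep_format_error")
  }
  fmt <- NULL
  samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        n_channels   = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, size = 4, endian = "little"),
        byte_rate    = readBin(con, "integer", 1, size = 4, endian = "little"),
        block_align  = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE),
        bits         = readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
      )
      extra <- size - 16L
      if (extra > 0) readBin(con, "raw", extra)
    } else if (identical(id, "data")) {
      if (is.null(fmt)) {
        abort("WAV 'data' chunk precedes 'fmt '", class = "bcgsleep_format_error")
      }
      if (fmt$n_channels != 1L) {
        abort(sprintf("only mono WAV supported; '%s' has %d channels", path, fmt$n_channels),
              class = "bcgsleep_format_error")
      }
      n <- size %/% (fmt$bits %/% 8L)
      if (fmt$audio_format == 1L && fmt$bits == 16L) {
        raw <- readBin(con, "integer", n, size = 2, endian = "little", signed = TRUE)
        samples <- raw / 32768
      } else if (fmt$audio_format == 1L && fmt$bits == 24L) {
        bytes <- readBin(con, "raw", size)
        b <- matrix(as.integer(bytes), nrow = 3)
        val <- b[1, ] + b[2, ] * 256L + b[3, ] * 65536L
        val <- ifelse(val >= 8388608, val - 16777216, val)
        samples <- val / 8388608
      } else if (fmt$audio_format == 3L && fmt$bits == 32L) {
        samples <- readBin(con, "double", n, size = 4, endian = "little")
      } else {
        abort(sprintf("unsupported WAV encoding (format %d, %d-bit)", fmt$audio_format, fmt$bits),
              class = "bcgsleep_format_error")
      }
      break
    } else {
      # skip unknown chunk (word-aligned)
      readBin(con, "raw", size + size %% 2L)
    }
  }
  if (is.null(samples)) {
    abort(sprintf("no 'data' chunk found in '%s'", path), class = "bcgsleep_format_error")
  }
  audio_recording(samples, fmt$sample_rate)
}

#' Write a mono WAV file
#'
#' @param audio An [audio_recording()].
#' @param path Output path.
#' @param bits Either `16` (integer PCM, default) or `32` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, path, bits = 16L) {
  stopifnot(inherits(audio, "audio_recording"))
  bits <- as.integer(bits)
  if (!bits %in% c(16L, 32L)) abort("bits must be 16 or 32")
  x <- audio$samples
  n <- length(x)
  bytes_per <- bits %/% 8L
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(as.integer(audio$sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(audio$sample_rate * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(bytes_per), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.double(x), con, size = 4, endian = "little")
  }
  invisible(path)
}
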