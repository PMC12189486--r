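# Minimal mono WAV I/O (RIFF/WAVE, PCM 16-bit or IEEE float32).
# Single-cycle PCG recordings are stored one per file.

#' Write a mono waveform to a WAV file
#'
#' @param waveform numeric vector of samples in `[-1, 1]`.
#' @param path output file path.
#' @param sampling_rate samples per second.
#' @param format `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sampling_rate, format = c("pcm16", "float32")) {
  format <- match.arg(format)
  stopifnot(is.numeric(waveform), length(waveform) > 0, sampling_rate > 0)
  n <- length(waveform)
  if (format == "pcm16") {
    bits <- 16L; audio_fmt <- 1L
    data_size <- 2L * n
  } else {
    bits <- 32L; audio_fmt <- 3L
    data_size <- 4L * n
  }
  block_align <- as.integer(bits / 8)
  con <- file(path, "wb")
  on.exit(close(con))
  w32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  w32(36L + data_size)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  w32(16L)
  w16(audio_fmt)
  w16(1L) # mono
  w32(as.integer(sampling_rate))
  w32(as.integer(sampling_rate) * block_align)
  w16(block_align)
  w16(bits)
  writeChar("data", con, eos = NULL)
  w32(data_size)
  if (format == "pcm16") {
    q <- as.integer(round(clamp(waveform, -1, 1) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(as.numeric(waveform), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' @param path WAV file written by [write_wav()] or any mono PCM16/float32
#'   RIFF file.
#' @return list with `waveform` (numeric, in `[-1, 1]` for PCM) and
#'   `sampling_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  r32 <- function() readBin(con, "integer", size = 4, endian = "little")
  r16 <- function() readBin(con, "integer", size = 2, endian = "little")
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path)
  r32()
  if (!identical(readChar(con, 4), "WAVE")) stop("not a RIFF/WAVE file: ", path)
  audio_fmt <- NULL; sr <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- r32()
    if (id == "fmt ") {
      audio_fmt <- r16(); channels <- r16(); sr <- r32(); r32(); r16()
      bits <- r16()
      if (size > 16) readBin(con, "raw", n = size - 16)
      if (channels != 1L) stop("only mono WAV supported")
    } else if (id == "data") {
      if (is.null(audio_fmt)) stop("malformed WAV: data before fmt")
      if (audio_fmt == 1L && bits == 16L) {
        samples <- readBin(con, "integer", n = size / 2, size = 2,
                           endian = "little") / 32767
      } else if (audio_fmt == 3L && bits == 32L) {
        samples <- readBin(con, "numeric", n = size / 4, size = 4,
                           endian = "little")
      } else {
        stop("unsupported WAV encoding (fmt ", audio_fmt, ", ", bits, " bit)")
      }
      break
    } else {
      readBin(con, "raw", n = size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  list(waveform = samples, sampling_rate = sr)
}
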