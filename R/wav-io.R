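# Minimal single-channel RIFF/WAVE reader and writer covering the two
# encodings the pipeline emits: PCM 16-bit integer and IEEE float32.
# Amplitudes are normalized to [-1, 1] on both paths.

#' Write an AudioRecording to a WAV file
#'
#' Writes mono PCM 16-bit (clipped to \[-1, 1\]) or IEEE float32.
#'
#' @param audio an [AudioRecording].
#' @param path output file path.
#' @param format `"pcm16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
writeWav <- function(audio, path, format = c("pcm16", "float32")) {
  stopifnot(is(audio, "AudioRecording"))
  format <- match.arg(format)
  x <- audioSamples(audio)
  fs <- as.integer(round(sampleRate(audio)))
  con <- file(path, "wb")
  on.exit(close(con))
  bits <- if (format == "pcm16") 16L else 32L
  bytesPerSample <- bits %/% 8L
  dataSize <- length(x) * bytesPerSample
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + dataSize), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  audioFormat <- if (format == "pcm16") 1L else 3L
  writeBin(audioFormat, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")          # mono
  writeBin(fs, con, size = 4, endian = "little")
  writeBin(as.integer(fs * bytesPerSample), con, size = 4,
           endian = "little")                             # byte rate
  writeBin(as.integer(bytesPerSample), con, size = 2, endian = "little")
  writeBin(bits, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(dataSize), con, size = 4, endian = "little")
  if (format == "pcm16") {
    q <- as.integer(round(pmax(-1, pmin(1, x)) * 32767))
    writeBin(q, con, size = 2, endian = "little")
  } else {
    writeBin(x, con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file into an AudioRecording
#'
#' Supports mono or multi-channel (first channel kept) PCM 16/24-bit and
#' IEEE float32 files.
#'
#' @param path WAV file path.
#' @return An [AudioRecording]; PCM samples are scaled to \[-1, 1\].
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  if (!identical(readChar(con, 4), "WAVE")) stop("not a WAVE file: ", path)
  fmt <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0L || nchar(id) < 4L) stop("no data chunk in ", path)
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, size = 2, endian = "little"),
        rate = readBin(raw[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, size = 2, endian = "little"))
    } else if (identical(id, "data")) {
      if (is.null(fmt)) stop("data chunk before fmt chunk in ", path)
      nch <- fmt$channels
      if (fmt$format == 3L && fmt$bits == 32L) {
        x <- readBin(con, "numeric", size = 4, n = size %/% 4,
                     endian = "little")
      } else if (fmt$format == 1L && fmt$bits == 16L) {
        x <- readBin(con, "integer", size = 2, n = size %/% 2,
                     endian = "little") / 32767
      } else if (fmt$format == 1L && fmt$bits == 24L) {
        raw <- readBin(con, "raw", size)
        n <- length(raw) %/% 3L
        b1 <- as.integer(raw[seq(1L, by = 3L, length.out = n)])
        b2 <- as.integer(raw[seq(2L, by = 3L, length.out = n)])
        b3 <- as.integer(raw[seq(3L, by = 3L, length.out = n)])
        v <- b1 + 256L * b2 + 65536L * b3
        v <- ifelse(v >= 8388608, v - 16777216, v)
        x <- v / 8388607
      } else {
        stop("unsupported WAV encoding (format ", fmt$format, ", ",
             fmt$bits, " bit)")
      }
      if (nch > 1L) x <- x[seq(1L, length(x), by = nch)]
      return(audioRecording(x, fmt$rate))
    } else {
      invisible(readBin(con, "raw", size + size %% 2L))
    }
  }
}
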