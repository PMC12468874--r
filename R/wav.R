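#' Read a WAV file
#'
#' Minimal RIFF/WAVE reader covering the encodings found in heart-sound
#' archives: integer PCM (8/16/24/32 bit) and IEEE float (32/64 bit).
#' Chunks other than \code{fmt } and \code{data} are skipped.
#'
#' @param path Path to a \code{.wav} file.
#' @return A list with \code{samples} (numeric matrix, one column per
#'   channel, amplitudes in \eqn{[-1, 1]} for integer PCM) and
#'   \code{rate} (sampling rate in Hz).
#' @seealso [write_wav()]
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop("WAV file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")   # total size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (length(size) == 0) break
    if (identical(id, "fmt ")) {
      fmt_raw <- readBin(con, "raw", size)
      fmt <- list(
        format   = readBin(fmt_raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels = readBin(fmt_raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate     = readBin(fmt_raw[5:8], "integer", 1, 4, endian = "little"),
        bits     = readBin(fmt_raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))       # chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) stop("no fmt chunk in ", path)
  if (is.null(data_raw) || length(data_raw) == 0) stop("no audio payload in ", path)

  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real format in a sub-chunk we
  # do not parse; the PCM layouts below still apply for the common cases.
  samples <- switch(
    as.character(fmt$bits),
    "8"  = (as.numeric(readBin(data_raw, "integer", length(data_raw), 1,
                               signed = FALSE)) - 128) / 128,
    "16" = readBin(data_raw, "integer", length(data_raw) %/% 2L, 2,
                   signed = TRUE, endian = "little") / 32768,
    "24" = .pcm24_to_num(data_raw),
    "32" = if (fmt$format == 3L) {
      readBin(data_raw, "double", length(data_raw) %/% 4L, 4, endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) %/% 4L, 4,
              endian = "little") / 2147483648
    },
    "64" = readBin(data_raw, "double", length(data_raw) %/% 8L, 8, endian = "little"),
    stop("unsupported WAV bit depth: ", fmt$bits)
  )
  n <- length(samples) %/% fmt$channels
  if (n == 0L) stop("zero-length WAV payload in ", path)
  samples <- matrix(samples[seq_len(n * fmt$channels)],
                    ncol = fmt$channels, byrow = TRUE)
  if (any(!is.finite(samples))) stop("non-finite samples in ", path)
  list(samples = samples, rate = fmt$rate)
}

.pcm24_to_num <- function(raw) {
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(n * 3L)]), nrow = 3L)
  v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388608
}

#' Write a mono or multi-channel WAV file (16-bit PCM)
#'
#' @param samples Numeric vector or matrix (one column per channel);
#'   values are clipped to \eqn{[-1, 1]} before quantisation.
#' @param rate Sampling rate in Hz.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_wav <- function(samples, rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  stopifnot(is.numeric(samples), length(samples) > 0, rate > 0)
  q <- pmin(pmax(samples, -1), 32767 / 32768)
  pcm <- as.integer(round(t(q) * 32768))            # interleave channels
  n_bytes <- length(pcm) * 2L
  ch <- ncol(samples)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + n_bytes), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(c(1L, ch), con, 2, endian = "little")    # PCM, channels
  writeBin(as.integer(rate), con, 4, endian = "little")
  writeBin(as.integer(rate * ch * 2L), con, 4, endian = "little")
  writeBin(c(as.integer(ch * 2L), 16L), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(n_bytes, con, 4, endian = "little")
  writeBin(pcm, con, 2, endian = "little")
  invisible(path)
}
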