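#' STFT configuration
#'
#' Settings for the short-time Fourier transform used to build
#' spectrogram images. Defaults follow the study configuration for
#' 2000 Hz phonocardiograms: a 400-sample Hamming window with 50
#' samples of overlap.
#'
#' The printed setting "FFT size 50" alongside a 400-sample window is
#' ill-defined for a standard STFT (fewer transform points than window
#' samples). The default therefore uses `fft_length = window_length`;
#' setting `matlab_truncate = TRUE` reproduces the truncating behaviour
#' (each windowed frame cut to `fft_length` samples before the DFT).
#'
#' @param window_length Window size in samples.
#' @param overlap Overlapping samples between consecutive frames;
#'   must satisfy `0 <= overlap < window_length`.
#' @param fft_length DFT length; defaults to `window_length`.
#' @param matlab_truncate Truncate windowed frames to `fft_length`
#'   samples when `fft_length < window_length` instead of erroring.
#' @param freq_normalization `"normalized_radians"` labels the frequency
#'   axis in radians/sample (pi at Nyquist); `"hertz"` labels it in Hz.
#'   Axis labelling only — pixel values are unaffected.
#' @return An `stft_config` list.
#' @export
stft_config <- function(window_length = 400L, overlap = 50L,
                        fft_length = NULL, matlab_truncate = FALSE,
                        freq_normalization = c("normalized_radians", "hertz")) {
  freq_normalization <- match.arg(freq_normalization)
  window_length <- as.integer(window_length)
  overlap <- as.integer(overlap)
  if (is.null(fft_length)) fft_length <- window_length
  fft_length <- as.integer(fft_length)
  stopifnot(window_length >= 2L, overlap >= 0L, fft_length >= 1L)
  if (overlap >= window_length) stop("overlap must be < window_length")
  if (fft_length < window_length && !matlab_truncate) {
    stop("fft_length < window_length is only meaningful with matlab_truncate = TRUE")
  }
  structure(list(window_kind = "hamming", window_length = window_length,
                 overlap = overlap, fft_length = fft_length,
                 matlab_truncate = matlab_truncate,
                 freq_normalization = freq_normalization),
            class = "stft_config")
}

# MATLAB-convention periodic-symmetric Hamming window of length n.
.hamming <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' STFT magnitude grid of a PCG record
#'
#' Slides a Hamming window over the signal with hop
#' `window_length - overlap` and returns the one-sided DFT magnitude of
#' each frame. Frame count is
#' `floor((L - window_length) / hop) + 1`; the trailing partial frame is
#' dropped.
#'
#' @param record A [pcg_record()] (or plain numeric vector).
#' @param cfg An [stft_config()].
#' @return Matrix of non-negative magnitudes, `floor(fft_length/2)+1`
#'   frequency rows by one column per frame, with attributes
#'   `time_step` (s) and `freq_step` (unit per `freq_normalization`).
#' @export
stft_magnitude <- function(record, cfg = stft_config()) {
  x <- if (inherits(record, "pcg_record")) record$samples else as.numeric(record)
  rate <- if (inherits(record, "pcg_record")) record$rate else PCG_RATE
  id <- if (inherits(record, "pcg_record")) record$id else "<vector>"
  L <- length(x)
  win <- cfg$window_length
  if (L < win) {
    stop(sprintf("record %s has %d samples, shorter than one %d-sample window",
                 id, L, win))
  }
  hop <- win - cfg$overlap
  n_frames <- (L - win) %/% hop + 1L
  w <- .hamming(win)
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) x[(s + 1L):(s + win)] * w,
                   numeric(win))
  nfft <- cfg$fft_length
  if (nfft < win) {
    frames <- frames[seq_len(nfft), , drop = FALSE]     # matlab_truncate mode
  } else if (nfft > win) {
    frames <- rbind(frames, matrix(0, nfft - win, n_frames))
  }
  spec <- Mod(stats::mvfft(frames))[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  fstep <- if (cfg$freq_normalization == "hertz") rate / nfft else 2 * pi / nfft
  structure(spec, time_step = hop / rate, freq_step = fstep, source_id = id)
}

#' Convert a magnitude grid to a fixed-size spectrogram image
#'
#' Applies a decibel transform (`20*log10(mag + 1e-10)` by default),
#' rescales the image to `[0, 1]` by its own min-max range, and resizes
#' to `out_size` x `out_size` with bilinear interpolation. Under the dB
#' + min-max combination the image is invariant to any constant gain
#' applied to the input signal.
#'
#' @param grid Magnitude matrix from [stft_magnitude()].
#' @param out_size Output side length in pixels (default 200).
#' @param scale `"db"` (default) or `"linear"`.
#' @return A `spectrogram_image`: `out_size` x `out_size` matrix in
#'   `[0, 1]`, frequency along rows (low at row 1), time along columns.
#' @export
to_image <- function(grid, out_size = 200L, scale = c("db", "linear")) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(grid), length(grid) > 0)
  g <- if (scale == "db") 20 * log10(grid + 1e-10) else grid
  rng <- range(g)
  if (rng[2] - rng[1] <= .Machine$double.eps * max(1, abs(rng[2]))) {
    warning("degenerate spectrogram (constant magnitude); returning uniform image")
    g[] <- 0.5
  } else {
    g <- (g - rng[1]) / (rng[2] - rng[1])
  }
  img <- as.matrix(EBImage::imageData(EBImage::resize(g, w = out_size, h = out_size)))
  img <- matrix(pmin(pmax(img, 0), 1), out_size, out_size)
  structure(img, source_id = attr(grid, "source_id"), class = "spectrogram_image")
}

#' @export
print.spectrogram_image <- function(x, ...) {
  cat(sprintf("<spectrogram_image> %s: %dx%d, range [%.3f, %.3f]\n",
              attr(x, "source_id") %||% "?", nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spectrogram of one record in one call
#' @param record A [pcg_record()].
#' @param cfg An [stft_config()].
#' @param out_size Image side length (default 200).
#' @return A `spectrogram_image`.
#' @export
record_to_image <- function(record, cfg = stft_config(), out_size = 200L) {
  to_image(stft_magnitude(record, cfg), out_size = out_size)
}

#' Convert every record of a manifest to a spectrogram image
#'
#' Per-record failures are collected and reported at the end; the run
#' continues past them. Output is deterministic given the inputs.
#'
#' @param manifest A `pcg_manifest` (or a list of [pcg_record()]s).
#' @param cfg An [stft_config()].
#' @param out_size Image side length.
#' @param out_dir Optional directory: images are written as `.rds`
#'   arrays plus an `index.csv` (id, image path, label) and, when
#'   `png = TRUE`, 8-bit grayscale PNGs for inspection.
#' @param png Also write PNG renderings (requires `out_dir`).
#' @return Invisibly, a list with `images` (named list of matrices),
#'   `index` (data frame id/label), and `failures` (named character
#'   vector of error messages).
#' @export
batch_convert <- function(manifest, cfg = stft_config(), out_size = 200L,
                          out_dir = NULL, png = FALSE) {
  recs <- if (inherits(manifest, "pcg_manifest")) {
    lapply(seq_len(nrow(manifest)), function(i) {
      list(loader = function() read_record(manifest$path[i],
                                           label = as.character(manifest$label[i]),
                                           id = manifest$id[i]))
    })
  } else {
    lapply(manifest, function(r) list(loader = function() r))
  }
  images <- list(); labels <- character(); failures <- character()
  for (entry in recs) {
    rec <- try(entry$loader(), silent = TRUE)
    img <- if (inherits(rec, "try-error")) rec else
      try(record_to_image(rec, cfg, out_size), silent = TRUE)
    if (inherits(img, "try-error")) {
      rid <- if (inherits(rec, "pcg_record")) rec$id else "<unreadable>"
      failures[rid] <- conditionMessage(attr(img, "condition"))
    } else {
      images[[rec$id]] <- img
      labels[rec$id] <- as.character(rec$label)
    }
  }
  index <- data.frame(id = names(images), label = unname(labels),
                      stringsAsFactors = FALSE)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, paste0(index$id, ".rds"))
    for (i in seq_along(images)) saveRDS(images[[i]], paths[i])
    if (png) {
      for (i in seq_along(images)) {
        png::writePNG(images[[i]],
                      file.path(out_dir, paste0(index$id[i], ".png")))
      }
    }
    utils::write.csv(cbind(index, path = paths),
                     file.path(out_dir, "index.csv"), row.names = FALSE)
  }
  if (length(failures)) {
    message(length(failures), " of ", length(recs),
            " records failed spectrogram conversion: ",
            paste(names(failures), collapse = ", "))
  }
  invisible(list(images = images, index = index, failures = failures))
}
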