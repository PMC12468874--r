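#' @keywords internal
"_PACKAGE"

# Sampling-rate contract for ingested phonocardiograms (Hz).
PCG_RATE <- 2000L

.default_label_aliases <- c(
  "healthy"   = "healthy",
  "unhealthy" = "unhealthy",
  "normal"    = "healthy",
  "-1"        = "healthy",
  "1"         = "unhealthy"
)

.normalize_labels <- function(labels, aliases = .default_label_aliases,
                              context = "manifest") {
  key <- tolower(trimws(as.character(labels)))
  mapped <- unname(aliases[key])
  bad <- which(is.na(mapped))
  if (length(bad)) {
    stop(sprintf("unknown label '%s' in %s row %d (allowed: %s)",
                 labels[bad[1]], context, bad[1],
                 paste(unique(names(aliases)), collapse = ", ")))
  }
  factor(mapped, levels = c("healthy", "unhealthy"))
}

#' Construct a PCG record
#'
#' A `pcg_record` holds one labelled heart-sound signal: dimensionless
#' amplitude samples, a sampling rate, and a class label.
#'
#' @param id Record identifier (string).
#' @param samples Numeric vector of amplitudes; must be finite.
#' @param rate Sampling rate in samples/second.
#' @param label `"healthy"`, `"unhealthy"`, or `NA` for unlabelled data.
#' @return An object of class `pcg_record`.
#' @export
pcg_record <- function(id, samples, rate, label = NA) {
  stopifnot(is.character(id), length(id) == 1L, is.numeric(samples), rate > 0)
  if (any(!is.finite(samples))) stop("record ", id, " contains non-finite samples")
  dur <- length(samples) / rate
  if (dur < 0.2 || dur > 120) {
    stop(sprintf("record %s duration %.3f s outside the supported 0.2-120 s range",
                 id, dur))
  }
  lab <- if (is.na(label[1])) factor(NA, levels = c("healthy", "unhealthy"))
         else .normalize_labels(label, context = paste0("record ", id))
  structure(list(id = id, samples = as.numeric(samples),
                 rate = as.integer(rate), label = lab),
            class = "pcg_record")
}

#' @export
print.pcg_record <- function(x, ...) {
  cat(sprintf("<pcg_record> %s: %.2f s @ %d Hz, label %s\n",
              x$id, length(x$samples) / x$rate, x$rate,
              as.character(x$label)))
  invisible(x)
}

#' Load a label manifest
#'
#' Reads a CSV with header columns `filename,label` describing a labelled
#' PCG dataset. Labels are case-insensitive; the PhysioNet-style aliases
#' `-1` (healthy) and `1` (unhealthy) are accepted by default.
#'
#' @param path Path to the manifest CSV.
#' @param base_dir Directory WAV paths are resolved against (defaults to
#'   the manifest's own directory).
#' @param check_files If `TRUE` (default), fail when a listed file is
#'   missing.
#' @param aliases Named character vector mapping accepted label strings
#'   to `"healthy"`/`"unhealthy"`.
#' @return A `pcg_manifest`: data frame of (`id`, `path`, `label`) with a
#'   `class_counts` attribute.
#' @export
load_manifest <- function(path, base_dir = dirname(path), check_files = TRUE,
                          aliases = .default_label_aliases) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "label")
  if (!all(need %in% names(df))) {
    stop("manifest must have header columns 'filename,label'; found: ",
         paste(names(df), collapse = ","))
  }
  if (nrow(df) == 0L) {
    warning("manifest ", path, " lists no recordings")
    out <- data.frame(id = character(), path = character(),
                      label = factor(character(),
                                     levels = c("healthy", "unhealthy")))
    attr(out, "class_counts") <- c(healthy = 0L, unhealthy = 0L)
    class(out) <- c("pcg_manifest", "data.frame")
    return(out)
  }
  label <- .normalize_labels(df$label, aliases, context = basename(path))
  full <- ifelse(grepl("^(/|[A-Za-z]:)", df$filename), df$filename,
                 file.path(base_dir, df$filename))
  id <- tools::file_path_sans_ext(basename(df$filename))
  dup <- duplicated(id)
  if (any(dup)) stop("duplicate record id in manifest: ", id[which(dup)[1]])
  if (check_files) {
    missing <- !file.exists(full)
    if (any(missing)) {
      stop(sprintf("manifest row %d: file not found: %s",
                   which(missing)[1], full[which(missing)[1]]))
    }
  }
  out <- data.frame(id = id, path = full, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "class_counts") <- c(
    healthy   = sum(label == "healthy"),
    unhealthy = sum(label == "unhealthy")
  )
  class(out) <- c("pcg_manifest", "data.frame")
  out
}

#' Class counts of a manifest
#' @param manifest A `pcg_manifest`.
#' @return Named integer vector (`healthy`, `unhealthy`).
#' @export
class_counts <- function(manifest) attr(manifest, "class_counts")

#' Read one PCG recording
#'
#' Reads a WAV file, averages stereo channels to mono, and resamples to
#' `target_rate` with a polyphase anti-aliasing filter when the source
#' rate differs. Amplitudes are otherwise left untouched; normalisation
#' belongs to the spectrogram stage.
#'
#' @param path WAV path.
#' @param target_rate Required rate after ingestion (default 2000 Hz).
#' @param id Record id (default: file name without extension).
#' @param label Optional class label.
#' @return A [pcg_record()].
#' @export
read_record <- function(path, target_rate = PCG_RATE,
                        id = tools::file_path_sans_ext(basename(path)),
                        label = NA) {
  wav <- read_wav(path)
  x <- rowMeans(wav$samples)
  if (wav$rate != target_rate) {
    g <- .gcd(as.integer(target_rate), as.integer(wav$rate))
    x <- as.numeric(signal::resample(x, target_rate %/% g, wav$rate %/% g))
  }
  pcg_record(id, x, target_rate, label)
}

.gcd <- function(a, b) if (b == 0L) a else .gcd(b, a %% b)

#' Write a PCG record to a 16-bit WAV file
#' @param record A [pcg_record()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_record <- function(record, path) {
  stopifnot(inherits(record, "pcg_record"))
  write_wav(record$samples, record$rate, path)
}

#' Stratified train/validation split of a manifest
#'
#' @param manifest A `pcg_manifest`.
#' @param val_frac Fraction of each class held out for validation.
#' @param seed RNG seed for the shuffle.
#' @return List of two `pcg_manifest`s, `train` and `val`.
#' @export
split_manifest <- function(manifest, val_frac = 0.1, seed = 1L) {
  stopifnot(val_frac >= 0, val_frac < 1)
  set.seed(seed)
  val_idx <- unlist(lapply(levels(manifest$label), function(lv) {
    idx <- which(manifest$label == lv)
    sample(idx, size = floor(length(idx) * val_frac))
  }))
  keep_attrs <- function(df) {
    attr(df, "class_counts") <- c(healthy = sum(df$label == "healthy"),
                                  unhealthy = sum(df$label == "unhealthy"))
    class(df) <- c("pcg_manifest", "data.frame")
    df
  }
  list(train = keep_attrs(manifest[setdiff(seq_len(nrow(manifest)), val_idx), ]),
       val   = keep_attrs(manifest[sort(val_idx), ]))
}
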