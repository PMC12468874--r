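#' Fit the full heart-sound classification pipeline
#'
#' Runs the five stages end-to-end on labelled PCG recordings:
#' spectrogram conversion, network training, deep-feature extraction
#' from the last ReLU layer, NCA/ReliefF intersection feature
#' selection, and polynomial-SVM evaluation under repeated stratified
#' cross-validation. A final SVM is also fit on all samples so the
#' returned object can classify new recordings via [predict.pcgmixer()].
#'
#' @param records A `pcg_manifest` from [load_manifest()], a list of
#'   [pcg_record()]s, the output of [generate_pcg_dataset()], or a
#'   [synth_config()] (generated on the fly).
#' @param stft An [stft_config()].
#' @param image_size Spectrogram side length in pixels.
#' @param net A [ramm_config()]; its `input_size` must equal
#'   `image_size`.
#' @param train A [train_config()].
#' @param top_x Top feature indices taken from each weight ranking.
#' @param svm An [svm_config()].
#' @param folds,repeats Cross-validation protocol.
#' @param nca_args,relieff_args Extra arguments passed to
#'   [nca_weights()] / [relieff_weights()].
#' @param seed Master seed, propagated to every stochastic stage.
#' @param run_dir Optional directory for artifacts (feature matrix,
#'   weights, matched indices, history, metrics JSON, checkpoint).
#' @param features Optional precomputed `feature_matrix` (skips the
#'   spectrogram and network stages, e.g. to resume a run).
#' @param verbose Print stage progress.
#' @return An object of class `pcgmixer`; see [summary.pcgmixer()].
#' @export
pcgmixer <- function(records, stft = stft_config(), image_size = 200L,
                     net = NULL, train = NULL, top_x = 300L,
                     svm = svm_config(), folds = 10L, repeats = 1L,
                     nca_args = list(), relieff_args = list(),
                     seed = 1L, run_dir = NULL, features = NULL,
                     verbose = FALSE) {
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(run_dir)) dir.create(run_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  if (inherits(records, "synth_config")) {
    say("stage 0/5: generating %d synthetic records",
        records$n_healthy + records$n_unhealthy)
    records <- generate_pcg_dataset(records)
  }

  model <- NULL
  if (is.null(features)) {
    say("stage 1/5: spectrograms")
    conv <- batch_convert(records_or_manifest(records), stft,
                          out_size = image_size)
    if (length(conv$failures)) {
      stop("spectrogram stage failed for: ",
           paste(names(conv$failures), collapse = ", "))
    }
    images <- conv$images
    labels <- factor(conv$index$label, levels = c("healthy", "unhealthy"))
    ids <- conv$index$id
    if (is.null(net)) net <- ramm_config(input_size = image_size)
    if (net$input_size != image_size) {
      stop("net$input_size (", net$input_size, ") != image_size (",
           image_size, ")")
    }
    if (is.null(train)) train <- train_config(seed = seed)
    say("stage 2/5: training network (%d epochs)", train$epochs)
    model <- build_ramm(net, seed = seed)
    model <- train_ramm(model, images, labels, train, verbose = verbose)
    say("stage 3/5: extracting %d features per record", net$feature_dim)
    features <- extract_features(model, images, ids = ids, labels = labels)
    if (!is.null(run_dir)) save_ramm(model, file.path(run_dir, "checkpoint.rds"))
  } else {
    labels <- attr(features, "labels")
    if (is.null(labels)) stop("precomputed features need a 'labels' attribute")
    labels <- factor(as.character(labels), levels = c("healthy", "unhealthy"))
    ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  }

  say("stage 4/5: feature weighting and intersection selection (top_x = %d)",
      top_x)
  w_nca <- do.call(nca_weights,
                   c(list(X = features, y = labels, seed = seed), nca_args))
  if (is.null(relieff_args$k)) {
    # default neighbour count, capped so the smallest class stays legal
    relieff_args$k <- max(1L, min(10L, min(table(labels)) - 1L))
  }
  w_rel <- do.call(relieff_weights,
                   c(list(X = features, y = labels, seed = seed),
                     relieff_args))
  sel <- nrbmi_select(w_nca, w_rel, top_x = min(top_x, ncol(features)))
  keep <- if (length(sel$matched_indices)) sel$matched_indices else
    sel$top_nca
  Xsel <- as.matrix(features)[, keep, drop = FALSE]

  say("stage 5/5: %d-fold SVM cross-validation x %d repeat(s) on %d features",
      folds, repeats, ncol(Xsel))
  cv <- cross_validate(Xsel, labels, svm, folds = folds, repeats = repeats,
                       seed = seed)
  final_svm <- .fit_svm(Xsel, labels, svm)

  fit <- structure(list(
    call = match.call(), seed = seed,
    stft = stft, image_size = image_size, net = model$cfg, train = train,
    svm = svm, top_x = top_x, folds = folds, repeats = repeats,
    model = model, features = features, labels = labels, ids = ids,
    w_nca = w_nca, w_relief = w_rel, selection = sel,
    selected_indices = keep, cv = cv, final_svm = final_svm,
    elapsed = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  ), class = "pcgmixer")
  if (!is.null(run_dir)) .write_run_artifacts(fit, run_dir)
  fit
}

records_or_manifest <- function(records) {
  if (inherits(records, "pcg_manifest")) return(records)
  if (is.list(records) && !is.null(records$records)) return(records$records)
  records
}

.write_run_artifacts <- function(fit, run_dir) {
  utils::write.csv(data.frame(id = fit$ids, label = fit$labels,
                              as.data.frame(unclass(fit$features))),
                   file.path(run_dir, "features.csv"), row.names = FALSE)
  write_selection(fit$selection, file.path(run_dir, "weights.csv"),
                  file.path(run_dir, "matched_indices.csv"))
  if (!is.null(fit$model$history)) {
    utils::write.csv(fit$model$history, file.path(run_dir, "history.csv"),
                     row.names = FALSE)
  }
  metrics <- list(
    accuracy_mean = fit$cv$mean_accuracy,
    accuracy_sd = fit$cv$sd_accuracy,
    accuracies = fit$cv$accuracies,
    n_selected = length(fit$selected_indices),
    per_class = fit$cv$metrics,
    confusion = fit$cv$confusions[[1]],
    seed = fit$seed
  )
  jsonlite::write_json(metrics, file.path(run_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg_echo <- utils::capture.output({
    print(fit$stft); print(fit$net); print(fit$train); print(fit$svm)
  })
  writeLines(c(sprintf("seed: %d", fit$seed),
               sprintf("top_x: %d", fit$top_x),
               sprintf("folds: %d  repeats: %d", fit$folds, fit$repeats),
               cfg_echo),
             file.path(run_dir, "config.txt"))
  invisible(run_dir)
}

#' @export
print.pcgmixer <- function(x, ...) {
  cat(sprintf(paste0(
    "Heart-sound classification pipeline (pcgmixer)\n",
    "  records: %d (%d healthy / %d unhealthy)\n",
    "  features: %d extracted -> %d selected (top_x = %d per ranking)\n",
    "  CV accuracy: %.2f%% (sd %.2f, %d-fold x %d repeat%s)\n"),
    length(x$labels), sum(x$labels == "healthy"),
    sum(x$labels == "unhealthy"),
    ncol(x$features), length(x$selected_indices), x$top_x,
    x$cv$mean_accuracy, x$cv$sd_accuracy, x$folds, x$repeats,
    if (x$repeats > 1) "s" else ""))
  invisible(x)
}

#' Summarise a fitted pipeline
#'
#' Prints the per-class metric table (sensitivity, specificity,
#' precision, F1, percent to two decimals) and, for repeated CV, the
#' per-run accuracy table in blocks of ten runs with mean and standard
#' deviation.
#'
#' @param object A `pcgmixer` fit.
#' @param ... Unused.
#' @return Invisibly, a list with `metrics`, `accuracies`,
#'   `accuracy_table`.
#' @export
summary.pcgmixer <- function(object, ...) {
  print(object)
  cat("\nPer-class metrics (first repeat, pooled confusion matrix):\n")
  print(object$cv$metrics, row.names = FALSE)
  acc_tab <- accuracy_table(object$cv$accuracies)
  if (object$repeats > 1) {
    cat("\nPer-run CV accuracies (%):\n")
    print(acc_tab, row.names = FALSE)
  }
  cat(sprintf("\nMean accuracy %.2f%%, sd %.2f\n",
              object$cv$mean_accuracy, object$cv$sd_accuracy))
  invisible(list(metrics = object$cv$metrics,
                 accuracies = object$cv$accuracies,
                 accuracy_table = acc_tab))
}

#' Per-run accuracy table in blocks of ten
#' @param accs Numeric vector of per-run accuracies (percent).
#' @return Data frame with one column per block of ten runs.
#' @export
accuracy_table <- function(accs) {
  n <- length(accs)
  blocks <- split(accs, (seq_len(n) - 1L) %/% 10L)
  width <- max(lengths(blocks))
  cols <- lapply(blocks, function(b) round2(c(b, rep(NA, width - length(b)))))
  names(cols) <- vapply(seq_along(blocks), function(i)
    sprintf("%d-%d", (i - 1L) * 10L + 1L,
            min(i * 10L, n)), "")
  as.data.frame(cols, check.names = FALSE)
}

#' Classify new PCG recordings with a fitted pipeline
#'
#' @param object A `pcgmixer` fit (must contain a trained network, i.e.
#'   not fitted from precomputed features).
#' @param newrecords A list of [pcg_record()]s, a `pcg_manifest`, or
#'   the output of [generate_pcg_dataset()].
#' @param ... Unused.
#' @return Data frame with `id`, `predicted` and the class
#'   probabilities from the network head (`prob_healthy`,
#'   `prob_unhealthy`); `predicted` comes from the SVM on selected
#'   features.
#' @export
predict.pcgmixer <- function(object, newrecords, ...) {
  if (is.null(object$model)) {
    stop("this fit was built from precomputed features; no network ",
         "is available to embed new recordings")
  }
  conv <- batch_convert(records_or_manifest(newrecords), object$stft,
                        out_size = object$image_size)
  if (length(conv$failures)) {
    stop("spectrogram conversion failed for: ",
         paste(names(conv$failures), collapse = ", "))
  }
  out <- ramm_forward(object$model, conv$images)
  Xsel <- out$features[, object$selected_indices, drop = FALSE]
  pred <- stats::predict(object$final_svm, Xsel)
  data.frame(id = conv$index$id, predicted = pred,
             prob_healthy = out$probs[, 1], prob_unhealthy = out$probs[, 2])
}

#' Plot training history of a fitted pipeline
#' @param x A `pcgmixer` fit with a trained network.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.pcgmixer <- function(x, ...) {
  h <- x$model$history
  if (is.null(h)) stop("no training history to plot")
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(h$epoch, h$train_acc, type = "l", xlab = "epoch",
                 ylab = "accuracy", main = "training accuracy", ...)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy", main = "training loss", ...)
  invisible(x)
}
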