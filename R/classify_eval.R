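#' Support-vector-machine configuration
#'
#' The study's classifier is a polynomial-kernel SVM; degree 3 and
#' `C = 1` are the conventional defaults (only the kernel family is
#' prescribed).
#'
#' @param kernel `"polynomial"` (default), `"radial"` or `"linear"`.
#' @param poly_degree Polynomial degree (>= 1).
#' @param cost Box constraint C (> 0).
#' @param standardize Scale features to zero mean / unit variance
#'   inside the SVM.
#' @return An `svm_config` list.
#' @export
svm_config <- function(kernel = c("polynomial", "radial", "linear"),
                       poly_degree = 3L, cost = 1, standardize = TRUE) {
  kernel <- match.arg(kernel)
  stopifnot(poly_degree >= 1L, cost > 0)
  structure(list(kernel = kernel, poly_degree = as.integer(poly_degree),
                 cost = cost, standardize = isTRUE(standardize)),
            class = "svm_config")
}

.fit_svm <- function(X, y, cfg) {
  # suppress e1071's per-fold "cannot scale" notes for constant columns
  # (dead ReLU features); they are left unscaled, which is correct here
  suppressWarnings(
    e1071::svm(X, y, type = "C-classification", kernel = cfg$kernel,
               degree = cfg$poly_degree, cost = cfg$cost,
               scale = cfg$standardize, coef0 = 1)
  )
}

# Stratified fold assignment: within each class, shuffled samples are
# dealt round-robin into folds.
.stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  assign <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    if (length(idx) < folds) {
      stop("class '", lv, "' has ", length(idx),
           " samples, fewer than ", folds, " folds")
    }
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Repeated stratified k-fold cross-validation of an SVM
#'
#' For each repeat, samples are partitioned into stratified folds,
#' every sample is predicted exactly once by a model trained on the
#' remaining folds, and the pooled confusion matrix is recorded.
#'
#' @param X Feature matrix (samples x features).
#' @param y Class labels (factor; first level is the reference
#'   "healthy" class in reports).
#' @param cfg An [svm_config()].
#' @param folds Folds per repeat (default 10).
#' @param repeats Repetitions with re-drawn fold assignments
#'   (default 1; the study protocol uses 40).
#' @param seed Base seed; repeat `r` uses `seed + r - 1`.
#' @return A `cv_result`: `confusions` (list of 2x2 matrices, one per
#'   repeat), `accuracies` (% per repeat), `mean_accuracy`,
#'   `sd_accuracy`, `metrics` (per-class [confusion_metrics()] of the
#'   first repeat's pooled matrix), `folds`, `repeats`.
#' @export
cross_validate <- function(X, y, cfg = svm_config(), folds = 10L,
                           repeats = 1L, seed = 1L) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  stopifnot(nrow(X) == length(y), nlevels(y) == 2L, folds >= 2L,
            repeats >= 1L)
  confs <- vector("list", repeats)
  accs <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold_of <- .stratified_folds(y, folds, seed + r - 1L)
    pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
    for (f in seq_len(folds)) {
      test <- fold_of == f
      fit <- .fit_svm(X[!test, , drop = FALSE], y[!test], cfg)
      pred[test] <- stats::predict(fit, X[test, , drop = FALSE])
    }
    cm <- table(true = y, predicted = pred)
    confs[[r]] <- unclass(as.matrix(cm))
    accs[r] <- 100 * sum(diag(cm)) / length(y)
  }
  structure(list(confusions = confs, accuracies = accs,
                 mean_accuracy = mean(accs),
                 sd_accuracy = if (repeats > 1L) stats::sd(accs) else 0,
                 metrics = confusion_metrics_all(confs[[1]]),
                 folds = folds, repeats = repeats, cfg = cfg),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV x %d repeat(s): accuracy %.2f%% (sd %.2f)\n",
              x$folds, x$repeats, x$mean_accuracy, x$sd_accuracy))
  print(x$metrics)
  invisible(x)
}

# Two-decimal half-up rounding, the print convention of the metric tables.
round2 <- function(x) floor(x * 100 + 0.5) / 100

#' Confusion-matrix metrics for one positive class
#'
#' @param cm 2x2 confusion matrix, rows = true class, columns =
#'   predicted class, dimnames giving the class names.
#' @param positive Name of the class treated as positive.
#' @return Named numeric vector (percent, two decimals, half-up):
#'   `sensitivity`, `specificity`, `precision`, `f1`. A metric with a
#'   zero denominator is `NA` (undefined, not 0) with a warning.
#' @export
confusion_metrics <- function(cm, positive) {
  stopifnot(is.matrix(cm), all(dim(cm) == 2L), all(cm >= 0))
  classes <- rownames(cm)
  if (is.null(classes)) classes <- colnames(cm)
  stopifnot(positive %in% classes)
  neg <- setdiff(classes, positive)
  tp <- cm[positive, positive]; fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp; tn <- sum(cm) - tp - fn - fp
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator)")
      return(NA_real_)
    }
    100 * num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  spec <- safe(tn, tn + fp, "specificity")
  prec <- safe(tp, tp + fp, "precision")
  f1 <- if (is.na(prec) || is.na(sens) || prec + sens == 0) {
    warning("F1 undefined"); NA_real_
  } else 2 * prec * sens / (prec + sens)
  round2(c(sensitivity = sens, specificity = spec, precision = prec, f1 = f1))
}

#' Per-class metric table of a 2x2 confusion matrix
#' @param cm 2x2 confusion matrix (true x predicted).
#' @return Data frame, one row per class, in the per-class metric
#'   layout (sensitivity, specificity, precision, F1; percent).
#' @export
confusion_metrics_all <- function(cm) {
  classes <- rownames(cm)
  rows <- lapply(classes, function(cl) {
    m <- confusion_metrics(cm, cl)
    data.frame(class = cl, sensitivity = m["sensitivity"],
               specificity = m["specificity"], precision = m["precision"],
               f1 = m["f1"], row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$accuracy <- round2(100 * sum(diag(cm)) / sum(cm))
  out
}

#' Ablation comparison of feature-selection arms
#'
#' Runs the same paired cross-validation (identical fold assignments,
#' shared seed) on four feature sets: all features, the ReliefF top-x,
#' the NCA top-x, and the NCA/ReliefF intersection, mirroring the
#' selector ablation design.
#'
#' @param X Full feature matrix.
#' @param y Class labels.
#' @param selections Character subset of
#'   `c("none", "relieff", "nca", "nrbmi")`.
#' @param top_x Top indices per ranking.
#' @param cfg An [svm_config()].
#' @param folds,repeats,seed As in [cross_validate()].
#' @param nca_args,relieff_args Extra arguments for the weighting
#'   functions.
#' @return List with `table` (one metric row per arm plus accuracy and
#'   feature count), `results` (per-arm `cv_result`s) and
#'   `fold_assignments` (shared across arms).
#' @export
ablation_suite <- function(X, y, selections = c("none", "relieff", "nca", "nrbmi"),
                           top_x = 300L, cfg = svm_config(), folds = 10L,
                           repeats = 1L, seed = 1L,
                           nca_args = list(), relieff_args = list()) {
  selections <- match.arg(selections, several.ok = TRUE)
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  w_nca <- if (any(selections %in% c("nca", "nrbmi"))) {
    do.call(nca_weights, c(list(X = X, y = y), nca_args))
  }
  w_rel <- if (any(selections %in% c("relieff", "nrbmi"))) {
    do.call(relieff_weights, c(list(X = X, y = y), relieff_args))
  }
  D <- ncol(X)
  top_of <- function(w) order(-w, seq_len(D))[seq_len(min(top_x, D))]
  cols <- list()
  for (s in selections) {
    cols[[s]] <- switch(s,
      none = seq_len(D),
      relieff = top_of(w_rel),
      nca = top_of(w_nca),
      nrbmi = {
        sel <- nrbmi_select(w_nca, w_rel, min(top_x, D))
        if (length(sel$matched_indices) == 0L) top_of(w_nca) else
          sel$matched_indices
      })
  }
  results <- lapply(cols, function(ci)
    cross_validate(X[, ci, drop = FALSE], y, cfg, folds, repeats, seed))
  tab <- do.call(rbind, lapply(names(results), function(s) {
    r <- results[[s]]
    data.frame(arm = s, n_features = length(cols[[s]]),
               accuracy = round2(r$mean_accuracy),
               sensitivity_healthy = r$metrics$sensitivity[1],
               sensitivity_unhealthy = r$metrics$sensitivity[2],
               precision_unhealthy = r$metrics$precision[2])
  }))
  list(table = tab, results = results,
       fold_assignments = lapply(seq_len(repeats), function(r)
         .stratified_folds(y, folds, seed + r - 1L)))
}
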