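#' Feature weights by neighbourhood components analysis (NCA)
#'
#' Diagonal-transform NCA for feature weighting: with one non-negative
#' weight \eqn{w_r} per feature and squared-weight distance
#' \deqn{d_{ij} = \sum_r w_r^2 (x_{ir} - x_{jr})^2,}
#' each point \eqn{i} picks a neighbour \eqn{j} with soft-max
#' probability \eqn{p_{ij} = e^{-d_{ij}} / \sum_{k \ne i} e^{-d_{ik}}},
#' and the weights are chosen by gradient ascent to maximise the
#' expected leave-one-out classification score
#' \eqn{f = \sum_i \sum_{j \in \mathrm{class}(i)} p_{ij}}.
#' A backtracking step-size halving guarantees the objective is
#' non-decreasing across iterations.
#'
#' Features are standardised internally (zero mean, unit variance; a
#' small floor guards zero-variance columns) before the distance is
#' evaluated.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels (factor or vector), at least two classes.
#' @param learning_rate Initial gradient-ascent step size.
#' @param max_iters Maximum gradient iterations.
#' @param lambda Ridge penalty on the squared weights (>= 0).
#' @param tol Stop when the relative objective gain falls below this.
#' @param seed RNG seed (initialisation is deterministic; the seed is
#'   kept for interface symmetry with stochastic selectors).
#' @return Numeric vector of non-negative per-feature weights
#'   (squared diagonal entries, `w_r^2`), with the objective trace in
#'   the `objective` attribute.
#' @export
nca_weights <- function(X, y, learning_rate = 0.1, max_iters = 100L,
                        lambda = 0, tol = 1e-7, seed = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("NCA requires at least two classes")
  n <- nrow(X); D <- ncol(X)
  stopifnot(n >= 2L, learning_rate > 0, max_iters >= 1L, lambda >= 0)

  sds <- apply(X, 2L, stats::sd)
  zero_var <- sds < 1e-12
  if (any(zero_var)) {
    warning(sum(zero_var), " zero-variance feature(s); standardisation guarded")
  }
  Xs <- scale(X, center = TRUE, scale = pmax(sds, 1e-12))
  same <- outer(y, y, "==")
  diag(same) <- FALSE

  w <- rep(1, D)                       # uniform start
  obj_grad <- function(w) {
    w2 <- w * w
    Xw <- sweep(Xs, 2L, w, "*")
    d2 <- as.matrix(stats::dist(Xw))^2
    E <- exp(-d2)
    diag(E) <- 0
    denom <- pmax(rowSums(E), 1e-300)
    P <- E / denom
    f <- sum(P[same]) - lambda * sum(w2)
    # d f / d w_r = -2 w_r * sum_ij alpha_ij (x_ir - x_jr)^2, with
    # alpha_ij = P_ij [j in class(i)] - p_i P_ij, p_i = sum_{j in class(i)} P_ij
    p_i <- rowSums(P * same)
    alpha <- P * same - P * p_i
    sr <- rowSums(alpha); sc <- colSums(alpha)
    cross <- colSums(Xs * (alpha %*% Xs)) + colSums(Xs * (t(alpha) %*% Xs))
    quad <- drop(sr %*% Xs^2) + drop(sc %*% Xs^2) - cross
    grad <- -2 * w * quad - 2 * lambda * w
    list(f = f, grad = grad)
  }

  og <- obj_grad(w)
  trace <- og$f
  step <- learning_rate
  for (it in seq_len(max_iters)) {
    improved <- FALSE
    for (half in 0:20) {
      w_new <- w + step * og$grad
      og_new <- obj_grad(w_new)
      if (og_new$f >= og$f) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) break
    gain <- og_new$f - og$f
    w <- w_new; og <- og_new
    trace <- c(trace, og$f)
    step <- step * 1.2                 # cautious growth after a success
    if (gain < tol * max(1, abs(og$f))) break
  }
  structure(w * w, objective = trace)
}

#' Feature weights by ReliefF
#'
#' Starts from all-zero weights and, for each of `m` sampled instances
#' \eqn{R_i}, subtracts the range-scaled distance
#' \eqn{\mathrm{diff}(a, R_i, H_j) = |a_{R_i} - a_{H_j}| / (\max_a - \min_a)}
#' to the `k` nearest same-class hits and adds the prior-weighted
#' distance to the `k` nearest misses of every other class `c` with
#' factor \eqn{P(c) / (1 - P(\mathrm{class}(R_i)))}, each divided by
#' \eqn{m \cdot k}. With `m = NULL` (default) every instance is visited
#' once in order, making the result deterministic. Weights lie in
#' \eqn{[-1, 1]}; a feature constant across the data keeps weight 0.
#'
#' @param X Numeric matrix, samples in rows.
#' @param y Class labels; every class must have more than `k` members.
#' @param k Number of nearest hits/misses (default 10).
#' @param m Number of sampled instances; `NULL` = all, sequentially.
#' @param seed RNG seed, used only when `m` is smaller than the sample
#'   count.
#' @return Numeric vector of per-feature weights.
#' @export
relieff_weights <- function(X, y, k = 10L, m = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("X contains non-finite values")
  y <- droplevels(as.factor(y))
  n <- nrow(X); D <- ncol(X)
  k <- as.integer(k)
  cls <- levels(y)
  tab <- table(y)
  small <- names(tab)[tab <= k]
  if (length(small)) {
    stop("class '", small[1], "' has ", tab[small[1]],
         " members; needs more than k = ", k)
  }
  if (is.null(m)) {
    ridx <- seq_len(n)
  } else {
    stopifnot(m >= 1L)
    set.seed(seed)
    ridx <- if (m <= n) sample.int(n, m) else sample.int(n, m, replace = TRUE)
  }
  m_eff <- length(ridx)

  rng <- apply(X, 2L, max) - apply(X, 2L, min)
  scale <- ifelse(rng > 0, rng, Inf)   # constant feature -> diff 0
  prior <- as.numeric(tab) / n
  names(prior) <- cls

  # pairwise distances once (Euclidean on raw features, ties -> lower index)
  d2 <- as.matrix(stats::dist(X))^2
  W <- numeric(D)
  for (r in ridx) {
    dr <- d2[r, ]
    for (cl in cls) {
      members <- which(y == cl & seq_len(n) != r)
      ord <- members[order(dr[members], members)][seq_len(k)]
      diffs <- colSums(abs(X[ord, , drop = FALSE] -
                           rep(X[r, ], each = k)) / rep(scale, each = k))
      if (cl == y[r]) {
        W <- W - diffs / (m_eff * k)
      } else {
        W <- W + (prior[cl] / (1 - prior[as.character(y[r])])) *
          diffs / (m_eff * k)
      }
    }
  }
  unname(W)
}

#' Intersection-based feature selection from two weight rankings
#'
#' Ranks the features separately by the NCA and the ReliefF weight
#' vectors, takes the `top_x` highest-weighted indices from each, and
#' returns their intersection, ordered by descending NCA weight. Ties
#' at the `top_x` boundary are resolved by index order (lower index
#' first). An empty intersection is permitted and produces a warning,
#' not an error.
#'
#' @param w_nca Per-feature weights from [nca_weights()].
#' @param w_relief Per-feature weights from [relieff_weights()]; must
#'   have the same length.
#' @param top_x Number of top indices taken from each ranking
#'   (default 300).
#' @return A `selection_result` list: `matched_indices`, `top_nca`,
#'   `top_relief`, `w_nca`, `w_relief`, `top_x`.
#' @export
nrbmi_select <- function(w_nca, w_relief, top_x = 300L) {
  if (length(w_nca) != length(w_relief)) {
    stop("weight vectors differ in length: ", length(w_nca), " vs ",
         length(w_relief))
  }
  D <- length(w_nca)
  top_x <- as.integer(top_x)
  stopifnot(top_x >= 1L, top_x <= D)
  top_of <- function(w) order(-w, seq_len(D))[seq_len(top_x)]
  top_nca <- top_of(w_nca)
  top_rel <- top_of(w_relief)
  matched <- intersect(top_nca, top_rel)
  matched <- matched[order(-w_nca[matched], matched)]
  if (length(matched) == 0L) {
    warning("top-", top_x, " NCA and ReliefF index sets are disjoint; ",
            "no features selected")
  }
  structure(list(matched_indices = matched, top_nca = top_nca,
                 top_relief = top_rel, w_nca = w_nca, w_relief = w_relief,
                 top_x = top_x),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> top_x = %d per method -> %d matched indices\n",
              x$top_x, length(x$matched_indices)))
  invisible(x)
}

#' Write selection outputs as CSV
#' @param sel A `selection_result`.
#' @param weights_path CSV of (feature_index, w_nca, w_relief).
#' @param indices_path One-column CSV of matched indices.
#' @return Invisibly, `sel`.
#' @export
write_selection <- function(sel, weights_path, indices_path) {
  utils::write.csv(data.frame(feature_index = seq_along(sel$w_nca),
                              w_nca = sel$w_nca, w_relief = sel$w_relief),
                   weights_path, row.names = FALSE)
  utils::write.csv(data.frame(matched_index = sel$matched_indices),
                   indices_path, row.names = FALSE)
  invisible(sel)
}
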