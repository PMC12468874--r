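# Shared fixtures and independent oracles. Oracles are deliberately naive
# (nested loops, direct DFT) and never call the implementation paths they
# check.

# Small network configuration used wherever the full default would be slow.
tiny_net <- function(input_size = 40L, feature_dim = 32L) {
  ramm_config(input_size = input_size, residual_widths = c(4L, 6L),
              mixer_patch = 20L, mixer_depth = 1L, mixer_hidden_dim = 12L,
              mixer_token_dim = 8L, mixer_channel_dim = 16L,
              feature_dim = feature_dim, n_classes = 2L)
}

# Separable toy images: class A bright in the top band, class B in the
# bottom band, plus noise.
separable_images <- function(n_per_class, size = 40L, seed = 1L,
                             contrast = 0.8) {
  set.seed(seed)
  mk <- function(top) {
    img <- matrix(stats::runif(size * size, 0, 0.2), size, size)
    rows <- if (top) 1:(size / 4) else (3 * size / 4):size
    img[rows, ] <- img[rows, ] + contrast
    pmin(img, 1)
  }
  list(images = c(replicate(n_per_class, mk(TRUE), simplify = FALSE),
                  replicate(n_per_class, mk(FALSE), simplify = FALSE)),
       labels = factor(rep(c("healthy", "unhealthy"), each = n_per_class)))
}

# Direct DFT magnitude of one windowed frame (oracle for stft_magnitude).
oracle_frame_dft <- function(x_frame, nfft) {
  n <- length(x_frame)
  vapply(0:(nfft %/% 2), function(k) {
    Mod(sum(x_frame * exp(-2i * pi * k * (0:(n - 1)) / nfft)))
  }, numeric(1))
}

# Naive O(N^2 D) ReliefF, literal transcription of the weight-update rule:
# subtract range-scaled diffs to the k nearest hits, add prior-weighted
# diffs to the k nearest misses of each other class, each over m*k.
oracle_relieff <- function(X, y, k) {
  X <- as.matrix(X)
  y <- as.factor(y)
  n <- nrow(X)
  rng <- apply(X, 2, max) - apply(X, 2, min)
  dv <- function(i, j) {
    out <- abs(X[i, ] - X[j, ])
    ifelse(rng > 0, out / rng, 0)
  }
  prior <- table(y) / n
  W <- numeric(ncol(X))
  for (i in seq_len(n)) {
    d_all <- sqrt(colSums((t(X) - X[i, ])^2))
    for (cl in levels(y)) {
      cand <- setdiff(which(y == cl), i)
      nb <- cand[order(d_all[cand], cand)][seq_len(k)]
      contrib <- Reduce(`+`, lapply(nb, function(j) dv(i, j)))
      if (cl == as.character(y[i])) {
        W <- W - contrib / (n * k)
      } else {
        W <- W + as.numeric(prior[cl] / (1 - prior[as.character(y[i])])) *
          contrib / (n * k)
      }
    }
  }
  W
}

# Direct evaluation of the soft nearest-neighbour leave-one-out objective
# for diagonal feature weights w (on standardised data), by nested loops.
oracle_nca_objective <- function(X, y, w) {
  Xs <- scale(X, center = TRUE, scale = pmax(apply(X, 2, sd), 1e-12))
  n <- nrow(Xs)
  f <- 0
  for (i in seq_len(n)) {
    dins <- vapply(seq_len(n), function(j)
      sum(w^2 * (Xs[i, ] - Xs[j, ])^2), numeric(1))
    e <- exp(-dins)
    e[i] <- 0
    p <- e / sum(e)
    f <- f + sum(p[y == y[i]])     # p[i] is zero, so self is excluded
  }
  f
}

# Synthetic feature table with a few informative columns and many noise
# columns (for selection / ablation checks).
informative_features <- function(n_per_class = 30L, n_info = 20L,
                                 n_noise = 980L, shift = 1.5, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per_class
  X <- matrix(stats::rnorm(n * (n_info + n_noise)), n)
  y <- factor(rep(c("healthy", "unhealthy"), each = n_per_class))
  X[y == "unhealthy", seq_len(n_info)] <-
    X[y == "unhealthy", seq_len(n_info)] + shift
  list(X = X, y = y)
}

tmp_wav <- function(samples, rate) {
  path <- tempfile(fileext = ".wav")
  write_wav(samples, rate, path)
  path
}
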