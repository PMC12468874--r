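test_that("duplicated features receive equal NCA weights", {
  set.seed(1)
  x1 <- c(stats::rnorm(15, 0), stats::rnorm(15, 2))
  X <- cbind(x1, x1, stats::rnorm(30))
  y <- rep(c("healthy", "unhealthy"), each = 15)
  w <- nca_weights(X, y, max_iters = 40)
  expect_lt(abs(w[1] - w[2]), 1e-6)
  expect_gte(min(w), 0)
})

test_that("NCA upweights a class-separating feature over pure noise (grid oracle)", {
  set.seed(2)
  n <- 40
  y <- rep(c("healthy", "unhealthy"), each = n / 2)
  X <- cbind(ifelse(y == "healthy", 0, 3) + stats::rnorm(n, sd = 0.3),
             stats::rnorm(n))
  w <- nca_weights(X, y, max_iters = 60)
  expect_gt(w[1], w[2])
  # oracle: coarse grid over diagonal weights maximises the same objective
  grid <- expand.grid(w1 = seq(0, 3, by = 0.5), w2 = seq(0, 3, by = 0.5))
  objs <- apply(grid, 1, function(g) oracle_nca_objective(X, y, c(g[1], g[2])))
  best <- grid[which.max(objs), ]
  expect_gt(best$w1, best$w2)
})

test_that("returned NCA weights beat uniform weights on the 4-point instance", {
  X <- matrix(c(0, 0.3, 0.1, 0.9, 1, 0.1, 0.9, 0.8), ncol = 2, byrow = TRUE)
  y <- c("A", "A", "B", "B")
  w <- nca_weights(X, y, max_iters = 80)
  expect_gte(oracle_nca_objective(X, y, sqrt(w)),
             oracle_nca_objective(X, y, c(1, 1)) - 1e-9)
})

test_that("the NCA objective trace is non-decreasing", {
  set.seed(3)
  X <- matrix(stats::rnorm(30 * 6), 30)
  X[16:30, 1] <- X[16:30, 1] + 2
  y <- rep(c("a", "b"), each = 15)
  tr <- attr(nca_weights(X, y, max_iters = 50), "objective")
  expect_gte(length(tr), 2L)
  expect_true(all(diff(tr) >= -1e-12))
})

test_that("NCA rejects single-class input and guards zero variance", {
  X <- matrix(stats::rnorm(20), 10)
  expect_error(nca_weights(X, rep("a", 10)), "two classes")
  Xz <- cbind(X, 0)
  expect_warning(w <- nca_weights(Xz, rep(c("a", "b"), 5), max_iters = 5),
                 "zero-variance")
  expect_true(all(is.finite(w)))
})

test_that("constant features get ReliefF weight exactly 0", {
  set.seed(4)
  X <- cbind(stats::rnorm(20), 7)
  y <- rep(c("a", "b"), 10)
  w <- relieff_weights(X, y, k = 3)
  expect_identical(w[2], 0)
})

test_that("ReliefF ranks the separating feature above the noisy one on the 4-point instance", {
  X <- matrix(c(0, 0.3, 0.1, 0.9, 1, 0.1, 0.9, 0.8), ncol = 2, byrow = TRUE)
  y <- c("A", "A", "B", "B")
  w <- relieff_weights(X, y, k = 1)
  expect_gt(w[1], w[2])
  expect_equal(w, oracle_relieff(X, y, k = 1), tolerance = 1e-12)
  expect_true(all(w >= -1 & w <= 1))
})

test_that("ReliefF equals the naive nested-loop oracle on random instances", {
  set.seed(5)
  for (trial in 1:3) {
    n <- sample(12:30, 1)
    D <- sample(3:8, 1)
    X <- matrix(stats::rnorm(n * D), n)
    y <- factor(sample(c("a", "b"), n, replace = TRUE,
                       prob = c(0.6, 0.4)))
    while (min(table(y)) < 4) y <- factor(sample(c("a", "b"), n, replace = TRUE))
    w <- relieff_weights(X, y, k = 2)
    expect_equal(w, oracle_relieff(X, y, k = 2), tolerance = 1e-12)
  }
})

test_that("duplicating every sample preserves the ReliefF weight ordering", {
  set.seed(6)
  n <- 16
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", 0, 1.5) + stats::rnorm(n, sd = 0.2),
             stats::rnorm(n), stats::rnorm(n, sd = 2))
  w1 <- relieff_weights(X, y, k = 2)
  w2 <- relieff_weights(rbind(X, X), c(y, y), k = 2)
  # the informative feature stays on top; noise features keep weights near 0
  expect_equal(which.max(w1), which.max(w2))
  expect_gt(w2[1], max(abs(w2[-1])))
  # and the doubled-data result still matches the nested-loop oracle exactly
  expect_equal(w2, oracle_relieff(rbind(X, X), c(y, y), k = 2),
               tolerance = 1e-12)
})

test_that("ReliefF refuses k at or above the class size, naming the class", {
  X <- matrix(stats::rnorm(24), 12)
  y <- rep(c("big", "tiny"), c(9, 3))
  expect_error(relieff_weights(X, y, k = 3), "tiny")
})

test_that("intersection selection matches the worked examples", {
  # top-3 NCA {5,2,9}, top-3 ReliefF {2,9,7} -> matched {2,9}
  w_nca <- c(0.1, 0.8, 0.2, 0.05, 0.9, 0.15, 0.3, 0.0, 0.7, 0.25)
  w_rel <- c(0.0, 0.9, 0.1, 0.05, 0.1, 0.15, 0.6, 0.0, 0.8, 0.25)
  sel <- nrbmi_select(w_nca, w_rel, top_x = 3)
  expect_setequal(sel$matched_indices, c(2, 9))
  expect_equal(sel$matched_indices, c(2, 9))  # ordered by descending NCA weight

  # identical weight vectors -> full top_x matched
  sel2 <- nrbmi_select(w_nca, w_nca, top_x = 4)
  expect_length(sel2$matched_indices, 4L)

  # disjoint top sets -> empty result with warning, not an error
  expect_warning(sel3 <- nrbmi_select(c(1, 0, 0, 0), c(0, 0, 0, 1), top_x = 1),
                 "disjoint")
  expect_length(sel3$matched_indices, 0L)

  expect_error(nrbmi_select(1:3, 1:4, top_x = 2), "length")
})

test_that("selection output is always a subset of both top sets", {
  set.seed(7)
  for (trial in 1:20) {
    D <- sample(10:60, 1)
    top_x <- sample(seq_len(D), 1)
    wn <- stats::runif(D); wr <- stats::runif(D)
    sel <- suppressWarnings(nrbmi_select(wn, wr, top_x))
    expect_lte(length(sel$matched_indices), top_x)
    expect_true(all(sel$matched_indices %in% sel$top_nca))
    expect_true(all(sel$matched_indices %in% sel$top_relief))
  }
})

test_that("boundary ties are resolved by index order", {
  w <- c(0.5, 0.9, 0.5, 0.5, 0.1)
  sel <- nrbmi_select(w, w, top_x = 2)   # three-way tie at the boundary
  expect_equal(sort(sel$top_nca), c(1, 2))
})

test_that("permuting feature columns permutes all outputs consistently", {
  set.seed(8)
  n <- 24
  y <- rep(c("a", "b"), each = n / 2)
  X <- cbind(ifelse(y == "a", 0, 2) + stats::rnorm(n, sd = 0.4),
             stats::rnorm(n), stats::rnorm(n), stats::rnorm(n, sd = 0.5))
  perm <- c(3, 1, 4, 2)
  wr1 <- relieff_weights(X, y, k = 3)
  wr2 <- relieff_weights(X[, perm], y, k = 3)
  expect_equal(wr2, wr1[perm], tolerance = 1e-12)
  wn1 <- nca_weights(X, y, max_iters = 30)
  wn2 <- nca_weights(X[, perm], y, max_iters = 30)
  expect_equal(as.numeric(wn2), as.numeric(wn1[perm]), tolerance = 1e-8)
  s1 <- nrbmi_select(wn1, wr1, top_x = 2)
  s2 <- nrbmi_select(wn2, wr2, top_x = 2)
  expect_setequal(match(s1$matched_indices, perm), s2$matched_indices)
})
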