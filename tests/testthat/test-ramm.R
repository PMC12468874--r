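test_that("default build sizes: parameter count band and 1000-unit feature layer", {
  m <- build_ramm(ramm_config())
  expect_gte(m$n_params, 500000)
  expect_lte(m$n_params, 660000)
  expect_equal(ncol(m$params$head1$W), 1000L)   # last ReLU layer width
  expect_equal(m$cfg$feature_dim, 1000L)
})

test_that("patch/size mismatches are caught at build time", {
  expect_error(ramm_config(input_size = 200, mixer_patch = 30), "divisible")
  expect_error(ramm_config(input_size = 200, mixer_patch = 2,
                           residual_widths = c(4, 4)), "downsampling")
})

test_that("softmax rows normalise and features are non-negative", {
  m <- build_ramm(tiny_net(), seed = 2)
  set.seed(1)
  imgs <- replicate(3, matrix(stats::runif(1600), 40, 40), simplify = FALSE)
  out <- ramm_forward(m, imgs)
  expect_equal(rowSums(out$probs), rep(1, 3), tolerance = 1e-6)
  expect_gte(min(out$features), 0)
  expect_true(all(is.finite(out$features)))
  # zero image through a fresh model stays finite
  z <- ramm_forward(m, list(matrix(0, 40, 40)))
  expect_true(all(is.finite(z$probs)))
  expect_equal(sum(z$probs), 1, tolerance = 1e-6)
})

test_that("evaluation is deterministic and row-permutation equivariant", {
  m <- build_ramm(tiny_net(), seed = 3)
  set.seed(2)
  imgs <- replicate(4, matrix(stats::runif(1600), 40, 40), simplify = FALSE)
  a <- ramm_forward(m, imgs)
  b <- ramm_forward(m, imgs)
  expect_identical(a, b)
  perm <- c(3, 1, 4, 2)
  p <- ramm_forward(m, imgs[perm])
  expect_equal(p$features, a$features[perm, ], tolerance = 1e-12)
  expect_equal(p$probs, a$probs[perm, ], tolerance = 1e-12)
  # duplicated input rows give identical feature rows
  d <- ramm_forward(m, imgs[c(1, 1)])
  expect_equal(d$features[1, ], d$features[2, ])
})

test_that("channel-attention gates lie in (0,1) and a zero channel stays zero", {
  set.seed(4)
  C <- 5
  x <- array(stats::runif(6 * 6 * C), c(6, 6, C))
  x[, , 3] <- 0
  W1 <- matrix(stats::rnorm(C * 2), C, 2); W2 <- matrix(stats::rnorm(2 * C), 2, C)
  out <- pcgmixer:::se_fw(x, W1, stats::rnorm(2), W2, stats::rnorm(C))
  expect_true(all(out$gates > 0 & out$gates < 1))
  expect_equal(max(abs(out$out[, , 3])), 0)
})

test_that("residual block with zeroed conv weights is the identity on ReLU inputs", {
  m <- build_ramm(tiny_net(), seed = 5)
  for (nm in c("c1", "c2")) {
    m$params$res[[1]][[nm]]$W[] <- 0
    m$params$res[[1]][[nm]]$b[] <- 0
  }
  x <- array(stats::runif(40 * 40), c(40, 40, 1))
  fw <- pcgmixer:::.ramm_fw1(m, x)
  # recompute the stage-1 shortcut input: down conv + ReLU
  cd <- pcgmixer:::conv_fw(x, m$params$res[[1]]$down$W,
                           m$params$res[[1]]$down$b, m$idx$down[[1]])
  rd <- pmax(cd$out, 0)
  c1b <- pcgmixer:::conv_fw(rd, m$params$res[[1]]$c1$W,
                            m$params$res[[1]]$c1$b, m$idx$block[[1]])
  c2b <- pcgmixer:::conv_fw(pmax(c1b$out, 0), m$params$res[[1]]$c2$W,
                            m$params$res[[1]]$c2$b, m$idx$block[[1]])
  expect_equal(pmax(rd + c2b$out, 0), rd)   # block output == its input
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- ramm_config(input_size = 20, residual_widths = c(3, 4),
                     mixer_patch = 20, mixer_depth = 1, mixer_hidden_dim = 6,
                     mixer_token_dim = 5, mixer_channel_dim = 7,
                     feature_dim = 9, n_classes = 2)
  m <- build_ramm(cfg, seed = 3)
  set.seed(7)
  x <- array(stats::runif(400), c(20, 20, 1))
  yi <- 2L
  loss_of <- function(model) {
    fw <- pcgmixer:::.ramm_fw1(model, x)
    pr <- pcgmixer:::softmax_rows(matrix(fw$logits, 1))
    -log(pr[1, yi])
  }
  fw <- pcgmixer:::.ramm_fw1(m, x)
  pr <- pcgmixer:::softmax_rows(matrix(fw$logits, 1))
  dlog <- pr[1, ]; dlog[yi] <- dlog[yi] - 1
  bw <- pcgmixer:::.ramm_bw1(m, fw, dlog)
  paths <- list(c("res", 1, "down", "W"), c("res", 2, "c2", "W"),
                c("att", 1, "W"), c("se", "W1"), c("embed", "W"),
                c("mixer", 1, "t1", "W"), c("mixer", 1, "c2", "W"),
                c("lnf", "g"), c("head1", "W"), c("head2", "b"))
  get_leaf <- function(l, p) { for (k in p) l <- l[[k]]; l }
  set_leaf <- function(l, p, v) {
    if (length(p) == 1) { l[[p[[1]]]] <- v; return(l) }
    l[[p[[1]]]] <- set_leaf(l[[p[[1]]]], p[-1], v); l
  }
  eps <- 1e-5
  for (pa in paths) {
    arr <- get_leaf(m$params, pa)
    ga <- get_leaf(bw$grads, pa)
    set.seed(11)
    for (j in sample(length(arr), min(3, length(arr)))) {
      bump <- function(h) {
        a2 <- arr; a2[j] <- a2[j] + h
        m2 <- m; m2$params <- set_leaf(m$params, pa, a2)
        loss_of(m2)
      }
      num <- (bump(eps) - bump(-eps)) / (2 * eps)
      expect_equal(ga[j], num, tolerance = 1e-3,
                   label = paste("grad", paste(pa, collapse = "/"), j))
    }
  }
})

test_that("training separates separable images at least as well as a linear probe", {
  sep <- separable_images(20, size = 40, seed = 6)
  # independent oracle: ridge-regularised linear classifier on raw pixels
  P <- t(vapply(sep$images, as.vector, numeric(1600)))
  yn <- as.integer(sep$labels == "unhealthy")
  ridge <- function(X, y, lam = 1e-2) {
    Xc <- cbind(1, X)
    solve(crossprod(Xc) + lam * diag(ncol(Xc)), crossprod(Xc, y))
  }
  beta <- ridge(P, yn)
  oracle_acc <- mean((cbind(1, P) %*% beta > 0.5) == yn)
  expect_gte(oracle_acc, 0.9)

  m <- build_ramm(tiny_net(), seed = 6)
  m <- train_ramm(m, sep$images, sep$labels,
                  train_config(learning_rate = 0.01, epochs = 10,
                               batch_size = 8, seed = 6))
  expect_gte(utils::tail(m$history$train_acc, 1), 0.9)
  expect_gte(utils::tail(m$history$train_acc, 1), oracle_acc - 0.1)
  expect_equal(nrow(m$history), 10L)
})

test_that("zero learning rate leaves accuracy at its initial level", {
  sep <- separable_images(6, size = 40, seed = 8)
  m <- build_ramm(tiny_net(), seed = 8)
  m0 <- train_ramm(m, sep$images, sep$labels,
                   train_config(learning_rate = 0, epochs = 3,
                                batch_size = 6, seed = 8))
  expect_equal(stats::sd(m0$history$train_acc), 0)
  expect_equal(stats::sd(m0$history$train_loss), 0, tolerance = 1e-12)
})

test_that("fixed seed reproduces the loss curve exactly", {
  sep <- separable_images(6, size = 40, seed = 9)
  tc <- train_config(learning_rate = 0.01, epochs = 3, batch_size = 6,
                     seed = 123)
  h1 <- train_ramm(build_ramm(tiny_net(), seed = 1), sep$images,
                   sep$labels, tc)$history
  h2 <- train_ramm(build_ramm(tiny_net(), seed = 99), sep$images,
                   sep$labels, tc)$history
  expect_identical(h1, h2)    # training re-seeds weights from tcfg$seed
})

test_that("single-class training input is fatal", {
  sep <- separable_images(4, size = 40, seed = 10)
  keep <- sep$labels == "healthy"
  expect_error(train_ramm(build_ramm(tiny_net()), sep$images[keep],
                          droplevels(sep$labels[keep]), train_config(epochs = 1)),
               "single class")
})

test_that("feature extraction yields aligned non-negative matrices and flags untrained models", {
  m <- build_ramm(tiny_net(feature_dim = 48L), seed = 11)
  set.seed(11)
  imgs <- replicate(5, matrix(stats::runif(1600), 40, 40), simplify = FALSE)
  expect_warning(fm <- extract_features(m, imgs, ids = paste0("r", 1:5)),
                 "untrained")
  expect_equal(dim(fm), c(5L, 48L))
  expect_gte(min(fm), 0)
  expect_equal(rownames(fm), paste0("r", 1:5))
  expect_false(attr(fm, "trained"))
})

test_that("checkpoints round-trip through save/load", {
  m <- build_ramm(tiny_net(), seed = 12)
  p <- tempfile(fileext = ".rds")
  save_ramm(m, p)
  m2 <- load_ramm(p)
  set.seed(5)
  img <- list(matrix(stats::runif(1600), 40, 40))
  expect_equal(ramm_forward(m, img), ramm_forward(m2, img))
})
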