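#' Build the residual-attention mixer network
#'
#' Instantiates the network described by a [ramm_config()]: randomly
#' initialised weights (fan-in scaled), precomputed convolution index
#' maps, and the learnable-parameter count.
#'
#' @param cfg A [ramm_config()].
#' @param seed Seed for weight initialisation (training re-seeds from
#'   its own [train_config()]).
#' @return A `ramm_model` with elements `cfg`, `params`, `n_params`,
#'   `trained`, `history`.
#' @export
build_ramm <- function(cfg = ramm_config(), seed = 1L) {
  stopifnot(inherits(cfg, "ramm_config"))
  shapes <- .ramm_shapes(cfg)
  model <- structure(list(cfg = cfg, shapes = shapes,
                          idx = .ramm_idx(cfg),
                          params = .ramm_init(cfg, shapes, seed),
                          trained = FALSE, history = NULL),
                     class = "ramm_model")
  model$n_params <- count_ramm_params(model)
  model
}

#' Learnable-parameter count of a network
#' @param model A `ramm_model`.
#' @return Integer: total number of weights, biases and norm parameters.
#' @export
count_ramm_params <- function(model) {
  sum(unlist(lapply(unlist(model$params, recursive = TRUE), length)))
}

#' @export
print.ramm_model <- function(x, ...) {
  s <- x$shapes
  cat(sprintf(paste0(
    "<ramm_model> input %dx%dx%d -> %d-channel %dx%d map (%s merge)\n",
    "  mixer: %d tokens x %d ch, depth %d | feature layer %d (ReLU) -> %d classes\n",
    "  learnable parameters: %s | trained: %s\n"),
    x$cfg$input_size, x$cfg$input_size, x$cfg$input_channels,
    s$merged_c, s$map_size, s$map_size, x$cfg$merge,
    s$n_tokens, x$cfg$mixer_hidden_dim, x$cfg$mixer_depth,
    x$cfg$feature_dim, x$cfg$n_classes,
    format(x$n_params, big.mark = ","), x$trained))
  invisible(x)
}

.ramm_idx <- function(cfg) {
  widths <- cfg$residual_widths
  sz <- cfg$input_size
  cin <- cfg$input_channels
  down <- vector("list", length(widths))
  block <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    down[[i]] <- .im2col_idx(sz, sz, cin, k = 3L, s = 2L, p = 1L)
    sz <- sz %/% 2L
    block[[i]] <- .im2col_idx(sz, sz, widths[i], k = 3L, s = 1L, p = 1L)
    cin <- widths[i]
  }
  list(down = down, block = block)
}

.he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}
.he_dense <- function(din, dout) {
  matrix(stats::rnorm(din * dout, sd = sqrt(2 / din)), din, dout)
}

.ramm_init <- function(cfg, shapes, seed) {
  set.seed(seed)
  widths <- cfg$residual_widths
  cin <- cfg$input_channels
  res <- att <- vector("list", length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    res[[i]] <- list(down = list(W = .he_conv(3L, cin, w), b = numeric(w)),
                     c1 = list(W = .he_conv(3L, w, w), b = numeric(w)),
                     c2 = list(W = .he_conv(3L, w, w), b = numeric(w)))
    att[[i]] <- list(W = .he_conv(3L, cin, w), b = numeric(w))
    cin <- w
  }
  cr <- max(1L, shapes$branch_c %/% cfg$se_reduction)
  se <- list(W1 = .he_dense(shapes$branch_c, cr), b1 = numeric(cr),
             W2 = .he_dense(cr, shapes$branch_c), b2 = numeric(shapes$branch_c))
  C <- cfg$mixer_hidden_dim
  mixer <- lapply(seq_len(cfg$mixer_depth), function(d) list(
    ln1 = list(g = rep(1, C), b = numeric(C)),
    t1 = list(W = .he_dense(shapes$n_tokens, cfg$mixer_token_dim),
              b = numeric(cfg$mixer_token_dim)),
    t2 = list(W = .he_dense(cfg$mixer_token_dim, shapes$n_tokens),
              b = numeric(shapes$n_tokens)),
    ln2 = list(g = rep(1, C), b = numeric(C)),
    c1 = list(W = .he_dense(C, cfg$mixer_channel_dim),
              b = numeric(cfg$mixer_channel_dim)),
    c2 = list(W = .he_dense(cfg$mixer_channel_dim, C), b = numeric(C))
  ))
  list(res = res, att = att, se = se,
       embed = list(W = .he_dense(shapes$patch_dim, C), b = numeric(C)),
       mixer = mixer,
       lnf = list(g = rep(1, C), b = numeric(C)),
       head1 = list(W = .he_dense(C, cfg$feature_dim),
                    b = numeric(cfg$feature_dim)),
       head2 = list(W = .he_dense(cfg$feature_dim, cfg$n_classes),
                    b = numeric(cfg$n_classes)))
}

# Full forward pass for one sample; returns logits/features plus every
# intermediate needed for the backward pass.
.ramm_fw1 <- function(model, x) {
  p <- model$params; cfg <- model$cfg; idx <- model$idx; sh <- model$shapes
  ca <- list()

  r <- x
  for (i in seq_along(p$res)) {
    cd <- conv_fw(r, p$res[[i]]$down$W, p$res[[i]]$down$b, idx$down[[i]])
    rd <- relu_fw(cd$out)
    c1 <- conv_fw(rd$out, p$res[[i]]$c1$W, p$res[[i]]$c1$b, idx$block[[i]])
    r1 <- relu_fw(c1$out)
    c2 <- conv_fw(r1$out, p$res[[i]]$c2$W, p$res[[i]]$c2$b, idx$block[[i]])
    rs <- relu_fw(rd$out + c2$out)
    ca$res[[i]] <- list(cd = cd$cache, rd = rd$cache, c1 = c1$cache,
                        r1 = r1$cache, c2 = c2$cache, rs = rs$cache)
    r <- rs$out
  }

  a <- x
  for (i in seq_along(p$att)) {
    cd <- conv_fw(a, p$att[[i]]$W, p$att[[i]]$b, idx$down[[i]])
    rd <- relu_fw(cd$out)
    ca$att[[i]] <- list(cd = cd$cache, rd = rd$cache)
    a <- rd$out
  }
  se <- se_fw(a, p$se$W1, p$se$b1, p$se$W2, p$se$b2)
  ca$se <- se$cache

  merged <- if (cfg$merge == "concat") {
    array(c(r, se$out), c(sh$map_size, sh$map_size, sh$merged_c))
  } else r + se$out

  pt <- patchify_fw(merged, sh$patch)
  em <- dense_fw(pt$out, p$embed$W, p$embed$b)
  ca$pt_d <- pt$d; ca$em <- em$cache
  X <- em$out

  ca$mix <- vector("list", cfg$mixer_depth)
  for (d in seq_len(cfg$mixer_depth)) {
    b <- p$mixer[[d]]; cb <- list()
    l1 <- layernorm_fw(X, b$ln1$g, b$ln1$b); cb$l1 <- l1$cache
    U <- t(l1$out)
    d1 <- dense_fw(U, b$t1$W, b$t1$b); cb$d1 <- d1$cache
    u2 <- relu_fw(d1$out); cb$u2 <- u2$cache
    d2 <- dense_fw(u2$out, b$t2$W, b$t2$b); cb$d2 <- d2$cache
    X <- X + t(d2$out)
    l2 <- layernorm_fw(X, b$ln2$g, b$ln2$b); cb$l2 <- l2$cache
    d3 <- dense_fw(l2$out, b$c1$W, b$c1$b); cb$d3 <- d3$cache
    v2 <- relu_fw(d3$out); cb$v2 <- v2$cache
    d4 <- dense_fw(v2$out, b$c2$W, b$c2$b); cb$d4 <- d4$cache
    X <- X + d4$out
    ca$mix[[d]] <- cb
  }

  lf <- layernorm_fw(X, p$lnf$g, p$lnf$b); ca$lf <- lf$cache
  f0 <- matrix(colMeans(lf$out), 1L)
  h1 <- dense_fw(f0, p$head1$W, p$head1$b); ca$h1 <- h1$cache
  fr <- relu_fw(h1$out); ca$fr <- fr$cache
  h2 <- dense_fw(fr$out, p$head2$W, p$head2$b); ca$h2 <- h2$cache

  list(logits = drop(h2$out), features = drop(fr$out),
       gates = se$gates, cache = ca)
}

# Backward pass for one sample; dlogits is the gradient at the logits.
.ramm_bw1 <- function(model, fw, dlogits) {
  p <- model$params; cfg <- model$cfg; idx <- model$idx; sh <- model$shapes
  ca <- fw$cache
  g <- list()

  b2 <- dense_bw(matrix(dlogits, 1L), p$head2$W, ca$h2)
  g$head2 <- list(W = b2$dW, b = b2$db)
  dfr <- relu_bw(b2$dx, ca$fr)
  b1 <- dense_bw(dfr, p$head1$W, ca$h1)
  g$head1 <- list(W = b1$dW, b = b1$db)
  S <- sh$n_tokens
  dXf <- matrix(rep(drop(b1$dx) / S, each = S), S)
  lf <- layernorm_bw(dXf, p$lnf$g, ca$lf)
  g$lnf <- list(g = lf$dg, b = lf$db)
  dX <- lf$dx

  g$mixer <- vector("list", cfg$mixer_depth)
  for (d in rev(seq_len(cfg$mixer_depth))) {
    b <- p$mixer[[d]]; cb <- ca$mix[[d]]; gb <- list()
    d4 <- dense_bw(dX, b$c2$W, cb$d4)
    gb$c2 <- list(W = d4$dW, b = d4$db)
    dv1 <- relu_bw(d4$dx, cb$v2)
    d3 <- dense_bw(dv1, b$c1$W, cb$d3)
    gb$c1 <- list(W = d3$dW, b = d3$db)
    l2 <- layernorm_bw(d3$dx, b$ln2$g, cb$l2)
    gb$ln2 <- list(g = l2$dg, b = l2$db)
    dX <- dX + l2$dx
    dU3 <- t(dX)
    d2 <- dense_bw(dU3, b$t2$W, cb$d2)
    gb$t2 <- list(W = d2$dW, b = d2$db)
    du1 <- relu_bw(d2$dx, cb$u2)
    d1 <- dense_bw(du1, b$t1$W, cb$d1)
    gb$t1 <- list(W = d1$dW, b = d1$db)
    l1 <- layernorm_bw(t(d1$dx), b$ln1$g, cb$l1)
    gb$ln1 <- list(g = l1$dg, b = l1$db)
    dX <- dX + l1$dx
    g$mixer[[d]] <- gb
  }

  em <- dense_bw(dX, p$embed$W, ca$em)
  g$embed <- list(W = em$dW, b = em$db)
  dmerged <- patchify_bw(em$dx, sh$patch, ca$pt_d)

  bc <- sh$branch_c
  if (cfg$merge == "concat") {
    dr <- dmerged[, , seq_len(bc), drop = FALSE]
    da <- dmerged[, , bc + seq_len(bc), drop = FALSE]
  } else {
    dr <- dmerged; da <- dmerged
  }

  se <- se_bw(da, p$se$W1, p$se$W2, ca$se)
  g$se <- list(W1 = se$dW1, b1 = se$db1, W2 = se$dW2, b2 = se$db2)
  dcur <- se$dx
  g$att <- vector("list", length(p$att))
  for (i in rev(seq_along(p$att))) {
    dpre <- relu_bw(dcur, ca$att[[i]]$rd)
    cb <- conv_bw(dpre, p$att[[i]]$W, ca$att[[i]]$cd, idx$down[[i]])
    g$att[[i]] <- list(W = cb$dW, b = cb$db)
    dcur <- cb$dx
  }
  dx_att <- dcur

  dcur <- dr
  g$res <- vector("list", length(p$res))
  for (i in rev(seq_along(p$res))) {
    cr <- ca$res[[i]]
    dsum <- relu_bw(dcur, cr$rs)
    c2 <- conv_bw(dsum, p$res[[i]]$c2$W, cr$c2, idx$block[[i]])
    dr1 <- relu_bw(c2$dx, cr$r1)
    c1 <- conv_bw(dr1, p$res[[i]]$c1$W, cr$c1, idx$block[[i]])
    drd <- relu_bw(dsum + c1$dx, cr$rd)
    cd <- conv_bw(drd, p$res[[i]]$down$W, cr$cd, idx$down[[i]])
    g$res[[i]] <- list(down = list(W = cd$dW, b = cd$db),
                       c1 = list(W = c1$dW, b = c1$db),
                       c2 = list(W = c2$dW, b = c2$db))
    dcur <- cd$dx
  }

  list(grads = g, dx = dcur + dx_att)
}

.as_image_array <- function(images, cfg) {
  if (is.list(images)) {
    stopifnot(length(images) >= 1L)
    images <- lapply(images, function(m) {
      if (length(dim(m)) == 2L) array(m, c(dim(m), 1L)) else m
    })
  } else if (length(dim(images)) == 3L) {
    images <- lapply(seq_len(dim(images)[3]), function(i)
      array(images[, , i], c(dim(images)[1:2], 1L)))
  } else stop("images must be a list of matrices or an H x W x N array")
  d <- dim(images[[1]])
  if (d[1] != cfg$input_size || d[2] != cfg$input_size ||
      d[3] != cfg$input_channels) {
    stop(sprintf("image shape %dx%dx%d does not match model input %dx%dx%d",
                 d[1], d[2], d[3],
                 cfg$input_size, cfg$input_size, cfg$input_channels))
  }
  if (isTRUE(cfg$input_center)) {
    images <- lapply(images, function(a) a - mean(a))
  }
  images
}

#' Forward pass: deep features and class probabilities
#'
#' Deterministic in evaluation: the network has no stochastic layers,
#' so repeated calls on the same input give identical outputs.
#'
#' @param model A `ramm_model`.
#' @param images List of `input_size` x `input_size` matrices (or an
#'   H x W x N array).
#' @return List with `features` (N x `feature_dim`, non-negative,
#'   taken from the last ReLU layer) and `probs` (N x `n_classes`,
#'   rows summing to 1).
#' @export
ramm_forward <- function(model, images) {
  stopifnot(inherits(model, "ramm_model"))
  xs <- .as_image_array(images, model$cfg)
  feats <- matrix(0, length(xs), model$cfg$feature_dim)
  logits <- matrix(0, length(xs), model$cfg$n_classes)
  for (i in seq_along(xs)) {
    fw <- .ramm_fw1(model, xs[[i]])
    feats[i, ] <- fw$features
    logits[i, ] <- fw$logits
  }
  list(features = feats, probs = softmax_rows(logits))
}

#' Train the network with SGD + momentum and cross-entropy loss
#'
#' Weights are (re-)initialised from `tcfg$seed`, so a fixed seed gives
#' an identical loss curve on repeated runs.
#'
#' @param model A `ramm_model` from [build_ramm()].
#' @param images Training images (list of matrices or H x W x N array).
#' @param labels Factor or character vector of class labels (>= 2
#'   samples per class required).
#' @param tcfg A [train_config()].
#' @param val_images,val_labels Optional held-out set evaluated after
#'   each epoch.
#' @param verbose Print one line per epoch.
#' @return The trained `ramm_model`; `$history` holds per-epoch
#'   `train_loss`, `train_acc` and, when a validation set is given,
#'   `val_loss`, `val_acc`.
#' @export
train_ramm <- function(model, images, labels, tcfg = train_config(),
                       val_images = NULL, val_labels = NULL,
                       verbose = FALSE) {
  stopifnot(inherits(model, "ramm_model"), inherits(tcfg, "train_config"))
  xs <- .as_image_array(images, model$cfg)
  y <- .class_index(labels, model$cfg$n_classes)
  if (length(unique(y)) < 2L) stop("training data contains a single class")
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (length(xs) != length(y)) stop("images and labels disagree in length")

  set.seed(tcfg$seed)
  model$params <- .ramm_init(model$cfg, model$shapes, tcfg$seed)
  vel <- .zeros_like(model$params)
  n <- length(xs)
  hist <- vector("list", tcfg$epochs)

  for (ep in seq_len(tcfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = tcfg$batch_size)
    ep_loss <- 0; ep_hits <- 0L
    for (s in starts) {
      bi <- ord[s:min(s + tcfg$batch_size - 1L, n)]
      B <- length(bi)
      gacc <- NULL
      for (i in bi) {
        fw <- .ramm_fw1(model, xs[[i]])
        pr <- softmax_rows(matrix(fw$logits, 1L))
        ep_loss <- ep_loss - log(max(pr[1, y[i]], 1e-12))
        ep_hits <- ep_hits + (which.max(pr) == y[i])
        dlog <- pr[1, ]
        dlog[y[i]] <- dlog[y[i]] - 1
        bw <- .ramm_bw1(model, fw, dlog / B)
        gacc <- if (is.null(gacc)) bw$grads else .tree_add(gacc, bw$grads)
      }
      st <- .sgdm_step(model$params, gacc, vel,
                       tcfg$learning_rate, tcfg$momentum)
      model$params <- st$p
      vel <- st$v
    }
    row <- data.frame(epoch = ep, train_loss = ep_loss / n,
                      train_acc = ep_hits / n)
    if (!is.null(val_images)) {
      ev <- .ramm_eval(model, val_images, val_labels)
      row$val_loss <- ev$loss; row$val_acc <- ev$acc
    }
    hist[[ep]] <- row
    if (verbose) {
      cat(sprintf("epoch %d/%d loss %.4f acc %.3f%s\n", ep, tcfg$epochs,
                  row$train_loss, row$train_acc,
                  if (!is.null(val_images))
                    sprintf(" val_acc %.3f", row$val_acc) else ""))
    }
  }
  model$history <- do.call(rbind, hist)
  model$trained <- TRUE
  model
}

.class_index <- function(labels, n_classes) {
  f <- if (is.factor(labels)) labels
       else factor(labels, levels = sort(unique(as.character(labels))))
  y <- as.integer(f)
  if (max(y) > n_classes) stop("more label levels than model classes")
  attr(y, "levels") <- levels(f)
  y
}

.ramm_eval <- function(model, images, labels) {
  out <- ramm_forward(model, images)
  y <- .class_index(labels, model$cfg$n_classes)
  pred <- max.col(out$probs, ties.method = "first")
  loss <- -mean(log(pmax(out$probs[cbind(seq_along(y), y)], 1e-12)))
  list(loss = loss, acc = mean(pred == y))
}

#' Extract the deep feature matrix from the last ReLU layer
#'
#' @param model A `ramm_model` (a warning is issued if it has not been
#'   trained; features are still produced and flagged).
#' @param images Images as in [ramm_forward()].
#' @param ids Optional record ids (row names of the result).
#' @param labels Optional labels, attached as the `labels` attribute.
#' @return N x `feature_dim` non-negative matrix of class
#'   `feature_matrix`, rows aligned to `ids`.
#' @export
extract_features <- function(model, images, ids = NULL, labels = NULL) {
  stopifnot(inherits(model, "ramm_model"))
  if (!isTRUE(model$trained)) {
    warning("extracting features from an untrained network; ",
            "result flagged with attr 'trained' = FALSE")
  }
  fm <- ramm_forward(model, images)$features
  if (!is.null(ids)) rownames(fm) <- ids
  structure(fm, labels = labels, trained = isTRUE(model$trained),
            class = c("feature_matrix", class(fm)))
}

# ---- parameter-tree helpers ----

.zeros_like <- function(p) {
  if (is.list(p)) lapply(p, .zeros_like) else p * 0
}

# Parallel trees are paired by name where names exist (gradient trees are
# assembled in backward order), positionally otherwise.
.tree_keys <- function(p) {
  if (!is.null(names(p)) && all(nzchar(names(p)))) names(p) else seq_along(p)
}

.tree_add <- function(a, b) {
  if (is.list(a)) {
    for (k in .tree_keys(a)) a[[k]] <- .tree_add(a[[k]], b[[k]])
    a
  } else a + b
}

.sgdm_step <- function(p, g, v, lr, mom) {
  if (is.list(p)) {
    for (k in .tree_keys(p)) {
      st <- .sgdm_step(p[[k]], g[[k]], v[[k]], lr, mom)
      p[[k]] <- st$p
      v[[k]] <- st$v
    }
    list(p = p, v = v)
  } else {
    v2 <- mom * v - lr * g
    list(p = p + v2, v = v2)
  }
}

#' Save / load a model checkpoint
#' @param model A `ramm_model`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_ramm` returns `path` invisibly; `load_ramm` the model.
#' @export
save_ramm <- function(model, path) {
  stopifnot(inherits(model, "ramm_model"))
  saveRDS(model[setdiff(names(model), "idx")], path)
  invisible(path)
}

#' @rdname save_ramm
#' @export
load_ramm <- function(path) {
  m <- readRDS(path)
  m$idx <- .ramm_idx(m$cfg)
  structure(m[c("cfg", "shapes", "idx", "params", "trained", "history",
                "n_params")], class = "ramm_model")
}
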