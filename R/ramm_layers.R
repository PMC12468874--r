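# Layer primitives for the mixer network: each op has a forward returning
# (out, cache) and a backward mapping the upstream gradient to input and
# parameter gradients. Feature maps are (H, W, C) arrays per sample;
# token matrices are (S tokens, C channels).

# im2col gather-index for a 3D (H, W, C) map padded by p, kernel k, stride s.
# Rows: output positions (column-major). Columns: (kr, kc, cin) matching the
# column-major vectorisation of a (k, k, Cin, Cout) weight array.
.im2col_idx <- function(H, W, C, k, s, p) {
  Hp <- H + 2L * p; Wp <- W + 2L * p
  Ho <- (Hp - k) %/% s + 1L; Wo <- (Wp - k) %/% s + 1L
  r0 <- rep((seq_len(Ho) - 1L) * s, times = Wo)
  c0 <- rep((seq_len(Wo) - 1L) * s, each = Ho)
  kr <- rep(seq_len(k), times = k * C)
  kc <- rep(rep(seq_len(k), each = k), times = C)
  cc <- rep(seq_len(C), each = k * k)
  idx <- outer(r0, kr, "+") + Hp * outer(c0, kc - 1L, "+") +
    matrix((cc - 1L) * Hp * Wp, nrow = Ho * Wo, ncol = k * k * C, byrow = TRUE)
  storage.mode(idx) <- "integer"
  # scatter plan for the backward pass: sort the gather indices once, then
  # accumulate by cumsum over runs of equal target position
  ord <- order(idx)
  sorted <- idx[ord]
  ends <- which(c(sorted[-1L] != sorted[-length(sorted)], TRUE))
  structure(idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp, k = k, C = C, p = p,
            ord = ord, ends = ends, targets = sorted[ends])
}

.pad3 <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  xp
}

# 3x3 (or kxk) convolution, weights W (k,k,Cin,Cout), bias b (Cout).
conv_fw <- function(x, W, b, idx) {
  Ho <- attr(idx, "Ho"); Wo <- attr(idx, "Wo")
  xp <- .pad3(x, attr(idx, "p"))
  xcol <- matrix(xp[idx], nrow(idx), ncol(idx))
  Wm <- matrix(W, ncol(idx), length(b))
  y <- xcol %*% Wm
  y <- sweep(y, 2L, b, "+")
  list(out = array(y, c(Ho, Wo, length(b))),
       cache = list(xcol = xcol, dimx = dim(x)))
}

conv_bw <- function(dy, W, cache, idx) {
  Cout <- dim(W)[4]
  dym <- matrix(dy, ncol = Cout)
  dW <- array(crossprod(cache$xcol, dym), dim(W))
  db <- colSums(dym)
  dxcol <- dym %*% t(matrix(W, ncol(idx), Cout))
  Hp <- attr(idx, "Hp"); Wp <- attr(idx, "Wp"); p <- attr(idx, "p")
  C <- attr(idx, "C")
  cs <- cumsum(dxcol[attr(idx, "ord")])
  ends <- attr(idx, "ends")
  dxp <- numeric(Hp * Wp * C)
  dxp[attr(idx, "targets")] <- cs[ends] - c(0, cs[ends[-length(ends)]])
  dxp <- array(dxp, c(Hp, Wp, C))
  H <- cache$dimx[1]; Wd <- cache$dimx[2]
  dx <- if (p > 0L) dxp[(p + 1L):(p + H), (p + 1L):(p + Wd), , drop = FALSE] else dxp
  list(dx = array(dx, cache$dimx), dW = dW, db = db)
}

relu_fw <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bw <- function(dy, cache) dy * cache

# Squeeze-and-excitation channel attention: global average pool ->
# bottleneck MLP -> sigmoid gate, multiplied back onto each channel.
se_fw <- function(x, W1, b1, W2, b2) {
  d <- dim(x); hw <- d[1] * d[2]
  z <- colMeans(matrix(x, hw, d[3]))
  h_pre <- drop(z %*% W1) + b1
  h <- pmax(h_pre, 0)
  s <- 1 / (1 + exp(-(drop(h %*% W2) + b2)))
  out <- x * rep(s, each = hw)
  list(out = out, gates = s,
       cache = list(x = x, z = z, h = h, h_pre = h_pre, s = s, hw = hw, d = d))
}

se_bw <- function(dy, W1, W2, cache) {
  hw <- cache$hw; d <- cache$d
  dym <- matrix(dy, hw, d[3]); xm <- matrix(cache$x, hw, d[3])
  ds <- colSums(dym * xm)
  dx <- dy * rep(cache$s, each = hw)
  dpre2 <- ds * cache$s * (1 - cache$s)
  dW2 <- outer(cache$h, dpre2); db2 <- dpre2
  dh <- drop(W2 %*% dpre2) * (cache$h_pre > 0)
  dW1 <- outer(cache$z, dh); db1 <- dh
  dz <- drop(W1 %*% dh)
  dx <- dx + array(rep(dz / hw, each = hw), d)
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# Non-overlapping patch extraction: (H, W, C) map -> (S, p*p*C) tokens,
# tokens ordered column-major over the patch grid.
patchify_fw <- function(x, p) {
  d <- dim(x); gh <- d[1] %/% p; gw <- d[2] %/% p
  xr <- aperm(array(x, c(p, gh, p, gw, d[3])), c(1, 3, 5, 2, 4))
  list(out = matrix(xr, nrow = gh * gw, byrow = TRUE), d = d)
}

patchify_bw <- function(dy, p, d) {
  gh <- d[1] %/% p; gw <- d[2] %/% p
  xr <- array(t(dy), c(p, p, d[3], gh, gw))
  array(aperm(xr, c(1, 4, 2, 5, 3)), d)
}

dense_fw <- function(x, W, b) {
  y <- x %*% W
  list(out = sweep(y, 2L, b, "+"), cache = x)
}

dense_bw <- function(dy, W, cache) {
  list(dx = dy %*% t(W), dW = crossprod(cache, dy), db = colSums(dy))
}

# LayerNorm over the channel (last) dimension of an (S, C) token matrix.
layernorm_fw <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  istd <- 1 / sqrt(v + eps)
  xhat <- xc * istd
  list(out = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       cache = list(xhat = xhat, istd = istd))
}

layernorm_bw <- function(dy, g, cache) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat); db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, "*")
  m1 <- rowMeans(dxh); m2 <- rowMeans(dxh * xhat)
  dx <- (dxh - m1 - xhat * m2) * cache$istd
  list(dx = dx, dg = dg, db = db)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}
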