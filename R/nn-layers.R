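# Neural-network primitives. All spatial tensors are numeric arrays of
# shape (C, D, D, D, N) with the batch last; vector activations are
# matrices (features x N). Convolutions are computed as 27 (k^3) shifted
# GEMMs against the padded input, which keeps everything in BLAS. Every
# layer has an explicit backward pass; there is no autograd.

tensor5 <- function(x) {
  if (length(dim(x)) == 4) dim(x) <- c(dim(x), 1L)
  assert_that(length(dim(x)) == 5, "expected a (C, D, D, D, N) tensor")
  x
}

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4] + 2 * p, d[5]))
  out[, p + seq_len(d[2]), p + seq_len(d[3]), p + seq_len(d[4]), ] <- x
  out
}

# im2col buffers above this size (doubles) fall back to the slower
# offset-loop path to bound peak memory
.conv_buffer_limit <- 1.5e8

# cached integer gather indices that map a padded (C, P, P, P, N) tensor
# onto its im2col matrix (C*k^3, D^3*N); keyed by shape
.im2col_cache <- new.env(parent = emptyenv())

im2col_idx <- function(cc, k, sp, n) {
  key <- paste(cc, k, sp, n, sep = "_")
  hit <- .im2col_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1) %/% 2
  pp <- sp + 2 * p
  # column offsets (0-based, in elements) for each output position
  col_off <- outer(
    outer(cc * (seq_len(sp) - 1), cc * pp * (seq_len(sp) - 1), "+"),
    outer(cc * pp^2 * (seq_len(sp) - 1), cc * pp^3 * (seq_len(n) - 1), "+"),
    "+"
  )
  dim(col_off) <- NULL
  idx <- matrix(0L, cc * k^3, sp^3 * n)
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cs in seq_len(k)) {
    o <- a + k * (bb - 1) + k^2 * (cs - 1)
    base <- cc * ((a - 1) + pp * ((bb - 1) + pp * (cs - 1)))
    idx[(o - 1) * cc + seq_len(cc), ] <-
      outer(seq_len(cc), col_off + base, "+")
  }
  if (length(ls(.im2col_cache)) > 8) rm(list = ls(.im2col_cache),
                                        envir = .im2col_cache)
  .im2col_cache[[key]] <- idx
  idx
}

# W: (Cout, Cin, k, k, k); b: length Cout; same padding, stride 1.
# Fast path: materialize the im2col matrix (Cin*k^3, D^3*N) and run one
# large GEMM; this is also cached for the backward pass.
conv3d_forward <- function(x, W, b = NULL) {
  x <- tensor5(x)
  d <- dim(x)
  k <- dim(W)[3]
  p <- (k - 1) %/% 2
  cin <- dim(W)[2]
  cout <- dim(W)[1]
  assert_that(d[1] == cin,
              sprintf("conv3d: input has %d channels, weights expect %d", d[1], cin))
  sp <- d[2]
  n <- d[5]
  m <- sp^3 * n
  if (k == 1) {
    # pointwise channel mixing: a single GEMM, no patch extraction
    xm <- x
    dim(xm) <- c(cin, m)
    wcol <- W
    dim(wcol) <- c(cout, cin)
    y <- wcol %*% xm
    if (!is.null(b)) y <- y + b
    dim(y) <- c(cout, sp, sp, sp, n)
    return(list(out = y, xcol = xm, k = k, p = p, sp = sp, n = n,
                pointwise = TRUE))
  }
  xp <- pad_spatial(x, p)
  if (cin * k^3 * m <= .conv_buffer_limit) {
    xcol <- xp[im2col_idx(cin, k, sp, n)]
    dim(xcol) <- c(cin * k^3, m)
    wcol <- W
    dim(wcol) <- c(cout, cin * k^3)
    y <- wcol %*% xcol
    if (!is.null(b)) y <- y + b
    dim(y) <- c(cout, sp, sp, sp, n)
    return(list(out = y, xcol = xcol, k = k, p = p, sp = sp, n = n))
  }
  y <- matrix(0, cout, m)
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
    xs <- xp[, a + seq_len(sp) - 1, bb + seq_len(sp) - 1, cc + seq_len(sp) - 1, ,
             drop = FALSE]
    dim(xs) <- c(cin, m)
    wo <- W[, , a, bb, cc]
    dim(wo) <- c(cout, cin)
    y <- y + wo %*% xs
  }
  if (!is.null(b)) y <- y + b
  dim(y) <- c(cout, sp, sp, sp, n)
  list(out = y, xp = xp, k = k, p = p, sp = sp, n = n)
}

conv3d_backward <- function(cache, W, dout) {
  k <- cache$k
  p <- cache$p
  sp <- cache$sp
  cin <- dim(W)[2]
  cout <- dim(W)[1]
  n <- cache$n
  m <- sp^3 * n
  dy <- dout
  dim(dy) <- c(cout, m)
  db <- rowSums(dy)
  if (isTRUE(cache$pointwise)) {
    dW <- tcrossprod(dy, cache$xcol)
    dim(dW) <- dim(W)
    wcol <- W
    dim(wcol) <- c(cout, cin)
    dxm <- crossprod(wcol, dy)
    dim(dxm) <- c(cin, sp, sp, sp, n)
    return(list(dx = dxm, dW = dW, db = db))
  }
  # dx is the mirrored convolution of the padded output gradient:
  # dx(j) = sum_off W_off^T dy(j - off)
  dyp <- pad_spatial(dout, p)
  if (!is.null(cache$xcol)) {
    dW <- tcrossprod(dy, cache$xcol)
    dim(dW) <- dim(W)
    # mirrored gather: block o of dycol holds dyp shifted by (k-a, ...),
    # which is block (k+1-a, k+1-b, k+1-c) of the forward index map
    dycol <- dyp[im2col_idx(cout, k, sp, n)]
    dim(dycol) <- c(cout * k^3, m)
    mirror <- integer(cout * k^3)
    for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
      o <- a + k * (bb - 1) + k^2 * (cc - 1)
      om <- (k + 1 - a) + k * (k - bb) + k^2 * (k - cc)
      mirror[(o - 1) * cout + seq_len(cout)] <- (om - 1) * cout + seq_len(cout)
    }
    wrot <- aperm(W, c(2, 1, 3, 4, 5))
    dim(wrot) <- c(cin, cout * k^3)
    dxm <- wrot[, mirror, drop = FALSE] %*% dycol
    dim(dxm) <- c(cin, sp, sp, sp, n)
    return(list(dx = dxm, dW = dW, db = db))
  }
  xp <- cache$xp
  dW <- array(0, dim(W))
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
    xs <- xp[, a + seq_len(sp) - 1, bb + seq_len(sp) - 1, cc + seq_len(sp) - 1, ,
             drop = FALSE]
    dim(xs) <- c(cin, m)
    dW[, , a, bb, cc] <- tcrossprod(dy, xs)
  }
  dxm <- matrix(0, cin, m)
  for (a in seq_len(k)) for (bb in seq_len(k)) for (cc in seq_len(k)) {
    dys <- dyp[, (k - a) + seq_len(sp), (k - bb) + seq_len(sp),
               (k - cc) + seq_len(sp), , drop = FALSE]
    dim(dys) <- c(cout, m)
    wo <- W[, , a, bb, cc]
    dim(wo) <- c(cout, cin)
    dxm <- dxm + crossprod(wo, dys)
  }
  dim(dxm) <- c(cin, sp, sp, sp, n)
  list(dx = dxm, dW = dW, db = db)
}

# max pooling by factor s; trailing voxels beyond s * floor(D/s) dropped
maxpool_forward <- function(x, s = 2L) {
  x <- tensor5(x)
  d <- dim(x)
  dpool <- d[2] %/% s
  dc <- dpool * s
  out <- array(-Inf, c(d[1], dpool, dpool, dpool, d[5]))
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    cand <- x[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), , drop = FALSE]
    out <- pmax(out, cand)
  }
  list(out = out, x = x, s = s, dc = dc)
}

maxpool_backward <- function(cache, dout) {
  x <- cache$x
  s <- cache$s
  dc <- cache$dc
  d <- dim(x)
  ties <- array(0, dim(dout))
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    cand <- x[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), , drop = FALSE]
    ties <- ties + (cand == cache$out)
  }
  dx <- array(0, d)
  g <- dout / ties  # ties split the subgradient evenly
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    cand <- x[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), , drop = FALSE]
    dx[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), ] <-
      dx[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), , drop = FALSE] +
      g * (cand == cache$out)
  }
  dx
}

avgpool_forward <- function(x, s = 2L) {
  x <- tensor5(x)
  d <- dim(x)
  dpool <- d[2] %/% s
  dc <- dpool * s
  out <- array(0, c(d[1], dpool, dpool, dpool, d[5]))
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    out <- out + x[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), , drop = FALSE]
  }
  list(out = out / s^3, s = s, dc = dc, dims = d)
}

avgpool_backward <- function(cache, dout) {
  s <- cache$s
  dc <- cache$dc
  dx <- array(0, cache$dims)
  g <- dout / s^3
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    dx[, seq(i, dc, s), seq(j, dc, s), seq(k, dc, s), ] <- g
  }
  dx
}

# global spatial mean: (C, D, D, D, N) -> (C, N)
global_avgpool_forward <- function(x) {
  x <- tensor5(x)
  d <- dim(x)
  m <- x
  dim(m) <- c(d[1], prod(d[2:4]), d[5])
  out <- apply(m, 3, rowMeans)
  dim(out) <- c(d[1], d[5])
  list(out = out, dims = d)
}

global_avgpool_backward <- function(cache, dout) {
  d <- cache$dims
  nv <- prod(d[2:4])
  per <- dout / nv                       # (C, N), spread over all voxels
  big <- array(0, c(d[1], nv, d[5]))
  for (n in seq_len(d[5])) big[, , n] <- matrix(per[, n], d[1], nv)
  dim(big) <- d
  big
}

flatten_forward <- function(x) {
  x <- tensor5(x)
  d <- dim(x)
  y <- x
  dim(y) <- c(prod(d[1:4]), d[5])
  list(out = y, dims = d)
}

linear_forward <- function(x, W, b) {
  assert_that(nrow(x) == ncol(W),
              sprintf("linear: input has %d features, weights expect %d",
                      nrow(x), ncol(W)))
  list(out = W %*% x + b, x = x)
}

linear_backward <- function(cache, W, dout) {
  list(dx = crossprod(W, dout), dW = dout %*% t(cache$x), db = rowSums(dout))
}

relu_forward <- function(x) list(out = x * (x > 0), mask = x > 0)
relu_backward <- function(cache, dout) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- scalar LSTM over a sequence of embedding matrices ------------------
# Wx: (4H, E), Wh: (4H, H), b: 4H. Gate order: i, f, g, o.

lstm_forward <- function(xs, Wx, Wh, b) {
  h_dim <- nrow(Wh) / 4
  n <- ncol(xs[[1]])
  h <- matrix(0, h_dim, n)
  cc <- matrix(0, h_dim, n)
  caches <- vector("list", length(xs))
  for (t in seq_along(xs)) {
    z <- Wx %*% xs[[t]] + Wh %*% h + b
    i <- sigmoid(z[seq_len(h_dim), , drop = FALSE])
    f <- sigmoid(z[h_dim + seq_len(h_dim), , drop = FALSE])
    g <- tanh(z[2 * h_dim + seq_len(h_dim), , drop = FALSE])
    o <- sigmoid(z[3 * h_dim + seq_len(h_dim), , drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    caches[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = cc,
                        i = i, f = f, g = g, o = o, c_new = c_new)
    h <- h_new
    cc <- c_new
  }
  list(h = h, caches = caches)
}

lstm_backward <- function(caches, Wx, Wh, dh_last) {
  h_dim <- nrow(Wh) / 4
  t_len <- length(caches)
  dWx <- array(0, dim(Wx))
  dWh <- array(0, dim(Wh))
  db <- numeric(nrow(Wx))
  dh <- dh_last
  dc <- matrix(0, nrow(dh_last), ncol(dh_last))
  dxs <- vector("list", t_len)
  for (t in rev(seq_len(t_len))) {
    ca <- caches[[t]]
    tc <- tanh(ca$c_new)
    do_ <- dh * tc
    dc <- dc + dh * ca$o * (1 - tc^2)
    di <- dc * ca$g
    df <- dc * ca$c_prev
    dg <- dc * ca$i
    dz <- rbind(di * ca$i * (1 - ca$i),
                df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2),
                do_ * ca$o * (1 - ca$o))
    dWx <- dWx + dz %*% t(ca$x)
    dWh <- dWh + dz %*% t(ca$h_prev)
    db <- db + rowSums(dz)
    dxs[[t]] <- crossprod(Wx, dz)
    dh <- crossprod(Wh, dz)
    dc <- dc * ca$f
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}

# ---- convolutional LSTM cell -------------------------------------------
# Gates are 3D convolutions of the input and the previous hidden state:
# i, f, o = logistic(conv(x) + conv(h) + b), g = tanh(conv(x) + conv(h) + b),
# c_t = f * c_prev + i * g, h_t = o * tanh(c_t). No peephole terms.
# Wx: (4H, Cin, k, k, k); Wh: (4H, H, k, k, k); b: 4H.

#' One step of a convolutional LSTM
#'
#' Computes the gate pre-activations as same-padded 3D convolutions of
#' the current input and previous hidden state, then applies the
#' standard LSTM recurrences elementwise at every voxel:
#' `i, f, o = logistic(.)`, `g = tanh(.)`, `c_t = f * c_prev + i * g`,
#' `h_t = o * tanh(c_t)`. There are no peephole connections. With kernel
#' edge 1 this reduces, voxel by voxel, to an ordinary LSTM cell.
#'
#' @param x Input tensor `(Cin, D, D, D, N)` (or without batch dim).
#' @param h_prev,c_prev Hidden and cell state `(H, D, D, D, N)`.
#' @param Wx Input-to-gate kernels `(4H, Cin, k, k, k)`.
#' @param Wh Hidden-to-gate kernels `(4H, H, k, k, k)`.
#' @param b Gate biases, length `4H`, ordered (input, forget, candidate,
#'   output).
#' @return List with `h`, `c` (and a `cache` used by the training
#'   backward pass).
#' @export
convlstm_cell <- function(x, h_prev, c_prev, Wx, Wh, b) {
  x <- tensor5(x)
  h_prev <- tensor5(h_prev)
  c_prev <- tensor5(c_prev)
  assert_that(all(dim(x)[2:4] == dim(h_prev)[2:4]) &&
                all(dim(h_prev) == dim(c_prev)),
              "convlstm_cell: spatial shapes of x, h, c must agree")
  h_dim <- dim(Wh)[2]
  cx <- conv3d_forward(x, Wx, NULL)
  ch <- conv3d_forward(h_prev, Wh, NULL)
  z <- cx$out + ch$out
  dz <- dim(z)
  dim(z) <- c(dz[1], prod(dz[2:5]))
  z <- z + b
  dim(z) <- dz
  gate <- function(j) {
    g <- z[(j - 1) * h_dim + seq_len(h_dim), , , , , drop = FALSE]
    g
  }
  i <- sigmoid(gate(1))
  f <- sigmoid(gate(2))
  g <- tanh(gate(3))
  o <- sigmoid(gate(4))
  c_new <- f * c_prev + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new,
       cache = list(cx = cx, ch = ch, i = i, f = f, g = g, o = o,
                    c_prev = c_prev, c_new = c_new))
}

convlstm_cell_backward <- function(cache, Wx, Wh, dh, dc_in) {
  h_dim <- dim(Wh)[2]
  tc <- tanh(cache$c_new)
  do_ <- dh * tc
  dc <- dc_in + dh * cache$o * (1 - tc^2)
  di <- dc * cache$g
  df <- dc * cache$c_prev
  dg <- dc * cache$i
  dz_i <- di * cache$i * (1 - cache$i)
  dz_f <- df * cache$f * (1 - cache$f)
  dz_g <- dg * (1 - cache$g^2)
  dz_o <- do_ * cache$o * (1 - cache$o)
  dz <- abind_channels(list(dz_i, dz_f, dz_g, dz_o))
  bx <- conv3d_backward(cache$cx, Wx, dz)
  bh <- conv3d_backward(cache$ch, Wh, dz)
  dzm <- dz
  dim(dzm) <- c(4 * h_dim, length(dz) / (4 * h_dim))
  list(dx = bx$dx, dh_prev = bh$dx, dc_prev = dc * cache$f,
       dWx = bx$dW, dWh = bh$dW, db = rowSums(dzm))
}

# concatenate tensors along the channel (first) dimension
abind_channels <- function(tensors) {
  d1 <- dim(tensors[[1]])
  cs <- vapply(tensors, function(t) dim(t)[1], numeric(1))
  out <- array(0, c(sum(cs), d1[-1]))
  at <- 0
  for (t in tensors) {
    out[at + seq_len(dim(t)[1]), , , , ] <- t
    at <- at + dim(t)[1]
  }
  out
}

# ---- parameter initialization and the Adam optimizer --------------------

init_conv <- function(cout, cin, k) {
  fan_in <- cin * k^3
  array(rnorm(cout * cin * k^3, sd = sqrt(2 / fan_in)), c(cout, cin, k, k, k))
}

init_linear <- function(dout, din) {
  matrix(rnorm(dout * din, sd = sqrt(2 / din)), dout, din)
}

adam_init <- function(params) {
  zero_like <- function(p) {
    if (is.list(p)) purrr::map(p, zero_like) else p * 0
  }
  list(m = purrr::map(params, zero_like), v = purrr::map(params, zero_like),
       t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1
  t_ <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- purrr::pmap(list(p, g, m, v), upd)
      return(list(p = purrr::map(out, "p"), m = purrr::map(out, "m"),
                  v = purrr::map(out, "v")))
    }
    if (weight_decay > 0) g <- g + weight_decay * p
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t_)
    vhat <- v / (1 - beta2^t_)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  out <- purrr::pmap(list(params, grads, state$m, state$v), upd)
  list(params = purrr::map(out, "p"),
       state = list(m = purrr::map(out, "m"), v = purrr::map(out, "v"), t = t_))
}
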