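# Architecture contracts: shapes, determinism, dense-block channel
# arithmetic, the ConvLSTM cell against a per-voxel scalar LSTM oracle,
# and gradient flow for every family.

tiny_grid_cfg <- function(family, ...) {
  model_config(family, in_channels = 4, grid_edge = 6,
               conv_channels = c(5), conv_kernel = 3, pool = 2,
               n_blocks = 1, layers_per_block = 2, growth = 3,
               compression = 0.5, embed_dim = 6, lstm_hidden = 5,
               hidden_channels = 3, kernel_edge = 3, n_layers = 1,
               head = c(8), ...)
}

test_that("forward passes return one finite scalar per sample, deterministically", {
  for (family in c("cnn", "densenucy")) {
    m <- affinity_model(tiny_grid_cfg(family, seed = 3))
    set.seed(1)
    x <- array(rnorm(4 * 6^3 * 3), c(4, 6, 6, 6, 3))
    x[, , , , 3] <- x[, , , , 1]  # duplicate sample
    p <- predict(m, x)
    expect_length(p, 3)
    expect_true(all(is.finite(p)))
    expect_identical(p, predict(m, x))          # pure in eval mode
    expect_identical(p[1], p[3])                # duplicate -> identical
  }
  for (family in c("lrcn", "convlstm")) {
    m <- affinity_model(tiny_grid_cfg(family, seed = 4))
    set.seed(2)
    xs <- array(rnorm(2 * 4 * 6^3 * 3), c(2, 4, 6, 6, 6, 3))
    xs[, , , , , 3] <- xs[, , , , , 1]
    p <- predict(m, xs)
    expect_length(p, 3)
    expect_identical(p, predict(m, xs))
    expect_identical(p[1], p[3])
  }
})

test_that("shape mismatches are rejected with informative errors", {
  m <- affinity_model(tiny_grid_cfg("cnn"))
  expect_error(predict(m, array(0, c(4, 5, 5, 5, 1))), "does not match")
  expect_error(predict(m, array(0, c(3, 6, 6, 6, 1))), "does not match")
  ms <- affinity_model(tiny_grid_cfg("lrcn"))
  expect_error(predict(ms, array(0, c(4, 6, 6, 6))), "sequence model")
})

test_that("zero input through a zero-bias model predicts exactly zero", {
  zero_biases <- function(p) {
    rec <- function(q) {
      if (is.list(q) && !is.null(q$W)) q$b <- q$b * 0
      else if (is.list(q) && !is.null(q$Wx)) q$b <- q$b * 0
      else if (is.list(q)) q <- purrr::map(q, rec)
      q
    }
    purrr::map(p, rec)
  }
  for (family in c("cnn", "densenucy")) {
    m <- affinity_model(tiny_grid_cfg(family, seed = 5))
    m$params <- zero_biases(m$params)
    expect_identical(predict(m, array(0, c(4, 6, 6, 6, 2))), c(0, 0))
  }
  for (family in c("lrcn", "convlstm")) {
    m <- affinity_model(tiny_grid_cfg(family, seed = 6))
    m$params <- zero_biases(m$params)
    expect_identical(predict(m, array(0, c(3, 4, 6, 6, 6, 2))), c(0, 0))
  }
})

test_that("dense-block channel formula holds for random configurations", {
  set.seed(11)
  for (i in 1:50) {
    cin <- sample(1:64, 1)
    layers <- sample(0:6, 1)
    growth <- sample(1:32, 1)
    expect_equal(dense_block_channels(cin, layers, growth),
                 cin + layers * growth)
  }
  # realized output channels of an actual forward pass match the formula
  for (i in 1:5) {
    set.seed(20 + i)
    cin <- sample(2:6, 1)
    nl <- sample(1:3, 1)
    growth <- sample(2:5, 1)
    ly <- list(type = "dense_block", name = "db", n_layers = nl,
               growth = growth, k = 3L, cin = cin)
    params <- mdaffinity:::nn_init(list(ly))
    x <- array(rnorm(cin * 4^3 * 2), c(cin, 4, 4, 4, 2))
    out <- mdaffinity:::dense_block_forward(x, params$db, ly)$out
    expect_equal(dim(out)[1], dense_block_channels(cin, nl, growth))
  }
  # transition: compression then spatial halving
  expect_equal(transition_channels(84, 0.5), 42)
  expect_equal(transition_channels(83, 0.5), 41)  # floor
  cfg <- tiny_grid_cfg("densenucy")
  m <- affinity_model(cfg)
  x <- array(rnorm(4 * 6^3), c(4, 6, 6, 6, 1))
  fw <- mdaffinity:::nn_forward(m$compiled$body, m$params, x)
  # body output is flattened transition output: channels x (D/2)^3
  ch <- transition_channels(dense_block_channels(4, 2, 3), 0.5)
  expect_equal(nrow(fw$out), ch * 3^3)
  # a 0-layer block is the identity on channels
  expect_equal(dense_block_channels(19, 0, 16), 19)
})

test_that("convlstm cell matches a per-voxel scalar LSTM when kernel is 1", {
  # independent scalar LSTM oracle, written out longhand
  scalar_lstm_step <- function(x, h, c, wx, wh, b) {
    z <- wx %*% x + wh %*% h + b
    hd <- length(h)
    i <- plogis(z[1:hd]); f <- plogis(z[hd + 1:hd])
    g <- tanh(z[2 * hd + 1:hd]); o <- plogis(z[3 * hd + 1:hd])
    cn <- f * c + i * g
    list(h = o * tanh(cn), c = cn)
  }
  set.seed(31)
  cin <- 2; hd <- 3; d <- 4
  Wx <- array(rnorm(4 * hd * cin), c(4 * hd, cin, 1, 1, 1))
  Wh <- array(rnorm(4 * hd * hd), c(4 * hd, hd, 1, 1, 1))
  b <- rnorm(4 * hd)
  x <- array(rnorm(cin * d^3), c(cin, d, d, d, 1))
  h0 <- array(rnorm(hd * d^3), c(hd, d, d, d, 1))
  c0 <- array(rnorm(hd * d^3), c(hd, d, d, d, 1))
  st <- convlstm_cell(x, h0, c0, Wx, Wh, b)
  wx_m <- matrix(Wx, 4 * hd, cin)
  wh_m <- matrix(Wh, 4 * hd, hd)
  for (vox in list(c(1, 1, 1), c(2, 3, 4), c(4, 4, 4))) {
    want <- scalar_lstm_step(x[, vox[1], vox[2], vox[3], 1],
                             h0[, vox[1], vox[2], vox[3], 1],
                             c0[, vox[1], vox[2], vox[3], 1], wx_m, wh_m, b)
    expect_equal(st$h[, vox[1], vox[2], vox[3], 1], want$h, tolerance = 1e-6)
    expect_equal(st$c[, vox[1], vox[2], vox[3], 1], want$c, tolerance = 1e-6)
  }
})

test_that("convlstm cell analytics: zero case and forget-gate saturation", {
  cin <- 2; hd <- 2; d <- 3
  Wx <- array(0.3, c(4 * hd, cin, 1, 1, 1))
  Wh <- array(0.2, c(4 * hd, hd, 1, 1, 1))
  zero <- array(0, c(cin, d, d, d, 1))
  zh <- array(0, c(hd, d, d, d, 1))
  st <- convlstm_cell(zero, zh, zh, Wx, Wh, rep(0, 4 * hd))
  expect_equal(max(abs(st$h)), 0)   # g = tanh(0) = 0 forces c_t = 0
  expect_equal(max(abs(st$c)), 0)

  # f-gate bias -> +inf with zero input convs: c_t -> c_prev
  set.seed(41)
  c_prev <- array(rnorm(hd * d^3), c(hd, d, d, d, 1))
  b <- rep(0, 4 * hd)
  b[hd + 1:hd] <- 50
  st2 <- convlstm_cell(zero, zh, c_prev, Wx * 0, Wh * 0, b)
  expect_equal(st2$c, c_prev, tolerance = 1e-6)
  expect_error(convlstm_cell(zero, array(0, c(hd, 4, 4, 4, 1)), zh,
                             Wx, Wh, b), "shapes")
})

test_that("a 1-frame sequence reduces to encoder plus one recurrence step", {
  m <- affinity_model(tiny_grid_cfg("lrcn", seed = 8))
  set.seed(9)
  x1 <- array(rnorm(1 * 4 * 6^3), c(1, 4, 6, 6, 6, 1))
  p1 <- predict(m, x1)
  expect_length(p1, 1)
  # identical frames predict the same forwards and backwards in time
  xrep <- array(0, c(3, 4, 6, 6, 6, 1))
  for (t in 1:3) xrep[t, , , , , ] <- x1[1, , , , , ]
  expect_equal(predict(m, xrep), predict(m, xrep[3:1, , , , , , drop = FALSE]))
})

test_that("200 optimization steps shrink a 1-sample loss by 100x for every family", {
  for (family in c("cnn", "densenucy", "lrcn", "convlstm")) {
    cfg <- model_config(family, in_channels = 3, grid_edge = 4,
                        conv_channels = c(4), conv_kernel = 3, pool = 2,
                        n_blocks = 1, layers_per_block = 1, growth = 3,
                        embed_dim = 5, lstm_hidden = 4, hidden_channels = 3,
                        kernel_edge = 3, n_layers = 1, head = c(6), seed = 13)
    m <- affinity_model(cfg)
    set.seed(17)
    x <- if (family %in% c("lrcn", "convlstm")) {
      array(rnorm(2 * 3 * 4^3), c(2, 3, 4, 4, 4, 1))
    } else {
      array(rnorm(3 * 4^3), c(3, 4, 4, 4, 1))
    }
    y <- 2.0
    opt <- mdaffinity:::adam_init(m$params)
    loss0 <- NULL
    for (step in 1:200) {
      fw <- mdaffinity:::model_forward(m, x, train = TRUE)
      pred <- as.numeric(fw$out)
      loss <- (pred - y)^2
      if (step == 1) loss0 <- loss
      grads <- mdaffinity:::model_backward(m, fw, matrix(2 * (pred - y), 1))
      upd <- mdaffinity:::adam_step(m$params, grads[names(m$params)], opt,
                                    lr = 0.02)
      m$params <- upd$params
      opt <- upd$state
    }
    expect_lt(loss, loss0 / 100)
  }
})

test_that("checkpoints round-trip configuration and parameters", {
  m <- affinity_model(tiny_grid_cfg("densenucy", seed = 21))
  set.seed(3)
  x <- array(rnorm(4 * 6^3 * 2), c(4, 6, 6, 6, 2))
  path <- withr::local_tempfile(fileext = ".ckpt")
  save_model(m, path)
  back <- load_model(path)
  expect_equal(back$config, m$config)
  expect_identical(predict(back, x), predict(m, x))
  expect_equal(n_parameters(back), n_parameters(m))
  tab <- describe_model(m)
  expect_equal(tab$n_parameters[tab$module == "total"], n_parameters(m))
})
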