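# Architecture families. A model is a configuration plus a flat named
# parameter list; forwards cache intermediates so the training loop can
# run an explicit backward pass. Four families:
#   cnn        - plain 3D CNN (conv/relu/maxpool blocks, dense head)
#   densenucy  - dense blocks with transition layers instead of plain
#                conv blocks (input concatenated to every layer output)
#   lrcn       - shared per-frame CNN encoder feeding an LSTM over frames
#   convlstm   - stacked convolutional LSTM unrolled over frames
# Regression is linear on the pK scale (no output squashing).

#' Model configuration
#'
#' All layer counts and widths are configuration, with defaults in the
#' lineage of published pocket-grid CNNs: the plain CNN uses three conv
#' blocks (64/128/256,
#' kernel 5, maxpool 2); the dense-block family uses 3 blocks x 4 layers
#' with growth 16 and transition compression 0.5; the ConvLSTM uses
#' hidden 32, kernel 3, 2 layers; the fully connected head is
#' 1000-500-200-1. Desk-scale experiments shrink these through the same
#' arguments.
#'
#' @param family One of `"cnn"`, `"densenucy"`, `"lrcn"`, `"convlstm"`.
#' @param in_channels Input feature channels (default 19).
#' @param grid_edge Voxels per box side `D` (default 25).
#' @param conv_channels,conv_kernel,pool Conv stack for `cnn` and the
#'   `lrcn` encoder.
#' @param n_blocks,layers_per_block,growth,compression Dense-block spec
#'   for `densenucy`.
#' @param embed_dim,lstm_hidden Frame-embedding width and LSTM hidden
#'   size for `lrcn`.
#' @param hidden_channels,kernel_edge,n_layers ConvLSTM spec; the kernel
#'   edge must be odd.
#' @param head Widths of the fully connected head (final scalar layer is
#'   implicit).
#' @param dropout Dropout rate in the head (training only).
#' @param seed Seed for parameter initialization.
#' @return A `model_config` object.
#' @export
model_config <- function(family = c("cnn", "densenucy", "lrcn", "convlstm"),
                         in_channels = 19L, grid_edge = 25L,
                         conv_channels = c(64, 128, 256), conv_kernel = 5L,
                         pool = 2L,
                         n_blocks = 3L, layers_per_block = 4L, growth = 16L,
                         compression = 0.5,
                         embed_dim = 128L, lstm_hidden = 128L,
                         hidden_channels = 32L, kernel_edge = 3L, n_layers = 2L,
                         head = c(1000, 500, 200), dropout = 0,
                         seed = 1L) {
  family <- match.arg(family)
  assert_that(kernel_edge %% 2 == 1, "kernel_edge must be odd")
  assert_that(all(conv_kernel %% 2 == 1), "conv_kernel must be odd")
  assert_that(all(c(conv_channels, head, hidden_channels, embed_dim,
                    lstm_hidden) >= 1), "all widths must be >= 1")
  structure(
    list(family = family, in_channels = as.integer(in_channels),
         grid_edge = as.integer(grid_edge),
         conv_channels = as.integer(conv_channels),
         conv_kernel = as.integer(conv_kernel), pool = as.integer(pool),
         n_blocks = as.integer(n_blocks),
         layers_per_block = as.integer(layers_per_block),
         growth = as.integer(growth), compression = compression,
         embed_dim = as.integer(embed_dim),
         lstm_hidden = as.integer(lstm_hidden),
         hidden_channels = as.integer(hidden_channels),
         kernel_edge = as.integer(kernel_edge), n_layers = as.integer(n_layers),
         head = as.integer(head), dropout = dropout, seed = as.integer(seed)),
    class = "model_config"
  )
}

#' Output channels of a dense block
#'
#' Each of the `n_layers` internal layers sees the concatenation of the
#' block input and all previous layer outputs and emits `growth` new
#' channels, so the block output has `in_channels + n_layers * growth`
#' channels.
#'
#' @param in_channels,n_layers,growth Block spec.
#' @return Integer channel count.
#' @export
dense_block_channels <- function(in_channels, n_layers, growth) {
  as.integer(in_channels + n_layers * growth)
}

#' Output channels of a transition layer
#'
#' A transition compresses channels with a 1x1x1 convolution to
#' `floor(in_channels * compression)` and halves each spatial dimension
#' by average pooling.
#'
#' @param in_channels,compression Transition spec.
#' @return Integer channel count.
#' @export
transition_channels <- function(in_channels, compression) {
  as.integer(floor(in_channels * compression))
}

# ---- layer-list builders ------------------------------------------------

build_conv_stack <- function(cfg, d) {
  layers <- list()
  cin <- cfg$in_channels
  ks <- rep(cfg$conv_kernel, length.out = length(cfg$conv_channels))
  for (i in seq_along(cfg$conv_channels)) {
    cout <- cfg$conv_channels[i]
    layers <- c(layers, list(
      list(type = "conv", name = sprintf("conv%d", i), k = ks[i],
           cin = cin, cout = cout),
      list(type = "relu")
    ))
    # a 1x1x1 mixing layer keeps full resolution; others are pooled
    if (ks[i] > 1) {
      layers <- c(layers, list(list(type = "maxpool", s = cfg$pool)))
      d <- d %/% cfg$pool
    }
    cin <- cout
  }
  list(layers = layers, channels = cin, d = d)
}

build_dense_stack <- function(cfg, d) {
  layers <- list()
  cin <- cfg$in_channels
  for (i in seq_len(cfg$n_blocks)) {
    layers <- c(layers, list(
      list(type = "dense_block", name = sprintf("dense%d", i),
           n_layers = cfg$layers_per_block, growth = cfg$growth, k = 3L,
           cin = cin)
    ))
    cin <- dense_block_channels(cin, cfg$layers_per_block, cfg$growth)
    cout <- transition_channels(cin, cfg$compression)
    layers <- c(layers, list(
      list(type = "transition", name = sprintf("trans%d", i), cin = cin,
           cout = cout, s = 2L)
    ))
    cin <- cout
    d <- d %/% 2L
  }
  list(layers = layers, channels = cin, d = d)
}

build_head <- function(cfg, din, prefix = "fc") {
  layers <- list()
  for (i in seq_along(cfg$head)) {
    layers <- c(layers, list(
      list(type = "linear", name = sprintf("%s%d", prefix, i), din = din,
           dout = cfg$head[i]),
      list(type = "relu")
    ))
    if (cfg$dropout > 0) {
      layers <- c(layers, list(list(type = "dropout", rate = cfg$dropout)))
    }
    din <- cfg$head[i]
  }
  c(layers, list(list(type = "linear", name = sprintf("%s_out", prefix),
                      din = din, dout = 1L)))
}

compile_model <- function(cfg) {
  d <- cfg$grid_edge
  switch(cfg$family,
    cnn = {
      stack <- build_conv_stack(cfg, d)
      list(body = c(stack$layers, list(list(type = "flatten"))),
           head = build_head(cfg, stack$channels * stack$d^3))
    },
    densenucy = {
      stack <- build_dense_stack(cfg, d)
      list(body = c(stack$layers, list(list(type = "flatten"))),
           head = build_head(cfg, stack$channels * stack$d^3))
    },
    lrcn = {
      stack <- build_conv_stack(cfg, d)
      encoder <- c(stack$layers, list(
        list(type = "flatten"),
        list(type = "linear", name = "embed", din = stack$channels * stack$d^3,
             dout = cfg$embed_dim),
        list(type = "relu")
      ))
      list(encoder = encoder, head = build_head(cfg, cfg$lstm_hidden))
    },
    convlstm = {
      list(head = build_head(cfg, cfg$hidden_channels))
    }
  )
}

nn_init <- function(layers) {
  params <- list()
  for (ly in layers) {
    if (ly$type == "conv") {
      params[[ly$name]] <- list(W = init_conv(ly$cout, ly$cin, ly$k),
                                b = numeric(ly$cout))
    } else if (ly$type == "linear") {
      params[[ly$name]] <- list(W = init_linear(ly$dout, ly$din),
                                b = numeric(ly$dout))
    } else if (ly$type == "dense_block") {
      sub <- list()
      cin <- ly$cin
      for (j in seq_len(ly$n_layers)) {
        sub[[j]] <- list(W = init_conv(ly$growth, cin, ly$k),
                         b = numeric(ly$growth))
        cin <- cin + ly$growth
      }
      params[[ly$name]] <- sub
    } else if (ly$type == "transition") {
      params[[ly$name]] <- list(W = init_conv(ly$cout, ly$cin, 1L),
                                b = numeric(ly$cout))
    }
  }
  params
}

#' Instantiate an affinity model
#'
#' Initializes parameters (He-scaled Gaussians) from the config's seed.
#' The returned object predicts a single finite pK scalar per input
#' sample and is deterministic in evaluation mode.
#'
#' @param config A [model_config()].
#' @return An object of class `affinity_model`.
#' @export
affinity_model <- function(config) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  compiled <- compile_model(config)
  params <- withr::with_seed(config$seed, {
    p <- list()
    for (part in names(compiled)) {
      p <- c(p, nn_init(compiled[[part]]))
    }
    if (config$family == "lrcn") {
      h <- config$lstm_hidden
      e <- config$embed_dim
      p$lstm <- list(Wx = init_linear(4 * h, e) * sqrt(e / (e + h)),
                     Wh = init_linear(4 * h, h) * sqrt(h / (e + h)),
                     b = numeric(4 * h))
    }
    if (config$family == "convlstm") {
      cin <- config$in_channels
      for (l in seq_len(config$n_layers)) {
        hc <- config$hidden_channels
        p[[sprintf("cell%d", l)]] <- list(
          Wx = init_conv(4 * hc, cin, config$kernel_edge),
          Wh = init_conv(4 * hc, hc, config$kernel_edge) * 0.5,
          b = numeric(4 * hc)
        )
        cin <- hc
      }
    }
    p
  })
  structure(list(config = config, compiled = compiled, params = params),
            class = "affinity_model")
}

#' @export
print.affinity_model <- function(x, ...) {
  cat(sprintf("<affinity_model> family %s, %s parameters\n",
              x$config$family, format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model An [affinity_model()].
#' @return Integer count.
#' @export
n_parameters <- function(model) {
  count <- function(p) {
    if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  }
  sum(vapply(model$params, count, numeric(1)))
}

# ---- generic feedforward engine ----------------------------------------

nn_forward <- function(layers, params, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      pr <- params[[ly$name]]
      fw <- conv3d_forward(x, pr$W, pr$b)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "relu") {
      fw <- relu_forward(x)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "maxpool") {
      fw <- maxpool_forward(x, ly$s)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "avgpool") {
      fw <- avgpool_forward(x, ly$s)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "global_avgpool") {
      fw <- global_avgpool_forward(x)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "flatten") {
      fw <- flatten_forward(x)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "linear") {
      pr <- params[[ly$name]]
      fw <- linear_forward(x, pr$W, pr$b)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "dropout") {
      if (train && ly$rate > 0) {
        mask <- (matrix(runif(length(x)), nrow(x)) >= ly$rate) / (1 - ly$rate)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$type == "dense_block") {
      fw <- dense_block_forward(x, params[[ly$name]], ly)
      caches[[i]] <- fw
      x <- fw$out
    } else if (ly$type == "transition") {
      pr <- params[[ly$name]]
      cv <- conv3d_forward(x, pr$W, pr$b)
      ap <- avgpool_forward(cv$out, ly$s)
      caches[[i]] <- list(cv = cv, ap = ap)
      x <- ap$out
    } else {
      abort(sprintf("unknown layer type '%s'", ly$type))
    }
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, params, caches, dout) {
  grads <- list()
  dx <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    if (ly$type == "conv") {
      bw <- conv3d_backward(ca, params[[ly$name]]$W, dx)
      grads[[ly$name]] <- list(W = bw$dW, b = bw$db)
      dx <- bw$dx
    } else if (ly$type == "relu") {
      dx <- relu_backward(ca, dx)
    } else if (ly$type == "maxpool") {
      dx <- maxpool_backward(ca, dx)
    } else if (ly$type == "avgpool") {
      dx <- avgpool_backward(ca, dx)
    } else if (ly$type == "global_avgpool") {
      dx <- global_avgpool_backward(ca, dx)
    } else if (ly$type == "flatten") {
      dim(dx) <- ca$dims
    } else if (ly$type == "linear") {
      bw <- linear_backward(ca, params[[ly$name]]$W, dx)
      grads[[ly$name]] <- list(W = bw$dW, b = bw$db)
      dx <- bw$dx
    } else if (ly$type == "dropout") {
      if (!is.null(ca$mask)) dx <- dx * ca$mask
    } else if (ly$type == "dense_block") {
      bw <- dense_block_backward(ca, params[[ly$name]], ly, dx)
      grads[[ly$name]] <- bw$grads
      dx <- bw$dx
    } else if (ly$type == "transition") {
      dap <- avgpool_backward(ca$ap, dx)
      bw <- conv3d_backward(ca$cv, params[[ly$name]]$W, dap)
      grads[[ly$name]] <- list(W = bw$dW, b = bw$db)
      dx <- bw$dx
    }
  }
  list(dx = dx, grads = grads)
}

# dense block: layer j convolves the running concatenation (cin + (j-1) *
# growth channels) into `growth` new channels, ReLU, and appends them
dense_block_forward <- function(x, block_params, ly) {
  current <- tensor5(x)
  convs <- vector("list", ly$n_layers)
  relus <- vector("list", ly$n_layers)
  for (j in seq_len(ly$n_layers)) {
    pr <- block_params[[j]]
    cv <- conv3d_forward(current, pr$W, pr$b)
    rl <- relu_forward(cv$out)
    convs[[j]] <- cv
    relus[[j]] <- rl
    current <- abind_channels(list(current, rl$out))
  }
  list(out = current, convs = convs, relus = relus, cin = ly$cin,
       growth = ly$growth)
}

dense_block_backward <- function(cache, block_params, ly, dout) {
  growth <- ly$growth
  n_layers <- ly$n_layers
  dcurrent <- dout  # gradient wrt the full final concatenation
  grads <- vector("list", n_layers)
  for (j in rev(seq_len(n_layers))) {
    c_before <- ly$cin + (j - 1) * growth
    d_new <- dcurrent[c_before + seq_len(growth), , , , , drop = FALSE]
    dcurrent <- dcurrent[seq_len(c_before), , , , , drop = FALSE]
    drelu <- relu_backward(cache$relus[[j]], d_new)
    bw <- conv3d_backward(cache$convs[[j]], block_params[[j]]$W, drelu)
    grads[[j]] <- list(W = bw$dW, b = bw$db)
    dcurrent <- dcurrent + bw$dx
  }
  list(dx = dcurrent, grads = grads)
}

# ---- family forwards ----------------------------------------------------

# x: (C,D,D,D,N) for 3D families, (T,C,D,D,D,N) for sequence families
model_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  if (cfg$family %in% c("cnn", "densenucy")) {
    x <- tensor5(x)
    check_input_shape(cfg, dim(x)[1:4])
    body <- nn_forward(model$compiled$body, model$params, x, train)
    head <- nn_forward(model$compiled$head, model$params, body$out, train)
    list(out = head$out, cache = list(body = body, head = head))
  } else if (cfg$family == "lrcn") {
    x <- tensor6(x)
    check_input_shape(cfg, dim(x)[2:5])
    t_len <- dim(x)[1]
    enc_caches <- vector("list", t_len)
    embeds <- vector("list", t_len)
    for (t in seq_len(t_len)) {
      xt <- x[t, , , , , , drop = FALSE]
      dim(xt) <- dim(x)[-1]
      fw <- nn_forward(model$compiled$encoder, model$params, xt, train)
      enc_caches[[t]] <- if (train) fw$caches else NULL
      embeds[[t]] <- fw$out
    }
    lp <- model$params$lstm
    ls <- lstm_forward(embeds, lp$Wx, lp$Wh, lp$b)
    head <- nn_forward(model$compiled$head, model$params, ls$h, train)
    list(out = head$out,
         cache = list(enc = enc_caches, lstm = ls, head = head, dims = dim(x)))
  } else {
    x <- tensor6(x)
    check_input_shape(cfg, dim(x)[2:5])
    t_len <- dim(x)[1]
    n <- dim(x)[6]
    d <- dim(x)[3]
    hc <- cfg$hidden_channels
    hs <- cs <- purrr::map(seq_len(cfg$n_layers),
                           ~ array(0, c(hc, d, d, d, n)))
    cell_caches <- purrr::map(seq_len(cfg$n_layers), ~ vector("list", t_len))
    for (t in seq_len(t_len)) {
      inp <- x[t, , , , , , drop = FALSE]
      dim(inp) <- dim(x)[-1]
      for (l in seq_len(cfg$n_layers)) {
        pr <- model$params[[sprintf("cell%d", l)]]
        st <- convlstm_cell(inp, hs[[l]], cs[[l]], pr$Wx, pr$Wh, pr$b)
        hs[[l]] <- st$h
        cs[[l]] <- st$c
        cell_caches[[l]][[t]] <- if (train) st$cache else NULL
        inp <- st$h
      }
    }
    gp <- global_avgpool_forward(hs[[cfg$n_layers]])
    head <- nn_forward(model$compiled$head, model$params, gp$out, train)
    list(out = head$out,
         cache = list(cells = cell_caches, gp = gp, head = head,
                      dims = dim(x)))
  }
}

tensor6 <- function(x) {
  if (length(dim(x)) == 5) dim(x) <- c(dim(x), 1L)
  assert_that(length(dim(x)) == 6, "expected a (T, C, D, D, D, N) sequence tensor")
  x
}

check_input_shape <- function(cfg, got) {
  want <- c(cfg$in_channels, rep(cfg$grid_edge, 3))
  assert_that(all(got == want),
              sprintf("input shape (%s) does not match model (%s)",
                      paste(got, collapse = "x"), paste(want, collapse = "x")))
}

model_backward <- function(model, fw, dout) {
  cfg <- model$config
  cache <- fw$cache
  if (cfg$family %in% c("cnn", "densenucy")) {
    hb <- nn_backward(model$compiled$head, model$params, cache$head$caches, dout)
    bb <- nn_backward(model$compiled$body, model$params, cache$body$caches, hb$dx)
    c(hb$grads, bb$grads)
  } else if (cfg$family == "lrcn") {
    hb <- nn_backward(model$compiled$head, model$params, cache$head$caches, dout)
    lp <- model$params$lstm
    lb <- lstm_backward(cache$lstm$caches, lp$Wx, lp$Wh, hb$dx)
    enc_grads <- NULL
    for (t in seq_along(cache$enc)) {
      eb <- nn_backward(model$compiled$encoder, model$params, cache$enc[[t]],
                        lb$dxs[[t]])
      enc_grads <- if (is.null(enc_grads)) eb$grads else
        add_grads(enc_grads, eb$grads)
    }
    c(hb$grads, list(lstm = list(Wx = lb$dWx, Wh = lb$dWh, b = lb$db)),
      enc_grads)
  } else {
    hb <- nn_backward(model$compiled$head, model$params, cache$head$caches, dout)
    dh_last <- global_avgpool_backward(cache$gp, hb$dx)
    n_layers <- cfg$n_layers
    grads <- list()
    # dh[l][t]: gradient flowing into layer l's hidden state at step t
    dh_next <- purrr::map(seq_len(n_layers), ~ NULL)
    dc_next <- purrr::map(seq_len(n_layers), ~ NULL)
    dh_next[[n_layers]] <- dh_last
    dx_up <- vector("list", length(cache$cells[[1]]))  # grad from layer above
    for (l in rev(seq_len(n_layers))) {
      pr <- model$params[[sprintf("cell%d", l)]]
      dWx <- array(0, dim(pr$Wx)); dWh <- array(0, dim(pr$Wh))
      db <- numeric(length(pr$b))
      dh <- dh_next[[l]]
      dc <- NULL
      dx_below <- vector("list", length(cache$cells[[l]]))
      for (t in rev(seq_along(cache$cells[[l]]))) {
        ca <- cache$cells[[l]][[t]]
        dh_t <- if (t == length(cache$cells[[l]])) dh else dh_carry
        if (l < n_layers && !is.null(dx_up[[t]])) {
          dh_t <- if (is.null(dh_t)) dx_up[[t]] else dh_t + dx_up[[t]]
        }
        if (is.null(dh_t)) dh_t <- array(0, dim(ca$c_new))
        if (is.null(dc)) dc <- array(0, dim(ca$c_new))
        bw <- convlstm_cell_backward(ca, pr$Wx, pr$Wh, dh_t, dc)
        dWx <- dWx + bw$dWx; dWh <- dWh + bw$dWh; db <- db + bw$db
        dh_carry <- bw$dh_prev
        dc <- bw$dc_prev
        dx_below[[t]] <- bw$dx
      }
      grads[[sprintf("cell%d", l)]] <- list(Wx = dWx, Wh = dWh, b = db)
      dx_up <- dx_below
    }
    c(hb$grads, grads)
  }
}

add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- purrr::map2(a[[nm]], b[[nm]], function(x, y) {
      if (is.list(x)) purrr::map2(x, y, `+`) else x + y
    })
  }
  a
}

#' Predict binding affinity
#'
#' @param object An [affinity_model()].
#' @param newdata A [voxel_grid()], [voxel_sequence()], list of either,
#'   or a ready-made batch tensor (`(C, D, D, D, N)` or
#'   `(T, C, D, D, D, N)`).
#' @param ... Unused.
#' @return Numeric vector of predicted pK values, one per sample.
#' @export
predict.affinity_model <- function(object, newdata, ...) {
  x <- as_batch_tensor(newdata, object$config$family)
  fw <- model_forward(object, x, train = FALSE)
  as.numeric(fw$out)
}

as_batch_tensor <- function(newdata, family) {
  sequence_family <- family %in% c("lrcn", "convlstm")
  if (inherits(newdata, "voxel_grid")) newdata <- list(newdata)
  if (inherits(newdata, "voxel_sequence")) newdata <- list(newdata)
  if (is.list(newdata) && !is.null(newdata[[1]]) &&
      (inherits(newdata[[1]], "voxel_grid") ||
       inherits(newdata[[1]], "voxel_sequence"))) {
    arrs <- purrr::map(newdata, "values")
    dims <- dim(arrs[[1]])
    flat <- vapply(arrs, as.numeric, numeric(prod(dims)))
    newdata <- array(flat, c(dims, length(arrs)))
  }
  nd <- length(dim(newdata))
  if (sequence_family) {
    if (nd == 4) abort("sequence model requires (T, C, D, D, D) input")
    tensor6(newdata)
  } else {
    assert_that(nd %in% 4:5, "3D model requires (C, D, D, D [, N]) input")
    tensor5(newdata)
  }
}

#' Layer and parameter summary of a model
#'
#' @param model An [affinity_model()].
#' @return A tibble with one row per parameterized module.
#' @export
describe_model <- function(model) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, numeric(1))) else length(p)
  tibble::tibble(
    module = names(model$params),
    n_parameters = unname(vapply(model$params, count, numeric(1)))
  ) |>
    dplyr::bind_rows(tibble::tibble(module = "total",
                                    n_parameters = n_parameters(model)))
}

# ---- checkpoints --------------------------------------------------------

flatten_params <- function(params, prefix = "") {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(p) && is.null(names(p))) {
      for (j in seq_along(p)) {
        out <- c(out, flatten_params(p[[j]], paste0(key, "#", j, "/")))
      }
    } else if (is.list(p)) {
      out <- c(out, flatten_params(p, paste0(key, "/")))
    } else {
      out[[key]] <- p
    }
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single container file holding the JSON-encoded
#' configuration plus every parameter array.
#'
#' @param model An [affinity_model()].
#' @param path Checkpoint file path.
#' @return [load_model()]: the restored [affinity_model()].
#' @export
save_model <- function(model, path) {
  flat <- flatten_params(model$params)
  write_array_container(path, flat, meta = list(
    kind = "affinity_model_checkpoint",
    config = unclass(model$config)
  ))
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- read_array_container(path)
  assert_that(identical(raw$meta$kind, "affinity_model_checkpoint"),
              sprintf("'%s' is not a model checkpoint", path))
  cfg_list <- raw$meta$config
  cfg <- do.call(model_config, cfg_list[c(
    "family", "in_channels", "grid_edge", "conv_channels", "conv_kernel",
    "pool", "n_blocks", "layers_per_block", "growth", "compression",
    "embed_dim", "lstm_hidden", "hidden_channels", "kernel_edge", "n_layers",
    "head", "dropout", "seed")])
  model <- affinity_model(cfg)
  model$params <- restore_params(model$params, raw$arrays)
  model
}

restore_params <- function(template, flat, prefix = "") {
  for (nm in names(template)) {
    p <- template[[nm]]
    key <- paste0(prefix, nm)
    if (is.list(p) && is.null(names(p))) {
      for (j in seq_along(p)) {
        template[[nm]][[j]] <- restore_params(p[[j]], flat,
                                              paste0(key, "#", j, "/"))
      }
    } else if (is.list(p)) {
      template[[nm]] <- restore_params(p, flat, paste0(key, "/"))
    } else {
      stored <- flat[[key]]
      assert_that(!is.null(stored), sprintf("checkpoint missing '%s'", key))
      if (!is.null(dim(p))) dim(stored) <- dim(p)
      template[[nm]] <- stored
    }
  }
  template
}
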