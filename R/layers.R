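# Minimal layer framework backing the generator, critic and classifier.
#
# Activations flow as either a [H, W, C, N] array (spatial domain) or a
# [D, N] matrix (dense domain). Every layer implements forward (returning the
# output plus a cache) and backward (returning the input gradient and any
# parameter gradients). Activation layers additionally cache the elementwise
# slope mask so a linearized "tangent" pass can be run through the frozen
# network, which is what the exact gradient-penalty derivative needs.

same_pads <- function(n, k, stride) {
  # Keras 'same' convention: output ceiling(n / stride), extra pad goes to
  # the bottom/right side.
  out <- ceiling(n / stride)
  total <- max((out - 1L) * stride + k - n, 0L)
  c(floor(total / 2), total - floor(total / 2))
}

conv_out_shape <- function(in_shape, k, stride, padding) {
  h <- in_shape[1]; w <- in_shape[2]
  if (padding == "same") c(ceiling(h / stride), ceiling(w / stride))
  else c(floor((h - k) / stride) + 1L, floor((w - k) / stride) + 1L)
}

layer_conv <- function(in_ch, out_ch, k = 3L, stride = 1L,
                       padding = c("same", "valid")) {
  padding <- match.arg(padding)
  structure(list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = k,
                 stride = as.integer(stride), padding = padding,
                 w = NULL, b = NULL), class = "lg_layer")
}

layer_dense <- function(in_dim, out_dim) {
  structure(list(type = "dense", in_dim = in_dim, out_dim = out_dim,
                 w = NULL, b = NULL), class = "lg_layer")
}

layer_batchnorm <- function(channels, momentum = 0.9, eps = 1e-5) {
  structure(list(type = "batchnorm", channels = channels, momentum = momentum,
                 eps = eps, gamma = rep(1, channels), beta = rep(0, channels),
                 run_mean = rep(0, channels), run_var = rep(1, channels)),
            class = "lg_layer")
}

layer_activation <- function(fun = c("relu", "lrelu", "tanh"), alpha = 0.2) {
  fun <- match.arg(fun)
  structure(list(type = "activation", fun = fun, alpha = alpha),
            class = "lg_layer")
}

layer_upsample2 <- function() structure(list(type = "upsample2"), class = "lg_layer")
layer_maxpool2  <- function() structure(list(type = "maxpool2"),  class = "lg_layer")
layer_gap       <- function() structure(list(type = "gap"),       class = "lg_layer")
layer_flatten   <- function() structure(list(type = "flatten"),   class = "lg_layer")

# pads = c(top, bottom, left, right)
layer_zeropad <- function(pads) {
  structure(list(type = "zeropad", pads = as.integer(pads)), class = "lg_layer")
}

layer_reshape <- function(h, w, c) {
  structure(list(type = "reshape", h = h, w = w, c = c), class = "lg_layer")
}

# He-uniform for ReLU-family fan-ins, Glorot-uniform otherwise; the caller
# seeds the RNG, so initialization is deterministic per network seed.
init_layer <- function(layer) {
  if (layer$type == "conv") {
    fan_in <- layer$k * layer$k * layer$in_ch
    lim <- sqrt(6 / fan_in)
    layer$w <- array(runif(layer$k * layer$k * layer$in_ch * layer$out_ch,
                           -lim, lim),
                     dim = c(layer$k, layer$k, layer$in_ch, layer$out_ch))
    layer$b <- rep(0, layer$out_ch)
  } else if (layer$type == "dense") {
    lim <- sqrt(6 / (layer$in_dim + layer$out_dim))
    layer$w <- matrix(runif(layer$out_dim * layer$in_dim, -lim, lim),
                      layer$out_dim, layer$in_dim)
    layer$b <- rep(0, layer$out_dim)
  }
  layer
}

layer_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      d <- dim(x)
      if (layer$padding == "same") {
        ph <- same_pads(d[1], layer$k, layer$stride)
        pw <- same_pads(d[2], layer$k, layer$stride)
      } else ph <- pw <- c(0L, 0L)
      os <- conv_out_shape(d[1:2], layer$k, layer$stride, layer$padding)
      y <- conv2d_fw_cpp(x, dim(x), layer$w, dim(layer$w), layer$b,
                         layer$stride, ph[1], pw[1], os[1], os[2])
      list(out = y, cache = list(x = x, ph = ph, pw = pw, os = os))
    },
    dense = {
      y <- layer$w %*% x + layer$b
      list(out = y, cache = list(x = x))
    },
    batchnorm = {
      d <- dim(x); m <- d[1] * d[2] * d[4]
      xm <- aperm(x, c(1, 2, 4, 3)); dim(xm) <- c(m, d[3])
      if (train) {
        mu <- colMeans(xm)
        v <- colMeans(sweep(xm, 2, mu)^2)
      } else {
        mu <- layer$run_mean; v <- layer$run_var
      }
      istd <- 1 / sqrt(v + layer$eps)
      xhat <- sweep(sweep(xm, 2, mu), 2, istd, "*")
      ym <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
      dim(ym) <- c(d[1], d[2], d[4], d[3])
      y <- aperm(ym, c(1, 2, 4, 3))
      list(out = y,
           cache = list(xhat = xhat, istd = istd, d = d, m = m,
                        batch_mean = if (train) mu else NULL,
                        batch_var = if (train) v else NULL))
    },
    activation = {
      if (layer$fun == "tanh") {
        y <- tanh(x)
        list(out = y, cache = list(slope = NULL, y = y))
      } else {
        slope <- if (layer$fun == "relu") (x > 0) * 1
                 else (x > 0) + layer$alpha * (x <= 0)
        y <- x * slope
        list(out = y, cache = list(slope = slope))
      }
    },
    upsample2 = {
      d <- dim(x)
      y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
             drop = FALSE]
      list(out = y, cache = list(d = d))
    },
    maxpool2 = {
      r <- maxpool2_fw_cpp(x, dim(x))
      list(out = r$y, cache = list(argmax = r$argmax, d = dim(x)))
    },
    gap = {
      d <- dim(x)
      xm <- x; dim(xm) <- c(d[1] * d[2], d[3] * d[4])
      y <- colMeans(xm); dim(y) <- c(1, 1, d[3], d[4])
      list(out = y, cache = list(d = d))
    },
    flatten = {
      d <- dim(x)
      y <- x; dim(y) <- c(prod(d[1:3]), d[4])
      list(out = y, cache = list(d = d))
    },
    zeropad = {
      d <- dim(x); p <- layer$pads
      y <- array(0, dim = c(d[1] + p[1] + p[2], d[2] + p[3] + p[4], d[3], d[4]))
      y[p[1] + seq_len(d[1]), p[3] + seq_len(d[2]), , ] <- x
      list(out = y, cache = list(d = d))
    },
    reshape = {
      d <- dim(x)
      y <- x; dim(y) <- c(layer$h, layer$w, layer$c, d[2])
      list(out = y, cache = list(d = d))
    },
    stop("unknown layer type: ", layer$type)
  )
}

# Returns list(dx, grads) where grads is NULL or list(w=, b=) (batchnorm:
# list(gamma=, beta=)).
layer_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      r <- conv2d_bw_cpp(cache$x, dim(cache$x), layer$w, dim(layer$w), dy,
                         layer$stride, cache$ph[1], cache$pw[1],
                         cache$os[1], cache$os[2], TRUE, TRUE)
      list(dx = r$dx, grads = list(w = r$dw, b = r$db))
    },
    dense = {
      list(dx = crossprod(layer$w, dy),
           grads = list(w = tcrossprod(dy, cache$x), b = rowSums(dy)))
    },
    batchnorm = {
      d <- cache$d; m <- cache$m
      dym <- aperm(dy, c(1, 2, 4, 3)); dim(dym) <- c(m, d[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      dxhat <- sweep(dym, 2, layer$gamma, "*")
      dxm <- sweep(dxhat - matrix(colMeans(dxhat), m, d[3], byrow = TRUE) -
                     sweep(cache$xhat, 2,
                           colMeans(dxhat * cache$xhat), "*"),
                   2, cache$istd, "*")
      dim(dxm) <- c(d[1], d[2], d[4], d[3])
      list(dx = aperm(dxm, c(1, 2, 4, 3)),
           grads = list(gamma = dgamma, beta = dbeta))
    },
    activation = {
      if (layer$fun == "tanh") list(dx = dy * (1 - cache$y^2), grads = NULL)
      else list(dx = dy * cache$slope, grads = NULL)
    },
    upsample2 = {
      d <- cache$d
      io <- seq(1, 2 * d[1], by = 2); jo <- seq(1, 2 * d[2], by = 2)
      dx <- dy[io, jo, , , drop = FALSE] + dy[io + 1, jo, , , drop = FALSE] +
            dy[io, jo + 1, , , drop = FALSE] + dy[io + 1, jo + 1, , , drop = FALSE]
      list(dx = dx, grads = NULL)
    },
    maxpool2 = {
      list(dx = maxpool2_bw_cpp(dy, cache$argmax, cache$d), grads = NULL)
    },
    gap = {
      d <- cache$d
      g <- dy; dim(g) <- c(d[3], d[4])
      dx <- array(rep(g, each = d[1] * d[2]) / (d[1] * d[2]), dim = d)
      list(dx = dx, grads = NULL)
    },
    flatten = {
      dx <- dy; dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    },
    zeropad = {
      d <- cache$d; p <- layer$pads
      list(dx = dy[p[1] + seq_len(d[1]), p[3] + seq_len(d[2]), , , drop = FALSE],
           grads = NULL)
    },
    reshape = {
      dx <- dy; dim(dx) <- cache$d
      list(dx = dx, grads = NULL)
    }
  )
}

# Linearized (tangent) forward pass of direction `v` through the frozen
# network: linear layers apply their linear part without bias, activations
# multiply by the cached slope, max-pooling routes by the cached argmax.
# Exact almost everywhere for piecewise-linear networks (the critic).
layer_tangent <- function(layer, cache, v) {
  switch(layer$type,
    conv = {
      conv2d_fw_cpp(v, dim(v), layer$w, dim(layer$w),
                    rep(0, layer$out_ch), layer$stride,
                    cache$ph[1], cache$pw[1], cache$os[1], cache$os[2])
    },
    dense = layer$w %*% v,
    activation = {
      if (layer$fun == "tanh") stop("tangent pass requires piecewise-linear activations")
      v * cache$slope
    },
    maxpool2 = {
      d <- cache$d
      y <- v[cache$argmax]
      dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
      y
    },
    batchnorm = stop("tangent pass does not support batch normalization"),
    layer_forward(layer, v)$out
  )
}

# Shape bookkeeping used by the architecture audit. `in_shape` is c(H, W, C)
# or a scalar dense width; returns the output shape in the same convention.
layer_out_shape <- function(layer, in_shape) {
  switch(layer$type,
    conv = c(conv_out_shape(in_shape[1:2], layer$k, layer$stride,
                            layer$padding), layer$out_ch),
    dense = layer$out_dim,
    batchnorm = in_shape,
    activation = in_shape,
    upsample2 = c(in_shape[1] * 2, in_shape[2] * 2, in_shape[3]),
    maxpool2 = c(in_shape[1] / 2, in_shape[2] / 2, in_shape[3]),
    gap = c(1, 1, in_shape[3]),
    flatten = prod(in_shape),
    zeropad = c(in_shape[1] + layer$pads[1] + layer$pads[2],
                in_shape[2] + layer$pads[3] + layer$pads[4], in_shape[3]),
    reshape = c(layer$h, layer$w, layer$c)
  )
}
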