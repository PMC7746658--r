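#' Declarative network specification
#'
#' Describes one of the three networks (generator, discriminator/critic,
#' classifier) at an arbitrary scale. At the reference scale
#' (`image_size = 128`, `n_classes = 38`, `noise_dim = 1000`, base channel
#' widths 128/16/64) the layer-by-layer output sizes reproduce the published
#' architecture tables cell for cell (see [network_shape_audit()]); smaller
#' `image_size`/`base_channels` give CPU-friendly test-scale networks with the
#' same topology.
#'
#' @param role one of `"generator"`, `"discriminator"`, `"classifier"`.
#' @param image_size square image side in pixels. The generator requires a
#'   multiple of 16 (four 2x up-samplings from `image_size/16`); the
#'   classifier a multiple of 32 (five 2x max-poolings).
#' @param n_classes number of classes (reference scale: 38).
#' @param noise_dim generator noise dimension (reference scale: 1000).
#' @param base_channels width of the first block; all other widths scale from
#'   it (reference: generator 128, discriminator 16, classifier 64).
#' @return an object of class `network_spec`.
#' @export
network_spec <- function(role = c("generator", "discriminator", "classifier"),
                         image_size = 128L, n_classes = 38L,
                         noise_dim = 1000L, base_channels = NULL) {
  role <- match.arg(role)
  base_channels <- base_channels %||%
    switch(role, generator = 128L, discriminator = 16L, classifier = 64L)
  stopifnot(image_size >= 16, n_classes >= 2, noise_dim >= 1, base_channels >= 1)
  if (role == "generator") {
    if (image_size %% 16 != 0)
      stop("generator image_size must be a multiple of 16 (layer 'Dense ",
           image_size, "/16' would not be integral)")
    if (base_channels %% 4 != 0 && base_channels >= 4)
      stop("generator base_channels must be divisible by 4")
  }
  if (role == "classifier" && image_size %% 32 != 0)
    stop("classifier image_size must be a multiple of 32 (five max-poolings)")
  structure(list(role = role, image_size = as.integer(image_size),
                 n_classes = as.integer(n_classes),
                 noise_dim = as.integer(noise_dim),
                 base_channels = as.integer(base_channels)),
            class = "network_spec")
}

label_of <- function(layer, lab) { layer$label <- lab; layer }

generator_plan <- function(spec) {
  s0 <- spec$image_size %/% 16L
  b <- spec$base_channels
  c2 <- max(b %/% 2L, 1L); c3 <- max(b %/% 4L, 1L)
  list(
    layer_dense(spec$noise_dim, s0 * s0 * b),
    label_of(layer_reshape(s0, s0, b), "Dense"),
    layer_batchnorm(b), layer_activation("relu"),
    label_of(layer_upsample2(), "Up sampling"),
    label_of(layer_conv(b, b), sprintf("Conv3-%d", b)),
    layer_batchnorm(b), layer_activation("relu"),
    label_of(layer_upsample2(), "Up sampling"),
    label_of(layer_conv(b, c2), sprintf("Conv3-%d", c2)),
    layer_batchnorm(c2), layer_activation("relu"),
    label_of(layer_upsample2(), "Up sampling"),
    label_of(layer_conv(c2, c3), sprintf("Conv3-%d", c3)),
    layer_batchnorm(c3), layer_activation("relu"),
    label_of(layer_upsample2(), "Up sampling"),
    label_of(layer_conv(c3, 3L), "Conv3-3"),
    layer_activation("tanh")
  )
}

discriminator_plan <- function(spec) {
  b <- spec$base_channels
  list(
    label_of(layer_conv(3L, b, stride = 2L), sprintf("Conv3-%d(stride size = 2)", b)),
    layer_activation("lrelu"),
    label_of(layer_conv(b, 2L * b, stride = 2L), sprintf("Conv3-%d(stride size = 2)", 2L * b)),
    layer_activation("lrelu"),
    label_of(layer_zeropad(c(0L, 1L, 0L, 1L)), "Zero padding"),
    label_of(layer_conv(2L * b, 4L * b, stride = 2L), sprintf("Conv3-%d(stride size = 2)", 4L * b)),
    layer_activation("lrelu"),
    label_of(layer_conv(4L * b, 8L * b), sprintf("Conv3-%d", 8L * b)),
    layer_activation("lrelu"),
    layer_flatten()
  )
}

classifier_plan <- function(spec) {
  b <- spec$base_channels
  widths <- c(b, 2L * b, 4L * b, 8L * b, 8L * b)
  nconv <- c(2L, 2L, 3L, 3L, 3L)
  layers <- list()
  in_ch <- 3L
  for (blk in seq_len(5)) {
    for (j in seq_len(nconv[blk])) {
      layers <- c(layers, list(
        label_of(layer_conv(in_ch, widths[blk]), sprintf("Conv3-%d", widths[blk])),
        layer_activation("relu")))
      in_ch <- widths[blk]
    }
    layers <- c(layers, list(label_of(layer_maxpool2(), "MaxPooling")))
  }
  c(layers, list(
    label_of(layer_gap(), "AverPooling"),
    layer_flatten(),
    label_of(layer_dense(widths[5], widths[5]), sprintf("Dense %d", widths[5])),
    layer_activation("relu"),
    label_of(layer_dense(widths[5], spec$n_classes),
             sprintf("Dense %d", spec$n_classes))
  ))
}

chain_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

chain_backward <- function(layers, caches, dy, record_deltas = FALSE) {
  grads <- vector("list", length(layers))
  deltas <- if (record_deltas) vector("list", length(layers)) else NULL
  for (i in rev(seq_along(layers))) {
    if (record_deltas && !is.null(layers[[i]]$w)) deltas[[i]] <- dy
    r <- layer_backward(layers[[i]], caches[[i]], dy)
    dy <- r$dx
    grads[i] <- list(r$grads)   # keep NULL slots (plain [[<- would drop them)
  }
  list(dx = dy, grads = grads, deltas = deltas)
}

# Tangent (linearized) pass; returns the final tangent and the tangent seen
# at the *input* of every parametric layer (needed for the mixed second
# derivative of the gradient penalty).
chain_tangent <- function(layers, caches, v) {
  sin_ <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (!is.null(layers[[i]]$w)) sin_[[i]] <- v
    v <- layer_tangent(layers[[i]], caches[[i]], v)
  }
  list(out = v, inputs = sin_)
}

init_chain <- function(layers) lapply(layers, init_layer)

#' Build the conditional generator
#'
#' Maps a noise vector elementwise-multiplied with a per-class embedding row
#' to an RGB image in `[-1, 1]` (tanh output). Hidden layers use
#' batch-normalization + ReLU; spatial growth is four nearest-neighbour 2x
#' up-samplings from `image_size/16`.
#'
#' @param spec a [network_spec()] with `role = "generator"`.
#' @param seed integer seed for weight and embedding initialization.
#' @return an object of class `lg_generator`.
#' @export
build_generator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"), spec$role == "generator")
  with_seed(seed, {
    layers <- init_chain(generator_plan(spec))
    emb <- matrix(runif(spec$n_classes * spec$noise_dim, 0.5, 1.5),
                  spec$n_classes, spec$noise_dim)
  })
  structure(list(spec = spec, layers = layers, embedding = emb, seed = seed),
            class = c("lg_generator", "lg_network"))
}

#' Build the dual-head critic (discriminator)
#'
#' Convolutional trunk (LeakyReLU 0.2, no batch-norm so the per-sample
#' gradient penalty is well defined) feeding two heads: a 1-unit linear
#' validity score (Wasserstein critic) and an `n_classes`-unit class head.
#'
#' @inheritParams build_generator
#' @param spec a [network_spec()] with `role = "discriminator"`.
#' @return an object of class `lg_discriminator`.
#' @export
build_discriminator <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"), spec$role == "discriminator")
  shapes <- chain_shapes(discriminator_plan(spec),
                         c(spec$image_size, spec$image_size, 3))
  feat_dim <- shapes[[length(shapes)]]
  with_seed(seed, {
    layers <- init_chain(discriminator_plan(spec))
    head_v <- init_layer(layer_dense(feat_dim, 1L))
    head_c <- init_layer(layer_dense(feat_dim, spec$n_classes))
  })
  structure(list(spec = spec, layers = layers, head_v = head_v,
                 head_c = head_c, seed = seed),
            class = c("lg_discriminator", "lg_network"))
}

#' Build the VGG16-style classifier
#'
#' Five convolution blocks (2-2-3-3-3 convs, ReLU) each followed by 2x2
#' max-pooling, then global average pooling, a ReLU dense layer and a softmax
#' class output.
#'
#' @inheritParams build_generator
#' @param spec a [network_spec()] with `role = "classifier"`.
#' @return an object of class `lg_classifier`.
#' @export
build_classifier <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "network_spec"), spec$role == "classifier")
  layers <- with_seed(seed, init_chain(classifier_plan(spec)))
  structure(list(spec = spec, layers = layers, seed = seed),
            class = c("lg_classifier", "lg_network"))
}

chain_shapes <- function(layers, in_shape) {
  shapes <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    in_shape <- layer_out_shape(layers[[i]], in_shape)
    shapes[[i]] <- in_shape
  }
  shapes
}

#' Audit a network's layer-by-layer output sizes
#'
#' Walks the layer plan symbolically (no weights are allocated) and returns
#' one row per reportable layer with its output size, in the same layout as
#' the published architecture tables. Used to verify that the reference-scale
#' specs reproduce those tables exactly.
#'
#' @param spec a [network_spec()].
#' @return a data.frame with columns `layer`, `h`, `w`, `c` (dense layers
#'   report `h = w = NA` and `c` = unit count), plus an `Input Layer` row for
#'   the classifier.
#' @export
network_shape_audit <- function(spec) {
  plan <- switch(spec$role,
    generator = generator_plan(spec),
    discriminator = c(discriminator_plan(spec),
                      list(label_of(layer_dense(1, 1), "Dense 1"),
                           label_of(layer_dense(1, spec$n_classes),
                                    sprintf("Dense %d", spec$n_classes)))),
    classifier = classifier_plan(spec))
  in_shape <- if (spec$role == "generator") spec$noise_dim
              else c(spec$image_size, spec$image_size, 3)
  rows <- list()
  if (spec$role == "classifier")
    rows[[1]] <- data.frame(layer = "Input Layer", h = spec$image_size,
                            w = spec$image_size, c = 3)
  for (i in seq_along(plan)) {
    ly <- plan[[i]]
    if (ly$type == "dense" && spec$role == "discriminator" &&
        !is.null(ly$label) && grepl("^Dense", ly$label)) {
      # discriminator heads attach to the flattened trunk, not the chain tail
      rows[[length(rows) + 1]] <-
        data.frame(layer = ly$label, h = NA, w = NA, c = ly$out_dim)
      next
    }
    in_shape <- layer_out_shape(ly, in_shape)
    if (!is.null(ly$label)) {
      s <- in_shape
      rows[[length(rows) + 1]] <- if (length(s) == 3)
        data.frame(layer = ly$label, h = s[1], w = s[2], c = s[3])
      else data.frame(layer = ly$label, h = NA, w = NA, c = s)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Condition a noise vector on a class label
#'
#' The integer label indexes a learned embedding table (one row per class,
#' `noise_dim` wide); the conditioned generator input is the elementwise
#' product of the noise vector and the label's embedding row.
#'
#' @param label 0-based class index (scalar or vector of length `ncol(z)`).
#' @param z noise vector, or a `noise_dim x B` matrix of noise columns.
#' @param embedding `n_classes x noise_dim` embedding table (e.g.
#'   `generator$embedding`).
#' @return conditioned input with the same shape as `z`.
#' @export
embed_label <- function(label, z, embedding) {
  z <- as.matrix(z)
  if (any(label < 0 | label >= nrow(embedding)))
    stop("label out of range [0, ", nrow(embedding), ")")
  if (length(label) == 1L) label <- rep(label, ncol(z))
  stopifnot(length(label) == ncol(z), nrow(z) == ncol(embedding))
  z * t(embedding[label + 1L, , drop = FALSE])
}

generator_forward <- function(net, z, labels, train = FALSE) {
  cond <- embed_label(labels, z, net$embedding)
  r <- chain_forward(net$layers, cond, train)
  list(out = r$out, caches = r$caches, z = z, labels = labels)
}

generator_backward <- function(net, fwd, dimg) {
  r <- chain_backward(net$layers, fwd$caches, dimg)
  demb_rows <- r$dx * fwd$z                    # d(cond)/d(embedding row)
  demb <- matrix(0, nrow(net$embedding), ncol(net$embedding))
  acc <- rowsum(t(demb_rows), group = fwd$labels)
  demb[as.integer(rownames(acc)) + 1L, ] <- acc
  list(grads = r$grads, emb_grad = demb)
}

discriminator_forward <- function(net, x, train = FALSE) {
  r <- chain_forward(net$layers, x, train)
  feat <- r$out
  validity <- drop(net$head_v$w %*% feat + net$head_v$b)
  logits <- net$head_c$w %*% feat + net$head_c$b
  list(validity = validity, class_logits = logits,
       class_probs = softmax_cols(logits), feat = feat, caches = r$caches)
}

discriminator_backward <- function(net, fwd, dvalidity = NULL,
                                   dclass_logits = NULL,
                                   record_deltas = FALSE) {
  B <- ncol(fwd$feat)
  dfeat <- matrix(0, nrow(fwd$feat), B)
  gv <- gc_ <- NULL
  if (!is.null(dvalidity)) {
    dv <- matrix(dvalidity, 1L, B)
    gv <- list(w = tcrossprod(dv, fwd$feat), b = sum(dv))
    dfeat <- dfeat + crossprod(net$head_v$w, dv)
  }
  if (!is.null(dclass_logits)) {
    gc_ <- list(w = tcrossprod(dclass_logits, fwd$feat),
                b = rowSums(dclass_logits))
    dfeat <- dfeat + crossprod(net$head_c$w, dclass_logits)
  }
  r <- chain_backward(net$layers, fwd$caches, dfeat, record_deltas)
  list(dx = r$dx, grads = r$grads, head_v = gv, head_c = gc_,
       deltas = r$deltas)
}

classifier_forward <- function(net, x, train = FALSE) {
  r <- chain_forward(net$layers, x, train)
  list(logits = r$out, probs = softmax_cols(r$out), caches = r$caches)
}

classifier_backward <- function(net, fwd, dlogits) {
  chain_backward(net$layers, fwd$caches, dlogits)
}

#' Classifier class probabilities for a batch of images
#'
#' @param net an `lg_classifier`.
#' @param images `[H, W, 3, N]` array in `[0, 255]` (converted internally to
#'   the network input range `[-1, 1]`).
#' @return `n_classes x N` matrix of probabilities (columns sum to 1).
#' @export
predict_proba <- function(net, images) {
  classifier_forward(net, to_net_range(images))$probs
}

# [0,255] <-> [-1,1] conversions at the network boundary.
to_net_range <- function(img255) img255 / 127.5 - 1
from_net_range <- function(imgpm1) clamp((imgpm1 + 1) * 127.5, 0, 255)

# Linear critic used by tests and the gradient-penalty oracle: validity
# score w . x (flattened), arbitrary class head.
new_linear_critic <- function(w, image_dim, n_classes = 2L) {
  d <- prod(image_dim)
  stopifnot(length(w) == d)
  head_v <- layer_dense(d, 1L)
  head_v$w <- matrix(w, 1L, d); head_v$b <- 0
  head_c <- layer_dense(d, n_classes)
  head_c$w <- matrix(0, n_classes, d); head_c$b <- rep(0, n_classes)
  spec <- list(role = "discriminator", image_size = image_dim[1],
               n_classes = n_classes)
  structure(list(spec = spec, layers = list(layer_flatten()),
                 head_v = head_v, head_c = head_c, seed = NA),
            class = c("lg_discriminator", "lg_network"))
}
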