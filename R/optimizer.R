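# RMSprop (the optimizer used for both the GAN and the classifier) acting on
# the nested grads structure produced by the backward passes.

opt_rmsprop <- function(lr, rho = 0.9, eps = 1e-7) {
  list(lr = lr, rho = rho, eps = eps, ms = list())
}

rms_update <- function(param, grad, ms, opt) {
  if (is.null(ms)) ms <- param * 0
  ms <- opt$rho * ms + (1 - opt$rho) * grad^2
  list(param = param - opt$lr * grad / (sqrt(ms) + opt$eps), ms = ms)
}

# Sum two grads structures (lists parallel to layers, entries NULL or named
# lists of arrays).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  for (i in seq_along(b)) {
    if (is.null(b[[i]])) next
    if (is.null(a[[i]])) { a[[i]] <- b[[i]]; next }
    for (nm in names(b[[i]])) a[[i]][[nm]] <- a[[i]][[nm]] + b[[i]][[nm]]
  }
  a
}

# Apply one RMSprop update to a layer chain. `key` namespaces the optimizer
# state when one optimizer serves several chains (trunk + heads).
chain_update <- function(layers, grads, opt, key) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      sk <- paste0(key, ".", i, ".", nm)
      r <- rms_update(layers[[i]][[if (nm == "w") "w" else if (nm == "b") "b" else nm]],
                      g[[nm]], opt$ms[[sk]], opt)
      layers[[i]][[if (nm == "w") "w" else if (nm == "b") "b" else nm]] <- r$param
      opt$ms[[sk]] <- r$ms
    }
  }
  list(layers = layers, opt = opt)
}

dense_update <- function(layer, g, opt, key) {
  for (nm in names(g)) {
    sk <- paste0(key, ".", nm)
    r <- rms_update(layer[[nm]], g[[nm]], opt$ms[[sk]], opt)
    layer[[nm]] <- r$param
    opt$ms[[sk]] <- r$ms
  }
  list(layer = layer, opt = opt)
}
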