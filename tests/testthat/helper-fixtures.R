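# Shared in-code fixtures: small procedural datasets (memoized per spec) and
# a compact GAN configuration for smoke runs.

.fixtures <- new.env(parent = emptyenv())

tiny_leaf_ds <- function(n_classes = 2, train = 10, test = 5, size = 16,
                         strength = 1, seed = 1) {
  key <- paste(n_classes, train, test, size, strength, seed, sep = "_")
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- generate_dataset(
      leaf_dataset_spec(n_classes, train, test, size, strength, seed))
  .fixtures[[key]]
}

tiny_gan_config <- function(iters, seed = 1, critic_steps = 2, ...) {
  gan_train_config(total_iterations = iters, learning_rate = 2e-4,
                   batch_size = 8, critic_steps = critic_steps,
                   noise_dim = 16, base_channels_g = 8, base_channels_d = 4,
                   seed = seed, ...)
}

# weights-only view of a network (drops optimizer/history context)
net_weights <- function(net) {
  list(layers = lapply(net$layers, function(l)
         l[intersect(names(l), c("w", "b", "gamma", "beta"))]),
       head_v = net$head_v[c("w", "b")][!vapply(net$head_v[c("w", "b")],
                                                is.null, TRUE)],
       embedding = net$embedding)
}
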