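#' WGAN-GP-LSR training configuration
#'
#' Defaults follow the reference protocol: RMSprop with learning rate 5e-5,
#' gradient-penalty weight 10, label-smoothing epsilon 0.22, 5 critic updates
#' per generator update, Gaussian noise of dimension 1000 (scale
#' `noise_dim`/`base_channels_*` down for CPU-scale runs). One "iteration" is
#' `critic_steps` critic updates followed by one generator update.
#'
#' @param total_iterations iteration budget (reference scale trains ~22,000;
#'   fixed horizon, no early stopping).
#' @param learning_rate RMSprop learning rate for both networks.
#' @param batch_size minibatch size (>= 2; the gradient penalty interpolates
#'   pairs).
#' @param critic_steps critic updates per generator update.
#' @param lambda_gp gradient-penalty weight.
#' @param epsilon label-smoothing weight of the auxiliary class loss
#'   (0 disables smoothing, giving plain WGAN-GP with a cross-entropy class
#'   head).
#' @param class_loss_weight weight of the class loss relative to the
#'   Wasserstein + penalty terms.
#' @param noise_dim generator noise dimension.
#' @param base_channels_g,base_channels_d network widths
#'   ([network_spec()]).
#' @param augment optional [augment_config()]: when given, every real batch
#'   is passed through classic augmentation before the critic sees it
#'   (streaming augmentation, fresh draws per step).
#' @param seed master seed; every stochastic choice derives from it.
#' @param checkpoint_every iterations between checkpoints (`Inf` = none).
#' @param checkpoint_dir directory for checkpoints.
#' @export
gan_train_config <- function(total_iterations, learning_rate = 5e-5,
                             batch_size = 32L, critic_steps = 5L,
                             lambda_gp = 10, epsilon = 0.22,
                             class_loss_weight = 1, noise_dim = 1000L,
                             base_channels_g = 128L, base_channels_d = 16L,
                             augment = NULL, seed = 0L,
                             checkpoint_every = Inf, checkpoint_dir = NULL) {
  stopifnot(total_iterations >= 0, learning_rate >= 0, batch_size >= 2,
            critic_steps >= 1, lambda_gp >= 0, epsilon >= 0, epsilon <= 1,
            noise_dim >= 1)
  structure(list(total_iterations = as.integer(total_iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 critic_steps = as.integer(critic_steps),
                 lambda_gp = lambda_gp, epsilon = epsilon,
                 class_loss_weight = class_loss_weight,
                 noise_dim = as.integer(noise_dim),
                 base_channels_g = as.integer(base_channels_g),
                 base_channels_d = as.integer(base_channels_d),
                 augment = augment, seed = as.integer(seed),
                 checkpoint_every = checkpoint_every,
                 checkpoint_dir = checkpoint_dir),
            class = "gan_train_config")
}

#' Initialize a GAN training state
#'
#' @param image_size square image side (multiple of 16).
#' @param n_classes class count.
#' @param config a [gan_train_config()].
#' @return a `gan_train_state`: generator, discriminator, optimizers,
#'   iteration counter and an empty per-iteration history.
#' @export
gan_init <- function(image_size, n_classes, config) {
  gspec <- network_spec("generator", image_size, n_classes,
                        config$noise_dim, config$base_channels_g)
  dspec <- network_spec("discriminator", image_size, n_classes,
                        config$noise_dim, config$base_channels_d)
  structure(list(
    generator = build_generator(gspec, derive_seed(config$seed, 11L)),
    discriminator = build_discriminator(dspec, derive_seed(config$seed, 12L)),
    opt_g = opt_rmsprop(config$learning_rate),
    opt_d = opt_rmsprop(config$learning_rate),
    iteration = 0L,
    n_critic_updates = 0L, n_gen_updates = 0L,
    history = empty_history()),
    class = "gan_train_state")
}

empty_history <- function() {
  data.frame(iteration = integer(), critic_loss = numeric(),
             gen_loss = numeric(), wasserstein = numeric(),
             class_loss_real = numeric(), class_loss_fake = numeric(),
             gradient_penalty = numeric())
}

check_finite <- function(vals, what, iteration) {
  bad <- !vapply(vals, function(v) all(is.finite(v)), TRUE)
  if (any(bad))
    stop("non-finite ", paste(names(vals)[bad], collapse = ", "), " in ",
         what, " at iteration ", iteration,
         " (diagnostic: ", paste(names(vals), signif(vapply(vals, function(v)
           suppressWarnings(max(abs(v))), 1), 4), sep = "=",
           collapse = " "), ")")
}

update_bn_stats <- function(layers, caches) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "batchnorm" && !is.null(caches[[i]]$batch_mean)) {
      m <- ly$momentum
      layers[[i]]$run_mean <- m * ly$run_mean + (1 - m) * caches[[i]]$batch_mean
      layers[[i]]$run_var <- m * ly$run_var + (1 - m) * caches[[i]]$batch_var
    }
  }
  layers
}

#' One critic (discriminator) update
#'
#' Minimizes `-mean D(real) + mean D(fake) + lambda * GP + w_cls * LSR` on
#' the real images' class head. Real images carry validity label +1, fakes
#' -1; the generator is left untouched.
#'
#' @param state a `gan_train_state`.
#' @param real_batch a [labeled_image_set()] with at least 2 images.
#' @param config the [gan_train_config()].
#' @param step_seed seed for this step's noise, fake labels and
#'   interpolation draws (derived from `config$seed` and the iteration count
#'   when called from [train_wgan_gp_lsr()]).
#' @return the updated state, with nothing recorded in the history (the
#'   training loop records once per iteration); the step's losses are
#'   attached as attribute `"record"`.
#' @export
critic_step <- function(state, real_batch, config, step_seed = 0L) {
  B <- length(real_batch)
  if (B < 2) stop("critic_step needs a batch of >= 2 (pairwise interpolation)")
  G <- state$generator; D <- state$discriminator
  K <- D$spec$n_classes
  smp <- with_seed(step_seed, list(
    z = matrix(rnorm(config$noise_dim * B), config$noise_dim, B),
    labels = sample.int(K, B, replace = TRUE) - 1L,
    u = runif(B)))
  fake <- generator_forward(G, smp$z, smp$labels, train = TRUE)$out
  real <- to_net_range(real_batch$images)

  fr <- discriminator_forward(D, real)
  ff <- discriminator_forward(D, fake)
  w_loss <- wasserstein_critic_loss(fr$validity, ff$validity)
  cls_loss <- lsr_batch_loss(fr$class_probs, real_batch$labels, config$epsilon)
  gp <- gradient_penalty_full(D, real, fake, gp_params(config$lambda_gp),
                              u = smp$u, want_grads = TRUE)
  check_finite(list(wasserstein = w_loss, class_loss = cls_loss,
                    gradient_penalty = gp$penalty),
               "critic_step", state$iteration)

  br <- discriminator_backward(D, fr, dvalidity = rep(-1 / B, B),
                               dclass_logits = config$class_loss_weight *
                                 lsr_logit_grad(fr$class_probs,
                                                real_batch$labels,
                                                config$epsilon))
  bf <- discriminator_backward(D, ff, dvalidity = rep(1 / B, B))
  trunk_g <- grads_add(grads_add(br$grads, bf$grads), gp$grads)
  head_v_g <- Reduce(function(a, b) Map(`+`, a, b),
                     list(br$head_v, bf$head_v, gp$head_v))
  r <- chain_update(D$layers, trunk_g, state$opt_d, "trunk")
  D$layers <- r$layers; state$opt_d <- r$opt
  r <- dense_update(D$head_v, head_v_g, state$opt_d, "head_v")
  D$head_v <- r$layer; state$opt_d <- r$opt
  r <- dense_update(D$head_c, br$head_c, state$opt_d, "head_c")
  D$head_c <- r$layer; state$opt_d <- r$opt
  state$discriminator <- D
  state$n_critic_updates <- state$n_critic_updates + 1L
  attr(state, "record") <- list(
    critic_loss = w_loss + gp$penalty + config$class_loss_weight * cls_loss,
    wasserstein = mean(fr$validity) - mean(ff$validity),
    class_loss_real = cls_loss, gradient_penalty = gp$penalty)
  state
}

#' One generator (and label-embedding) update
#'
#' Minimizes `-mean D(G(z, y)) + w_cls * LSR(class head of D on fakes, y)`;
#' the discriminator is left untouched.
#'
#' @inheritParams critic_step
#' @export
generator_step <- function(state, config, step_seed = 0L) {
  G <- state$generator; D <- state$discriminator
  B <- config$batch_size
  K <- D$spec$n_classes
  smp <- with_seed(step_seed, list(
    z = matrix(rnorm(config$noise_dim * B), config$noise_dim, B),
    labels = sample.int(K, B, replace = TRUE) - 1L))
  fg <- generator_forward(G, smp$z, smp$labels, train = TRUE)
  fd <- discriminator_forward(D, fg$out)
  g_loss <- wasserstein_generator_loss(fd$validity)
  cls_loss <- lsr_batch_loss(fd$class_probs, smp$labels, config$epsilon)
  check_finite(list(gen_loss = g_loss, class_loss = cls_loss),
               "generator_step", state$iteration)
  bd <- discriminator_backward(D, fd, dvalidity = rep(-1 / B, B),
                               dclass_logits = config$class_loss_weight *
                                 lsr_logit_grad(fd$class_probs, smp$labels,
                                                config$epsilon))
  bg <- generator_backward(G, fg, bd$dx)
  r <- chain_update(G$layers, bg$grads, state$opt_g, "gen")
  G$layers <- r$layers; state$opt_g <- r$opt
  re <- rms_update(G$embedding, bg$emb_grad, state$opt_g$ms[["embedding"]],
                   state$opt_g)
  G$embedding <- re$param; state$opt_g$ms[["embedding"]] <- re$ms
  G$layers <- update_bn_stats(G$layers, fg$caches)
  state$generator <- G
  state$n_gen_updates <- state$n_gen_updates + 1L
  attr(state, "record") <- list(gen_loss = g_loss, class_loss_fake = cls_loss)
  state
}

#' Train a conditional WGAN-GP-LSR
#'
#' Runs `critic_steps` critic updates then one generator update per
#' iteration, for `total_iterations` iterations. Real batches are drawn
#' uniformly from `train_set` (every class must be represented at least
#' once) and, when `config$augment` is set, passed through classic
#' augmentation with fresh per-step draws. The history records one row per
#' iteration; checkpoints are written on the configured schedule.
#'
#' @param train_set a [labeled_image_set()] covering every class.
#' @param config a [gan_train_config()].
#' @param state optional state to resume from (default: fresh [gan_init()]).
#' @return the final `gan_train_state`.
#' @export
train_wgan_gp_lsr <- function(train_set, config, state = NULL) {
  stopifnot(inherits(train_set, "labeled_image_set"),
            inherits(config, "gan_train_config"))
  d <- dim(train_set$images)
  K <- length(train_set$class_names)
  missing_cls <- setdiff(seq_len(K) - 1L, unique(train_set$labels))
  if (length(missing_cls) > 0)
    stop("classes with zero training examples: ",
         paste(missing_cls, collapse = ", "))
  if (is.null(state)) state <- gan_init(d[1], K, config)
  n <- length(train_set)
  for (it in seq_len(config$total_iterations)) {
    state$iteration <- state$iteration + 1L
    rec_c <- NULL
    for (j in seq_len(config$critic_steps)) {
      idx <- with_seed(derive_seed(config$seed, state$iteration, j, 1L),
                       sample.int(n, min(config$batch_size, n)))
      rb <- train_set[idx]
      if (!is.null(config$augment))
        rb <- augment_batch(rb, config$augment,
                            derive_seed(config$seed, state$iteration, j, 2L))
      state <- critic_step(state, rb, config,
                           derive_seed(config$seed, state$iteration, j, 3L))
      rec_c <- attr(state, "record")
    }
    state <- generator_step(state, config,
                            derive_seed(config$seed, state$iteration, 0L, 4L))
    rec_g <- attr(state, "record")
    state$history <- rbind(state$history, data.frame(
      iteration = state$iteration, critic_loss = rec_c$critic_loss,
      gen_loss = rec_g$gen_loss, wasserstein = rec_c$wasserstein,
      class_loss_real = rec_c$class_loss_real,
      class_loss_fake = rec_g$class_loss_fake,
      gradient_penalty = rec_c$gradient_penalty))
    if (is.finite(config$checkpoint_every) &&
        state$iteration %% config$checkpoint_every == 0 &&
        !is.null(config$checkpoint_dir))
      save_gan_checkpoint(state, config$checkpoint_dir)
  }
  attr(state, "record") <- NULL
  state$config <- config
  state
}

#' Generate labeled synthetic images from a trained state
#'
#' Generates `n_per_class` images conditioned on each class. The final label
#' is either the conditioning label or the class the discriminator's class
#' head finds most probable (`discriminator_argmax`, ties to the lowest
#' index); the disagreement rate between the two labelings is attached as
#' attribute `"relabel_disagreement"`.
#'
#' @param state a trained `gan_train_state`.
#' @param n_per_class images per class.
#' @param labeling `"discriminator_argmax"` (default) or `"conditioning"`.
#' @param seed seed for the noise draws.
#' @return a [labeled_image_set()] with `n_per_class * n_classes` images in
#'   `[0, 255]`.
#' @export
synthesize_labeled_images <- function(state, n_per_class,
                                      labeling = c("discriminator_argmax",
                                                   "conditioning"),
                                      seed = 0L) {
  labeling <- match.arg(labeling)
  G <- state$generator; D <- state$discriminator
  K <- G$spec$n_classes
  n <- K * n_per_class
  imgs <- array(0, c(G$spec$image_size, G$spec$image_size, 3, n))
  cond <- integer(n)
  at <- 0L
  for (k in seq_len(K) - 1L) {
    z <- with_seed(derive_seed(seed, k, 7L),
                   matrix(rnorm(G$spec$noise_dim * n_per_class),
                          G$spec$noise_dim, n_per_class))
    out <- generator_forward(G, z, rep(k, n_per_class), train = FALSE)$out
    imgs[, , , at + seq_len(n_per_class)] <- from_net_range(out)
    cond[at + seq_len(n_per_class)] <- k
    at <- at + n_per_class
  }
  pred <- apply(discriminator_forward(D, to_net_range(imgs))$class_probs, 2,
                which.max) - 1L
  labels <- if (labeling == "conditioning") cond else pred
  res <- labeled_image_set(imgs, labels,
                           sprintf("class_%02d", seq_len(K) - 1L))
  attr(res, "relabel_disagreement") <- mean(pred != cond)
  res
}

#' Save / load GAN checkpoints
#'
#' Weights go to an iteration-stamped `.rds` (R's native serialization); a
#' JSON sidecar records the network specs, iteration and seed.
#'
#' @param state a `gan_train_state`.
#' @param dir checkpoint directory (created if missing).
#' @return the checkpoint path, invisibly.
#' @export
save_gan_checkpoint <- function(state, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- file.path(dir, sprintf("checkpoint_%06d", state$iteration))
  saveRDS(state, paste0(stem, ".rds"))
  jsonlite::write_json(list(iteration = state$iteration,
                            generator_spec = unclass(state$generator$spec),
                            discriminator_spec = unclass(state$discriminator$spec),
                            generator_seed = state$generator$seed,
                            discriminator_seed = state$discriminator$seed),
                       paste0(stem, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(paste0(stem, ".rds"))
}

#' @rdname save_gan_checkpoint
#' @param path an `.rds` checkpoint path.
#' @export
load_gan_checkpoint <- function(path) readRDS(path)
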