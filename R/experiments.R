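#' Training-regime specification
#'
#' The four regimes of the comparison protocol. Per epoch the classifier
#' sees, for a training set of `N` real images across `K` classes:
#' regime I — the `N` originals, unchanged every epoch; regime II — `N`
#' freshly augmented images (0 originals); regimes III/IV — `N` freshly
#' augmented images plus `n_synthetic_per_class * K` freshly generated
#' synthetic images (GAN trained without LSR for III, with LSR for IV).
#' Reference-protocol defaults: 700 epochs, batch size 100, RMSprop
#' learning rate 1e-4, 30 synthetic images per class per epoch.
#'
#' @param regime `"I"`, `"II"`, `"III"` or `"IV"`.
#' @param epochs training epochs.
#' @param batch_size classifier minibatch size.
#' @param learning_rate RMSprop learning rate.
#' @param n_synthetic_per_class synthetic images per class per epoch
#'   (regimes III/IV).
#' @param labeling label assignment for synthetic images
#'   ([synthesize_labeled_images()]).
#' @param base_channels classifier width knob ([network_spec()]).
#' @param seed master seed for initialization, shuffling and per-epoch
#'   randomness.
#' @export
regime_spec <- function(regime = c("I", "II", "III", "IV"), epochs = 700L,
                        batch_size = 100L, learning_rate = 1e-4,
                        n_synthetic_per_class = 30L,
                        labeling = c("discriminator_argmax", "conditioning"),
                        base_channels = 64L, seed = 0L) {
  regime <- match.arg(regime)
  labeling <- match.arg(labeling)
  stopifnot(epochs >= 0, batch_size >= 1, learning_rate >= 0,
            n_synthetic_per_class >= 1)
  structure(list(regime = regime, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 n_synthetic_per_class = as.integer(n_synthetic_per_class),
                 labeling = labeling, lsr_for_gan = regime == "IV",
                 base_channels = as.integer(base_channels),
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' Per-epoch data composition of a regime
#'
#' Returns the counts of original, classic-augmented and synthetic images a
#' regime uses in every epoch, for a training set of `n_train` images over
#' `n_classes` classes.
#'
#' @param regime regime letter or a [regime_spec()].
#' @param n_train training-set size.
#' @param n_classes class count.
#' @param n_synthetic_per_class synthetic images per class (III/IV).
#' @return list with `n_original`, `n_classic_aug`, `n_synthetic`.
#' @export
regime_epoch_plan <- function(regime, n_train, n_classes,
                              n_synthetic_per_class = 30L) {
  if (inherits(regime, "regime_spec")) {
    n_synthetic_per_class <- regime$n_synthetic_per_class
    regime <- regime$regime
  }
  switch(regime,
    I = list(n_original = n_train, n_classic_aug = 0L, n_synthetic = 0L),
    II = list(n_original = 0L, n_classic_aug = n_train, n_synthetic = 0L),
    III = ,
    IV = list(n_original = 0L, n_classic_aug = n_train,
              n_synthetic = n_synthetic_per_class * n_classes),
    stop("unknown regime: ", regime))
}

#' Assemble the dataset one epoch of a regime trains on
#'
#' @param train_set the real training [labeled_image_set()].
#' @param regime a [regime_spec()].
#' @param gan_state trained `gan_train_state` (required for III/IV).
#' @param epoch epoch number (drives the fresh augmentation/synthesis
#'   draws).
#' @param aug_config the [augment_config()] for the classic transforms.
#' @return a [labeled_image_set()] whose composition matches
#'   [regime_epoch_plan()].
#' @export
compose_epoch_dataset <- function(train_set, regime, gan_state = NULL,
                                  epoch = 1L, aug_config = augment_config()) {
  stopifnot(inherits(regime, "regime_spec"))
  if (regime$regime %in% c("III", "IV") && is.null(gan_state))
    stop("regime ", regime$regime, " requires a trained gan_state")
  if (regime$regime == "I") return(train_set)
  aug <- augment_batch(train_set, aug_config,
                       derive_seed(regime$seed, epoch, 31L))
  if (regime$regime == "II") return(aug)
  synth <- synthesize_labeled_images(gan_state, regime$n_synthetic_per_class,
                                     regime$labeling,
                                     derive_seed(regime$seed, epoch, 32L))
  lis_concat(aug, synth)
}

classifier_accuracy <- function(net, images, labels, chunk = 100L) {
  n <- dim(images)[4]
  correct <- 0L
  at <- 1L
  while (at <= n) {
    ix <- at:min(at + chunk - 1L, n)
    pr <- classifier_forward(net, to_net_range(images[, , , ix, drop = FALSE]))
    correct <- correct + sum(max.col(t(pr$probs), ties.method = "first") - 1L ==
                               labels[ix])
    at <- at + chunk
  }
  correct / n
}

classifier_predict <- function(net, images, chunk = 100L) {
  n <- dim(images)[4]
  out <- integer(n)
  at <- 1L
  while (at <= n) {
    ix <- at:min(at + chunk - 1L, n)
    pr <- classifier_forward(net, to_net_range(images[, , , ix, drop = FALSE]))
    out[ix] <- max.col(t(pr$probs), ties.method = "first") - 1L
    at <- at + chunk
  }
  out
}

#' Train the classifier under one regime
#'
#' Recomposes the epoch dataset per [compose_epoch_dataset()], trains the
#' VGG16-style classifier with RMSprop and softmax cross-entropy, and
#' evaluates on the fixed test set every epoch. Training accuracy is
#' measured on the composed (augmented + synthetic) epoch data — the data
#' the optimizer actually sees — via the predictions made during the
#' training forward passes.
#'
#' @param train_set,test_set disjoint [labeled_image_set()]s of equal image
#'   size.
#' @param regime a [regime_spec()].
#' @param gan_state trained GAN state (regimes III/IV).
#' @param aug_config [augment_config()] for the classic transforms.
#' @return an `experiment_report`: regime, final accuracies, per-epoch
#'   curves, test confusion matrix and per-class metrics.
#' @export
train_classifier <- function(train_set, test_set, regime, gan_state = NULL,
                             aug_config = augment_config()) {
  stopifnot(inherits(train_set, "labeled_image_set"),
            inherits(test_set, "labeled_image_set"))
  d <- dim(train_set$images)
  K <- length(train_set$class_names)
  spec <- network_spec("classifier", d[1], K,
                       base_channels = regime$base_channels)
  net <- build_classifier(spec, derive_seed(regime$seed, 21L))
  opt <- opt_rmsprop(regime$learning_rate)
  curves <- data.frame(epoch = integer(), train_accuracy = numeric(),
                       test_accuracy = numeric())
  composition <- data.frame(epoch = integer(), n_original = integer(),
                            n_classic_aug = integer(), n_synthetic = integer())
  for (epoch in seq_len(regime$epochs)) {
    ds <- compose_epoch_dataset(train_set, regime, gan_state, epoch,
                                aug_config)
    plan <- regime_epoch_plan(regime, length(train_set), K)
    composition <- rbind(composition, data.frame(
      epoch = epoch, n_original = plan$n_original,
      n_classic_aug = plan$n_classic_aug, n_synthetic = plan$n_synthetic))
    ord <- with_seed(derive_seed(regime$seed, epoch, 33L),
                     sample.int(length(ds)))
    correct <- 0L
    at <- 1L
    while (at <= length(ds)) {
      ix <- ord[at:min(at + regime$batch_size - 1L, length(ds))]
      x <- to_net_range(ds$images[, , , ix, drop = FALSE])
      y <- ds$labels[ix]
      B <- length(ix)
      fw <- classifier_forward(net, x, train = TRUE)
      loss <- lsr_batch_loss(fw$probs, y, 0)
      if (!is.finite(loss))
        stop("non-finite classifier loss at epoch ", epoch)
      correct <- correct + sum(max.col(t(fw$probs), ties.method = "first") -
                                 1L == y)
      dlogits <- lsr_logit_grad(fw$probs, y, 0)
      bw <- classifier_backward(net, fw, dlogits)
      r <- chain_update(net$layers, bw$grads, opt, "clf")
      net$layers <- r$layers; opt <- r$opt
      at <- at + regime$batch_size
    }
    curves <- rbind(curves, data.frame(
      epoch = epoch, train_accuracy = correct / length(ds),
      test_accuracy = classifier_accuracy(net, test_set$images,
                                          test_set$labels)))
  }
  pred <- classifier_predict(net, test_set$images)
  cm <- confusion_matrix(test_set$labels, pred, K, test_set$class_names)
  structure(list(
    regime = regime$regime,
    final_train_accuracy = if (nrow(curves)) curves$train_accuracy[nrow(curves)]
                           else classifier_accuracy(net, train_set$images,
                                                    train_set$labels),
    final_test_accuracy = if (nrow(curves)) curves$test_accuracy[nrow(curves)]
                          else classifier_accuracy(net, test_set$images,
                                                   test_set$labels),
    curves = curves, composition = composition, confusion = cm,
    per_class = per_class_metrics(cm), classifier = net),
    class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("<experiment_report> regime %s: train %.3f, test %.3f (%d epochs)\n",
              x$regime, x$final_train_accuracy, x$final_test_accuracy,
              nrow(x$curves)))
  invisible(x)
}

#' Run the four-regime comparison suite
#'
#' Trains the WGAN-GP twice on the streaming classic-augmented training data
#' — once with `epsilon = 0` (regime III) and once with the configured
#' label-smoothing epsilon (regime IV) — then trains the classifier under
#' regimes I-IV against the identical test set and tabulates the comparison.
#'
#' @param train_set,test_set the real data split.
#' @param gan_config a [gan_train_config()]; its `epsilon` is used for the
#'   regime-IV GAN and forced to 0 for the regime-III GAN, its `augment`
#'   is forced to `aug_config`.
#' @param regime_template a [regime_spec()] providing the shared classifier
#'   settings (epochs, batch size, learning rate, widths, seed); the regime
#'   letter is overridden per run.
#' @param aug_config classic augmentation settings.
#' @return list with `reports` (named I-IV), `comparison` (data.frame:
#'   regime, training_accuracy, test_accuracy) and `test_checksum` (test-set
#'   fixity fingerprint).
#' @export
run_experiment_suite <- function(train_set, test_set, gan_config,
                                 regime_template = regime_spec("I"),
                                 aug_config = augment_config()) {
  gan_config$augment <- aug_config
  cfg3 <- gan_config; cfg3$epsilon <- 0
  cfg4 <- gan_config
  gan3 <- train_wgan_gp_lsr(train_set, cfg3)
  gan4 <- train_wgan_gp_lsr(train_set, cfg4)
  reports <- list()
  for (rg in c("I", "II", "III", "IV")) {
    rs <- regime_template
    rs$regime <- rg
    rs$lsr_for_gan <- rg == "IV"
    gs <- switch(rg, III = gan3, IV = gan4, NULL)
    reports[[rg]] <- train_classifier(train_set, test_set, rs, gs, aug_config)
  }
  comparison <- data.frame(
    regime = c("I", "II", "III", "IV"),
    training_accuracy = vapply(reports, `[[`, 1.0, "final_train_accuracy"),
    test_accuracy = vapply(reports, `[[`, 1.0, "final_test_accuracy"))
  rownames(comparison) <- NULL
  list(reports = reports, comparison = comparison,
       test_checksum = sprintf("%dx%dx%d:%.6f:%d",
                               dim(test_set$images)[1],
                               dim(test_set$images)[2],
                               dim(test_set$images)[4],
                               sum(test_set$images),
                               sum(test_set$labels)),
       gan_states = list(III = gan3, IV = gan4))
}

#' Write an experiment report (curves, metrics, comparison) as CSV/JSON
#'
#' @param report an `experiment_report` or the result of
#'   [run_experiment_suite()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_experiment_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$comparison)) {
    write.csv(report$comparison, file.path(dir, "comparison.csv"),
              row.names = FALSE)
    for (rg in names(report$reports))
      write_experiment_report(report$reports[[rg]],
                              file.path(dir, paste0("regime_", rg)))
    return(invisible(dir))
  }
  write.csv(report$curves, file.path(dir, "accuracy_curves.csv"),
            row.names = FALSE)
  write.csv(report$per_class, file.path(dir, "per_class_metrics.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(unclass(report$confusion)),
            file.path(dir, "confusion_matrix.csv"))
  jsonlite::write_json(list(regime = report$regime,
                            final_train_accuracy = report$final_train_accuracy,
                            final_test_accuracy = report$final_test_accuracy),
                       file.path(dir, "summary.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}
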