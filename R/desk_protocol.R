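# CPU-scale validation protocol: fixed small-problem configurations under
# which the pipeline's directional behaviors (Wasserstein convergence;
# classic augmentation beating no augmentation) are checked. Problem sizes
# are chosen so one run fits in CPU minutes; the methods vignette discusses
# what these runs do and do not show about the full-scale protocol.

#' Desk-scale WGAN-GP-LSR convergence run
#'
#' Trains the GAN on a 2-class 16x16 procedural leaf set (20 images per
#' class, batch 8, 5 critic steps, noise dimension 32, widths 8/4, learning
#' rate 2e-4) for `total_iterations` iterations and summarizes the
#' Wasserstein-estimate trajectory by its leading and trailing 100-iteration
#' window means. Past the critic's warm-up rise the estimate should decay,
#' so `trailing < leading` is the expected signature of convergence.
#'
#' @param seed master seed (drives data, initialization and every draw).
#' @param total_iterations iteration budget (default 1200).
#' @return list with `state`, `leading_mean`, `trailing_mean`, `history`.
#' @export
desk_gan_run <- function(seed = 1L, total_iterations = 1200L) {
  spec <- leaf_dataset_spec(n_classes = 2, n_per_class_train = 20,
                            n_per_class_test = 5, image_size = 16,
                            feature_strength = 1,
                            seed = derive_seed(seed, 41L))
  ds <- generate_dataset(spec)
  cfg <- gan_train_config(total_iterations = total_iterations,
                          learning_rate = 2e-4, batch_size = 8L,
                          critic_steps = 5L, noise_dim = 32L,
                          base_channels_g = 8L, base_channels_d = 4L,
                          seed = seed)
  st <- train_wgan_gp_lsr(ds$train, cfg)
  w <- st$history$wasserstein
  n <- length(w)
  win <- min(100L, max(1L, n %/% 2L))
  list(state = st, history = st$history,
       leading_mean = mean(w[seq_len(win)]),
       trailing_mean = mean(w[(n - win + 1L):n]))
}

#' Desk-scale regime I vs regime II comparison
#'
#' Trains the classifier with and without classic augmentation on a 3-class
#' 32x32 procedural leaf set (10 training / 12 test images per class,
#' classifier widths from base 4, 60 epochs, batch 10, learning rate 5e-4)
#' for each seed, and reports per-seed and median test accuracies. Mirrors
#' the full protocol's expectation that augmentation improves limited-data
#' test accuracy; asserted on medians across seeds, never single runs.
#'
#' @param seeds integer vector of classifier seeds (default `1:3`).
#' @param epochs training epochs per run.
#' @param data_seed seed of the shared dataset.
#' @return list with `per_seed` (data.frame: seed, acc_I, acc_II),
#'   `median_I`, `median_II`.
#' @export
desk_regime_comparison <- function(seeds = 1:3, epochs = 60L,
                                   data_seed = 1L) {
  spec <- leaf_dataset_spec(n_classes = 3, n_per_class_train = 10,
                            n_per_class_test = 12, image_size = 32,
                            feature_strength = 1, seed = data_seed)
  ds <- generate_dataset(spec)
  rows <- lapply(seeds, function(sd) {
    rs <- regime_spec("I", epochs = epochs, batch_size = 10L,
                      learning_rate = 5e-4, base_channels = 4L, seed = sd)
    a1 <- train_classifier(ds$train, ds$test, rs)$final_test_accuracy
    rs$regime <- "II"
    a2 <- train_classifier(ds$train, ds$test, rs)$final_test_accuracy
    data.frame(seed = sd, acc_I = a1, acc_II = a2)
  })
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       median_I = stats::median(per_seed$acc_I),
       median_II = stats::median(per_seed$acc_II))
}
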