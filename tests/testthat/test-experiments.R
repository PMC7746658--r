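test_that("per-epoch composition reproduces the reference protocol counts", {
  # reference scale: 873 training images, 38 classes, 30 synthetic per class
  expect_equal(regime_epoch_plan("I", 873, 38),
               list(n_original = 873, n_classic_aug = 0L, n_synthetic = 0L))
  expect_equal(regime_epoch_plan("II", 873, 38),
               list(n_original = 0L, n_classic_aug = 873, n_synthetic = 0L))
  for (rg in c("III", "IV"))
    expect_equal(regime_epoch_plan(rg, 873, 38),
                 list(n_original = 0L, n_classic_aug = 873,
                      n_synthetic = 1140L))
  expect_error(regime_epoch_plan("V", 10, 2), "unknown regime")
})

test_that("epoch composition materializes per plan and needs a GAN for III/IV", {
  ds <- tiny_leaf_ds()
  rs <- regime_spec("III", n_synthetic_per_class = 4, seed = 1)
  expect_error(compose_epoch_dataset(ds$train, rs), "trained gan_state")
  st <- gan_init(16, 2, tiny_gan_config(1))
  out <- compose_epoch_dataset(ds$train, rs, st, epoch = 1)
  expect_equal(length(out), length(ds$train) + 4 * 2)
  # regime II with all-zero augmentation passes originals through unchanged
  rs2 <- regime_spec("II", seed = 1)
  cfg0 <- augment_config(rotation_range = 0, width_shift_range = 0,
                         height_shift_range = 0, zoom_range = 0,
                         horizontal_flip = FALSE, vertical_flip = FALSE)
  out2 <- compose_epoch_dataset(ds$train, rs2, epoch = 3, aug_config = cfg0)
  expect_identical(out2$images, ds$train$images)
  # regime I is the untouched training set
  expect_identical(compose_epoch_dataset(ds$train, regime_spec("I")),
                   ds$train)
})

test_that("an untrained classifier scores at chance and training is deterministic", {
  ds <- tiny_leaf_ds(n_classes = 3, train = 5, test = 20, size = 32,
                     strength = 1, seed = 2)
  rs <- regime_spec("I", epochs = 0, base_channels = 4, seed = 1)
  rep0 <- train_classifier(ds$train, ds$test, rs)
  # 60 balanced test items: binomial 4-sigma band around 1/3
  expect_lt(abs(rep0$final_test_accuracy - 1 / 3),
            4 * sqrt((1 / 3) * (2 / 3) / 60))
  rs2 <- regime_spec("II", epochs = 2, batch_size = 5, learning_rate = 5e-4,
                     base_channels = 4, seed = 3)
  a <- train_classifier(ds$train, ds$test, rs2)
  b <- train_classifier(ds$train, ds$test, rs2)
  expect_identical(a$curves, b$curves)
})

test_that("a short augmented run learns beyond chance on separable leaves", {
  ds <- tiny_leaf_ds(n_classes = 2, train = 10, test = 10, size = 32,
                     strength = 1, seed = 4)
  rs <- regime_spec("II", epochs = 20, batch_size = 10, learning_rate = 5e-4,
                    base_channels = 4, seed = 1)
  rep_ <- train_classifier(ds$train, ds$test, rs)
  expect_gt(rep_$final_train_accuracy, 0.5)
  expect_equal(nrow(rep_$curves), 20)
  expect_equal(sum(rep_$confusion), length(ds$test))
  expect_true(all(rep_$composition$n_classic_aug == 20))
})

test_that("the four-regime suite shares one test set and orders its comparison", {
  ds <- tiny_leaf_ds(n_classes = 2, train = 8, test = 6, size = 32,
                     strength = 1, seed = 5)
  gcfg <- gan_train_config(total_iterations = 8, learning_rate = 2e-4,
                           batch_size = 8, critic_steps = 2, noise_dim = 16,
                           base_channels_g = 8, base_channels_d = 4, seed = 2)
  rt <- regime_spec("I", epochs = 2, batch_size = 8, learning_rate = 5e-4,
                    n_synthetic_per_class = 3, base_channels = 4, seed = 2)
  suite <- run_experiment_suite(ds$train, ds$test, gcfg, rt)
  expect_named(suite$reports, c("I", "II", "III", "IV"))
  expect_equal(suite$comparison$regime, c("I", "II", "III", "IV"))
  expect_true(all(suite$comparison$test_accuracy >= 0 &
                    suite$comparison$test_accuracy <= 1))
  # every regime evaluated the identical test set
  for (rg in names(suite$reports))
    expect_equal(sum(suite$reports[[rg]]$confusion), length(ds$test))
  # composition ledger per regime
  expect_equal(unique(suite$reports$IV$composition$n_synthetic), 6L)
  expect_equal(unique(suite$reports$II$composition$n_synthetic), 0L)
  # III and IV GANs differ only in the smoothing epsilon
  c3 <- suite$gan_states$III$config
  c4 <- suite$gan_states$IV$config
  expect_equal(c3$epsilon, 0)
  expect_equal(c4$epsilon, gcfg$epsilon)
  c3$epsilon <- c4$epsilon
  expect_identical(c3, c4)
})
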