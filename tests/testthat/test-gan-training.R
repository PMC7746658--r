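test_that("zero learning rate leaves weights unchanged while recording losses", {
  ds <- tiny_leaf_ds()
  cfg <- tiny_gan_config(1)
  cfg$learning_rate <- 0
  st0 <- gan_init(16, 2, cfg)
  st1 <- train_wgan_gp_lsr(ds$train, cfg, st0)
  expect_equal(net_weights(st1$generator), net_weights(st0$generator))
  expect_equal(net_weights(st1$discriminator), net_weights(st0$discriminator))
  expect_equal(nrow(st1$history), 1)
  expect_true(all(is.finite(as.matrix(st1$history))))
})

test_that("training is bit-deterministic under a fixed seed", {
  ds <- tiny_leaf_ds()
  cfg <- tiny_gan_config(3, seed = 9)
  a <- train_wgan_gp_lsr(ds$train, cfg)
  b <- train_wgan_gp_lsr(ds$train, cfg)
  expect_identical(net_weights(a$generator), net_weights(b$generator))
  expect_identical(net_weights(a$discriminator), net_weights(b$discriminator))
  expect_identical(a$history, b$history)
})

test_that("a short smoke run keeps every recorded loss finite and audits alternation", {
  ds <- tiny_leaf_ds()
  cfg <- tiny_gan_config(25, seed = 0, critic_steps = 3)
  st <- train_wgan_gp_lsr(ds$train, cfg)
  expect_equal(nrow(st$history), 25)
  expect_true(all(is.finite(as.matrix(st$history))))
  # alternation audit: critic updates = critic_steps x generator updates
  expect_equal(st$n_gen_updates, 25L)
  expect_equal(st$n_critic_updates, 3L * 25L)
})

test_that("critic and generator steps do not touch each other's weights", {
  ds <- tiny_leaf_ds()
  cfg <- tiny_gan_config(1)
  st <- gan_init(16, 2, cfg)
  st_c <- critic_step(st, ds$train[1:8], cfg, step_seed = 5)
  expect_identical(net_weights(st_c$generator), net_weights(st$generator))
  expect_false(identical(net_weights(st_c$discriminator),
                         net_weights(st$discriminator)))
  st_g <- generator_step(st, cfg, step_seed = 5)
  expect_identical(net_weights(st_g$discriminator),
                   net_weights(st$discriminator))
  expect_false(identical(net_weights(st_g$generator),
                         net_weights(st$generator)))
  expect_error(critic_step(st, ds$train[1], cfg), ">= 2")
})

test_that("zero-iteration training returns the initial state with empty history", {
  ds <- tiny_leaf_ds()
  cfg <- tiny_gan_config(0)
  st <- train_wgan_gp_lsr(ds$train, cfg)
  expect_equal(st$iteration, 0L)
  expect_equal(nrow(st$history), 0)
  # class coverage is validated before training starts
  broken <- ds$train
  broken$labels[broken$labels == 1L] <- 0L
  expect_error(train_wgan_gp_lsr(broken, cfg), "zero training examples")
})

test_that("checkpoints round-trip to identical synthesis", {
  ds <- tiny_leaf_ds()
  st <- train_wgan_gp_lsr(ds$train, tiny_gan_config(2))
  dir <- file.path(tempdir(), "gan_ckpt")
  unlink(dir, recursive = TRUE)
  path <- save_gan_checkpoint(st, dir)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.rds$", ".json", path)))
  st2 <- load_gan_checkpoint(path)
  a <- synthesize_labeled_images(st, 2, "conditioning", seed = 3)
  b <- synthesize_labeled_images(st2, 2, "conditioning", seed = 3)
  expect_identical(a$images, b$images)
})

test_that("synthesis yields n_per_class images per class with the requested labeling", {
  ds <- tiny_leaf_ds()
  st <- gan_init(16, 2, tiny_gan_config(1))
  out <- synthesize_labeled_images(st, 3, "conditioning", seed = 1)
  expect_equal(length(out), 6)
  expect_equal(out$labels, rep(0:1, each = 3))
  expect_true(all(out$images >= 0 & out$images <= 255))
  # untrained discriminator: argmax labels agree with conditioning at chance
  big <- synthesize_labeled_images(st, 100, "discriminator_argmax", seed = 2)
  agree <- 1 - attr(big, "relabel_disagreement")
  expect_gt(agree, 0.5 - 0.12)
  expect_lt(agree, 0.5 + 0.12)
})
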