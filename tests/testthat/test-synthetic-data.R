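test_that("leaf rendering is a pure function of (spec, class, draw seed)", {
  spec <- leaf_dataset_spec(n_classes = 3, image_size = 32, seed = 7)
  a <- generate_leaf_image(0L, spec, draw_seed = 7)
  b <- generate_leaf_image(0L, spec, draw_seed = 7)
  expect_identical(a, b)
  expect_equal(dim(a), c(32, 32, 3))
  expect_true(all(a >= 0 & a <= 255) && all(a == round(a)))
  expect_false(identical(a, generate_leaf_image(0L, spec, draw_seed = 8)))
  expect_error(generate_leaf_image(3L, spec), "out of range")
})

test_that("feature_strength 0 makes classes identically distributed", {
  spec0 <- leaf_dataset_spec(n_classes = 4, image_size = 16,
                             feature_strength = 0, seed = 3)
  # identical generative parameters ...
  expect_identical(leaf_class_params(spec0, 0L), leaf_class_params(spec0, 3L))
  # ... hence identical draws at the same draw seed
  for (ds in c(1, 9, 55))
    expect_identical(generate_leaf_image(0L, spec0, ds),
                     generate_leaf_image(2L, spec0, ds))
})

test_that("class hue separation dominates within-class jitter at strength 1", {
  spec <- leaf_dataset_spec(n_classes = 2, image_size = 16,
                            feature_strength = 1, seed = 3)
  # analytic oracle straight from the parameterization
  p0 <- leaf_class_params(spec, 0L); p1 <- leaf_class_params(spec, 1L)
  expect_gt(abs(p1$hue - p0$hue), 3 * max(p0$hue_jitter_sd, p1$hue_jitter_sd))
  # and measured from 200 rendered images per class
  hue_of <- function(img) {
    m <- apply(img[5:12, 5:12, , drop = FALSE], 3, mean)
    grDevices::rgb2hsv(m[1], m[2], m[3], maxColorValue = 255)[1, 1]
  }
  h0 <- vapply(1:200, function(i) hue_of(generate_leaf_image(0L, spec, i)), 1)
  h1 <- vapply(1:200, function(i) hue_of(generate_leaf_image(1L, spec, i)), 1)
  expect_gt(abs(mean(h1) - mean(h0)), 3 * max(sd(h0), sd(h1)))
})

test_that("generate_dataset bookkeeping: sizes, balance, determinism, disjointness", {
  spec <- leaf_dataset_spec(n_classes = 38, n_per_class_train = 10,
                            n_per_class_test = 2, image_size = 16, seed = 5)
  ds <- generate_dataset(spec)
  expect_equal(length(ds$train), 380)
  expect_equal(length(ds$test), 76)
  expect_true(all(table(ds$train$labels) == 10))
  ds2 <- generate_dataset(spec)
  expect_identical(ds$train$labels, ds2$train$labels)
  expect_identical(ds$train$images, ds2$train$images)
  # train and test come from disjoint draw-seed streams
  expect_false(identical(ds$train$images[, , , 1], ds$test$images[, , , 1]))
})

test_that("a small classifier separates strength-1 classes near perfectly", {
  ds <- tiny_leaf_ds(n_classes = 2, train = 50, test = 20, size = 16,
                     strength = 1, seed = 2)
  feat <- function(lis) t(apply(lis$images, 4, function(a) {
    img <- array(a, dim(lis$images)[1:3])
    c(apply(img, 3, mean), apply(img, 3, stats::sd),
      apply(img[5:12, 5:12, , drop = FALSE], 3, mean))
  }))
  fit <- MASS::lda(feat(ds$train), grouping = factor(ds$train$labels))
  acc <- mean(predict(fit, feat(ds$test))$class == factor(ds$test$labels))
  expect_gt(acc, 0.9)
})

test_that("held-out separability is non-decreasing in feature_strength", {
  feat <- function(lis) t(apply(lis$images, 4, function(a) {
    img <- array(a, dim(lis$images)[1:3])
    c(apply(img, 3, mean), apply(img, 3, stats::sd),
      apply(img[5:12, 5:12, , drop = FALSE], 3, mean))
  }))
  acc_for <- function(strength, seed) {
    ds <- generate_dataset(leaf_dataset_spec(
      n_classes = 2, n_per_class_train = 30, n_per_class_test = 20,
      image_size = 16, feature_strength = strength, seed = seed))
    fit <- MASS::lda(feat(ds$train), grouping = factor(ds$train$labels))
    mean(predict(fit, feat(ds$test))$class == factor(ds$test$labels))
  }
  means <- vapply(c(0, 0.5, 1), function(s)
    mean(vapply(1:3, function(sd) acc_for(s, sd), 1)), 1)
  expect_true(all(diff(means) >= 0))
})

test_that("directory splitting partitions deterministically with documented rounding", {
  root <- file.path(tempdir(), "split_fixture")
  unlink(root, recursive = TRUE)
  spec <- leaf_dataset_spec(n_classes = 3, n_per_class_train = 10,
                            n_per_class_test = 1, image_size = 16, seed = 9)
  ds <- generate_dataset(spec)
  # write only the 30 training images as the mock labeled tree
  for (i in seq_len(30)) {
    cls <- ds$train$class_names[ds$train$labels[i] + 1]
    d <- file.path(root, cls)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(ds$train$images[, , , i] / 255,
                  file.path(d, sprintf("img_%03d.png", i)))
  }
  sp <- split_labeled_directory(root, 0.8, seed = 1)
  expect_equal(length(sp$train), 24)
  expect_equal(length(sp$test), 6)
  expect_true(all(table(sp$train$labels) == 8))
  # partition: every image lands exactly once (match by pixel sums)
  key <- function(lis) sort(apply(lis$images, 4, sum))
  expect_equal(sort(c(apply(sp$train$images, 4, sum),
                      apply(sp$test$images, 4, sum))),
               key(ds$train))
  # determinism
  sp2 <- split_labeled_directory(root, 0.8, seed = 1)
  expect_identical(sp$train$images, sp2$train$images)
  # fraction 1: empty test with a warning
  expect_warning(spf <- split_labeled_directory(root, 1, seed = 1),
                 "test set is empty")
  expect_equal(length(spf$test), 0)
  expect_equal(length(spf$train), 30)
})

test_that("split rounding over the 38-class benchmark layout behaves as documented", {
  counts <- benchmark_tables()$class_counts
  sizes <- counts$n_test * 10            # class sizes of the source corpus
  expect_equal(sum(sizes), 43840)
  got <- vapply(sizes, split_counts, 1, train_fraction = 0.019)
  # oracle: the documented rule evaluated directly
  oracle <- pmax(1, floor(0.019 * sizes))
  oracle <- pmin(oracle, sizes - 1)
  expect_equal(got, pmax(oracle, 1))
  # total lands near fraction x corpus (floor rule loses < 1 image/class)
  expect_lt(abs(sum(got) - 0.019 * sum(sizes)), 38)
})
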