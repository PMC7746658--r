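#' Labeled image set
#'
#' The container flowing through augmentation, GAN training and
#' classification: a stack of same-sized RGB images with integer class labels
#' and an ordered class-name map. Images are stored 8-bit style as values in
#' `[0, 255]`; networks convert to `[-1, 1]` at their input.
#'
#' @param images `[H, W, 3, N]` numeric array with values in `[0, 255]`.
#' @param labels integer vector of length `N`; 0-based class indices.
#' @param class_names character vector naming classes `0 .. K-1`.
#' @return an object of class `labeled_image_set`.
#' @export
labeled_image_set <- function(images, labels, class_names) {
  stopifnot(length(dim(images)) == 4, dim(images)[3] == 3)
  labels <- as.integer(labels)
  if (dim(images)[4] != length(labels))
    stop("length(images) != length(labels)")
  if (any(labels < 0) || any(labels >= length(class_names)))
    stop("every label must lie in [0, n_classes)")
  if (length(images) > 0 && (min(images) < 0 || max(images) > 255))
    stop("pixel intensities must lie in [0, 255]")
  structure(list(images = images, labels = labels,
                 class_names = as.character(class_names)),
            class = "labeled_image_set")
}

#' @export
print.labeled_image_set <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<labeled_image_set> %d images, %dx%dx3, %d classes\n",
              d[4], d[1], d[2], length(x$class_names)))
  invisible(x)
}

#' @export
length.labeled_image_set <- function(x) dim(x$images)[4]

#' Subset a labeled image set
#' @param x a [labeled_image_set()].
#' @param i index vector over images.
#' @param ... unused.
#' @export
`[.labeled_image_set` <- function(x, i, ...) {
  labeled_image_set(x$images[, , , i, drop = FALSE], x$labels[i],
                    x$class_names)
}

#' Concatenate labeled image sets (shared class map required)
#' @param ... `labeled_image_set` objects with identical image shape and
#'   class names.
#' @export
lis_concat <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && is.list(xs[[1]]) && !inherits(xs[[1]], "labeled_image_set"))
    xs <- xs[[1]]
  stopifnot(length(xs) >= 1)
  cn <- xs[[1]]$class_names
  for (x in xs) stopifnot(identical(x$class_names, cn))
  imgs <- array(0, dim = c(dim(xs[[1]]$images)[1:3],
                           sum(vapply(xs, length, 1L))))
  at <- 0L
  for (x in xs) {
    n <- length(x)
    if (n > 0) imgs[, , , at + seq_len(n)] <- x$images
    at <- at + n
  }
  labeled_image_set(imgs, unlist(lapply(xs, `[[`, "labels")), cn)
}

#' Specification of a procedural leaf-image dataset
#'
#' The generator renders an elliptical "leaf" on a textured background with
#' class-keyed base hue, lesion count and lesion shape/colour. With
#' `feature_strength = 0` every class draws from the identical distribution;
#' at 1 the class signal is strong. Identical specs yield bit-identical
#' datasets.
#'
#' @param n_classes number of classes (>= 2; the benchmark layout uses 38).
#' @param n_per_class_train,n_per_class_test images per class (>= 1).
#' @param image_size square side in pixels (>= 16).
#' @param feature_strength class-separability knob in `[0, 1]`.
#' @param seed master seed; per-image seeds derive from it by a counter
#'   scheme ([derive_seed()]), so generation order is immaterial.
#' @export
leaf_dataset_spec <- function(n_classes = 38L, n_per_class_train = 10L,
                              n_per_class_test = 5L, image_size = 32L,
                              feature_strength = 1, seed = 0L) {
  stopifnot(n_classes >= 2, image_size >= 16, n_per_class_train >= 1,
            n_per_class_test >= 1, feature_strength >= 0,
            feature_strength <= 1)
  structure(list(n_classes = as.integer(n_classes),
                 n_per_class_train = as.integer(n_per_class_train),
                 n_per_class_test = as.integer(n_per_class_test),
                 image_size = as.integer(image_size),
                 feature_strength = feature_strength,
                 seed = as.integer(seed)),
            class = "leaf_dataset_spec")
}

#' Deterministic per-class rendering parameters
#'
#' Exposes the generative parameterization so tests can reason about class
#' separability analytically (e.g. between-class hue gap vs within-class hue
#' jitter) without going through a classifier.
#'
#' @param spec a [leaf_dataset_spec()].
#' @param class_index 0-based class.
#' @return list with `hue` (leaf base hue in `[0, 1)`), `hue_jitter_sd`,
#'   `n_lesions`, `lesion_aspect`, `lesion_hue`.
#' @export
leaf_class_params <- function(spec, class_index) {
  stopifnot(class_index >= 0, class_index < spec$n_classes)
  s <- spec$feature_strength
  frac <- if (spec$n_classes > 1) class_index / (spec$n_classes - 1) else 0
  list(hue = (0.30 + 0.55 * s * frac) %% 1,
       hue_jitter_sd = 0.02,
       n_lesions = 1L + as.integer(round(s * (class_index %% 3))),
       lesion_aspect = 1 + 0.8 * s * (class_index %% 2),
       lesion_hue = 0.08 + 0.10 * s * ((class_index %% 4) / 3))
}

hsv1 <- function(h, s, v) as.numeric(grDevices::col2rgb(grDevices::hsv(h %% 1, clamp(s, 0, 1), clamp(v, 0, 1)))) / 255

box_blur3 <- function(m) {
  # 3x3 box blur with edge clamping, used to soften lesion masks
  n <- nrow(m); p <- ncol(m)
  pad <- matrix(0, n + 2, p + 2)
  pad[2:(n + 1), 2:(p + 1)] <- m
  pad[1, ] <- pad[2, ]; pad[n + 2, ] <- pad[n + 1, ]
  pad[, 1] <- pad[, 2]; pad[, p + 2] <- pad[, p + 1]
  acc <- matrix(0, n, p)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + seq_len(n), dj + seq_len(p)]
  acc / 9
}

#' Render one procedural leaf image
#'
#' Pure function of `(spec, class_index, draw_seed)`: the class index fixes
#' base hue, lesion count, lesion shape and lesion colour (all modulated by
#' `feature_strength`); the draw seed fixes background texture, leaf pose and
#' lesion placement.
#'
#' @param class_index 0-based class (< `spec$n_classes`).
#' @param spec a [leaf_dataset_spec()].
#' @param draw_seed non-negative integer identifying the draw.
#' @return `[size, size, 3]` array of integers in `[0, 255]`.
#' @export
generate_leaf_image <- function(class_index, spec, draw_seed = 0L) {
  if (class_index < 0 || class_index >= spec$n_classes)
    stop("class_index out of range [0, ", spec$n_classes, ")")
  pars <- leaf_class_params(spec, class_index)
  n <- spec$image_size
  with_seed(derive_seed(spec$seed, draw_seed), {
    gx <- matrix(rep((seq_len(n) - 0.5) / n, n), n, n)        # column coord
    gy <- t(gx)                                               # row coord
    img <- array(0, dim = c(n, n, 3))
    bg <- c(0.52, 0.48, 0.42)
    for (ch in 1:3)
      img[, , ch] <- bg[ch] + matrix(rnorm(n * n, 0, 0.04), n, n)
    # leaf pose varies broadly (arbitrary orientation, scale and placement,
    # as in hand-held photographs); illumination varies per image
    cx <- 0.5 + runif(1, -0.10, 0.10); cy <- 0.5 + runif(1, -0.10, 0.10)
    rx <- runif(1, 0.24, 0.40); ry <- runif(1, 0.18, 0.32)
    th <- runif(1, 0, 2 * pi)
    dx <- gx - cx; dy <- gy - cy
    u <- dx * cos(th) + dy * sin(th); v <- -dx * sin(th) + dy * cos(th)
    leaf_mask <- (u / rx)^2 + (v / ry)^2 <= 1
    hue <- pars$hue + rnorm(1, 0, pars$hue_jitter_sd)
    leaf_col <- hsv1(hue, 0.65 + runif(1, -0.05, 0.05),
                     0.50 + runif(1, -0.12, 0.12))
    tex <- matrix(rnorm(n * n, 0, 0.03), n, n)
    for (ch in 1:3)
      img[, , ch][leaf_mask] <- (leaf_col[ch] + tex)[leaf_mask]
    # lesions: blurred ellipses inside the leaf
    for (l in seq_len(pars$n_lesions)) {
      # rejection-sample a centre inside the leaf (bounded attempts)
      lc <- c(cx, cy)
      for (try in 1:20) {
        cand <- c(cx + runif(1, -rx, rx) * 0.7, cy + runif(1, -ry, ry) * 0.7)
        uu <- (cand[1] - cx) * cos(th) + (cand[2] - cy) * sin(th)
        vv <- -(cand[1] - cx) * sin(th) + (cand[2] - cy) * cos(th)
        if ((uu / rx)^2 + (vv / ry)^2 <= 0.6) { lc <- cand; break }
      }
      lr <- runif(1, 0.05, 0.09)
      lth <- runif(1, 0, pi)
      ldx <- gx - lc[1]; ldy <- gy - lc[2]
      lu <- ldx * cos(lth) + ldy * sin(lth)
      lv <- -ldx * sin(lth) + ldy * cos(lth)
      lmask <- ((lu * pars$lesion_aspect / lr)^2 + (lv / lr)^2 <= 1) * 1
      alpha <- box_blur3(lmask) * leaf_mask
      lcol <- hsv1(pars$lesion_hue + rnorm(1, 0, 0.01), 0.75, 0.42)
      for (ch in 1:3)
        img[, , ch] <- img[, , ch] * (1 - alpha) + lcol[ch] * alpha
    }
    round(clamp(img, 0, 1) * 255)
  })
}

#' Generate a train/test pair of procedural leaf datasets
#'
#' Train and test draws come from disjoint seed streams of the same master
#' seed, so the split is a partition by construction and both halves are
#' class-balanced.
#'
#' @param spec a [leaf_dataset_spec()].
#' @return list with elements `train` and `test`, both [labeled_image_set()].
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "leaf_dataset_spec"))
  cn <- sprintf("class_%02d", seq_len(spec$n_classes) - 1L)
  make_half <- function(stream, n_per_class) {
    n <- spec$n_classes * n_per_class
    imgs <- array(0, dim = c(spec$image_size, spec$image_size, 3, n))
    labels <- integer(n)
    at <- 0L
    for (k in seq_len(spec$n_classes) - 1L) {
      for (i in seq_len(n_per_class)) {
        at <- at + 1L
        imgs[, , , at] <- generate_leaf_image(k, spec,
                                              derive_seed(stream, k, i))
        labels[at] <- k
      }
    }
    labeled_image_set(imgs, labels, cn)
  }
  list(train = make_half(1L, spec$n_per_class_train),
       test = make_half(2L, spec$n_per_class_test))
}

#' Per-class train-set size under the split rounding rule
#'
#' The rule: `floor(train_fraction * n)`, but at least 1 training image, and
#' (when `train_fraction < 1`) at least 1 test image per class.
#'
#' @param n images available in the class.
#' @param train_fraction fraction assigned to training.
#' @return number of training images for the class.
#' @export
split_counts <- function(n, train_fraction) {
  stopifnot(n >= 1, train_fraction >= 0, train_fraction <= 1)
  k <- max(1L, as.integer(floor(train_fraction * n)))
  if (train_fraction < 1) k <- min(k, n - 1L)
  max(k, if (n == 1L) 1L else k)
}

#' Split a class-per-subdirectory PNG tree into train and test sets
#'
#' Expects `root_path` to contain one subdirectory per class, each holding at
#' least one PNG image; all images must share one size. The per-class split
#' uses [split_counts()] and is deterministic under `seed`.
#'
#' @param root_path directory of class subdirectories.
#' @param train_fraction per-class fraction assigned to training.
#' @param seed integer seed for the per-class shuffles.
#' @param skip_unreadable if `TRUE`, unreadable files are reported and
#'   skipped; if `FALSE` (default) they are an error.
#' @return list with `train` and `test` [labeled_image_set()]s (the test set
#'   may be empty when `train_fraction = 1`, with a warning).
#' @export
split_labeled_directory <- function(root_path, train_fraction, seed = 0L,
                                    skip_unreadable = FALSE) {
  stopifnot(dir.exists(root_path), train_fraction > 0, train_fraction <= 1)
  classes <- sort(list.dirs(root_path, recursive = FALSE, full.names = FALSE))
  if (length(classes) < 1) stop("no class subdirectories under ", root_path)
  tr_imgs <- list(); tr_lab <- integer()
  te_imgs <- list(); te_lab <- integer()
  for (k in seq_along(classes)) {
    files <- sort(list.files(file.path(root_path, classes[k]),
                             pattern = "\\.png$", ignore.case = TRUE,
                             full.names = TRUE))
    imgs <- list()
    for (f in files) {
      im <- tryCatch(png::readPNG(f), error = function(e) NULL)
      if (is.null(im)) {
        msg <- paste0("unreadable image: ", f)
        if (skip_unreadable) { warning(msg); next } else stop(msg)
      }
      if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3))
      imgs[[length(imgs) + 1]] <- round(im[, , 1:3] * 255)
    }
    if (length(imgs) == 0) stop("empty class directory: ", classes[k])
    ord <- with_seed(derive_seed(seed, k), sample.int(length(imgs)))
    ntr <- split_counts(length(imgs), train_fraction)
    tr_idx <- ord[seq_len(ntr)]
    te_idx <- if (ntr < length(imgs)) ord[(ntr + 1):length(imgs)] else integer()
    tr_imgs <- c(tr_imgs, imgs[tr_idx]); tr_lab <- c(tr_lab, rep(k - 1L, length(tr_idx)))
    te_imgs <- c(te_imgs, imgs[te_idx]); te_lab <- c(te_lab, rep(k - 1L, length(te_idx)))
  }
  stack <- function(lst, lab) {
    if (length(lst) == 0) {
      d <- dim(tr_imgs[[1]])
      return(labeled_image_set(array(0, c(d[1], d[2], 3, 0)), integer(),
                               classes))
    }
    d <- dim(lst[[1]])
    for (im in lst) if (!identical(dim(im), d))
      stop("all images must share one size; found ",
           paste(dim(im)[1:2], collapse = "x"), " vs ",
           paste(d[1:2], collapse = "x"))
    a <- array(0, c(d[1], d[2], 3, length(lst)))
    for (i in seq_along(lst)) a[, , , i] <- lst[[i]]
    labeled_image_set(a, lab, classes)
  }
  if (train_fraction == 1)
    warning("train_fraction = 1: test set is empty")
  list(train = stack(tr_imgs, tr_lab), test = stack(te_imgs, te_lab))
}

#' Write a train/test dataset as a PNG tree with a JSON manifest
#'
#' Layout: `root/train/<class>/img_*.png`, `root/test/<class>/img_*.png`,
#' plus `root/dataset.json` recording the spec, seed, class names and split
#' membership.
#'
#' @param train,test [labeled_image_set()]s.
#' @param root output directory (created if missing).
#' @param spec optional [leaf_dataset_spec()] recorded in the manifest.
#' @return `root`, invisibly.
#' @export
write_image_tree <- function(train, test, root, spec = NULL) {
  dir.create(root, showWarnings = FALSE, recursive = TRUE)
  dump_half <- function(lis, sub) {
    files <- character(length(lis))
    for (i in seq_len(length(lis))) {
      cls <- lis$class_names[lis$labels[i] + 1L]
      d <- file.path(root, sub, cls)
      dir.create(d, showWarnings = FALSE, recursive = TRUE)
      files[i] <- file.path(sub, cls, sprintf("img_%05d.png", i))
      png::writePNG(lis$images[, , , i] / 255, file.path(root, files[i]))
    }
    files
  }
  manifest <- list(
    class_names = train$class_names,
    spec = if (!is.null(spec)) unclass(spec) else NULL,
    train_files = dump_half(train, "train"),
    test_files = dump_half(test, "test"))
  jsonlite::write_json(manifest, file.path(root, "dataset.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(root)
}
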