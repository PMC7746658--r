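#' Classic augmentation configuration
#'
#' Sampling semantics follow the common image-generator convention: rotation
#' uniform in `[-rotation_range, +rotation_range]` degrees; shifts uniform in
#' `+/- range` times the image side; `zoom_range = z` draws a scale factor
#' uniform in `[1 - z, 1 + z]`; flips are fair coin flips when enabled.
#' Photometric jitter (brightness/contrast/sharpness factor ranges) is off by
#' default — the four-regime protocol uses the geometric list only — and when
#' enabled defaults to `[0.7, 1.3]`, a range containing the identity.
#'
#' @param rotation_range degrees (default 360).
#' @param width_shift_range,height_shift_range fraction of the image side
#'   (default 0.3).
#' @param zoom_range zoom amplitude (default 0.3).
#' @param horizontal_flip,vertical_flip enable random flips (default `TRUE`).
#' @param brightness_range,contrast_range,sharpness_range length-2 factor
#'   ranges, or `NULL` to disable that jitter.
#' @param fill_mode `"nearest"` (edge replication) or `"constant"` (zeros)
#'   for pixels mapped from outside the frame.
#' @param seed base seed mixed with the epoch seed and image counter.
#' @export
augment_config <- function(rotation_range = 360, width_shift_range = 0.3,
                           height_shift_range = 0.3, zoom_range = 0.3,
                           horizontal_flip = TRUE, vertical_flip = TRUE,
                           brightness_range = NULL, contrast_range = NULL,
                           sharpness_range = NULL,
                           fill_mode = c("nearest", "constant"), seed = 0L) {
  fill_mode <- match.arg(fill_mode)
  stopifnot(rotation_range >= 0, width_shift_range >= 0,
            height_shift_range >= 0, zoom_range >= 0, zoom_range < 1)
  for (r in list(brightness_range, contrast_range, sharpness_range))
    if (!is.null(r)) stopifnot(length(r) == 2, r[1] > 0, r[1] <= r[2])
  structure(list(rotation_range = rotation_range,
                 width_shift_range = width_shift_range,
                 height_shift_range = height_shift_range,
                 zoom_range = zoom_range, horizontal_flip = horizontal_flip,
                 vertical_flip = vertical_flip,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 sharpness_range = sharpness_range,
                 fill_mode = fill_mode, seed = as.integer(seed)),
            class = "augment_config")
}

#' Geometric transform (rotation, shift, zoom, flips)
#'
#' Applies flips as exact axis reversals, then one affine warp (rotation
#' about the image centre composed with isotropic zoom and translation) using
#' bilinear sampling. Rotations by multiples of 90 degrees map pixel centres
#' onto pixel centres and are therefore exact. Out-of-frame samples are
#' filled per `fill_mode`.
#'
#' @param image `[H, W, 3]` (or `[H, W]`) numeric array.
#' @param rotation degrees, counterclockwise.
#' @param shift_x,shift_y translation as a fraction of width/height.
#' @param zoom scale factor (> 0; 1 = identity).
#' @param flip_h,flip_v horizontal (left-right) / vertical (up-down) flip.
#' @param fill_mode `"nearest"` or `"constant"`.
#' @return array of the same shape.
#' @export
geometric_transform <- function(image, rotation = 0, shift_x = 0, shift_y = 0,
                                zoom = 1, flip_h = FALSE, flip_v = FALSE,
                                fill_mode = c("nearest", "constant")) {
  fill_mode <- match.arg(fill_mode)
  if (zoom <= 0) stop("zoom must be positive (empty crop)")
  d <- dim(image)
  flat <- length(d) == 2
  if (flat) { image <- array(image, c(d, 1)); d <- dim(image) }
  H <- d[1]; W <- d[2]
  if (flip_h) image <- image[, W:1, , drop = FALSE]
  if (flip_v) image <- image[H:1, , , drop = FALSE]
  if (rotation %% 360 == 0 && shift_x == 0 && shift_y == 0 && zoom == 1) {
    out <- image
  } else {
    th <- rotation * pi / 180
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    # output pixel grid, centred; inverse map into source coordinates
    oy <- matrix(rep(seq_len(H), W), H, W) - cy
    ox <- matrix(rep(seq_len(W), each = H), H, W) - cx
    oy2 <- oy - shift_y * H; ox2 <- ox - shift_x * W
    # inverse of rotate(th) followed by scale(zoom): rotate(-th)/zoom
    sx <- (cos(-th) * ox2 - sin(-th) * oy2) / zoom + cx
    sy <- (sin(-th) * ox2 + cos(-th) * oy2) / zoom + cy
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    cl <- function(v, n) pmin(pmax(as.vector(v), 1), n)
    ia <- cbind(cl(y0, H),     cl(x0, W))
    ib <- cbind(cl(y0, H),     cl(x0 + 1, W))
    ic <- cbind(cl(y0 + 1, H), cl(x0, W))
    id_ <- cbind(cl(y0 + 1, H), cl(x0 + 1, W))
    out <- array(0, d)
    for (ch in seq_len(d[3])) {
      m <- image[, , ch]
      out[, , ch] <- m[ia] * (1 - fx) * (1 - fy) + m[ib] * fx * (1 - fy) +
                     m[ic] * (1 - fx) * fy + m[id_] * fx * fy
    }
    if (fill_mode == "constant") {
      outside <- sx < 1 | sx > W | sy < 1 | sy > H
      for (ch in seq_len(d[3])) {
        m <- out[, , ch]; m[outside] <- 0; out[, , ch] <- m
      }
    }
  }
  if (flat) out[, , 1] else out
}

#' Photometric transform (brightness, contrast, sharpness)
#'
#' Applied in the order brightness, contrast, sharpness, then clipped to
#' `[0, 255]`. Formulas: brightness `x * b`; contrast `m + (x - m) * c` with
#' `m` the mean intensity over all pixels and channels; sharpness
#' `blur + s * (x - blur)` with a 3x3 box blur. All factors 1 is the exact
#' identity.
#'
#' @param image `[H, W, 3]` array in `[0, 255]`.
#' @param brightness,contrast,sharpness positive factors.
#' @return array of the same shape, clipped to `[0, 255]`.
#' @export
photometric_transform <- function(image, brightness = 1, contrast = 1,
                                  sharpness = 1) {
  stopifnot(brightness >= 0, contrast >= 0, sharpness >= 0)
  x <- image
  if (brightness != 1) x <- x * brightness
  if (contrast != 1) {
    m <- mean(x)
    x <- m + (x - m) * contrast
  }
  if (sharpness != 1) {
    blur <- x
    for (ch in seq_len(dim(x)[3])) blur[, , ch] <- box_blur3(x[, , ch])
    x <- blur + sharpness * (x - blur)
  }
  clamp(x, 0, 255)
}

sample_augment_params <- function(config) {
  # fixed sampling order pins cross-platform reproducibility
  p <- list(
    rotation = runif(1, -config$rotation_range, config$rotation_range),
    shift_x = runif(1, -config$width_shift_range, config$width_shift_range),
    shift_y = runif(1, -config$height_shift_range, config$height_shift_range),
    zoom = runif(1, 1 - config$zoom_range, 1 + config$zoom_range),
    flip_h = config$horizontal_flip && runif(1) < 0.5,
    flip_v = config$vertical_flip && runif(1) < 0.5)
  for (nm in c("brightness", "contrast", "sharpness")) {
    r <- config[[paste0(nm, "_range")]]
    p[[nm]] <- if (is.null(r)) 1 else runif(1, r[1], r[2])
  }
  p
}

#' Stochastically augment every image of a batch
#'
#' Each image is independently transformed with parameters drawn from the
#' config ranges; labels and batch size are preserved. The per-image seed is
#' derived from `(config$seed, epoch_seed, image index)`, so the same triple
#' always reproduces the same batch while different epochs yield fresh draws.
#'
#' @param batch a [labeled_image_set()].
#' @param config an [augment_config()].
#' @param epoch_seed integer varied per epoch.
#' @return a [labeled_image_set()] of the same size and labels.
#' @export
augment_batch <- function(batch, config, epoch_seed = 0L) {
  stopifnot(inherits(batch, "labeled_image_set"),
            inherits(config, "augment_config"))
  n <- length(batch)
  if (n == 0) stop("non-empty batch required")
  out <- batch$images
  for (i in seq_len(n)) {
    p <- with_seed(derive_seed(config$seed, epoch_seed, i),
                   sample_augment_params(config))
    im <- geometric_transform(batch$images[, , , i], p$rotation, p$shift_x,
                              p$shift_y, p$zoom, p$flip_h, p$flip_v,
                              config$fill_mode)
    out[, , , i] <- photometric_transform(im, p$brightness, p$contrast,
                                          p$sharpness)
  }
  labeled_image_set(out, batch$labels, batch$class_names)
}

#' Write a contact sheet of augmented variants of one image
#'
#' @param image `[H, W, 3]` array in `[0, 255]`.
#' @param config an [augment_config()].
#' @param file output PNG path.
#' @param nrow,ncol grid size.
#' @param seed seed for the variant draws.
#' @return `file`, invisibly.
#' @export
augment_contact_sheet <- function(image, config, file, nrow = 4, ncol = 6,
                                  seed = 0L) {
  d <- dim(image)
  sheet <- array(0, c(d[1] * nrow, d[2] * ncol, 3))
  k <- 0
  for (r in seq_len(nrow)) for (cc in seq_len(ncol)) {
    k <- k + 1
    p <- with_seed(derive_seed(seed, k), sample_augment_params(config))
    im <- geometric_transform(image, p$rotation, p$shift_x, p$shift_y,
                              p$zoom, p$flip_h, p$flip_v, config$fill_mode)
    im <- photometric_transform(im, p$brightness, p$contrast, p$sharpness)
    sheet[(r - 1) * d[1] + seq_len(d[1]), (cc - 1) * d[2] + seq_len(d[2]), ] <- im
  }
  png::writePNG(sheet / 255, file)
  invisible(file)
}
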