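#' Augmentation parameter sets
#'
#' `augment_params()` defaults to the offline balancing policy (rotation up
#' to 15 degrees either way, brightness/contrast jitter of 10%, zoom up to
#' 20%). `train_augment_params()` defaults to the train-time policy used
#' for all model families: horizontal flip with probability 0.5, color
#' jitter of 40% brightness, 70% contrast, 70% saturation and hue factor
#' 0.015, rectangle erasure with probability 0.4, and translation up to 10%
#' of the image size. Saturation/hue jitter is an exact no-op on grayscale
#' (zero-saturation) frames; the parameters are kept for fidelity to the
#' stated policy and documented as such.
#'
#' @param max_rotation Max rotation magnitude, degrees.
#' @param brightness_jitter,contrast_jitter,saturation_jitter,hue_jitter
#'   Jitter fractions (factor drawn from `1 +/- jitter`).
#' @param max_zoom Max zoom fraction (offline only).
#' @param hflip_prob,erase_prob Probabilities (train-time only).
#' @param translate_frac Max translation fraction of each dim (train-time).
#' @param erase_area Range of erased-rectangle area as a fraction of image
#'   area.
#' @param erase_aspect Range of erased-rectangle aspect ratios (sampled
#'   log-uniformly).
#' @return A list of class `augment_params`.
#' @export
augment_params <- function(max_rotation = 15, brightness_jitter = 0.10,
                           contrast_jitter = 0.10, saturation_jitter = 0,
                           hue_jitter = 0, max_zoom = 0.20, hflip_prob = 0,
                           erase_prob = 0, translate_frac = 0,
                           erase_area = c(0.02, 0.20),
                           erase_aspect = c(0.3, 3.3)) {
  stopifnot(max_rotation >= 0, max_rotation <= 180,
            brightness_jitter >= 0, contrast_jitter >= 0,
            saturation_jitter >= 0, hue_jitter >= 0, max_zoom >= 0,
            hflip_prob >= 0, hflip_prob <= 1,
            erase_prob >= 0, erase_prob <= 1,
            translate_frac >= 0, translate_frac <= 1)
  structure(as.list(environment()), class = "augment_params")
}

#' @rdname augment_params
#' @export
train_augment_params <- function(max_rotation = 0, brightness_jitter = 0.40,
                                 contrast_jitter = 0.70,
                                 saturation_jitter = 0.70, hue_jitter = 0.015,
                                 max_zoom = 0, hflip_prob = 0.5,
                                 erase_prob = 0.4, translate_frac = 0.10,
                                 erase_area = c(0.02, 0.20),
                                 erase_aspect = c(0.3, 3.3)) {
  augment_params(max_rotation, brightness_jitter, contrast_jitter,
                 saturation_jitter, hue_jitter, max_zoom, hflip_prob,
                 erase_prob, translate_frac, erase_area, erase_aspect)
}

# Rotate by theta degrees and zoom by factor s about the image center,
# bilinear interpolation, zero fill outside. Content rotates so that a
# pixel at offset (dr, dc) from center maps to
# (dr cos - dc sin, dr sin + dc cos) * s.
rotate_zoom <- function(image, theta_deg, zoom = 1) {
  th <- theta_deg * pi / 180
  h <- nrow(image); w <- ncol(image)
  ctr <- c((h - 1) / 2, (w - 1) / 2)
  a <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2) / zoom  # inverse map
  b <- ctr - a %*% ctr
  affine_warp(image, a[1, 1], a[1, 2], a[2, 1], a[2, 2], b[1], b[2], h, w)
}

translate_image <- function(image, dr, dc) {
  affine_warp(image, 1, 0, 0, 1, -dr, -dc, nrow(image), ncol(image))
}

apply_brightness <- function(image, f) clip255(image * f)

apply_contrast <- function(image, f) clip255((image - mean(image)) * f + mean(image))

#' Offline balancing augmentation
#'
#' Applies, in order: rotation with angle drawn uniformly from
#' `+/- max_rotation`, zoom drawn from `1 +/- max_zoom` (cropped/padded back
#' to the input dims), brightness then contrast scaling each drawn from
#' `1 +/- jitter`. Bilinear interpolation with zero fill (the ultrasound
#' background is black). Fully deterministic under `seed`.
#'
#' @param image Numeric matrix (0-255).
#' @param params An [augment_params()] set.
#' @param seed Integer seed.
#' @return Augmented image, same dims, values in \[0, 255\].
#' @export
offline_augment <- function(image, params = augment_params(), seed = 1L) {
  assert_image(image)
  withr::with_seed(substream_seed(seed, "offline"), {
    theta <- runif(1, -params$max_rotation, params$max_rotation)
    zoom <- runif(1, 1 - params$max_zoom, 1 + params$max_zoom)
    bf <- runif(1, 1 - params$brightness_jitter, 1 + params$brightness_jitter)
    cf <- runif(1, 1 - params$contrast_jitter, 1 + params$contrast_jitter)
    out <- image
    if (theta != 0 || zoom != 1) out <- rotate_zoom(out, theta, zoom)
    out <- apply_contrast(apply_brightness(out, bf), cf)
    out
  })
}

#' Train-time augmentation
#'
#' Applies, in order: horizontal flip with probability `hflip_prob`; color
#' jitter (brightness and contrast factors drawn from `1 +/- jitter`;
#' saturation and hue are exact no-ops on grayscale and skipped); random
#' rectangle erasure with probability `erase_prob` (area fraction uniform
#' in `erase_area`, aspect log-uniform in `erase_aspect`, filled with 0);
#' and a translation drawn uniformly within `+/- translate_frac` of each
#' dimension. Dims are preserved.
#'
#' @inheritParams offline_augment
#' @export
train_time_augment <- function(image, params = train_augment_params(),
                               seed = 1L) {
  assert_image(image)
  h <- nrow(image); w <- ncol(image)
  withr::with_seed(substream_seed(seed, "traintime"), {
    out <- image
    if (runif(1) < params$hflip_prob) out <- out[, rev(seq_len(w)), drop = FALSE]
    bf <- runif(1, 1 - params$brightness_jitter, 1 + params$brightness_jitter)
    cf <- runif(1, 1 - params$contrast_jitter, 1 + params$contrast_jitter)
    out <- apply_contrast(apply_brightness(out, bf), cf)
    if (runif(1) < params$erase_prob) {
      area <- runif(1, params$erase_area[1], params$erase_area[2]) * h * w
      aspect <- exp(runif(1, log(params$erase_aspect[1]), log(params$erase_aspect[2])))
      eh <- max(1L, min(h, round(sqrt(area * aspect))))
      ew <- max(1L, min(w, round(sqrt(area / aspect))))
      r0 <- sample.int(h - eh + 1L, 1)
      c0 <- sample.int(w - ew + 1L, 1)
      out[seq(r0, r0 + eh - 1L), seq(c0, c0 + ew - 1L)] <- 0
    }
    if (params$translate_frac > 0) {
      dr <- runif(1, -params$translate_frac, params$translate_frac) * h
      dc <- runif(1, -params$translate_frac, params$translate_frac) * w
      out <- translate_image(out, dr, dc)
    }
    clip255(out)
  })
}
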