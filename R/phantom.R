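#' Population-level parameters for the synthetic ultrasound phantom
#'
#' Defines the distributions from which per-individual latent anatomy is
#' drawn. A transverse abalone ultrasound shows a bright specimen ellipse on
#' a dark background, a cone-shaped digestive gland inside it, and a thin
#' high-echogenicity gonad band hugging the cone boundary. Sex differences
#' are encoded as configurable offsets on band geometry and texture:
#' females get a thicker, darker, higher-contrast band; males a thinner,
#' brighter, homogeneous one. `sex_effect = 0` makes the female and male
#' parameter distributions identical (no learnable signal).
#'
#' @param sex_effect Multiplier on all sex-conditional offsets (default 1).
#' @param canvas_h,canvas_w Canvas size in pixels.
#' @param speckle_shape Gamma shape of the unit-mean multiplicative speckle
#'   applied inside the specimen; larger = less noise, `Inf` disables it.
#' @param frame_jitter_scale Scale of the per-frame probe-repositioning
#'   jitter (pixels of translation noise).
#' @param band_thickness_base Baseline gonad-band thickness as a fraction of
#'   the specimen minor axis.
#' @param band_thickness_delta,band_echo_delta,band_texture_delta Half the
#'   F-M gap in band thickness fraction, band echogenicity, and band texture
#'   shape at `sex_effect = 1`.
#' @param gain_delta Half the F-M gap in overall specimen echogenicity gain
#'   (default 0: brightness carries no sex signal). A non-zero value makes
#'   the sex effect linear in pixel space, which a linear classifier can
#'   exploit.
#' @return A list of class `phantom_population` with distribution settings.
#' @export
population_params <- function(sex_effect = 1,
                              canvas_h = 128, canvas_w = 160,
                              speckle_shape = 6,
                              frame_jitter_scale = 1,
                              band_thickness_base = 0.16,
                              band_thickness_delta = 0.05,
                              band_echo_delta = 12,
                              band_texture_delta = 3,
                              gain_delta = 0) {
  stopifnot(canvas_h > 0, canvas_w > 0, speckle_shape > 0)
  if (sex_effect < 0) abort("`sex_effect` must be non-negative.")
  structure(list(
    sex_effect = sex_effect,
    canvas_h = canvas_h, canvas_w = canvas_w,
    specimen_ax_r = c(mean = 0.30, sd = 0.04),   # fractions of canvas dims
    specimen_ax_c = c(mean = 0.30, sd = 0.04),
    center_sd = 0.04,
    cone_half_angle = c(mean = 0.55, sd = 0.12),
    gain = c(mean = 1, sd = 0.08, delta = gain_delta),  # per-animal overall echogenicity
    band_thickness = c(base = band_thickness_base, delta = band_thickness_delta, sd = 0.015),
    band_echo = c(base = 180, delta = band_echo_delta, sd = 5),
    band_texture = c(base = 8, delta = band_texture_delta, sd = 0.8),
    gland_echo = c(mean = 140, sd = 12),
    coelom_echo = c(mean = 90, sd = 10),
    speckle_shape = speckle_shape,
    frame_jitter_scale = frame_jitter_scale
  ), class = "phantom_population")
}

#' Draw the latent anatomy of one synthetic individual
#'
#' All frames of an individual are rendered from the single `phantom_spec`
#' returned here, so the same call (same sex, size class, seed, index)
#' always yields a bit-identical spec — this per-individual latent anatomy
#' is what makes frames of one animal correlated and image-level splits
#' leaky.
#'
#' @param sex `"F"` or `"M"`.
#' @param size_class `"small"` or `"large"`; small specimens are drawn at
#'   75% linear scale.
#' @param params A [population_params()] object.
#' @param seed Integer master seed.
#' @param index Individual index within (sex, size_class); part of the
#'   random substream and of the individual id.
#' @return A list of class `phantom_spec`.
#' @export
sample_individual <- function(sex, size_class = "large",
                              params = population_params(),
                              seed = 1L, index = 1L) {
  sex <- match.arg(sex, c("F", "M"))
  size_class <- match.arg(size_class, c("small", "large"))
  stopifnot(inherits(params, "phantom_population"))
  e <- params$sex_effect
  sgn <- if (sex == "F") 1 else -1
  scale <- if (size_class == "small") 0.75 else 1
  h <- params$canvas_h; w <- params$canvas_w

  clamp2sd <- function(x, mean, sd) min(max(x, mean - 2 * sd), mean + 2 * sd)
  with_substream(seed, "indiv", sex, size_class, index, code = {
    # axes and centers are clamped to +/- 2 sd so an artifact-free specimen
    # always sits fully inside the field of view
    ar <- params$specimen_ax_r; ac <- params$specimen_ax_c
    ax_r <- h * scale * clamp2sd(rnorm(1, ar["mean"], ar["sd"]), ar["mean"], ar["sd"])
    ax_c <- w * scale * clamp2sd(rnorm(1, ac["mean"], ac["sd"]), ac["mean"], ac["sd"])
    cs <- params$center_sd
    ctr <- c(h / 2 + h * clamp2sd(rnorm(1, 0, cs), 0, cs),
             w / 2 + w * clamp2sd(rnorm(1, 0, cs), 0, cs))
    bt <- params$band_thickness
    thick <- rnorm(1, bt["base"] + sgn * e * bt["delta"], bt["sd"])
    thick <- min(max(thick, 0.02), 0.45)
    be <- params$band_echo
    band_mu <- min(max(rnorm(1, be["base"] - sgn * e * be["delta"], be["sd"]), 0), 255)
    btx <- params$band_texture
    band_shape <- max(rnorm(1, btx["base"] - sgn * e * btx["delta"], btx["sd"]), 1.5)
    spec <- list(
      individual_id = sprintf("A%s%03d", toupper(substr(size_class, 1, 1)), as.integer(index)),
      sex = sex, size_class = size_class,
      canvas_h = h, canvas_w = w,
      specimen_ellipse = list(center = ctr, axes = c(ax_r, ax_c)),
      cone_apex = c(ctr[1] - 0.55 * ax_r * rnorm(1, 1, 0.12),
                    ctr[2] - 0.25 * ax_c * rnorm(1, 1, 0.3)),
      cone_half_angle = rnorm(1, params$cone_half_angle["mean"], params$cone_half_angle["sd"]),
      cone_len = 1.35 * ax_r * rnorm(1, 1, 0.1),
      gain = max(rnorm(1, params$gain["mean"] + sgn * e * params$gain["delta"],
                       params$gain["sd"]), 0.1),
      band_thickness_frac = thick,
      band_echogenicity_mean = band_mu,
      band_texture_shape = band_shape,
      gland_echogenicity_mean = min(max(rnorm(1, params$gland_echo["mean"], params$gland_echo["sd"]), 0), 255),
      coelom_echogenicity_mean = rnorm(1, params$coelom_echo["mean"], params$coelom_echo["sd"]),
      speckle_shape = params$speckle_shape,
      frame_jitter_scale = params$frame_jitter_scale
    )
    structure(spec, class = "phantom_spec")
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec %s sex=%s size=%s band_frac=%.3f band_mu=%.1f>\n",
              x$individual_id, x$sex, x$size_class,
              x$band_thickness_frac, x$band_echogenicity_mean))
  invisible(x)
}

#' Quality-defect profile for a rendered frame
#'
#' Encodes the three defect families the quality filter must catch:
#' (a) echo ghost — an attenuated, shifted copy of the specimen added back;
#' (b) suppressed gonad — the band rendered at digestive-gland intensity so
#' the anatomy is unidentifiable; (c) truncated field of view — the
#' specimen shifted off a corner so it is cut by the image borders. An
#' optional device overlay border (constant frame plus a burned-in text
#' band) can be drawn on top.
#'
#' @param echo_ghost Add a ghost copy?
#' @param ghost_offset Integer (row, col) shift of the ghost in pixels.
#' @param ghost_gain Intensity multiplier of the ghost copy.
#' @param truncate_fov Shift the specimen off-corner?
#' @param truncate_frac Fraction of each canvas dimension to shift by, in
#'   \[0, 0.9\].
#' @param suppress_gonad Render the gonad band at gland intensity?
#' @param overlay_px Constant border width in pixels (0 = no overlay).
#' @param text_band_px Height of the synthetic burned-in text band drawn
#'   below the top border.
#' @return A list of class `artifact_profile`.
#' @export
artifact_profile <- function(echo_ghost = FALSE, ghost_offset = c(18L, 24L),
                             ghost_gain = 0.45,
                             truncate_fov = FALSE, truncate_frac = 0.35,
                             suppress_gonad = FALSE,
                             overlay_px = 0L, text_band_px = 0L) {
  if (truncate_frac < 0 || truncate_frac > 0.9) {
    abort("`truncate_frac` must lie in [0, 0.9].")
  }
  structure(list(
    echo_ghost = echo_ghost, ghost_offset = as.integer(ghost_offset),
    ghost_gain = ghost_gain,
    truncate_fov = truncate_fov, truncate_frac = truncate_frac,
    suppress_gonad = suppress_gonad,
    overlay_px = as.integer(overlay_px), text_band_px = as.integer(text_band_px)
  ), class = "artifact_profile")
}

# Geometry masks of a phantom at a given per-frame jitter. Returns logical
# matrices: specimen (full ellipse), gland (cone interior), band (ring of
# band_thickness hugging the cone, inside the specimen), background.
#' Region masks of a phantom's anatomy
#'
#' Exposes the exact geometry the renderer uses, so tests and quality
#' detectors can compute masked means against ground truth.
#'
#' @param spec A [sample_individual()] spec.
#' @param jitter Numeric (row, col) translation applied to all anatomy.
#' @param axis_scale Multiplier on the ellipse axes (per-frame jitter).
#' @return Named list of logical matrices: `specimen`, `gland`, `band`,
#'   `coelom`, `background`.
#' @export
phantom_masks <- function(spec, jitter = c(0, 0), axis_scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$canvas_h; w <- spec$canvas_w
  ax <- spec$specimen_ellipse$axes * axis_scale
  if (any(ax <= 0)) abort("Degenerate specimen ellipse (non-positive axis).")
  ctr <- spec$specimen_ellipse$center + jitter
  rr <- matrix(seq_len(h), h, w) - ctr[1]
  cc <- matrix(seq_len(w), h, w, byrow = TRUE) - ctr[2]
  specimen <- (rr / ax[1])^2 + (cc / ax[2])^2 <= 1

  apex <- spec$cone_apex + jitter
  pr <- matrix(seq_len(h), h, w) - apex[1]
  pc <- matrix(seq_len(w), h, w, byrow = TRUE) - apex[2]
  d <- sqrt(pr^2 + pc^2)
  # cone axis points straight down the image (toward the foot surface)
  ang <- acos(pmin(pmax(ifelse(d > 0, pr / d, 1), -1), 1))
  in_cone <- d <= spec$cone_len & ang <= spec$cone_half_angle
  gland <- in_cone & specimen

  band_px <- spec$band_thickness_frac * min(ax)
  # ring around the cone: within band_px of the cone set but outside it
  near_cone <- d <= spec$cone_len + band_px &
    ang <= spec$cone_half_angle + band_px / pmax(d, 1)
  band <- near_cone & !in_cone & specimen

  list(specimen = specimen, gland = gland, band = band,
       coelom = specimen & !gland & !band, background = !specimen)
}

#' Render one synthetic ultrasound frame
#'
#' Composes the deterministic anatomy phantom for `spec`, applies per-frame
#' geometric jitter (probe repositioning), unit-mean gamma multiplicative
#' speckle inside the specimen, then any quality defects, and finally the
#' device overlay border. Background sits at intensity 2, strictly below
#' the default ROI threshold of 5.
#'
#' @param spec A [sample_individual()] spec.
#' @param frame_index Non-negative frame number (part of the random
#'   substream).
#' @param artifacts An [artifact_profile()].
#' @param seed Integer master seed.
#' @return Numeric matrix, values in \[0, 255\].
#' @export
render_frame <- function(spec, frame_index = 0L,
                         artifacts = artifact_profile(), seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), frame_index >= 0)
  h <- spec$canvas_h; w <- spec$canvas_w
  with_substream(seed, "frame", spec$individual_id, spec$sex, frame_index, code = {
    jit <- rnorm(2, 0, 1.5 * spec$frame_jitter_scale)
    axs <- 1 + rnorm(1, 0, 0.01 * spec$frame_jitter_scale)
    if (artifacts$truncate_fov) {
      jit <- jit + artifacts$truncate_frac * c(h, w)
    }
    m <- phantom_masks(spec, jitter = jit, axis_scale = axs)
    gain <- spec$gain %||% 1
    img <- matrix(2, h, w)
    img[m$coelom] <- gain * spec$coelom_echogenicity_mean
    img[m$gland] <- gain * spec$gland_echogenicity_mean
    if (artifacts$suppress_gonad) {
      # criterion (b): neither gonad band nor digestive gland identifiable -
      # the whole anatomy renders at coelom intensity
      img[m$band] <- gain * spec$coelom_echogenicity_mean
      img[m$gland] <- gain * spec$coelom_echogenicity_mean
    } else {
      img[m$band] <- gain * spec$band_echogenicity_mean
      # sex-linked internal band texture: multiplicative gamma with the
      # individual's texture shape (lower shape = higher contrast)
      if (is.finite(spec$band_texture_shape)) {
        nb <- sum(m$band)
        img[m$band] <- img[m$band] *
          rgamma(nb, shape = spec$band_texture_shape, rate = spec$band_texture_shape)
      }
    }
    if (is.finite(spec$speckle_shape)) {
      ns <- sum(m$specimen)
      img[m$specimen] <- img[m$specimen] *
        rgamma(ns, shape = spec$speckle_shape, rate = spec$speckle_shape)
    }
    if (artifacts$echo_ghost) {
      off <- artifacts$ghost_offset
      ghost <- matrix(0, h, w)
      src_r <- seq_len(h) - off[1]; src_c <- seq_len(w) - off[2]
      ok_r <- src_r >= 1 & src_r <= h; ok_c <- src_c >= 1 & src_c <= w
      ghost[ok_r, ok_c] <- (img * m$specimen)[src_r[ok_r], src_c[ok_c]]
      img <- img + artifacts$ghost_gain * ghost
    }
    img <- clip255(img)
    if (artifacts$overlay_px > 0) {
      b <- artifacts$overlay_px
      if (2 * b >= min(h, w)) abort("Overlay border consumes the whole canvas.")
      img[seq_len(b), ] <- 40
      img[seq(h - b + 1, h), ] <- 40
      img[, seq_len(b)] <- 40
      img[, seq(w - b + 1, w)] <- 40
      if (artifacts$text_band_px > 0) {
        tb <- b + seq_len(artifacts$text_band_px)
        txt <- matrix(rbinom(length(tb) * (w - 2 * b), 1, 0.3) * 255,
                      length(tb), w - 2 * b)
        img[tb, seq(b + 1, w - b)] <- txt
      }
    }
    img <- round(img)
    # expose the sampled per-frame geometry so masked-mean oracles can
    # reconstruct the exact masks via phantom_masks(spec, jitter, axis_scale)
    attr(img, "geometry") <- list(jitter = jit, axis_scale = axs)
    img
  })
}
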