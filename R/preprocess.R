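#' Strip device overlay borders from a frame
#'
#' Ultrasound consoles burn a border and text overlays (IDs, acquisition
#' parameters) into exported frames; kept in place they would let a model
#' classify from text instead of anatomy. In `"auto"` mode the maximal
#' constant-intensity margin is detected independently per side and
#' removed, plus `text_band` extra rows from the top (where burned-in text
#' sits below the border). Explicit margins may be given instead.
#'
#' @param image Numeric matrix (grayscale, 0-255).
#' @param border `"auto"` or an integer vector of margins
#'   (top, bottom, left, right), recycled to length 4.
#' @param text_band Extra rows to drop below the detected top border
#'   (default 0).
#' @param bg_max Auto mode treats a constant margin as overlay only if its
#'   value exceeds this (default 5, the ROI threshold): a constant margin
#'   at background intensity is empty background, not a device border.
#' @return The interior sub-image.
#' @export
strip_overlay <- function(image, border = "auto", text_band = 0L, bg_max = 5) {
  assert_image(image)
  h <- nrow(image); w <- ncol(image)
  if (identical(border, "auto")) {
    const_run <- function(get_line, n_max) {
      v <- get_line(1L)[1]
      if (v <= bg_max) return(0L)
      k <- 0L
      while (k < n_max) {
        line <- get_line(k + 1L)
        if (!all(line == v)) break
        k <- k + 1L
      }
      k
    }
    m <- c(
      const_run(function(i) image[i, ], h %/% 2),
      const_run(function(i) image[h - i + 1L, ], h %/% 2),
      const_run(function(i) image[, i], w %/% 2),
      const_run(function(i) image[, w - i + 1L], w %/% 2)
    )
    m[1] <- m[1] + as.integer(text_band)
  } else {
    m <- as.integer(rep(border, length.out = 4))
  }
  if (m[1] + m[2] >= h || m[3] + m[4] >= w) {
    abort("Overlay margins consume the entire image.")
  }
  image[seq(m[1] + 1L, h - m[2]), seq(m[3] + 1L, w - m[4]), drop = FALSE]
}

#' Extract the specimen region of interest
#'
#' Binarizes the frame at a fixed intensity threshold (foreground =
#' strictly greater than `threshold`, so tie pixels are background),
#' labels 8-connected foreground components, selects the component with
#' the largest pixel area, and returns its axis-aligned bounding box
#' together with the original image cropped to it. Equal-area ties are
#' broken toward the box whose (row0, col0) is lexicographically smallest.
#'
#' @param image Numeric matrix (grayscale, 0-255).
#' @param threshold Intensity threshold (default 5 on the 0-255 scale; the
#'   imaging background is uniformly dark, so this cleanly separates the
#'   specimen).
#' @return A list with `box` (a one-row tibble: `row0`, `col0`, `height`,
#'   `width`; 0-based, inclusive origin) and `image` (the crop).
#' @export
extract_roi <- function(image, threshold = 5) {
  assert_image(image)
  fg <- image > threshold
  if (!any(fg)) {
    abort("Empty specimen: no pixel above the ROI threshold.",
          class = "sonosex_empty_specimen")
  }
  lab <- label_components(fg)
  areas <- tabulate(lab[lab > 0L])
  boxes <- lapply(which(areas == max(areas)), function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    c(row0 = min(idx[, 1]) - 1L, col0 = min(idx[, 2]) - 1L,
      height = diff(range(idx[, 1])) + 1L, width = diff(range(idx[, 2])) + 1L)
  })
  ord <- order(vapply(boxes, `[[`, 0L, "row0"), vapply(boxes, `[[`, 0L, "col0"))
  b <- boxes[[ord[1]]]
  crop <- image[seq(b["row0"] + 1L, b["row0"] + b["height"]),
                seq(b["col0"] + 1L, b["col0"] + b["width"]), drop = FALSE]
  list(
    box = tibble(row0 = b[["row0"]], col0 = b[["col0"]],
                 height = b[["height"]], width = b[["width"]]),
    image = crop
  )
}

#' Zero-pad an image to target dimensions
#'
#' @param image Numeric matrix.
#' @param target_h,target_w Output dims, each at least the input dims.
#' @param anchor `"center"` (default), `"topleft"`.
#' @return `target_h` x `target_w` matrix: original pixels verbatim at the
#'   anchored position, all added pixels 0.
#' @export
zero_pad <- function(image, target_h, target_w, anchor = c("center", "topleft")) {
  assert_image(image)
  anchor <- match.arg(anchor)
  h <- nrow(image); w <- ncol(image)
  if (target_h < h || target_w < w) {
    abort("Padding target is smaller than the image.")
  }
  out <- matrix(0, target_h, target_w)
  r0 <- if (anchor == "center") (target_h - h) %/% 2 else 0L
  c0 <- if (anchor == "center") (target_w - w) %/% 2 else 0L
  out[r0 + seq_len(h), c0 + seq_len(w)] <- image
  out
}

FILENAME_RE <- "^([A-Za-z0-9]+)_([A-Za-z0-9]+)_([FM])_(small|large)_(\\d{8})_(\\d+)\\.png$"

#' Parse and format canonical frame filenames
#'
#' The canonical grammar is
#' `<ID>_<location>_<sex>_<size>_<YYYYMMDD>_<frame>.png` with sex in
#' {F, M} and size in {small, large}. `parse_filename()` and
#' [format_filename()] round-trip.
#'
#' @param name Filename (directories are dropped).
#' @return A one-row tibble: `individual_id`, `location`, `sex`,
#'   `size_class`, `date`, `frame_index`.
#' @export
parse_filename <- function(name) {
  base <- basename(name)
  m <- regmatches(base, regexec(FILENAME_RE, base))[[1]]
  if (length(m) == 0) {
    parts <- strsplit(sub("\\.png$", "", base), "_")[[1]]
    field <- c("individual_id", "location", "sex", "size_class", "date", "frame_index")
    bad <- if (length(parts) != 6) {
      "overall structure (expected 6 underscore-separated fields)"
    } else if (!grepl("^[FM]$", parts[3])) {
      "sex"
    } else if (!parts[4] %in% c("small", "large")) {
      "size_class"
    } else if (!grepl("^\\d{8}$", parts[5])) {
      "date"
    } else if (!grepl("^\\d+$", parts[6])) {
      "frame_index"
    } else {
      field[which(!grepl("^[A-Za-z0-9]+$", parts[1:2]))[1]]
    }
    abort(sprintf("Malformed filename '%s': invalid %s.", base, bad),
          class = "sonosex_parse_error")
  }
  tibble(
    individual_id = m[2], location = m[3], sex = m[4], size_class = m[5],
    date = as.Date(m[6], format = "%Y%m%d"),
    frame_index = as.integer(m[7])
  )
}

#' @rdname parse_filename
#' @param individual_id,location,sex,size_class,date,frame_index Field
#'   values.
#' @export
format_filename <- function(individual_id, location, sex, size_class, date,
                            frame_index) {
  sprintf("%s_%s_%s_%s_%s_%02d.png", individual_id, location, sex, size_class,
          format(as.Date(date), "%Y%m%d"), as.integer(frame_index))
}

#' Quality-filter rule set
#'
#' Automated stand-ins for visual quality control, one detector per
#' exclusion criterion: (a) echo ghosts — a secondary peak in the spatial
#' autocorrelation of the frame above `ghost_peak`; (b) missing
#' gonad/gland anatomy — band-vs-gland intensity contrast below
#' `anatomy_contrast`; (c) incomplete capture — above-threshold foreground
#' touching at least `border_touch` image borders. Detectors are
#' deliberately conservative (they fire only on clear defects; borderline
#' frames are retained).
#'
#' @param echo,anatomy,capture Enable each criterion.
#' @param ghost_peak Autocorrelation peak-prominence threshold in (0, 1).
#' @param ghost_min_lag Minimum lag (pixels) for a peak to count as a ghost.
#' @param anatomy_contrast Minimum (p90 - median)/median intensity contrast
#'   inside the specimen.
#' @param border_touch Number of touched borders at which criterion (c)
#'   fires.
#' @param roi_threshold Foreground threshold shared with [extract_roi()].
#' @return A list of class `quality_rules`.
#' @export
quality_rules <- function(echo = TRUE, anatomy = TRUE, capture = TRUE,
                          ghost_peak = 0.085, ghost_min_lag = 10,
                          anatomy_contrast = 0.40, border_touch = 2L,
                          roi_threshold = 5) {
  structure(list(echo = echo, anatomy = anatomy, capture = capture,
                 ghost_peak = ghost_peak, ghost_min_lag = ghost_min_lag,
                 anatomy_contrast = anatomy_contrast,
                 border_touch = as.integer(border_touch),
                 roi_threshold = roi_threshold),
            class = "quality_rules")
}

# (a) ghost detector: a shifted duplicate of the specimen creates a local
# secondary bump in the spatial autocorrelation. The statistic is the peak
# prominence — normalized autocorrelation minus its own smoothed background
# — over lags beyond ghost_min_lag; a clean specimen's autocorrelation
# decays smoothly and has near-zero prominence everywhere.
detect_ghost <- function(image, rules) {
  x <- image - mean(image)
  f <- stats::fft(x)
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE)) / length(x)
  ac <- ac / ac[1, 1]
  prom <- ac - box_blur5(box_blur5(ac))
  h <- nrow(x); w <- ncol(x)
  lag_r <- pmin(0:(h - 1), h - 0:(h - 1))
  lag_c <- pmin(0:(w - 1), w - 0:(w - 1))
  far <- outer(lag_r, lag_c, function(a, b) pmax(a, b)) >= rules$ghost_min_lag
  max(prom[far]) > rules$ghost_peak
}

# 5x5 box blur via integral image (suppresses speckle before contrast
# statistics).
box_blur5 <- function(image) {
  h <- nrow(image); w <- ncol(image)
  pad <- matrix(0, h + 5, w + 5)
  pad[3:(h + 2), 3:(w + 2)] <- image
  ii <- apply(apply(pad, 2, cumsum), 1, cumsum)  # transposed integral image
  # counts of in-bounds pixels per window for edge normalization
  cnt <- matrix(0, h + 5, w + 5)
  cnt[3:(h + 2), 3:(w + 2)] <- 1
  ci <- apply(apply(cnt, 2, cumsum), 1, cumsum)
  win <- function(m) {
    t(m[(1:w) + 5, (1:h) + 5] - m[(1:w), (1:h) + 5] -
        m[(1:w) + 5, (1:h)] + m[(1:w), (1:h)])
  }
  win(ii) / win(ci)
}

# (b) anatomy detector: after speckle-suppressing smoothing, the gonad
# band and digestive gland stand out as bright structures over the coelom
# bulk. Contrast = (p98 - p30) / p30 of smoothed specimen pixels (p30 sits
# in the coelom, p98 in gland/band); a frame with no identifiable anatomy
# is near-uniform and flattens the statistic.
detect_missing_anatomy <- function(image, rules) {
  sm <- box_blur5(image)
  fg <- sm[image > rules$roi_threshold]
  if (length(fg) < 25) return(TRUE)
  q <- quantile(fg, c(0.30, 0.98), names = FALSE)
  contrast <- (q[2] - q[1]) / max(q[1], 1)
  contrast < rules$anatomy_contrast
}

# (c) capture detector: foreground cut by >= border_touch image borders.
# A border counts only when foreground covers at least 10% of it — a
# truncated specimen leaves a long chord on the border, while a specimen
# merely grazing the edge touches a handful of pixels.
detect_truncation <- function(image, rules) {
  fg <- image > rules$roi_threshold
  frac <- c(mean(fg[1, ]), mean(fg[nrow(fg), ]),
            mean(fg[, 1]), mean(fg[, ncol(fg)]))
  sum(frac >= 0.10) >= rules$border_touch
}

#' Partition a manifest into quality-passing and excluded frames
#'
#' Runs the enabled defect detectors of a [quality_rules()] set on every
#' frame and splits the manifest. Detectors see only pixels — never the
#' sex label — so quality control cannot leak label information. Each
#' excluded row carries the codes of the criteria that fired
#' (`a` = echo ghost, `b` = missing anatomy, `c` = incomplete capture).
#'
#' @param manifest A manifest tibble (with `image` list-column or readable
#'   `path`s).
#' @param rules A [quality_rules()] set.
#' @return List with tibbles `kept` and `excluded`; `excluded` gains a
#'   `fired_codes` column.
#' @export
filter_quality <- function(manifest, rules = quality_rules()) {
  if (nrow(manifest) == 0) {
    return(list(kept = manifest, excluded = mutate(manifest, fired_codes = character())))
  }
  codes <- vapply(seq_len(nrow(manifest)), function(i) {
    img <- manifest_image(manifest, i)
    fired <- c(
      if (rules$echo && detect_ghost(img, rules)) "a",
      if (rules$anatomy && detect_missing_anatomy(img, rules)) "b",
      if (rules$capture && detect_truncation(img, rules)) "c"
    )
    paste(fired, collapse = "")
  }, character(1))
  keep <- codes == ""
  list(
    kept = manifest[keep, , drop = FALSE],
    excluded = mutate(manifest[!keep, , drop = FALSE], fired_codes = codes[!keep])
  )
}

#' Run the full preprocessing pipeline over a manifest
#'
#' For each frame: strip the device overlay, crop to the specimen ROI at
#' the fixed threshold, then zero-pad all frames to common dimensions
#' (dataset-wide maxima by default, centered). Frames whose specimen is
#' empty are dropped with a warning.
#'
#' @param manifest Manifest tibble.
#' @param threshold ROI threshold (default 5).
#' @param pad `"auto"` (dataset-wide max dims) or integer c(h, w).
#' @param border,text_band Passed to [strip_overlay()].
#' @return The manifest with an `image` list-column of preprocessed frames
#'   and `roi_row0`, `roi_col0`, `roi_height`, `roi_width` columns.
#' @export
preprocess_manifest <- function(manifest, threshold = 5, pad = "auto",
                                border = "auto", text_band = 0L) {
  crops <- vector("list", nrow(manifest))
  boxes <- vector("list", nrow(manifest))
  ok <- rep(TRUE, nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    img <- strip_overlay(manifest_image(manifest, i), border, text_band)
    roi <- tryCatch(extract_roi(img, threshold), sonosex_empty_specimen = function(e) NULL)
    if (is.null(roi)) { ok[i] <- FALSE; next }
    crops[[i]] <- roi$image
    boxes[[i]] <- roi$box
  }
  if (!all(ok)) {
    warning(sprintf("%d frame(s) dropped: empty specimen.", sum(!ok)))
  }
  manifest <- manifest[ok, , drop = FALSE]
  crops <- crops[ok]
  boxes <- bind_rows(boxes[ok])
  names(boxes) <- paste0("roi_", names(boxes))
  if (identical(pad, "auto")) {
    pad <- c(max(vapply(crops, nrow, 0L)), max(vapply(crops, ncol, 0L)))
  }
  manifest$image <- lapply(crops, zero_pad, target_h = pad[1], target_w = pad[2])
  bind_cols_safe(manifest, boxes)
}

bind_cols_safe <- function(x, y) {
  for (nm in names(y)) x[[nm]] <- y[[nm]]
  x
}
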