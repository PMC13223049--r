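#' Generate a labeled synthetic ultrasound dataset
#'
#' Draws `n_per_sex` individuals of each sex for the given size class,
#' renders an uneven number of frames per individual (frame counts per
#' animal vary, as in real scanning sessions), injects quality defects at
#' the requested rate, and returns a tidy manifest with ground-truth
#' quality flags. Filenames follow the canonical grammar
#' `<ID>_<location>_<sex>_<size>_<YYYYMMDD>_<frame>.png`.
#'
#' @param n_per_sex Individuals per sex (default 22, a full large-class
#'   cohort).
#' @param size_class `"large"` or `"small"`.
#' @param frames_range Integer length-2: inclusive range of frames per
#'   individual (default 5-8, deliberately uneven).
#' @param defect_rate Per-frame probability of injecting one defect, drawn
#'   uniformly from {echo ghost (a), suppressed gonad (b), truncated field
#'   of view (c)}.
#' @param overlay_px,text_band_px Device overlay drawn on every frame
#'   (0 disables).
#' @param params [population_params()] controlling anatomy and sex effect.
#' @param seed Integer master seed; the same seed reproduces the manifest
#'   and every image bit-for-bit.
#' @param out_dir Directory for PNG files and `manifest.csv`. If `NULL`,
#'   no files are written and the manifest carries an `image` list-column.
#' @param location Site code used in filenames.
#' @return A tibble manifest with columns `path`, `individual_id`,
#'   `location`, `sex`, `size_class`, `date`, `frame_index`,
#'   `quality_pass`, `defect_codes` (and `image` when `out_dir = NULL`).
#' @export
generate_dataset <- function(n_per_sex = 22L, size_class = "large",
                             frames_range = c(5L, 8L), defect_rate = 0,
                             overlay_px = 0L, text_band_px = 0L,
                             params = population_params(), seed = 1L,
                             out_dir = NULL, location = "BML") {
  stopifnot(n_per_sex >= 1, frames_range[1] >= 1,
            frames_range[2] >= frames_range[1],
            defect_rate >= 0, defect_rate <= 1)
  size_class <- match.arg(size_class, c("small", "large"))
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create output directory '%s'.", out_dir))
  }

  rows <- list()
  for (sex in c("F", "M")) {
    for (idx in seq_len(n_per_sex)) {
      spec <- sample_individual(sex, size_class, params, seed = seed, index = idx)
      meta <- with_substream(seed, "meta", sex, size_class, idx, code = {
        nf_choices <- seq(frames_range[1], frames_range[2])
        nf <- nf_choices[sample.int(length(nf_choices), 1)]
        day <- sample(0:120, 1)
        list(nf = nf, date = as.Date("2024-03-01") + day)
      })
      for (fi in seq_len(meta$nf)) {
        defect <- with_substream(seed, "defect", sex, size_class, idx, fi, code = {
          if (runif(1) < defect_rate) sample(c("a", "b", "c"), 1) else ""
        })
        art <- artifact_profile(
          echo_ghost = defect == "a",
          suppress_gonad = defect == "b",
          truncate_fov = defect == "c",
          overlay_px = overlay_px, text_band_px = text_band_px
        )
        img <- render_frame(spec, frame_index = fi, artifacts = art, seed = seed)
        fname <- format_filename(
          individual_id = spec$individual_id, location = location, sex = sex,
          size_class = size_class, date = meta$date, frame_index = fi
        )
        path <- if (is.null(out_dir)) fname else file.path(out_dir, fname)
        if (!is.null(out_dir)) write_frame(img, path)
        rows[[length(rows) + 1L]] <- tibble(
          path = path, individual_id = spec$individual_id,
          location = location, sex = sex, size_class = size_class,
          date = meta$date, frame_index = fi,
          quality_pass = defect == "", defect_codes = defect,
          image = if (is.null(out_dir)) list(img) else list(NULL)
        )
      }
    }
  }
  manifest <- bind_rows(rows)
  if (is.null(out_dir)) return(manifest)
  manifest$image <- NULL
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  manifest
}

#' Read a dataset manifest written by [generate_dataset()]
#'
#' @param path Path to a `manifest.csv` or to the directory containing it.
#' @return A tibble manifest with `date` parsed and paths made relative to
#'   the manifest's directory.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- as_tibble(read.csv(path, colClasses = "character"))
  m$date <- as.Date(m$date)
  m$frame_index <- as.integer(m$frame_index)
  m$quality_pass <- as.logical(m$quality_pass)
  m$defect_codes[is.na(m$defect_codes)] <- ""
  m
}

# Load the raster for a manifest row, from the image list-column when
# present, otherwise from disk.
manifest_image <- function(manifest, i) {
  if ("image" %in% names(manifest) && !is.null(manifest$image[[i]])) {
    return(manifest$image[[i]])
  }
  read_frame(manifest$path[i])
}

manifest_images <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) manifest_image(manifest, i))
}

# Individual identity key per the grouping convention:
# (individual_id, location, sex, size_class).
individual_key <- function(manifest) {
  paste(manifest$individual_id, manifest$location, manifest$sex,
        manifest$size_class, sep = "|")
}
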