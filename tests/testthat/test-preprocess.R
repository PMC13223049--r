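test_that("strip_overlay removes exactly the drawn border", {
  spec <- sample_individual("F", "large", seed = 3, index = 1)
  img <- render_frame(spec, 0, artifact_profile(overlay_px = 20), seed = 3)
  out <- strip_overlay(img, "auto")
  expect_identical(dim(out), dim(img) - c(40L, 40L))
  # explicit zero margins and overlay-free auto mode are identities
  plain <- render_frame(spec, 0, seed = 3)
  expect_equal(strip_overlay(plain, border = 0), unclass(plain),
               ignore_attr = TRUE)
  expect_identical(dim(strip_overlay(plain, "auto")), dim(plain))
  expect_error(strip_overlay(plain, border = c(70, 70, 0, 0)), "entire image")
})

test_that("strip_overlay drops the configured text band below the top border", {
  spec <- sample_individual("M", "large", seed = 3, index = 2)
  img <- render_frame(spec, 0, artifact_profile(overlay_px = 10, text_band_px = 6),
                      seed = 3)
  out <- strip_overlay(img, "auto", text_band = 6)
  expect_identical(dim(out), dim(img) - c(26L, 20L))
})

test_that("extract_roi matches the coordinate oracle on simple scenes", {
  img <- matrix(0, 100, 100)
  img[11:30, 41:80] <- 200
  roi <- extract_roi(img)
  expect_identical(unlist(roi$box), c(row0 = 10L, col0 = 40L, height = 20L, width = 40L))
  expect_identical(dim(roi$image), c(20L, 40L))
  # largest of two components wins
  img2 <- matrix(0, 100, 100)
  img2[5:14, 5:24] <- 100    # 200 px
  img2[40:59, 40:69] <- 100  # 600 px
  expect_identical(unlist(extract_roi(img2)$box),
                   c(row0 = 39L, col0 = 39L, height = 20L, width = 30L))
  expect_error(extract_roi(matrix(0, 10, 10)), class = "sonosex_empty_specimen")
  # threshold is strict: pixels at exactly 5 are background
  img3 <- matrix(5, 10, 10)
  img3[3, 3] <- 6
  expect_identical(unlist(extract_roi(img3)$box),
                   c(row0 = 2L, col0 = 2L, height = 1L, width = 1L))
})

test_that("extract_roi is idempotent and equals the brute-force oracle", {
  for (i in 1:40) {
    sex <- c("F", "M")[i %% 2 + 1]
    spec <- sample_individual(sex, "large", seed = 13, index = i)
    art <- artifact_profile(echo_ghost = i %% 5 == 0, truncate_fov = i %% 7 == 0)
    img <- render_frame(spec, i, art, seed = 13)
    roi <- extract_roi(img)
    expect_identical(unlist(roi$box), oracle_largest_component_box(img))
    again <- extract_roi(roi$image)
    expect_identical(unlist(again$box)[c("height", "width")],
                     c(height = nrow(roi$image), width = ncol(roi$image)))
  }
})

test_that("zero_pad preserves pixels, conserves intensity, and validates dims", {
  img <- matrix(runif(600, 0, 255), 20, 30)
  out <- zero_pad(img, 64, 64)
  expect_identical(dim(out), c(64L, 64L))
  expect_equal(sum(out), sum(img))
  expect_identical(out[23:42, 18:47], img)
  expect_identical(zero_pad(img, 20, 30), img)
  expect_error(zero_pad(img, 10, 64), "smaller")
})

test_that("filenames parse, round-trip and reject malformed fields", {
  meta <- parse_filename("A012_BML_F_large_20240301_03.png")
  expect_identical(meta$individual_id, "A012")
  expect_identical(meta$location, "BML")
  expect_identical(meta$sex, "F")
  expect_identical(meta$size_class, "large")
  expect_identical(meta$date, as.Date("2024-03-01"))
  expect_identical(meta$frame_index, 3L)
  # property: format(parse(x)) == x over generated names
  man <- tiny_manifest(n_per_sex = 3, seed = 8)
  for (nm in basename(man$path)) {
    p <- parse_filename(nm)
    expect_identical(
      format_filename(p$individual_id, p$location, p$sex, p$size_class,
                      p$date, p$frame_index), nm)
  }
  expect_error(parse_filename("A012_BML_X_large_20240301_03.png"),
               "sex", class = "sonosex_parse_error")
  expect_error(parse_filename("A012_BML_F_huge_20240301_03.png"), "size")
})

test_that("quality filtering excludes exactly the injected defects", {
  man <- generate_dataset(n_per_sex = 8, defect_rate = 0.25,
                          params = population_params(), seed = 4)
  parts <- filter_quality(man)
  expect_identical(sort(parts$excluded$path),
                   sort(man$path[man$defect_codes != ""]))
  # each fired code matches the injected defect family
  joined <- dplyr::left_join(parts$excluded, man[, c("path", "defect_codes")],
                             by = "path")
  expect_true(all(mapply(grepl, joined$defect_codes.y, joined$fired_codes)))
  # defect-free dataset passes wholesale; disabled rules keep everything
  clean <- tiny_manifest(seed = 2)
  expect_identical(nrow(filter_quality(clean)$excluded), 0L)
  off <- quality_rules(echo = FALSE, anatomy = FALSE, capture = FALSE)
  expect_identical(filter_quality(man, off)$kept, man)
})

test_that("quality filtering never inspects sex labels", {
  man <- generate_dataset(n_per_sex = 5, defect_rate = 0.3, seed = 14)
  flipped <- man
  flipped$sex <- rev(flipped$sex)
  expect_identical(filter_quality(man)$excluded$path,
                   filter_quality(flipped)$excluded$path)
})

test_that("preprocess_manifest pads all frames to common dims", {
  man <- tiny_manifest(n_per_sex = 3, seed = 9)
  pm <- preprocess_manifest(man)
  dims <- vapply(pm$image, dim, integer(2))
  expect_identical(nrow(unique(t(dims))), 1L)
  expect_true(all(c("roi_row0", "roi_height") %in% names(pm)))
})
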