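test_that("sampled specs propagate fields and respect invariants", {
  spec <- sample_individual("F", "large", seed = 1, index = 1)
  expect_s3_class(spec, "phantom_spec")
  expect_identical(spec$sex, "F")
  expect_identical(spec$size_class, "large")
  expect_gt(spec$band_thickness_frac, 0)
  expect_lt(spec$band_thickness_frac, 0.5)
  expect_gte(spec$band_echogenicity_mean, 0)
  expect_lte(spec$band_echogenicity_mean, 255)
  expect_error(sample_individual("X", "large"), "arg")
})

test_that("identical calls yield bit-identical specs and frames", {
  s1 <- sample_individual("M", "small", seed = 7, index = 3)
  s2 <- sample_individual("M", "small", seed = 7, index = 3)
  expect_identical(s1, s2)
  f1 <- render_frame(s1, 2, seed = 7)
  f2 <- render_frame(s2, 2, seed = 7)
  expect_identical(f1, f2)
})

test_that("zero effect size leaves F and M parameter distributions identical", {
  p0 <- population_params(sex_effect = 0)
  draw <- function(sex, field) {
    vapply(1:500, function(i) {
      sample_individual(sex, "large", p0, seed = 2, index = i)[[field]]
    }, numeric(1))
  }
  for (field in c("band_thickness_frac", "band_echogenicity_mean",
                  "band_texture_shape")) {
    p <- t.test(draw("F", field), draw("M", field))$p.value
    expect_gt(p, 0.01)
  }
})

test_that("zero-noise limit renders the deterministic phantom exactly", {
  p0 <- population_params(speckle_shape = Inf)
  spec <- sample_individual("M", "large", p0, seed = 4, index = 2)
  spec$band_texture_shape <- Inf
  img <- render_frame(spec, 0, seed = 4)
  g <- attr(img, "geometry")
  m <- phantom_masks(spec, g$jitter, g$axis_scale)
  # reconstruct the noiseless composite independently from the spec fields
  expected <- matrix(2, spec$canvas_h, spec$canvas_w)
  expected[m$coelom] <- spec$gain * spec$coelom_echogenicity_mean
  expected[m$gland] <- spec$gain * spec$gland_echogenicity_mean
  expected[m$band] <- spec$gain * spec$band_echogenicity_mean
  expect_equal(unclass(img), round(pmin(pmax(expected, 0), 255)),
               ignore_attr = TRUE)
})

test_that("masked means: band brighter than background; suppression flattens it", {
  for (i in 1:5) {
    spec <- sample_individual(c("F", "M")[i %% 2 + 1], "large", seed = 11, index = i)
    img <- render_frame(spec, i, seed = 11)
    g <- attr(img, "geometry")
    m <- phantom_masks(spec, g$jitter, g$axis_scale)
    expect_gt(mean(img[m$band]), mean(img[m$background]))
    sup <- render_frame(spec, i, artifact_profile(suppress_gonad = TRUE), seed = 11)
    gs <- attr(sup, "geometry")
    ms <- phantom_masks(spec, gs$jitter, gs$axis_scale)
    # both regions render at coelom intensity: means within speckle noise
    expect_lt(abs(mean(sup[ms$band]) - mean(sup[ms$gland])) /
                mean(sup[ms$gland]), 0.15)
  }
})

test_that("pixel range is 8-bit and background sits below the ROI threshold", {
  spec <- sample_individual("F", "large", seed = 5, index = 1)
  img <- render_frame(spec, 1, seed = 5)
  expect_gte(min(img), 0)
  expect_lte(max(img), 255)
  g <- attr(img, "geometry")
  m <- phantom_masks(spec, g$jitter, g$axis_scale)
  expect_lt(max(img[m$background]), 5)
})

test_that("frames of one individual correlate more than frames across individuals", {
  frames <- function(sp) {
    vapply(1:4, function(f) as.vector(render_frame(sp, f, seed = 9)),
           numeric(128 * 160))
  }
  gaps <- vapply(1:4, function(i) {
    fa <- frames(sample_individual("F", "large", seed = 9, index = i))
    fb <- frames(sample_individual("F", "large", seed = 9, index = i + 10))
    mean(cor(fa)[upper.tri(diag(4))]) - mean(cor(fa, fb))
  }, numeric(1))
  expect_gt(mean(gaps), 0.05)
})

test_that("generate_dataset writes a reproducible manifest with ground truth", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  m1 <- generate_dataset(n_per_sex = 3, frames_range = c(2L, 3L),
                         defect_rate = 0.5, seed = 6, out_dir = dir1)
  m2 <- generate_dataset(n_per_sex = 3, frames_range = c(2L, 3L),
                         defect_rate = 0.5, seed = 6, out_dir = dir2)
  expect_identical(m1$defect_codes, m2$defect_codes)
  expect_identical(basename(m1$path), basename(m2$path))
  expect_identical(read_frame(m1$path[1]), read_frame(m2$path[1]))
  expect_identical(sum(!m1$quality_pass), sum(m1$defect_codes != ""))
  # 22 F + 22 M large with uneven frames -> 44 unique individuals
  m3 <- tiny_manifest(n_per_sex = 22, frames = c(5L, 8L), seed = 1)
  expect_identical(dplyr::n_distinct(m3$individual_id, m3$sex), 44L)
  # defect rate 0 -> all pass
  expect_true(all(tiny_manifest(seed = 2)$quality_pass))
})

test_that("degenerate geometry and invalid profiles error", {
  spec <- sample_individual("F", "large", seed = 1, index = 1)
  spec$specimen_ellipse$axes <- c(0, 10)
  expect_error(phantom_masks(spec), "Degenerate")
  expect_error(artifact_profile(truncate_frac = 1.2), "0.9")
})
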