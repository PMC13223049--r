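#' @useDynLib sonosex, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang %||% abort .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join count n across
#' @importFrom stats prcomp kmeans rgamma runif rnorm rbinom quantile median
#'   sd dist predict qnorm binom.test
#' @importFrom utils head write.csv read.csv
NULL

MOD31 <- 2147483647

# Deterministic substream seed: folds an arbitrary sequence of integers and
# strings into one seed in [1, 2^31 - 2]. Keeps every intermediate below
# 2^53 so the arithmetic is exact in doubles.
substream_seed <- function(seed, ...) {
  parts <- list(...)
  acc <- as.numeric(seed) %% MOD31
  for (p in parts) {
    if (is.character(p)) {
      p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) %% MOD31
    }
    for (v in as.numeric(p)) {
      acc <- (acc * 69069 + (v %% MOD31) + 1) %% MOD31
    }
  }
  as.integer(acc %% (MOD31 - 2) + 1)
}

with_substream <- function(seed, ..., code) {
  withr::with_seed(substream_seed(seed, ...), code)
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

assert_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    abort(sprintf("`%s` must be a numeric matrix (grayscale raster).", arg))
  }
  invisible(image)
}

#' Read and write 8-bit grayscale PNG images
#'
#' Images are represented throughout the package as plain numeric matrices
#' with intensities on the 0-255 scale (rows = image rows). Multi-channel
#' PNGs are converted to grayscale by channel averaging on read.
#'
#' @param path File path.
#' @param image Numeric matrix, values in \[0, 255\].
#' @return `read_frame()` returns a numeric matrix; `write_frame()` returns
#'   `path` invisibly.
#' @export
read_frame <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3) x <- apply(x[, , 1:min(3, dim(x)[3]), drop = FALSE], c(1, 2), mean)
  round(x * 255)
}

#' @rdname read_frame
#' @export
write_frame <- function(image, path) {
  assert_image(image)
  png::writePNG(clip255(round(image)) / 255, path)
  invisible(path)
}

# Bilinear resize to target dims via the affine kernel, border-replicated
# so a constant image resizes to itself.
resize_bilinear <- function(image, out_h, out_w) {
  assert_image(image)
  sr <- nrow(image) / out_h
  sc <- ncol(image) / out_w
  # align pixel centers: source = (dest + 0.5) * scale - 0.5
  affine_warp(image, sr, 0, 0, sc, 0.5 * sr - 0.5, 0.5 * sc - 0.5,
              out_h, out_w, clamp_edges = TRUE)
}
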