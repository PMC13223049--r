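#' Extract intermediate activations and a rendered overlay
#'
#' Runs one frame through the model, keeps the post-ReLU output of the
#' requested convolution layer (layers numbered 1..blocks*convs_per_block
#' in forward order), and renders an overlay: the channel-mean map,
#' min-max normalized, upsampled bilinearly to the frame size and
#' alpha-blended onto the input.
#'
#' @param model A `cnn_model`.
#' @param frame Grayscale matrix (resized to the model input as needed).
#' @param layer_index Convolution layer to read.
#' @param alpha Overlay blend weight in \[0, 1\].
#' @return List: `maps` (H x W x C array of activations), `overlay`
#'   (matrix, 0-255 blend), `mean_map` (normalized channel mean).
#' @export
extract_activations <- function(model, frame, layer_index = 1L, alpha = 0.5) {
  stopifnot(inherits(model, "cnn_model"))
  n_layers <- length(model$conv)
  if (layer_index < 1 || layer_index > n_layers) {
    abort(sprintf("layer_index must be in 1..%d.", n_layers))
  }
  x <- images_to_batch(list(frame), model$config$input_size)
  fwd <- nn_forward(model, x$X, 1L, training = FALSE, keep_activations = TRUE)
  act <- fwd$activations[[layer_index]]
  h <- act$h; w <- act$w; cc <- ncol(act$values)
  maps <- array(0, c(h, w, cc))
  for (ch in seq_len(cc)) {
    maps[, , ch] <- matrix(act$values[, ch], h, w, byrow = TRUE)
  }
  mean_map <- apply(maps, c(1, 2), mean)
  rng <- range(mean_map)
  norm <- if (diff(rng) > 0) (mean_map - rng[1]) / diff(rng) else mean_map * 0
  target <- if (nrow(frame) == model$config$input_size &&
                ncol(frame) == model$config$input_size) frame
            else resize_bilinear(frame, model$config$input_size,
                                 model$config$input_size)
  up <- resize_bilinear(norm, nrow(target), ncol(target))
  overlay <- clip255((1 - alpha) * target + alpha * 255 * up)
  list(maps = maps, overlay = overlay, mean_map = norm)
}

#' Silhouette score of a labelled feature matrix
#'
#' Mean over samples of `(b - a) / max(a, b)`, with `a` the mean distance
#' to same-cluster points and `b` the smallest mean distance to another
#' cluster. Singleton clusters contribute 0 (their cohesion is undefined).
#'
#' @param features Numeric matrix (n x d).
#' @param labels Cluster labels, at least two distinct values.
#' @return A value in \[-1, 1\].
#' @export
silhouette_score <- function(features, labels) {
  features <- as.matrix(features)
  n <- nrow(features)
  labels <- as.character(labels)
  if (n < 3) abort("Need at least 3 samples.")
  if (length(unique(labels)) < 2) abort("Need at least 2 clusters.")
  d <- as.matrix(dist(features))
  sil <- vapply(seq_len(n), function(i) {
    same <- labels == labels[i]
    n_same <- sum(same) - 1L
    if (n_same == 0L) return(0)
    a <- sum(d[i, same]) / n_same
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(sil)
}

#' Select the number of clusters by silhouette with an elbow cross-check
#'
#' Runs k-means (10 seeded restarts, best inertia kept) for each candidate
#' K, recording the within-cluster sum of squares and the mean silhouette.
#' The selected K is the silhouette argmax; the elbow K — the point of
#' maximum second difference of the WCSS curve — is reported alongside,
#' and when the two disagree the silhouette wins (logged in the result).
#'
#' @param features Numeric matrix (n x d).
#' @param k_range Candidate cluster counts (default 2:9).
#' @param seed Integer seed for the k-means restarts.
#' @param nstart Restarts per K.
#' @return A list of class `cluster_selection`: `curve` tibble (k, wcss,
#'   silhouette), `selected_k`, `elbow_k`, `agree`.
#' @export
select_k <- function(features, k_range = 2:9, seed = 1L, nstart = 10L) {
  features <- as.matrix(features)
  if (nrow(features) <= max(k_range)) {
    abort("Need more points than the largest candidate K.")
  }
  fits <- withr::with_seed(substream_seed(seed, "kmeans"), {
    lapply(k_range, function(k) kmeans(features, centers = k, nstart = nstart,
                                       iter.max = 100))
  })
  curve <- tibble(
    k = as.integer(k_range),
    wcss = vapply(fits, `[[`, 0, "tot.withinss"),
    silhouette = vapply(seq_along(fits), function(i) {
      silhouette_score(features, fits[[i]]$cluster)
    }, numeric(1))
  )
  selected <- curve$k[which.max(curve$silhouette)]
  # anchor the elbow curve at K = 1 (total scatter) so a bend at the
  # smallest candidate K is detectable by the second difference
  wcss1 <- sum(sweep(features, 2, colMeans(features))^2)
  ek <- c(1L, curve$k); ew <- c(wcss1, curve$wcss)
  elbow <- if (length(ew) >= 3) {
    d2 <- diff(ew, differences = 2)
    ek[which.max(d2) + 1L]
  } else {
    curve$k[1]
  }
  structure(list(curve = curve, selected_k = selected, elbow_k = elbow,
                 agree = selected == elbow),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("<cluster_selection K=%d (silhouette argmax; elbow K=%d%s)>\n",
              x$selected_k, x$elbow_k,
              if (x$agree) ", agree" else ", disagree - silhouette wins"))
  invisible(x)
}

#' Tidy a cluster-selection curve
#'
#' @param x A `cluster_selection`.
#' @param ... Unused.
#' @export
tidy.cluster_selection <- function(x, ...) x$curve

#' @rdname tidy.cluster_selection
#' @export
glance.cluster_selection <- function(x, ...) {
  tibble(selected_k = x$selected_k, elbow_k = x$elbow_k, agree = x$agree)
}

#' Exact t-SNE embedding of a feature matrix
#'
#' A direct O(n^2) implementation of t-distributed stochastic neighbor
#' embedding: Gaussian input affinities calibrated per point to the target
#' perplexity by bisection, symmetrized; Student-t output affinities;
#' KL-divergence gradient descent with momentum and early exaggeration.
#' Deterministic under `seed`. Suitable for the few hundred frames this
#' pipeline visualizes.
#'
#' @param features Numeric matrix (n x d).
#' @param seed Integer seed (initialization).
#' @param perplexity Target perplexity; requires `n > 3 * perplexity`.
#' @param n_iter Gradient-descent iterations.
#' @param learning_rate Step size.
#' @return Tibble with `tsne1`, `tsne2` in input row order.
#' @export
tsne_embed <- function(features, seed = 1L, perplexity = 10,
                       n_iter = 500L, learning_rate = 100) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n <= 3 * perplexity) {
    abort("Perplexity too large: need n > 3 * perplexity.")
  }
  d2 <- as.matrix(dist(x))^2
  target_h <- log(perplexity)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- 1e-20; hi <- 1e20; beta <- 1
    for (it in 1:60) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { hi <- beta; beta <- (lo + hi) / 2; next }
      pj <- w / sw
      h <- -sum(pj[pj > 0] * log(pj[pj > 0]))
      if (abs(h - target_h) < 1e-5) break
      if (h > target_h) lo <- beta else hi <- beta
      beta <- if (is.finite(hi) && hi < 1e19) (lo + hi) / 2 else beta * 2
    }
    p[i, -i] <- w / sum(w)
  }
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)

  y <- withr::with_seed(substream_seed(seed, "tsne"),
                        matrix(rnorm(n * 2, 0, 1e-4), n, 2))
  inc <- matrix(0, n, 2)
  for (iter in seq_len(n_iter)) {
    exag <- if (iter <= 100) 4 else 1
    momentum <- if (iter <= 250) 0.5 else 0.8
    yd2 <- as.matrix(dist(y))^2
    num <- 1 / (1 + yd2)
    diag(num) <- 0
    q <- pmax(num / sum(num), 1e-12)
    l <- (exag * p - q) * num
    grad <- 4 * (diag(rowSums(l)) - l) %*% y
    inc <- momentum * inc - learning_rate * grad
    y <- y + inc
    y <- sweep(y, 2, colMeans(y))
  }
  tibble(tsne1 = y[, 1], tsne2 = y[, 2])
}

#' Pool a CNN's penultimate features for diagnostics
#'
#' Global-average-pools the post-dropout, pre-flatten activation of each
#' frame into one feature vector per image (channels as features) — the
#' default feature space for PCA/k-means/t-SNE diagnostics.
#'
#' @param model A `cnn_model`.
#' @param images List of grayscale matrices.
#' @return Matrix n x C_last.
#' @export
pooled_features <- function(model, images) {
  x <- images_to_batch(images, model$config$input_size)
  fwd <- nn_forward(model, x$X, x$n, training = FALSE, keep_activations = TRUE)
  act <- fwd$activations[[length(model$conv)]]
  hw <- act$h * act$w
  t(vapply(seq_len(x$n), function(i) {
    colMeans(act$values[(i - 1L) * hw + seq_len(hw), , drop = FALSE])
  }, numeric(ncol(act$values))))
}
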