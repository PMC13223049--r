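test_that("activation extraction honors the layer contract", {
  model <- build_cnn(cnn_config(schedule = c(4L, 2L), input_size = 16L,
                                dropout_rate = 0, dense_head = 4L,
                                convs_per_block = 1L), seed = 1)
  frame <- matrix(0, 16, 16)
  act <- extract_activations(model, frame, layer_index = 1)
  # zero input through a bias-free first conv: all activations zero,
  # overlay uniform
  expect_true(all(act$maps == 0))
  expect_identical(length(unique(as.vector(act$overlay))), 1L)
  expect_identical(dim(act$overlay), dim(frame))
  expect_identical(dim(act$maps)[3], 4L)
  expect_error(extract_activations(model, frame, layer_index = 10), "layer_index")
})

test_that("a hand-set edge filter activates along a step edge", {
  model <- build_cnn(cnn_config(schedule = 1L, input_size = 16L,
                                dropout_rate = 0, dense_head = 2L,
                                convs_per_block = 1L), seed = 1)
  # vertical-edge kernel: -1 0 1 in each kernel row (columns of the image)
  k <- matrix(c(-1, 0, 1, -1, 0, 1, -1, 0, 1), 3, 3, byrow = TRUE)
  # weight rows are ordered k*C + ch with k = (dr+1)*3 + (dc+1)
  W <- numeric(9)
  for (dr in -1:1) for (dc in -1:1) W[(dr + 1) * 3 + (dc + 1) + 1] <- k[dr + 2, dc + 2]
  model$conv[[1]]$W <- matrix(W, 9, 1)
  step <- matrix(0, 16, 16)
  step[, 9:16] <- 255
  act <- extract_activations(model, step, layer_index = 1)
  hot <- which(act$maps[, , 1] == max(act$maps), arr.ind = TRUE)
  expect_true(all(hot[, 2] %in% 8:9))  # maximal response hugs the step
})

test_that("select_k recovers the constructed number of clusters", {
  x2 <- rbind(gaussian_blob(100, c(0, 0, 0), seed = 1),
              gaussian_blob(100, c(12, 0, 0), seed = 2))
  sel2 <- select_k(x2, 2:9, seed = 7)
  expect_identical(sel2$selected_k, 2L)
  expect_identical(sel2$elbow_k, 2L)
  expect_true(all(diff(sel2$curve$wcss) <= 1e-8))  # WCSS non-increasing
  expect_true(all(abs(sel2$curve$silhouette) <= 1))
  x3 <- rbind(gaussian_blob(70, c(0, 0, 0), seed = 3),
              gaussian_blob(70, c(12, 0, 0), seed = 4),
              gaussian_blob(70, c(0, 12, 0), seed = 5))
  expect_identical(select_k(x3, 2:9, seed = 7)$selected_k, 3L)
  expect_identical(select_k(x2, k_range = 2, seed = 1)$selected_k, 2L)
})

test_that("silhouette_score matches brute force and the cluster package", {
  x <- rbind(gaussian_blob(25, c(0, 0), seed = 6),
             gaussian_blob(25, c(4, 4), seed = 7))
  labels <- rep(c("a", "b"), each = 25)
  # brute force: explicit double loop over pairwise distances
  d <- as.matrix(dist(x))
  brute <- mean(vapply(1:50, function(i) {
    a <- mean(d[i, labels == labels[i]][-which(which(labels == labels[i]) == i)])
    b <- mean(d[i, labels != labels[i]])
    (b - a) / max(a, b)
  }, numeric(1)))
  expect_equal(silhouette_score(x, labels), brute, tolerance = 1e-10)
  skip_if_not_installed("cluster")
  ref <- mean(cluster::silhouette(as.integer(factor(labels)), dist(x))[, 3])
  expect_equal(silhouette_score(x, labels), ref, tolerance = 1e-10)
})

test_that("silhouette limits: separated clusters near 1, random labels near 0", {
  tight <- rbind(gaussian_blob(20, c(0, 0), sd = 0.01, seed = 8),
                 gaussian_blob(20, c(1e5, 0), sd = 0.01, seed = 9))
  expect_gt(silhouette_score(tight, rep(1:2, each = 20)), 0.999)
  blob <- gaussian_blob(500, c(0, 0, 0), seed = 10)
  rnd <- withr::with_seed(11, sample(1:2, 500, replace = TRUE))
  expect_lt(abs(silhouette_score(blob, rnd)), 0.05)
  expect_error(silhouette_score(blob, rep(1, 500)), "2 clusters")
})

test_that("t-SNE is deterministic and preserves coarse structure", {
  x <- rbind(gaussian_blob(60, c(0, 0, 0, 0), seed = 12),
             gaussian_blob(60, c(50, 0, 0, 0), seed = 13))
  e1 <- tsne_embed(x, seed = 3, perplexity = 10)
  e2 <- tsne_embed(x, seed = 3, perplexity = 10)
  expect_identical(e1, e2)
  y <- as.matrix(e1)
  between <- sqrt(sum((colMeans(y[1:60, ]) - colMeans(y[61:120, ]))^2))
  expect_gt(between, median(dist(y[1:60, ])))
  # duplicated points embed as tight neighborhoods
  dup <- x[c(1:20, 1:20), ]
  ed <- as.matrix(tsne_embed(dup, seed = 4, perplexity = 8))
  for (i in 1:20) {
    twin_dist <- sqrt(sum((ed[i, ] - ed[i + 20, ])^2))
    expect_lt(twin_dist, median(dist(ed)))
  }
  expect_error(tsne_embed(x[1:20, ], perplexity = 10), "erplexity")
})

test_that("overlapping classes: high accuracy can coexist with low silhouette", {
  # two 10-D Gaussians shifted along one axis: a linear rule is ~85%
  # accurate, yet the clusters barely separate geometrically
  xa <- gaussian_blob(200, c(2.2, rep(0, 9)), seed = 14)
  xb <- gaussian_blob(200, c(0, rep(0, 9)), seed = 15)
  x <- rbind(xa, xb)
  y <- rep(c("M", "F"), each = 200)
  expect_lt(silhouette_score(x, y), 0.15)
  tr <- c(1:150, 201:350); te <- setdiff(1:400, tr)
  fit <- sonosex:::fit_logistic_newton(x[tr, ], as.integer(y[tr] == "M"),
                                       C = 1, weights = rep(1, 300))
  acc <- mean(ifelse(sonosex:::predict_logistic(fit, x[te, ]) >= 0.5,
                     "M", "F") == y[te])
  expect_gt(acc, 0.8)
})
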