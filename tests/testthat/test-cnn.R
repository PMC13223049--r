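# Tiny architectures keep the unit tests fast; the full-width reverse-L
# build is exercised once for the schedule introspection.

tiny_cfg <- function(family = "reverse", schedule = c(4L, 2L), input = 16L,
                     dropout = 0, head = 4L, convs = 1L) {
  cnn_config(family = family, schedule = schedule, input_size = input,
             dropout_rate = dropout, dense_head = head, convs_per_block = convs)
}

separable_frames <- function(n_per_class = 8, size = 16) {
  bright <- lapply(seq_len(n_per_class), function(i) {
    withr::with_seed(i, matrix(runif(size^2, 120, 255), size, size))
  })
  dark <- lapply(seq_len(n_per_class), function(i) {
    withr::with_seed(100 + i, matrix(runif(size^2, 0, 100), size, size))
  })
  list(images = c(bright, dark),
       labels = rep(c("M", "F"), each = n_per_class))
}

test_that("the reverse-L build introspects to the canonical channel schedule", {
  model <- build_cnn(cnn_config(family = "reverse", size_variant = "L",
                                input_size = 64L), seed = 1)
  sched <- channel_schedule(model)
  expect_identical(unname(sched), c(512L, 256L, 128L, 64L))
  expect_identical(unname(sched[1]), 512L)
  expect_identical(model$pre_flatten_spatial, 4L)  # 64 / 2^4
  # parameter count is a pure function of the config
  expect_identical(n_parameters(model),
                   n_parameters(build_cnn(model$config, seed = 99)))
})

test_that("family monotonicity and divisibility are enforced", {
  expect_error(cnn_config(family = "reverse", schedule = c(64, 128)),
               "decreasing")
  expect_error(cnn_config(family = "forward", schedule = c(128, 64)),
               "increasing")
  expect_error(cnn_config(schedule = c(8, 4), input_size = 30L), "divisible")
  fwd <- cnn_config(family = "forward", size_variant = "M", width_scale = 1 / 8)
  expect_identical(fwd$schedule, c(8L, 16L, 32L))
})

test_that("a zero-weight model outputs exactly 0.5 and honors thresholds", {
  model <- build_cnn(tiny_cfg(), seed = 1)
  model$conv <- lapply(model$conv, function(l) { l$W[] <- 0; l })
  model$dense <- lapply(model$dense, function(l) { l$W[] <- 0; l })
  imgs <- separable_frames(3)$images
  pred <- predict(model, imgs)
  expect_true(all(pred$score == 0.5))
  expect_true(all(pred$label == "M"))  # score >= threshold ties to M
  expect_true(all(predict(model, imgs, threshold = 0)$label == "M"))
  expect_true(all(predict(model, imgs, threshold = 1.01)$label == "F"))
})

test_that("prediction scores are invariant to frame order", {
  model <- build_cnn(tiny_cfg(), seed = 2)
  imgs <- separable_frames(4)$images
  p1 <- predict(model, imgs)$score
  perm <- c(5, 2, 7, 1, 8, 3, 6, 4)
  p2 <- predict(model, imgs[perm])$score
  expect_equal(p2, p1[perm], tolerance = 1e-12)
})

test_that("grid enumeration counts structures times combinations", {
  structures <- lapply(1:22, function(i) tiny_cfg(schedule = c(2L * i + 2L, 2L)))
  grid <- hyperparameter_grid(structures,
                              learning_rates = 10^seq(-4, -2, length.out = 11),
                              dropout_rates = c(0.2, 0.4),
                              optimizers = c("adam", "sgd"))
  specs <- enumerate_grid(grid)
  expect_identical(nrow(specs), 968L)
  # oracle: brute-force nested loop count
  cnt <- 0L
  for (s in grid$structures) for (lr in grid$learning_rates)
    for (dr in grid$dropout_rates) for (op in grid$optimizers) cnt <- cnt + 1L
  expect_identical(nrow(specs), cnt)
  g1 <- hyperparameter_grid(structures[1], 1e-3, 0.2, "adam")
  expect_identical(nrow(enumerate_grid(g1)), 1L)
  expect_identical(enumerate_grid(g1)$config[[1]]$dropout_rate, 0.2)
})

test_that("one small optimization step decreases a single example's loss", {
  model <- build_cnn(tiny_cfg(), seed = 3)
  img <- separable_frames(1)$images[[1]]
  y <- 1L
  b <- sonosex:::images_to_batch(list(img), 16L)
  loss_of <- function(m) {
    p <- sonosex:::nn_forward(m, b$X, b$n, training = FALSE)$prob
    -(y * log(p) + (1 - y) * log(1 - p))
  }
  fwd <- sonosex:::nn_forward(model, b$X, b$n, training = TRUE,
                              dropout_seed = 1, keep_cache = TRUE)
  bwd <- sonosex:::nn_backward(model, fwd, y)
  cfg <- train_config(optimizer = "sgd", learning_rate = 1e-3)
  st <- sonosex:::new_optimizer_state(model, "sgd")
  st$t <- 1L
  upd <- sonosex:::apply_gradients(model, bwd$grads, st, cfg)
  expect_lt(loss_of(upd$model), loss_of(model))
})

test_that("training drives a separable problem to perfect accuracy, reproducibly", {
  d <- separable_frames(8)
  model <- build_cnn(tiny_cfg(head = 8L), seed = 4)
  cfg <- train_config(batch_size = 4, learning_rate = 3e-3, max_epochs = 40,
                      monitor_start_epoch = 40, patience = 100, seed = 5)
  fit <- train_model(model, d$images, d$labels, d$images, d$labels, cfg)
  expect_identical(mean(predict(fit$model, d$images)$label == d$labels), 1)
  fit2 <- train_model(build_cnn(tiny_cfg(head = 8L), seed = 4),
                      d$images, d$labels, d$images, d$labels, cfg)
  expect_equal(fit$history$val_loss, fit2$history$val_loss, tolerance = 1e-6)
})

test_that("early stopping fires after `patience` unimproved epochs", {
  d <- separable_frames(3)
  model <- build_cnn(tiny_cfg(), seed = 6)
  # learning rate below double-precision resolution: weights never change,
  # so the validation loss is exactly constant across epochs
  cfg <- train_config(optimizer = "sgd", learning_rate = 1e-25,
                      max_epochs = 50, monitor_start_epoch = 0, patience = 1,
                      seed = 1)
  fit <- train_model(model, d$images, d$labels, d$images, d$labels, cfg)
  expect_identical(fit$stopped_epoch, 2L)
  expect_identical(nrow(fit$history), 2L)
})

test_that("no checkpoint is taken above the validation-loss gate", {
  d <- separable_frames(3)
  model <- build_cnn(tiny_cfg(), seed = 7)
  cfg <- train_config(optimizer = "sgd", learning_rate = 1e-25,
                      max_epochs = 3, monitor_start_epoch = 10,
                      checkpoint_gate = 0.1, seed = 1)
  fit <- train_model(model, d$images, d$labels, d$images, d$labels, cfg)
  expect_false(fit$gate_passed)
  expect_true(all(fit$history$val_loss > 0.1))
  expect_true(is.na(fit$best_epoch))
})

test_that("warm starts require an exactly matching architecture", {
  d <- separable_frames(3)
  donor <- build_cnn(tiny_cfg(), seed = 8)
  model <- build_cnn(tiny_cfg(), seed = 9)
  cfg <- train_config(max_epochs = 1, monitor_start_epoch = 5, seed = 1,
                      warm_start = donor)
  fit <- train_model(model, d$images, d$labels, d$images, d$labels, cfg)
  expect_s3_class(fit, "cnn_fit")
  other <- build_cnn(tiny_cfg(schedule = c(8L, 2L)), seed = 8)
  cfg_bad <- train_config(max_epochs = 1, seed = 1, warm_start = other)
  expect_error(train_model(model, d$images, d$labels, d$images, d$labels,
                           cfg_bad), "architecture")
})

test_that("reverse family matches forward on the speckle benchmark (5 seeds)", {
  pp <- population_params(sex_effect = 2, speckle_shape = 3,
                          band_thickness_delta = 0.005, band_echo_delta = 16,
                          band_texture_delta = 4)
  man <- generate_dataset(n_per_sex = 10, frames_range = c(4L, 5L),
                          params = pp, seed = 31)
  pm <- preprocess_manifest(man)
  accs <- list()
  for (s in 1:5) {
    a <- assign_splits(roster_from_manifest(pm), n_val_per_sex = 2,
                       n_test_per_sex = 2, seed = s)
    fr <- apply_splits(pm, a)
    tr <- dplyr::filter(fr, split == "train")
    va <- dplyr::filter(fr, split == "val")
    te <- dplyr::filter(fr, split == "test")
    for (fam in c("reverse", "forward")) {
      head_w <- if (fam == "reverse") 64L else 32L  # matched parameter budgets
      model <- build_cnn(cnn_config(family = fam, size_variant = "S",
                                    width_scale = 1 / 16, input_size = 64L,
                                    dropout_rate = 0.2, dense_head = head_w),
                         seed = s)
      fit <- train_model(model, tr$image, tr$sex, va$image, va$sex,
                         cfg = train_config(max_epochs = 20,
                                            monitor_start_epoch = 8,
                                            patience = 6, batch_size = 16,
                                            seed = s))
      accs[[paste(fam, s)]] <- mean(predict(fit$model, te$image)$label == te$sex)
    }
  }
  rev_mean <- mean(unlist(accs[paste("reverse", 1:5)]))
  fwd_mean <- mean(unlist(accs[paste("forward", 1:5)]))
  expect_gte(rev_mean, fwd_mean - 0.02)
})
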