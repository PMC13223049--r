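# Minibatch CNN engine. A batch of N single-channel images is stored as an
# (N*H*W) x C activation matrix (row of image n, pixel (r, c) = n*H*W +
# r*W + c, 0-based); 3x3 convolutions run as im2col (Rcpp) followed by a
# BLAS matrix product, pooling and the im2col adjoint also live in src/.

images_to_batch <- function(images, input_size) {
  if (is.matrix(images)) images <- list(images)
  n <- length(images)
  rows <- lapply(images, function(img) {
    assert_image(img)
    if (nrow(img) != input_size || ncol(img) != input_size) {
      img <- resize_bilinear(img, input_size, input_size)
    }
    as.vector(t(img)) / 255
  })
  list(X = matrix(unlist(rows), ncol = 1L), n = n)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. Returns the sigmoid probabilities plus (optionally) every
# cache needed for the backward pass; with keep_activations = TRUE the
# post-ReLU output of every convolution is retained for activation maps.
nn_forward <- function(model, X, n, training = FALSE, dropout_seed = NULL,
                       keep_cache = FALSE, keep_activations = FALSE) {
  cfg <- model$config
  h <- cfg$input_size; w <- cfg$input_size
  act <- X
  caches <- list()
  activations <- list()
  li <- 0L
  for (b in seq_along(cfg$schedule)) {
    for (j in seq_len(cfg$convs_per_block)) {
      li <- li + 1L
      layer <- model$conv[[li]]
      cols <- im2col3(act, n, h, w)
      pre <- sweep(cols %*% layer$W, 2, layer$b, "+")
      out <- pre * (pre > 0)
      if (keep_cache) {
        caches[[paste0("conv", li)]] <- list(cols = cols, mask = pre > 0, h = h, w = w,
                             c_in = layer$c_in)
      }
      if (keep_activations) {
        activations[[li]] <- list(values = out, h = h, w = w)
      }
      act <- out
    }
    pool <- maxpool2(act, n, h, w)
    act <- pool$values
    if (keep_cache) {
      caches[[paste0("pool", b)]] <- list(argmax = pool$argmax,
                                          n_in = n * h * w)
    }
    h <- h %/% 2L; w <- w %/% 2L
  }
  # single dropout stage at the end of the conv stack, before flattening
  drop_mask <- NULL
  if (training && cfg$dropout_rate > 0) {
    drop_mask <- withr::with_seed(dropout_seed %||% 1L, {
      matrix(rbinom(length(act), 1, 1 - cfg$dropout_rate), nrow(act), ncol(act))
    }) / (1 - cfg$dropout_rate)
    act <- act * drop_mask
  }
  hw <- h * w
  flat <- t(vapply(seq_len(n), function(i) {
    as.vector(act[(i - 1L) * hw + seq_len(hw), , drop = FALSE])
  }, numeric(hw * ncol(act))))
  z <- flat
  dense_caches <- list()
  nd <- length(model$dense)
  for (d in seq_len(nd)) {
    layer <- model$dense[[d]]
    pre <- sweep(z %*% layer$W, 2, layer$b, "+")
    if (d < nd) {
      out <- pre * (pre > 0)
      if (keep_cache) dense_caches[[d]] <- list(input = z, mask = pre > 0)
      z <- out
    } else {
      if (keep_cache) dense_caches[[d]] <- list(input = z)
      z <- pre
    }
  }
  logits <- drop(z)
  list(prob = sigmoid(logits), logits = logits, caches = caches,
       dense_caches = dense_caches, drop_mask = drop_mask,
       flat_dims = c(h = h, w = w, c = ncol(act)), n = n,
       activations = activations)
}

# Backward pass of binary cross-entropy through the whole net.
# Returns mean loss and gradients shaped like the parameters.
nn_backward <- function(model, fwd, y01) {
  cfg <- model$config
  n <- fwd$n
  p <- fwd$prob
  eps <- 1e-12
  loss <- -mean(y01 * log(p + eps) + (1 - y01) * log(1 - p + eps))
  dlogit <- matrix((p - y01) / n, ncol = 1L)

  grads <- list(conv = vector("list", length(model$conv)),
                dense = vector("list", length(model$dense)))
  dz <- dlogit
  for (d in rev(seq_along(model$dense))) {
    cache <- fwd$dense_caches[[d]]
    if (d < length(model$dense)) dz <- dz * cache$mask
    grads$dense[[d]] <- list(W = crossprod(cache$input, dz), b = colSums(dz))
    dz <- dz %*% t(model$dense[[d]]$W)
  }
  # unflatten: rows of image i are the i-th row of dz reshaped (hw x C)
  h <- fwd$flat_dims["h"]; w <- fwd$flat_dims["w"]; cc <- fwd$flat_dims["c"]
  hw <- h * w
  dact <- matrix(0, n * hw, cc)
  for (i in seq_len(n)) {
    dact[(i - 1L) * hw + seq_len(hw), ] <- matrix(dz[i, ], hw, cc)
  }
  if (!is.null(fwd$drop_mask)) dact <- dact * fwd$drop_mask

  li <- length(model$conv)
  for (b in rev(seq_along(cfg$schedule))) {
    pool <- fwd$caches[[paste0("pool", b)]]
    dact <- maxpool2_backward(dact, pool$argmax, pool$n_in)
    for (j in rev(seq_len(cfg$convs_per_block))) {
      cache <- fwd$caches[[paste0("conv", li)]]
      dpre <- dact * cache$mask
      grads$conv[[li]] <- list(W = crossprod(cache$cols, dpre),
                               b = colSums(dpre))
      if (li > 1L || TRUE) {
        dcols <- dpre %*% t(model$conv[[li]]$W)
        dact <- col2im3(dcols, n, cache$h, cache$w, cache$c_in)
      }
      li <- li - 1L
    }
  }
  list(loss = loss, grads = grads)
}

new_optimizer_state <- function(model, optimizer) {
  zero_like <- function(l) list(W = l$W * 0, b = l$b * 0)
  st <- list(
    m = list(conv = lapply(model$conv, zero_like),
             dense = lapply(model$dense, zero_like)),
    t = 0L
  )
  if (optimizer == "adam") {
    st$v <- st$m
  }
  st
}

apply_gradients <- function(model, grads, state, cfg) {
  lr <- cfg$learning_rate
  upd <- function(kind, i, field) {
    g <- grads[[kind]][[i]][[field]]
    if (cfg$optimizer == "sgd") {
      m <- 0.9 * state$m[[kind]][[i]][[field]] + g
      state$m[[kind]][[i]][[field]] <<- m
      model[[if (kind == "conv") "conv" else "dense"]][[i]][[field]] <<-
        model[[if (kind == "conv") "conv" else "dense"]][[i]][[field]] - lr * m
    } else {
      m <- 0.9 * state$m[[kind]][[i]][[field]] + 0.1 * g
      v <- 0.999 * state$v[[kind]][[i]][[field]] + 0.001 * g^2
      state$m[[kind]][[i]][[field]] <<- m
      state$v[[kind]][[i]][[field]] <<- v
      mh <- m / (1 - 0.9^state$t)
      vh <- v / (1 - 0.999^state$t)
      model[[if (kind == "conv") "conv" else "dense"]][[i]][[field]] <<-
        model[[if (kind == "conv") "conv" else "dense"]][[i]][[field]] -
        lr * mh / (sqrt(vh) + 1e-8)
    }
  }
  state$t <- state$t + 1L
  for (i in seq_along(model$conv)) { upd("conv", i, "W"); upd("conv", i, "b") }
  for (i in seq_along(model$dense)) { upd("dense", i, "W"); upd("dense", i, "b") }
  list(model = model, state = state)
}

nn_evaluate <- function(model, X, n, y01) {
  fwd <- nn_forward(model, X, n, training = FALSE)
  p <- fwd$prob
  eps <- 1e-12
  list(loss = -mean(y01 * log(p + eps) + (1 - y01) * log(1 - p + eps)),
       accuracy = mean((p >= 0.5) == (y01 == 1)))
}

#' Train a CNN with early stopping and gated checkpointing
#'
#' Minibatch training on binary cross-entropy over a single sigmoid
#' output. Per-epoch training and validation loss/accuracy are recorded;
#' the kept weights are those of the epoch with the lowest validation loss
#' among epochs whose loss is below `checkpoint_gate` (no checkpoint is
#' ever taken above the gate; if no epoch passes it, the final weights are
#' returned and flagged). Early stopping monitors validation loss from
#' `monitor_start_epoch`, with the configured patience. The whole run —
#' shuffling, dropout masks, augmentation — is driven by the config seed.
#'
#' @param model A [build_cnn()] model (or the architecture to warm-start
#'   from `cfg$warm_start`).
#' @param train_images,val_images Lists of grayscale matrices.
#' @param train_y,val_y Label vectors (`"F"`/`"M"`, or 0/1 with 1 = M).
#' @param cfg A [train_config()].
#' @param augment Optional train-time augmentation `function(image, seed)`.
#' @return List of class `cnn_fit`: `model` (best weights), `history`
#'   tibble, `best_epoch`, `best_val_loss`, `gate_passed`, `stopped_epoch`.
#' @export
train_model <- function(model, train_images, train_y, val_images, val_y,
                        cfg = train_config(), augment = NULL) {
  stopifnot(inherits(model, "cnn_model"), inherits(cfg, "train_config"))
  if (length(train_images) == 0 || length(val_images) == 0) {
    abort("Empty training or validation partition.")
  }
  to01 <- function(y) {
    if (is.numeric(y)) y <- ifelse(y > 0, "M", "F")
    if (!all(y %in% c("F", "M"))) abort("Labels must be binary F/M.")
    as.integer(y == "M")
  }
  ytr <- to01(train_y); yva <- to01(val_y)
  if (length(unique(ytr)) < 2) abort("Training labels are single-class.")
  if (!is.null(cfg$warm_start)) {
    ws <- cfg$warm_start
    stopifnot(inherits(ws, "cnn_model"))
    if (!identical(ws$config$schedule, model$config$schedule) ||
        !identical(ws$config$convs_per_block, model$config$convs_per_block) ||
        !identical(ws$config$dense_head, model$config$dense_head) ||
        !identical(ws$config$input_size, model$config$input_size)) {
      abort("Warm-start architecture does not match the model.")
    }
    model$conv <- ws$conv
    model$dense <- ws$dense
  }
  size <- model$config$input_size
  val_batch <- images_to_batch(val_images, size)
  # resize once up front; augmentation then operates at network resolution
  train_images <- lapply(train_images, function(img) {
    if (nrow(img) == size && ncol(img) == size) img
    else resize_bilinear(img, size, size)
  })
  ntr <- length(train_images)
  state <- new_optimizer_state(model, cfg$optimizer)

  history <- list()
  best <- list(loss = Inf, epoch = NA_integer_, conv = NULL, dense = NULL)
  no_improve <- 0L
  stopped <- cfg$max_epochs
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- withr::with_seed(substream_seed(cfg$seed, "shuffle", epoch),
                            sample.int(ntr))
    ep_loss <- 0; ep_n <- 0; ep_correct <- 0
    for (start in seq(1L, ntr, by = cfg$batch_size)) {
      idx <- ord[seq(start, min(start + cfg$batch_size - 1L, ntr))]
      imgs <- lapply(seq_along(idx), function(j) {
        img <- train_images[[idx[j]]]
        if (is.null(augment)) img
        else augment(img, substream_seed(cfg$seed, "aug", epoch, idx[j]))
      })
      batch <- images_to_batch(imgs, size)
      fwd <- nn_forward(model, batch$X, batch$n, training = TRUE,
                        dropout_seed = substream_seed(cfg$seed, "drop", epoch, start),
                        keep_cache = TRUE)
      bwd <- nn_backward(model, fwd, ytr[idx])
      res <- apply_gradients(model, bwd$grads, state, cfg)
      model <- res$model; state <- res$state
      ep_loss <- ep_loss + bwd$loss * length(idx); ep_n <- ep_n + length(idx)
      ep_correct <- ep_correct + sum((fwd$prob >= 0.5) == (ytr[idx] == 1))
    }
    val <- nn_evaluate(model, val_batch$X, val_batch$n, yva)
    # train metrics are the running minibatch averages of the epoch
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = ep_loss / ep_n,
      train_accuracy = ep_correct / ep_n,
      val_loss = val$loss, val_accuracy = val$accuracy
    )
    if (val$loss < cfg$checkpoint_gate && val$loss < best$loss) {
      best <- list(loss = val$loss, epoch = epoch,
                   conv = model$conv, dense = model$dense)
    }
    if (epoch > cfg$monitor_start_epoch) {
      improved <- length(history) == 1 ||
        val$loss < min(vapply(history[-epoch], `[[`, 0, "val_loss"))
      if (improved) no_improve <- 0L else no_improve <- no_improve + 1L
      if (no_improve >= cfg$patience) { stopped <- epoch; break }
    }
  }
  gate_passed <- !is.null(best$conv)
  if (gate_passed) {
    model$conv <- best$conv
    model$dense <- best$dense
  }
  structure(list(
    model = model, history = bind_rows(history),
    best_epoch = if (gate_passed) best$epoch else NA_integer_,
    best_val_loss = if (gate_passed) best$loss else NA_real_,
    gate_passed = gate_passed, stopped_epoch = stopped
  ), class = "cnn_fit")
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit %d epochs | best val loss %s @ epoch %s | gate %s>\n",
              nrow(x$history),
              if (x$gate_passed) sprintf("%.4f", x$best_val_loss) else "-",
              if (x$gate_passed) x$best_epoch else "-",
              if (x$gate_passed) "passed" else "NOT passed"))
  invisible(x)
}

#' Tidy the per-epoch training history
#'
#' @param x A `cnn_fit`.
#' @param ... Unused.
#' @export
tidy.cnn_fit <- function(x, ...) x$history

#' @rdname tidy.cnn_fit
#' @export
glance.cnn_fit <- function(x, ...) {
  tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
         best_val_loss = x$best_val_loss, gate_passed = x$gate_passed,
         final_train_accuracy = x$history$train_accuracy[nrow(x$history)],
         final_val_accuracy = x$history$val_accuracy[nrow(x$history)])
}
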