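#' Configuration of a custom forward / reverse CNN
#'
#' The reverse ("double compression") family starts wide and narrows with
#' depth — canonical schedule 512, 256, 128, 64 — so that channel depth and
#' spatial resolution (one 2x2 max-pool per block) shrink together, forming
#' an aggressive information bottleneck. The forward family is its mirror
#' (increasing channels), the classical widening pattern. Size variants
#' S/M/L use 2/3/4 blocks, truncating the canonical schedule from the high
#' end (L uses all four values). Exactly one dropout stage sits at the end
#' of the convolutional stack, immediately before flattening.
#'
#' @param family `"reverse"` or `"forward"`.
#' @param size_variant `"S"`, `"M"` or `"L"` (2/3/4 blocks); ignored when
#'   `schedule` is given.
#' @param schedule Explicit per-block output channel counts; must be
#'   strictly decreasing for the reverse family, strictly increasing for
#'   forward.
#' @param convs_per_block 3x3 stride-1 convolutions per block (default 2).
#' @param input_size Input side length in pixels (default 64); must be
#'   divisible by `2^blocks`.
#' @param dropout_rate Dropout rate of the single pre-flatten dropout stage.
#' @param dense_head Widths of the fully connected layers before the single
#'   sigmoid output.
#' @param width_scale Multiplier on the canonical channel counts (desk-scale
#'   runs shrink the net without changing its shape).
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(family = c("reverse", "forward"),
                       size_variant = c("S", "M", "L"),
                       schedule = NULL, convs_per_block = 2L,
                       input_size = 64L, dropout_rate = 0.3,
                       dense_head = 64L, width_scale = 1) {
  family <- match.arg(family)
  size_variant <- match.arg(size_variant)
  canonical <- c(512L, 256L, 128L, 64L)
  if (is.null(schedule)) {
    blocks <- c(S = 2L, M = 3L, L = 4L)[[size_variant]]
    schedule <- utils::tail(canonical, blocks)
    if (family == "forward") schedule <- rev(schedule)
    schedule <- pmax(1L, as.integer(round(schedule * width_scale)))
  }
  schedule <- as.integer(schedule)
  d <- diff(schedule)
  if (family == "reverse" && (length(d) > 0 && any(d >= 0))) {
    abort("Reverse-family schedules must be strictly decreasing.")
  }
  if (family == "forward" && (length(d) > 0 && any(d <= 0))) {
    abort("Forward-family schedules must be strictly increasing.")
  }
  blocks <- length(schedule)
  if (input_size %% 2^blocks != 0) {
    abort(sprintf("input_size %d is not divisible by 2^%d.", input_size, blocks))
  }
  structure(list(
    family = family, size_variant = size_variant, schedule = schedule,
    convs_per_block = as.integer(convs_per_block),
    input_size = as.integer(input_size), dropout_rate = dropout_rate,
    dense_head = as.integer(dense_head), width_scale = width_scale
  ), class = "cnn_config")
}

#' Build an executable CNN from a configuration
#'
#' Initializes all parameters (He-scaled Gaussian conv/dense weights, zero
#' biases) deterministically under `seed`. Block structure, per-block
#' channel counts, dropout placement and the scalar sigmoid output are all
#' introspectable from the returned object; the parameter count is a
#' deterministic function of the configuration.
#'
#' @param config A [cnn_config()].
#' @param seed Integer seed for initialization.
#' @return An object of class `cnn_model`.
#' @export
build_cnn <- function(config, seed = 1L) {
  stopifnot(inherits(config, "cnn_config"))
  withr::with_seed(substream_seed(seed, "init", config$family,
                                  length(config$schedule)), {
    conv <- list()
    c_in <- 1L
    for (b in seq_along(config$schedule)) {
      c_out <- config$schedule[b]
      for (j in seq_len(config$convs_per_block)) {
        fan_in <- 9L * c_in
        conv[[length(conv) + 1L]] <- list(
          W = matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out),
          b = numeric(c_out), block = b, c_in = c_in, c_out = c_out
        )
        c_in <- c_out
      }
    }
    s <- config$input_size / 2^length(config$schedule)
    flat <- as.integer(s * s * c_in)
    widths <- c(flat, config$dense_head, 1L)
    dense <- lapply(seq_len(length(widths) - 1L), function(i) {
      list(W = matrix(rnorm(widths[i] * widths[i + 1], 0, sqrt(2 / widths[i])),
                      widths[i], widths[i + 1]),
           b = numeric(widths[i + 1]))
    })
    structure(list(config = config, conv = conv, dense = dense,
                   flat_dim = flat, pre_flatten_spatial = as.integer(s)),
              class = "cnn_model")
  })
}

#' Introspect a CNN's per-block channel schedule
#'
#' Reads the output channel counts back from the built convolution
#' parameters (not from the config), one entry per block.
#'
#' @param model A `cnn_model`.
#' @return Integer vector of per-block output channels.
#' @export
channel_schedule <- function(model) {
  stopifnot(inherits(model, "cnn_model"))
  blocks <- vapply(model$conv, `[[`, 0L, "block")
  vapply(split(model$conv, blocks), function(ls) ls[[length(ls)]]$c_out, 0L)
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(
    "<cnn_model %s-%s | blocks %s | %d convs/block | input %d | dropout %.2f before flatten | %s params>\n",
    x$config$family, x$config$size_variant,
    paste(channel_schedule(x), collapse = "-"), x$config$convs_per_block,
    x$config$input_size, x$config$dropout_rate,
    format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters of a CNN
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(c(model$conv, model$dense),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

#' Training configuration for the CNN families
#'
#' Early stopping monitors validation loss: monitoring begins after
#' `monitor_start_epoch` epochs and training stops when the loss has not
#' improved for `patience` monitored epochs (or at `max_epochs`).
#' Checkpoints are gated: the best epoch is the one with the lowest
#' validation loss among epochs where that loss is below
#' `checkpoint_gate`; no checkpoint is ever written above the gate.
#'
#' @param batch_size Minibatch size.
#' @param optimizer `"adam"` (adaptive moment estimation) or `"sgd"`
#'   (stochastic gradient descent with momentum 0.9).
#' @param learning_rate Positive step size.
#' @param max_epochs Maximum epochs.
#' @param monitor_start_epoch Epoch after which early-stop monitoring
#'   begins (default 100).
#' @param patience Monitored epochs without improvement before stopping
#'   (default 500).
#' @param checkpoint_gate Validation-loss quality gate (default 0.70).
#' @param seed Integer seed covering shuffling, dropout and augmentation.
#' @param warm_start Optional `cnn_model` whose weights initialize this
#'   run (transfer learning); architectures must match exactly.
#' @return A list of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, optimizer = c("adam", "sgd"),
                         learning_rate = 1e-3, max_epochs = 300L,
                         monitor_start_epoch = 100L, patience = 500L,
                         checkpoint_gate = 0.70, seed = 1L,
                         warm_start = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(batch_size >= 1, learning_rate > 0, max_epochs >= 1,
            monitor_start_epoch >= 0, patience >= 1)
  structure(list(batch_size = as.integer(batch_size), optimizer = optimizer,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 monitor_start_epoch = as.integer(monitor_start_epoch),
                 patience = as.integer(patience),
                 checkpoint_gate = checkpoint_gate, seed = as.integer(seed),
                 warm_start = warm_start),
            class = "train_config")
}

#' Hyperparameter grid over CNN structures
#'
#' Cartesian product of model structures with per-structure training
#' combinations (learning rates x dropout rates x optimizers); the number
#' of specs is `|structures| * |combinations|`, e.g. 22 structures x 44
#' combinations = 968 models.
#'
#' @param structures List of [cnn_config()] objects.
#' @param learning_rates,dropout_rates,optimizers Vectors of candidate
#'   values.
#' @return `hyperparameter_grid()`: a list of class `hyperparameter_grid`;
#'   `enumerate_grid()`: a tibble with one row per (structure,
#'   combination) pair in deterministic order, carrying the `cnn_config`
#'   in a list-column.
#' @export
hyperparameter_grid <- function(structures, learning_rates = c(1e-3, 1e-4),
                                dropout_rates = c(0.2, 0.4),
                                optimizers = c("adam", "sgd")) {
  stopifnot(length(structures) >= 1)
  structure(list(structures = structures, learning_rates = learning_rates,
                 dropout_rates = dropout_rates, optimizers = optimizers),
            class = "hyperparameter_grid")
}

#' @rdname hyperparameter_grid
#' @param grid A `hyperparameter_grid`.
#' @export
enumerate_grid <- function(grid) {
  stopifnot(inherits(grid, "hyperparameter_grid"))
  combos <- tidyr::expand_grid(
    structure_id = seq_along(grid$structures),
    learning_rate = grid$learning_rates,
    dropout_rate = grid$dropout_rates,
    optimizer = grid$optimizers
  )
  combos$config <- lapply(seq_len(nrow(combos)), function(i) {
    cfg <- grid$structures[[combos$structure_id[i]]]
    cfg$dropout_rate <- combos$dropout_rate[i]
    cfg
  })
  combos
}

#' Predict sex labels with a CNN
#'
#' @param object A `cnn_model` (trained or freshly built).
#' @param images List of grayscale matrices; resized to the model's input
#'   size as needed.
#' @param threshold Decision threshold on the sigmoid score: label M iff
#'   score >= threshold (so a zero-weight model, scoring exactly 0.5
#'   everywhere, labels M at the default threshold).
#' @param ... Unused.
#' @return Tibble with `score` (sigmoid output) and `label`.
#' @export
predict.cnn_model <- function(object, images, threshold = 0.5, ...) {
  x <- images_to_batch(images, object$config$input_size)
  p <- nn_forward(object, x$X, x$n, training = FALSE)$prob
  tibble(score = p, label = ifelse(p >= threshold, "M", "F"))
}
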