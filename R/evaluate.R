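#' Confusion matrix for binary sex labels
#'
#' Rows are ground truth (F, M), columns predicted (F, M); cells are raw
#' counts.
#'
#' @param truth,predicted Label vectors over \{F, M\}, equal length.
#' @return A 2x2 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!all(c(truth, predicted) %in% c("F", "M"))) {
    abort("Labels must be 'F' or 'M'.")
  }
  cm <- table(factor(truth, c("F", "M")), factor(predicted, c("F", "M")))
  out <- matrix(as.integer(cm), 2, 2,
                dimnames = list(truth = c("F", "M"), predicted = c("F", "M")))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' Accuracy and per-class precision/recall/F1 from a confusion matrix
#'
#' Accuracy is the diagonal sum over the total; per-class recall is the
#' diagonal cell over its row sum, precision over its column sum, F1 their
#' harmonic mean. Ratios with a zero denominator are reported as `NaN` and
#' flagged in `undefined`, never silently zeroed.
#'
#' @param cm A [confusion()] matrix.
#' @param split Optional split name carried into the report.
#' @return A list of class `eval_report`: `split`, `confusion`, `accuracy`,
#'   `per_class` tibble, `undefined` (character vector of metric names that
#'   were undefined).
#' @export
metrics_from_confusion <- function(cm, split = NA_character_) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  if (total == 0) abort("Empty confusion matrix.")
  classes <- rownames(cm)
  per <- lapply(classes, function(cl) {
    tp <- cm[cl, cl]
    rec <- tp / sum(cm[cl, ])
    prec <- tp / sum(cm[, cl])
    f1 <- 2 * prec * rec / (prec + rec)
    tibble(class = cl, precision = prec, recall = rec, f1 = f1)
  })
  per <- bind_rows(per)
  undefined <- c(
    paste0("precision_", per$class[is.nan(per$precision)]),
    paste0("recall_", per$class[is.nan(per$recall)]),
    paste0("f1_", per$class[is.nan(per$f1)])
  )
  structure(list(
    split = split, confusion = cm,
    accuracy = sum(diag(cm)) / total,
    per_class = per, undefined = undefined
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report%s accuracy %.3f>\n",
              if (is.na(x$split)) "" else paste0(" [", x$split, "]"),
              x$accuracy))
  print(unclass(x$confusion))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `eval_report`.
#' @param ... Unused.
#' @return Per-class metric tibble.
#' @export
tidy.eval_report <- function(x, ...) x$per_class

#' @rdname tidy.eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble(split = x$split, accuracy = x$accuracy, n = sum(x$confusion),
         n_undefined = length(x$undefined))
}

#' Evaluate predictions on a split
#'
#' @param truth,predicted Label vectors.
#' @param split Split name.
#' @return An `eval_report`.
#' @export
evaluate_split <- function(truth, predicted, split = NA_character_) {
  metrics_from_confusion(confusion(truth, predicted), split = split)
}

#' Leakage-inflation experiment
#'
#' Quantifies how much apparent accuracy is inflated when correlated frames
#' of the same animal cross partitions. For each seed, twin classifiers are
#' trained on (i) a frame-level random split, which lets an individual's
#' near-duplicate frames land on both sides, and (ii) an individual-level
#' split of matched holdout size; each is evaluated on its own held-out
#' frames. The default classifier is the package's PCA + logistic baseline
#' on a small fixed grid.
#'
#' @param manifest Manifest with an `image` list-column or readable paths.
#' @param n_seeds Number of replicate splits.
#' @param holdout_frac Fraction of frames (or individuals) held out.
#' @param fit_fun `function(train_images, train_y, seed)` returning a
#'   `function(images)` that predicts labels; defaults to the baseline.
#' @param seed Master seed.
#' @return List with `runs` (per seed and strategy: holdout accuracy,
#'   leaked individual count) and `summary` (per strategy mean accuracy
#'   and the inflation gap).
#' @export
leakage_inflation_experiment <- function(manifest, n_seeds = 5,
                                         holdout_frac = 0.2,
                                         fit_fun = NULL, seed = 1L) {
  key <- individual_key(manifest)
  if (max(table(key)) < 2) {
    warning("Fewer than 2 frames per individual: strategies are equivalent.")
  }
  images <- manifest_images(manifest)
  labels <- manifest$sex
  fit_fun <- fit_fun %||% baseline_fit_fun
  n <- nrow(manifest)

  one_run <- function(s, strategy) {
    hold <- withr::with_seed(substream_seed(seed, "leak", s, strategy), {
      if (strategy == "frame") {
        sample.int(n, max(1L, round(holdout_frac * n)))
      } else {
        inds <- unique(key)
        hold_ind <- sample(inds, max(1L, round(holdout_frac * length(inds))))
        which(key %in% hold_ind)
      }
    })
    train <- setdiff(seq_len(n), hold)
    leaked <- length(intersect(unique(key[train]), unique(key[hold])))
    predict_fn <- fit_fun(images[train], labels[train],
                          substream_seed(seed, "leakfit", s, strategy))
    acc <- mean(predict_fn(images[hold]) == labels[hold])
    tibble(seed_rep = s, strategy = strategy, holdout_accuracy = acc,
           n_leaked_individuals = leaked, n_holdout = length(hold))
  }
  runs <- bind_rows(lapply(seq_len(n_seeds), function(s) {
    bind_rows(one_run(s, "frame"), one_run(s, "individual"))
  }))
  summary <- runs |>
    group_by(.data$strategy) |>
    summarise(mean_accuracy = mean(.data$holdout_accuracy), .groups = "drop")
  gap <- summary$mean_accuracy[summary$strategy == "frame"] -
    summary$mean_accuracy[summary$strategy == "individual"]
  list(runs = runs, summary = summary, inflation_gap = gap)
}

# Default leakage-experiment classifier: flatten -> standardize -> PCA ->
# ridge logistic, trained at a single small grid point for speed.
baseline_fit_fun <- function(train_images, train_y, seed) {
  x <- flatten_features(train_images, size = 32)
  st <- fit_standardizer(x)
  xs <- apply_standardizer(x, st)
  k <- min(30L, nrow(xs) - 1L)
  pca <- fit_pca(xs, k)
  z <- project_pca(xs, pca)
  fit <- fit_logistic_newton(z, as.integer(train_y == "M"), C = 1,
                             weights = class_weights(train_y))
  function(images) {
    z_new <- project_pca(
      apply_standardizer(flatten_features(images, size = 32), st), pca)
    ifelse(predict_logistic(fit, z_new) >= 0.5, "M", "F")
  }
}
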