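#' Flatten images into a feature matrix
#'
#' Resizes each grayscale frame to `size` x `size` with bilinear
#' interpolation and flattens it row-major, so the default 64 x 64 yields a
#' 4,096-dimensional feature vector per image.
#'
#' @param images List of numeric matrices (0-255).
#' @param size Target side length (default 64).
#' @return An `n x size^2` numeric matrix, rows in input order.
#' @export
flatten_features <- function(images, size = 64L) {
  if (length(images) == 0) abort("`images` is empty.")
  t(vapply(images, function(img) {
    assert_image(img)
    if (nrow(img) != size || ncol(img) != size) {
      img <- resize_bilinear(img, size, size)
    }
    as.vector(t(img))
  }, numeric(size * size)))
}

#' Hyperparameter grid for the linear baseline
#'
#' The default grid crosses 13 regularization strengths, two penalties, two
#' solver variants and seven PCA dimensionalities: 13 x 2 x 2 x 7 = 364
#' candidates. The `newton` (ridge-IRLS) solver supports only the L2
#' penalty; `coordinate` (glmnet coordinate descent) supports both. Invalid
#' penalty/solver pairs are enumerated but skipped during search.
#'
#' @param C_values Inverse regularization strengths.
#' @param penalties Subset of `c("l1", "l2")`.
#' @param solvers Subset of `c("coordinate", "newton")`.
#' @param pca_components Candidate numbers of retained components.
#' @return A list of class `grid_spec`.
#' @export
grid_spec <- function(C_values = c(0.001, 0.01, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 50, 100),
                      penalties = c("l1", "l2"),
                      solvers = c("coordinate", "newton"),
                      pca_components = c(5, 10, 20, 30, 50, 75, 100)) {
  stopifnot(all(C_values > 0), all(pca_components >= 1),
            all(penalties %in% c("l1", "l2")),
            all(solvers %in% c("coordinate", "newton")))
  structure(list(C_values = C_values, penalties = penalties,
                 solvers = solvers, pca_components = as.integer(pca_components)),
            class = "grid_spec")
}

#' @rdname grid_spec
#' @param grid A `grid_spec`.
#' @return `enumerate_baseline_grid()`: a tibble of all candidates with a
#'   `valid` flag.
#' @export
enumerate_baseline_grid <- function(grid = grid_spec()) {
  g <- tidyr::expand_grid(
    k = grid$pca_components, C = grid$C_values,
    penalty = grid$penalties, solver = grid$solvers
  )
  mutate(g, valid = !(.data$solver == "newton" & .data$penalty == "l1"))
}

fit_standardizer <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  list(mean = mu, scale = s)
}

apply_standardizer <- function(x, st) {
  sweep(sweep(x, 2, st$mean, "-"), 2, st$scale, "/")
}

#' Principal component analysis of standardized features
#'
#' Thin wrapper over [stats::prcomp()] that keeps the orthonormal basis and
#' the explained-variance curve; `k` larger than the matrix rank is reduced
#' with a warning.
#'
#' @param x Standardized feature matrix (observations x features).
#' @param k Number of components to retain.
#' @return List of class `pca_basis`: `basis` (features x k),
#'   `explained_variance_ratio`, `cumulative_variance`, `k`.
#' @export
fit_pca <- function(x, k) {
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (k > rank_max) {
    warning(sprintf("k = %d exceeds the matrix rank; reduced to %d.", k, rank_max))
    k <- rank_max
  }
  p <- prcomp(x, center = FALSE, scale. = FALSE)
  evr <- p$sdev^2 / sum(p$sdev^2)
  structure(list(
    basis = p$rotation[, seq_len(k), drop = FALSE],
    explained_variance_ratio = evr[seq_len(k)],
    cumulative_variance = cumsum(evr),
    k = k
  ), class = "pca_basis")
}

project_pca <- function(x, pca, k = pca$k) {
  x %*% pca$basis[, seq_len(k), drop = FALSE]
}

#' Balanced accuracy
#'
#' The mean of per-class recalls; robust to class imbalance and degenerate
#' majority-class predictors (an all-one-class predictor scores 0.5 on a
#' two-class problem).
#'
#' @param truth,predicted Label vectors of equal length.
#' @return A fraction in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  classes <- sort(unique(truth))
  if (length(classes) < 2) {
    abort("Balanced accuracy needs every class present in `truth`.")
  }
  mean(vapply(classes, function(cl) {
    mean(predicted[truth == cl] == cl)
  }, numeric(1)))
}

# Inverse class-frequency weights: class c gets n / (n_classes * n_c).
class_weights <- function(y) {
  tab <- table(y)
  w <- length(y) / (length(tab) * tab)
  as.numeric(w[as.character(y)])
}

# glmnet coordinate-descent logistic fit at a single lambda. sklearn-style
# C maps to lambda = 1 / (C * n) (glmnet scales the loss by 1/n).
fit_logistic_coordinate <- function(x, y01, C, penalty, weights) {
  fit <- glmnet::glmnet(
    x, factor(y01), family = "binomial",
    alpha = if (penalty == "l1") 1 else 0,
    lambda = 1 / (C * length(y01)), weights = weights,
    standardize = FALSE, thresh = 1e-9, maxit = 1e6
  )
  list(beta = as.numeric(fit$beta), intercept = as.numeric(fit$a0))
}

# Ridge-penalized IRLS (Newton) logistic fit; L2 only, intercept
# unpenalized. Convergence tol 1e-4 on the coefficient step, 5000 max
# iterations.
fit_logistic_newton <- function(x, y01, C, weights, tol = 1e-4, max_iter = 5000) {
  xb <- cbind(1, x)
  p <- ncol(xb)
  pen <- diag(c(0, rep(1 / C, p - 1L)))
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xb %*% beta)
    mu <- 1 / (1 + exp(-eta))
    wts <- weights * pmax(mu * (1 - mu), 1e-10)
    g <- drop(crossprod(xb, weights * (y01 - mu))) - pen %*% beta
    hess <- crossprod(xb * wts, xb) + pen
    step <- solve(hess, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(beta = beta[-1], intercept = beta[1])
}

predict_logistic <- function(fit, x) {
  1 / (1 + exp(-(drop(x %*% fit$beta) + fit$intercept)))
}

#' Grid search for the PCA + logistic-regression baseline
#'
#' Standardizes features with training-set statistics only, fits one PCA on
#' the training matrix (components are nested, so each candidate `k` reuses
#' its leading columns), then exhaustively evaluates the candidate grid
#' with inverse class-frequency loss weights, selecting the configuration
#' with the highest validation balanced accuracy. Ties are broken toward
#' parsimony: smaller `k`, then smaller `C`, then L2 before L1. The test
#' partition is never touched.
#'
#' @param train_x,val_x Feature matrices (e.g. from [flatten_features()]).
#' @param train_y,val_y Label vectors (`"F"`/`"M"`).
#' @param grid A [grid_spec()].
#' @param seed Integer seed (stochastic solver variants are seeded).
#' @return An object of class `baseline_model` with the fitted
#'   standardizer, PCA basis, classifier, chosen hyperparameters,
#'   validation balanced accuracy, and the full grid results.
#' @export
grid_search_baseline <- function(train_x, train_y, val_x, val_y,
                                 grid = grid_spec(), seed = 1L) {
  candidates <- enumerate_baseline_grid(grid)
  if (nrow(candidates) == 0) abort("Empty hyperparameter grid.")
  if (length(unique(train_y)) < 2) {
    abort("Training labels are single-class; cannot fit a classifier.")
  }
  st <- fit_standardizer(train_x)
  xtr <- apply_standardizer(train_x, st)
  xva <- apply_standardizer(val_x, st)
  k_max <- min(max(grid$pca_components), nrow(xtr) - 1L, ncol(xtr))
  pca <- fit_pca(xtr, k_max)
  ytr <- as.integer(train_y == "M")
  w <- class_weights(train_y)

  candidates$val_balanced_accuracy <- NA_real_
  fits <- vector("list", nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    if (!cand$valid) next
    k <- min(cand$k, pca$k)
    ztr <- project_pca(xtr, pca, k)
    zva <- project_pca(xva, pca, k)
    fit <- withr::with_seed(substream_seed(seed, "grid", i), {
      if (cand$solver == "newton") {
        fit_logistic_newton(ztr, ytr, cand$C, w)
      } else {
        fit_logistic_coordinate(ztr, ytr, cand$C, cand$penalty, w)
      }
    })
    pred <- ifelse(predict_logistic(fit, zva) >= 0.5, "M", "F")
    candidates$val_balanced_accuracy[i] <- balanced_accuracy(val_y, pred)
    fits[[i]] <- fit
  }
  scored <- candidates |>
    mutate(.row = dplyr::row_number()) |>
    filter(.data$valid, !is.na(.data$val_balanced_accuracy)) |>
    arrange(dplyr::desc(.data$val_balanced_accuracy), .data$k, .data$C,
            dplyr::desc(.data$penalty), .data$solver)
  best <- scored[1, ]
  structure(list(
    standardizer = st,
    pca = pca,
    classifier = fits[[best$.row]],
    chosen = as.list(select(best, "k", "C", "penalty", "solver")),
    val_balanced_accuracy = best$val_balanced_accuracy,
    grid_results = select(candidates, -dplyr::any_of(".row")),
    levels = c("F", "M"),
    seed = as.integer(seed)
  ), class = "baseline_model")
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf(
    "<baseline_model k=%d C=%g penalty=%s solver=%s | val balanced accuracy %.3f>\n",
    x$chosen$k, x$chosen$C, x$chosen$penalty, x$chosen$solver,
    x$val_balanced_accuracy))
  invisible(x)
}

#' Predict sex labels with a fitted baseline model
#'
#' @param object A `baseline_model`.
#' @param newdata Feature matrix or list of images (flattened with the
#'   model's input size).
#' @param type `"class"` or `"prob"` (probability of class M).
#' @param threshold Decision threshold on P(M) (default 0.5; at exactly
#'   0.5 the label is M).
#' @param ... Unused.
#' @export
predict.baseline_model <- function(object, newdata, type = c("class", "prob"),
                                   threshold = 0.5, ...) {
  type <- match.arg(type)
  if (is.list(newdata) && !is.matrix(newdata)) {
    newdata <- flatten_features(newdata, size = sqrt(length(object$standardizer$mean)))
  }
  z <- project_pca(apply_standardizer(newdata, object$standardizer),
                   object$pca, object$chosen$k)
  p <- predict_logistic(object$classifier, z)
  if (type == "prob") return(p)
  ifelse(p >= threshold, "M", "F")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the baseline grid-search results
#'
#' @param x A `baseline_model`.
#' @param ... Unused.
#' @return One row per grid candidate with its validation balanced
#'   accuracy (`NA` for skipped invalid penalty/solver pairs).
#' @export
tidy.baseline_model <- function(x, ...) x$grid_results

#' @rdname tidy.baseline_model
#' @return `glance()`: a one-row summary of the selected configuration.
#' @export
glance.baseline_model <- function(x, ...) {
  tibble(k = x$chosen$k, C = x$chosen$C, penalty = x$chosen$penalty,
         solver = x$chosen$solver,
         val_balanced_accuracy = x$val_balanced_accuracy,
         n_candidates = nrow(x$grid_results),
         n_evaluated = sum(!is.na(x$grid_results$val_balanced_accuracy)))
}
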