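#' Individual roster of a manifest
#'
#' One row per unique individual identity key
#' (`individual_id`, `location`, `sex`, `size_class`).
#'
#' @param manifest Manifest tibble.
#' @return Tibble with `individual_key`, `sex` and `n_frames`.
#' @export
roster_from_manifest <- function(manifest) {
  manifest |>
    mutate(individual_key = individual_key(manifest)) |>
    group_by(.data$individual_key, .data$sex) |>
    summarise(n_frames = dplyr::n(), .groups = "drop")
}

#' Assign individuals to train/validation/test splits
#'
#' Draws `n_val_per_sex` then `n_test_per_sex` individuals of each sex
#' uniformly at random without replacement; the remainder goes to the
#' training split. Every individual lands in exactly one split, so no
#' animal's frames can cross partitions. With the default 4-per-sex draws
#' on a 22 F + 22 M roster, 28 individuals (14 per sex) remain in training.
#'
#' @param roster Tibble with `individual_key` and `sex` columns (see
#'   [roster_from_manifest()]), or a manifest from which one is derived.
#' @param n_val_per_sex,n_test_per_sex Individuals of each sex for the
#'   validation and test splits (default 4 each).
#' @param seed Integer seed; the assignment is deterministic under it.
#' @return Tibble of class `split_assignment`: `individual_key`, `sex`,
#'   `split` (factor train/val/test), with the seed as an attribute.
#' @export
assign_splits <- function(roster, n_val_per_sex = 4L, n_test_per_sex = 4L,
                          seed = 1L) {
  if (!"individual_key" %in% names(roster)) roster <- roster_from_manifest(roster)
  roster <- arrange(roster, .data$individual_key)
  out <- withr::with_seed(substream_seed(seed, "split"), {
    parts <- lapply(split(roster, roster$sex), function(r) {
      need <- n_val_per_sex + n_test_per_sex
      if (nrow(r) < need + 1) {
        abort(sprintf(
          "Insufficient individuals of sex %s: have %d, need more than %d.",
          r$sex[1], nrow(r), need))
      }
      drawn <- sample(r$individual_key, need)
      r$split <- "train"
      r$split[match(drawn[seq_len(n_val_per_sex)], r$individual_key)] <- "val"
      if (n_test_per_sex > 0) {
        r$split[match(drawn[n_val_per_sex + seq_len(n_test_per_sex)],
                      r$individual_key)] <- "test"
      }
      r
    })
    bind_rows(parts)
  })
  out$split <- factor(out$split, levels = c("train", "val", "test"))
  out <- select(out, "individual_key", "sex", "split")
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("split_assignment", class(out))
  out
}

#' Audit a split assignment for individual-level leakage
#'
#' @param assignment A [assign_splits()] tibble (or any tibble mapping
#'   `individual_key` to `split`; an individual listed under more than one
#'   split counts as leaked).
#' @param manifest Manifest whose frames are tallied per split.
#' @return List with `n_leaked`, `leaked_individuals`, and a `tallies`
#'   tibble (per split: individuals, frames).
#' @export
check_leakage <- function(assignment, manifest) {
  key <- individual_key(manifest)
  unknown <- setdiff(key, assignment$individual_key)
  if (length(unknown) > 0) {
    abort(sprintf("Manifest contains %d individual(s) absent from the assignment (e.g. %s).",
                  length(unknown), unknown[1]))
  }
  per_ind <- assignment |>
    group_by(.data$individual_key) |>
    summarise(n_splits = dplyr::n_distinct(.data$split), .groups = "drop")
  leaked <- per_ind$individual_key[per_ind$n_splits > 1]
  frames <- tibble(individual_key = key) |>
    left_join(as_tibble(assignment), by = "individual_key",
              relationship = "many-to-many") |>
    group_by(.data$split) |>
    summarise(n_frames = dplyr::n(),
              n_individuals = dplyr::n_distinct(.data$individual_key),
              .groups = "drop")
  list(n_leaked = length(leaked), leaked_individuals = leaked, tallies = frames)
}

#' Frame-level split membership
#'
#' @param manifest Manifest tibble.
#' @param assignment A [assign_splits()] result.
#' @return The manifest with `individual_key` and `split` columns.
#' @export
apply_splits <- function(manifest, assignment) {
  manifest$individual_key <- individual_key(manifest)
  left_join(manifest, select(as_tibble(assignment), "individual_key", "split"),
            by = "individual_key")
}

#' Balance per-individual representation in the training split
#'
#' Appends offline-augmented copies of under-represented training
#' individuals' frames until each individual has `min(target, cap)`
#' frames. Originals are never removed; source frames are cycled in
#' filename order so the procedure is deterministic. Augmentation happens
#' only after split assignment, so no augmented copy can cross splits.
#'
#' @param train_manifest Training-split manifest (with `image` list-column
#'   or readable paths).
#' @param target Frames per individual, or `"auto"` = the current maximum
#'   per-individual count.
#' @param cap Hard upper bound on the target.
#' @param params [augment_params()] for the offline augmenter.
#' @param seed Integer seed.
#' @param out_dir If given, augmented PNGs are written there; otherwise
#'   they are kept in the `image` list-column.
#' @return The manifest plus augmented rows, with a `synthetic` flag.
#' @export
balance_training_set <- function(train_manifest, target = "auto", cap = Inf,
                                 params = augment_params(), seed = 1L,
                                 out_dir = NULL) {
  if (nrow(train_manifest) == 0) abort("Empty training manifest.")
  train_manifest$synthetic <- FALSE
  if (!"image" %in% names(train_manifest)) {
    train_manifest$image <- vector("list", nrow(train_manifest))
  }
  key <- individual_key(train_manifest)
  counts <- table(key)
  if (identical(target, "auto")) target <- max(counts)
  target <- min(target, cap)
  new_rows <- list()
  for (k in names(counts)) {
    n_add <- max(0L, target - counts[[k]])
    if (n_add == 0L) next
    idx <- which(key == k)
    idx <- idx[order(basename(train_manifest$path[idx]))]
    for (j in seq_len(n_add)) {
      src <- idx[(j - 1L) %% length(idx) + 1L]
      img <- manifest_image(train_manifest, src)
      aug <- offline_augment(img, params, seed = substream_seed(seed, "balance", k, j))
      row <- train_manifest[src, , drop = FALSE]
      row$path <- sub("\\.png$", sprintf("_aug%02d.png", j), row$path)
      row$synthetic <- TRUE
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        row$path <- file.path(out_dir, basename(row$path))
        write_frame(aug, row$path)
        row$image <- list(NULL)
      } else {
        row$image <- list(aug)
      }
      new_rows[[length(new_rows) + 1L]] <- row
    }
  }
  bind_rows(train_manifest, bind_rows(new_rows))
}
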