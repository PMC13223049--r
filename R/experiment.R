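#' Build a full-experiment configuration
#'
#' One nested configuration drives the whole pipeline: simulate ->
#' preprocess -> split -> balance -> baseline -> cnn -> evaluate ->
#' interpret. Defaults are desk-scale: a full synthetic cohort but a small
#' baseline grid and a narrow reverse-family CNN, so an end-to-end run
#' stays in the minutes range on one core. A verbatim copy of the config
#' is written into the output directory before any stage runs.
#'
#' @param out_dir Output root (default: a timestamped directory under
#'   `tempdir()`).
#' @param seed Global integer seed.
#' @param simulate,preprocess,split,balance,baseline,cnn,interpret Named
#'   lists of per-stage parameters overriding the defaults below.
#' @param stages Character vector of stages to run.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(out_dir = NULL, seed = 1L,
                              simulate = list(), preprocess = list(),
                              split = list(), balance = list(),
                              baseline = list(), cnn = list(),
                              interpret = list(),
                              stages = c("simulate", "preprocess", "split",
                                         "balance", "baseline", "cnn",
                                         "evaluate", "interpret")) {
  defaults <- list(
    out_dir = out_dir %||% file.path(tempdir(), format(Sys.time(), "run-%Y%m%dT%H%M%S")),
    seed = as.integer(seed),
    stages = stages,
    simulate = list(n_per_sex = 22L, frames_range = c(5L, 8L),
                    defect_rate = 0.1, overlay_px = 8L, text_band_px = 4L,
                    sex_effect = 1, speckle_shape = 6),
    preprocess = list(threshold = 5, qc = TRUE, text_band = 4L),
    split = list(n_val_per_sex = 4L, n_test_per_sex = 4L),
    balance = list(target = "auto", cap = 12L),
    baseline = list(C_values = c(0.01, 1, 100), penalties = "l2",
                    solvers = "newton", pca_components = c(10L, 30L)),
    cnn = list(family = "reverse", size_variant = "S", width_scale = 1 / 8,
               input_size = 64L, dropout_rate = 0.2, max_epochs = 40L,
               monitor_start_epoch = 10L, patience = 10L, batch_size = 16L,
               learning_rate = 1e-3, optimizer = "adam"),
    interpret = list(k_range = 2:9, perplexity = 8)
  )
  for (nm in c("simulate", "preprocess", "split", "balance", "baseline",
               "cnn", "interpret")) {
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], get(nm))
  }
  structure(defaults, class = "experiment_config")
}

log_line <- function(path, stage, seed, t0, note = "") {
  entry <- jsonlite::toJSON(list(
    stage = stage, seed = seed,
    seconds = round(as.numeric(Sys.time()) - t0, 2),
    time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), note = note
  ), auto_unbox = TRUE)
  cat(entry, "\n", file = path, append = TRUE)
}

stage_done <- function(dir, stage, hash) {
  marker <- file.path(dir, paste0(".", stage, ".done"))
  file.exists(marker) && identical(readLines(marker, warn = FALSE)[1], hash)
}

mark_done <- function(dir, stage, hash) {
  writeLines(hash, file.path(dir, paste0(".", stage, ".done")))
}

#' Run the full experiment from one configuration
#'
#' Executes the enabled stages in order with a fixed on-disk layout under
#' `config$out_dir` (`data/`, `processed/`, `splits/`, `models/`,
#' `reports/`, `figures/`), logging per-stage seeds and durations to
#' `log.jsonl`. Completed stages are skipped on rerun when their
#' configuration hash matches (resumability). Frames of the test split are
#' read only by the evaluate stage.
#'
#' @param config An [experiment_config()].
#' @return The output directory, invisibly; stage results as the
#'   `results` attribute.
#' @export
run_experiment <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(config), file.path(out, "config.yaml"))
  log_path <- file.path(out, "log.jsonl")
  res <- list()
  seed <- config$seed

  run_stage <- function(stage, hash_extra, fn) {
    if (!stage %in% config$stages) return(NULL)
    hash <- rlang::hash(list(config[[stage]] %||% hash_extra, seed, hash_extra))
    if (stage_done(out, stage, hash)) {
      log_line(log_path, stage, seed, as.numeric(Sys.time()), "cached")
      return("cached")
    }
    t0 <- as.numeric(Sys.time())
    fn()
    mark_done(out, stage, hash)
    log_line(log_path, stage, seed, t0)
    "ran"
  }

  # --- simulate ------------------------------------------------------------
  data_dir <- file.path(out, "data")
  run_stage("simulate", "v1", function() {
    sc <- config$simulate
    generate_dataset(
      n_per_sex = sc$n_per_sex, frames_range = sc$frames_range,
      defect_rate = sc$defect_rate, overlay_px = sc$overlay_px,
      text_band_px = sc$text_band_px,
      params = population_params(sex_effect = sc$sex_effect,
                                 speckle_shape = sc$speckle_shape),
      seed = seed, out_dir = data_dir
    )
  })
  manifest <- read_manifest(data_dir)

  # --- preprocess ----------------------------------------------------------
  proc_dir <- file.path(out, "processed")
  run_stage("preprocess", "v1", function() {
    pc <- config$preprocess
    # quality filtering runs on overlay-stripped full frames (criterion (c)
    # inspects the image borders, which ROI cropping would destroy)
    work <- manifest
    work$image <- lapply(seq_len(nrow(manifest)), function(i) {
      strip_overlay(manifest_image(manifest, i), "auto", pc$text_band)
    })
    if (isTRUE(pc$qc)) {
      parts <- filter_quality(work, quality_rules(roi_threshold = pc$threshold))
      write.csv(select(parts$excluded, -"image"),
                file.path(out, "excluded.csv"), row.names = FALSE)
      work <- parts$kept
    }
    pm <- preprocess_manifest(work, threshold = pc$threshold,
                              border = c(0, 0, 0, 0), text_band = 0L)
    dir.create(proc_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(pm))) {
      write_frame(pm$image[[i]], file.path(proc_dir, basename(pm$path[i])))
    }
    pm$path <- file.path(proc_dir, basename(pm$path))
    write.csv(select(pm, -"image"), file.path(proc_dir, "manifest.csv"),
              row.names = FALSE)
  })
  processed <- read_manifest(proc_dir)

  # --- split ---------------------------------------------------------------
  split_dir <- file.path(out, "splits")
  run_stage("split", "v1", function() {
    assignment <- assign_splits(roster_from_manifest(processed),
                                n_val_per_sex = config$split$n_val_per_sex,
                                n_test_per_sex = config$split$n_test_per_sex,
                                seed = seed)
    audit <- check_leakage(assignment, processed)
    if (audit$n_leaked > 0) abort("Leaked individuals in split assignment.")
    dir.create(split_dir, showWarnings = FALSE)
    df <- as_tibble(assignment)
    df$seed <- seed
    write.csv(df, file.path(split_dir, "assignment.csv"), row.names = FALSE)
  })
  assignment <- as_tibble(read.csv(file.path(split_dir, "assignment.csv"),
                                   colClasses = "character"))
  frames <- apply_splits(processed, assignment)
  train_m <- filter(frames, .data$split == "train")
  val_m <- filter(frames, .data$split == "val")
  test_m <- filter(frames, .data$split == "test")

  # --- balance (training split only) ---------------------------------------
  bal_path <- file.path(split_dir, "train_balanced.csv")
  run_stage("balance", "v1", function() {
    bal <- balance_training_set(train_m, target = config$balance$target,
                                cap = config$balance$cap, seed = seed,
                                out_dir = file.path(out, "augmented"))
    write.csv(select(bal, -dplyr::any_of("image")), bal_path, row.names = FALSE)
  })
  train_bal <- if (file.exists(bal_path)) {
    as_tibble(read.csv(bal_path, colClasses = "character"))
  } else train_m

  models_dir <- file.path(out, "models")
  dir.create(models_dir, showWarnings = FALSE)
  train_images <- manifest_images(train_bal)
  val_images <- manifest_images(val_m)

  # --- baseline ------------------------------------------------------------
  run_stage("baseline", "v1", function() {
    bc <- config$baseline
    grid <- grid_spec(C_values = bc$C_values, penalties = bc$penalties,
                      solvers = bc$solvers, pca_components = bc$pca_components)
    fit <- grid_search_baseline(
      flatten_features(train_images), train_bal$sex,
      flatten_features(val_images), val_m$sex, grid = grid, seed = seed
    )
    saveRDS(fit, file.path(models_dir, "baseline.rds"))
    jsonlite::write_json(glance(fit), file.path(models_dir, "baseline.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # --- cnn -----------------------------------------------------------------
  run_stage("cnn", "v1", function() {
    cc <- config$cnn
    model <- build_cnn(cnn_config(family = cc$family,
                                  size_variant = cc$size_variant,
                                  width_scale = cc$width_scale,
                                  input_size = cc$input_size,
                                  dropout_rate = cc$dropout_rate),
                       seed = seed)
    fit <- train_model(
      model, train_images, train_bal$sex, val_images, val_m$sex,
      cfg = train_config(batch_size = cc$batch_size, optimizer = cc$optimizer,
                         learning_rate = cc$learning_rate,
                         max_epochs = cc$max_epochs,
                         monitor_start_epoch = cc$monitor_start_epoch,
                         patience = cc$patience, seed = seed),
      augment = function(img, s) train_time_augment(img, seed = s)
    )
    saveRDS(fit, file.path(models_dir, "cnn.rds"))
    write.csv(fit$history, file.path(models_dir, "cnn_history.csv"),
              row.names = FALSE)
  })

  # --- evaluate (the only stage that reads test frames) --------------------
  reports_dir <- file.path(out, "reports")
  run_stage("evaluate", "v1", function() {
    dir.create(reports_dir, showWarnings = FALSE)
    test_images <- manifest_images(test_m)
    reports <- list()
    bl_path <- file.path(models_dir, "baseline.rds")
    if (file.exists(bl_path)) {
      bl <- readRDS(bl_path)
      pred <- predict(bl, flatten_features(test_images))
      reports$baseline <- evaluate_split(test_m$sex, pred, "test")
    }
    cnn_path <- file.path(models_dir, "cnn.rds")
    if (file.exists(cnn_path)) {
      fit <- readRDS(cnn_path)
      pred <- predict(fit$model, test_images)
      reports$cnn <- evaluate_split(test_m$sex, pred$label, "test")
    }
    out_json <- lapply(reports, function(r) {
      list(split = r$split, accuracy = r$accuracy,
           confusion = unclass(r$confusion),
           per_class = r$per_class)
    })
    jsonlite::write_json(out_json, file.path(reports_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
  })

  # --- interpret -----------------------------------------------------------
  run_stage("interpret", "v1", function() {
    dir.create(reports_dir, showWarnings = FALSE)
    cnn_path <- file.path(models_dir, "cnn.rds")
    feats <- if (file.exists(cnn_path)) {
      pooled_features(readRDS(cnn_path)$model, train_images)
    } else {
      x <- flatten_features(train_images)
      st <- fit_standardizer(x)
      project_pca(apply_standardizer(x, st),
                  fit_pca(apply_standardizer(x, st), 5))
    }
    ks <- select_k(prcomp(feats)$x[, 1:2, drop = FALSE],
                   k_range = config$interpret$k_range, seed = seed)
    write.csv(ks$curve, file.path(reports_dir, "cluster_selection.csv"),
              row.names = FALSE)
    emb <- tsne_embed(feats, seed = seed,
                      perplexity = min(config$interpret$perplexity,
                                       (nrow(feats) - 1) / 4))
    emb$sex <- train_bal$sex
    write.csv(emb, file.path(reports_dir, "tsne.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(selected_k = ks$selected_k, elbow_k = ks$elbow_k,
           silhouette_by_sex = silhouette_score(feats, train_bal$sex)),
      file.path(reports_dir, "interpret.json"), auto_unbox = TRUE, digits = NA)
  })

  invisible(structure(out, results = res))
}
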