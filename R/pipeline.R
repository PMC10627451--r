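# End-to-end orchestration: generate phantoms -> train/apply the W-Net
# segmenter -> extract ghost features from foreground-masked images ->
# tune and fit the DESN classifier -> evaluate. Every stage is seeded from
# the config and timed; artifacts are persisted when an output directory
# is configured and a manifest summarizes the run.

pipeline_defaults <- function() {
  list(
    run_id = "run-1",
    phantoms = list(n_tumor = 250L, n_non_tumor = 250L, image_size = 64L,
                    noise_sigma = 0.05, seed = 101L),
    split = list(train_fraction = 0.8, stratified = TRUE, seed = 202L),
    wnet = list(levels = 3L, base_channels = 8L, max_channels = 32L,
                classes = 2L, epochs = 20L, learning_rate = 3e-3,
                batch_size = 8L, optimizer = "adam", lambda_tv = "auto",
                mode = "supervised", train_subset = 40L, seed = 303L),
    ghost = list(blocks = c(16L, 32L, 64L), stem_channels = 8L, s = 2L,
                 epochs = 10L, learning_rate = 1e-3, batch_size = 16L,
                 optimizer = "adam", mode = "masked", seed = 404L),
    desn = list(layers = 2L, N_res = 100L, rho = 0.9, alpha = 0.5,
                gamma = 1, density = 0.1, input_scaling = 1, lambda = 0,
                encoding = "repeat", repeat_T = 5L, seed = 505L),
    tsa = list(enabled = TRUE, n_pop = 20L, max_iter = 30L,
               holdout_fraction = 0.25, seed = 606L),
    output = list(dir = NULL)
  )
}

#' Build a pipeline configuration
#'
#' Starts from the reference defaults (500 balanced 64-pixel phantoms,
#' supervised 3-level W-Net for 20 epochs on a 40-sample subset, 10-epoch
#' ghost extractor, 20 x 30 tunicate-swarm tuning, 80:20 stratified split)
#' and merges any overrides given as nested lists, e.g.
#' `pipeline_config(split = list(train_fraction = 0.6))`.
#'
#' @param ... Named sections (`phantoms`, `split`, `wnet`, `ghost`,
#'   `desn`, `tsa`, `output`) each a list of overrides, plus optionally
#'   `run_id`.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  overrides <- list(...)
  cfg <- pipeline_defaults()
  for (nm in names(overrides)) {
    if (!nm %in% names(cfg)) {
      stop("unknown config section: ", nm, call. = FALSE)
    }
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) {
      for (k in names(overrides[[nm]])) cfg[[nm]][k] <- list(overrides[[nm]][[k]])
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Accepts a nested list or the path of a YAML file, checks every key
#' against the schema, fills defaults, and reports all violations in a
#' single error. Seeds are coerced to integers.
#'
#' @param config Nested list or YAML file path.
#' @return A `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- pipeline_defaults()
  problems <- character()
  for (nm in names(config)) {
    if (!nm %in% names(defaults)) {
      problems <- c(problems, paste0("unknown section `", nm, "`"))
    }
  }
  cfg <- defaults
  for (nm in intersect(names(config), names(defaults))) {
    if (is.list(defaults[[nm]])) {
      for (k in names(config[[nm]])) {
        if (!k %in% names(defaults[[nm]])) {
          problems <- c(problems, paste0("unknown key `", nm, ".", k, "`"))
        } else {
          cfg[[nm]][k] <- list(config[[nm]][[k]])
        }
      }
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  tf <- cfg$split$train_fraction
  if (!is.numeric(tf) || tf <= 0 || tf >= 1) {
    problems <- c(problems,
                  paste0("`split.train_fraction` must lie in (0, 1), got ", tf))
  }
  if (cfg$phantoms$n_tumor < 0 || cfg$phantoms$n_non_tumor < 0) {
    problems <- c(problems, "phantom counts must be non-negative")
  }
  if (cfg$phantoms$image_size < 32) {
    problems <- c(problems, "`phantoms.image_size` must be >= 32")
  }
  if (length(problems)) {
    stop("invalid pipeline config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  for (sec in c("phantoms", "split", "wnet", "ghost", "desn", "tsa")) {
    if (!is.null(cfg[[sec]]$seed)) cfg[[sec]]$seed <- as.integer(cfg[[sec]]$seed)
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full pipeline on synthetic phantoms
#'
#' Executes, in order: phantom generation, stratified train/test split,
#' supervised W-Net training on a subset of the training split, whole-set
#' segmentation, ghost-extractor training on foreground-masked training
#' images, feature extraction, optional tunicate-swarm hyperparameter
#' tuning, closed-form DESN fitting, and evaluation of both phases. The
#' run is deterministic for a fixed config.
#'
#' @param config A `pipeline_config` (see [pipeline_config()]).
#' @param out_dir Optional output directory overriding `config$output$dir`;
#'   when set, images, masks, features, metrics, tuning history, and the
#'   manifest are persisted there.
#' @return A `pipeline_result`: `metrics` (train/test `metrics_report`s),
#'   `test_dice` (mean foreground Dice on the held-out split),
#'   `segmenter`, `extractor`, `classifier`, `tuning` (or `NULL`),
#'   `features`, `manifest`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  config <- validate_config(unclass(config))
  out_dir <- out_dir %||% config$output$dir
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    val
  }

  pcfg <- phantom_config(image_size = config$phantoms$image_size,
                         noise_sigma = config$phantoms$noise_sigma,
                         seed = config$phantoms$seed)
  dataset <- clock("generate", make_dataset(config$phantoms$n_tumor,
                                            config$phantoms$n_non_tumor,
                                            pcfg, seed = config$phantoms$seed))
  sp <- split_dataset(dataset, split_spec(config$split$train_fraction,
                                          config$split$stratified,
                                          config$split$seed))

  wc <- config$wnet
  wcfg <- wnet_config(levels = wc$levels, base_channels = wc$base_channels,
                      max_channels = wc$max_channels, classes = wc$classes,
                      epochs = wc$epochs, learning_rate = wc$learning_rate,
                      batch_size = wc$batch_size, optimizer = wc$optimizer,
                      lambda_tv = wc$lambda_tv, mode = wc$mode, seed = wc$seed)
  n_train <- length(sp$train$samples)
  sub_n <- min(wc$train_subset, n_train)
  sub_ids <- with_seed(derive_seed(wc$seed, 41L), {
    unlist(lapply(split(seq_len(n_train), sp$train$index$label), function(ids) {
      sample(ids, size = max(1L, round(sub_n * length(ids) / n_train)))
    }), use.names = FALSE)
  })
  segmenter <- clock("train_seg", train_wnet(sp$train$samples[sub_ids], wcfg))

  all_images <- lapply(dataset$samples, function(s) s$image)
  pred_masks <- clock("segment", segment_batch(all_images, segmenter))

  gc_ <- config$ghost
  gcfg <- ghost_config(blocks = gc_$blocks, stem_channels = gc_$stem_channels,
                       s = gc_$s, epochs = gc_$epochs,
                       learning_rate = gc_$learning_rate,
                       batch_size = gc_$batch_size, optimizer = gc_$optimizer,
                       seed = gc_$seed)
  masked_or_raw <- function(ids) {
    if (gc_$mode == "masked") {
      lapply(ids, function(i) all_images[[i]] * (pred_masks[[i]] != 0))
    } else all_images[ids]
  }
  extractor <- clock("train_extractor",
                     train_extractor(masked_or_raw(sp$train_ids),
                                     dataset$index$label[sp$train_ids], gcfg))

  features <- clock("extract", {
    f <- extract_features_batch(all_images, pred_masks, extractor,
                                mode = gc_$mode,
                                labels = dataset$index$label)
    f$split <- ifelse(f$sample_id %in% sp$train_ids, "train", "test")
    f
  })
  tr_feat <- features[features$split == "train", ]
  te_feat <- features[features$split == "test", ]

  dc <- config$desn
  dcfg <- desn_config(layers = dc$layers, N_res = dc$N_res, rho = dc$rho,
                      alpha = dc$alpha, gamma = dc$gamma, density = dc$density,
                      input_scaling = dc$input_scaling, lambda = dc$lambda,
                      encoding = dc$encoding, repeat_T = dc$repeat_T,
                      seed = dc$seed)
  tuning <- NULL
  if (isTRUE(config$tsa$enabled)) {
    tuning <- clock("tune", tune_desn(tr_feat, tr_feat$label,
                                      n_pop = config$tsa$n_pop,
                                      max_iter = config$tsa$max_iter,
                                      holdout_fraction = config$tsa$holdout_fraction,
                                      config = dcfg, seed = config$tsa$seed))
    classifier <- tuning$model
  } else {
    classifier <- clock("train_clf", desn_fit(tr_feat, tr_feat$label, dcfg))
  }

  metrics <- clock("evaluate", {
    cls <- c("non_tumor", "tumor")
    list(train = evaluate_split(tr_feat$label, predict(classifier, tr_feat)$label,
                                K = 2L, class_names = cls),
         test = evaluate_split(te_feat$label, predict(classifier, te_feat)$label,
                               K = 2L, class_names = cls))
  })
  test_dice <- mean(vapply(sp$test_ids, function(i) {
    dice_coefficient(pred_masks[[i]], binary_foreground(dataset$samples[[i]]$mask))
  }, numeric(1)))

  artifacts <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    split_col <- ifelse(dataset$index$sample_id %in% sp$train_ids, "train", "test")
    write_dataset(dataset, file.path(out_dir, "data"), split = split_col)
    dir.create(file.path(out_dir, "pred_masks"), showWarnings = FALSE)
    for (i in seq_along(pred_masks)) {
      png::writePNG(pred_masks[[i]] / 255,
                    file.path(out_dir, "pred_masks", sprintf("mask_%04d.png", i)))
    }
    utils::write.csv(features, file.path(out_dir, "features.csv"), row.names = FALSE)
    write_metrics_report(metrics$train, out_dir, "training")
    write_metrics_report(metrics$test, out_dir, "testing")
    if (!is.null(tuning)) {
      utils::write.csv(tuning$result$history,
                       file.path(out_dir, "tuning_history.csv"), row.names = FALSE)
      yaml::write_yaml(as.list(tuning$best_params),
                       file.path(out_dir, "best_hyperparameters.yaml"))
    }
    yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
    artifacts <- list.files(out_dir, recursive = TRUE)
  }

  manifest <- list(
    run_id = config$run_id,
    config = unclass(config),
    timings = timings,
    n_samples = nrow(dataset$index),
    n_train = length(sp$train_ids), n_test = length(sp$test_ids),
    test_overall_accuracy = metrics$test$overall_accuracy,
    train_overall_accuracy = metrics$train$overall_accuracy,
    test_dice = test_dice,
    artifacts = artifacts
  )
  if (!is.null(out_dir)) {
    # atomic write: temp file then rename
    tmp <- file.path(out_dir, ".manifest.tmp")
    yaml::write_yaml(manifest, tmp)
    file.rename(tmp, file.path(out_dir, "manifest.yaml"))
  }

  structure(list(metrics = metrics, test_dice = test_dice,
                 segmenter = segmenter, extractor = extractor,
                 classifier = classifier, tuning = tuning,
                 features = features, split = sp, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>", x$manifest$n_samples, "phantoms;",
      x$manifest$n_train, "train /", x$manifest$n_test, "test\n")
  cat("  test accuracy:",
      format(round_half_up(x$metrics$test$overall_accuracy, 2), nsmall = 2),
      "%  test Dice:", round(x$test_dice, 4), "\n")
  invisible(x)
}
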