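# Workflow layer tying the modules together: enhancement -> feature
# extraction -> branch heads -> out-of-fold stacking -> meta-model ->
# evaluation, driven by a validated configuration with one global seed that
# fans out deterministically to every stage.

#' Derive a stage seed from the global seed
#'
#' `(seed + 7919 * offset) mod (2^31 - 1)`: a fixed affine fan-out so every
#' stage gets a distinct, reproducible seed from one global value.
#'
#' @param seed Global integer seed.
#' @param offset Stage offset (small integer).
#' @return Integer seed.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * offset) %% (2^31 - 1))
}

#' Pipeline configuration
#'
#' Validated bundle of paths and stage parameters. `overrides` (e.g. parsed
#' CLI flags) replace config-file keys; everything else falls back to the
#' documented defaults.
#'
#' @param path Optional YAML file with any of the keys below.
#' @param overrides Named list taking precedence over the file.
#' @return List of class `pipeline_config` with elements `paths` (`images`,
#'   `metadata`, `out`), `kernel`, `window`, `C`, `sigma`, `backbone`
#'   (`weights_source`, `depth`), `head` / `clinical` / `meta` configs,
#'   `folds`, `test_frac`, `val_frac`, `synth` (n_samples, signal), `seed`,
#'   `log_level`.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    paths = list(images = NULL, metadata = NULL, out = "dermastack_out"),
    kernel = 9L, window = 61L, C = 5, sigma = 1.0,
    backbone = list(weights_source = "seeded-test", depth = 2L),
    head = list(gamma = 2, alpha = 0.25, epochs = 300L, learning_rate = 0.5,
                val_frac = 0),
    clinical = list(nrounds = 300L, max_depth = 6L, eta = 0.1),
    meta = list(lambda = 0.01),
    folds = 10L, test_frac = 0.2, val_frac = 0.2,
    synth = list(n_samples = 600L, signal = 1),
    seed = 1L, log_level = "info"
  )
  if (!is.null(path)) {
    cfg <- utils::modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- utils::modifyList(cfg, overrides)
  if (cfg$kernel %% 2L == 0L || cfg$window %% 2L == 0L) {
    stop("kernel and window sizes must be odd")
  }
  if (cfg$folds < 2L) stop("folds must be >= 2")
  if (is.null(cfg$seed)) stop("a global seed must be set")
  structure(cfg, class = "pipeline_config")
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(format(Sys.time(), "[%H:%M:%S] "), ...)
}

read_dataset_dir <- function(cfg) {
  meta <- utils::read.csv(cfg$paths$metadata, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  img_dir <- cfg$paths$images
  paths <- file.path(img_dir, paste0(meta$img_id, ".png"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    alt <- file.path(img_dir, paste0(meta$img_id, ".jpg"))
    paths[missing] <- alt[missing]
    if (any(!file.exists(paths))) {
      stop("missing image file(s), e.g. ", paths[!file.exists(paths)][1])
    }
  }
  list(metadata = meta, image_paths = paths)
}

pipeline_features <- function(images, cfg, backbone) {
  k <- structuring_element("ellipse", cfg$kernel)
  tc <- threshold_config(cfg$window, cfg$C, cfg$sigma)
  feats <- matrix(0, length(images), backbone$spec$embed_dim)
  for (i in seq_along(images)) {
    img <- images[[i]]
    if (is.character(img)) img <- read_lesion_image(img)
    img <- resize_image(img)
    feats[i, ] <- fused_gap_features(enhance_triplet(img, k, tc), backbone)
  }
  feats
}

pipeline_backbone <- function(cfg) {
  build_backbone(backbone_spec(cfg$backbone$weights_source,
                               seed = derive_seed(cfg$seed, 1L),
                               depth = cfg$backbone$depth))
}

#' Train the full hybrid model on a dataset directory
#'
#' Runs enhancement, feature extraction, the out-of-fold stacking protocol
#' inside the training split, fits the meta-model on the out-of-fold vectors,
#' refits both base models on the full training split for deployment, and
#' saves a versioned model artifact. The 80/20 train/test split is made
#' first; cross-validation operates inside the training 80%.
#'
#' @param cfg A [pipeline_config()] whose `paths` point at an image directory
#'   and metadata CSV.
#' @return Invisibly, the fitted model bundle (also written to
#'   `paths$out/model.rds`).
#' @export
pipeline_train <- function(cfg) {
  ds <- read_dataset_dir(cfg)
  cleaned <- clean_metadata(ds$metadata)
  labels <- cleaned$labels
  backbone <- pipeline_backbone(cfg)
  log_msg(cfg, "extracting fused features for ", length(labels), " images")
  feats <- pipeline_features(as.list(ds$image_paths), cfg, backbone)

  split <- split_dataset(length(labels), labels, cfg$test_frac, cfg$val_frac,
                         seed = derive_seed(cfg$seed, 2L))
  tr <- sort(c(split$train, split$validation))   # CV operates inside the 80%
  plan <- make_fold_plan(labels[tr], cfg$folds, derive_seed(cfg$seed, 3L))
  h_cfg <- head_config(gamma = cfg$head$gamma, alpha = cfg$head$alpha,
                       epochs = cfg$head$epochs,
                       learning_rate = cfg$head$learning_rate,
                       val_frac = cfg$head$val_frac,
                       seed = derive_seed(cfg$seed, 4L))
  c_cfg <- clinical_config(cfg$clinical$nrounds, cfg$clinical$max_depth,
                           cfg$clinical$eta, seed = derive_seed(cfg$seed, 5L))
  log_msg(cfg, "building out-of-fold stack over ", plan$K, " folds")
  oof <- make_oof_stack(feats[tr, , drop = FALSE],
                        cleaned$table[tr, , drop = FALSE],
                        labels[tr], plan, h_cfg, c_cfg)
  meta <- fit_meta(oof$stack, oof$labels, meta_config(cfg$meta$lambda))
  head <- fit_image_head(feats[tr, , drop = FALSE], labels[tr], h_cfg)
  clin <- fit_clinical_model(cleaned$table[tr, , drop = FALSE], labels[tr], c_cfg)

  model <- list(version = "1", config = unclass(cfg), backbone_spec = backbone$spec,
                head = head, clinical = clin, meta = meta, split = split,
                fold_plan = plan, features = feats, labels = labels,
                img_id = ds$metadata$img_id, clinical_table = cleaned$table)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, file.path(cfg$paths$out, "model.rds"))
  utils::write.csv(
    data.frame(img_id = ds$metadata$img_id[tr], fold = plan$fold),
    file.path(cfg$paths$out, "fold_plan.csv"), row.names = FALSE)
  utils::write.csv(
    cbind(data.frame(img_id = ds$metadata$img_id[tr]),
          as.data.frame(oof$stack), label = labels[tr]),
    file.path(cfg$paths$out, "oof_stack.csv"), row.names = FALSE)
  log_msg(cfg, "model written to ", file.path(cfg$paths$out, "model.rds"))
  invisible(model)
}

#' Evaluate a trained model on its held-out test split
#'
#' Predicts the test split with both branches and the stacked meta-model, and
#' writes the confusion matrix, the per-class metrics report and the macro
#' averages as CSV.
#'
#' @param cfg A [pipeline_config()]; reads `paths$out/model.rds`.
#' @return Invisibly, a list with branch and stacked accuracies, the
#'   confusion matrix and the metrics report.
#' @export
pipeline_evaluate <- function(cfg) {
  model <- readRDS(file.path(cfg$paths$out, "model.rds"))
  te <- model$split$test
  p_img <- predict_image_probs(model$head, model$features[te, , drop = FALSE])
  p_cli <- predict_clinical_probs(model$clinical,
                                  model$clinical_table[te, , drop = FALSE])
  stacked <- cbind(p_img, p_cli)
  colnames(stacked) <- c(paste0("img_", CLASS_NAMES), paste0("clin_", CLASS_NAMES))
  final <- predict_final(model$meta, stacked)
  y <- model$labels[te]
  cm <- confusion_matrix(y, final$label)
  report <- per_class_metrics(cm)
  res <- list(
    accuracy_image = mean((apply(p_img, 1, which.max) - 1L) == y),
    accuracy_clinical = mean((apply(p_cli, 1, which.max) - 1L) == y),
    accuracy_stacked = mean(final$label == y),
    confusion = cm, report = report
  )
  out <- cfg$paths$out
  utils::write.csv(as.data.frame(cm), file.path(out, "confusion.csv"))
  write_metrics_report(report, file.path(out, "metrics.csv"))
  utils::write.csv(data.frame(branch = c("image", "clinical", "stacked"),
                              accuracy = c(res$accuracy_image,
                                           res$accuracy_clinical,
                                           res$accuracy_stacked)),
                   file.path(out, "accuracy.csv"), row.names = FALSE)
  log_msg(cfg, sprintf("test accuracy image %.3f | clinical %.3f | stacked %.3f",
                       res$accuracy_image, res$accuracy_clinical,
                       res$accuracy_stacked))
  invisible(res)
}

#' Predict one sample with a trained model
#'
#' @param cfg A [pipeline_config()]; reads `paths$out/model.rds`.
#' @param image_path Path to one PNG/JPEG photograph.
#' @param metadata_row One-row data frame in the metadata schema.
#' @return The [predict_final()] result; also writes
#'   `paths$out/prediction.csv` (img_id + six probabilities).
#' @export
pipeline_predict <- function(cfg, image_path, metadata_row) {
  model <- readRDS(file.path(cfg$paths$out, "model.rds"))
  backbone <- build_backbone(model$backbone_spec)
  feats <- pipeline_features(list(image_path), cfg, backbone)
  row <- clean_metadata(metadata_row,
                        encodings = model$clinical$encodings)$table
  p_img <- predict_image_probs(model$head, feats)
  p_cli <- predict_clinical_probs(model$clinical, row)
  final <- predict_final(model$meta, stack_probs(p_img[1, ], p_cli[1, ]))
  out_df <- data.frame(img_id = sub("\\.[^.]+$", "", basename(image_path)),
                       as.data.frame(final$probs))
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out_df, file.path(cfg$paths$out, "prediction.csv"),
                   row.names = FALSE)
  invisible(final)
}

#' Run one pipeline command
#'
#' Entry point behind the command-line tool. Commands: `synth` (write a
#' synthetic dataset to `paths$out`), `enhance` (write Black-Hat and adaptive
#' PNGs per image), `extract` (write fused pooled features as CSV), `train`,
#' `evaluate`, `predict`.
#'
#' @param cfg A [pipeline_config()].
#' @param command One of `"synth"`, `"enhance"`, `"extract"`, `"train"`,
#'   `"evaluate"`, `"predict"`.
#' @param ... Extra arguments for `predict` (`image_path`, `metadata_row`).
#' @return Command-specific result, invisibly.
#' @export
run_pipeline <- function(cfg, command = c("synth", "enhance", "extract",
                                          "train", "evaluate", "predict"), ...) {
  command <- match.arg(command)
  stopifnot(inherits(cfg, "pipeline_config"))
  log_msg(cfg, "command `", command, "` with seed ", cfg$seed)
  switch(command,
    synth = {
      sc <- synth_config(n_samples = cfg$synth$n_samples,
                         signal = cfg$synth$signal,
                         seed = derive_seed(cfg$seed, 0L))
      out <- generate_dataset(sc, dir = cfg$paths$out)
      log_msg(cfg, "wrote ", length(out$labels), " samples to ", cfg$paths$out)
      invisible(out)
    },
    enhance = {
      ds <- read_dataset_dir(cfg)
      k <- structuring_element("ellipse", cfg$kernel)
      tc <- threshold_config(cfg$window, cfg$C, cfg$sigma)
      dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
      for (p in ds$image_paths) {
        img <- resize_image(read_lesion_image(p))
        tri <- enhance_triplet(img, k, tc)
        id <- sub("\\.[^.]+$", "", basename(p))
        write_image_png(tri$blackhat, file.path(cfg$paths$out, paste0(id, "_blackhat.png")))
        write_image_png(tri$adaptive, file.path(cfg$paths$out, paste0(id, "_adaptive.png")))
      }
      invisible(cfg$paths$out)
    },
    extract = {
      ds <- read_dataset_dir(cfg)
      backbone <- pipeline_backbone(cfg)
      feats <- pipeline_features(as.list(ds$image_paths), cfg, backbone)
      dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
      df <- cbind(data.frame(img_id = ds$metadata$img_id), as.data.frame(feats))
      utils::write.csv(df, file.path(cfg$paths$out, "features.csv"), row.names = FALSE)
      invisible(feats)
    },
    train = pipeline_train(cfg),
    evaluate = pipeline_evaluate(cfg),
    predict = pipeline_predict(cfg, ...)
  )
}
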