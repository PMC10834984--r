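#' Default pipeline configuration
#'
#' Every tunable of the pipeline in one nested list: dataset shape, denoising
#' window, segmentation, render geometry, keypoint-detector thresholds,
#' feature-image fusion mode, SMOTE neighborhood, CNN hyperparameters and
#' cross-validation settings. Defaults mirror the reference study design:
#' 96/30/36 records of 65,535 samples, six segments per record, 200 x 200 x 3
#' renders, batch size 16, 30 epochs, Adam with categorical cross-entropy.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    outdir = "siftecg_out",
    dataset = list(counts = c(ARR = 96L, CHF = 30L, NSR = 36L),
                   n_samples = 65535L, sampling_rate = 128, noise_sd = 0.03),
    preprocess = list(window = 5L, n_segments = 6L),
    render = list(width = 200L, height = 200L, line_width = 1L,
                  y_scale = "per_segment"),
    sift = list(n_octaves = 4L, n_intervals = 3L, base_sigma = 1.6,
                contrast_threshold = 0.03, edge_r = 10,
                fusion = "overlay"),
    smote = list(k_neighbors = 5L),
    cnn = list(epochs = 30L, batch_size = 16L, lr = 1e-3, hidden = 64L,
               dropout = 0.5, n_filters = 32L, kernel = 3L, n_blocks = 3L),
    cv = list(k = 5L, holdout_fraction = 0.2)
  )
}

#' Validate and complete a configuration
#'
#' Unknown keys (at any nesting level) are rejected; missing keys are filled
#' from [default_config()].
#'
#' @param config partial configuration list.
#' @return Completed configuration.
#' @export
validate_config <- function(config = list()) {
  merge_checked <- function(def, usr, path = "") {
    extra <- setdiff(names(usr), names(def))
    if (length(extra) > 0)
      stop("unknown config key", if (length(extra) > 1) "s", ": ",
           paste0(path, extra, collapse = ", "))
    for (nm in names(usr)) {
      if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
        def[[nm]] <- merge_checked(def[[nm]], as.list(usr[[nm]]),
                                   paste0(path, nm, "$"))
      } else {
        def[[nm]] <- usr[[nm]]
      }
    }
    def
  }
  cfg <- merge_checked(default_config(), as.list(config))
  # JSON configs arrive with counts as a named list
  cfg$dataset$counts <- vapply(cfg$dataset$counts, as.integer, integer(1))
  if (!cfg$sift$fusion %in% c("overlay", "passthrough"))
    stop("sift$fusion must be 'overlay' or 'passthrough'")
  if (!cfg$render$y_scale %in% c("per_segment"))
    stop("render$y_scale: only 'per_segment' is implemented")
  cfg
}

# Polynomial rolling hash (mod a Mersenne prime) of the canonical JSON form
# of the config, for manifests.
config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  h <- 0
  for (b in utf8ToInt(as.character(s)))
    h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.manifest <- function(config, stage, ...) {
  list(stage = stage, config_hash = config_hash(config), seed = config$seed, ...)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.require_artifact <- function(path, stage) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run stage '", stage, "' first")
  path
}

#' Run one pipeline stage, writing artifacts to disk
#'
#' Stages: `generate` (synthetic records -> signals.csv), `preprocess`
#' (denoise/normalize/segment -> segments.csv), `render` (-> images/*.png +
#' render_manifest.csv), `features` (keypoints CSVs, descriptor matrices,
#' overlaid PNGs), `balance` (SMOTE on the flattened feature images ->
#' balance_manifest.csv), `train` (stratified hold-out split with SMOTE
#' applied inside the training partition only -> model.rds, history.json,
#' split.json), `evaluate` (-> metrics.json, confusion.csv), `run-all`
#' (all of the above in order). Each stage writes a manifest JSON recording
#' the config hash, seed and artifact counts; identical config + seed gives
#' identical artifacts.
#'
#' @param stage stage name as above.
#' @param config configuration (see [validate_config()]).
#' @return Invisibly, the stage manifest.
#' @export
run_stage <- function(stage, config = list()) {
  cfg <- validate_config(config)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stages <- c("generate", "preprocess", "render", "features", "balance",
              "train", "evaluate")
  if (identical(stage, "run-all")) {
    manifests <- lapply(stages, run_stage, config = cfg)
    names(manifests) <- stages
    man <- .manifest(cfg, "run-all",
                     n_records = manifests$generate$n_records,
                     n_segments = manifests$preprocess$n_segments,
                     n_images = manifests$render$n_images)
    .write_json(man, file.path(out, "manifest.json"))
    return(invisible(man))
  }
  if (!stage %in% stages) stop("unknown stage '", stage, "'")

  man <- switch(stage,
    generate = {
      records <- generate_dataset(cfg$dataset$counts, seed = cfg$seed,
                                  n_samples = cfg$dataset$n_samples,
                                  sampling_rate = cfg$dataset$sampling_rate,
                                  noise_sd = cfg$dataset$noise_sd)
      write_signal_table(records, file.path(out, "signals.csv"))
      .manifest(cfg, stage, n_records = length(records),
                path = file.path(out, "signals.csv"))
    },
    preprocess = {
      records <- read_signal_table(
        .require_artifact(file.path(out, "signals.csv"), "generate"),
        cfg$dataset$sampling_rate)
      segs <- preprocess_records(records, cfg$preprocess$window,
                                 cfg$preprocess$n_segments)
      con <- file(file.path(out, "segments.csv"), "w")
      seg_len <- length(segs[[1]]$samples)
      writeLines(paste(c("parent_id", "segment_index", "label",
                         paste0("s", seq_len(seg_len))), collapse = ","), con)
      for (s in segs)
        writeLines(paste(c(s$parent_id, s$segment_index, s$label,
                           formatC(s$samples, digits = 10, format = "g")),
                         collapse = ","), con)
      close(con)
      .manifest(cfg, stage, n_segments = length(segs), segment_length = seg_len,
                path = file.path(out, "segments.csv"))
    },
    render = {
      segs <- .read_segments(
        .require_artifact(file.path(out, "segments.csv"), "preprocess"))
      img_dir <- file.path(out, "images")
      dir.create(img_dir, showWarnings = FALSE)
      rows <- lapply(segs, function(s) {
        img <- render_segment(s, cfg$render$width, cfg$render$height,
                              cfg$render$line_width)
        path <- file.path(img_dir, sprintf("%s_s%d.png", s$parent_id,
                                           s$segment_index))
        write_signal_image(img, path)
        data.frame(parent_id = s$parent_id, segment_index = s$segment_index,
                   label = s$label, path = path)
      })
      manifest_df <- do.call(rbind, rows)
      write.csv(manifest_df, file.path(out, "render_manifest.csv"),
                row.names = FALSE)
      .manifest(cfg, stage, n_images = nrow(manifest_df),
                width = cfg$render$width, height = cfg$render$height)
    },
    features = {
      mdf <- read.csv(.require_artifact(file.path(out, "render_manifest.csv"),
                                        "render"))
      kp_dir <- file.path(out, "keypoints"); dir.create(kp_dir, showWarnings = FALSE)
      ov_dir <- file.path(out, "overlaid"); dir.create(ov_dir, showWarnings = FALSE)
      de_dir <- file.path(out, "descriptors"); dir.create(de_dir, showWarnings = FALSE)
      n_kp <- 0L
      for (r in seq_len(nrow(mdf))) {
        px <- read_signal_image(mdf$path[r])
        img <- structure(list(pixels = px, label = mdf$label[r],
                              parent_id = mdf$parent_id[r],
                              segment_index = mdf$segment_index[r]),
                         class = "signal_image")
        ft <- detect_and_describe(img, cfg$sift$n_octaves, cfg$sift$n_intervals,
                                  cfg$sift$base_sigma,
                                  cfg$sift$contrast_threshold, cfg$sift$edge_r)
        stem <- sprintf("%s_s%d", mdf$parent_id[r], mdf$segment_index[r])
        write.csv(ft$keypoints, file.path(kp_dir, paste0(stem, ".csv")),
                  row.names = FALSE)
        write_descriptor_matrix(ft$descriptors, file.path(de_dir, stem))
        ov <- if (cfg$sift$fusion == "overlay")
          overlay_keypoints(img, ft$keypoints) else img
        write_signal_image(ov, file.path(ov_dir, paste0(stem, ".png")))
        n_kp <- n_kp + nrow(ft$keypoints)
      }
      .manifest(cfg, stage, n_images = nrow(mdf), n_keypoints = n_kp,
                fusion = cfg$sift$fusion)
    },
    balance = {
      ds <- .load_feature_images(out, cfg)
      flat <- ds$flat
      bal <- smote(feature_dataset(flat, ds$labels), cfg$smote$k_neighbors,
                   seed = cfg$seed)
      write.csv(data.frame(label = bal$labels, provenance = bal$provenance),
                file.path(out, "balance_manifest.csv"), row.names = FALSE)
      .manifest(cfg, stage, class_counts = as.list(table(bal$labels)),
                n_rows = nrow(bal$features))
    },
    train = {
      ds <- .load_feature_images(out, cfg)
      split <- holdout_cv(ds$labels, cfg$cv$holdout_fraction, cfg$seed)
      fit <- .fit_split(ds, split$train_idx, cfg, seed = cfg$seed)
      saveRDS(fit, file.path(out, "model.rds"))
      .write_json(split, file.path(out, "split.json"))
      .write_json(fit$history, file.path(out, "history.json"))
      .manifest(cfg, stage, n_train = length(split$train_idx),
                n_test = length(split$test_idx),
                final_train_accuracy = fit$history$accuracy[nrow(fit$history)])
    },
    evaluate = {
      model_path <- file.path(out, "model.rds")
      if (!file.exists(model_path))
        stop("missing upstream artifact '", model_path, "'; run stage 'train' first")
      fit <- readRDS(model_path)
      split <- jsonlite::read_json(file.path(out, "split.json"),
                                   simplifyVector = TRUE)
      ds <- .load_feature_images(out, cfg)
      test_idx <- split$test_idx
      pred <- predict_cnn(fit, ds$array[, , , test_idx, drop = FALSE])
      rep <- evaluate_predictions(ds$labels[test_idx], pred$labels,
                                  pred$probabilities)
      .write_json(list(
        overall_accuracy = rep$overall_accuracy, macro = as.list(rep$macro),
        mcc = rep$mcc, kappa = rep$kappa, rmse = rep$rmse),
        file.path(out, "metrics.json"))
      write.csv(as.data.frame(unclass(rep$confusion)),
                file.path(out, "confusion.csv"))
      .manifest(cfg, stage, accuracy = rep$overall_accuracy, mcc = rep$mcc,
                kappa = rep$kappa, rmse = rep$rmse)
    })
  .write_json(man, file.path(out, paste0("manifest_", stage, ".json")))
  invisible(man)
}

.read_segments <- function(path) {
  lines <- readLines(path)
  fields <- strsplit(lines, ",", fixed = TRUE)
  lapply(fields[-1], function(f) {
    structure(list(parent_id = f[1], segment_index = as.integer(f[2]),
                   label = f[3], samples = as.numeric(f[-(1:3)])),
              class = "ecg_segment")
  })
}

# Load the CNN input images for the configured fusion mode: overlaid PNGs if
# the features stage ran with fusion = "overlay", raw renders otherwise.
.load_feature_images <- function(out, cfg) {
  mdf <- read.csv(.require_artifact(file.path(out, "render_manifest.csv"),
                                    "render"))
  dirn <- if (cfg$sift$fusion == "overlay") "overlaid" else "images"
  imgs <- lapply(seq_len(nrow(mdf)), function(r) {
    stem <- sprintf("%s_s%d.png", mdf$parent_id[r], mdf$segment_index[r])
    p <- file.path(out, dirn, stem)
    if (cfg$sift$fusion == "overlay")
      .require_artifact(p, "features")
    structure(list(pixels = read_signal_image(p), label = mdf$label[r],
                   parent_id = mdf$parent_id[r],
                   segment_index = mdf$segment_index[r]),
              class = "signal_image")
  })
  arr <- stack_images(imgs)
  d <- dim(arr)
  flat <- t(matrix(arr, d[1] * d[2] * d[3], d[4]))
  list(array = arr, flat = flat, labels = mdf$label, dims = d[1:3])
}

# Fit the CNN on a training partition: SMOTE inside the partition, reshape the
# balanced rows back to images, train.
.fit_split <- function(ds, train_idx, cfg, seed) {
  bal <- smote(feature_dataset(ds$flat[train_idx, , drop = FALSE],
                               ds$labels[train_idx]),
               cfg$smote$k_neighbors, seed = seed)
  n_bal <- nrow(bal$features)
  x <- array(t(bal$features), dim = c(ds$dims, n_bal))
  spec <- cnn_spec(input_shape = ds$dims, n_classes = length(unique(ds$labels)),
                   n_filters = cfg$cnn$n_filters, kernel = cfg$cnn$kernel,
                   n_blocks = cfg$cnn$n_blocks, hidden = cfg$cnn$hidden,
                   dropout = cfg$cnn$dropout, epochs = cfg$cnn$epochs,
                   batch_size = cfg$cnn$batch_size, lr = cfg$cnn$lr)
  model <- build_cnn(spec, seed = seed)
  train_cnn(model, x, bal$labels, seed = seed)
}

#' Persist / load a descriptor matrix (little-endian float32 + JSON sidecar)
#'
#' @param descriptors n x d numeric matrix.
#' @param stem file stem; writes `<stem>.bin` and `<stem>.json`.
#' @return The stem, invisibly; `read_descriptor_matrix()` returns the matrix.
#' @export
write_descriptor_matrix <- function(descriptors, stem) {
  if (is.null(descriptors)) descriptors <- matrix(0, 0, 128)
  con <- file(paste0(stem, ".bin"), "wb")
  # row-major write
  writeBin(as.numeric(t(descriptors)), con, size = 4, endian = "little")
  close(con)
  .write_json(list(n = nrow(descriptors), d = ncol(descriptors),
                   dtype = "float32", order = "row-major",
                   endian = "little"), paste0(stem, ".json"))
  invisible(stem)
}

#' @rdname write_descriptor_matrix
#' @export
read_descriptor_matrix <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  v <- readBin(con, "numeric", n = meta$n * meta$d, size = 4, endian = "little")
  close(con)
  matrix(v, nrow = meta$n, ncol = meta$d, byrow = TRUE)
}

#' Run the full experiment in memory
#'
#' Generates the synthetic dataset, preprocesses and renders it, detects and
#' overlays keypoints, then evaluates the CNN under a stratified hold-out
#' split and (optionally) stratified k-fold cross-validation. SMOTE and all
#' fitting happen inside each training partition. This is the programmatic
#' equivalent of `run_stage("run-all", ...)` without disk artifacts.
#'
#' @param config configuration; see [default_config()].
#' @param kfold also run k-fold cross-validation (default TRUE).
#' @param verbose print progress.
#' @return List with `counts` (records/segments/keypoints), `holdout`
#'   (`metric_report`), and `kfold` (`cv_result` or NULL).
#' @export
run_experiment <- function(config = list(), kfold = TRUE, verbose = FALSE) {
  cfg <- validate_config(config)
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating %d records", sum(cfg$dataset$counts))
  records <- generate_dataset(cfg$dataset$counts, seed = cfg$seed,
                              n_samples = cfg$dataset$n_samples,
                              sampling_rate = cfg$dataset$sampling_rate,
                              noise_sd = cfg$dataset$noise_sd)
  segs <- preprocess_records(records, cfg$preprocess$window,
                             cfg$preprocess$n_segments)
  say("rendering %d segments at %dx%d", length(segs), cfg$render$width,
      cfg$render$height)
  n_kp <- 0L
  imgs <- lapply(segs, function(s) {
    img <- render_segment(s, cfg$render$width, cfg$render$height,
                          cfg$render$line_width)
    if (cfg$sift$fusion == "overlay") {
      ft <- detect_and_describe(img, cfg$sift$n_octaves, cfg$sift$n_intervals,
                                cfg$sift$base_sigma,
                                cfg$sift$contrast_threshold, cfg$sift$edge_r,
                                descriptors = FALSE)
      n_kp <<- n_kp + nrow(ft$keypoints)
      img <- overlay_keypoints(img, ft$keypoints)
    }
    img
  })
  labels <- vapply(segs, function(s) s$label, character(1))
  arr <- stack_images(imgs)
  d <- dim(arr)
  ds <- list(array = arr, flat = t(matrix(arr, d[1] * d[2] * d[3], d[4])),
             labels = labels, dims = d[1:3])

  train_fn <- function(train_idx, seed) .fit_split(ds, train_idx, cfg, seed)
  eval_fn <- function(fit, test_idx) {
    pred <- predict_cnn(fit, ds$array[, , , test_idx, drop = FALSE])
    evaluate_predictions(ds$labels[test_idx], pred$labels, pred$probabilities,
                         classes = sort(unique(ds$labels)))
  }

  say("hold-out evaluation (fraction %.2f)", cfg$cv$holdout_fraction)
  holdout <- holdout_cv(ds$labels, cfg$cv$holdout_fraction, cfg$seed,
                        train_fn, eval_fn)
  kf <- NULL
  if (kfold) {
    say("%d-fold cross-validation", cfg$cv$k)
    kf <- kfold_cv(ds$labels, cfg$cv$k, cfg$seed, train_fn, eval_fn)
  }
  list(counts = list(n_records = length(records), n_segments = length(segs),
                     n_keypoints = n_kp,
                     segment_length = length(segs[[1]]$samples),
                     class_segments = table(labels)),
       holdout = holdout, kfold = kf, config = cfg)
}
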