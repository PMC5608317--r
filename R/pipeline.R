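#' Read an RGB image into an `[0, 1]` array
#'
#' PNG, TIFF and JPEG are supported (8- or 16-bit); values are scaled to
#' `[0, 1]` by the decoding library (dtype maximum). An alpha channel, if
#' present, is dropped; grayscale images are rejected (the dynamical model
#' is defined on the three color channels).
#'
#' @param path Image file path.
#' @return An `H x W x 3` numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    abort_grassvlad(paste0("image not found: ", path), "grassvlad_data_error")
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        abort_grassvlad("package 'tiff' required for TIFF input", "grassvlad_config_error")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        abort_grassvlad("package 'jpeg' required for JPEG input", "grassvlad_config_error")
      jpeg::readJPEG(path)
    },
    abort_grassvlad(paste0("unsupported image format: ", path),
                    "grassvlad_data_error"))
  if (length(dim(img)) == 2L) {
    abort_grassvlad(paste0("grayscale image not supported: ", path),
                    "grassvlad_data_error")
  }
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  check_image(img)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `path,label,patient_id,magnification`
#' (magnification optional). Malformed rows are reported with their line
#' numbers; duplicate paths are kept with a warning.
#'
#' @param path Manifest CSV path.
#' @return A tibble of image records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort_grassvlad(paste0("manifest not found: ", path), "grassvlad_data_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    abort_grassvlad("empty manifest", "grassvlad_data_error")
  }
  need <- c("path", "label", "patient_id")
  if (!all(need %in% names(df))) {
    abort_grassvlad(paste0("manifest must have columns ",
                           paste(need, collapse = ", ")),
                    "grassvlad_data_error")
  }
  bad <- which(!nzchar(df$path) | !nzchar(df$label) | !nzchar(df$patient_id) |
                 is.na(df$path) | is.na(df$label) | is.na(df$patient_id))
  if (length(bad)) {
    abort_grassvlad(paste0("malformed manifest rows (line ",
                           paste(bad + 1L, collapse = ", "), ")"),
                    "grassvlad_data_error")
  }
  if (anyDuplicated(df$path)) {
    warning("manifest contains duplicate paths; all rows kept")
  }
  if (is.null(df$magnification)) df$magnification <- NA_character_
  tibble::as_tibble(df[, c("path", "label", "patient_id", "magnification")])
}

#' Embed every image of a manifest as a cloud of Grassmann points
#'
#' For each image: cut patches under `patching`, add the four directional
#' rotation variants (optional), identify an HLDS per patch tensor
#' (degenerate patches are excluded and counted), stabilize unstable
#' transition matrices, and map each system to its orthonormalized
#' observability subspace.
#'
#' @param manifest A manifest tibble ([read_manifest()] or [make_dataset()]).
#' @param patching A [patch_config()].
#' @param m Observability horizon (default 3).
#' @param four_directions Model all four scan directions (default TRUE).
#' @param ridge,stab_tol,stab_max_iter Identification controls.
#' @param workdir Optional cache directory: per-image clouds are stored
#'   keyed by a content hash of the stage configuration and reused on reruns.
#' @param verbose Print per-image progress.
#' @return The manifest tibble plus list column `points`
#'   (`3m x 3 x n_points` arrays) and counter columns `n_points`,
#'   `n_degenerate`, `n_stabilized`, `n_stab_failed`.
#' @export
embed_images <- function(manifest, patching = patch_config(), m = 3L,
                         four_directions = TRUE, ridge = 1e-8,
                         stab_tol = 1e-6, stab_max_iter = 50L,
                         workdir = NULL, verbose = FALSE) {
  stage_key <- NULL
  if (!is.null(workdir)) {
    dir.create(file.path(workdir, "clouds"), showWarnings = FALSE, recursive = TRUE)
    stage_key <- md5_of_string(paste(
      jsonlite::toJSON(unclass(patching), auto_unbox = TRUE),
      m, four_directions, ridge, stab_tol, stab_max_iter, sep = "|"))
  }
  res <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- manifest$path[i]
    cache_file <- NULL
    if (!is.null(stage_key)) {
      cache_file <- file.path(workdir, "clouds",
                              paste0(md5_of_string(paste(stage_key, path)), ".rds"))
      if (file.exists(cache_file)) {
        res[[i]] <- readRDS(cache_file)
        if (verbose) message("cache hit: ", path)
        next
      }
    }
    img <- withCallingHandlers(
      read_image(path),
      error = function(e) e)
    if (inherits(img, "error")) {
      abort_grassvlad(paste0("stage embed failed for ", path, ": ",
                             conditionMessage(img)),
                      "grassvlad_data_error")
    }
    og <- patch_origins(dim(img)[1], dim(img)[2], patching)
    fit <- cpp_fit_image(img, og, patching$size, four_directions, as.integer(m),
                         ridge, stab_tol, as.integer(stab_max_iter), 1e-8)
    out <- list(points = fit$bases, n_points = fit$n_points,
                n_degenerate = fit$n_degenerate,
                n_stabilized = sum(fit$stabilized),
                n_stab_failed = sum(fit$stab_failed))
    if (!is.null(cache_file)) saveRDS(out, cache_file)
    res[[i]] <- out
    if (verbose) message(sprintf("embedded %s: %d points (%d degenerate)",
                                 path, out$n_points, out$n_degenerate))
  }
  out <- manifest
  out$points <- lapply(res, `[[`, "points")
  out$n_points <- vapply(res, function(r) as.integer(r$n_points), integer(1))
  out$n_degenerate <- vapply(res, function(r) as.integer(r$n_degenerate), integer(1))
  out$n_stabilized <- vapply(res, function(r) as.integer(r$n_stabilized), integer(1))
  out$n_stab_failed <- vapply(res, function(r) as.integer(r$n_stab_failed), integer(1))
  out
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end pipeline. Round-trips losslessly
#' through JSON, and every report embeds the resolved configuration.
#'
#' @param patching A [patch_config()].
#' @param m Observability horizon.
#' @param four_directions Model all four scan directions.
#' @param stab_tol,stab_max_iter,ridge Identification controls.
#' @param k,codebook_seed,subsample_cap,refine_iters,variant Encoding controls.
#' @param protocol,n_folds,train_frac,n_trials,eval_seed Evaluation controls.
#' @param svm_seed Seed for the inner SVM grid search.
#' @param shared_codebook If `TRUE`, one codebook is learned from training
#'   points of the first fold and shared across folds (logged as the laxer
#'   protocol); default `FALSE` = a fresh codebook inside every training fold.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(patching = patch_config(), m = 3L,
                            four_directions = TRUE, stab_tol = 1e-6,
                            stab_max_iter = 50L, ridge = 1e-8, k = 16L,
                            codebook_seed = 1L, subsample_cap = 3000L,
                            refine_iters = 10L, variant = "scalar",
                            protocol = "kfold", n_folds = 5L,
                            train_frac = 0.7, n_trials = 5L, eval_seed = 1L,
                            svm_seed = 1L, shared_codebook = FALSE) {
  structure(list(patching = patching, m = as.integer(m),
                 four_directions = four_directions, stab_tol = stab_tol,
                 stab_max_iter = as.integer(stab_max_iter), ridge = ridge,
                 k = as.integer(k), codebook_seed = as.integer(codebook_seed),
                 subsample_cap = as.integer(subsample_cap),
                 refine_iters = as.integer(refine_iters),
                 variant = resolve_variant(variant), protocol = protocol,
                 n_folds = as.integer(n_folds), train_frac = train_frac,
                 n_trials = as.integer(n_trials),
                 eval_seed = as.integer(eval_seed),
                 svm_seed = as.integer(svm_seed),
                 shared_codebook = shared_codebook),
            class = "pipeline_config")
}

#' Run the full pipeline on a manifest
#'
#' extract -> identify/stabilize -> embed -> (per-training-fold) codebook ->
#' encode -> SVM -> report. Codebooks are learned from training-fold images
#' only (no vocabulary leakage into the test fold) unless
#' `shared_codebook = TRUE` is requested explicitly.
#'
#' @param manifest A manifest tibble or path to a manifest CSV.
#' @param config A [pipeline_config()].
#' @param workdir Optional cache/working directory.
#' @param embedded Optionally, a precomputed [embed_images()] result for this
#'   manifest (skips the embedding stage).
#' @param verbose Print stage progress.
#' @return A `grassvlad_eval` report; see [tidy.grassvlad_eval()],
#'   [glance.grassvlad_eval()] and [autoplot.grassvlad_eval()].
#' @export
run_pipeline <- function(manifest, config = pipeline_config(), workdir = NULL,
                         embedded = NULL, verbose = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  missing <- !file.exists(manifest$path)
  if (is.null(embedded) && any(missing)) {
    abort_grassvlad(paste0("missing image file(s): ",
                           paste(manifest$path[missing], collapse = ", ")),
                    "grassvlad_data_error")
  }
  if (is.null(embedded)) {
    if (verbose) message("stage embed: ", nrow(manifest), " images")
    embedded <- embed_images(manifest, patching = config$patching,
                             m = config$m,
                             four_directions = config$four_directions,
                             ridge = config$ridge, stab_tol = config$stab_tol,
                             stab_max_iter = config$stab_max_iter,
                             workdir = workdir, verbose = verbose)
  }
  plan <- make_split(embedded, protocol = config$protocol,
                     seed = config$eval_seed, n_folds = config$n_folds,
                     train_frac = config$train_frac, n_trials = config$n_trials)
  labels <- factor(embedded$label)
  shared_cb <- NULL
  fold_rows <- list()
  pred_rows <- list()
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train
    te <- plan$folds[[f]]$test
    if (config$shared_codebook && !is.null(shared_cb)) {
      cb <- shared_cb
    } else {
      if (verbose) message("fold ", f, ": learning codebook")
      cb <- learn_codebook(embedded[tr, ], k = config$k,
                           seed = config$codebook_seed,
                           subsample_cap = config$subsample_cap,
                           refine_iters = config$refine_iters)
      if (config$shared_codebook) shared_cb <- cb
    }
    codes <- encode_images(embedded[c(tr, te), ], cb, variant = config$variant)
    keep <- !codes$is_zero
    codemat <- do.call(rbind, codes$code)
    in_train <- seq_along(c(tr, te)) <= length(tr)
    svm <- train_classifier(codemat[in_train & keep, , drop = FALSE],
                            codes$label[in_train & keep],
                            seed = config$svm_seed)
    test_keep <- !in_train & keep
    pred <- predict(svm, codemat[test_keep, , drop = FALSE])
    truth <- codes$label[test_keep]
    rate <- classification_rate(pred, truth)
    cm <- table(truth = factor(truth, levels(labels)),
                pred = factor(pred, levels(labels)))
    fold_rows[[f]] <- tibble::tibble(fold = f, n_test = sum(test_keep),
                                     rate = rate, confusion = list(cm))
    pred_rows[[f]] <- tibble::tibble(
      path = codes$path[test_keep], fold = f,
      truth = as.character(truth), pred = as.character(pred),
      patient_id = codes$patient_id[test_keep])
  }
  folds <- dplyr::bind_rows(fold_rows)
  predictions <- dplyr::bind_rows(pred_rows)
  pscores <- patient_score(predictions$pred, predictions$truth,
                           predictions$patient_id)
  if (plan$protocol == "patient_holdout") {
    trial_rates <- vapply(split(predictions, predictions$fold), function(d) {
      global_patient_rate(patient_score(d$pred, d$truth, d$patient_id))
    }, numeric(1))
    gpr <- mean(trial_rates)
  } else {
    gpr <- global_patient_rate(pscores)
  }
  structure(list(folds = folds, predictions = predictions,
                 mean_rate = mean(folds$rate), sd_rate = sd(folds$rate),
                 patient_scores = pscores, global_patient_rate = gpr,
                 protocol = plan$protocol, config = config,
                 counters = list(
                   n_points = sum(embedded$n_points),
                   n_degenerate = sum(embedded$n_degenerate),
                   n_stabilized = sum(embedded$n_stabilized),
                   n_stab_failed = sum(embedded$n_stab_failed))),
            class = "grassvlad_eval")
}

#' @export
print.grassvlad_eval <- function(x, ...) {
  cat(sprintf("<grassvlad_eval> %s: mean rate %.4f (sd %.4f) over %d folds; global patient rate %.4f\n",
              x$protocol, x$mean_rate, x$sd_rate, nrow(x$folds),
              x$global_patient_rate))
  invisible(x)
}

#' Tidy per-fold results of an evaluation report
#'
#' @param x A `grassvlad_eval` report.
#' @param ... Unused.
#' @return A tibble with one row per fold (`fold`, `n_test`, `rate`).
#' @method tidy grassvlad_eval
#' @export
tidy.grassvlad_eval <- function(x, ...) {
  dplyr::select(x$folds, "fold", "n_test", "rate")
}

#' One-row summary of an evaluation report
#'
#' @param x A `grassvlad_eval` report.
#' @param ... Unused.
#' @return A one-row tibble with the protocol, mean/sd fold rates, the
#'   global patient rate and pipeline counters.
#' @method glance grassvlad_eval
#' @export
glance.grassvlad_eval <- function(x, ...) {
  tibble::tibble(protocol = x$protocol, n_folds = nrow(x$folds),
                 mean_rate = x$mean_rate, sd_rate = x$sd_rate,
                 global_patient_rate = x$global_patient_rate,
                 n_points = x$counters$n_points,
                 n_degenerate = x$counters$n_degenerate,
                 n_stabilized = x$counters$n_stabilized)
}

#' Plot per-fold classification rates
#'
#' @param object A `grassvlad_eval` report.
#' @param ... Unused.
#' @return A ggplot: fold rates with the mean as a dashed line.
#' @method autoplot grassvlad_eval
#' @export
autoplot.grassvlad_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_rate, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "classification rate",
                  title = sprintf("%s evaluation: mean rate %.3f",
                                  object$protocol, object$mean_rate))
}

#' Plot the pairwise word distances of a codebook
#'
#' @param object A `grassvlad_codebook`.
#' @param ... Unused.
#' @return A ggplot tile map of geodesic distances between words.
#' @method autoplot grassvlad_codebook
#' @export
autoplot.grassvlad_codebook <- function(object, ...) {
  D <- cloud_self_dist(object$words)
  df <- expand.grid(i = seq_len(nrow(D)), j = seq_len(ncol(D)))
  df$distance <- as.vector(D)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "word", y = "word", fill = "geodesic\ndistance")
}

#' Write an evaluation report to disk
#'
#' Emits `<path>.json` (machine-readable, with the resolved configuration),
#' `<path>.txt` (human-readable table) and `<path>_predictions.csv`
#' (per-image predictions: path, truth, predicted, fold, patient id).
#'
#' @param report A `grassvlad_eval`.
#' @param path Output path prefix (extensions are appended).
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(report, path) {
  out <- list(protocol = report$protocol,
              folds = report$folds[, c("fold", "n_test", "rate")],
              mean_rate = report$mean_rate, sd_rate = report$sd_rate,
              global_patient_rate = report$global_patient_rate,
              patient_scores = report$patient_scores,
              counters = report$counters,
              config = unclass_config(report$config))
  jp <- paste0(path, ".json")
  jsonlite::write_json(out, jp, auto_unbox = TRUE, digits = NA)
  tp <- paste0(path, ".txt")
  lines <- c(sprintf("protocol: %s", report$protocol),
             sprintf("fold %d: rate %.4f (n = %d)", report$folds$fold,
                     report$folds$rate, report$folds$n_test),
             sprintf("mean rate: %.4f (sd %.4f)", report$mean_rate, report$sd_rate),
             sprintf("global patient rate: %.4f", report$global_patient_rate))
  writeLines(lines, tp)
  utils::write.csv(report$predictions[, c("path", "truth", "pred", "fold",
                                          "patient_id")],
                   paste0(path, "_predictions.csv"), row.names = FALSE,
                   quote = FALSE)
  invisible(jp)
}

unclass_config <- function(cfg) {
  out <- unclass(cfg)
  out$patching <- unclass(out$patching)
  out
}

#' Write / read a pipeline configuration
#'
#' JSON serialization of a [pipeline_config()]; the round trip is lossless
#' (`read_config(write_config(cfg, f))` reconstructs an identical object).
#'
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @return `read_config` returns the `pipeline_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_config(config), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  pc <- raw$patching
  patching <- patch_config(pc$size, pc$strategy,
                           overlap_fraction = pc$overlap_fraction,
                           n_random = pc$n_random, seed = pc$seed)
  raw$patching <- NULL
  do.call(pipeline_config, c(list(patching = patching), raw))
}

#' Export per-image VLAD codes as CSV
#'
#' One row per image: `path`, `label`, `patient_id`, then the code
#' components (`code_1` ... `code_d`).
#'
#' @param codes A tibble from [encode_images()].
#' @param path Output CSV path.
#' @return Invisibly, the path.
#' @export
write_codes <- function(codes, path) {
  mat <- do.call(rbind, codes$code)
  colnames(mat) <- paste0("code_", seq_len(ncol(mat)))
  out <- cbind(codes[, c("path", "label", "patient_id")], as.data.frame(mat))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a codebook
#'
#' @param codebook A `grassvlad_codebook`.
#' @param path File path (RDS container).
#' @return `load_codebook` returns the codebook.
#' @export
save_codebook <- function(codebook, path) {
  saveRDS(codebook, path)
  invisible(path)
}

#' @rdname save_codebook
#' @export
load_codebook <- function(path) {
  cb <- readRDS(path)
  if (!inherits(cb, "grassvlad_codebook")) {
    abort_grassvlad("file does not contain a codebook", "grassvlad_data_error")
  }
  cb
}
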