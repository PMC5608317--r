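#' Image-level classification rate
#'
#' The ratio of correctly classified images to all images, `N_c / N_all`.
#'
#' @param pred,truth Equal-length vectors of predicted and true labels.
#' @return A scalar in `[0, 1]`.
#' @export
classification_rate <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) == 0L) {
    abort_grassvlad("`pred` and `truth` must be nonempty and equal length",
                    "grassvlad_data_error")
  }
  mean(as.character(pred) == as.character(truth))
}

#' Per-patient scores
#'
#' For each patient, the fraction of that patient's images classified
#' correctly (`N_c / N_P`). No aggregation across patients is performed.
#'
#' @param pred,truth Predicted and true labels.
#' @param patient_ids Patient identifier per image.
#' @return A tibble with columns `patient_id`, `n_images`, `score`.
#' @export
patient_score <- function(pred, truth, patient_ids) {
  if (any(is.na(patient_ids)) || any(!nzchar(patient_ids))) {
    abort_grassvlad("every image needs a patient id", "grassvlad_data_error")
  }
  tibble::tibble(patient_id = as.character(patient_ids),
                 correct = as.character(pred) == as.character(truth)) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_images = dplyr::n(), score = mean(.data$correct),
                     .groups = "drop")
}

#' Global patient classification rate
#'
#' The mean of the per-patient scores (each patient weighted equally).
#'
#' @param scores A tibble from [patient_score()] or a numeric vector of
#'   patient scores.
#' @return A scalar in `[0, 1]`.
#' @export
global_patient_rate <- function(scores) {
  s <- if (is.data.frame(scores)) scores$score else as.numeric(scores)
  if (length(s) == 0L) {
    abort_grassvlad("no patient scores", "grassvlad_data_error")
  }
  mean(s)
}

#' Build an evaluation split plan
#'
#' Two protocols: `"kfold"` performs stratified (by label) k-fold
#' cross-validation at the image level; `"patient_holdout"` partitions
#' *patients* (per class) into ~`train_frac` training and the rest testing,
#' repeated for `n_trials` independent seeded draws, guaranteeing that no
#' patient contributes images to both sides of any split.
#'
#' @param manifest A tibble with `label` and (for patient_holdout)
#'   `patient_id` columns.
#' @param protocol `"kfold"` or `"patient_holdout"`.
#' @param seed Integer seed.
#' @param n_folds Folds for kfold (default 5).
#' @param train_frac Training fraction of patients for patient_holdout
#'   (default 0.7).
#' @param n_trials Seeded trials for patient_holdout (default 5).
#' @return An object of class `split_plan`: list with `protocol`, `seed`,
#'   `patient_aware`, and `folds` — a list of `list(train =, test =)` row
#'   index vectors.
#' @export
make_split <- function(manifest, protocol = c("kfold", "patient_holdout"),
                       seed = 1L, n_folds = 5L, train_frac = 0.7,
                       n_trials = 5L) {
  protocol <- match.arg(protocol)
  labels <- as.character(manifest$label)
  n <- length(labels)
  folds <- list()
  if (protocol == "kfold") {
    counts <- table(labels)
    if (any(counts < n_folds)) {
      abort_grassvlad(
        paste0("cannot stratify: class counts ",
               paste(sprintf("%s=%d", names(counts), counts), collapse = ", "),
               " with ", n_folds, " folds"),
        "grassvlad_config_error")
    }
    fold_of <- integer(n)
    with_seed(seed, {
      for (cl in names(counts)) {
        idx <- sample(which(labels == cl))
        fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
    })
    for (f in seq_len(n_folds)) {
      folds[[f]] <- list(train = which(fold_of != f), test = which(fold_of == f))
    }
  } else {
    pid <- as.character(manifest$patient_id)
    upat <- unique(data.frame(pid = pid, label = labels))
    per_class <- split(upat, upat$label)
    if (any(vapply(per_class, nrow, integer(1)) < 2L)) {
      abort_grassvlad("patient_holdout needs >= 2 patients per class",
                      "grassvlad_config_error")
    }
    trial_seeds <- derive_seeds(seed, n_trials)
    for (t in seq_len(n_trials)) {
      train_pids <- character()
      with_seed(trial_seeds[t], {
        for (cl in names(per_class)) {
          pc <- unique(per_class[[cl]]$pid)
          n_train <- max(1L, min(length(pc) - 1L, round(train_frac * length(pc))))
          train_pids <- c(train_pids, sample(pc, n_train))
        }
      })
      folds[[t]] <- list(train = which(pid %in% train_pids),
                         test = which(!pid %in% train_pids))
      stopifnot(length(intersect(pid[folds[[t]]$train], pid[folds[[t]]$test])) == 0L)
    }
  }
  structure(list(protocol = protocol, seed = as.integer(seed),
                 patient_aware = protocol == "patient_holdout",
                 n_folds = length(folds), folds = folds),
            class = "split_plan")
}

#' Train an RBF-kernel SVM on VLAD codes
#'
#' Hyperparameters (`cost` in `{1, 10, 100}`, kernel width in
#' `{0.01, 0.1, 1, 10}` scaled by the squared median pairwise code distance)
#' are selected by an inner seeded 3-fold grid search on the training set
#' only; multiclass is handled one-vs-one (the `e1071`/libsvm default).
#'
#' @param codes Numeric matrix, one row per image.
#' @param labels Class labels (>= 2 classes).
#' @param seed Integer seed for the inner folds.
#' @param cost_grid,width_grid Hyperparameter grids.
#' @return An object of class `grassvlad_svm` wrapping the fitted
#'   `e1071::svm` model and the grid-search table.
#' @export
train_classifier <- function(codes, labels, seed = 1L,
                             cost_grid = c(1, 10, 100),
                             width_grid = c(0.01, 0.1, 1, 10)) {
  codes <- as.matrix(codes)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) {
    abort_grassvlad("need at least two classes", "grassvlad_config_error")
  }
  med2 <- stats::median(stats::dist(codes))^2
  if (!is.finite(med2) || med2 <= 0) med2 <- 1
  gammas <- width_grid / med2
  n <- nrow(codes)
  inner <- with_seed(seed, {
    fo <- integer(n)
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      fo[idx] <- rep_len(1:3, length(idx))
    }
    fo
  })
  grid <- expand.grid(cost = cost_grid, gamma = gammas)
  grid$accuracy <- NA_real_
  for (g in seq_len(nrow(grid))) {
    acc <- rep(NA_real_, 3)
    for (f in 1:3) {
      tr <- inner != f
      if (!any(!tr) || length(unique(labels[tr])) < 2L) next
      fit <- e1071::svm(codes[tr, , drop = FALSE], labels[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE)
      acc[f] <- mean(predict(fit, codes[!tr, , drop = FALSE]) == labels[!tr])
    }
    grid$accuracy[g] <- if (all(is.na(acc))) 0 else mean(acc, na.rm = TRUE)
  }
  best <- grid[which.max(grid$accuracy), ]   # ties: first (lowest cost/gamma)
  model <- e1071::svm(codes, labels, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE)
  structure(list(model = model, grid = tibble::as_tibble(grid),
                 cost = best$cost, gamma = best$gamma, levels = levels(labels)),
            class = "grassvlad_svm")
}

#' @export
predict.grassvlad_svm <- function(object, newdata, ...) {
  predict(object$model, as.matrix(newdata), ...)
}

#' @export
print.grassvlad_svm <- function(x, ...) {
  cat(sprintf("<grassvlad_svm> RBF SVM, cost = %g, gamma = %.4g, %d classes\n",
              x$cost, x$gamma, length(x$levels)))
  invisible(x)
}
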