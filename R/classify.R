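#' Collapse the twelve class labels to the detection task
#'
#' Detection is two-class: cotton lint versus everything else
#' (`"foreign_matter"`). Identification keeps all twelve labels.
#'
#' @param labels Character (or factor) labels from the study vocabulary.
#' @param vocabulary Allowed labels; defaults to the twelve study classes.
#' @param cotton_label The label treated as cotton.
#' @return Character vector of `"cotton"` / `"foreign_matter"`.
#' @export
detection_labels <- function(labels, vocabulary = names(study_classes()),
                             cotton_label = "cotton") {
  labels <- as.character(labels)
  if (length(labels) == 0) return(character(0))
  unknown <- setdiff(unique(labels), vocabulary)
  if (length(unknown) > 0) {
    stop("unknown class label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  ifelse(labels == cotton_label, "cotton", "foreign_matter")
}

# z-score with parameters from the training fold only; zero-sd columns get
# scale 1 so degenerate features pass through unchanged
fold_standardizer <- function(train_x) {
  center <- colMeans(train_x)
  scale <- apply(train_x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  function(x) sweep(sweep(x, 2, center), 2, scale, "/")
}

# classical Gaussian LDA with a ridge-shrunk pooled covariance; fallback for
# folds where MASS::lda rejects (within-group constant variables etc.)
ridge_lda_predict <- function(train_x, train_y, test_x) {
  levels <- unique(train_y)
  p <- ncol(train_x)
  n <- nrow(train_x)
  sw <- matrix(0, p, p)
  mus <- matrix(0, length(levels), p)
  priors <- numeric(length(levels))
  for (i in seq_along(levels)) {
    xi <- train_x[train_y == levels[i], , drop = FALSE]
    mus[i, ] <- colMeans(xi)
    sw <- sw + crossprod(sweep(xi, 2, mus[i, ]))
    priors[i] <- nrow(xi) / n
  }
  sw <- sw / (n - length(levels))
  sw <- sw + (1e-6 * mean(diag(sw)) + 1e-12) * diag(p)
  si <- solve(sw)
  disc <- test_x %*% si %*% t(mus) -
    matrix(0.5 * rowSums((mus %*% si) * mus), nrow(test_x), length(levels),
           byrow = TRUE) +
    matrix(log(priors), nrow(test_x), length(levels), byrow = TRUE)
  levels[max.col(disc, ties.method = "first")]
}

fit_predict <- function(train_x, train_y, test_x, classifier) {
  std <- fold_standardizer(train_x)
  train_z <- std(train_x)
  test_z <- std(test_x)
  if (classifier == "lda") {
    fit <- tryCatch(MASS::lda(train_z, grouping = factor(train_y)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("LDA covariance degenerate in a fold: using ridge-shrunk LDA",
              call. = FALSE)
      return(ridge_lda_predict(train_z, train_y, test_z))
    }
    as.character(stats::predict(fit, test_z)$class)
  } else {
    df_train <- as.data.frame(train_z)
    df_test <- as.data.frame(test_z)
    fit <- e1071::svm(x = df_train, y = factor(train_y), kernel = "linear",
                      cost = 1, scale = FALSE)
    as.character(stats::predict(fit, df_test))
  }
}

#' Leave-one-out cross-validated classification
#'
#' For each sample, a classifier is trained on the remaining `n - 1` samples
#' — feature standardization parameters estimated on the training fold only
#' — and the held-out sample is predicted. LDA uses pooled within-class
#' covariance with proportional priors (ridge-shrunk only if a fold is
#' singular); the SVM is linear-kernel, cost 1, one-vs-one for multiclass.
#' The procedure is deterministic given the table.
#'
#' @param data Data frame with a class column and feature columns.
#' @param features Feature column names to classify on.
#' @param task `"identification"` (all labels) or `"detection"` (cotton vs
#'   foreign matter via [detection_labels()]).
#' @param classifier `"lda"` or `"svm"`.
#' @param class_col Name of the class column.
#' @param id_col Optional sample-id column carried into the predictions.
#' @return An object of class `loocv_report`: `predictions` tibble
#'   (truth/predicted per sample), `accuracy`, `confusion` matrix
#'   (true x predicted), `task`, `classifier`, `features`.
#' @export
loocv <- function(data, features, task = c("identification", "detection"),
                  classifier = c("lda", "svm"), class_col = "class",
                  id_col = NULL) {
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  stopifnot(is.data.frame(data), all(features %in% names(data)))
  labels <- as.character(data[[class_col]])
  if (task == "detection") labels <- detection_labels(labels)
  levels <- sort(unique(labels))
  if (length(levels) < 2) {
    stop("LOOCV needs at least 2 classes in the task labels", call. = FALSE)
  }
  if (any(table(labels) < 2)) {
    stop("every class needs at least 2 samples for LOOCV", call. = FALSE)
  }
  x <- as.matrix(data[, features, drop = FALSE])
  n <- nrow(x)
  predicted <- character(n)
  for (i in seq_len(n)) {
    predicted[i] <- fit_predict(x[-i, , drop = FALSE], labels[-i],
                                x[i, , drop = FALSE], classifier)
  }
  confusion <- table(factor(labels, levels = levels),
                     factor(predicted, levels = levels),
                     dnn = c("truth", "predicted"))
  ids <- if (!is.null(id_col)) as.character(data[[id_col]]) else
    as.character(seq_len(n))
  structure(list(
    predictions = tibble::tibble(sample_id = ids, truth = labels,
                                 predicted = predicted),
    accuracy = mean(predicted == labels),
    confusion = confusion,
    task = task, classifier = classifier, features = features),
    class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %s / %s on %d features: accuracy %.4f (n = %d)\n",
              x$task, x$classifier, length(x$features),
              x$accuracy, nrow(x$predictions)))
  invisible(x)
}

#' @rdname loocv
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @method tidy loocv_report
#' @export
tidy.loocv_report <- function(x, ...) x$predictions

#' @rdname loocv
#' @method glance loocv_report
#' @export
glance.loocv_report <- function(x, ...) {
  tibble::tibble(task = x$task, classifier = x$classifier,
                 n_features = length(x$features),
                 n = nrow(x$predictions), accuracy = x$accuracy)
}

#' Accuracy as a function of the number of amplitude features
#'
#' The preliminary sweep that selects the amplitude feature count: LOOCV
#' accuracy using the `k` lowest-frequency amplitudes of one analysis mode,
#' for `k = 1 .. k_max` (default 15).
#'
#' @param data Feature table.
#' @param mode `"whole"`, `"rising"` or `"falling"`.
#' @param task,classifier Passed to [loocv()].
#' @param k_max Largest feature count (must not exceed the available
#'   amplitude columns).
#' @param class_col Name of the class column.
#' @return Tibble with `k` and `accuracy`.
#' @export
feature_count_sweep <- function(data, mode = "whole",
                                task = "detection", classifier = "svm",
                                k_max = 15, class_col = "class") {
  mode <- match.arg(mode, c("whole", "rising", "falling"))
  cols_all <- sprintf("amp_%s_%d", mode, seq_len(k_max))
  missing <- setdiff(cols_all, names(data))
  if (length(missing) > 0) {
    stop("k_max exceeds the available amplitude features (missing ",
         missing[1], ")", call. = FALSE)
  }
  purrr::map_dfr(seq_len(k_max), function(k) {
    rep <- loocv(data, cols_all[seq_len(k)], task = task,
                 classifier = classifier, class_col = class_col)
    tibble::tibble(k = k, accuracy = rep$accuracy)
  })
}

#' Full grid of classification trials
#'
#' The 4 x 2 x 2 grid of the study's summary table: four feature sets
#' (waveform; whole/rising/falling amplitudes `1:k`), two tasks (detection,
#' identification) and two classifiers (LDA, SVM), each scored by LOOCV
#' accuracy.
#'
#' @param data Feature table with waveform and amplitude columns.
#' @param feature_count Number of amplitude components per set (default 10,
#'   the count selected by the preliminary sweep).
#' @param classifiers,tasks Subsets of the grid to run.
#' @param class_col Name of the class column.
#' @return A tibble with `feature_set`, `n_features`, `task`, `classifier`,
#'   `accuracy` and a list-column `report` of [loocv()] results.
#' @export
run_classification_grid <- function(data, feature_count = 10,
                                    classifiers = c("lda", "svm"),
                                    tasks = c("detection", "identification"),
                                    class_col = "class") {
  sets <- c("waveform",
            sprintf("whole_amp_1_%d", feature_count),
            sprintf("rising_amp_1_%d", feature_count),
            sprintf("falling_amp_1_%d", feature_count))
  grid <- tidyr::expand_grid(feature_set = sets, task = tasks,
                             classifier = classifiers)
  res <- purrr::pmap(grid, function(feature_set, task, classifier) {
    cols <- feature_set_columns(feature_set)
    missing <- setdiff(cols, names(data))
    if (length(missing) > 0) {
      stop("feature table lacks columns for set ", feature_set, call. = FALSE)
    }
    loocv(data, cols, task = task, classifier = classifier,
          class_col = class_col)
  })
  dplyr::mutate(grid,
                n_features = lengths(purrr::map(grid$feature_set,
                                                feature_set_columns)),
                accuracy = purrr::map_dbl(res, "accuracy"),
                report = res,
                .after = "feature_set")
}

#' Pivot a classification grid to the classic summary layout
#'
#' @param grid Output of [run_classification_grid()].
#' @return Tibble with one row per feature set and one accuracy column per
#'   task/classifier combination.
#' @export
classification_table <- function(grid) {
  grid |>
    dplyr::select("feature_set", "n_features", "task", "classifier",
                  "accuracy") |>
    tidyr::pivot_wider(names_from = c("task", "classifier"),
                       values_from = "accuracy")
}
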