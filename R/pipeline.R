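#' Default per-class segmentation strategies
#'
#' Cotton lint fills the field of view and gets the fixed center window;
#' paper samples (with their marked borders) get the centered rectangle;
#' every other class is segmented by Otsu thresholding of the peak frame.
#'
#' @param class_names Character vector of class names.
#' @return Named character vector of strategies.
#' @export
default_strategies <- function(class_names) {
  s <- stats::setNames(rep("otsu", length(class_names)), class_names)
  s[class_names == "cotton"] <- "center_window"
  s[class_names == "paper"] <- "center_rect"
  s
}

#' Run the full pulsed-thermography study pipeline
#'
#' Executes the four stages end to end on synthetic data: generate ->
#' segment -> extract features -> statistics + classification. Videos are
#' rendered one at a time and discarded after feature extraction, so the
#' full 240-video study replica runs in bounded memory. Deterministic for a
#' fixed `config$seed`.
#'
#' @param config A [dataset_config()].
#' @param feature_count Amplitude components per classification feature set.
#' @param strategies Named per-class segmentation strategies; defaults to
#'   [default_strategies()].
#' @param run_stats,run_grid Toggle the statistics / classification stages.
#' @param out_dir Optional directory: writes `features.csv`,
#'   `pvalues_waveform.csv`, `pvalues_amplitude.csv`, `scores_waveform.csv`,
#'   `scores_amplitude.csv`, `classification.csv` and per-cell confusion
#'   matrices.
#' @param verbose Print one progress line per class.
#' @return An object of class `pulsetherm_run` with elements `features`
#'   (tibble, one row per sample), `pvalues` (list of
#'   [pairwise_hotelling()] results), `cda` (list of
#'   [canonical_discriminant()] results), `grid` (classification grid
#'   tibble) and `config`.
#' @export
run_pipeline <- function(config = dataset_config(), feature_count = 10,
                         strategies = NULL, run_stats = TRUE,
                         run_grid = TRUE, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "dataset_config"))
  specs <- config$class_specs
  if (is.null(strategies)) strategies <- default_strategies(names(specs))
  rows <- vector("list", length(specs) * config$samples_per_class)
  k <- 0L
  for (ci in seq_along(specs)) {
    if (verbose) message("rendering + extracting: ", specs[[ci]]$class_name)
    for (si in seq_len(config$samples_per_class)) {
      k <- k + 1L
      seed_i <- derive_seed(config$seed, ci, si)
      rendered <- render_video(specs[[ci]], config, seed_i)
      mask <- segment_video(rendered$video,
                            strategies[[specs[[ci]]$class_name]])
      feats <- extract_features(rendered$video, mask)
      rows[[k]] <- dplyr::bind_cols(
        tibble::tibble(sample_id = sprintf("%s_%02d",
                                           specs[[ci]]$class_name, si),
                       class = specs[[ci]]$class_name, seed = seed_i),
        feats)
    }
  }
  features <- dplyr::bind_rows(rows)

  amp_set <- feature_set_columns(sprintf("whole_amp_1_%d", feature_count))
  wf_set <- feature_set_columns("waveform")
  pvalues <- cda <- NULL
  if (run_stats) {
    pvalues <- list(waveform = pairwise_hotelling(features, wf_set),
                    amplitude = pairwise_hotelling(features, amp_set))
    cda <- list(waveform = canonical_discriminant(features, wf_set),
                amplitude = canonical_discriminant(features, amp_set))
  }
  grid <- if (run_grid) {
    run_classification_grid(features, feature_count = feature_count)
  }

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    if (run_stats) {
      readr::write_csv(tidy.pairwise_hotelling(pvalues$waveform),
                       file.path(out_dir, "pvalues_waveform.csv"))
      readr::write_csv(tidy.pairwise_hotelling(pvalues$amplitude),
                       file.path(out_dir, "pvalues_amplitude.csv"))
      readr::write_csv(tidy.canonical_discriminant(cda$waveform),
                       file.path(out_dir, "scores_waveform.csv"))
      readr::write_csv(tidy.canonical_discriminant(cda$amplitude),
                       file.path(out_dir, "scores_amplitude.csv"))
    }
    if (run_grid) {
      readr::write_csv(classification_table(grid),
                       file.path(out_dir, "classification.csv"))
      for (i in seq_len(nrow(grid))) {
        fn <- sprintf("confusion_%s_%s_%s.csv", grid$feature_set[i],
                      grid$task[i], grid$classifier[i])
        utils::write.csv(as.matrix(grid$report[[i]]$confusion),
                         file.path(out_dir, fn))
      }
    }
  }
  structure(list(features = features, pvalues = pvalues, cda = cda,
                 grid = grid, config = config),
            class = "pulsetherm_run")
}

#' @export
print.pulsetherm_run <- function(x, ...) {
  cat(sprintf("<pulsetherm_run> %d samples x %d classes\n",
              nrow(x$features), length(x$config$class_specs)))
  if (!is.null(x$grid)) {
    print(classification_table(x$grid))
  }
  invisible(x)
}
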