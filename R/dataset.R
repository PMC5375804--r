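#' Default calibration of the twelve study classes
#'
#' Eleven common cotton contaminants (bark, bract, brown leaves, green
#' leaves, hulls, module cover, paper, seed coats, seeds, stems, twine) plus
#' cleaned cotton lint. The thermal calibration is qualitative: brown leaves
#' are the hottest class (gain 50 degrees C above a 25 degrees C ambient,
#' peak near 75) and seed coats the coolest (gain 10, peak near 35); bract,
#' green leaves and brown leaves share overlapping parameters and form a
#' deliberately confusable triplet; bark and paper overlap; cotton heats
#' moderately but cools much more slowly than the thin botanical classes.
#' Module cover gets a strong edge-cooling factor so its edges stand out in
#' phasegrams. Only the two peak temperatures are anchored to observation;
#' all other values are plausible free choices, not measurements.
#'
#' @param frame_size Reference frame side in pixels; geometry size ranges
#'   scale linearly with it (defaults sized for 80 x 80 frames).
#' @return Named list of twelve [class_spec()] objects.
#' @export
study_classes <- function(frame_size = 80) {
  s <- frame_size
  # peak = observed lamp-off temperature under the default 5-s stimulation;
  # the equilibrium gain is back-computed from it and tau_heat
  mk <- function(name, geometry, size_frac, peak, tau_heat, tau_cool,
                 jitter = 0.10, edge = 1.5, sample_cv = 0.10) {
    gain <- (peak - 25) / (1 - exp(-5 / tau_heat))
    class_spec(name, geometry, round(size_frac * s),
               material_params(ambient_temp = 25, gain = gain,
                               tau_heat = tau_heat, tau_cool = tau_cool,
                               pixel_jitter_cv = jitter,
                               edge_cooling_factor = edge),
               sample_cv = sample_cv)
  }
  specs <- list(
    mk("bark",         "linear",      c(0.50, 0.80), 49, 2.0, 4.0),
    mk("bract",        "broad_leaf",  c(0.30, 0.50), 72, 2.0, 3.0),
    mk("brown_leaves", "broad_leaf",  c(0.30, 0.50), 75, 2.0, 3.1),
    mk("green_leaves", "broad_leaf",  c(0.30, 0.50), 70, 2.1, 3.3),
    mk("hulls",        "blob",        c(0.25, 0.40), 55, 2.5, 5.0,
       edge = 1.3, sample_cv = 0.08),
    mk("module_cover", "rectangle",   c(0.35, 0.50), 60, 1.5, 2.5,
       jitter = 0.08, edge = 2.5, sample_cv = 0.08),
    mk("paper",        "rectangle",   c(0.45, 0.60), 48, 1.6, 4.2,
       jitter = 0.06),
    mk("seed_coats",   "blob",        c(0.15, 0.25), 35, 2.0, 5.0,
       edge = 1.3),
    mk("seeds",        "blob",        c(0.15, 0.25), 40, 3.0, 6.0,
       jitter = 0.08, edge = 1.2, sample_cv = 0.08),
    mk("stems",        "linear",      c(0.50, 0.80), 45, 2.2, 4.5,
       sample_cv = 0.09),
    mk("twine",        "linear",      c(0.50, 0.80), 53, 1.8, 3.5,
       sample_cv = 0.09),
    mk("cotton",       "full_window", c(1, 1),       69, 2.2, 8.0,
       jitter = 0.05, edge = 1, sample_cv = 0.06)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "class_name"))
}

#' The bract / green-leaf / brown-leaf confusable triplet
#'
#' The three broad-thin botanical classes whose thermal parameters overlap
#' by design; identification errors are expected to concentrate among them.
#' @return Character vector of three class names.
#' @export
confusable_triplet <- function() c("bract", "green_leaves", "brown_leaves")

#' Configuration of a synthetic pulsed-thermography dataset
#'
#' Defaults replicate the study design: 12 classes x 20 samples = 240
#' videos, 1/5/10/1 s protocol at 30 fps, camera noise at the NETD of
#' 0.045 degrees C, 80 x 80 frames (a memory-friendly stand-in for the
#' camera's 320 x 240 sensor; geometry scales with frame size).
#'
#' @param class_specs List of [class_spec()] objects with unique names.
#' @param samples_per_class Samples (videos) per class, >= 1.
#' @param protocol An [acquisition_protocol()].
#' @param frame_height,frame_width Frame dimensions in pixels.
#' @param noise_sd Camera noise sd per pixel per frame, degrees C.
#' @param background_temp Reflective-stage background temperature, degrees C.
#' @param seed Integer master seed; per-sample streams are derived from it.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(class_specs = study_classes(),
                           samples_per_class = 20,
                           protocol = acquisition_protocol(),
                           frame_height = 80, frame_width = 80,
                           noise_sd = 0.045, background_temp = 25,
                           seed = 1L) {
  stopifnot(length(class_specs) >= 1,
            all(vapply(class_specs, inherits, TRUE, "class_spec")))
  names <- vapply(class_specs, `[[`, "", "class_name")
  if (anyDuplicated(names)) {
    stop("duplicate class names in dataset config", call. = FALSE)
  }
  if (samples_per_class < 1) stop("samples_per_class must be >= 1", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  stopifnot(inherits(protocol, "acquisition_protocol"),
            frame_height >= 1, frame_width >= 1)
  structure(list(class_specs = stats::setNames(class_specs, names),
                 samples_per_class = as.integer(samples_per_class),
                 protocol = protocol,
                 frame_height = as.integer(frame_height),
                 frame_width = as.integer(frame_width),
                 noise_sd = noise_sd, background_temp = background_temp,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

# Lehmer-step integer hash: per-sample streams survive reordering of the
# generation loop. Kept below 2^31.
derive_seed <- function(seed, class_index, sample_index) {
  m <- 2147483647
  a <- (as.numeric(seed) %% m + m) %% m
  a <- (a * 48271) %% m
  a <- ((a + class_index) * 48271) %% m
  a <- ((a + sample_index) * 48271) %% m
  as.integer(a)
}

#' Generate a labeled synthetic dataset
#'
#' Renders `|classes| * samples_per_class` videos with deterministic
#' per-sample seeds derived from `config$seed`. With `out_dir` set, each
#' video is written as a PTIV container and a manifest tibble
#' (`sample_id`, `class`, `seed`, `file`) is returned (and saved as
#' `manifest.csv`); otherwise the rendered videos and ground-truth masks are
#' returned in memory.
#'
#' @param config A [dataset_config()].
#' @param out_dir Optional output directory for PTIV files + manifest.
#' @return With `out_dir`: the manifest tibble. Without: a list with
#'   `samples` (list of `list(video, mask, class_name, sample_id)`) and
#'   `manifest`.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "dataset_config"))
  specs <- config$class_specs
  rows <- list(); samples <- list()
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  k <- 0L
  for (ci in seq_along(specs)) {
    for (si in seq_len(config$samples_per_class)) {
      k <- k + 1L
      seed_i <- derive_seed(config$seed, ci, si)
      sample_id <- sprintf("%s_%02d", specs[[ci]]$class_name, si)
      rendered <- render_video(specs[[ci]], config, seed_i)
      file_i <- NA_character_
      if (write_out) {
        file_i <- file.path(out_dir, paste0(sample_id, ".ptiv"))
        write_thermal_video(rendered$video, file_i)
      } else {
        samples[[k]] <- list(video = rendered$video, mask = rendered$mask,
                             class_name = specs[[ci]]$class_name,
                             sample_id = sample_id)
      }
      rows[[k]] <- tibble::tibble(sample_id = sample_id,
                                  class = specs[[ci]]$class_name,
                                  seed = seed_i, file = file_i)
    }
  }
  manifest <- dplyr::bind_rows(rows)
  if (write_out) {
    readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
    return(manifest)
  }
  list(samples = samples, manifest = manifest)
}
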