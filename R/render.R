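#' Specification of one sample class for the synthetic generator
#'
#' Couples a class label with a spatial geometry family and lumped thermal
#' parameters. Geometries follow the morphology of the real contaminant
#' classes: leaves and bract are broad and thin, bark/stem/twine are linear,
#' seeds and seed coats are compact blobs, cotton lint fills the imaging
#' window and paper scraps are rectangles.
#'
#' @param class_name Class label (unique within a dataset).
#' @param geometry One of `"broad_leaf"`, `"linear"`, `"blob"`,
#'   `"full_window"`, `"rectangle"`.
#' @param size_range Length-2 numeric, min and max characteristic size in
#'   pixels (major-axis length for leaves/linear shapes, diameter for blobs,
#'   side length for rectangles). Ignored for `full_window`.
#' @param thermal_params A [material_params()].
#' @param sample_cv Coefficient of variation of per-sample lognormal
#'   multipliers applied to the gain and time constants — the
#'   replicate-to-replicate biological variation within a class.
#' @return An object of class `class_spec`.
#' @export
class_spec <- function(class_name, geometry, size_range, thermal_params,
                       sample_cv = 0.08) {
  geometry <- match.arg(geometry,
                        c("broad_leaf", "linear", "blob", "full_window",
                          "rectangle"))
  stopifnot(inherits(thermal_params, "material_params"))
  if (geometry != "full_window") {
    stopifnot(length(size_range) == 2, size_range[1] <= size_range[2],
              size_range[1] >= 1)
  }
  if (sample_cv < 0) stop("sample_cv must be >= 0", call. = FALSE)
  structure(list(class_name = class_name, geometry = geometry,
                 size_range = size_range, thermal_params = thermal_params,
                 sample_cv = sample_cv),
            class = "class_spec")
}

# ---- geometry rasterizers (draw from the active RNG stream) ----

draw_geometry_mask <- function(geometry, size_range, h, w) {
  if (geometry == "full_window") return(matrix(TRUE, h, w))
  size <- stats::runif(1, size_range[1], size_range[2])
  if (size > min(h, w)) {
    stop("sample geometry larger than the frame", call. = FALSE)
  }
  if (geometry == "rectangle") {
    # rectangles (paper, module cover) are staged centered, as in protocols
    # that rely on a fixed center region for segmentation
    cy <- (h + 1) / 2
    cx <- (w + 1) / 2
  } else {
    # center jittered within the middle half of the frame, clamped so the
    # shape stays inside
    margin <- size / 2 + 1
    cy <- stats::runif(1, max(margin, h / 4), min(h - margin, 3 * h / 4))
    cx <- stats::runif(1, max(margin, w / 4), min(w - margin, 3 * w / 4))
  }
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - cy
  dx <- cols - cx
  mask <- switch(
    geometry,
    broad_leaf = {
      theta <- stats::runif(1, 0, pi)
      a <- size / 2
      b <- a * stats::runif(1, 0.45, 0.75)
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      (u / a)^2 + (v / b)^2 <= 1
    },
    linear = {
      theta <- stats::runif(1, 0, pi)
      width <- stats::runif(1, 1.5, 2.5)
      u <- dx * cos(theta) + dy * sin(theta)
      v <- -dx * sin(theta) + dy * cos(theta)
      abs(u) <= size / 2 & abs(v) <= width
    },
    blob = dy^2 + dx^2 <= (size / 2)^2,
    rectangle = {
      half_h <- size / 2
      half_w <- size / 2 * stats::runif(1, 0.7, 1)
      abs(dy) <= half_h & abs(dx) <= half_w
    })
  if (!any(mask)) mask[round(cy), round(cx)] <- TRUE
  mask
}

# pixels of mask with at least one 4-neighbor outside the mask (or on the
# frame border)
mask_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  interior <- pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
  mask & !interior
}

#' Render one synthetic thermal video
#'
#' Spatializes the lumped-capacitance trace over a randomly drawn geometry
#' mask. Sample pixels follow the class's thermal model with per-sample
#' lognormal variation of the parameters (`sample_cv`), per-pixel gain
#' jitter (`pixel_jitter_cv`) and accelerated cooling at mask-boundary
#' pixels (`edge_cooling_factor`). Background pixels stay at
#' `background_temp` (the reflective steel stage barely heats). i.i.d.
#' Gaussian camera noise with sd `noise_sd` is added everywhere. Fully
#' deterministic for a fixed `sample_seed`.
#'
#' @param spec A [class_spec()].
#' @param config A [dataset_config()].
#' @param sample_seed Integer seed for this sample's RNG stream.
#' @return A list with `video` (a [thermal_video()]) and `mask` (logical
#'   `H x W` ground-truth sample mask).
#' @export
render_video <- function(spec, config, sample_seed) {
  stopifnot(inherits(spec, "class_spec"), inherits(config, "dataset_config"))
  h <- config$frame_height; w <- config$frame_width
  p <- spec$thermal_params
  idx <- protocol_frame_indices(config$protocol)
  f <- idx$total
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(sample_seed %% 2147483647))

  # per-sample biological variation
  mult <- function(cv) if (cv > 0) exp(stats::rnorm(1, 0, cv)) else 1
  gain_s <- p$gain * mult(spec$sample_cv)
  tau_h_s <- p$tau_heat * mult(spec$sample_cv / 2)
  tau_c_s <- p$tau_cool * mult(spec$sample_cv)

  mask <- draw_geometry_mask(spec$geometry, spec$size_range, h, w)
  px <- which(mask)
  n_px <- length(px)

  gain_px <- gain_s * pmax(0, 1 + p$pixel_jitter_cv * stats::rnorm(n_px))
  tau_c_px <- rep(tau_c_s, n_px)
  on_edge <- mask_boundary(mask)[px]
  tau_c_px[on_edge] <- tau_c_s / p$edge_cooling_factor

  times <- (seq_len(f) - 1) / config$protocol$fps
  temps <- lumped_temperature(times,
                              t_on = config$protocol$front_buffer_s,
                              t_off = config$protocol$front_buffer_s +
                                config$protocol$heat_s,
                              ambient = p$ambient_temp,
                              gain = gain_px, tau_heat = tau_h_s,
                              tau_cool = tau_c_px)

  frames <- array(config$background_temp, dim = c(h, w, f))
  frames[rep(px, f) + (rep(seq_len(f), each = n_px) - 1L) * (h * w)] <-
    as.numeric(temps)
  if (config$noise_sd > 0) {
    frames <- frames + stats::rnorm(length(frames), 0, config$noise_sd)
  }
  video <- thermal_video(frames, fps = config$protocol$fps,
                         metadata = list(class = spec$class_name,
                                         seed = sample_seed,
                                         protocol = unclass(config$protocol)))
  list(video = video, mask = mask)
}
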