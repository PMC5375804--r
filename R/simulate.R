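#' Lumped-capacitance thermal parameters for one material class
#'
#' Parametric stand-in for the material properties that shape a sample's
#' thermal response under a radiative pulse (thermal diffusivity, heat
#' capacity, geometry). The model is zero-dimensional: during stimulation the
#' temperature rises exponentially toward an asymptote `ambient_temp + gain`
#' with time constant `tau_heat`; after lamp-off it relaxes exponentially
#' toward ambient with time constant `tau_cool`.
#'
#' @param ambient_temp Resting/ambient temperature, degrees C.
#' @param gain Asymptotic temperature rise under the lamp, degrees C (>= 0).
#' @param tau_heat Heating time constant, seconds (> 0).
#' @param tau_cool Cooling time constant, seconds (> 0).
#' @param pixel_jitter_cv Coefficient of variation of the per-pixel gain
#'   (spatial inhomogeneity of absorption), dimensionless (>= 0).
#' @param edge_cooling_factor Multiplier on `1/tau_cool` at mask-boundary
#'   pixels (>= 1); models faster heat loss at sample edges.
#' @return An object of class `material_params`.
#' @export
material_params <- function(ambient_temp = 25, gain = 30, tau_heat = 2,
                            tau_cool = 4, pixel_jitter_cv = 0,
                            edge_cooling_factor = 1) {
  if (gain < 0) stop("gain must be non-negative", call. = FALSE)
  if (tau_heat <= 0 || tau_cool <= 0) {
    stop("time constants must be strictly positive", call. = FALSE)
  }
  if (pixel_jitter_cv < 0) stop("pixel_jitter_cv must be >= 0", call. = FALSE)
  if (edge_cooling_factor < 1) {
    stop("edge_cooling_factor must be >= 1", call. = FALSE)
  }
  structure(list(ambient_temp = ambient_temp, gain = gain,
                 tau_heat = tau_heat, tau_cool = tau_cool,
                 pixel_jitter_cv = pixel_jitter_cv,
                 edge_cooling_factor = edge_cooling_factor),
            class = "material_params")
}

# Closed-form lumped-capacitance temperature at frame times.
# t_on/t_off in seconds; gain and tau_cool may be per-pixel vectors, in which
# case a (pixels x frames) matrix is returned.
lumped_temperature <- function(times, t_on, t_off, ambient, gain,
                               tau_heat, tau_cool) {
  n_px <- max(length(gain), length(tau_cool))
  gain <- rep_len(gain, n_px)
  tau_cool <- rep_len(tau_cool, n_px)
  out <- matrix(ambient, nrow = n_px, ncol = length(times))
  heating <- times >= t_on & times < t_off
  cooling <- times >= t_off
  if (any(heating)) {
    rise <- 1 - exp(-(times[heating] - t_on) / tau_heat)
    out[, heating] <- ambient + gain %o% rise
  }
  if (any(cooling)) {
    peak_rise <- gain * (1 - exp(-(t_off - t_on) / tau_heat))
    decay <- exp(-outer(1 / tau_cool, times[cooling] - t_off))
    out[, cooling] <- ambient + peak_rise * decay
  }
  out
}

#' Simulate a noiseless mean thermal trace
#'
#' Evaluates the lumped-capacitance model at every frame time of the
#' protocol. The front buffer rests at ambient; heating frames follow the
#' exponential rise; the peak lands exactly on the lamp-off frame (the first
#' cooling frame); cooling and the rear buffer relax exponentially toward
#' ambient.
#'
#' @param params A [material_params()].
#' @param protocol An [acquisition_protocol()].
#' @return A `temperature_trace`: per-frame temperatures (degrees C) with the
#'   protocol attached, untrimmed.
#' @examples
#' tr <- simulate_trace(material_params(gain = 50, tau_heat = 2),
#'                      acquisition_protocol())
#' max(tr$values)  # peak at lamp-off: 25 + 50 * (1 - exp(-2.5))
#' @export
simulate_trace <- function(params, protocol) {
  stopifnot(inherits(params, "material_params"),
            inherits(protocol, "acquisition_protocol"))
  idx <- protocol_frame_indices(protocol)
  times <- (seq_len(idx$total) - 1) / protocol$fps
  vals <- lumped_temperature(times,
                             t_on = protocol$front_buffer_s,
                             t_off = protocol$front_buffer_s + protocol$heat_s,
                             ambient = params$ambient_temp,
                             gain = params$gain,
                             tau_heat = params$tau_heat,
                             tau_cool = params$tau_cool)
  temperature_trace(as.numeric(vals), protocol, trimmed = FALSE)
}

#' Per-frame temperature trace
#'
#' Container for a per-frame mean temperature signal tied to an acquisition
#' protocol. `trimmed = TRUE` marks a trace whose buffers have been removed
#' (heating + cooling frames only); split rising/falling parts carry a
#' `part` tag.
#'
#' @param values Numeric per-frame temperatures, degrees C.
#' @param protocol The [acquisition_protocol()] the trace was acquired under.
#' @param trimmed Logical; buffers removed?
#' @param part One of `"full"`, `"rising"`, `"falling"`.
#' @return An object of class `temperature_trace`.
#' @export
temperature_trace <- function(values, protocol, trimmed = FALSE,
                              part = "full") {
  stopifnot(is.numeric(values), inherits(protocol, "acquisition_protocol"))
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  idx <- protocol_frame_indices(protocol)
  expected <- if (!trimmed) idx$total else switch(
    part,
    full = idx$cutoff - idx$lamp_on,
    rising = idx$lamp_off - idx$lamp_on,
    falling = idx$cutoff - idx$lamp_off,
    stop("unknown trace part: ", part, call. = FALSE))
  if (length(values) != expected) {
    stop(sprintf("trace length %d does not match protocol (expected %d)",
                 length(values), expected), call. = FALSE)
  }
  structure(list(values = values, fps = protocol$fps, protocol = protocol,
                 trimmed = trimmed, part = part),
            class = "temperature_trace")
}

#' @export
print.temperature_trace <- function(x, ...) {
  cat(sprintf("<temperature_trace> %d frames @ %g fps (%s%s)\n",
              length(x$values), x$fps, x$part,
              if (x$trimmed) ", trimmed" else ""))
  invisible(x)
}

#' @export
length.temperature_trace <- function(x) length(x$values)

#' @rdname temperature_trace
#' @param x A `temperature_trace`.
#' @param ... Unused.
#' @method tidy temperature_trace
#' @export
tidy.temperature_trace <- function(x, ...) {
  tibble::tibble(frame = seq_along(x$values) - 1L,
                 time_s = (seq_along(x$values) - 1L) / x$fps,
                 temperature = x$values)
}
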