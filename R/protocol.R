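#' Acquisition protocol for a pulsed-thermography video
#'
#' Fixes the timing of the four phases of an acquisition — a resting front
#' buffer, radiative heating (lamps on), cooling (lamps off), and a rear
#' buffer — together with the frame rate. All frame-index arithmetic in the
#' package derives from this object. Defaults match the study design:
#' 1 s front buffer, 5 s heating, 10 s cooling, 1 s rear buffer at 30 fps.
#'
#' @param front_buffer_s Seconds of resting video before lamp activation (>= 0).
#' @param heat_s Seconds of thermal stimulation (> 0).
#' @param cool_s Seconds of cooling after lamp deactivation (> 0).
#' @param rear_buffer_s Seconds of video after the data cutoff (>= 0).
#' @param fps Frame rate in frames per second (> 0). Every phase duration
#'   multiplied by `fps` must give a whole number of frames.
#'
#' @return An object of class `acquisition_protocol`.
#' @examples
#' p <- acquisition_protocol()
#' protocol_frame_indices(p)
#' @export
acquisition_protocol <- function(front_buffer_s = 1, heat_s = 5, cool_s = 10,
                                 rear_buffer_s = 1, fps = 30) {
  stopifnot(is.numeric(front_buffer_s), is.numeric(heat_s), is.numeric(cool_s),
            is.numeric(rear_buffer_s), is.numeric(fps))
  if (heat_s <= 0 || cool_s <= 0) {
    stop("heating and cooling durations must be strictly positive", call. = FALSE)
  }
  if (front_buffer_s < 0 || rear_buffer_s < 0) {
    stop("buffer durations must be non-negative", call. = FALSE)
  }
  if (fps <= 0) stop("fps must be positive", call. = FALSE)
  durs <- c(front_buffer_s, heat_s, cool_s, rear_buffer_s)
  frames <- durs * fps
  if (any(abs(frames - round(frames)) > 1e-9)) {
    stop("phase durations must give whole frame counts at the given fps",
         call. = FALSE)
  }
  structure(
    list(front_buffer_s = front_buffer_s, heat_s = heat_s, cool_s = cool_s,
         rear_buffer_s = rear_buffer_s, fps = fps),
    class = "acquisition_protocol"
  )
}

#' Frame indices of the protocol phase boundaries
#'
#' Converts phase durations to 0-based frame indices. Phases are half-open
#' intervals `[start, end)`: the front buffer occupies
#' `[0, lamp_on)`, heating `[lamp_on, lamp_off)`, cooling
#' `[lamp_off, cutoff)` and the rear buffer `[cutoff, total)`. A boundary
#' frame belongs to the later phase, so the `lamp_off` frame is the first
#' cooling frame and carries the peak temperature of a noiseless trace.
#'
#' @param protocol An [acquisition_protocol()].
#' @return A named list with integer entries `lamp_on`, `lamp_off`,
#'   `cutoff` and `total` (total frame count).
#' @examples
#' protocol_frame_indices(acquisition_protocol()) # 30, 180, 480, 510
#' @export
protocol_frame_indices <- function(protocol) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  fps <- protocol$fps
  lamp_on <- as.integer(round(protocol$front_buffer_s * fps))
  lamp_off <- lamp_on + as.integer(round(protocol$heat_s * fps))
  cutoff <- lamp_off + as.integer(round(protocol$cool_s * fps))
  total <- cutoff + as.integer(round(protocol$rear_buffer_s * fps))
  list(lamp_on = lamp_on, lamp_off = lamp_off, cutoff = cutoff, total = total)
}

#' @export
print.acquisition_protocol <- function(x, ...) {
  idx <- protocol_frame_indices(x)
  cat(sprintf(
    "<acquisition_protocol> %g s buffer | %g s heat | %g s cool | %g s buffer @ %g fps (%d frames)\n",
    x$front_buffer_s, x$heat_s, x$cool_s, x$rear_buffer_s, x$fps, idx$total))
  invisible(x)
}
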