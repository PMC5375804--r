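#' Mean temperature trace of the masked sample pixels
#'
#' The per-frame arithmetic mean temperature over the sample's pixels — the
#' input signal for both waveform and Fourier feature extraction.
#'
#' @param video A [thermal_video()].
#' @param mask A `sample_mask` or logical matrix matching the frame size.
#' @return An untrimmed [temperature_trace()].
#' @export
mean_trace <- function(video, mask) {
  stopifnot(inherits(video, "thermal_video"))
  m <- if (inherits(mask, "sample_mask")) mask$mask else mask
  d <- dim(video$frames)
  stopifnot(is.logical(m), all(dim(m) == d[1:2]))
  if (!any(m)) stop("empty mask", call. = FALSE)
  px <- which(m)
  vals <- colMeans(matrix(video$frames, d[1] * d[2], d[3])[px, , drop = FALSE])
  proto <- video$metadata$protocol
  protocol <- if (!is.null(proto)) {
    acquisition_protocol(proto$front_buffer_s, proto$heat_s, proto$cool_s,
                         proto$rear_buffer_s, proto$fps)
  } else {
    stop("video metadata carries no acquisition protocol; construct the trace with temperature_trace()",
         call. = FALSE)
  }
  temperature_trace(vals, protocol, trimmed = FALSE)
}

#' Remove the front and rear buffers from a trace
#'
#' Keeps the frames `[lamp_on, cutoff)` — the rising and falling portions
#' only. Under the default 1/5/10/1 s protocol at 30 fps this leaves
#' precisely 450 frames.
#'
#' @param trace An untrimmed [temperature_trace()].
#' @return The trimmed trace.
#' @export
trim_buffers <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (trace$trimmed) stop("trace is already trimmed", call. = FALSE)
  idx <- protocol_frame_indices(trace$protocol)
  vals <- trace$values[(idx$lamp_on + 1):idx$cutoff]
  temperature_trace(vals, trace$protocol, trimmed = TRUE, part = "full")
}

#' Waveform features: temperature gains after heating and after cooling
#'
#' `peak_minus_rest` is the mean temperature at lamp deactivation minus the
#' mean temperature at lamp activation (the gain after heating);
#' `final_minus_rest` subtracts the resting temperature from the temperature
#' at the data cutoff (the net gain after heating and cooling). Reads are
#' single frames at the protocol's phase boundaries, optionally smoothed
#' over `+/- smooth` frames.
#'
#' @param trace An untrimmed [temperature_trace()] (the rest read needs the
#'   front-buffer frame; with a zero front buffer `lamp_on = 0` still works).
#' @param smooth Half-width in frames of an optional mean smoothing window
#'   around each read (default 0: single-frame reads).
#' @return A one-row tibble with `peak_minus_rest` and `final_minus_rest`
#'   (degrees C).
#' @export
waveform_features <- function(trace, smooth = 0) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (trace$trimmed) stop("waveform features need the untrimmed trace", call. = FALSE)
  idx <- protocol_frame_indices(trace$protocol)
  n <- length(trace$values)
  read_at <- function(i0) {
    i0 <- min(i0, n - 1L)   # cutoff frame absent when the rear buffer is 0
    lo <- max(0L, i0 - smooth); hi <- min(n - 1L, i0 + smooth)
    mean(trace$values[(lo + 1):(hi + 1)])
  }
  rest <- read_at(idx$lamp_on)
  peak <- read_at(idx$lamp_off)
  final <- read_at(idx$cutoff)
  tibble::tibble(peak_minus_rest = peak - rest,
                 final_minus_rest = final - rest)
}

#' Split a trimmed trace into its rising and falling portions
#'
#' Rising = the heating frames (first `heat_s * fps` of the trimmed trace,
#' 150 by default); falling = the cooling remainder (300 by default). Their
#' concatenation reproduces the input exactly.
#'
#' @param trace A trimmed [temperature_trace()] (`part = "full"`).
#' @return List with `rising` and `falling` traces.
#' @export
split_trace <- function(trace) {
  stopifnot(inherits(trace, "temperature_trace"))
  if (!trace$trimmed || trace$part != "full") {
    stop("split_trace needs the trimmed full trace", call. = FALSE)
  }
  n_rise <- as.integer(round(trace$protocol$heat_s * trace$fps))
  list(
    rising = temperature_trace(trace$values[seq_len(n_rise)], trace$protocol,
                               trimmed = TRUE, part = "rising"),
    falling = temperature_trace(trace$values[-seq_len(n_rise)], trace$protocol,
                                trimmed = TRUE, part = "falling")
  )
}

#' Pulse-phase (Fourier) features of a thermal trace
#'
#' Discrete Fourier transform of the N-frame trace. Components at and above
#' the Nyquist frequency are aliased copies carrying no new information, so
#' only indices `0 .. N/2 - 1` are retained (frequencies `k * fps / N`).
#' Amplitudes are the raw (unnormalized) phasor moduli; phases are phasor
#' angles in `(-pi, pi]` for indices `1 .. N/2 - 1` — the 0-Hz phase is
#' identically zero and is discarded. For the default protocol this yields
#' 225 amplitudes and 224 phases for the whole trace, 75/74 for the rising
#' part and 150/149 for the falling part.
#'
#' @param trace A trimmed [temperature_trace()]: the whole signal
#'   (`mode = "whole"`) or a part from [split_trace()] (`"rising"`,
#'   `"falling"`). Length must be even.
#' @param mode Analysis mode tag; must agree with the trace's `part`.
#' @return An object of class `spectral_features` with `mode`,
#'   `frequencies` (Hz), `amplitudes` and `phases` (radians).
#' @export
spectral_features <- function(trace, mode = c("whole", "rising", "falling")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace, "temperature_trace"))
  if (!trace$trimmed) stop("spectral features need a trimmed trace", call. = FALSE)
  expected_part <- if (mode == "whole") "full" else mode
  if (trace$part != expected_part) {
    stop(sprintf("mode '%s' expects the %s trace, got '%s'",
                 mode, expected_part, trace$part), call. = FALSE)
  }
  n <- length(trace$values)
  if (n %% 2L != 0L) {
    stop("odd trace length: the retained-component convention requires even N",
         call. = FALSE)
  }
  spectrum <- stats::fft(trace$values)
  keep <- seq_len(n %/% 2L)           # indices 0 .. N/2 - 1
  structure(list(mode = mode,
                 n = n,
                 frequencies = (keep - 1) * trace$fps / n,
                 amplitudes = Mod(spectrum[keep]),
                 phases = Arg(spectrum[keep[-1]])),
            class = "spectral_features")
}

#' @export
print.spectral_features <- function(x, ...) {
  cat(sprintf("<spectral_features> mode=%s: %d amplitudes, %d phases (0-%.3g Hz)\n",
              x$mode, length(x$amplitudes), length(x$phases),
              max(x$frequencies)))
  invisible(x)
}

#' @rdname spectral_features
#' @param x A `spectral_features` object.
#' @param ... Unused.
#' @method tidy spectral_features
#' @export
tidy.spectral_features <- function(x, ...) {
  tibble::tibble(mode = x$mode,
                 component = seq_along(x$amplitudes),
                 frequency = x$frequencies,
                 amplitude = x$amplitudes,
                 phase = c(NA_real_, x$phases))
}

#' The k lowest-frequency amplitudes
#'
#' Cumulative amplitude feature sets ("amp 1:k") used in the preliminary
#' feature-count sweep and the classification trials.
#'
#' @param features A [spectral_features()] object.
#' @param k Number of components, `1 <= k <=` retained count.
#' @return Numeric vector of the first `k` amplitudes in increasing
#'   frequency order.
#' @export
amplitude_subset <- function(features, k) {
  stopifnot(inherits(features, "spectral_features"))
  if (k < 1 || k > length(features$amplitudes)) {
    stop(sprintf("k must lie in 1..%d", length(features$amplitudes)),
         call. = FALSE)
  }
  features$amplitudes[seq_len(k)]
}

#' Phasegram and ampligram of a video at one frequency component
#'
#' Per-pixel temporal DFT of the trimmed video: the ampligram maps each
#' pixel to its amplitude at the requested component, the phasegram to its
#' phase. Pixels outside the mask are set to `NA`. Ampligrams largely mirror
#' peak temperature; phasegrams expose heating/cooling dynamics, e.g.
#' edge-cooled rims of a sample differ in phase from its interior.
#'
#' @param video A [thermal_video()] covering the analysis window (it is
#'   trimmed internally using its protocol metadata if untrimmed).
#' @param mask A `sample_mask` or logical matrix; `NULL` for all pixels.
#' @param component_index 0-based retained component index
#'   (`0 .. N/2 - 1`; 0 = 0 Hz). Phases are undefined at 0.
#' @return List with matrices `ampligram` and `phasegram` (the phasegram is
#'   all-`NA` at component 0) and the component `frequency` in Hz.
#' @export
pixelwise_spectra <- function(video, mask = NULL, component_index) {
  stopifnot(inherits(video, "thermal_video"))
  d <- dim(video$frames)
  frames <- matrix(video$frames, d[1] * d[2], d[3])
  proto <- video$metadata$protocol
  if (!is.null(proto)) {
    protocol <- acquisition_protocol(proto$front_buffer_s, proto$heat_s,
                                     proto$cool_s, proto$rear_buffer_s,
                                     proto$fps)
    idx <- protocol_frame_indices(protocol)
    if (d[3] == idx$total) {
      frames <- frames[, (idx$lamp_on + 1):idx$cutoff, drop = FALSE]
    }
  }
  n <- ncol(frames)
  n_keep <- n %/% 2L
  if (component_index < 0 || component_index >= n_keep) {
    stop(sprintf("component_index must lie in 0..%d", n_keep - 1L),
         call. = FALSE)
  }
  m <- if (is.null(mask)) matrix(TRUE, d[1], d[2]) else {
    if (inherits(mask, "sample_mask")) mask$mask else mask
  }
  px <- which(m)
  # DFT at a single frequency: project onto the complex exponential
  k <- component_index
  phasor <- exp(-2i * pi * k * (seq_len(n) - 1) / n)
  coef <- frames[px, , drop = FALSE] %*% phasor
  amp <- matrix(NA_real_, d[1], d[2])
  pha <- matrix(NA_real_, d[1], d[2])
  amp[px] <- Mod(coef)
  if (k > 0) pha[px] <- Arg(coef)
  list(ampligram = amp, phasegram = pha, frequency = k * video$fps / n)
}

#' Full feature vector for one segmented video
#'
#' Computes the mean trace, trims the buffers, and extracts the waveform
#' features plus whole / rising / falling spectral features. Columns follow
#' the feature-table convention: `wf_peak_minus_rest`,
#' `wf_final_minus_rest`, `amp_<mode>_<k>` and `phase_<mode>_<k>`, with `k`
#' the 1-based component rank in increasing frequency (so `amp_whole_1` is
#' the 0-Hz amplitude and phases start at `k = 2`).
#'
#' @param video A [thermal_video()].
#' @param mask A `sample_mask` or logical matrix.
#' @param include_phases Store phase columns too? (Phases are extracted but
#'   excluded from default classification.)
#' @return A one-row wide tibble.
#' @export
extract_features <- function(video, mask, include_phases = TRUE) {
  trace <- mean_trace(video, mask)
  wf <- waveform_features(trace)
  trimmed <- trim_buffers(trace)
  parts <- split_trace(trimmed)
  specs <- list(whole = spectral_features(trimmed, "whole"),
                rising = spectral_features(parts$rising, "rising"),
                falling = spectral_features(parts$falling, "falling"))
  cols <- list(wf_peak_minus_rest = wf$peak_minus_rest,
               wf_final_minus_rest = wf$final_minus_rest)
  for (mode in names(specs)) {
    sp <- specs[[mode]]
    amp <- as.list(sp$amplitudes)
    names(amp) <- sprintf("amp_%s_%d", mode, seq_along(sp$amplitudes))
    cols <- c(cols, amp)
    if (include_phases) {
      ph <- as.list(sp$phases)
      names(ph) <- sprintf("phase_%s_%d", mode, seq_along(sp$phases) + 1L)
      cols <- c(cols, ph)
    }
  }
  tibble::as_tibble(cols)
}

#' Column names of a named feature set
#'
#' Maps the feature-set names used in the classification trials to feature
#'-table columns: `"waveform"` (2 columns), `"whole_amp_1_k"`,
#' `"rising_amp_1_k"`, `"falling_amp_1_k"` (k lowest-frequency amplitudes,
#' default k = 10).
#'
#' @param name Feature-set name, e.g. `"whole_amp_1_10"`.
#' @return Character vector of column names.
#' @export
feature_set_columns <- function(name) {
  if (name == "waveform") {
    return(c("wf_peak_minus_rest", "wf_final_minus_rest"))
  }
  m <- regmatches(name, regexec("^(whole|rising|falling)_amp_1_(\\d+)$", name))[[1]]
  if (length(m) == 0) stop("unknown feature set: ", name, call. = FALSE)
  sprintf("amp_%s_%d", m[2], seq_len(as.integer(m[3])))
}
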