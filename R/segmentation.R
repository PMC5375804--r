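#' Index of the frame of peak temperature
#'
#' The frame whose spatial mean temperature is maximal — the natural frame
#' to segment on, since sample/background contrast peaks at lamp-off. The
#' spatial mean (rather than the single hottest pixel) is robust to isolated
#' noisy pixels. Ties break to the earliest frame.
#'
#' @param video A [thermal_video()].
#' @return 0-based frame index.
#' @export
peak_frame_index <- function(video) {
  stopifnot(inherits(video, "thermal_video"))
  d <- dim(video$frames)
  means <- colMeans(matrix(video$frames, d[1] * d[2], d[3]))
  which.max(means) - 1L
}

sample_mask <- function(mask, strategy, threshold_used = NULL) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) stop("segmentation produced an empty mask", call. = FALSE)
  structure(list(mask = mask, strategy = strategy,
                 threshold_used = threshold_used),
            class = "sample_mask")
}

#' @export
print.sample_mask <- function(x, ...) {
  cat(sprintf("<sample_mask> %d x %d, %d px, strategy=%s%s\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask), x$strategy,
              if (!is.null(x$threshold_used))
                sprintf(", threshold=%.3f", x$threshold_used) else ""))
  invisible(x)
}

#' Otsu threshold of a temperature frame
#'
#' Builds a 256-bin histogram spanning the frame's min-max range and returns
#' the bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2`. Ties break to the lowest threshold.
#'
#' @param frame Numeric matrix of temperatures.
#' @param n_bins Number of histogram bins.
#' @return The threshold (degrees C).
#' @export
otsu_threshold <- function(frame, n_bins = 256) {
  x <- as.numeric(frame)
  r <- range(x)
  if (r[1] == r[2]) {
    stop("constant frame: Otsu thresholding is degenerate; supply a manual threshold",
         call. = FALSE)
  }
  edges <- seq(r[1], r[2], length.out = n_bins + 1)
  bin <- findInterval(x, edges, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  w0 <- cumsum(counts)[-n_bins]
  mu0_sum <- cumsum(counts * centers)[-n_bins]
  total <- length(x)
  mu_total <- sum(counts * centers)
  w1 <- total - w0
  between <- ifelse(w0 == 0 | w1 == 0, -Inf,
                    w0 * w1 * (mu0_sum / w0 - (mu_total - mu0_sum) / w1)^2)
  edges[which.max(between) + 1L]
}

#' Otsu (or manual-threshold) segmentation of one frame
#'
#' Foreground is above-threshold: samples absorb the lamp radiation while
#' the reflective steel stage stays cool. With `manual_threshold` set the
#' Otsu search is skipped and the given cut is used — the per-sample manual
#' override for frames Otsu mis-segments.
#'
#' @param frame Numeric matrix of temperatures (typically the peak frame).
#' @param manual_threshold Optional threshold in degrees C.
#' @param foreground `"above"` (default) or `"below"` the threshold.
#' @return A `sample_mask` with the threshold used.
#' @export
otsu_mask <- function(frame, manual_threshold = NULL, foreground = "above") {
  foreground <- match.arg(foreground, c("above", "below"))
  thr <- if (is.null(manual_threshold)) otsu_threshold(frame) else manual_threshold
  mask <- if (foreground == "above") frame > thr else frame < thr
  strategy <- if (is.null(manual_threshold)) "otsu" else "manual_threshold"
  sample_mask(mask, strategy, threshold_used = thr)
}

centered_span <- function(dim, extent) {
  if (extent > dim) {
    stop("requested region exceeds the frame dimensions", call. = FALSE)
  }
  start <- floor((dim - extent) / 2) + 1L
  seq.int(start, start + extent - 1L)
}

#' Centered square-window mask
#'
#' A `side x side` window centered in the frame (the strategy used for
#' cotton lint, which fills the field of view). With odd leftovers the extra
#' margin goes to the bottom/right: the 0-based start is
#' `floor((dim - side) / 2)`.
#'
#' @param video A [thermal_video()] (or its `H x W x F` dimensions).
#' @param side Window side in pixels, `<= min(H, W)`.
#' @return A `sample_mask`.
#' @export
center_window_mask <- function(video, side) {
  d <- if (inherits(video, "thermal_video")) dim(video$frames) else video
  mask <- matrix(FALSE, d[1], d[2])
  mask[centered_span(d[1], side), centered_span(d[2], side)] <- TRUE
  sample_mask(mask, "center_window")
}

#' Centered rectangle mask
#'
#' A `height x width` rectangle centered by the same floor rule as
#' [center_window_mask()] (the strategy used for paper samples, whose marked
#' borders must be excluded).
#'
#' @param video A [thermal_video()] (or its dimensions).
#' @param height,width Rectangle extents in pixels.
#' @return A `sample_mask`.
#' @export
center_rect_mask <- function(video, height, width) {
  d <- if (inherits(video, "thermal_video")) dim(video$frames) else video
  mask <- matrix(FALSE, d[1], d[2])
  mask[centered_span(d[1], height), centered_span(d[2], width)] <- TRUE
  sample_mask(mask, "center_rect")
}

#' Segment a video by a named strategy
#'
#' Dispatcher used by the pipeline: `"otsu"` / `"manual_threshold"` run
#' [otsu_mask()] on the peak-temperature frame; `"center_window"` and
#' `"center_rect"` produce fixed center regions.
#'
#' @param video A [thermal_video()].
#' @param strategy One of `"otsu"`, `"center_window"`, `"center_rect"`.
#' @param side Window side for `center_window` (default: 100 capped at the
#'   frame's smaller dimension, mirroring the 100 x 100 cotton window).
#' @param height,width Rectangle extents for `center_rect` (default: a
#'   quarter of each frame dimension).
#' @param manual_threshold Optional manual override for the Otsu strategy.
#' @return A `sample_mask`.
#' @export
segment_video <- function(video, strategy,
                          side = NULL, height = NULL, width = NULL,
                          manual_threshold = NULL) {
  strategy <- match.arg(strategy, c("otsu", "center_window", "center_rect"))
  d <- dim(video$frames)
  switch(strategy,
         otsu = {
           pk <- peak_frame_index(video) + 1L
           otsu_mask(video$frames[, , pk], manual_threshold = manual_threshold)
         },
         center_window = {
           if (is.null(side)) side <- min(100L, d[1], d[2])
           center_window_mask(video, side)
         },
         center_rect = {
           if (is.null(height)) height <- max(1L, d[1] %/% 4L)
           if (is.null(width)) width <- max(1L, d[2] %/% 4L)
           center_rect_mask(video, height, width)
         })
}
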