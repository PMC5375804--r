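#' Thermal video object
#'
#' A temporally ordered stack of per-pixel temperature frames (degrees
#' Celsius) plus acquisition metadata. Frames are stored as an `H x W x F`
#' array. Temperatures are quantized to 32-bit float precision on
#' construction, so a video written with [write_thermal_video()] and read
#' back with [read_thermal_video()] is bit-identical to the in-memory object.
#'
#' @param frames Numeric `H x W x F` array (or `H x W` matrix for a single
#'   frame) of finite temperatures in degrees Celsius.
#' @param fps Frame rate, frames per second (> 0).
#' @param metadata Named list of textual metadata (class label, seed, ...).
#'   Stored as JSON in the container.
#' @return An object of class `thermal_video` with elements `frames`, `fps`
#'   and `metadata`.
#' @export
thermal_video <- function(frames, fps, metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  if (any(dim(frames) < 1L)) stop("frame dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(frames))) stop("temperatures must be finite", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  storage <- float32(as.numeric(frames))
  dim(storage) <- dim(frames)
  structure(list(frames = storage, fps = fps, metadata = metadata),
            class = "thermal_video")
}

#' @export
print.thermal_video <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<thermal_video> %d x %d px, %d frames @ %g fps", d[1], d[2], d[3], x$fps))
  if (!is.null(x$metadata$class)) cat(sprintf(" [%s]", x$metadata$class))
  cat("\n")
  invisible(x)
}

#' @export
dim.thermal_video <- function(x) dim(x$frames)

# round-trip through 4-byte IEEE floats; gives the value a float32 camera
# export would carry
float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L, endian = "little"),
          what = "numeric", n = length(x), size = 4L, endian = "little")
}

PTIV_MAGIC <- charToRaw("PTIV")
PTIV_VERSION <- 1L

#' Write a thermal video to the PTIV binary container
#'
#' Container layout: magic `"PTIV"`, format version (uint16), frame height,
#' width and count (uint32 each), fps (float64), metadata byte length
#' (uint32) followed by UTF-8 JSON metadata, then the frames as little-endian
#' 32-bit floats, frame-major and row-major within each frame. The payload is
#' exactly `4 * F * H * W` bytes.
#'
#' @param video A [thermal_video()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_thermal_video()]
#' @export
write_thermal_video <- function(video, path) {
  stopifnot(inherits(video, "thermal_video"))
  con <- file(path, "wb")
  on.exit(close(con))
  d <- dim(video$frames)
  writeBin(PTIV_MAGIC, con)
  writeBin(PTIV_VERSION, con, size = 2L, endian = "little")
  writeBin(as.integer(c(d[1], d[2], d[3])), con, size = 4L, endian = "little")
  writeBin(as.numeric(video$fps), con, size = 8L, endian = "little")
  meta_raw <- charToRaw(enc2utf8(as.character(
    jsonlite::toJSON(video$metadata, auto_unbox = TRUE, digits = NA))))
  writeBin(length(meta_raw), con, size = 4L, endian = "little")
  writeBin(meta_raw, con)
  # aperm to (W, H, F) so the linearized vector is row-major within frame
  writeBin(as.numeric(aperm(video$frames, c(2, 1, 3))), con,
           size = 4L, endian = "little")
  invisible(path)
}

#' Read a thermal video from the PTIV binary container
#'
#' Exact inverse of [write_thermal_video()]. Fails on a wrong magic number,
#' an unsupported format version, or a payload whose size does not match the
#' header (`header + 4*F*H*W` bytes).
#'
#' @param path Path to a PTIV file.
#' @return A [thermal_video()].
#' @export
read_thermal_video <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) < 4L || !identical(magic, PTIV_MAGIC)) {
    stop("not a PTIV container (bad magic)", call. = FALSE)
  }
  version <- readBin(con, "integer", size = 2L, signed = FALSE, endian = "little")
  if (!identical(version, PTIV_VERSION)) {
    stop("unsupported PTIV version: ", version, call. = FALSE)
  }
  dims <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  h <- dims[1]; w <- dims[2]; f <- dims[3]
  fps <- readBin(con, "numeric", size = 8L, endian = "little")
  meta_len <- readBin(con, "integer", size = 4L, endian = "little")
  meta_raw <- readBin(con, "raw", n = meta_len)
  meta_json <- rawToChar(meta_raw)
  Encoding(meta_json) <- "UTF-8"
  metadata <- jsonlite::fromJSON(meta_json, simplifyVector = TRUE)
  header_bytes <- 4L + 2L + 12L + 8L + 4L + meta_len
  expected <- header_bytes + 4 * as.numeric(h) * w * f
  actual <- file.size(path)
  if (!isTRUE(all.equal(expected, actual))) {
    stop(sprintf("corrupt PTIV payload: expected %d bytes, file has %d",
                 expected, actual), call. = FALSE)
  }
  v <- readBin(con, "numeric", n = h * w * f, size = 4L, endian = "little")
  frames <- aperm(array(v, dim = c(w, h, f)), c(2, 1, 3))
  structure(list(frames = frames, fps = fps, metadata = as.list(metadata)),
            class = "thermal_video")
}
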