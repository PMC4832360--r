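#' Movie stack: calibrated grayscale time-lapse
#'
#' The common currency of simulation and tracking: an ordered stack of
#' grayscale frames together with its spatial calibration (nm per pixel)
#' and temporal calibration (frames per second).
#'
#' Frames are stored as an integer array of dimension `rows x cols x time`
#' with intensities on the 16-bit camera scale (0..65535). Physical
#' coordinates follow the image convention used throughout the package:
#' `x_nm = (col - 1) * pixel_size_nm`, `y_nm = (row - 1) * pixel_size_nm`,
#' with y increasing down the image, and angles measured in degrees from
#' the +x axis towards +y.
#'
#' @param frames numeric or integer array, `rows x cols x time`, at least
#'   2 frames, all intensities finite and >= 0.
#' @param pixel_size_nm length of one pixel side in nanometres (> 0).
#' @param frame_rate_hz acquisition rate in frames per second (> 0).
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, pixel_size_nm, frame_rate_hz) {
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("frames: must be a 3-D array (rows x cols x time)")
  if (dim(frames)[3] < 2L)
    stop("frames: a movie needs at least 2 frames")
  if (!all(is.finite(frames)) || any(frames < 0))
    stop("frames: intensities must be finite and >= 0")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1L || pixel_size_nm <= 0)
    stop("pixel_size_nm: must be a single positive number")
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0)
    stop("frame_rate_hz: must be a single positive number")
  storage.mode(frames) <- "integer"
  structure(
    list(frames = frames,
         pixel_size_nm = as.numeric(pixel_size_nm),
         frame_rate_hz = as.numeric(frame_rate_hz)),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("movie_stack: %d frames of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  pixel size %.1f nm/px, frame rate %.3g Hz (%.1f s)\n",
              x$pixel_size_nm, x$frame_rate_hz, (d[3] - 1) / x$frame_rate_hz))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

#' Number of frames in a movie
#' @param movie a `movie_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(movie) dim(movie$frames)[3]

#' Extract one frame as a matrix
#' @param movie a `movie_stack`.
#' @param i frame index (1-based).
#' @return numeric matrix of intensities.
#' @export
get_frame <- function(movie, i) {
  nt <- n_frames(movie)
  if (i < 1L || i > nt) stop("frame index out of range")
  movie$frames[, , i]
}

#' Write a movie as a multi-page 16-bit TIFF with sidecar metadata
#'
#' One TIFF page per frame, 16-bit unsigned; calibration (and any extra
#' metadata such as the generating seed and model configuration) goes to
#' a JSON sidecar named `<path without extension>.json`.
#'
#' @param movie a `movie_stack`.
#' @param path output TIFF path (conventionally `.tif`).
#' @param metadata optional named list merged into the sidecar JSON.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path, metadata = list()) {
  stopifnot(inherits(movie, "movie_stack"))
  nt <- n_frames(movie)
  pages <- lapply(seq_len(nt), function(i) movie$frames[, , i] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- c(list(pixel_size_nm = movie$pixel_size_nm,
                 frame_rate_hz = movie$frame_rate_hz,
                 n_frames = nt),
            metadata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie()]
#'
#' @param path TIFF path; the JSON sidecar must sit next to it unless
#'   calibration is supplied explicitly.
#' @param pixel_size_nm,frame_rate_hz optional calibration overrides for
#'   TIFFs lacking a sidecar.
#' @return a `movie_stack`; sidecar metadata is attached as attribute
#'   `"metadata"`.
#' @export
read_movie <- function(path, pixel_size_nm = NULL, frame_rate_hz = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  frames <- array(0L, dim = c(d[1], d[2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  meta <- list()
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  px <- if (!is.null(pixel_size_nm)) pixel_size_nm else meta$pixel_size_nm
  fr <- if (!is.null(frame_rate_hz)) frame_rate_hz else meta$frame_rate_hz
  if (is.null(px) || is.null(fr))
    stop("calibration missing: no sidecar JSON and no explicit pixel_size_nm/frame_rate_hz")
  m <- movie_stack(frames, px, fr)
  attr(m, "metadata") <- meta
  m
}

sidecar_path <- function(path) {
  ext <- tools::file_ext(path)
  if (nzchar(ext)) sub(paste0("\\.", ext, "$"), ".json", path) else paste0(path, ".json")
}
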