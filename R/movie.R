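#' Fluorescence movie container
#'
#' A `movie_stack` wraps a T x H x W array of non-negative fluorescence
#' intensities (arbitrary units) together with the frame period and optional
#' per-frame metadata.
#'
#' @param data numeric array, T x H x W, all values finite and non-negative.
#' @param frame_period_s frame period in seconds (> 0). The 32-ms period of a
#'   resonant scanner running at 32 frames per second is the conventional
#'   default.
#' @param meta optional named list of acquisition metadata kept alongside the
#'   pixel data (written to the JSON sidecar).
#' @return an object of class `movie_stack` with elements `data`,
#'   `frame_period_s` and `meta`.
#' @examples
#' m <- movie_stack(array(100, dim = c(4, 8, 8)))
#' dim(m)
#' @export
movie_stack <- function(data, frame_period_s = 0.032, meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a T x H x W array")
  if (dim(data)[1] < 1L) stopf("movie has zero frames")
  if (anyNA(data) || any(!is.finite(data))) stopf("movie contains non-finite values")
  if (any(data < 0)) stopf("movie intensities must be non-negative")
  if (!is.numeric(frame_period_s) || length(frame_period_s) != 1L || frame_period_s <= 0)
    stopf("`frame_period_s` must be a single positive number")
  structure(list(data = data, frame_period_s = frame_period_s, meta = meta),
            class = "movie_stack")
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("movie_stack: %d frames of %d x %d px, frame period %.4g s (%.3g fps)\n",
              d[1], d[2], d[3], x$frame_period_s, 1 / x$frame_period_s))
  invisible(x)
}

#' Frame times of a movie
#'
#' @param movie a [movie_stack()].
#' @return numeric vector of frame-start times in seconds (first frame at 0).
#' @export
frame_times <- function(movie) {
  (seq_len(dim(movie$data)[1]) - 1) * movie$frame_period_s
}

#' Read a fluorescence movie from a multi-page TIFF
#'
#' Movies are stored as single-channel 16-bit unsigned multi-page TIFFs with a
#' JSON sidecar (`<path>.json`) holding the frame period and any metadata. The
#' sidecar is optional; without it the default 32-ms frame period is assumed.
#'
#' @param path path to the TIFF file.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stopf("movie file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stopf("movie has zero frames: %s", path)
  dims <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stopf("inconsistent dimensions across TIFF pages in %s", path)
  arr <- array(0, dim = c(length(pages), dims[1, 1], dims[2, 1]))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  sidecar <- paste0(path, ".json")
  fp <- 0.032; meta <- list()
  if (file.exists(sidecar)) {
    sc <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    fp <- sc$frame_period_s %||% fp
    meta <- sc$meta %||% list()
  }
  movie_stack(arr, frame_period_s = fp, meta = meta)
}

#' Write a fluorescence movie to a multi-page TIFF
#'
#' Pixel values are rounded to integers and clipped to the 16-bit range
#' `[0, 65535]` (the container's native depth); integer-valued movies therefore
#' round-trip exactly through [read_movie()]. The frame period and metadata go
#' to a JSON sidecar at `<path>.json`.
#'
#' @param movie a [movie_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  stopifnot(inherits(movie, "movie_stack"))
  d <- dim(movie$data)
  vals <- pmin(pmax(round(movie$data), 0), 65535)
  pages <- lapply(seq_len(d[1]), function(i) vals[i, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(
    list(frame_period_s = movie$frame_period_s, meta = movie$meta),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
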