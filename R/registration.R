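#' Build a registration template by frame averaging
#'
#' Pixelwise mean of up to `n_frames` frames taken from the middle of the
#' session: with `T` frames the averaged block is `min(n_frames, T)` frames
#' centered at `T/2`.
#'
#' @param movie a [movie_stack()].
#' @param n_frames frames to average (default 1000).
#' @return an object of class `registration_template`: list with `image`
#'   (H x W matrix) and `frame_range` (first, last 1-based frame index).
#' @export
build_template <- function(movie, n_frames = 1000L) {
  d <- dim(movie$data)
  nT <- d[1]
  k <- min(n_frames, nT)
  first <- floor((nT - k) / 2) + 1L
  last <- first + k - 1L
  img <- apply(movie$data[first:last, , , drop = FALSE], c(2, 3), mean)
  structure(list(image = img, frame_range = c(first, last)),
            class = "registration_template")
}

# normalized cross-correlation of frame vs template at one integer shift,
# zero-mean unit-variance within the overlap region
ncc_at_shift <- function(frame, template, sr, sc) {
  H <- nrow(frame); W <- ncol(frame)
  r1 <- max(1, 1 + sr); r2 <- min(H, H + sr)
  c1 <- max(1, 1 + sc); c2 <- min(W, W + sc)
  if (r1 > r2 || c1 > c2) return(-Inf)
  a <- as.vector(frame[r1:r2, c1:c2])
  b <- as.vector(template[(r1 - sr):(r2 - sr), (c1 - sc):(c2 - sc)])
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Align one frame to a template by normalized cross-correlation
#'
#' Exhaustively evaluates the normalized cross-correlation (zero-mean,
#' unit-variance within the overlap region per candidate shift) over all
#' integer translations within `max_shift`, then refines the peak to subpixel
#' precision by separable 3-point quadratic interpolation.
#'
#' @param frame H x W matrix.
#' @param template a [build_template()] result, or an H x W matrix.
#' @param max_shift maximum shift searched, pixels (default 20).
#' @return list with `dx`, `dy` (frame's displacement relative to the
#'   template, subpixel), `peak_r` (peak correlation, in `[-1, 1]`) and
#'   `reliable` (peak above `reliability_threshold`).
#' @param reliability_threshold peak correlation below which the estimate is
#'   flagged unreliable (default 0.3).
#' @export
ncc_align <- function(frame, template, max_shift = 20L,
                      reliability_threshold = 0.3) {
  tpl <- if (inherits(template, "registration_template")) template$image else template
  if (!all(dim(frame) == dim(tpl))) stopf("frame/template dimension mismatch")
  if (max_shift < 0) stopf("max_shift must be non-negative")
  if (2 * max_shift >= min(dim(frame)))
    stopf("max_shift exceeds half the image size")
  if (stats::sd(frame) == 0) stopf("flat (zero-variance) frame")

  shifts <- -max_shift:max_shift
  n <- length(shifts)
  cc <- matrix(-Inf, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    cc[i, j] <- ncc_at_shift(frame, tpl, shifts[i], shifts[j])
  best <- arrayInd(which.max(cc), dim(cc))
  bi <- best[1]; bj <- best[2]
  dx <- shifts[bi]; dy <- shifts[bj]
  peak <- cc[bi, bj]

  # 3-point quadratic refinement, separable in x and y
  sub <- function(cm, c0, cp) {
    den <- cm - 2 * c0 + cp
    if (!is.finite(den) || den >= 0) return(0)
    d <- 0.5 * (cm - cp) / den
    max(min(d, 0.5), -0.5)
  }
  ddx <- ddy <- 0
  if (peak < 1 - 1e-9) {  # a perfect match needs no subpixel refinement
    if (bi > 1 && bi < n && is.finite(cc[bi - 1, bj]) && is.finite(cc[bi + 1, bj]))
      ddx <- sub(cc[bi - 1, bj], peak, cc[bi + 1, bj])
    if (bj > 1 && bj < n && is.finite(cc[bi, bj - 1]) && is.finite(cc[bi, bj + 1]))
      ddy <- sub(cc[bi, bj - 1], peak, cc[bi, bj + 1])
  }

  list(dx = dx + ddx, dy = dy + ddy, peak_r = min(max(peak, -1), 1),
       reliable = peak >= reliability_threshold)
}

#' Motion-correct a movie against a template
#'
#' Estimates each frame's translation by [ncc_align()] and shifts the frame
#' back by the negated estimate (bilinear interpolation; uncovered edge
#' pixels take the frame median).
#'
#' @param movie a [movie_stack()].
#' @param template a [build_template()] result (default: built from the
#'   movie).
#' @param max_shift maximum shift searched, pixels (default 20).
#' @return list with `movie` (registered [movie_stack()]) and `shifts`
#'   (data.frame: `frame`, `dx`, `dy`, `peak_r`, `reliable`).
#' @export
register_movie <- function(movie, template = build_template(movie),
                           max_shift = 20L) {
  d <- dim(movie$data)
  out <- movie$data
  shifts <- data.frame(frame = seq_len(d[1]), dx = 0, dy = 0, peak_r = 0,
                       reliable = NA)
  for (f in seq_len(d[1])) {
    fr <- movie$data[f, , ]
    al <- ncc_align(fr, template, max_shift = max_shift)
    shifts$dx[f] <- al$dx; shifts$dy[f] <- al$dy
    shifts$peak_r[f] <- al$peak_r; shifts$reliable[f] <- al$reliable
    if (al$dx != 0 || al$dy != 0)
      out[f, , ] <- pmax(translate_image(fr, -al$dx, -al$dy), 0)
  }
  list(movie = movie_stack(out, frame_period_s = movie$frame_period_s,
                           meta = movie$meta),
       shifts = shifts)
}
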