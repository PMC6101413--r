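# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Translate an image by a (possibly fractional) pixel shift
#'
#' Shifts `img` by `dx` rows (down) and `dy` columns (right), with bilinear
#' interpolation for fractional shifts. Destination pixels whose source falls
#' outside the image are set to `fill`.
#'
#' @param img numeric matrix (H x W).
#' @param dx,dy shift in pixels along rows / columns; positive moves content
#'   toward larger indices.
#' @param fill value for uncovered pixels (default: median of `img`).
#' @return shifted matrix of the same dimensions.
#' @keywords internal
translate_image <- function(img, dx, dy, fill = stats::median(img)) {
  H <- nrow(img); W <- ncol(img)
  r <- seq_len(H) - dx           # source row coordinate per destination row
  c <- seq_len(W) - dy
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0

  cl <- function(v, n) pmin(pmax(v, 1L), n)
  # corners with zero interpolation weight may be clamped freely
  m00 <- img[cl(r0, H),     cl(c0, W),     drop = FALSE]
  m10 <- img[cl(r0 + 1, H), cl(c0, W),     drop = FALSE]
  m01 <- img[cl(r0, H),     cl(c0 + 1, W), drop = FALSE]
  m11 <- img[cl(r0 + 1, H), cl(c0 + 1, W), drop = FALSE]
  out <- outer(1 - fr, 1 - fc) * m00 + outer(fr, 1 - fc) * m10 +
         outer(1 - fr, fc) * m01 + outer(fr, fc) * m11
  out[r < 1 | r > H, ] <- fill
  out[, c < 1 | c > W] <- fill
  out
}

# FNV-1a 32-bit hash of a character vector, as 8-hex-digit string.
# Used for config fingerprints in run manifests.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor only touches the low byte because b < 256 (stay in doubles: h >= 2^31)
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply by the FNV prime 16777619, overflow-safe
    lo <- h %% 65536; hi <- h %/% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
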