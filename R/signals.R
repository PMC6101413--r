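#' Region-of-interest set (disc ROIs)
#'
#' @param id unique integer ids.
#' @param center_r,center_c ROI centers, pixel coordinates.
#' @param radius disc radius per ROI, pixels.
#' @param fov numeric length-2, (H, W); masks must fall inside it.
#' @return a `data.frame` of class `roi_set`.
#' @export
roi_set <- function(id, center_r, center_c, radius, fov) {
  if (anyDuplicated(id)) stopf("ROI ids must be unique")
  if (any(center_r - radius < 0.5 | center_r + radius > fov[1] + 0.5 |
          center_c - radius < 0.5 | center_c + radius > fov[2] + 0.5))
    stopf("ROI mask extends outside the FOV")
  df <- data.frame(id = as.integer(id), center_r = center_r,
                   center_c = center_c, radius = radius)
  attr(df, "fov") <- as.integer(fov)
  class(df) <- c("roi_set", "data.frame")
  df
}

# linear pixel indices of one disc ROI in an H x W image
roi_mask_idx <- function(roi_row, fov) {
  H <- fov[1]; W <- fov[2]
  rr <- seq_len(H); cc <- seq_len(W)
  m <- outer((rr - roi_row$center_r)^2, (cc - roi_row$center_c)^2, "+") <=
    roi_row$radius^2
  idx <- which(m)
  if (!length(idx)) stopf("empty ROI mask (id %d)", roi_row$id)
  idx
}

#' Extract ROI-mean fluorescence traces
#'
#' @param movie a registered [movie_stack()].
#' @param rois a [roi_set()].
#' @return a `trace_matrix`: list with `F` (ROI x time matrix, a.u.),
#'   `time_s` (frame times) and `roi_id`.
#' @export
extract_traces <- function(movie, rois) {
  d <- dim(movie$data)
  fov <- c(d[2], d[3])
  Fm <- matrix(0, nrow = nrow(rois), ncol = d[1])
  flat <- matrix(movie$data, nrow = d[1])  # frames x (H*W), column-major pixels
  for (i in seq_len(nrow(rois))) {
    idx <- roi_mask_idx(rois[i, ], fov)
    Fm[i, ] <- rowMeans(flat[, idx, drop = FALSE])
  }
  structure(list(F = Fm, time_s = frame_times(movie), roi_id = rois$id),
            class = "trace_matrix")
}

#' Per-trial baseline and response amplitudes (dF/F)
#'
#' For every (ROI, trial) pair: `F0` is the mean fluorescence over the
#' baseline window ending at trial onset, and the response amplitude `r` is
#' the mean of `(F - F0)/F0` over the response window (stimulus duration plus
#' `response_extra_s`, capturing the slow indicator tail).
#'
#' @param traces a [extract_traces()] result.
#' @param trials a [trial_table()].
#' @param baseline_window_s baseline length before onset, seconds
#'   (default 1).
#' @param response_extra_s window extension past stimulus offset, seconds
#'   (default 1).
#' @return a `data.frame` of class `response_table`: columns `roi_id`,
#'   `trial_id`, `condition`, `F0`, `r`.
#' @export
compute_dff <- function(traces, trials, baseline_window_s = 1,
                        response_extra_s = 1) {
  tt <- traces$time_s
  out <- vector("list", nrow(trials))
  for (j in seq_len(nrow(trials))) {
    on <- trials$onset_s[j]
    base_idx <- which(tt >= on - baseline_window_s & tt < on)
    if (!length(base_idx)) base_idx <- max(1L, which.min(abs(tt - on)) - 1L)
    resp_end <- on + trials$duration_ms[j] / 1000 + response_extra_s
    resp_idx <- which(tt >= on & tt <= resp_end)
    if (!length(resp_idx)) resp_idx <- which.min(abs(tt - on))
    F0 <- rowMeans(traces$F[, base_idx, drop = FALSE])
    if (any(F0 <= 0)) stopf("non-positive baseline F0 (trial %d)", trials$trial_id[j])
    r <- rowMeans((traces$F[, resp_idx, drop = FALSE] - F0) / F0)
    out[[j]] <- data.frame(roi_id = traces$roi_id, trial_id = trials$trial_id[j],
                           condition = trials$condition[j], F0 = F0, r = r)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("response_table", "data.frame")
  res
}

#' Trial-averaged differential image (F - F0)
#'
#' Pixelwise mean over trials of (mean frame in the response window minus
#' mean frame in the baseline window). The classic stimulated-minus-baseline
#' image that lights up responsive somata.
#'
#' @inheritParams compute_dff
#' @param movie a registered [movie_stack()].
#' @return H x W numeric matrix.
#' @export
differential_image <- function(movie, trials, baseline_window_s = 1,
                               response_extra_s = 1) {
  if (nrow(trials) == 0L) stopf("no trials")
  tt <- frame_times(movie)
  d <- dim(movie$data)
  acc <- matrix(0, d[2], d[3])
  for (j in seq_len(nrow(trials))) {
    on <- trials$onset_s[j]
    base_idx <- which(tt >= on - baseline_window_s & tt < on)
    resp_end <- on + trials$duration_ms[j] / 1000 + response_extra_s
    resp_idx <- which(tt >= on & tt <= resp_end)
    if (!length(base_idx) || !length(resp_idx))
      stopf("trial %d has no frames in its analysis windows", trials$trial_id[j])
    mb <- apply(movie$data[base_idx, , , drop = FALSE], c(2, 3), mean)
    mr <- apply(movie$data[resp_idx, , , drop = FALSE], c(2, 3), mean)
    acc <- acc + (mr - mb)
  }
  acc / nrow(trials)
}

#' Compare visual versus optogenetic response amplitudes per ROI
#'
#' Two-sample rank-sum (Wilcoxon) test per ROI between its VisualStim and
#' OptoStim trial amplitudes. Cells are classed `similar` (p > alpha),
#' `visual_stronger` or `opto_stronger` (p < alpha, by sign of the mean
#' difference).
#'
#' @param responses a [compute_dff()] result.
#' @param alpha significance level (default 0.05).
#' @return `data.frame` of class `mode_comparison`: `roi_id`,
#'   `mean_visual_r`, `mean_opto_r`, `p_value`, `class`.
#' @export
compare_modes <- function(responses, alpha = 0.05) {
  ids <- unique(responses$roi_id)
  out <- data.frame(roi_id = ids, mean_visual_r = NA_real_,
                    mean_opto_r = NA_real_, p_value = NA_real_,
                    class = NA_character_)
  for (k in seq_along(ids)) {
    v <- responses$r[responses$roi_id == ids[k] & responses$condition == "VisualStim"]
    o <- responses$r[responses$roi_id == ids[k] & responses$condition == "OptoStim"]
    if (length(v) < 2L || length(o) < 2L)
      stopf("ROI %d needs >= 2 trials per stimulation mode", ids[k])
    p <- if (all(v == v[1]) && all(o == o[1]) && v[1] == o[1]) 1
         else suppressWarnings(stats::wilcox.test(v, o)$p.value)
    out$mean_visual_r[k] <- mean(v)
    out$mean_opto_r[k] <- mean(o)
    out$p_value[k] <- p
    out$class[k] <- if (p >= alpha) "similar"
                    else if (mean(v) > mean(o)) "visual_stronger"
                    else "opto_stronger"
  }
  class(out) <- c("mode_comparison", "data.frame")
  out
}

#' First-versus-last trial-block stability
#'
#' Per ROI, the mean amplitude over its first `k` and last `k` trials
#' (within a condition if given); points on the unity line indicate stable
#' responses across the session.
#'
#' @param responses a [compute_dff()] result.
#' @param k trials per block (default 4).
#' @param condition optional condition filter.
#' @return `data.frame`: `roi_id`, `first_mean`, `last_mean`.
#' @export
stability_first_last <- function(responses, k = 4L, condition = NULL) {
  if (!is.null(condition))
    responses <- responses[responses$condition == condition, , drop = FALSE]
  ids <- unique(responses$roi_id)
  out <- data.frame(roi_id = ids, first_mean = NA_real_, last_mean = NA_real_)
  for (i in seq_along(ids)) {
    r <- responses[responses$roi_id == ids[i], , drop = FALSE]
    r <- r[order(r$trial_id), , drop = FALSE]
    if (nrow(r) < 2 * k) stopf("ROI %d has fewer than 2k = %d trials", ids[i], 2 * k)
    out$first_mean[i] <- mean(r$r[seq_len(k)])
    out$last_mean[i] <- mean(r$r[seq(nrow(r) - k + 1, nrow(r))])
  }
  out
}

#' Coefficient of determination against the unity line
#'
#' `R^2 = 1 - sum((y - x)^2) / sum((y - mean(y))^2)`: how much of the
#' variance in `y` the line `y = x` explains. Used for cross-day response
#' stability scatter; can be negative.
#'
#' @param x,y equal-length numeric vectors (n >= 2); `y` non-constant.
#' @return scalar R-squared.
#' @examples
#' unity_r2(c(1, 2, 3), c(1, 2, 3))  # 1
#' @export
unity_r2 <- function(x, y) {
  if (length(x) != length(y) || length(y) < 2L)
    stopf("x and y must have equal length >= 2")
  ssy <- sum((y - mean(y))^2)
  if (ssy == 0) stopf("zero variance in y")
  1 - sum((y - x)^2) / ssy
}
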