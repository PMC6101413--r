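#' Spiral photostimulation trajectory parameters
#'
#' The two-photon stimulation focus is swept in an expanding spiral over the
#' target soma. Defaults follow the standard recipe: 5 rotations, 1.2
#' expansion rate, 0.01 pixel/us scan speed, 30 repetitions.
#'
#' @param center numeric length-2, spiral center in pixels.
#' @param start_radius_px radius at the first sample (> 0 unless
#'   `expansion_rate == 1`).
#' @param rotations number of full turns (>= 1, default 5).
#' @param expansion_rate geometric radius growth per rotation
#'   (`r(phi) = r0 * rate^(phi/2pi)`, default 1.2). `speed_px_per_us` may
#'   instead be read as a dwell time per pixel via `speed_is_dwell`.
#' @param speed_px_per_us galvo scan speed along the path, pixels per
#'   microsecond (default 0.01).
#' @param speed_is_dwell if `TRUE`, interpret `speed_px_per_us` as dwell time
#'   (us per pixel) instead of speed; the printed unit is ambiguous between
#'   the two readings (default `FALSE` = speed).
#' @param repetitions times the spiral is retraced (default 30).
#' @return object of class `spiral_params`.
#' @export
spiral_params <- function(center = c(0, 0), start_radius_px = 2,
                          rotations = 5L, expansion_rate = 1.2,
                          speed_px_per_us = 0.01, speed_is_dwell = FALSE,
                          repetitions = 30L) {
  if (rotations < 1) stopf("rotations must be >= 1")
  if (expansion_rate <= 0) stopf("expansion_rate must be positive")
  if (repetitions < 1) stopf("repetitions must be >= 1")
  if (start_radius_px <= 0 && expansion_rate != 1)
    stopf("degenerate spiral: zero start radius with expansion")
  structure(list(center = as.numeric(center),
                 start_radius_px = start_radius_px,
                 rotations = as.integer(rotations),
                 expansion_rate = expansion_rate,
                 speed_px_per_us = speed_px_per_us,
                 speed_is_dwell = isTRUE(speed_is_dwell),
                 repetitions = as.integer(repetitions)),
            class = "spiral_params")
}

#' Sample a spiral stimulation path
#'
#' Radius grows geometrically with angle, `r(phi) = r0 * rate^(phi/2pi)`,
#' over `rotations * 2pi` of total sweep. Samples are spaced at most
#' `max_step_px` apart along the path; timestamps accumulate as arc length
#' divided by scan speed (or times dwell per pixel). The full path is the
#' single spiral retraced `repetitions` times with time running on.
#'
#' @param params a [spiral_params()].
#' @param max_step_px maximum distance between consecutive samples
#'   (default 0.25 px).
#' @return `data.frame`: `sample`, `rep`, `x_px`, `y_px`, `t_us`, `phi_rad`.
#' @examples
#' p <- spiral_path(spiral_params(rotations = 5, expansion_rate = 1.2,
#'                                start_radius_px = 2, repetitions = 1))
#' max(p$phi_rad) / (2 * pi)  # 5 turns
#' @export
spiral_path <- function(params, max_step_px = 0.25) {
  stopifnot(inherits(params, "spiral_params"))
  total_phi <- params$rotations * 2 * pi
  r_of <- function(phi) params$start_radius_px *
    params$expansion_rate^(phi / (2 * pi))
  # step in phi small enough that r * dphi (plus radial growth) < max_step
  r_max <- r_of(total_phi)
  dphi <- max_step_px / max(r_max, params$start_radius_px, 1e-9) / 2
  phi <- seq(0, total_phi, by = dphi)
  if (phi[length(phi)] < total_phi) phi <- c(phi, total_phi)
  r <- r_of(phi)
  x <- params$center[1] + r * cos(phi)
  y <- params$center[2] + r * sin(phi)
  seg <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seg))
  us_per_px <- if (params$speed_is_dwell) params$speed_px_per_us
               else 1 / params$speed_px_per_us
  t1 <- arc * us_per_px
  lap_us <- t1[length(t1)]
  n <- length(phi)
  reps <- params$repetitions
  out <- data.frame(
    sample = seq_len(n * reps),
    rep = rep(seq_len(reps), each = n),
    x_px = rep(x, reps), y_px = rep(y, reps),
    t_us = rep(t1, reps) + rep((seq_len(reps) - 1) * lap_us, each = n),
    phi_rad = rep(phi, reps))
  attr(out, "lap_duration_us") <- lap_us
  attr(out, "max_step_px") <- max(seg)
  out
}

#' Spatial specificity of targeted stimulation over a site grid
#'
#' Given the target ROI's evoked response at each site of a K x K
#' stimulation grid, computes the on-target index: the response at the site
#' containing the ROI center divided by the sum of all site responses
#' (negative responses clipped to 0). An index of 1 means the cell responds
#' only when stimulated directly; uniform responses over K^2 sites give
#' 1/K^2.
#'
#' @param site_response K x K matrix of evoked dF/F of the target ROI, sites
#'   in image orientation (row = grid row).
#' @param site_centers list with matrices `r` and `c` (K x K site-center
#'   pixel coordinates), or `NULL` when `target_site` is given directly.
#' @param roi_center target ROI center, pixels.
#' @param target_site optional (row, col) of the site containing the ROI
#'   center, overriding the geometric lookup.
#' @return list of class `specificity_map`: `site_response`, `normalized`
#'   (clipped responses summing to 1 when any site responds), `target_site`,
#'   `on_target_index`.
#' @export
grid_specificity <- function(site_response, site_centers = NULL,
                             roi_center = NULL, target_site = NULL) {
  K <- nrow(site_response)
  stopifnot(ncol(site_response) == K)
  if (is.null(target_site)) {
    if (is.null(site_centers) || is.null(roi_center))
      stopf("need site_centers and roi_center (or target_site)")
    d2 <- (site_centers$r - roi_center[1])^2 + (site_centers$c - roi_center[2])^2
    # grid spacing bound: the ROI center must fall inside the grid footprint
    sp <- max(abs(diff(t(site_centers$r))), abs(diff(t(site_centers$c))),
              abs(diff(site_centers$r)), abs(diff(site_centers$c)))
    if (min(d2) > (sp / sqrt(2) + 1e-9)^2)
      stopf("stimulation grid does not cover the ROI center")
    target_site <- arrayInd(which.min(d2), dim(d2))[1, ]
  }
  clipped <- pmax(site_response, 0)
  tot <- sum(clipped)
  normalized <- if (tot > 0) clipped / tot else clipped
  idx <- if (tot > 0) normalized[target_site[1], target_site[2]] else NA_real_
  structure(list(site_response = site_response, normalized = normalized,
                 target_site = as.integer(target_site),
                 on_target_index = idx),
            class = "specificity_map")
}

#' @export
print.specificity_map <- function(x, ...) {
  cat(sprintf("specificity_map: %d x %d sites, target site (%d, %d), on-target index %.4g\n",
              nrow(x$site_response), ncol(x$site_response),
              x$target_site[1], x$target_site[2], x$on_target_index))
  invisible(x)
}

#' Sequential multi-cell targeting matrix
#'
#' Builds the matrix `M[i, j]` = mean response of ROI `i` while ROI `j` is
#' stimulated, and its diagonal-dominance score (mean diagonal over mean
#' off-diagonal). With perfectly specific stimulation every cell responds
#' only when it is itself the target, so off-diagonal entries vanish.
#'
#' @param responses `data.frame` with columns `stim_roi`, `rec_roi`, `r`
#'   (one row per trial); every (stimulated, recorded) pair must appear.
#' @return list of class `targeting_matrix`: `M` (recorded x stimulated),
#'   `score` (`NA` + `flagged = TRUE` when the off-diagonal mean is not
#'   positive or nothing responds), `contrast` (per-ROI targeted vs
#'   untargeted mean response).
#' @export
sequential_targeting <- function(responses) {
  stopifnot(all(c("stim_roi", "rec_roi", "r") %in% names(responses)))
  ids <- sort(unique(c(responses$stim_roi, responses$rec_roi)))
  n <- length(ids)
  M <- matrix(NA_real_, n, n, dimnames = list(rec = ids, stim = ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- responses$r[responses$rec_roi == ids[i] & responses$stim_roi == ids[j]]
    if (!length(v)) stopf("missing cell: recorded ROI %s under stimulation of %s",
                          ids[i], ids[j])
    M[i, j] <- mean(v)
  }
  diag_mean <- mean(diag(M))
  off <- M[row(M) != col(M)]
  flagged <- FALSE
  score <- if (length(off) && mean(off) > 0 && diag_mean > 0) {
    diag_mean / mean(off)
  } else {
    flagged <- TRUE
    NA_real_
  }
  contrast <- data.frame(
    roi_id = ids,
    targeted_r = diag(M),
    untargeted_r = vapply(seq_len(n), function(i) mean(M[i, -i]), numeric(1)))
  structure(list(M = M, score = score, flagged = flagged, contrast = contrast),
            class = "targeting_matrix")
}

#' @export
print.targeting_matrix <- function(x, ...) {
  cat(sprintf("targeting_matrix: %d ROIs, diagonal-dominance score %s\n",
              nrow(x$M),
              if (x$flagged) "undefined (flagged)" else sprintf("%.4g", x$score)))
  invisible(x)
}
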