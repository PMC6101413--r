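#' Default orientation sampling: six equally spaced orientations
#' @export
ORIENTATIONS_DEG <- seq(0, 150, by = 30)

#' Attach grating orientations to a response table
#'
#' Joins each VisualStim trial's `orientation_deg` parameter onto a
#' [compute_dff()] result, yielding the per-ROI, per-orientation amplitudes
#' that [anova_select()] consumes.
#'
#' @param responses a [compute_dff()] result.
#' @param trials the matching [trial_table()].
#' @return `data.frame` with columns `roi_id`, `orientation`, `r`
#'   (VisualStim trials with a known orientation only).
#' @export
orientation_responses <- function(responses, trials) {
  ori <- trial_param(trials, "orientation_deg")
  map <- stats::setNames(ori, trials$trial_id)
  keep <- responses$condition == "VisualStim" &
    !is.na(map[as.character(responses$trial_id)])
  data.frame(roi_id = responses$roi_id[keep],
             orientation = unname(map[as.character(responses$trial_id[keep])]),
             r = responses$r[keep])
}

#' Select orientation-tuned ROIs by one-way ANOVA
#'
#' Per ROI, a one-way ANOVA of trial amplitudes across the six grating
#' orientations; ROIs with `p < alpha` are selected as tuned. Degenerate
#' inputs with zero between-group variance get `p = 1`.
#'
#' @param responses a [compute_dff()] result whose VisualStim trials carry an
#'   `orientation_deg` value in `orientation` (see Details), or a
#'   `data.frame` with columns `roi_id`, `orientation`, `r`.
#' @param alpha selection level (default 0.05).
#' @return `data.frame`: `roi_id`, `p_value`, `selected`, plus per-orientation
#'   mean responses in attribute `orientation_means` (ROI x orientation
#'   matrix, column names = degrees).
#' @export
anova_select <- function(responses, alpha = 0.05) {
  stopifnot(all(c("roi_id", "orientation", "r") %in% names(responses)))
  ids <- unique(responses$roi_id)
  oris <- sort(unique(responses$orientation))
  means <- matrix(NA_real_, length(ids), length(oris),
                  dimnames = list(ids, oris))
  out <- data.frame(roi_id = ids, p_value = NA_real_, selected = NA)
  for (i in seq_along(ids)) {
    d <- responses[responses$roi_id == ids[i], , drop = FALSE]
    cnt <- table(factor(d$orientation, levels = oris))
    if (any(cnt < 2)) stopf("ROI %s: every orientation needs >= 2 trials", ids[i])
    grp <- factor(d$orientation)
    means[i, ] <- tapply(d$r, factor(d$orientation, levels = oris), mean)
    gm <- tapply(d$r, grp, mean)
    if (max(gm) - min(gm) == 0) {
      p <- 1
    } else {
      p <- summary(stats::aov(r ~ grp, data = d))[[1]][["Pr(>F)"]][1]
    }
    out$p_value[i] <- p
    out$selected[i] <- p < alpha
  }
  attr(out, "orientation_means") <- means
  attr(out, "alpha") <- alpha
  out
}

#' Fit a circular-Gaussian orientation tuning curve
#'
#' Least-squares fit of `r(theta) = B + A * exp((cos(2*(theta - theta_p)) - 1)
#' / sigma_c^2)` (angles in degrees, period 180) to mean responses at the
#' sampled orientations, with multi-start over preferred orientations to
#' avoid local minima of the periodic objective.
#'
#' @param theta_deg orientations, degrees (should span `[0, 180)`).
#' @param r mean response per orientation (dF/F).
#' @param starts_deg preferred-orientation starting points (default
#'   `seq(0, 150, 30)`).
#' @return object of class `circ_gauss_fit`: coefficients `B`, `A`,
#'   `theta_p_deg` (mod 180), `sigma_c` (concentration), derived
#'   `sigma_deg` (small-angle Gaussian SD, `sigma_c/2` in radians), `rss`,
#'   and `flat` (TRUE when the amplitude is negligible and `theta_p` is
#'   unidentifiable).
#' @examples
#' th <- seq(0, 150, 30)
#' r <- 0.2 + exp((cos(2 * (th - 45) * pi / 180) - 1) / 0.8^2)
#' coef(fit_circular_gaussian(th, r))
#' @export
fit_circular_gaussian <- function(theta_deg, r,
                                  starts_deg = seq(0, 150, by = 30)) {
  stopifnot(length(theta_deg) == length(r), length(r) >= 4L)
  if (stats::sd(r) < 1e-12 * max(abs(r), 1)) {
    # flat data: amplitude is zero and the preference is unidentifiable
    return(structure(list(coefficients = c(B = mean(r), A = 0,
                                           theta_p_deg = NA_real_,
                                           sigma_c = NA_real_),
                          sigma_deg = NA_real_, rss = 0, flat = TRUE,
                          theta_deg = theta_deg, r = r),
                     class = "circ_gauss_fit"))
  }
  df <- data.frame(th = theta_deg, r = r)
  best <- NULL
  for (s in starts_deg) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        r ~ B + A * exp((cos(2 * (th - thp) * pi / 180) - 1) / sc^2),
        data = df,
        start = list(B = min(r), A = max(r) - min(r) + 1e-6, thp = s, sc = 0.8),
        lower = c(B = -Inf, A = 0, thp = -360, sc = 1e-3),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) stopf("circular-Gaussian fit failed to converge from all starts")
  cf <- stats::coef(best$fit)
  flat <- cf[["A"]] < 1e-8 * max(abs(r), 1e-12) ||
          cf[["A"]] < 1e-3 * max(stats::sd(r), 1e-12)
  thp <- cf[["thp"]] %% 180
  structure(list(coefficients = c(B = cf[["B"]], A = cf[["A"]],
                                  theta_p_deg = thp, sigma_c = cf[["sc"]]),
                 sigma_deg = cf[["sc"]] / 2 * 180 / pi,
                 rss = best$rss, flat = flat,
                 theta_deg = theta_deg, r = r),
            class = "circ_gauss_fit")
}

#' @export
coef.circ_gauss_fit <- function(object, ...) object$coefficients

#' @export
print.circ_gauss_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("circular-Gaussian tuning fit: B=%.4g A=%.4g theta_p=%.2f deg sigma_c=%.4g%s\n",
              cf["B"], cf["A"], cf["theta_p_deg"], cf["sigma_c"],
              if (x$flat) " [flat: theta_p unidentifiable]" else ""))
  invisible(x)
}

#' @export
predict.circ_gauss_fit <- function(object, newdata = NULL, ...) {
  th <- if (is.null(newdata)) object$theta_deg
        else if (is.list(newdata)) newdata$th %||% newdata$theta_deg
        else newdata
  cf <- object$coefficients
  if (object$flat) return(rep(cf[["B"]], length(th)))
  cf[["B"]] + cf[["A"]] *
    exp((cos(2 * (th - cf[["theta_p_deg"]]) * pi / 180) - 1) / cf[["sigma_c"]]^2)
}

#' Align tuning curves to their preferred orientation and average
#'
#' Circularly shifts each ROI's orientation-mean curve so its preferred
#' orientation lands on 0 degrees (nearest sampled bin), then averages
#' pointwise across ROIs — the standard population tuning curve.
#'
#' @param orientation_means ROI x orientation matrix (column names =
#'   degrees), e.g. `attr(anova_select(...), "orientation_means")`.
#' @param theta_p_deg preferred orientation per ROI, degrees.
#' @param selected optional logical mask of ROIs to include (default all).
#' @return list with `offsets_deg` (orientation offsets, 0 first) and
#'   `mean_r` (population average per offset), plus `n` ROIs averaged.
#' @export
align_and_average <- function(orientation_means, theta_p_deg, selected = NULL) {
  if (!is.null(selected)) {
    orientation_means <- orientation_means[selected, , drop = FALSE]
    theta_p_deg <- theta_p_deg[selected]
  }
  if (nrow(orientation_means) == 0L) stopf("no selected ROIs to average")
  oris <- as.numeric(colnames(orientation_means))
  step <- diff(sort(oris))[1]
  k <- length(oris)
  shifted <- matrix(NA_real_, nrow(orientation_means), k)
  for (i in seq_len(nrow(orientation_means))) {
    bin <- round((theta_p_deg[i] %% 180) / step) %% k  # bin of theta_p
    shifted[i, ] <- orientation_means[i, 1 + ((seq_len(k) - 1 + bin) %% k)]
  }
  list(offsets_deg = oris, mean_r = colMeans(shifted),
       n = nrow(orientation_means))
}

#' Pixelwise orientation-preference map
#'
#' For every pixel: mean dF/F response per orientation (stimulus window
#' versus pre-onset baseline), then the preferred orientation as half the
#' argument of the orientation vector sum `sum(r(theta) * exp(2i*theta))` and
#' the response strength as the mean response across orientations. Maps of
#' this kind expose the pinwheel organization of primate V1.
#'
#' @param movie a registered [movie_stack()].
#' @param trials a [trial_table()] whose VisualStim trials carry
#'   `orientation_deg` params.
#' @param baseline_window_s,response_extra_s analysis windows as in
#'   [compute_dff()].
#' @return list of H x W matrices: `orientation_deg` (in `[0, 180)`, `NA`
#'   where undefined), `strength` (>= 0).
#' @export
pixel_orientation_map <- function(movie, trials, baseline_window_s = 1,
                                  response_extra_s = 1) {
  vt <- trials[trials$condition == "VisualStim", , drop = FALSE]
  ori <- trial_param(vt, "orientation_deg")
  if (nrow(vt) == 0L || all(is.na(ori))) stopf("no orientation trials present")
  oris <- sort(unique(ori[!is.na(ori)]))
  tt <- frame_times(movie)
  d <- dim(movie$data)
  resp <- array(0, dim = c(length(oris), d[2], d[3]))
  for (k in seq_along(oris)) {
    sel <- which(ori == oris[k])
    acc <- matrix(0, d[2], d[3])
    for (j in sel) {
      on <- vt$onset_s[j]
      base_idx <- which(tt >= on - baseline_window_s & tt < on)
      resp_end <- on + vt$duration_ms[j] / 1000 + response_extra_s
      resp_idx <- which(tt >= on & tt <= resp_end)
      mb <- apply(movie$data[base_idx, , , drop = FALSE], c(2, 3), mean)
      mr <- apply(movie$data[resp_idx, , , drop = FALSE], c(2, 3), mean)
      acc <- acc + (mr - mb) / pmax(mb, .Machine$double.eps)
    }
    resp[k, , ] <- acc / length(sel)
  }
  rpos <- pmax(resp, 0)  # negative responses carry no orientation signal
  zr <- matrix(0, d[2], d[3]); zi <- matrix(0, d[2], d[3])
  for (k in seq_along(oris)) {
    ang <- 2 * oris[k] * pi / 180
    zr <- zr + rpos[k, , ] * cos(ang)
    zi <- zi + rpos[k, , ] * sin(ang)
  }
  strength <- apply(rpos, c(2, 3), mean)
  pref <- (atan2(zi, zr) / 2 * 180 / pi) %% 180
  pref[zr == 0 & zi == 0] <- NA_real_  # no response: orientation undefined
  list(orientation_deg = pref, strength = strength)
}

#' Fit a saturating laser-intensity dose-response curve
#'
#' Least-squares fit of the hyperbolic (Michaelis-type) model
#' `r(I) = Rmax * I / (I + I50)` to mean responses across intensity levels.
#' The saturation intensity is where the curve reaches
#' `saturation_level * Rmax`, i.e. `I50 * level / (1 - level)`.
#'
#' @param intensity laser intensities, mW/mm^2 (>= 3 distinct values).
#' @param r response amplitudes (dF/F), same length.
#' @param saturation_level fraction of `Rmax` defining "saturated"
#'   (default 0.9).
#' @return object of class `dose_response_fit`: coefficients `Rmax`, `I50`,
#'   `saturation_intensity` (mW/mm^2, `NA` when flagged), `flagged`
#'   (negligible or non-monotone response), per-level means and SEs.
#' @examples
#' I <- c(0.1, 0.2, 0.4, 0.8, 1.6, 2.4)
#' fit_dose_response(I, 2 * I / (I + 0.0889))
#' @export
fit_dose_response <- function(intensity, r, saturation_level = 0.9) {
  stopifnot(length(intensity) == length(r))
  if (length(unique(intensity)) < 3L) stopf("need >= 3 distinct intensities")
  if (saturation_level <= 0 || saturation_level >= 1)
    stopf("saturation_level must be in (0, 1)")
  df <- data.frame(I = intensity, r = r)
  lev <- sort(unique(intensity))
  mu <- vapply(lev, function(l) mean(r[intensity == l]), numeric(1))
  se <- vapply(lev, function(l) {
    v <- r[intensity == l]
    if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  }, numeric(1))

  flagged <- FALSE
  if (max(abs(mu)) < 1e-12) {
    cf <- c(Rmax = 0, I50 = NA_real_)
    flagged <- TRUE
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ Rmax * I / (I + I50), data = df,
                        start = list(Rmax = max(mu), I50 = stats::median(intensity)),
                        lower = c(Rmax = 0, I50 = 1e-9),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) stopf("dose-response fit failed to converge")
    cf <- stats::coef(fit)
    # flag wildly non-monotone level means: the model is still returned
    if (length(mu) >= 3 && any(diff(mu) < -0.5 * max(abs(mu)))) flagged <- TRUE
    if (cf[["Rmax"]] < 1e-9) flagged <- TRUE
  }
  sat <- if (flagged || is.na(cf[["I50"]])) NA_real_
         else cf[["I50"]] * saturation_level / (1 - saturation_level)
  structure(list(coefficients = c(Rmax = unname(cf[["Rmax"]]),
                                  I50 = unname(cf[["I50"]])),
                 saturation_intensity = sat,
                 saturation_level = saturation_level,
                 flagged = flagged,
                 levels = data.frame(intensity = lev, mean_r = mu, se_r = se)),
            class = "dose_response_fit")
}

#' @export
coef.dose_response_fit <- function(object, ...) object$coefficients

#' @export
print.dose_response_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf("dose-response fit: Rmax=%.4g, I50=%.4g mW/mm^2; saturation (%.0f%% Rmax) at %.4g mW/mm^2%s\n",
              cf["Rmax"], cf["I50"], 100 * x$saturation_level,
              x$saturation_intensity, if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' @export
predict.dose_response_fit <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$levels$intensity
       else if (is.list(newdata)) newdata$I %||% newdata$intensity
       else newdata
  cf <- object$coefficients
  cf[["Rmax"]] * I / (I + cf[["I50"]])
}
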