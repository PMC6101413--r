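#' Ground-truth neuron for the movie generator
#'
#' Describes one simulated cell: a disc of pixels with a fluorescence
#' baseline, an orientation-tuned visual response, and (when it expresses the
#' opsin) an optogenetic response that saturates with laser intensity as
#' `amp * I / (I + dose_half_saturation)`.
#'
#' @param center numeric length-2, (row, col) pixel coordinates of the soma.
#' @param radius soma radius in pixels (> 0).
#' @param baseline_F baseline fluorescence, arbitrary units (> 0).
#' @param preferred_orientation_deg preferred grating orientation in
#'   `[0, 180)`.
#' @param tuning_width_conc circular-Gaussian concentration parameter of the
#'   tuning curve (dimensionless; smaller = sharper).
#' @param visual_amplitude peak visual dF/F at the preferred orientation
#'   (>= 0).
#' @param opsin_expressing does the cell carry the opsin?
#' @param opto_amplitude saturating-dose dF/F ceiling for optogenetic drive
#'   (>= 0).
#' @param dose_half_saturation laser intensity giving half-maximal response,
#'   mW/mm^2. The default 0.0889 puts 90%-of-max at 0.8 mW/mm^2.
#' @return an object of class `neuron_gt`.
#' @export
neuron_gt <- function(center, radius = 4, baseline_F = 100,
                      preferred_orientation_deg = 0, tuning_width_conc = 0.8,
                      visual_amplitude = 1.0, opsin_expressing = TRUE,
                      opto_amplitude = 1.0, dose_half_saturation = 0.0889) {
  if (radius <= 0) stopf("radius must be positive")
  if (visual_amplitude < 0 || opto_amplitude < 0)
    stopf("amplitudes must be non-negative")
  if (preferred_orientation_deg < 0 || preferred_orientation_deg >= 180)
    stopf("preferred orientation must lie in [0, 180)")
  structure(list(center = as.numeric(center), radius = radius,
                 baseline_F = baseline_F,
                 preferred_orientation_deg = preferred_orientation_deg,
                 tuning_width_conc = tuning_width_conc,
                 visual_amplitude = visual_amplitude,
                 opsin_expressing = isTRUE(opsin_expressing),
                 opto_amplitude = opto_amplitude,
                 dose_half_saturation = dose_half_saturation),
            class = "neuron_gt")
}

#' Calcium-indicator impulse response
#'
#' Peak-normalized double-exponential kernel
#' `k(t) = (exp(-t/decay) - exp(-t/rise)) / peak` for `t >= 0`. Defaults are
#' slow-indicator-like (0.18-s rise, 1-s decay); both are configurable.
#'
#' @param rise_tau_s rise time constant, seconds.
#' @param decay_tau_s decay time constant, seconds (> rise).
#' @return an object of class `calcium_kernel`; call [eval_kernel()] to
#'   evaluate it.
#' @export
calcium_kernel <- function(rise_tau_s = 0.18, decay_tau_s = 1.0) {
  if (!(decay_tau_s > rise_tau_s && rise_tau_s > 0))
    stopf("need decay_tau > rise_tau > 0")
  t_peak <- log(decay_tau_s / rise_tau_s) * rise_tau_s * decay_tau_s /
    (decay_tau_s - rise_tau_s)
  peak <- exp(-t_peak / decay_tau_s) - exp(-t_peak / rise_tau_s)
  structure(list(rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
                 t_peak_s = t_peak, peak = peak),
            class = "calcium_kernel")
}

#' Evaluate a calcium kernel at times `t`
#' @param kernel a [calcium_kernel()].
#' @param t numeric vector of seconds (values < 0 give 0).
#' @return kernel values, peak-normalized to 1.
#' @export
eval_kernel <- function(kernel, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / kernel$decay_tau_s) -
               exp(-t[pos] / kernel$rise_tau_s)) / kernel$peak
  out
}

#' Mean of the calcium kernel over a window (closed form)
#'
#' Average of the peak-normalized kernel over `[0, T]`; the factor by which a
#' window-mean dF/F understates the underlying response amplitude.
#'
#' @param kernel a [calcium_kernel()].
#' @param window_s window length T in seconds.
#' @return scalar in (0, 1).
#' @export
kernel_window_mean <- function(kernel, window_s) {
  td <- kernel$decay_tau_s; tr <- kernel$rise_tau_s
  (td * (1 - exp(-window_s / td)) - tr * (1 - exp(-window_s / tr))) /
    (kernel$peak * window_s)
}

# per-trial response amplitude of one neuron (dF/F units)
trial_amplitude <- function(neuron, condition, orientation_deg, intensity) {
  if (condition == "VisualStim") {
    if (is.na(orientation_deg)) return(neuron$visual_amplitude)
    d <- (orientation_deg - neuron$preferred_orientation_deg) * pi / 180
    neuron$visual_amplitude *
      exp((cos(2 * d) - 1) / neuron$tuning_width_conc^2)
  } else if (condition == "OptoStim") {
    if (!neuron$opsin_expressing) return(0)
    i <- if (is.na(intensity)) 0.8 else intensity
    neuron$opto_amplitude * i / (i + neuron$dose_half_saturation)
  } else 0
}

#' Generate a synthetic two-photon movie with ground truth
#'
#' Builds a T x H x W movie in which each neuron's fluorescence is
#' `baseline_F * (1 + dF/F(t))`, with dF/F the sum of per-trial responses
#' convolved with the indicator kernel. Visual responses follow each cell's
#' circular-Gaussian orientation tuning of the trial's grating (trial param
#' `orientation_deg`); optogenetic responses occur only in opsin-expressing
#' cells and saturate with the trial's laser intensity (trial param
#' `intensity_mw_mm2`). Frames are globally translated by Gaussian
#' per-frame motion and carry additive Gaussian noise; pixel values are
#' rounded to integers (PMT-count-like).
#'
#' @param neurons list of [neuron_gt()] objects, all inside the FOV.
#' @param trials a [trial_table()].
#' @param scan a [scan_config()] (sets the frame period).
#' @param kernel a [calcium_kernel()].
#' @param fov numeric length-2, (H, W) in pixels (default `c(128, 128)`).
#' @param duration_s movie length in seconds (default: last trial onset +
#'   5 s).
#' @param background_F background fluorescence level, a.u. (default 20).
#' @param motion_sd_px per-frame translation SD in pixels (default 0).
#' @param noise_sd additive Gaussian noise SD, a.u. (default 0, must be
#'   >= 0).
#' @param seed integer RNG seed.
#' @return list with `movie` (a [movie_stack()]) and `truth`: dF/F traces
#'   (neurons x frames), the injected `shifts` (data.frame `dx`, `dy`), the
#'   noiseless `baseline_image`, per-neuron labels, and the ROI set of the
#'   generating discs.
#' @export
gen_movie <- function(neurons, trials, scan = scan_config(),
                      kernel = calcium_kernel(), fov = c(128, 128),
                      duration_s = NULL, background_F = 20,
                      motion_sd_px = 0, noise_sd = 0, seed = 1L) {
  if (noise_sd < 0) stopf("noise sd must be non-negative")
  H <- fov[1]; W <- fov[2]
  for (nr in neurons) {
    if (nr$center[1] - nr$radius < 1 || nr$center[1] + nr$radius > H ||
        nr$center[2] - nr$radius < 1 || nr$center[2] + nr$radius > W)
      stopf("neuron at (%g, %g) extends outside the %d x %d FOV",
            nr$center[1], nr$center[2], H, W)
  }
  # stored frames are averages of `frames_averaged` raw scans (e.g. 8 fps
  # from a 32-fps resonant scan)
  fp <- scan$frame_period_s * scan$frames_averaged
  if (is.null(duration_s))
    duration_s <- if (nrow(trials)) max(trials$onset_s) + 5 else 2
  nT <- max(1L, ceiling(duration_s / fp))
  tt <- (seq_len(nT) - 1) * fp

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # per-neuron dF/F traces
  ori <- trial_param(trials, "orientation_deg")
  inten <- trial_param(trials, "intensity_mw_mm2")
  traces <- matrix(0, nrow = length(neurons), ncol = nT)
  for (i in seq_along(neurons)) {
    for (j in seq_len(nrow(trials))) {
      a <- trial_amplitude(neurons[[i]], trials$condition[j], ori[j], inten[j])
      if (a > 0)
        traces[i, ] <- traces[i, ] + a * eval_kernel(kernel, tt - trials$onset_s[j])
    }
  }

  # baseline image and per-neuron pixel masks
  base <- matrix(background_F, H, W)
  masks <- vector("list", length(neurons))
  rc <- expand.grid(r = seq_len(H), c = seq_len(W))
  for (i in seq_along(neurons)) {
    nr <- neurons[[i]]
    m <- (rc$r - nr$center[1])^2 + (rc$c - nr$center[2])^2 <= nr$radius^2
    masks[[i]] <- which(m)
    base[masks[[i]]] <- nr$baseline_F
  }

  shifts <- data.frame(
    dx = if (motion_sd_px > 0) stats::rnorm(nT, 0, motion_sd_px) else numeric(nT),
    dy = if (motion_sd_px > 0) stats::rnorm(nT, 0, motion_sd_px) else numeric(nT))

  arr <- array(0, dim = c(nT, H, W))
  for (f in seq_len(nT)) {
    img <- base
    for (i in seq_along(neurons))
      img[masks[[i]]] <- neurons[[i]]$baseline_F * (1 + traces[i, f])
    if (shifts$dx[f] != 0 || shifts$dy[f] != 0)
      img <- translate_image(img, shifts$dx[f], shifts$dy[f], fill = background_F)
    if (noise_sd > 0) img <- img + stats::rnorm(H * W, 0, noise_sd)
    arr[f, , ] <- pmax(round(img), 0)
  }

  rois <- roi_set(
    id = seq_along(neurons),
    center_r = vapply(neurons, function(n) n$center[1], numeric(1)),
    center_c = vapply(neurons, function(n) n$center[2], numeric(1)),
    radius = vapply(neurons, function(n) n$radius, numeric(1)),
    fov = c(H, W))

  labels <- data.frame(
    id = seq_along(neurons),
    preferred_orientation_deg =
      vapply(neurons, function(n) n$preferred_orientation_deg, numeric(1)),
    opsin_expressing = vapply(neurons, function(n) n$opsin_expressing, logical(1)),
    visual_amplitude = vapply(neurons, function(n) n$visual_amplitude, numeric(1)),
    opto_amplitude = vapply(neurons, function(n) n$opto_amplitude, numeric(1)))

  list(movie = movie_stack(arr, frame_period_s = fp,
                           meta = list(synthetic = TRUE, seed = seed)),
       truth = list(traces = traces, shifts = shifts, baseline_image = base,
                    labels = labels, rois = rois, frame_times = tt))
}

#' Inject the widefield stimulation artifact into a movie
#'
#' Emulates stimulation light leaking into the PMT: every scan line acquired
#' while the laser is on is driven to `saturation_level`. Lines map to time
#' within the frame in raster order, so with frame-locked gating that blanks
#' the central 75% of the FOV only the top and bottom image margins are
#' contaminated and the central band stays artifact-free; with continuous
#' stimulation the whole image saturates.
#'
#' @param movie a [movie_stack()].
#' @param schedule a [build_gating()] schedule covering exactly the movie's
#'   frames.
#' @param saturation_level saturated pixel value, a.u. (default 65535).
#' @return a [movie_stack()] with the artifact applied.
#' @export
inject_stim_artifact <- function(movie, schedule, saturation_level = 65535) {
  d <- dim(movie$data)
  if (attr(schedule, "n_frames") != d[1])
    stopf("schedule covers %d frames but movie has %d",
          attr(schedule, "n_frames"), d[1])
  fp <- attr(schedule, "frame_period_s")
  H <- d[2]
  arr <- movie$data
  row_start <- (seq_len(H) - 1) / H * fp  # acquisition window per line
  row_end <- seq_len(H) / H * fp
  for (f in seq_len(d[1])) {
    iv <- schedule[schedule$frame == f, , drop = FALSE]
    if (!nrow(iv)) next
    t0 <- (f - 1) * fp
    sat <- rep(FALSE, H)
    eps <- 1e-9 * fp  # guard against accumulated float error at line edges
    for (k in seq_len(nrow(iv))) {
      a <- iv$on_start_s[k] - t0; b <- iv$on_end_s[k] - t0
      sat <- sat | (row_start < b - eps & a + eps < row_end)
    }
    if (any(sat)) arr[f, sat, ] <- saturation_level
  }
  movie_stack(arr, frame_period_s = movie$frame_period_s, meta = movie$meta)
}

#' Generate synthetic eye-position traces with ground truth
#'
#' GO trials (VisualStim, OptoStim) contain a saccade modeled as a smooth
#' logistic position step toward the trial's endpoint, timed so the true
#' 1-degree crossing falls exactly at cue onset + latency. NO-GO-like trials
#' (NoStim, MisStim) hold fixation, apart from spontaneous saccades at
#' `guess_rate`. Fixation noise is white Gaussian per component.
#'
#' @param trials a [trial_table()].
#' @param latency_mean_ms,latency_sd_ms saccade latency distribution (ms from
#'   cue onset). Defaults 119 and 10.
#' @param endpoint_deg length-2 target endpoint (degrees from fixation),
#'   default `c(3, 0)` (about 3 degrees eccentric).
#' @param endpoint_sd_deg per-component scatter of trial endpoints (degrees),
#'   default 0.22.
#' @param fixation_noise_sd_deg fixation noise SD per component (degrees),
#'   default 0.05.
#' @param guess_rate probability a NO-GO-like trial contains a spontaneous
#'   saccade (default 0).
#' @param go_prob probability a GO trial actually contains a saccade
#'   (default 1); lower values emulate missed percepts.
#' @param sample_rate_hz eye-tracker sampling rate (default 120).
#' @param trial_duration_s trace length per trial (default 2.5).
#' @param transit_ms saccade transit time, 10-90% (default 30).
#' @param seed integer RNG seed.
#' @return list with `traces` (list of `eye_trace` objects: `time_s`, `x_deg`,
#'   `y_deg`, `trial_id`, `cue_onset_s`, `sample_rate_hz`) and `truth`
#'   (data.frame: trial_id, condition, has_saccade, latency_ms, endpoint x/y).
#' @export
gen_eye_traces <- function(trials, latency_mean_ms = 119, latency_sd_ms = 10,
                           endpoint_deg = c(3, 0), endpoint_sd_deg = 0.22,
                           fixation_noise_sd_deg = 0.05, guess_rate = 0,
                           go_prob = 1, sample_rate_hz = 120,
                           trial_duration_s = 2.5, transit_ms = 30,
                           seed = 1L) {
  if (sample_rate_hz <= 0) stopf("sample rate must be positive")
  if (latency_mean_ms / 1000 >= trial_duration_s)
    stopf("mean latency exceeds the trial duration")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)

  nt <- nrow(trials)
  tgrid <- seq(0, trial_duration_s, by = 1 / sample_rate_hz)
  s_scale <- (transit_ms / 1000) / 6  # logistic scale: ~full transit in 6 s.d.
  traces <- vector("list", nt)
  gt <- data.frame(trial_id = trials$trial_id, condition = trials$condition,
                   has_saccade = FALSE, latency_ms = NA_real_,
                   endpoint_x = NA_real_, endpoint_y = NA_real_)

  for (j in seq_len(nt)) {
    cue <- 0.2  # cue onset within the trace, seconds
    x <- stats::rnorm(length(tgrid), 0, fixation_noise_sd_deg)
    y <- stats::rnorm(length(tgrid), 0, fixation_noise_sd_deg)
    go <- trials$condition[j] %in% c("VisualStim", "OptoStim")
    make_sacc <- if (go) stats::runif(1) < go_prob else stats::runif(1) < guess_rate
    if (make_sacc) {
      lat_s <- if (go) {
        max(0.02, stats::rnorm(1, latency_mean_ms, latency_sd_ms) / 1000)
      } else stats::runif(1, 0.15, trial_duration_s - cue - 0.3)
      ep <- endpoint_deg + stats::rnorm(2, 0, endpoint_sd_deg)
      A <- sqrt(sum(ep^2))
      if (A > 1) {
        # place the logistic so the 1-degree crossing sits at cue + latency
        t0 <- cue + lat_s + s_scale * log(A - 1)
        prof <- A / (1 + exp(-(tgrid - t0) / s_scale))
        u <- ep / A
        x <- x + u[1] * prof
        y <- y + u[2] * prof
        gt$has_saccade[j] <- TRUE
        gt$latency_ms[j] <- lat_s * 1000
        gt$endpoint_x[j] <- ep[1]
        gt$endpoint_y[j] <- ep[2]
      }
    }
    traces[[j]] <- structure(list(time_s = tgrid, x_deg = x, y_deg = y,
                                  trial_id = trials$trial_id[j],
                                  cue_onset_s = cue,
                                  sample_rate_hz = sample_rate_hz),
                             class = "eye_trace")
  }
  list(traces = traces, truth = gt)
}

#' Write eye traces to CSV (long format)
#' @param traces list of `eye_trace` objects from [gen_eye_traces()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_eye_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trial_id = tr$trial_id, time_s = tr$time_s,
               x_deg = tr$x_deg, y_deg = tr$y_deg)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
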