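#' Resonant-scan configuration
#'
#' Geometry and timing of the imaging scan against which widefield
#' stimulation is gated. With the defaults — a 32-ms frame of which the
#' central 75% is blanked — stimulation is allowed for 8 ms of every frame:
#' a 25% duty cycle repeating at 31.25 Hz.
#'
#' @param frame_period_s raw scan-frame period in seconds (default 0.032).
#' @param fov_lines number of scan lines per frame (default 512).
#' @param blank_fraction fraction of each frame during which stimulation is
#'   forced off, i.e. while the scan covers the central portion of the field
#'   of view (default 0.75).
#' @param frames_averaged raw frames averaged into one stored frame
#'   (default 4).
#' @param raw_rate_fps raw scan rate in frames per second (default 32).
#' @return an object of class `scan_config`.
#' @examples
#' s <- scan_config()
#' effective_rate(s)  # 8 fps: 32 fps raw, averaging every 4 frames
#' @export
scan_config <- function(frame_period_s = 0.032, fov_lines = 512L,
                        blank_fraction = 0.75, frames_averaged = 4L,
                        raw_rate_fps = 32) {
  if (frame_period_s <= 0) stopf("frame_period_s must be positive")
  if (blank_fraction < 0 || blank_fraction > 1)
    stopf("blank_fraction must lie in [0, 1]")
  if (frames_averaged < 1L) stopf("frames_averaged must be >= 1")
  structure(list(frame_period_s = frame_period_s,
                 fov_lines = as.integer(fov_lines),
                 blank_fraction = blank_fraction,
                 frames_averaged = as.integer(frames_averaged),
                 raw_rate_fps = raw_rate_fps),
            class = "scan_config")
}

#' Effective imaging rate after frame averaging
#' @param scan a [scan_config()].
#' @return frames per second of the stored movie (raw rate / frames averaged).
#' @export
effective_rate <- function(scan) scan$raw_rate_fps / scan$frames_averaged

#' Stimulation protocol
#'
#' @param kind `"single_pulse"`, `"pulse_train"` or `"frame_locked"`.
#' @param wavelength_nm laser wavelength (default 532).
#' @param intensity_mw_mm2 irradiance at the cortex in mW/mm^2 (>= 0).
#' @param pulse_on_ms pulse on-time (ms, > 0 for active protocols).
#' @param pulse_off_ms off-time between pulses (ms, >= 0); period =
#'   `pulse_on_ms + pulse_off_ms` for pulse trains.
#' @param n_pulses number of pulses per trial.
#' @param spot_diameter_mm stimulation spot diameter (default 1).
#' @return an object of class `stim_protocol`.
#' @examples
#' # 15-Hz, 33%-duty train: 22 ms on, 44 ms off
#' p <- stim_protocol("pulse_train", intensity_mw_mm2 = 0.8,
#'                    pulse_on_ms = 22, pulse_off_ms = 44, n_pulses = 8)
#' duty_cycle(p)
#' @export
stim_protocol <- function(kind = c("single_pulse", "pulse_train", "frame_locked"),
                          wavelength_nm = 532, intensity_mw_mm2 = 0.8,
                          pulse_on_ms = 66, pulse_off_ms = 0, n_pulses = 1L,
                          spot_diameter_mm = 1) {
  kind <- match.arg(kind)
  if (intensity_mw_mm2 < 0) stopf("intensity must be non-negative")
  if (pulse_on_ms <= 0) stopf("pulse_on_ms must be positive for active protocols")
  if (pulse_off_ms < 0) stopf("pulse_off_ms must be non-negative")
  structure(list(kind = kind, wavelength_nm = wavelength_nm,
                 intensity_mw_mm2 = intensity_mw_mm2,
                 pulse_on_ms = pulse_on_ms, pulse_off_ms = pulse_off_ms,
                 n_pulses = as.integer(n_pulses),
                 spot_diameter_mm = spot_diameter_mm),
            class = "stim_protocol")
}

#' Pulse onset times of a protocol relative to cue onset
#' @param protocol a [stim_protocol()].
#' @return numeric vector of onsets in seconds (first pulse at 0).
#' @export
pulse_onsets <- function(protocol) {
  period_s <- (protocol$pulse_on_ms + protocol$pulse_off_ms) / 1000
  (seq_len(protocol$n_pulses) - 1) * period_s
}

#' Build a frame-locked gating schedule
#'
#' Models the blanking circuit that powers the widefield stimulation laser
#' down whenever the imaging scan covers the central `blank_fraction` of the
#' field of view. Each frame gets `frame_period_s * (1 - blank_fraction)` of
#' stimulation time, placed in the peripheral scan segments at the frame's
#' start and end (the scan enters and leaves the central band mid-frame), or
#' as one contiguous end-of-frame window when `split = FALSE`.
#'
#' @param scan a [scan_config()].
#' @param n_frames number of frames to schedule (default 1).
#' @param split logical; split the on-window across the frame's start and end
#'   (default `TRUE`, matching a bidirectional raster).
#' @return an object of class `gating_schedule`: a data.frame with columns
#'   `frame`, `on_start_s`, `on_end_s` (absolute times), plus attributes
#'   `duty_cycle`, `repetition_hz` and `frame_period_s`.
#' @examples
#' g <- build_gating(scan_config())          # 8 ms on per 32-ms frame
#' attr(g, "duty_cycle")                     # 0.25
#' attr(g, "repetition_hz")                  # 31.25
#' @export
build_gating <- function(scan, n_frames = 1L, split = TRUE) {
  stopifnot(inherits(scan, "scan_config"))
  fp <- scan$frame_period_s
  on_total <- fp * (1 - scan$blank_fraction)
  rows <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    t0 <- (f - 1) * fp
    if (on_total <= 0) {
      rows[[f]] <- data.frame(frame = integer(), on_start_s = numeric(),
                              on_end_s = numeric())
    } else if (split && on_total < fp) {
      half <- on_total / 2
      rows[[f]] <- data.frame(frame = c(f, f),
                              on_start_s = c(t0, t0 + fp - half),
                              on_end_s = c(t0 + half, t0 + fp))
    } else {
      rows[[f]] <- data.frame(frame = f, on_start_s = t0 + fp - on_total,
                              on_end_s = t0 + fp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            duty_cycle = on_total / fp,
            repetition_hz = 1 / fp,
            frame_period_s = fp,
            n_frames = as.integer(n_frames),
            class = c("gating_schedule", "data.frame"))
}

#' Duty cycle of a gating schedule or pulse protocol
#'
#' Fraction of time the stimulation light is on: total on-time over total
#' time for a frame-locked [gating_schedule][build_gating], and
#' `pulse_on / (pulse_on + pulse_off)` for a pulse train.
#'
#' @param x a `gating_schedule` or [stim_protocol()].
#' @return duty cycle in `[0, 1]`.
#' @examples
#' duty_cycle(build_gating(scan_config()))                      # 0.25
#' duty_cycle(stim_protocol("pulse_train", pulse_on_ms = 22,
#'                          pulse_off_ms = 44, n_pulses = 8))   # 1/3
#' @export
duty_cycle <- function(x) UseMethod("duty_cycle")

#' @export
duty_cycle.gating_schedule <- function(x) {
  total <- attr(x, "n_frames") * attr(x, "frame_period_s")
  if (total <= 0) stopf("zero total period")
  sum(x$on_end_s - x$on_start_s) / total
}

#' @export
duty_cycle.stim_protocol <- function(x) {
  period <- x$pulse_on_ms + x$pulse_off_ms
  if (period <= 0) stopf("zero total period")
  x$pulse_on_ms / period
}

#' Repetition frequency of a stimulation pattern
#'
#' For frame-locked gating this is the scan-frame rate (`1 / frame_period`);
#' for a pulse train it is the reciprocal of the pulse period. A 22-ms-on /
#' 44-ms-off train therefore reports 1/0.066 s = 15.15 Hz (colloquially a
#' "15 Hz" train).
#'
#' @param x a `gating_schedule` or [stim_protocol()].
#' @return repetition frequency in Hz.
#' @examples
#' repetition_frequency(build_gating(scan_config()))  # 31.25 Hz
#' @export
repetition_frequency <- function(x) UseMethod("repetition_frequency")

#' @export
repetition_frequency.gating_schedule <- function(x) {
  if (attr(x, "n_frames") < 1L) stopf("empty schedule")
  attr(x, "repetition_hz")
}

#' @export
repetition_frequency.stim_protocol <- function(x) {
  period_s <- (x$pulse_on_ms + x$pulse_off_ms) / 1000
  if (period_s <= 0) stopf("zero total period")
  1 / period_s
}

#' Schedule interleaved trials at fixed condition ratios
#'
#' Allocates `n` trials across conditions proportionally to integer weights
#' (largest-remainder rounding when `n` does not divide evenly), randomizes
#' the order, and lays trials out with at least `isi_s` between onsets.
#' Typical designs: 1:1 NoStim:VisualStim in visual sessions, and
#' 8:3:1 NoStim:OptoStim:MisStim in optogenetic sessions (66.7% NoStim,
#' 8.3% MisStim).
#'
#' @param ratio named numeric vector of positive weights, names in
#'   [TRIAL_CONDITIONS], e.g. `c(NoStim = 8, OptoStim = 3, MisStim = 1)`.
#' @param n total number of trials.
#' @param seed integer RNG seed for the interleaving order.
#' @param isi_s minimum interval between trial onsets in seconds
#'   (default 3; the design calls for > 2-s interstimulus intervals).
#' @param duration_ms stimulus duration per trial (default 66).
#' @param params optional named vector/list mapping condition to a params
#'   string attached to its trials.
#' @return a [trial_table()] with `n` rows.
#' @examples
#' tt <- schedule_trials(c(NoStim = 8, OptoStim = 3, MisStim = 1),
#'                       n = 1200, seed = 1)
#' table(tt$condition) / nrow(tt)
#' @export
schedule_trials <- function(ratio, n, seed = 1L, isi_s = 3, duration_ms = 66,
                            params = NULL) {
  if (length(ratio) == 0L) stopf("empty condition ratio")
  if (is.null(names(ratio)) || any(!nzchar(names(ratio))))
    stopf("ratio must be a named vector of condition weights")
  bad <- setdiff(names(ratio), TRIAL_CONDITIONS)
  if (length(bad)) stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  if (any(ratio <= 0)) stopf("weights must be positive")

  # largest-remainder apportionment: exact when n divides the weight sum
  quota <- n * ratio / sum(ratio)
  counts <- floor(quota)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  labels <- rep(names(ratio), times = counts)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- sample(labels)
  onsets <- (seq_len(n) - 1) * isi_s
  par_str <- vapply(labels, function(cc) {
    if (!is.null(params) && cc %in% names(params)) as.character(params[[cc]]) else ""
  }, character(1), USE.NAMES = FALSE)
  trial_table(seq_len(n), labels, onsets, duration_ms, par_str)
}

# save/restore the global RNG state so scheduling does not perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
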