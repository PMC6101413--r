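#' Detect a saccade in an eye trace by threshold crossing
#'
#' Finds the first sample at which the Euclidean distance from fixation
#' exceeds `threshold_deg` and stays above it for `confirm_samples`
#' consecutive samples (rejecting single-sample noise spikes). Latency is
#' measured from cue onset to that crossing; the endpoint is the gaze
#' position `settle_s` after the crossing (clamped to the trace end).
#'
#' @param trace an `eye_trace` (see [gen_eye_traces()]) or a list with
#'   `time_s`, `x_deg`, `y_deg`, `cue_onset_s`.
#' @param fixation length-2 fixation-point position, degrees (default
#'   `c(0, 0)`).
#' @param threshold_deg displacement threshold (default 1).
#' @param confirm_samples samples the displacement must stay above threshold
#'   (default 2).
#' @param settle_s endpoint read-out delay after crossing, seconds
#'   (default 0.05).
#' @return a `saccade_event` (list: `trial_id`, `crossing_s`, `latency_ms`,
#'   `endpoint` (x, y), `amplitude_deg`) or `NULL` when no crossing is found.
#' @export
detect_saccade <- function(trace, fixation = c(0, 0), threshold_deg = 1,
                           confirm_samples = 2L, settle_s = 0.05) {
  if (!length(trace$time_s)) stopf("empty eye trace")
  if (threshold_deg <= 0) stopf("threshold must be positive")
  d <- sqrt((trace$x_deg - fixation[1])^2 + (trace$y_deg - fixation[2])^2)
  above <- d > threshold_deg
  n <- length(above)
  k <- max(1L, as.integer(confirm_samples))
  cross <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run == k) { cross <- i - k + 1L; break }
  }
  if (is.na(cross)) return(NULL)
  tc <- trace$time_s[cross]
  cue <- trace$cue_onset_s %||% 0
  ei <- which.min(abs(trace$time_s - (tc + settle_s)))
  ep <- c(trace$x_deg[ei], trace$y_deg[ei])
  structure(list(trial_id = trace$trial_id %||% NA_integer_,
                 crossing_s = tc,
                 latency_ms = (tc - cue) * 1000,
                 endpoint = ep,
                 amplitude_deg = sqrt(sum((ep - fixation)^2))),
            class = "saccade_event")
}

#' Score one trial under the GO/NO-GO rules
#'
#' GO trials (VisualStim: respond to a flashed cue; OptoStim / MisStim:
#' respond to the laser) succeed when a saccade crosses threshold within the
#' GO window and reaches the block's amplitude rule (1 degree in visual
#' blocks — the threshold itself — and 2 degrees in optogenetic blocks).
#' NO-GO trials (NoStim) succeed when fixation is held — no threshold
#' crossing — for the full hold period.
#'
#' @param condition the trial's condition label (see [TRIAL_CONDITIONS]).
#' @param event a [detect_saccade()] result or `NULL`.
#' @param config a [pipeline_config()] carrying the GO window, NO-GO hold and
#'   amplitude rules.
#' @return `"success"` or `"fail"`.
#' @export
score_trial <- function(condition, event, config = pipeline_config()) {
  if (!condition %in% TRIAL_CONDITIONS) stopf("no rule for condition %s", condition)
  if (condition == "NoStim") {
    ok <- is.null(event) ||
      (event$latency_ms > config$nogo_hold_ms)
    return(if (ok) "success" else "fail")
  }
  amp_rule <- if (condition == "VisualStim") config$saccade_threshold_deg
              else config$opto_amplitude_deg
  ok <- !is.null(event) &&
    !is.na(event$latency_ms) && event$latency_ms >= 0 &&
    event$latency_ms <= config$go_window_ms &&
    event$amplitude_deg >= amp_rule
  if (ok) "success" else "fail"
}

#' Summarize behavior per condition
#'
#' Per condition: trial count, response rate (detected saccade with latency
#' inside the GO window), success rate under the condition's rule, latency
#' mean and SE, and the endpoint SD — the pooled per-component SD of
#' endpoints about the condition's mean endpoint.
#'
#' @param trials a [trial_table()].
#' @param events list of [detect_saccade()] results (or `NULL`s), one per
#'   trial, in trial order.
#' @param config a [pipeline_config()].
#' @return `data.frame` of class `behavior_summary`: `condition`, `n`,
#'   `response_rate`, `success_rate`, `latency_mean_ms`, `latency_se_ms`,
#'   `endpoint_sd_deg`.
#' @export
summarize_behavior <- function(trials, events, config = pipeline_config()) {
  stopifnot(length(events) == nrow(trials))
  outcomes <- vapply(seq_len(nrow(trials)), function(j)
    score_trial(trials$condition[j], events[[j]], config), character(1))
  conds <- unique(trials$condition)
  out <- lapply(conds, function(cc) {
    sel <- which(trials$condition == cc)
    ev <- events[sel]
    has <- !vapply(ev, is.null, logical(1))
    lat <- vapply(ev[has], function(e) e$latency_ms, numeric(1))
    responded <- has
    responded[has] <- lat >= 0 & lat <= config$go_window_ms
    epx <- vapply(ev[has], function(e) e$endpoint[1], numeric(1))
    epy <- vapply(ev[has], function(e) e$endpoint[2], numeric(1))
    ep_sd <- if (sum(has) >= 2) {
      sqrt((sum((epx - mean(epx))^2) + sum((epy - mean(epy))^2)) /
             (2 * (sum(has) - 1)))
    } else NA_real_
    data.frame(condition = cc, n = length(sel),
               response_rate = mean(responded),
               success_rate = mean(outcomes[sel] == "success"),
               latency_mean_ms = if (any(has)) mean(lat) else NA_real_,
               latency_se_ms = if (sum(has) > 1)
                 stats::sd(lat) / sqrt(sum(has)) else NA_real_,
               endpoint_sd_deg = ep_sd)
  })
  res <- do.call(rbind, out)
  class(res) <- c("behavior_summary", "data.frame")
  res
}

#' Split saccade latencies across the pulses of a train
#'
#' Under pulse-train stimulation a saccade may be driven by any pulse, not
#' just the first. Each saccade is assigned to the latest pulse whose onset
#' precedes `crossing - min_reaction_ms`; its within-group latency is then
#' measured from that pulse's onset. Crossings earlier than the first pulse
#' plus the minimum reaction time are flagged anticipatory.
#'
#' @param events list of [detect_saccade()] results (non-`NULL`).
#' @param protocol a [stim_protocol()] pulse train (`pulse_onsets()` gives
#'   onsets relative to cue).
#' @param min_reaction_ms physiological reaction-time floor (default 60).
#' @return `data.frame`: `trial_id`, `crossing_latency_ms` (from cue),
#'   `pulse` (1-based group, `NA` when anticipatory), `pulse_latency_ms`
#'   (from the assigned pulse's onset), `anticipatory`.
#' @export
latency_split <- function(events, protocol, min_reaction_ms = 60) {
  onsets_ms <- pulse_onsets(protocol) * 1000
  rows <- lapply(events, function(e) {
    lat <- e$latency_ms
    eligible <- which(onsets_ms <= lat - min_reaction_ms)
    if (!length(eligible)) {
      data.frame(trial_id = e$trial_id, crossing_latency_ms = lat,
                 pulse = NA_integer_, pulse_latency_ms = NA_real_,
                 anticipatory = TRUE)
    } else {
      g <- max(eligible)
      data.frame(trial_id = e$trial_id, crossing_latency_ms = lat,
                 pulse = g, pulse_latency_ms = lat - onsets_ms[g],
                 anticipatory = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Success rate versus laser pulse duration
#'
#' @param duration_ms pulse duration per trial (ms).
#' @param outcome per-trial `"success"`/`"fail"` (or logical).
#' @return `data.frame`: `duration_ms`, `n`, `success_rate`, `se` (binomial
#'   standard error).
#' @export
success_vs_duration <- function(duration_ms, outcome) {
  stopifnot(length(duration_ms) == length(outcome))
  succ <- if (is.logical(outcome)) outcome else outcome == "success"
  lev <- sort(unique(duration_ms))
  out <- lapply(lev, function(d) {
    s <- succ[duration_ms == d]
    p <- mean(s)
    data.frame(duration_ms = d, n = length(s), success_rate = p,
               se = sqrt(p * (1 - p) / length(s)))
  })
  do.call(rbind, out)
}
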