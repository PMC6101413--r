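#' Run the full synthetic-session pipeline
#'
#' Generates a ground-truth-labeled synthetic session from `config` (movie,
#' trial schedule, eye traces), then runs every analysis stage over it:
#' frame-locked gating, motion registration, ROI trace extraction, dF/F
#' responses, visual-vs-opto comparison, orientation tuning and behavior
#' scoring. All outputs plus a run manifest (config hash, seed, package
#' version) are written under `out_dir`. Deterministic given the config's
#' seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @param n_trials trials in the synthetic schedule (default 12).
#' @param n_neurons simulated neurons (default 5).
#' @param fov movie size in pixels (default `c(64, 64)`).
#' @param motion_sd_px injected per-frame motion SD (default 1).
#' @param noise_sd movie noise SD, a.u. (default 3).
#' @param quiet suppress stage logging.
#' @return (invisibly) list of stage results: `trials`, `gating`,
#'   `registration shifts`, `responses`, `mode_comparison`, `behavior`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = "opto2p_run",
                         n_trials = 12L, n_neurons = 5L, fov = c(64, 64),
                         motion_sd_px = 1, noise_sd = 3, quiet = FALSE) {
  log_stage <- function(...) if (!quiet) message("[opto2p] ", sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  log_stage("simulate: %d trials, %d neurons, %d x %d px, seed %d",
            n_trials, n_neurons, fov[1], fov[2], seed)
  trials <- run("simulate", schedule_trials(
    c(NoStim = 8, VisualStim = 3, OptoStim = 3), n = n_trials, seed = seed,
    isi_s = 4, duration_ms = 500,
    params = c(VisualStim = format_params(orientation_deg = 90),
               OptoStim = format_params(intensity_mw_mm2 = 0.8))))
  make_neurons <- function() {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(seed + 1)
    lapply(seq_len(n_neurons), function(i)
      neuron_gt(center = c(stats::runif(1, 12, fov[1] - 12),
                           stats::runif(1, 12, fov[2] - 12)),
                radius = 4, baseline_F = 120,
                preferred_orientation_deg = (i - 1) * 180 / n_neurons,
                visual_amplitude = 0.8, opto_amplitude = 0.8))
  }
  neurons <- run("simulate", make_neurons())
  sim <- run("simulate", gen_movie(neurons, trials, scan = config$scan,
                                   fov = fov, motion_sd_px = motion_sd_px,
                                   noise_sd = noise_sd, seed = seed))
  write_movie(sim$movie, file.path(out_dir, "movie_raw.tif"))
  write_trials(trials, file.path(out_dir, "trials.csv"))

  log_stage("gate: duty cycle %.3g", 1 - config$scan$blank_fraction)
  gating <- run("gate", build_gating(config$scan, n_frames = dim(sim$movie)[1]))
  utils::write.csv(as.data.frame(gating), file.path(out_dir, "gating.csv"),
                   row.names = FALSE)

  log_stage("register: %d frames", dim(sim$movie)[1])
  reg <- run("register", register_movie(sim$movie, max_shift = 4L))
  write_movie(reg$movie, file.path(out_dir, "movie_registered.tif"))
  utils::write.csv(reg$shifts, file.path(out_dir, "shifts.csv"), row.names = FALSE)

  log_stage("traces: %d ROIs", nrow(sim$truth$rois))
  traces <- run("traces", extract_traces(reg$movie, sim$truth$rois))
  tr_df <- data.frame(roi_id = rep(traces$roi_id, ncol(traces$F)),
                      time_s = rep(traces$time_s, each = nrow(traces$F)),
                      F = as.vector(traces$F))
  utils::write.csv(tr_df, file.path(out_dir, "traces.csv"), row.names = FALSE)

  responses <- run("traces", compute_dff(
    traces, trials, baseline_window_s = config$baseline_window_s,
    response_extra_s = config$response_window_s))
  utils::write.csv(as.data.frame(responses), file.path(out_dir, "responses.csv"),
                   row.names = FALSE)

  log_stage("compare modes")
  modes <- run("tuning", compare_modes(responses, alpha = config$anova_alpha))
  utils::write.csv(as.data.frame(modes), file.path(out_dir, "mode_comparison.csv"),
                   row.names = FALSE)

  log_stage("behavior: synthetic eye traces")
  eyes <- run("behavior", gen_eye_traces(trials, seed = seed))
  write_eye_traces(eyes$traces, file.path(out_dir, "eye_traces.csv"))
  events <- run("behavior", lapply(eyes$traces, function(tr)
    detect_saccade(tr, threshold_deg = config$saccade_threshold_deg)))
  behav <- run("behavior", summarize_behavior(trials, events, config))
  utils::write.csv(as.data.frame(behav), file.path(out_dir, "behavior.csv"),
                   row.names = FALSE)

  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  manifest <- list(
    config_hash = fnv1a32(readLines(cfg_path, warn = FALSE)),
    seed = seed,
    package = "opto2p",
    package_version = as.character(utils::packageVersion("opto2p")),
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  log_stage("done: outputs in %s", out_dir)

  invisible(list(trials = trials, gating = gating, shifts = reg$shifts,
                 responses = responses, mode_comparison = modes,
                 behavior = behav, manifest = manifest))
}
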