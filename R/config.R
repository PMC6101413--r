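#' Pipeline configuration
#'
#' Bundles the scan geometry, stimulation protocols, analysis windows,
#' decision thresholds and the random seed for a full pipeline run. All times
#' are seconds unless a field name says otherwise.
#'
#' @param scan a [scan_config()].
#' @param protocols list of [stim_protocol()] objects.
#' @param baseline_window_s length of the pre-onset baseline window used for
#'   F0 (seconds, >= 0).
#' @param response_window_s length of the post-onset response window added to
#'   the stimulus duration (seconds, >= 0); slow indicators keep the response
#'   elevated well past stimulus offset.
#' @param anova_alpha significance level for orientation-tuning selection
#'   (one-way ANOVA across orientations), in (0, 1). Default 0.05.
#' @param saccade_threshold_deg displacement from fixation that counts as a
#'   saccade (degrees). Default 1.
#' @param go_window_ms time allowed after cue onset for a rewarded saccade on
#'   GO trials (ms). Default 500.
#' @param nogo_hold_ms fixation hold required on NO-GO trials (ms).
#'   Default 2000.
#' @param opto_amplitude_deg minimum saccade amplitude on optogenetic GO
#'   trials (degrees). Default 2 (visual GO trials use the 1-degree
#'   threshold itself).
#' @param seed integer RNG seed, fixed per run and recorded in the run
#'   manifest.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(scan = scan_config(),
                            protocols = list(),
                            baseline_window_s = 1.0,
                            response_window_s = 1.0,
                            anova_alpha = 0.05,
                            saccade_threshold_deg = 1.0,
                            go_window_ms = 500,
                            nogo_hold_ms = 2000,
                            opto_amplitude_deg = 2.0,
                            seed = 1L) {
  stopifnot(inherits(scan, "scan_config"))
  if (baseline_window_s < 0 || response_window_s < 0)
    stopf("analysis windows must have non-negative length")
  if (anova_alpha <= 0 || anova_alpha >= 1) stopf("anova_alpha must be in (0,1)")
  if (saccade_threshold_deg <= 0) stopf("saccade threshold must be positive")
  structure(list(scan = scan, protocols = protocols,
                 baseline_window_s = baseline_window_s,
                 response_window_s = response_window_s,
                 anova_alpha = anova_alpha,
                 saccade_threshold_deg = saccade_threshold_deg,
                 go_window_ms = go_window_ms, nogo_hold_ms = nogo_hold_ms,
                 opto_amplitude_deg = opto_amplitude_deg,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The format is chosen by file extension (`.json` vs `.yml`/`.yaml`).
#'
#' @param path config file path.
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else stopf("unsupported config extension: .%s", ext)
  sc <- do.call(scan_config, as.list(raw$scan %||% list()))
  pr <- raw$protocols %||% list()
  if (is.data.frame(pr)) pr <- lapply(seq_len(nrow(pr)), function(i) as.list(pr[i, ]))
  prot <- lapply(pr, function(p) do.call(stim_protocol, as.list(p)))
  args <- raw[setdiff(names(raw), c("scan", "protocols"))]
  do.call(pipeline_config, c(list(scan = sc, protocols = prot), args))
}

#' Write a pipeline configuration to JSON or YAML
#' @param config a [pipeline_config()].
#' @param path output path (`.json`, `.yml` or `.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$scan <- unclass(x$scan)
  x$protocols <- lapply(x$protocols, unclass)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else if (ext %in% c("yml", "yaml")) yaml::write_yaml(x, path)
  else stopf("unsupported config extension: .%s", ext)
  invisible(path)
}
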