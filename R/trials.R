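#' Trial conditions recognized by the pipeline
#'
#' `NoStim` (catch / NO-GO), `VisualStim` (grating or patch GO cue),
#' `OptoStim` (laser GO cue on the opsin-expressing site) and `MisStim`
#' (laser redirected to a non-expressing site; artifact control).
#' @export
TRIAL_CONDITIONS <- c("NoStim", "VisualStim", "OptoStim", "MisStim")

#' Construct a trial table
#'
#' An ordered table of trials with condition labels, onset times and protocol
#' parameters. Onsets are seconds from session start and must be
#' non-decreasing.
#'
#' @param trial_id integer ids (unique).
#' @param condition character, each in [TRIAL_CONDITIONS].
#' @param onset_s trial (cue/stimulus) onset in seconds, non-decreasing.
#' @param duration_ms stimulus duration in milliseconds.
#' @param params free-form per-trial parameter string
#'   (`"key=value;key=value"`), e.g. grating orientation or laser intensity.
#' @return a `data.frame` of class `trial_table`.
#' @export
trial_table <- function(trial_id, condition, onset_s, duration_ms,
                        params = "") {
  bad <- setdiff(unique(condition), TRIAL_CONDITIONS)
  if (length(bad))
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  if (is.unsorted(onset_s)) stopf("trial onsets must be non-decreasing")
  if (anyDuplicated(trial_id)) stopf("trial ids must be unique")
  df <- data.frame(trial_id = as.integer(trial_id),
                   condition = as.character(condition),
                   onset_s = as.numeric(onset_s),
                   duration_ms = rep_len(as.numeric(duration_ms),
                                         length(trial_id)),
                   params = rep_len(as.character(params), length(trial_id)),
                   stringsAsFactors = FALSE)
  df <- df[order(df$onset_s), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("trial_table", "data.frame")
  df
}

#' Read a trial table from CSV
#'
#' Expects columns `trial_id, condition, onset_s, duration_ms, params`.
#' Rows are returned ordered by onset. An empty CSV yields an empty table
#' with a warning.
#'
#' @param path CSV path.
#' @return a [trial_table()].
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stopf("trial file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(params = "character"))
  need <- c("trial_id", "condition", "onset_s", "duration_ms", "params")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("trial CSV missing column(s): %s", paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty trial table: ", path, call. = FALSE)
    return(trial_table(integer(), character(), numeric(), numeric(), character()))
  }
  trial_table(df$trial_id, df$condition, df$onset_s, df$duration_ms, df$params)
}

#' Write a trial table to CSV
#' @param trials a [trial_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' Extract a numeric parameter from trial `params` strings
#'
#' @param trials a [trial_table()].
#' @param key parameter name, e.g. `"orientation_deg"` or
#'   `"intensity_mw_mm2"`.
#' @param default value when a trial does not carry the key.
#' @return numeric vector, one element per trial.
#' @export
trial_param <- function(trials, key, default = NA_real_) {
  vapply(trials$params, function(p) {
    if (is.na(p) || !nzchar(p)) return(default)
    kv <- strsplit(strsplit(p, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (x in kv) if (length(x) == 2L && x[1] == key) return(as.numeric(x[2]))
    default
  }, numeric(1), USE.NAMES = FALSE)
}

# build a params string from named values
format_params <- function(...) {
  v <- c(...)
  if (!length(v)) return("")
  paste(sprintf("%s=%.10g", names(v), as.numeric(v)), collapse = ";")
}
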