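mk_trace <- function(x, y, rate = 120, cue = 0, trial_id = 1L) {
  n <- length(x)
  structure(list(time_s = (seq_len(n) - 1) / rate, x_deg = x, y_deg = y,
                 trial_id = trial_id, cue_onset_s = cue,
                 sample_rate_hz = rate), class = "eye_trace")
}

test_that("fixation noise below threshold yields no detection", {
  set.seed(16)
  tr <- mk_trace(rnorm(240, 0, 0.1), rnorm(240, 0, 0.1))
  expect_null(detect_saccade(tr))
  expect_error(detect_saccade(mk_trace(numeric(), numeric())), "empty")
})

test_that("a step saccade is detected at the first sample past its onset", {
  rate <- 120
  n <- 121
  t_step <- 0.100                       # step to 3 degrees at 100 ms
  x <- ifelse((seq_len(n) - 1) / rate >= t_step, 3, 0)
  tr <- mk_trace(x, numeric(n) * 0)
  ev <- detect_saccade(tr)
  expect_false(is.null(ev))
  # crossing lands on the first sample at or after the step: within one sample
  expect_lte(abs(ev$latency_ms - 100), 1000 / rate)
  expect_gte(ev$latency_ms, 100 - 1e-9)
  expect_equal(ev$amplitude_deg, 3)
  expect_equal(ev$endpoint, c(3, 0))
})

test_that("detection latency error is at most one sample at any onset phase", {
  rate <- 120
  for (t_step in seq(0.050, 0.300, by = 0.013)) {
    n <- 121
    x <- ifelse((seq_len(n) - 1) / rate >= t_step, 2.5, 0)
    ev <- detect_saccade(mk_trace(x, numeric(n)))
    expect_lte(ev$latency_ms - t_step * 1000, 1000 / rate + 1e-9)
    expect_gte(ev$latency_ms - t_step * 1000, -1e-9)
  }
})

test_that("single-sample noise spikes are rejected by confirmation", {
  x <- numeric(240); x[100] <- 5      # one-sample glitch
  expect_null(detect_saccade(mk_trace(x, numeric(240)), confirm_samples = 2))
  x[101] <- 5                          # sustained for two samples
  ev <- detect_saccade(mk_trace(x, numeric(240)), confirm_samples = 2)
  expect_equal(ev$crossing_s, 99 / 120)
})

test_that("generator latencies are recovered within one sample", {
  tt <- trial_table(1:200, rep("OptoStim", 200),
                    seq(0, by = 3, length.out = 200), 66)
  eyes <- gen_eye_traces(tt, latency_mean_ms = 119, latency_sd_ms = 8,
                         fixation_noise_sd_deg = 0.05, seed = 17)
  det <- vapply(seq_along(eyes$traces), function(i)
    detect_saccade(eyes$traces[[i]])$latency_ms, numeric(1))
  # detection quantizes up to the next sample; fixation noise can move the
  # measured crossing by at most about one further sample either way
  err <- det - eyes$truth$latency_ms
  expect_true(all(err >= -1000 / 120 - 1e-6))
  expect_true(all(err <= 2 * 1000 / 120 + 1e-6))
  expect_lte(abs(mean(det) - 119), 1000 / 120)  # mean within one sample
})

test_that("GO/NO-GO scoring follows the window, hold and amplitude rules", {
  cfg <- pipeline_config()
  ev <- function(lat, amp) structure(
    list(trial_id = 1L, crossing_s = lat / 1000, latency_ms = lat,
         endpoint = c(amp, 0), amplitude_deg = amp), class = "saccade_event")
  # GO: saccade at 300 ms, amplitude 3 degrees -> success
  expect_equal(score_trial("VisualStim", ev(300, 3), cfg), "success")
  expect_equal(score_trial("OptoStim", ev(300, 3), cfg), "success")
  # outside the 500-ms window -> fail
  expect_equal(score_trial("VisualStim", ev(600, 3), cfg), "fail")
  # amplitude rules: visual 1 degree, opto 2 degrees
  expect_equal(score_trial("VisualStim", ev(300, 1.5), cfg), "success")
  expect_equal(score_trial("OptoStim", ev(300, 1.5), cfg), "fail")
  # NO-GO: holding fixation succeeds, breaking it fails
  expect_equal(score_trial("NoStim", NULL, cfg), "success")
  expect_equal(score_trial("NoStim", ev(800, 3), cfg), "fail")
  expect_equal(score_trial("NoStim", ev(2500, 3), cfg), "success")
  expect_equal(score_trial("MisStim", NULL, cfg), "fail")
  expect_error(score_trial("Foo", NULL, cfg), "no rule")
})

test_that("shrinking the GO window never converts a fail to a success", {
  ev <- function(lat) structure(
    list(trial_id = 1L, crossing_s = lat / 1000, latency_ms = lat,
         endpoint = c(3, 0), amplitude_deg = 3), class = "saccade_event")
  lats <- seq(50, 900, by = 50)
  windows <- c(900, 700, 500, 300, 100)
  prev <- rep(TRUE, length(lats))
  for (w in windows) {
    cfg <- pipeline_config(go_window_ms = w)
    cur <- vapply(lats, function(l)
      score_trial("OptoStim", ev(l), cfg) == "success", logical(1))
    expect_true(all(cur <= prev))  # monotone in the window
    prev <- cur
  }
})

test_that("behavior summaries aggregate rates, latencies and endpoint scatter", {
  tt <- schedule_trials(c(NoStim = 1, VisualStim = 1), n = 188, seed = 18)
  eyes <- gen_eye_traces(tt, endpoint_sd_deg = 0.22, guess_rate = 0, seed = 18)
  events <- lapply(eyes$traces, detect_saccade)
  bs <- summarize_behavior(tt, events)
  vis <- bs[bs$condition == "VisualStim", ]   # n = 94 GO trials
  expect_equal(vis$n, 94L)
  expect_equal(vis$success_rate, 1)
  expect_equal(vis$response_rate, 1)
  # endpoint scatter recovered at the generator's 0.22-degree SD
  expect_equal(vis$endpoint_sd_deg, 0.22, tolerance = 0.2)
  nos <- bs[bs$condition == "NoStim", ]
  expect_equal(nos$response_rate, 0)
  expect_equal(nos$success_rate, 1)
})

test_that("latencies split across pulses by the minimum reaction time", {
  train <- stim_protocol("pulse_train", pulse_on_ms = 22, pulse_off_ms = 44,
                         n_pulses = 4)
  ev <- function(id, lat) structure(
    list(trial_id = id, crossing_s = lat / 1000, latency_ms = lat,
         endpoint = c(3, 0), amplitude_deg = 3), class = "saccade_event")
  # crossings at 96 and 96 + 66 ms: pulses 1 and 2, both 96 ms within group
  ls <- latency_split(list(ev(1, 96), ev(2, 96 + 66)), train)
  expect_equal(ls$pulse, c(1L, 2L))
  expect_equal(ls$pulse_latency_ms, c(96, 96))
  expect_false(any(ls$anticipatory))
  # single-pulse protocol: one group only
  single <- stim_protocol("single_pulse", pulse_on_ms = 66, n_pulses = 1)
  ls1 <- latency_split(list(ev(1, 96), ev(2, 250)), single)
  expect_equal(ls1$pulse, c(1L, 1L))
  # crossing before first pulse + minimum reaction time: anticipatory
  ls0 <- latency_split(list(ev(1, 10)), train)
  expect_true(ls0$anticipatory)
  expect_true(is.na(ls0$pulse))
})

test_that("pulse-group assignment shifts with whole pulse periods", {
  train <- stim_protocol("pulse_train", pulse_on_ms = 22, pulse_off_ms = 44,
                         n_pulses = 6)
  ev <- function(lat) structure(
    list(trial_id = 1L, crossing_s = lat / 1000, latency_ms = lat,
         endpoint = c(3, 0), amplitude_deg = 3), class = "saccade_event")
  base <- latency_split(list(ev(100)), train)
  for (k in 1:3) {
    shifted <- latency_split(list(ev(100 + k * 66)), train)
    expect_equal(shifted$pulse, base$pulse + k)
    expect_equal(shifted$pulse_latency_ms, base$pulse_latency_ms)
  }
})

test_that("success rates by pulse duration carry binomial errors", {
  # deterministic generator: no responses at 22 ms, all respond at 44 ms
  dur <- rep(c(22, 44), each = 50)
  out <- c(rep("fail", 50), rep("success", 50))
  sv <- success_vs_duration(dur, out)
  expect_equal(sv$success_rate, c(0, 1))
  expect_equal(sv$se, c(0, 0))
  # p = 0.92 at 44 ms cumulative duration, n = 100
  set.seed(19)
  succ <- runif(100) < 0.92
  sv2 <- success_vs_duration(rep(44, 100), succ)
  expect_equal(sv2$success_rate, 0.92, tolerance = 3 * sqrt(0.92 * 0.08 / 100))
  expect_equal(sv2$se, sqrt(sv2$success_rate * (1 - sv2$success_rate) / 100))
  # single trial per duration: rates are 0 or 1
  sv3 <- success_vs_duration(c(22, 44, 66), c(FALSE, TRUE, TRUE))
  expect_true(all(sv3$success_rate %in% c(0, 1)))
})
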