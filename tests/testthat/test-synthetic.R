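test_that("zero amplitude, noise and motion give a constant baseline movie", {
  neurons <- list(neuron_gt(c(20, 20), visual_amplitude = 0, opto_amplitude = 0))
  tt <- fixture_opto_trials(n = 2)
  sim <- gen_movie(neurons, tt, fov = c(40, 40), seed = 1)
  expect_true(all(apply(sim$movie$data, 1, function(f)
    identical(f, sim$truth$baseline_image))))
  expect_equal(max(sim$truth$traces), 0)
})

test_that("a saturating opto trial peaks at the opto amplitude", {
  amp <- 1.2
  nr <- neuron_gt(c(20, 20), opto_amplitude = amp, dose_half_saturation = 1e-9)
  tt <- fixture_opto_trials(n = 1, intensity = 10)  # far above half-saturation
  sim <- gen_movie(list(nr), tt, fov = c(40, 40), seed = 1)
  # kernel is peak-normalized, so the trace maximum approaches amp at the
  # kernel peak (frame sampling sits within one frame of the true peak)
  k <- calcium_kernel()
  tpk <- k$t_peak_s
  fp <- sim$movie$frame_period_s
  expect_gte(max(sim$truth$traces), amp * min(eval_kernel(k, tpk - fp),
                                              eval_kernel(k, tpk + fp)))
  expect_lte(max(sim$truth$traces), amp)
})

test_that("non-expressing neurons ignore optogenetic trials", {
  nr <- neuron_gt(c(20, 20), opsin_expressing = FALSE, opto_amplitude = 2)
  sim <- gen_movie(list(nr), fixture_opto_trials(n = 3), fov = c(40, 40),
                   seed = 1)
  expect_equal(max(abs(sim$truth$traces)), 0)
  expect_true(all(apply(sim$movie$data, 1, function(f)
    identical(f, sim$truth$baseline_image))))
})

test_that("visual responses follow the cell's orientation tuning", {
  nr <- neuron_gt(c(20, 20), preferred_orientation_deg = 60,
                  visual_amplitude = 1, tuning_width_conc = 0.8)
  tt <- fixture_orientation_trials(reps = 1, isi = 8)
  sim <- gen_movie(list(nr), tt, fov = c(40, 40), seed = 1)
  # peak amplitude per trial scales with the circular-Gaussian tuning weight
  fp <- sim$movie$frame_period_s
  per_trial_peak <- vapply(seq_len(nrow(tt)), function(j) {
    win <- sim$truth$frame_times >= tt$onset_s[j] &
      sim$truth$frame_times < tt$onset_s[j] + 4
    max(sim$truth$traces[1, win])
  }, numeric(1))
  w <- exp((cos(2 * (seq(0, 150, 30) - 60) * pi / 180) - 1) / 0.8^2)
  expect_equal(per_trial_peak / max(per_trial_peak), w / max(w), tolerance = 0.02)
})

test_that("generators are pure functions of parameters and seed", {
  neurons <- fixture_neurons(3, fov = c(40, 40))
  tt <- fixture_opto_trials(n = 2)
  a <- gen_movie(neurons, tt, fov = c(40, 40), motion_sd_px = 1, noise_sd = 3,
                 seed = 9)
  b <- gen_movie(neurons, tt, fov = c(40, 40), motion_sd_px = 1, noise_sd = 3,
                 seed = 9)
  expect_identical(a$movie$data, b$movie$data)
  expect_identical(a$truth$shifts, b$truth$shifts)
  c <- gen_movie(neurons, tt, fov = c(40, 40), motion_sd_px = 1, noise_sd = 3,
                 seed = 10)
  expect_false(identical(a$movie$data, c$movie$data))
  expect_error(gen_movie(list(neuron_gt(c(2, 2))), tt, fov = c(40, 40)),
               "outside")
  expect_error(gen_movie(neurons, tt, fov = c(40, 40), noise_sd = -1),
               "non-negative")
})

test_that("with zero motion, frames differ only by evoked signal", {
  nr <- neuron_gt(c(20, 20), opto_amplitude = 1)
  tt <- fixture_opto_trials(n = 1)
  sim <- gen_movie(list(nr), tt, fov = c(40, 40), seed = 1)
  mask_out <- sim$truth$baseline_image == 20  # background pixels
  for (f in seq_len(dim(sim$movie)[1]))
    expect_true(all(sim$movie$data[f, , ][mask_out] == 20))
})

test_that("stimulation artifact saturates exactly the scan lines lit by the laser", {
  neurons <- list(neuron_gt(c(32, 32)))
  tt <- fixture_opto_trials(n = 1)
  sim <- gen_movie(neurons, tt, fov = c(64, 64), seed = 1)
  nT <- dim(sim$movie)[1]

  # continuous stimulation (duty 1): every pixel saturates
  g_all <- build_gating(scan_config(blank_fraction = 0), n_frames = nT)
  m_all <- inject_stim_artifact(sim$movie, g_all)
  expect_true(all(m_all$data == 65535))

  # frame-locked gating blanking the central 75%: central band untouched
  g <- build_gating(scan_config(blank_fraction = 0.75), n_frames = nT)
  m <- inject_stim_artifact(sim$movie, g)
  central <- (64 / 8 + 1):(64 - 64 / 8)   # rows acquired in the central 75%
  expect_identical(m$data[, central, ], sim$movie$data[, central, ])
  margins <- c(1:(64 / 8), (64 - 64 / 8 + 1):64)
  expect_true(all(m$data[, margins, ] == 65535))

  # duty 0: movie unchanged
  g0 <- build_gating(scan_config(blank_fraction = 1), n_frames = nT)
  expect_identical(inject_stim_artifact(sim$movie, g0)$data, sim$movie$data)

  expect_error(inject_stim_artifact(sim$movie,
                                    build_gating(scan_config(), n_frames = 2)),
               "frames")
})

test_that("NO-GO eye traces stay under threshold when noise is small", {
  tt <- trial_table(1:50, rep("NoStim", 50), seq(0, by = 3, length.out = 50), 0)
  eyes <- gen_eye_traces(tt, guess_rate = 0, fixation_noise_sd_deg = 0.05,
                         seed = 1)
  expect_true(all(vapply(eyes$traces, function(tr)
    max(sqrt(tr$x_deg^2 + tr$y_deg^2)) < 1, logical(1))))
  expect_true(all(!eyes$truth$has_saccade))
})

test_that("with zero latency spread the true crossing is exactly the mean", {
  tt <- trial_table(1:20, rep("OptoStim", 20), seq(0, by = 3, length.out = 20), 66)
  eyes <- gen_eye_traces(tt, latency_mean_ms = 119, latency_sd_ms = 0,
                         fixation_noise_sd_deg = 0, endpoint_sd_deg = 0,
                         seed = 2)
  expect_true(all(eyes$truth$has_saccade))
  expect_equal(eyes$truth$latency_ms, rep(119, 20))
  # noiseless logistic profile crosses 1 degree at cue + latency by construction
  tr <- eyes$traces[[1]]
  d <- sqrt(tr$x_deg^2 + tr$y_deg^2)
  t_cross <- tr$cue_onset_s + 0.119
  before <- tr$time_s < t_cross - 1 / tr$sample_rate_hz
  after <- tr$time_s > t_cross + 1 / tr$sample_rate_hz
  expect_true(all(d[before] < 1))
  expect_true(all(d[after & tr$time_s < t_cross + 0.2] > 1))
})

test_that("endpoint scatter matches the generator SD", {
  tt <- trial_table(1:200, rep("VisualStim", 200),
                    seq(0, by = 3, length.out = 200), 22)
  eyes <- gen_eye_traces(tt, endpoint_sd_deg = 0.2, seed = 3)
  sdx <- sd(eyes$truth$endpoint_x)
  sdy <- sd(eyes$truth$endpoint_y)
  expect_equal(sdx, 0.2, tolerance = 0.15)   # sampling error at n = 200
  expect_equal(sdy, 0.2, tolerance = 0.15)
})
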