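test_that("ROI traces read out exactly what the pixels contain", {
  arr <- array(50, c(6, 20, 20))
  arr[, 5, 5] <- c(10, 20, 30, 40, 50, 60)
  m <- movie_stack(arr, frame_period_s = 0.1)
  rois <- roi_set(1:2, c(5, 15), c(5, 15), c(0.4, 2), fov = c(20, 20))
  tr <- extract_traces(m, rois)
  expect_equal(tr$F[1, ], c(10, 20, 30, 40, 50, 60))  # single-pixel ROI
  expect_equal(tr$F[2, ], rep(50, 6))                 # uniform region
  expect_error(roi_set(1, 2, 2, 5, fov = c(20, 20)), "outside")
})

test_that("traces from a noisy synthetic movie track the ground truth", {
  neurons <- fixture_neurons(5, fov = c(48, 48))
  sim <- gen_movie(neurons, fixture_opto_trials(n = 3), fov = c(48, 48),
                   noise_sd = 4, seed = 5)
  tr <- extract_traces(sim$movie, sim$truth$rois)
  cc <- vapply(seq_len(5), function(i)
    cor(tr$F[i, ], sim$truth$traces[i, ]), numeric(1))
  expect_true(all(cc >= 0.9))
})

test_that("dF/F amplitudes behave on constructed traces", {
  tt <- trial_table(1L, "OptoStim", 5, 1000)
  time_s <- seq(0, 10, by = 0.1)
  mk <- function(f) structure(list(F = matrix(f, 1), time_s = time_s,
                                   roi_id = 1L), class = "trace_matrix")
  # constant trace: dF/F identically zero
  r0 <- compute_dff(mk(rep(80, length(time_s))), tt)
  expect_equal(r0$r, 0)
  expect_equal(r0$F0, 80)
  # F doubles throughout the response window: r = 1
  f <- rep(80, length(time_s))
  f[time_s >= 5 & time_s <= 7] <- 160
  expect_equal(compute_dff(mk(f), tt)$r, 1)
  # non-positive baseline is an error
  expect_error(compute_dff(mk(rep(0, length(time_s))), tt), "F0")
})

test_that("window-mean dF/F matches the closed-form kernel integral", {
  amp <- 0.9
  nr <- neuron_gt(c(24, 24), opto_amplitude = amp, dose_half_saturation = 1e-9)
  tt <- fixture_opto_trials(n = 1, intensity = 5, duration_ms = 500)
  sim <- gen_movie(list(nr), tt, fov = c(48, 48), seed = 6)
  tr <- extract_traces(sim$movie, sim$truth$rois)
  r <- compute_dff(tr, tt, baseline_window_s = 1, response_extra_s = 1)$r
  # oracle: analytic kernel evaluated on the same frame grid
  k <- calcium_kernel()
  off <- sim$truth$frame_times - tt$onset_s[1]
  sel <- off >= 0 & off <= 1.5
  oracle <- amp * mean((exp(-off[sel] / k$decay_tau_s) -
                          exp(-off[sel] / k$rise_tau_s)) / k$peak)
  expect_equal(r, oracle, tolerance = 0.02)  # pixel quantization only
})

test_that("dF/F is invariant to rescaling and differential images to offsets", {
  neurons <- fixture_neurons(4, fov = c(40, 40))
  tt <- fixture_opto_trials(n = 2)
  sim <- gen_movie(neurons, tt, fov = c(40, 40), seed = 7)
  tr <- extract_traces(sim$movie, sim$truth$rois)
  r1 <- compute_dff(tr, tt)$r
  tr2 <- tr; tr2$F <- tr$F * 3.7          # multiplicative gain change
  expect_equal(compute_dff(tr2, tt)$r, r1)

  d1 <- differential_image(sim$movie, tt)
  m2 <- movie_stack(sim$movie$data + 500, frame_period_s = sim$movie$frame_period_s)
  expect_equal(differential_image(m2, tt), d1)
})

test_that("differential images localize responding neurons", {
  nr <- neuron_gt(c(12, 30), opto_amplitude = 1.5, dose_half_saturation = 1e-9)
  tt <- fixture_opto_trials(n = 2, intensity = 5)
  sim <- gen_movie(list(nr), tt, fov = c(40, 40), seed = 8)
  img <- differential_image(sim$movie, tt)
  peak <- arrayInd(which.max(img), dim(img))
  expect_lte(sqrt(sum((peak - c(12, 30))^2)), nr$radius)  # max inside the soma
  # two equal-response trials equal the single-trial image
  img1 <- differential_image(sim$movie, tt[1, , drop = FALSE])
  expect_equal(img, img1, tolerance = 0.05)  # onsets sit at different frame phases

  # a movie with no response is flat to within noise
  sim0 <- gen_movie(list(neuron_gt(c(12, 30), visual_amplitude = 0,
                                   opto_amplitude = 0)),
                    tt, fov = c(40, 40), noise_sd = 2, seed = 9)
  img0 <- differential_image(sim0$movie, tt)
  noise_se <- 2 / sqrt(2 * 8)  # noise sd over sqrt(frames averaged per trial)
  expect_lte(max(abs(mean(img0))), 3 * noise_se)
  expect_error(differential_image(sim$movie, tt[0, , drop = FALSE]), "no trials")
})

test_that("mode comparison classes cells by rank test and sign", {
  # clear separation: visual response, no opto response
  resp <- data.frame(roi_id = 1L, trial_id = 1:20,
                     condition = rep(c("VisualStim", "OptoStim"), each = 10),
                     F0 = 100, r = rep(c(1, 0), each = 10))
  mc <- compare_modes(resp)
  expect_equal(mc$class, "visual_stronger")
  expect_lt(mc$p_value, 0.05)
  # mirrored: opto stronger
  resp$r <- rep(c(0, 1), each = 10)
  expect_equal(compare_modes(resp)$class, "opto_stronger")
  # identical trial sets: p = 1, similar
  resp$r <- rep(c(0.4, 0.4), each = 10)
  mc2 <- compare_modes(resp)
  expect_equal(mc2$p_value, 1)
  expect_equal(mc2$class, "similar")
  expect_error(compare_modes(resp[c(1, 11), ]), ">= 2 trials")
})

test_that("first/last block means summarize session stability", {
  resp <- data.frame(roi_id = 1L, trial_id = 1:12,
                     condition = "OptoStim", F0 = 100,
                     r = seq(1.2, by = -0.1, length.out = 12))  # decaying
  st <- stability_first_last(resp, k = 4)
  expect_gt(st$first_mean, st$last_mean)
  expect_equal(st$first_mean, mean(resp$r[1:4]))
  expect_equal(st$last_mean, mean(resp$r[9:12]))
  st1 <- stability_first_last(resp, k = 1)
  expect_equal(c(st1$first_mean, st1$last_mean), c(1.2, 0.1))
  expect_error(stability_first_last(resp, k = 7), "fewer")
})

test_that("unity-line R2 follows its definition", {
  expect_equal(unity_r2(c(1, 2, 3), c(1, 2, 3)), 1)
  # hand computation: sum((y-x)^2) = 1, sum((y-mean(y))^2) = 42/9
  expect_equal(unity_r2(c(1, 2, 3), c(1, 2, 4)), 1 - 1 / (42 / 9))
  expect_error(unity_r2(1:3, rep(2, 3)), "variance")
  expect_error(unity_r2(1:3, 1:4), "equal length")
  # y unrelated to x: non-positive in expectation
  set.seed(10)
  vals <- replicate(1000, unity_r2(rnorm(20), rnorm(20)))
  expect_lt(mean(vals), 0)
})
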