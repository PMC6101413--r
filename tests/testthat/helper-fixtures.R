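# shared fixture builders; everything is generated in code at test time

# a small movie with a few textured cells, suitable for NCC registration
fixture_neurons <- function(n = 8, fov = c(64, 64), seed = 11) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    neuron_gt(center = c(sample(12:(fov[1] - 12), 1), sample(12:(fov[2] - 12), 1)),
              radius = 3 + (i %% 2), baseline_F = 90 + 10 * i,
              preferred_orientation_deg = 30 * ((i - 1) %% 6),
              visual_amplitude = 0.8, opto_amplitude = 0.8))
}

fixture_opto_trials <- function(n = 4, isi = 6, intensity = 0.8,
                                duration_ms = 500) {
  trial_table(seq_len(n), rep("OptoStim", n), seq(2, by = isi, length.out = n),
              duration_ms,
              sprintf("intensity_mw_mm2=%g", intensity))
}

fixture_orientation_trials <- function(reps = 2, isi = 4, duration_ms = 500,
                                       orientations = seq(0, 150, 30)) {
  oris <- rep(orientations, each = reps)
  trial_table(seq_along(oris), rep("VisualStim", length(oris)),
              seq(2, by = isi, length.out = length(oris)), duration_ms,
              sprintf("orientation_deg=%g", oris))
}

# brute-force integer-shift NCC oracle: plain nested loop, no refinement
oracle_int_shift <- function(frame, template, max_shift) {
  best <- c(NA, NA); best_r <- -Inf
  H <- nrow(frame); W <- ncol(frame)
  for (sr in -max_shift:max_shift) for (sc in -max_shift:max_shift) {
    r1 <- max(1, 1 + sr); r2 <- min(H, H + sr)
    c1 <- max(1, 1 + sc); c2 <- min(W, W + sc)
    a <- as.vector(frame[r1:r2, c1:c2])
    b <- as.vector(template[(r1 - sr):(r2 - sr), (c1 - sc):(c2 - sc)])
    if (sd(a) == 0 || sd(b) == 0) next
    r <- cor(a, b)
    if (r > best_r) { best_r <- r; best <- c(sr, sc) }
  }
  list(shift = best, r = best_r)
}

# response table drawn from one null distribution for both stimulation modes
null_mode_responses <- function(n_per_mode = 10) {
  data.frame(roi_id = 1L,
             trial_id = seq_len(2 * n_per_mode),
             condition = rep(c("VisualStim", "OptoStim"), each = n_per_mode),
             F0 = 100,
             r = rnorm(2 * n_per_mode))
}
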