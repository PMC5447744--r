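# Oddball-EEG simulator: stimulus statistics, background noise model,
# response kernels, session structure, and cohort determinism.

test_that("stimulus codes follow the protocol probabilities", {
  cfg <- sim_config()
  ev <- generate_stimulus_sequence(cfg, 100000, seed = 123)
  frac <- mean(ev$kind == "target")
  band <- 3 * sqrt(0.135 * 0.865 / 100000)
  expect_lt(abs(frac - 0.135), band)
  expect_lt(abs(mean(ev$kind == "nontarget") - 0.83),
            3 * sqrt(0.83 * 0.17 / 100000))
  # spacing is exactly one stimulus interval
  expect_true(all(diff(ev$onset_sample) == 1000))
})

test_that("degenerate probabilities and determinism behave as contracted", {
  cfg <- sim_config(p_target = 1, p_nontarget = 0, p_distractor = 0)
  ev <- generate_stimulus_sequence(cfg, 10, seed = 1)
  expect_true(all(ev$kind == "target"))
  expect_identical(generate_stimulus_sequence(sim_config(), 500, seed = 9),
                   generate_stimulus_sequence(sim_config(), 500, seed = 9))
  expect_error(generate_stimulus_sequence(sim_config(), 0, seed = 1),
               "positive")
  expect_error(sim_config(p_target = 0.2), "sum to 1")
})

test_that("background components match their configured amplitudes", {
  cfg_white <- small_sim(noise_model = noise_model(pink_sd = 0, alpha_amplitude = 0,
                                                   white_sd = 1))
  bg <- generate_background(cfg_white, 100000, seed = 4)
  sds <- apply(bg, 1, sd)
  expect_true(all(abs(sds - 1) < 0.05))

  bg0 <- generate_background(small_sim(noise_model = no_noise()), 500, seed = 4)
  expect_true(all(bg0 == 0))
})

test_that("pink noise concentrates power at low frequencies", {
  cfg <- small_sim(noise_model = noise_model(pink_sd = 1, alpha_amplitude = 0,
                                             white_sd = 0))
  n <- 60000
  bg <- generate_background(cfg, n, seed = 8)
  # periodogram oracle on one channel: band power at 2 Hz vs 40 Hz
  p <- Mod(fft(bg[1, ]))^2 / n
  freq <- (0:(n - 1)) * cfg$sampling_rate / n
  band <- function(f0) mean(p[freq >= f0 - 1 & freq <= f0 + 1])
  expect_gt(band(2), band(40))
})

test_that("event responses have the contracted shape", {
  cfg <- small_sim(noise_model = no_noise())
  prof <- steady_profile(amplitude = 7)
  expect_true(all(generate_event_response(prof, "nontarget", cfg) == 0))
  # no distractor response configured -> zero waveform
  expect_true(all(generate_event_response(prof, "distractor", cfg) == 0))

  r <- generate_event_response(prof, "target", cfg)
  pz <- which(names(prof$topography) == "Pz")
  expect_equal(max(r[pz, ]), 7)                      # peak = amplitude at max gain
  expect_equal(which.max(r[pz, ]) - 1L, 400L)        # at the configured latency
  # every channel is the kernel scaled by its gain
  expect_equal(r[1, ] / 7, r[pz, ] * prof$topography[1] / 7, tolerance = 1e-12)
})

test_that("empirical peak-latency jitter matches the configured sd", {
  cfg <- small_sim(noise_model = no_noise())
  prof <- subject_profile(p300_amplitude = 5, latency_jitter_sd = 30)
  peaks <- vapply(1:1000, function(s) {
    r <- generate_event_response(prof, "target", cfg, seed = s)
    (which.max(r[19, ]) - 1)  # ms at 1 kHz
  }, numeric(1))
  expect_lt(abs(sd(peaks) - 30), 3)   # Monte-Carlo oracle, n = 1000
})

test_that("sessions meet the per-phase target quotas", {
  cfg <- sim_config()  # 3 phases x 30 targets
  rec <- simulate_session(cfg, steady_profile(3), seed = 21)
  kinds <- rec$metadata$kinds
  expect_identical(sum(kinds == "target"), 90L)
  bounds <- c(0L, rec$metadata$phase_last_event)
  per_phase <- vapply(1:3, function(p) {
    sum(kinds[(bounds[p] + 1):bounds[p + 1]] == "target")
  }, integer(1))
  expect_identical(per_phase, rep(30L, 3))
  # each phase ends on its final target
  expect_true(all(kinds[rec$metadata$phase_last_event] == "target"))
})

test_that("sessions superpose background and deterministic response track", {
  cfg <- small_sim(targets_per_phase = 4, noise_model = quiet_noise())
  sess_a <- simulate_session(cfg, steady_profile(5), seed = 31)
  sess_0 <- simulate_session(cfg, steady_profile(0), seed = 31)
  cfg_silent <- small_sim(targets_per_phase = 4, noise_model = no_noise())
  sess_r <- simulate_session(cfg_silent, steady_profile(5), seed = 31)
  expect_identical(sess_a$markers, sess_0$markers)
  expect_identical(sess_a$markers, sess_r$markers)
  expect_equal(sess_a$signal, sess_0$signal + sess_r$signal, tolerance = 1e-14)
})

test_that("grand-average target response peaks inside the latency window", {
  cfg <- small_sim(targets_per_phase = 8, noise_model = quiet_noise())
  prof <- steady_profile(6)
  rec <- simulate_session(cfg, prof, seed = 77)
  es <- extract_epochs(rec)
  avg_t <- apply(es$data[es$labels == "target", 19, ], 2, mean)
  avg_n <- apply(es$data[es$labels == "nontarget", 19, ], 2, mean)
  diff_wave <- avg_t - avg_n
  peak_ms <- which.max(diff_wave) - es$t0_offset - 1
  expect_gte(peak_ms, prof$p300_latency - prof$p300_width)
  expect_lte(peak_ms, prof$p300_latency + prof$p300_width)
})

test_that("amplitude-0 sessions show no target/non-target difference", {
  cfg <- small_sim(targets_per_phase = 10, noise_model = quiet_noise())
  rec <- simulate_session(cfg, steady_profile(0), seed = 55)
  es <- extract_epochs(rec)
  # mean over the peak window 350-450 ms at Pz, per trial
  win <- es$t0_offset + 350:450
  vals <- rowMeans(es$data[, 19, win])
  p <- t.test(vals[es$labels == "target"], vals[es$labels == "nontarget"])$p.value
  expect_gt(p, 0.01)
})

test_that("cohorts are sized, deterministic, and reject empty profile lists", {
  cfg <- small_sim(targets_per_phase = 2, noise_model = quiet_noise())
  profs <- make_cohort_profiles(15, seed = 2, latency_jitter_sd = 0)
  cohort <- simulate_cohort(cfg, profs, seed = 41)
  expect_length(cohort, 15)
  cohort2 <- simulate_cohort(cfg, profs, seed = 41)
  expect_identical(cohort, cohort2)
  expect_error(simulate_cohort(cfg, list(), seed = 1), "at least one")
})

test_that("distractor responses appear only when the profile defines them", {
  cfg <- small_sim(targets_per_phase = 3, noise_model = no_noise(),
                   p_nontarget = 0.5, p_target = 0.25, p_distractor = 0.25)
  p3a <- list(amplitude = 4, latency = 300, width = 40,
              topography = frontal_topography(19))
  prof_with <- subject_profile(p300_amplitude = 0, latency_jitter_sd = 0,
                               distractor_response = p3a)
  rec <- simulate_session(cfg, prof_with, seed = 13)
  has_distractor <- any(rec$metadata$kinds == "distractor")
  if (has_distractor) {
    fz <- which(rec$channel_labels == "Fz")
    expect_gt(max(abs(rec$signal[fz, ])), 0)
  }
  prof_without <- steady_profile(0)
  rec0 <- simulate_session(cfg, prof_without, seed = 13)
  expect_true(all(rec0$signal == 0))
})

test_that("profile invariants are enforced", {
  expect_error(subject_profile(topography = rep(0.5, 19)), "max entry")
  expect_error(subject_profile(topography = rep(1, 5), n_channels = 19),
               "n_channels")
  expect_error(subject_profile(p300_latency = 950, p300_width = 100),
               "fit inside")
})
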