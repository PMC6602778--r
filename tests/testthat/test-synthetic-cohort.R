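# Synthetic cohort generator: burst-train synthesis, Poisson event process,
# determinism and cohort plumbing.

test_that("synth_bowel_sound builds the requested burst train", {
  sr <- 8000
  # single burst: damped sinusoid, silent outside its support
  y <- synth_bowel_sound(1, numeric(0), 300, 80, 0.5, sr)
  expect_gt(sum(y^2), 0)
  t <- seq_along(y) / sr
  expect_equal(y, 0.5 * exp(-80 * t) * sin(2 * pi * 300 * t),
               tolerance = 1e-12)
  # two bursts 0.1 s apart: envelope-peak spacing ~ 0.1 s (within 5 ms)
  y2 <- synth_bowel_sound(2, 0.1, 300, 80, 0.5, sr)
  half <- round(0.1 * sr)
  p1 <- which.max(abs(y2[1:half]))
  p2 <- half + which.max(abs(y2[(half + 1):length(y2)]))
  expect_lt(abs((p2 - p1) / sr - 0.1), 0.005)
  # invalid parameters rejected
  expect_error(synth_bowel_sound(0, numeric(0), 300, 80, 0.5, sr), "burst")
  expect_error(synth_bowel_sound(2, numeric(0), 300, 80, 0.5, sr),
               "component intervals")
  expect_error(synth_bowel_sound(1, numeric(0), -300, 80, 0.5, sr),
               "positive")
})

test_that("burst-count draws follow the configured distribution", {
  probs <- c(0.3, 0.3, 0.2, 0.12, 0.08)
  set.seed(11)
  draws <- sample.int(5L, 1000, replace = TRUE, prob = probs)
  mu <- sum(seq_len(5) * probs)
  sdv <- sqrt(sum(seq_len(5)^2 * probs) - mu^2)
  expect_lt(abs(mean(draws) - mu), 3 * sdv / sqrt(1000))
  # and the generator's events reproduce it: pool truth burst counts
  cfg <- tiny_cohort(fasted_duration = 120, noise_rms = 0, artifact_rate = 0)
  p <- generate_participant("HC001", "healthy", cfg)
  bc <- lengths(strsplit(p$truth$burst_onsets_s[p$truth$is_bowel], ";"))
  expect_lt(abs(mean(bc) - mu), 3 * sdv / sqrt(length(bc)))
})

test_that("generate_participant is deterministic and truth is physical", {
  cfg <- tiny_cohort()
  a <- generate_participant("IBS001", "IBS", cfg)
  b <- generate_participant("IBS001", "IBS", cfg)
  expect_identical(a$fasted$channels, b$fasted$channels)
  expect_identical(a$fed$channels, b$fed$channels)
  expect_identical(a$truth, b$truth)
  # invariants: 4 equal-length channels in [-1, 1]; onsets ordered in truth
  expect_equal(ncol(a$fasted$channels), 4)
  expect_lte(max(abs(a$fasted$channels)), 1)
  tr <- a$truth
  expect_true(all(tr$onset_s < tr$offset_s))
  # every truth event present in the waveform: local RMS above noise
  sr <- cfg$sample_rate
  bowel <- tr[tr$is_bowel & tr$period == "fasted", ]
  for (i in seq_len(min(10, nrow(bowel)))) {
    q <- match(bowel$quadrant[i], a$fasted$quadrant_map)
    idx <- round(bowel$onset_s[i] * sr):round(bowel$offset_s[i] * sr)
    idx <- idx[idx >= 1 & idx <= nrow(a$fasted$channels)]
    expect_gt(sqrt(mean(a$fasted$channels[idx, q]^2)), 2 * cfg$noise_rms)
  }
})

test_that("fed period rate is multiplied as configured (Poisson oracle)", {
  cfg <- cohort_config(n_ibs = 1, n_healthy = 1, seed = 3,
                       fasted_duration = 600, fed_duration = 600,
                       sample_rate = 500, carrier_freq_range = c(50, 150),
                       density_healthy_fasted = 1.0, fed_rate_multiplier = 2,
                       noise_rms = 0.005, artifact_rate = 0)
  p <- generate_participant("HC001", "healthy", cfg)
  n_fast <- sum(p$truth$period == "fasted" & p$truth$is_bowel)
  n_fed <- sum(p$truth$period == "fed" & p$truth$is_bowel)
  expect_lt(abs(n_fast - 600), 3 * sqrt(600))
  expect_lt(abs(n_fed - 1200), 3 * sqrt(1200))
})

test_that("silence case: zero noise and density give empty output", {
  cfg <- tiny_cohort(noise_rms = 0, artifact_rate = 0,
                     density_ibs_fasted = 0, density_healthy_fasted = 0)
  p <- generate_participant("IBS001", "IBS", cfg)
  expect_identical(unique(as.numeric(p$fasted$channels)), 0)
  expect_identical(nrow(p$truth), 0L)
})

test_that("event rate matches the configured density (chi-square GOF)", {
  # 100 replicate counts at rate 1/s over 60 s, binned by Poisson quantiles
  set.seed(17)
  counts <- replicate(100, length(ibsacoustics:::draw_event_times(1, 60)))
  qs <- qpois(c(0.2, 0.4, 0.6, 0.8), 60)
  bins <- cut(counts, c(-Inf, qs, Inf))
  p_bins <- diff(c(0, ppois(qs, 60), 1))
  gof <- suppressWarnings(chisq.test(table(bins), p = p_bins))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort plumbing: shapes, manifests, validation", {
  expect_equal(nrow(cohort_participants(cohort_config(31, 37))), 68)
  expect_equal(nrow(cohort_participants(cohort_config(15, 15))), 30)
  expect_error(cohort_config(n_ibs = 0), ">= 1")
  expect_error(cohort_config(fed_rate_multiplier = 0.5), "fed_rate")
  expect_error(cohort_config(noise_rms = -1), "noise_rms")

  dir <- withr::local_tempdir()
  cfg <- tiny_cohort(fasted_duration = 5, fed_duration = 5)
  man <- generate_cohort(cfg, dir = dir)
  expect_equal(nrow(man$participants), 4)
  expect_true(all(file.exists(man$participants$fasted_wav)))
  expect_true(all(file.exists(man$participants$fed_wav)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  # WAV round trip preserves the simulated audio at 16-bit resolution
  rec <- read_recording(man$participants$fasted_wav[1])
  p <- generate_participant(man$participants$participant_id[1],
                            man$participants$group[1], cfg)
  expect_lt(max(abs(rec$channels - p$fasted$channels)), 2^-14)
})
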