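# Per-sound features, subband ratios, density/summed-amplitude, aggregation.

test_that("spectral features of analytic signals", {
  sr <- 8000
  x <- tone(500, 0.1, sr)
  f <- sound_features(x, sr)
  bin <- sr / length(x)
  expect_lt(abs(f$spectral_centroid - 500), bin)
  expect_lt(abs(f$peak_frequency - 500), bin)
  expect_error(sound_features(numeric(100), sr), "degenerate")
  # crest factor: brute-force recomputation on the raw samples
  set.seed(5)
  y <- runif(4000, -1, 1)
  g <- sound_features(y, sr)
  expect_equal(g$crest_factor, max(abs(y)) / sqrt(mean(y^2)),
               tolerance = 1e-12)
  expect_equal(g$rms_energy, sqrt(mean(y^2)), tolerance = 1e-12)
})

test_that("white noise has high spectral flatness (Monte-Carlo)", {
  set.seed(6)
  fl <- replicate(100, sound_features(rnorm(2000), 8000)$spectral_flatness)
  expect_gte(mean(fl), 0.8)
})

test_that("subband energy ratios split energy as constructed", {
  sr <- 8000
  edges <- c(60, 250, 500, 1000, 1500)
  spec <- function(x) {
    P <- Mod(fft(x))^2
    nf <- floor(length(x) / 2) + 1
    list(P = P[1:nf], f = (0:(nf - 1)) * sr / length(x))
  }
  s1 <- spec(tone(200, 0.5, sr))
  r1 <- subband_energy_ratios(s1$P, s1$f, edges)
  expect_equal(r1, c(1, 0, 0, 0), tolerance = 1e-6)
  s2 <- spec(tone(300, 0.5, sr) + tone(700, 0.5, sr))
  r2 <- subband_energy_ratios(s2$P, s2$f, edges)
  expect_equal(r2, c(0, 0.5, 0.5, 0), tolerance = 0.01)
  set.seed(8)
  s3 <- spec(rnorm(4000))
  expect_equal(sum(subband_energy_ratios(s3$P, s3$f, edges)), 1,
               tolerance = 1e-9)
  expect_error(subband_energy_ratios(numeric(10) , seq(100, 1000, 100),
                                     edges), "degenerate")
})

test_that("quantity density and summed amplitude follow their definitions", {
  expect_equal(quantity_density(120, 60), 2.0)
  expect_equal(quantity_density(0, 10), 0)
  expect_error(quantity_density(5, 0), "positive")
  set.seed(9)
  n <- rpois(1, 1.5 * 600)
  expect_lt(abs(quantity_density(n, 600) - 1.5), 3 * sqrt(1.5 / 600))
  amps <- c(0.1, 0.2, 0.3)
  expect_equal(summed_amplitude(amps, 40, 40), 0.6)
  expect_equal(summed_amplitude(amps, 120, 40), 0.2)
  expect_equal(summed_amplitude(2 * amps, 120, 40),
               2 * summed_amplitude(amps, 120, 40))
  expect_error(summed_amplitude(amps, 0), "positive")
})

test_that("amplitude features scale with gain, spectral features do not", {
  sr <- 4000
  y <- synth_bowel_sound(3, c(0.05, 0.06), 400, 80, 0.3, sr)
  f1 <- sound_features(y, sr)
  f2 <- sound_features(3 * y, sr)
  expect_equal(f2$peak_amplitude, 3 * f1$peak_amplitude, tolerance = 1e-9)
  expect_equal(f2$rms_energy, 3 * f1$rms_energy, tolerance = 1e-9)
  expect_equal(f2$spectral_centroid, f1$spectral_centroid, tolerance = 1e-9)
  expect_equal(f2$spectral_flatness, f1$spectral_flatness, tolerance = 1e-9)
  expect_equal(f2$subband_energy_ratios, f1$subband_energy_ratios,
               tolerance = 1e-9)
})

test_that("aggregate_participant matches direct recomputation", {
  reg <- feature_registry()
  durations <- c(fasted = 60, fed = 20)
  set.seed(10)
  n <- 100
  sounds <- data.frame(
    period = sample(c("fasted", "fed"), n, replace = TRUE),
    quadrant = sample(c("RUQ", "LUQ", "RLQ", "LLQ"), n, replace = TRUE),
    peak_amplitude = runif(n, 0.1, 0.5),
    burst_number = sample(1:5, n, replace = TRUE),
    mean_component_interval = ifelse(runif(n) < 0.3, NA, runif(n, 0.03, 0.1)),
    duration = runif(n, 0.05, 0.4),
    spectral_centroid = runif(n, 100, 900),
    spectral_bandwidth = runif(n, 50, 300),
    spectral_rolloff_85 = runif(n, 200, 1200),
    peak_frequency = runif(n, 100, 900),
    spectral_flatness = runif(n),
    subband_1 = runif(n), subband_2 = runif(n), subband_3 = runif(n),
    subband_4 = runif(n))
  v <- aggregate_participant(sounds, durations, reg, extended = TRUE)
  expect_named(v, c(reg$name, "quantity_density_fasted",
                    "summed_amplitude_fasted", "quantity_density_fed",
                    "summed_amplitude_fed")[
                      c(1:nrow(reg), nrow(reg) + c(1, 2, 3, 4))],
               ignore.order = TRUE)
  expect_equal(unname(v["spectral_centroid_mean"]),
               mean(sounds$spectral_centroid))
  expect_equal(unname(v["spectral_centroid_sd"]), sd(sounds$spectral_centroid))
  expect_equal(unname(v["component_interval_mean"]),
               mean(sounds$mean_component_interval, na.rm = TRUE))
  expect_equal(unname(v["quantity_density"]), 100 / 80)
  expect_equal(unname(v["summed_amplitude"]),
               sum(sounds$peak_amplitude) * 20 / 80)
  fed <- sounds[sounds$period == "fed", ]
  expect_equal(unname(v["quantity_density_fed"]), nrow(fed) / 20)
  # order invariance
  v2 <- aggregate_participant(sounds[sample(n), ], durations, reg,
                              extended = TRUE)
  expect_equal(v, v2)
  # single sound: mean = value, sd = 0
  v3 <- aggregate_participant(sounds[1, ], durations, reg)
  expect_equal(unname(v3["spectral_centroid_mean"]),
               sounds$spectral_centroid[1])
  expect_equal(unname(v3["spectral_centroid_sd"]), 0)
  expect_error(aggregate_participant(sounds[0, ], durations, reg),
               "unusable")
})
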