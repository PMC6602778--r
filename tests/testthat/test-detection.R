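# Detector: band-pass contracts, event detection, burst segmentation,
# origin assignment, matching-based scoring, and the detector invariants.

make_recording <- function(channels, sr = 4000, period = "fasted") {
  structure(list(participant_id = "T", group = "healthy", period = period,
                 sample_rate = sr, channels = channels,
                 quadrant_map = c("RUQ", "LUQ", "RLQ", "LLQ")),
            class = "bs_recording")
}

test_that("preprocess rejects the stopband and keeps the passband", {
  sr <- 8000
  rms <- function(x) sqrt(mean(x^2))
  x50 <- tone(50, 1, sr)
  x300 <- tone(300, 1, sr)
  cfg <- detector_config(bandpass = c(60, 1500))
  expect_lt(rms(preprocess(x50, cfg, sample_rate = sr)), 0.05 * rms(x50))
  expect_gt(rms(preprocess(x300, cfg, sample_rate = sr)), 0.90 * rms(x300))
  expect_identical(preprocess(numeric(100), cfg, sample_rate = sr),
                   numeric(100))
  expect_error(preprocess(x50, detector_config(bandpass = c(60, 5000)),
                          sample_rate = sr), "Nyquist")
  ch <- make_recording(cbind(x300, x300, x300, x300), sr)
  filt <- preprocess(ch, cfg)
  expect_equal(dim(filt$channels), dim(ch$channels))
})

test_that("a single inserted burst is found within 50 ms", {
  sr <- 4000
  set.seed(4)
  x <- rnorm(10 * sr, 0, 0.01)
  burst <- synth_bowel_sound(1, numeric(0), 300, 60, 0.2, sr)  # ~26 dB SNR
  at <- round(4.2 * sr)
  x[at:(at + length(burst) - 1)] <- x[at:(at + length(burst) - 1)] + burst
  rec <- make_recording(cbind(x, rnorm(10 * sr, 0, 0.01),
                              rnorm(10 * sr, 0, 0.01),
                              rnorm(10 * sr, 0, 0.01)), sr)
  ev <- detect_recording(rec)
  expect_equal(nrow(ev), 1L)
  expect_lt(abs(ev$onset_s - 4.2), 0.05)
  expect_identical(ev$quadrant, "RUQ")
  # silence in, nothing out
  silent <- make_recording(matrix(rnorm(4 * sr * 4, 0, 0.01), ncol = 4), sr)
  expect_equal(nrow(detect_recording(silent)), 0L)
})

test_that("segment_bursts resolves burst structure", {
  sr <- 4000
  cfg <- detector_config()
  y1 <- synth_bowel_sound(1, numeric(0), 400, 100, 0.3, sr)
  s1 <- segment_bursts(y1 + rnorm(length(y1), 0, 0.005), sr, cfg)
  expect_equal(s1$n_bursts, 1L)
  expect_length(s1$intervals, 0)
  y2 <- synth_bowel_sound(2, 0.1, 400, 100, 0.3, sr)
  s2 <- segment_bursts(y2 + rnorm(length(y2), 0, 0.005), sr, cfg)
  expect_equal(s2$n_bursts, 2L)
  expect_lt(abs(s2$intervals - 0.1), 0.01)
  expect_error(segment_bursts(numeric(100), sr, cfg), "degenerate")
})

test_that("burst counts agree exactly with generator truth >= 95%", {
  set.seed(7)
  cfg <- detector_config()
  sr <- 4000
  ok <- vapply(seq_len(200), function(i) {
    bc <- sample(1:5, 1, prob = c(.3, .3, .2, .12, .08))
    iv <- if (bc > 1) rlnorm(bc - 1, log(0.05), 0.2) else numeric(0)
    y <- synth_bowel_sound(bc, iv, runif(1, 100, 1000), runif(1, 20, 200),
                           0.25 * rlnorm(1, 0, 0.3), sr)
    segment_bursts(y + rnorm(length(y), 0, 0.01), sr, cfg)$n_bursts == bc
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("origin assignment follows the loudest channel with RUQ tie-break", {
  sr <- 4000
  burst <- synth_bowel_sound(1, numeric(0), 300, 60, 0.3, sr)
  n <- 2 * sr
  base <- matrix(rnorm(n * 4, 0, 0.005), ncol = 4)
  at <- sr %/% 2
  idx <- at:(at + length(burst) - 1)
  ch <- base
  for (q in 1:4) ch[idx, q] <- ch[idx, q] + burst * ifelse(q == 3, 1, 0.3)
  rec <- preprocess(make_recording(ch, sr))
  expect_identical(assign_origin(at / sr, (at + length(burst)) / sr, rec),
                   "RLQ")
  # identical envelopes on all four channels -> RUQ by the tie rule
  ch_tie <- base * 0
  for (q in 1:4) ch_tie[idx, q] <- burst
  rec_tie <- make_recording(ch_tie, sr)
  expect_identical(assign_origin(at / sr, (at + length(burst)) / sr, rec_tie),
                   "RUQ")
})

test_that("score_detection matches the brute-force optimal matching", {
  expect_error(score_detection(1, 1, tolerance = -1), "non-negative")
  s <- score_detection(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$precision, 1)
  expect_equal(s$recall, 1)
  s0 <- score_detection(numeric(0), c(1, 2))
  expect_equal(s0$precision, 1)   # documented convention
  expect_equal(s0$recall, 0)
  set.seed(12)
  for (rep in 1:20) {
    truth <- sort(runif(sample(3:10, 1), 0, 5))
    pred <- sort(c(truth + rnorm(length(truth), 0, 0.05),
                   runif(sample(0:3, 1), 0, 5)))
    g <- score_detection(pred, truth, 0.05)$n_matched
    opt <- optimal_matching(pred, truth, 0.05)
    expect_lte(g, opt)
    expect_gte(g, ceiling(opt / 2))   # greedy guarantee
  }
})

test_that("detector invariants: scale equivariance, threshold monotonicity,
           ordered disjoint events", {
  cfg <- tiny_cohort()
  p <- generate_participant("HC001", "healthy", cfg)
  ev1 <- detect_recording(p$fasted)
  rec5 <- p$fasted
  rec5$channels <- rec5$channels * 0.2   # stays within [-1, 1]
  ev5 <- detect_recording(rec5)
  expect_equal(ev1$onset_s, ev5$onset_s, tolerance = 1e-9)
  expect_equal(ev1$n_bursts, ev5$n_bursts)
  # raising threshold_k never increases the event count
  n_lo <- nrow(detect_recording(p$fasted, detector_config(threshold_k = 3)))
  n_hi <- nrow(detect_recording(p$fasted, detector_config(threshold_k = 8)))
  expect_lte(n_hi, n_lo)
  # per-recording events are disjoint and time-ordered
  expect_true(all(diff(ev1$onset_s) > 0))
  expect_true(all(ev1$onset_s[-1] >= head(ev1$offset_s, -1) - 1e-9))
})
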