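# Shared fixtures: tiny cohort configurations, tone generators and
# brute-force oracles. Everything is generated in code at test time.

tone <- function(freq, duration, sample_rate, amplitude = 1) {
  amplitude * sin(2 * pi * freq * seq_len(round(duration * sample_rate)) /
                    sample_rate)
}

# Small, fast cohort: 4 kHz, short periods; statistical structure as default.
tiny_cohort <- function(...) {
  args <- list(n_ibs = 2, n_healthy = 2, seed = 42, fasted_duration = 30,
               fed_duration = 15, sample_rate = 4000)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohort_config, args)
}

# Gaussian feature cohort with a single informative dimension (no audio);
# delta = group mean separation in SDs of the informative feature.
gaussian_cohort <- function(n_ibs, n_healthy, delta, p_noise = 3, seed = 1) {
  set.seed(seed)
  n <- n_ibs + n_healthy
  y <- rep(c("IBS", "healthy"), c(n_ibs, n_healthy))
  x <- cbind(signal = rnorm(n) + delta * (y == "IBS"),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  list(x = x, y = y)
}

# Exhaustive maximum bipartite matching between prediction and truth onsets
# under a distance tolerance: the brute-force oracle for score_detection.
optimal_matching <- function(pred, truth, tol) {
  np <- length(pred); nt <- length(truth)
  if (!np || !nt) return(0L)
  ok <- abs(outer(pred, truth, "-")) <= tol
  best <- 0L
  rec <- function(i, used, count) {
    if (count + (np - i + 1) <= best) return()
    if (i > np) { best <<- max(best, count); return() }
    for (j in which(ok[i, ] & !used)) {
      used[j] <- TRUE
      rec(i + 1L, used, count + 1L)
      used[j] <- FALSE
    }
    rec(i + 1L, used, count)
  }
  rec(1L, logical(nt), 0L)
  best
}

# Truth-vs-detection bookkeeping used by the detector-validity tests:
# match detections to bowel-truth onsets and count origin agreement.
origin_agreement <- function(events, truth, tol = 0.05) {
  ok <- 0L; n <- 0L
  for (i in seq_len(nrow(events))) {
    j <- which.min(abs(truth$onset_s - events$onset_s[i]))
    if (length(j) && abs(truth$onset_s[j] - events$onset_s[i]) <= tol) {
      n <- n + 1L
      ok <- ok + (truth$quadrant[j] == events$quadrant[i])
    }
  }
  list(accuracy = if (n) ok / n else NA_real_, n = n)
}
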