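# Synthetic cohorts of four-channel abdominal recordings with ground truth.
#
# A bowel sound is modelled as a train of 1-5 exponentially damped sinusoid
# bursts; successive burst onsets are separated by the "component interval
# time". Event times follow a (optionally MMC-modulated) Poisson process whose
# rate differs by group (healthy > IBS by default) and rises after feeding.

#' Configuration for a synthetic abdominal-sound cohort
#'
#' Captures every dial of the generator: cohort shape, recording durations,
#' per-group event densities and amplitude scales, the burst-count and
#' component-interval distributions, carrier/damping ranges of individual
#' bursts, background noise, artifact rate, cross-channel leakage and
#' optional migrating-motor-complex (MMC) rate modulation during fasting.
#'
#' Defaults mirror a two-hour fasted plus 40-minute fed session at 44.1 kHz
#' with a 31 IBS / 37 healthy model-building cohort. Tests and examples pass
#' shorter durations and lower sample rates; the statistical structure is
#' unchanged.
#'
#' @param n_ibs,n_healthy participants per group (>= 1).
#' @param seed master integer seed; per-participant streams are derived from
#'   it by stable hashing, so any participant can be regenerated in isolation.
#' @param fasted_duration,fed_duration recording durations in seconds.
#' @param sample_rate sampling rate in Hz.
#' @param density_healthy_fasted,density_ibs_fasted fasted-state bowel-sound
#'   rates in events per second, summed over all four quadrants.
#' @param fed_rate_multiplier multiplicative rate increase after feeding
#'   (>= 1).
#' @param amplitude_scale named numeric `c(IBS=, healthy=)`: median per-event
#'   peak amplitude per group (dimensionless, waveform units).
#' @param burst_count_probs named list of probability vectors over burst
#'   counts 1..5, one per group.
#' @param component_interval_meanlog named numeric: log-normal `meanlog` of
#'   the component interval (s) per group.
#' @param component_interval_sdlog shared log-normal `sdlog`.
#' @param carrier_freq_range,damping_range uniform sampling ranges for burst
#'   carrier frequency (Hz) and exponential damping (1/s).
#' @param noise_rms RMS of additive Gaussian background noise.
#' @param artifact_rate rate (events/s) of labelled non-bowel artifacts
#'   (broadband clicks and low-frequency rumble).
#' @param leakage attenuation applied when copying an event onto the three
#'   non-origin channels.
#' @param mmc_enabled if `TRUE`, the fasted-state event rate is modulated by
#'   a sinusoid of period `mmc_period` (depth 0.5), emulating MMC cycling.
#' @param mmc_period MMC modulation period in seconds.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_ibs = 31L, n_healthy = 37L, seed = 1L,
                          fasted_duration = 7200, fed_duration = 2400,
                          sample_rate = 44100,
                          density_healthy_fasted = 1.2,
                          density_ibs_fasted = 0.8,
                          fed_rate_multiplier = 1.5,
                          amplitude_scale = c(IBS = 0.30, healthy = 0.20),
                          burst_count_probs = list(
                            IBS = c(0.50, 0.25, 0.15, 0.07, 0.03),
                            healthy = c(0.30, 0.30, 0.20, 0.12, 0.08)),
                          component_interval_meanlog = c(IBS = log(0.06),
                                                         healthy = log(0.045)),
                          component_interval_sdlog = 0.2,
                          carrier_freq_range = c(100, 1000),
                          damping_range = c(20, 200),
                          noise_rms = 0.01,
                          artifact_rate = 0.02,
                          leakage = 0.3,
                          mmc_enabled = FALSE,
                          mmc_period = 5400) {
  if (n_ibs < 1 || n_healthy < 1)
    stop_invalid("n_ibs and n_healthy must both be >= 1 (got %s/%s)",
                 n_ibs, n_healthy)
  if (fasted_duration <= 0 || fed_duration <= 0 || sample_rate <= 0)
    stop_invalid("durations and sample_rate must be positive")
  if (density_healthy_fasted < 0 || density_ibs_fasted < 0)
    stop_invalid("event densities must be non-negative")
  if (fed_rate_multiplier < 1)
    stop_invalid("fed_rate_multiplier must be >= 1")
  if (!all(c("IBS", "healthy") %in% names(amplitude_scale)) ||
      any(amplitude_scale <= 0))
    stop_invalid("amplitude_scale needs positive entries named IBS, healthy")
  for (g in c("IBS", "healthy")) {
    p <- burst_count_probs[[g]]
    if (is.null(p) || any(p < 0) || sum(p) <= 0)
      stop_invalid("burst_count_probs$%s must be a non-negative vector", g)
    burst_count_probs[[g]] <- p / sum(p)
  }
  if (carrier_freq_range[1] <= 0 || diff(carrier_freq_range) < 0 ||
      damping_range[1] <= 0 || diff(damping_range) < 0)
    stop_invalid("carrier_freq_range and damping_range must be positive, ordered")
  if (carrier_freq_range[2] >= sample_rate / 2)
    stop_invalid("carrier frequencies must stay below Nyquist (%g Hz)",
                 sample_rate / 2)
  if (noise_rms < 0 || artifact_rate < 0 || leakage < 0 || leakage > 1)
    stop_invalid("noise_rms, artifact_rate >= 0 and leakage in [0, 1] required")
  if (mmc_period <= 0) stop_invalid("mmc_period must be positive")
  structure(list(
    n_ibs = as.integer(n_ibs), n_healthy = as.integer(n_healthy),
    seed = as.integer(seed),
    fasted_duration = fasted_duration, fed_duration = fed_duration,
    sample_rate = sample_rate,
    density_healthy_fasted = density_healthy_fasted,
    density_ibs_fasted = density_ibs_fasted,
    fed_rate_multiplier = fed_rate_multiplier,
    amplitude_scale = amplitude_scale,
    burst_count_probs = burst_count_probs,
    component_interval_meanlog = component_interval_meanlog,
    component_interval_sdlog = component_interval_sdlog,
    carrier_freq_range = carrier_freq_range,
    damping_range = damping_range,
    noise_rms = noise_rms, artifact_rate = artifact_rate,
    leakage = leakage,
    mmc_enabled = isTRUE(mmc_enabled), mmc_period = mmc_period
  ), class = "cohort_config")
}

#' Synthesise one bowel sound as a damped-sinusoid burst train
#'
#' Each burst is `a * exp(-d t) * sin(2 pi f t)`; burst onsets are spaced by
#' the supplied component intervals, so the envelope-peak spacing of the
#' output equals the intervals by construction.
#'
#' @param burst_count number of bursts (>= 1).
#' @param component_intervals numeric vector of `burst_count - 1` inter-burst
#'   onset gaps in seconds.
#' @param carrier_freq carrier frequency in Hz.
#' @param damping exponential damping in 1/s.
#' @param amplitude peak amplitude (dimensionless).
#' @param sample_rate sampling rate in Hz.
#' @return numeric waveform segment.
#' @export
synth_bowel_sound <- function(burst_count, component_intervals, carrier_freq,
                              damping, amplitude, sample_rate) {
  if (burst_count < 1) stop_invalid("burst_count must be >= 1")
  if (length(component_intervals) != burst_count - 1)
    stop_invalid("need exactly burst_count - 1 component intervals")
  if (length(component_intervals) && any(component_intervals <= 0))
    stop_invalid("component intervals must be positive")
  if (carrier_freq <= 0 || damping <= 0 || amplitude <= 0 || sample_rate <= 0)
    stop_invalid("carrier_freq, damping, amplitude, sample_rate must be positive")
  burst_dur <- min(6 / damping, 0.3)         # envelope decayed to < 0.25 %
  onsets <- cumsum(c(0, component_intervals))
  total <- onsets[burst_count] + burst_dur
  n <- as.integer(ceiling(total * sample_rate))
  y <- numeric(n)
  nb <- as.integer(round(burst_dur * sample_rate))
  t <- seq_len(nb) / sample_rate
  burst <- amplitude * exp(-damping * t) * sin(2 * pi * carrier_freq * t)
  for (on in onsets) {
    i0 <- as.integer(round(on * sample_rate))
    idx <- (i0 + 1L):min(n, i0 + nb)
    y[idx] <- y[idx] + burst[seq_along(idx)]
  }
  y
}

# Draw event onset times on [0, duration] from a Poisson process. When MMC
# modulation is active the rate is lambda(t) = rate * (1 + 0.5 sin(2 pi t /
# period)) and sampling is by thinning.
draw_event_times <- function(rate, duration, mmc = FALSE, mmc_period = 5400) {
  if (rate <= 0) return(numeric(0))
  if (!mmc) {
    n <- stats::rpois(1L, rate * duration)
    return(sort(stats::runif(n, 0, duration)))
  }
  lam_max <- rate * 1.5
  n <- stats::rpois(1L, lam_max * duration)
  t <- sort(stats::runif(n, 0, duration))
  keep <- stats::runif(n) < (1 + 0.5 * sin(2 * pi * t / mmc_period)) / 1.5
  t[keep]
}

#' Generate one participant's fasted and fed recordings plus ground truth
#'
#' Produces two four-channel recordings (fasted then fed) and the event truth
#' table. Each bowel sound is placed on its origin quadrant's channel at full
#' amplitude and on the other three channels attenuated by `config$leakage`.
#' Deterministic given `(config$seed, participant_id)`.
#'
#' @param participant_id character id.
#' @param group `"IBS"` or `"healthy"`.
#' @param config a [cohort_config()].
#' @return list with `fasted`, `fed` (class `bs_recording`: `channels` an
#'   n-by-4 matrix in `[-1, 1]`, `sample_rate`, `quadrant_map`, metadata) and
#'   `truth`, a data frame with one row per inserted event
#'   (`participant_id, period, quadrant, onset_s, offset_s, burst_onsets_s,
#'   peak_amplitude, is_bowel`).
#' @export
generate_participant <- function(participant_id, group, config) {
  stopifnot(inherits(config, "cohort_config"))
  group <- match.arg(group, c("IBS", "healthy"))
  seed_p <- stable_seed(config$seed, participant_id)
  with_seed(seed_p, {
    base_rate <- if (group == "IBS") config$density_ibs_fasted else
      config$density_healthy_fasted
    out <- list()
    truth <- list()
    for (period in c("fasted", "fed")) {
      dur <- if (period == "fasted") config$fasted_duration else
        config$fed_duration
      rate <- base_rate * if (period == "fed") config$fed_rate_multiplier else 1
      sr <- config$sample_rate
      nsamp <- as.integer(round(dur * sr))
      ch <- matrix(0, nrow = nsamp, ncol = 4L,
                   dimnames = list(NULL, QUADRANTS))
      times <- draw_event_times(rate, dur,
                                mmc = config$mmc_enabled && period == "fasted",
                                mmc_period = config$mmc_period)
      rows <- vector("list", length(times))
      for (k in seq_along(times)) {
        q <- sample.int(4L, 1L)
        bc <- sample.int(5L, 1L, prob = config$burst_count_probs[[group]])
        iv <- if (bc > 1)
          stats::rlnorm(bc - 1L, config$component_interval_meanlog[[group]],
                        config$component_interval_sdlog) else numeric(0)
        f <- stats::runif(1, config$carrier_freq_range[1],
                          config$carrier_freq_range[2])
        d <- stats::runif(1, config$damping_range[1], config$damping_range[2])
        a <- min(0.85, config$amplitude_scale[[group]] *
                   stats::rlnorm(1, 0, 0.3))
        seg <- synth_bowel_sound(bc, iv, f, d, a, sr)
        i0 <- as.integer(round(times[k] * sr))
        if (i0 + 2L > nsamp) next     # event would start past the recording
        idx <- (i0 + 1L):min(nsamp, i0 + length(seg))
        seg <- seg[seq_along(idx)]
        for (c_i in 1:4)
          ch[idx, c_i] <- ch[idx, c_i] +
            seg * if (c_i == q) 1 else config$leakage
        rows[[k]] <- data.frame(
          participant_id = participant_id, period = period,
          quadrant = QUADRANTS[q],
          onset_s = times[k], offset_s = times[k] + length(seg) / sr,
          burst_onsets_s = paste(
            format(times[k] + cumsum(c(0, iv)), digits = 8, trim = TRUE),
            collapse = ";"),
          peak_amplitude = a, is_bowel = TRUE,
          stringsAsFactors = FALSE)
      }
      # labelled non-bowel artifacts: clicks (one channel) and rumble (all)
      n_art <- stats::rpois(1L, config$artifact_rate * dur)
      if (n_art > 0) {
        at <- sort(stats::runif(n_art, 0, dur))
        for (k in seq_len(n_art)) {
          click <- stats::runif(1) < 0.7
          i0 <- as.integer(round(at[k] * sr))
          if (i0 + 2L > nsamp) next
          if (click) {
            len <- as.integer(round(0.005 * sr))
            idx <- (i0 + 1L):min(nsamp, i0 + len)
            q <- sample.int(4L, 1L)
            ch[idx, q] <- ch[idx, q] + stats::rnorm(length(idx), 0, 0.2)
            qn <- QUADRANTS[q]
          } else {
            len <- as.integer(round(0.5 * sr))
            idx <- (i0 + 1L):min(nsamp, i0 + len)
            tt <- seq_along(idx) / sr
            rum <- 0.1 * sin(2 * pi * 30 * tt)
            ch[idx, ] <- ch[idx, ] + rum
            qn <- "RUQ"
          }
          rows[[length(rows) + 1L]] <- data.frame(
            participant_id = participant_id, period = period, quadrant = qn,
            onset_s = at[k], offset_s = at[k] + length(idx) / sr,
            burst_onsets_s = "", peak_amplitude = 0.2, is_bowel = FALSE,
            stringsAsFactors = FALSE)
        }
      }
      if (config$noise_rms > 0)
        ch <- ch + matrix(stats::rnorm(length(ch), 0, config$noise_rms),
                          nrow = nsamp)
      ch[ch > 1] <- 1; ch[ch < -1] <- -1
      out[[period]] <- structure(list(
        participant_id = participant_id, group = group, period = period,
        sample_rate = sr, channels = ch, quadrant_map = QUADRANTS),
        class = "bs_recording")
      truth[[period]] <- if (length(rows)) do.call(rbind, rows) else
        empty_truth()
    }
    tr <- do.call(rbind, truth)
    tr <- tr[order(tr$period, tr$onset_s), , drop = FALSE]
    rownames(tr) <- NULL
    list(fasted = out$fasted, fed = out$fed, truth = tr)
  })
}

empty_truth <- function() {
  data.frame(participant_id = character(0), period = character(0),
             quadrant = character(0), onset_s = numeric(0),
             offset_s = numeric(0), burst_onsets_s = character(0),
             peak_amplitude = numeric(0), is_bowel = logical(0),
             stringsAsFactors = FALSE)
}

#' Participant identifiers of a cohort, IBS first
#' @param config a [cohort_config()].
#' @return data frame with `participant_id` and `group`.
#' @export
cohort_participants <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  data.frame(
    participant_id = c(sprintf("IBS%03d", seq_len(config$n_ibs)),
                       sprintf("HC%03d", seq_len(config$n_healthy))),
    group = rep(c("IBS", "healthy"), c(config$n_ibs, config$n_healthy)),
    stringsAsFactors = FALSE)
}

#' Generate a full synthetic cohort
#'
#' With `dir = NULL` the recordings are returned in memory (suitable for
#' small test-scale configurations only). With a directory, each recording is
#' written as a 4-channel 16-bit PCM WAV and only the manifest and truth
#' tables are kept in memory; `manifest.csv` and `truth.csv` are written
#' alongside.
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory.
#' @return list of class `cohort_manifest`: `participants` (data frame with
#'   id, group and, when written, per-period WAV paths), `truth` (combined
#'   truth table), `config`, and `recordings` (named list, in-memory mode
#'   only).
#' @export
generate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  parts <- cohort_participants(config)
  truth <- vector("list", nrow(parts))
  recs <- if (is.null(dir)) vector("list", nrow(parts)) else NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    if (!dir.exists(dir)) stop_invalid("cannot create output dir %s", dir)
    parts$fasted_wav <- file.path(dir, paste0(parts$participant_id,
                                              "_fasted.wav"))
    parts$fed_wav <- file.path(dir, paste0(parts$participant_id, "_fed.wav"))
  }
  for (i in seq_len(nrow(parts))) {
    p <- generate_participant(parts$participant_id[i], parts$group[i], config)
    truth[[i]] <- p$truth
    if (is.null(dir)) {
      recs[[i]] <- p[c("fasted", "fed")]
    } else {
      write_wav(p$fasted$channels, config$sample_rate, parts$fasted_wav[i])
      write_wav(p$fed$channels, config$sample_rate, parts$fed_wav[i])
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  if (!is.null(recs)) names(recs) <- parts$participant_id
  man <- structure(list(participants = parts, truth = truth, config = config,
                        recordings = recs), class = "cohort_manifest")
  if (!is.null(dir)) {
    utils::write.csv(parts, file.path(dir, "manifest.csv"), row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  man
}
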