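# Per-sound time/frequency features and per-participant aggregation.
#
# The classifier's default registry has exactly 26 features: 8 time-domain
# and 18 frequency-domain. The identity of each feature is a documented
# package choice (the families - burst structure, component interval,
# amplitude, quantity density, summed amplitude, spectrum shape/bandwidth,
# waveform shape, subband energy ratios - are fixed; see the vignette).

#' Default subband edges (Hz)
#' @export
default_subband_edges <- function() c(60, 250, 500, 1000, 1500)

#' Subband energy ratios of a power spectrum
#'
#' Fraction of the in-band spectral energy falling between successive band
#' edges. Ratios sum to 1.
#'
#' @param power numeric power spectrum (one-sided).
#' @param freqs frequencies (Hz) of the spectrum bins, same length.
#' @param edges increasing band edges in Hz (default
#'   [default_subband_edges()], giving 4 bands).
#' @return numeric vector of `length(edges) - 1` ratios.
#' @export
subband_energy_ratios <- function(power, freqs,
                                  edges = default_subband_edges()) {
  if (length(edges) < 3) stop_invalid("need at least 2 bands")
  if (is.unsorted(edges, strictly = TRUE))
    stop_invalid("band edges must be strictly increasing")
  inband <- freqs >= edges[1] & freqs <= edges[length(edges)]
  total <- sum(power[inband])
  if (!is.finite(total) || total <= 0)
    stop_invalid("degenerate signal: no in-band spectral energy")
  bands <- cut(freqs[inband], edges, include.lowest = TRUE, right = FALSE)
  e <- tapply(power[inband], bands, sum, default = 0)
  as.numeric(e / total)
}

#' Time- and frequency-domain features of one bowel sound
#'
#' Spectral statistics use the magnitude-squared FFT of the Hann-windowed
#' event, restricted to the analysis band. Spectral flatness is computed
#' after averaging the periodogram in blocks of 8 bins, which tames the
#' exponential noise of raw periodogram ordinates (white noise then scores
#' about 0.95 rather than 0.56).
#'
#' @param x numeric event waveform.
#' @param sample_rate sampling rate in Hz.
#' @param burst_onsets burst onset times (s) from [segment_bursts()]; used
#'   for `burst_number` and `mean_component_interval`. Default: one burst.
#' @param band analysis band in Hz.
#' @param subband_edges edges for [subband_energy_ratios()].
#' @return object of class `sound_features`: a named list with `duration`,
#'   `burst_number`, `mean_component_interval` (`NA` for single-burst
#'   sounds), `peak_amplitude`, `rms_energy`, `zero_crossing_rate`,
#'   `waveform_skewness`, `waveform_kurtosis`, `crest_factor`,
#'   `spectral_centroid`, `spectral_bandwidth`, `spectral_rolloff_85`,
#'   `peak_frequency`, `spectral_flatness` and `subband_energy_ratios`.
#' @export
sound_features <- function(x, sample_rate, burst_onsets = 0,
                           band = c(60, 1500),
                           subband_edges = default_subband_edges()) {
  n <- length(x)
  if (!n || all(x == 0)) stop_invalid("degenerate (all-zero) event waveform")
  duration <- n / sample_rate
  rms <- sqrt(mean(x^2))
  m <- mean(x); xc <- x - m
  s2 <- mean(xc^2)
  skew <- if (s2 > 0) mean(xc^3) / s2^1.5 else 0
  kurt <- if (s2 > 0) mean(xc^4) / s2^2 else 0
  zcr <- sum(x[-1] * x[-n] < 0) / duration
  crest <- max(abs(x)) / rms
  # one-sided power spectrum, Hann window
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  P <- Mod(stats::fft(x * w))^2
  nf <- floor(n / 2) + 1L
  P <- P[seq_len(nf)]
  fr <- (seq_len(nf) - 1) * sample_rate / n
  ib <- fr >= band[1] & fr <= band[2]
  if (!any(ib) || sum(P[ib]) <= 0)
    stop_invalid("degenerate signal: no in-band spectral energy")
  Pb <- P[ib]; fb <- fr[ib]
  tot <- sum(Pb)
  centroid <- sum(fb * Pb) / tot
  bw <- sqrt(sum((fb - centroid)^2 * Pb) / tot)
  rolloff <- fb[which(cumsum(Pb) >= 0.85 * tot)[1]]
  peak_f <- fb[which.max(Pb)]
  blocks <- ceiling(seq_along(Pb) / 8)
  Ps <- tapply(Pb, blocks, mean)
  flat <- exp(mean(log(pmax(Ps, 1e-300)))) / mean(Ps)
  structure(list(
    duration = duration,
    burst_number = length(burst_onsets),
    mean_component_interval = if (length(burst_onsets) > 1)
      mean(diff(burst_onsets)) else NA_real_,
    peak_amplitude = max(abs(x)),
    rms_energy = rms,
    zero_crossing_rate = zcr,
    waveform_skewness = skew,
    waveform_kurtosis = kurt,
    crest_factor = crest,
    spectral_centroid = centroid,
    spectral_bandwidth = bw,
    spectral_rolloff_85 = rolloff,
    peak_frequency = peak_f,
    spectral_flatness = unname(flat),
    subband_energy_ratios = subband_energy_ratios(P, fr, subband_edges)
  ), class = "sound_features")
}

#' Bowel-sound quantity density
#'
#' Number of sounds per second over a recording period.
#'
#' @param events event table (data frame) or an event count.
#' @param duration period duration in seconds (> 0).
#' @return sounds per second.
#' @export
quantity_density <- function(events, duration) {
  if (duration <= 0) stop_invalid("duration must be positive")
  n <- if (is.data.frame(events)) nrow(events) else as.numeric(events)
  n / duration
}

#' Duration-scaled summed amplitude (sound index)
#'
#' Sum of per-sound peak amplitudes, scaled by `reference_duration /
#' duration` so that periods of different length are comparable (the fasted
#' recording is three times as long as the fed one at full scale).
#'
#' @param events event table with `peak_amplitude`, or a numeric vector of
#'   peak amplitudes.
#' @param duration period duration in seconds (> 0).
#' @param reference_duration scaling reference in seconds (default:
#'   `duration`, i.e. no scaling).
#' @return scaled summed amplitude (>= 0).
#' @export
summed_amplitude <- function(events, duration, reference_duration = duration) {
  if (duration <= 0) stop_invalid("duration must be positive")
  a <- if (is.data.frame(events)) events$peak_amplitude else as.numeric(events)
  sum(a) * reference_duration / duration
}

#' The default final-model feature registry
#'
#' Exactly 26 features: 8 time-domain (burst number mean/SD, component
#' interval mean/SD, duration mean, peak amplitude mean, quantity density,
#' summed amplitude) and 18 frequency-domain (mean and SD of spectral
#' centroid, bandwidth, 85% rolloff, peak frequency, flatness, and of the 4
#' subband energy ratios).
#'
#' @return data frame with `name`, `domain` (`"time"`/`"frequency"`),
#'   `source` (per-sound feature or period statistic) and `stat`.
#' @export
feature_registry <- function() {
  time_feats <- data.frame(
    name = c("burst_number_mean", "burst_number_sd",
             "component_interval_mean", "component_interval_sd",
             "duration_mean", "peak_amplitude_mean",
             "quantity_density", "summed_amplitude"),
    domain = "time",
    source = c("burst_number", "burst_number",
               "mean_component_interval", "mean_component_interval",
               "duration", "peak_amplitude",
               "quantity_density", "summed_amplitude"),
    stat = c("mean", "sd", "mean", "sd", "mean", "mean", "period", "period"),
    stringsAsFactors = FALSE)
  spec_src <- c("spectral_centroid", "spectral_bandwidth",
                "spectral_rolloff_85", "peak_frequency", "spectral_flatness",
                paste0("subband_", 1:4))
  freq_feats <- data.frame(
    name = c(paste0(spec_src, "_mean"), paste0(spec_src, "_sd")),
    domain = "frequency",
    source = rep(spec_src, 2),
    stat = rep(c("mean", "sd"), each = length(spec_src)),
    stringsAsFactors = FALSE)
  rbind(time_feats, freq_feats)
}

#' Aggregate per-sound features into a participant feature vector
#'
#' Pools all detected sounds of a participant (both periods, all quadrants)
#' and computes the registry statistics, plus per-period quantity density and
#' scaled summed amplitude. Feature ordering is fixed by the registry.
#' Statistics ignore missing per-sound values (e.g. component interval of
#' single-burst sounds); a statistic with no usable values is `NA` and is
#' imputed later from training-set medians.
#'
#' @param sounds data frame with one row per sound: columns `period`,
#'   `peak_amplitude` and the per-sound features named in the registry
#'   `source` column (subband ratios as `subband_1..subband_4`).
#' @param durations named numeric `c(fasted=, fed=)` period durations (s).
#' @param registry feature registry (default [feature_registry()]).
#' @param reference_duration scaling reference for summed amplitude;
#'   default: the fed duration.
#' @param extended if `TRUE`, append per-period `quantity_density_*` and
#'   `summed_amplitude_*` (used by the group-statistics stage, not by the
#'   classifier).
#' @return named numeric vector in registry order.
#' @export
aggregate_participant <- function(sounds, durations,
                                  registry = feature_registry(),
                                  reference_duration = durations[["fed"]],
                                  extended = FALSE) {
  if (!is.data.frame(sounds) || !nrow(sounds))
    stop_invalid("unusable participant: no detected sounds")
  if (!all(c("fasted", "fed") %in% names(durations)))
    stop_invalid("durations must be named c(fasted=, fed=)")
  total_dur <- sum(durations)
  out <- numeric(nrow(registry))
  names(out) <- registry$name
  for (i in seq_len(nrow(registry))) {
    src <- registry$source[i]
    if (registry$stat[i] == "period") {
      out[i] <- if (src == "quantity_density")
        quantity_density(sounds, total_dur)
      else summed_amplitude(sounds, total_dur, reference_duration)
    } else {
      v <- sounds[[src]]
      v <- v[is.finite(v)]
      out[i] <- if (!length(v)) NA_real_
      else if (registry$stat[i] == "mean") mean(v)
      else if (length(v) > 1) stats::sd(v) else 0
    }
  }
  if (extended) {
    for (p in c("fasted", "fed")) {
      sub <- sounds[sounds$period == p, , drop = FALSE]
      out[paste0("quantity_density_", p)] <-
        quantity_density(sub, durations[[p]])
      out[paste0("summed_amplitude_", p)] <-
        summed_amplitude(sub, durations[[p]], reference_duration)
    }
  }
  out
}

# Per-sound feature extraction for every event of one recording: runs
# detect_recording and sound_features, returning the event table augmented
# with feature columns (subband ratios unpacked to subband_1..subband_4).
extract_sounds <- function(recording, config = detector_config()) {
  ev <- detect_recording(recording, config)
  if (!nrow(ev)) return(ev)
  filt <- preprocess(recording, config)
  sr <- filt$sample_rate
  qcol <- match(ev$quadrant, filt$quadrant_map)
  feats <- vector("list", nrow(ev))
  for (i in seq_len(nrow(ev))) {
    idx <- max(1L, floor(ev$onset_s[i] * sr)):
      min(nrow(filt$channels), ceiling(ev$offset_s[i] * sr))
    seg <- filt$channels[idx, qcol[i]]
    iv <- suppressWarnings(as.numeric(strsplit(
      ev$component_intervals_s[i], ";", fixed = TRUE)[[1]]))
    onsets <- cumsum(c(0, iv[is.finite(iv)]))
    f <- sound_features(seg, sr, burst_onsets = onsets,
                        band = config$bandpass)
    feats[[i]] <- data.frame(
      burst_number = f$burst_number,
      duration = f$duration, mean_component_interval =
        f$mean_component_interval, rms_energy = f$rms_energy,
      zero_crossing_rate = f$zero_crossing_rate,
      waveform_skewness = f$waveform_skewness,
      waveform_kurtosis = f$waveform_kurtosis, crest_factor = f$crest_factor,
      spectral_centroid = f$spectral_centroid,
      spectral_bandwidth = f$spectral_bandwidth,
      spectral_rolloff_85 = f$spectral_rolloff_85,
      peak_frequency = f$peak_frequency,
      spectral_flatness = f$spectral_flatness,
      subband_1 = f$subband_energy_ratios[1],
      subband_2 = f$subband_energy_ratios[2],
      subband_3 = f$subband_energy_ratios[3],
      subband_4 = f$subband_energy_ratios[4])
  }
  cbind(ev, do.call(rbind, feats))
}
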