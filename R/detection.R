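# Bowel-sound detection: zero-phase band-pass, envelope thresholding against
# a robust noise floor, burst segmentation and origin-quadrant assignment.

#' Detector configuration
#'
#' @param bandpass numeric `c(low, high)` pass band in Hz; must sit below the
#'   Nyquist frequency of the signal it is applied to.
#' @param frame envelope RMS frame length in seconds (50% overlap).
#' @param threshold_k detection threshold in robust (MAD) units above the
#'   median envelope. The threshold is relative to the noise floor, so the
#'   detector is invariant to overall gain.
#' @param min_event_duration minimum event length in seconds.
#' @param merge_gap events separated by less than this gap (s) are merged;
#'   must exceed the intra-sound component-interval scale (about 40-90 ms)
#'   or one burst train is reported as several events.
#' @param burst_gap minimum separation (s) between bursts within an event.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(bandpass = c(60, 1500), frame = 0.010,
                            threshold_k = 4, min_event_duration = 0.018,
                            merge_gap = 0.060, burst_gap = 0.025) {
  if (length(bandpass) != 2 || bandpass[1] <= 0 || bandpass[2] <= bandpass[1])
    stop_invalid("bandpass must be c(low, high) with 0 < low < high")
  if (frame <= 0 || min_event_duration <= 0 || merge_gap <= 0 ||
      burst_gap <= 0)
    stop_invalid("all detector durations must be positive")
  if (threshold_k <= 0) stop_invalid("threshold_k must be positive")
  structure(list(bandpass = bandpass, frame = frame,
                 threshold_k = threshold_k,
                 min_event_duration = min_event_duration,
                 merge_gap = merge_gap, burst_gap = burst_gap),
            class = "detector_config")
}

# Zero-phase band-pass by spectral masking with raised-cosine transitions
# (width 5% of each edge frequency). Output length equals input length.
fft_bandpass <- function(x, sample_rate, low, high) {
  if (high >= sample_rate / 2)
    stop_invalid("bandpass high edge %g Hz is not below Nyquist %g Hz",
                 high, sample_rate / 2)
  n <- length(x)
  if (n == 0) return(x)
  nfft <- stats::nextn(n, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  f <- seq.int(0, nfft - 1) / nfft * sample_rate
  f <- pmin(f, sample_rate - f)            # fold negative frequencies
  ramp <- function(fr, edge, width) pmin(1, pmax(0, (fr - edge) / width + 0.5))
  mask <- ramp(f, low, 0.05 * low) * (1 - ramp(f, high, 0.05 * high))
  Re(stats::fft(X * mask, inverse = TRUE) / nfft)[seq_len(n)]
}

#' Band-pass filter a recording (zero phase)
#'
#' Applies the detector's band-pass to every channel. Zero-phase filtering is
#' done in the frequency domain, so event onsets are not delayed.
#'
#' @param recording a `bs_recording` (see [generate_participant()]) or a
#'   numeric vector/matrix of samples, in which case `sample_rate` must be
#'   supplied via the attribute-free argument.
#' @param config a [detector_config()].
#' @param sample_rate required when `recording` is a bare vector/matrix.
#' @return same shape as the input, filtered.
#' @export
preprocess <- function(recording, config = detector_config(),
                       sample_rate = NULL) {
  stopifnot(inherits(config, "detector_config"))
  if (inherits(recording, "bs_recording")) {
    sr <- recording$sample_rate
    if (sr <= 2 * config$bandpass[2])
      stop_invalid("sample rate %g Hz too low for bandpass high edge %g Hz",
                   sr, config$bandpass[2])
    recording$channels <- apply(recording$channels, 2, fft_bandpass,
                                sample_rate = sr,
                                low = config$bandpass[1],
                                high = config$bandpass[2])
    recording$filtered <- TRUE
    return(recording)
  }
  if (is.null(sample_rate)) stop_invalid("sample_rate required for raw input")
  if (is.matrix(recording))
    apply(recording, 2, fft_bandpass, sample_rate = sample_rate,
          low = config$bandpass[1], high = config$bandpass[2])
  else
    fft_bandpass(recording, sample_rate, config$bandpass[1],
                 config$bandpass[2])
}

# Detect events on one filtered channel. Returns a data frame of onset_s,
# offset_s, peak_amplitude, peak_env; empty frame when silent.
detect_events_channel <- function(x, sample_rate, config) {
  env <- rms_envelope(x, sample_rate, config$frame)
  med <- stats::median(env$e)
  madv <- stats::mad(env$e)                 # 1.4826 * MAD
  thr <- max(med + config$threshold_k * madv, 1e-12)
  above <- env$e > thr
  if (!any(above)) return(empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on_i <- starts[r$values]
  off_i <- ends[r$values]
  onset <- env$t[on_i] - env$frame / 2
  offset <- env$t[off_i] + env$frame / 2
  # merge runs separated by less than merge_gap
  if (length(onset) > 1) {
    keep_start <- c(TRUE, onset[-1] - offset[-length(offset)] >=
                      config$merge_gap)
    g <- cumsum(keep_start)
    onset <- tapply(onset, g, min)
    offset <- tapply(offset, g, max)
  }
  dur <- offset - onset
  sel <- dur >= config$min_event_duration
  onset <- pmax(0, onset[sel]); offset <- offset[sel]
  if (!length(onset)) return(empty_events())
  peak_amp <- peak_env <- numeric(length(onset))
  for (i in seq_along(onset)) {
    idx <- max(1L, floor(onset[i] * sample_rate)):
      min(length(x), ceiling(offset[i] * sample_rate))
    peak_amp[i] <- max(abs(x[idx]))
    fr <- env$t >= onset[i] & env$t <= offset[i]
    peak_env[i] <- if (any(fr)) max(env$e[fr]) else peak_amp[i]
  }
  data.frame(onset_s = as.numeric(onset), offset_s = as.numeric(offset),
             peak_amplitude = peak_amp, peak_env = peak_env)
}

empty_events <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             peak_amplitude = numeric(0), peak_env = numeric(0))
}

#' Detect bowel-sound events on each channel of a recording
#'
#' Events are regions where the smoothed RMS envelope exceeds
#' `threshold_k` robust (MAD) units above the median envelope for at least
#' `min_event_duration`; events closer than `merge_gap` are merged. Detection
#' runs per channel; use [detect_recording()] for the deduplicated,
#' origin-assigned event table.
#'
#' @param recording a filtered `bs_recording` (see [preprocess()]).
#' @param config a [detector_config()].
#' @return named list (one entry per quadrant) of event data frames with
#'   `onset_s`, `offset_s`, `peak_amplitude`, `peak_env`, sorted by onset and
#'   non-overlapping within a channel.
#' @export
detect_events <- function(recording, config = detector_config()) {
  stopifnot(inherits(recording, "bs_recording"))
  out <- lapply(seq_len(ncol(recording$channels)), function(i)
    detect_events_channel(recording$channels[, i], recording$sample_rate,
                          config))
  names(out) <- recording$quadrant_map
  out
}

#' Segment an event waveform into bursts
#'
#' Bursts are local envelope maxima separated by at least `burst_gap` with an
#' intervening valley below 60% of the smaller peak; candidates below 15% of
#' the event's peak envelope are ignored. Burst onsets are the 50%-of-peak
#' rising crossings; component intervals are successive onset gaps.
#'
#' @param x numeric event waveform (filtered).
#' @param sample_rate sampling rate in Hz.
#' @param config a [detector_config()] (`burst_gap` is used).
#' @return list with `n_bursts`, `onsets` (s, relative to segment start),
#'   `bursts` (two-column matrix of onset/offset) and `intervals`
#'   (`diff(onsets)`).
#' @export
segment_bursts <- function(x, sample_rate, config = detector_config()) {
  if (!length(x) || all(x == 0))
    stop_invalid("degenerate (all-zero) event waveform")
  env <- rms_envelope(x, sample_rate, frame = 0.005, hop = 0.00125)
  e <- env$e; tt <- env$t
  if (length(e) < 3) {
    return(list(n_bursts = 1L, onsets = 0, intervals = numeric(0),
                bursts = matrix(c(0, length(x) / sample_rate), 1)))
  }
  d <- diff(e)
  pk <- which(diff(sign(c(d[1], d))) < 0)   # interior local maxima
  if (e[1] >= e[2]) pk <- c(1L, pk)         # instant attack at segment start
  if (e[length(e)] > e[length(e) - 1]) pk <- c(pk, length(e))
  if (!length(pk)) pk <- which.max(e)
  pk <- pk[e[pk] >= 0.15 * max(e)]
  if (!length(pk)) pk <- which.max(e)
  accepted <- integer(0)
  for (i in pk[order(e[pk], decreasing = TRUE)]) {
    ok <- TRUE
    for (j in accepted) {
      if (abs(tt[i] - tt[j]) < config$burst_gap) { ok <- FALSE; break }
      rng <- if (i < j) i:j else j:i
      valley <- min(e[rng])
      if (valley > 0.6 * min(e[i], e[j])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  accepted <- sort(accepted)
  # burst onsets: last rise through 50% of the peak before each peak
  bounds <- c(1L, vapply(seq_len(length(accepted) - 1), function(k) {
    rng <- accepted[k]:accepted[k + 1]
    rng[which.min(e[rng])]
  }, integer(1)), length(e))
  onsets <- offsets <- numeric(length(accepted))
  for (k in seq_along(accepted)) {
    i <- accepted[k]
    lo <- bounds[k]
    below <- which(e[lo:i] < 0.5 * e[i])
    onsets[k] <- tt[if (length(below)) lo + max(below) - 1L else lo]
    hi <- bounds[k + 1]
    under <- which(e[i:hi] < 0.15 * e[i])
    offsets[k] <- tt[if (length(under)) i + min(under) - 1L else hi]
  }
  list(n_bursts = length(accepted), onsets = onsets,
       intervals = diff(onsets),
       bursts = cbind(onset = onsets, offset = pmax(offsets, onsets + 1e-4)))
}

#' Assign the origin quadrant of an event window
#'
#' The origin is the quadrant whose channel has the maximal peak envelope
#' within the window; exact ties are broken in the fixed order
#' RUQ, LUQ, RLQ, LLQ.
#'
#' @param onset_s,offset_s event window in seconds.
#' @param recording filtered `bs_recording` with all four channels.
#' @return quadrant name.
#' @export
assign_origin <- function(onset_s, offset_s, recording) {
  stopifnot(inherits(recording, "bs_recording"))
  idx <- max(1L, floor(onset_s * recording$sample_rate)):
    min(nrow(recording$channels),
        ceiling(offset_s * recording$sample_rate))
  peaks <- apply(abs(recording$channels[idx, , drop = FALSE]), 2, max)
  recording$quadrant_map[which.max(peaks)]   # which.max takes first on ties
}

#' Detect, deduplicate and segment all bowel sounds in a recording
#'
#' Full detection path for one recording: band-pass, per-channel detection,
#' cross-channel deduplication (events overlapping in time on several
#' channels are one physical sound; the copy on the loudest channel is kept
#' and that channel is the origin quadrant), then burst segmentation on each
#' kept event.
#'
#' @param recording a `bs_recording` (raw; filtering is applied internally).
#' @param config a [detector_config()].
#' @return event table: one row per physical sound with `participant_id`,
#'   `period`, `quadrant` (origin), `onset_s`, `offset_s`, `n_bursts`,
#'   `component_intervals_s` (`;`-separated), `peak_amplitude`.
#' @export
detect_recording <- function(recording, config = detector_config()) {
  filt <- preprocess(recording, config)
  per_ch <- detect_events(filt, config)
  all_ev <- do.call(rbind, lapply(seq_along(per_ch), function(i) {
    ev <- per_ch[[i]]
    if (nrow(ev)) ev$channel <- i
    ev
  }))
  if (is.null(all_ev) || !nrow(all_ev)) return(empty_event_table())
  all_ev <- all_ev[order(all_ev$onset_s), , drop = FALSE]
  # cluster events that overlap in time across channels
  grp <- integer(nrow(all_ev))
  grp[1] <- 1L
  cur_end <- all_ev$offset_s[1]
  for (i in seq_len(nrow(all_ev))[-1]) {
    if (all_ev$onset_s[i] < cur_end) {
      grp[i] <- grp[i - 1]
      cur_end <- max(cur_end, all_ev$offset_s[i])
    } else {
      grp[i] <- grp[i - 1] + 1L
      cur_end <- all_ev$offset_s[i]
    }
  }
  kept <- lapply(split(seq_len(nrow(all_ev)), grp), function(ix) {
    sub <- all_ev[ix, , drop = FALSE]
    # loudest channel wins; which.max keeps quadrant order on exact ties
    sub[order(sub$channel), , drop = FALSE][
      which.max(sub$peak_env[order(sub$channel)]), , drop = FALSE]
  })
  kept <- do.call(rbind, kept)
  rows <- vector("list", nrow(kept))
  sr <- filt$sample_rate
  for (i in seq_len(nrow(kept))) {
    idx <- max(1L, floor(kept$onset_s[i] * sr)):
      min(nrow(filt$channels), ceiling(kept$offset_s[i] * sr))
    seg <- filt$channels[idx, kept$channel[i]]
    sb <- segment_bursts(seg, sr, config)
    rows[[i]] <- data.frame(
      participant_id = recording$participant_id %||% NA_character_,
      period = recording$period %||% NA_character_,
      quadrant = filt$quadrant_map[kept$channel[i]],
      onset_s = kept$onset_s[i], offset_s = kept$offset_s[i],
      n_bursts = sb$n_bursts,
      component_intervals_s = paste(format(sb$intervals, digits = 6,
                                           trim = TRUE), collapse = ";"),
      peak_amplitude = kept$peak_amplitude[i],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_event_table <- function() {
  data.frame(participant_id = character(0), period = character(0),
             quadrant = character(0), onset_s = numeric(0),
             offset_s = numeric(0), n_bursts = integer(0),
             component_intervals_s = character(0),
             peak_amplitude = numeric(0), stringsAsFactors = FALSE)
}

#' Score detections against a truth table
#'
#' One-to-one greedy matching: candidate (prediction, truth) pairs with onset
#' distance at most `tolerance` are accepted in order of increasing distance,
#' each event used at most once. Precision with an empty prediction set (and
#' recall with an empty truth set) is 1 by convention.
#'
#' @param events detected events: data frame with `onset_s` or numeric onsets.
#' @param truth truth events, same forms accepted.
#' @param tolerance matching tolerance in seconds (default 0.05).
#' @return list with `n_matched`, `precision`, `recall`, `f1`.
#' @export
score_detection <- function(events, truth, tolerance = 0.05) {
  if (tolerance < 0) stop_invalid("tolerance must be non-negative")
  p <- if (is.data.frame(events)) events$onset_s else as.numeric(events)
  t <- if (is.data.frame(truth)) truth$onset_s else as.numeric(truth)
  np <- length(p); nt <- length(t)
  m <- 0L
  if (np && nt) {
    dm <- abs(outer(p, t, "-"))
    cand <- which(dm <= tolerance, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(dm[cand]), , drop = FALSE]
      used_p <- logical(np); used_t <- logical(nt)
      for (i in seq_len(nrow(cand))) {
        a <- cand[i, 1]; b <- cand[i, 2]
        if (!used_p[a] && !used_t[b]) {
          used_p[a] <- used_t[b] <- TRUE
          m <- m + 1L
        }
      }
    }
  }
  precision <- if (np == 0) 1 else m / np
  recall <- if (nt == 0) 1 else m / nt
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(n_matched = m, precision = precision, recall = recall, f1 = f1)
}
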