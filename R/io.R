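# Minimal PCM-16 WAV I/O and recording assembly. No audio package ships
# with the target environment, so the RIFF/PCM codec is implemented here;
# only uncompressed 16-bit PCM is supported, which is all the pipeline
# writes.

#' Write a waveform as a 16-bit PCM WAV file
#'
#' @param x numeric vector (mono) or n-by-channels matrix with samples in
#'   `[-1, 1]`; values outside are clipped.
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_wav <- function(x, sample_rate, path) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n_ch <- ncol(x); n <- nrow(x)
  pcm <- as.integer(round(pmax(-1, pmin(1, t(x))) * 32767))
  data_bytes <- 2L * n * n_ch
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")            # PCM
  writeBin(n_ch, con, size = 2, endian = "little")
  writeBin(as.integer(sample_rate), con, size = 4, endian = "little")
  writeBin(as.integer(sample_rate * n_ch * 2L), con, size = 4,
           endian = "little")
  writeBin(as.integer(n_ch * 2L), con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a 16-bit PCM WAV file
#'
#' @param path WAV path.
#' @return list with `samples` (n-by-channels matrix, scaled to
#'   `[-1, 1]`) and `sample_rate`.
#' @export
read_wav <- function(path) {
  if (!file.exists(path)) stop_invalid("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  readBin(con, integer(), size = 4, endian = "little")
  wave <- readChar(con, 4)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE"))
    stop_invalid("corrupt file (not RIFF/WAVE): %s", path)
  sample_rate <- NULL; n_ch <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, integer(), size = 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, integer(), n = 2, size = 2, endian = "little")
      if (fmt[1] != 1) stop_invalid("only PCM WAV supported: %s", path)
      n_ch <- fmt[2]
      sample_rate <- readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 4, endian = "little")
      readBin(con, integer(), size = 2, endian = "little")
      bits <- readBin(con, integer(), size = 2, endian = "little")
      if (bits != 16) stop_invalid("only 16-bit PCM supported: %s", path)
      if (sz > 16) readBin(con, raw(), n = sz - 16)
    } else if (identical(id, "data")) {
      pcm <- readBin(con, integer(), n = sz / 2, size = 2,
                     endian = "little", signed = TRUE)
      samples <- t(matrix(pcm / 32767, nrow = n_ch))   # mirrors write scale
    } else {
      readBin(con, raw(), n = sz + sz %% 2)
    }
    if (!is.null(samples) && !is.null(sample_rate)) break
  }
  if (is.null(samples)) stop_invalid("corrupt file (no data chunk): %s", path)
  list(samples = samples, sample_rate = sample_rate)
}

#' Assemble a four-quadrant recording from WAV files
#'
#' Accepts either one interleaved 4-channel WAV or four mono WAVs (one per
#' quadrant, in `quadrant_map` order).
#'
#' @param paths character vector of length 1 or 4.
#' @param quadrant_map quadrant names in channel order (default
#'   RUQ, LUQ, RLQ, LLQ).
#' @param participant_id,group,period metadata attached to the recording.
#' @return a `bs_recording`.
#' @export
read_recording <- function(paths, quadrant_map = QUADRANTS,
                           participant_id = NA_character_,
                           group = NA_character_, period = NA_character_) {
  if (length(quadrant_map) != 4 || !setequal(quadrant_map, QUADRANTS))
    stop_invalid("quadrant_map must name the 4 quadrants")
  if (length(paths) == 1) {
    w <- read_wav(paths)
    if (ncol(w$samples) != 4)
      stop_invalid("expected 4 channels, found %d in %s",
                   ncol(w$samples), paths)
    ch <- w$samples
    sr <- w$sample_rate
  } else if (length(paths) == 4) {
    ws <- lapply(paths, read_wav)
    srs <- vapply(ws, `[[`, numeric(1), "sample_rate")
    if (length(unique(srs)) != 1)
      stop_invalid("sample-rate mismatch across quadrant files")
    lens <- vapply(ws, function(w) nrow(w$samples), integer(1))
    if (any(vapply(ws, function(w) ncol(w$samples), integer(1)) != 1))
      stop_invalid("per-quadrant files must be mono")
    if (length(unique(lens)) != 1)
      stop_invalid("length mismatch across quadrant files")
    ch <- do.call(cbind, lapply(ws, `[[`, "samples"))
    sr <- srs[1]
  } else {
    stop_invalid("need 1 interleaved or 4 mono WAV paths (got %d)",
                 length(paths))
  }
  colnames(ch) <- quadrant_map
  structure(list(participant_id = participant_id, group = group,
                 period = period, sample_rate = sr, channels = ch,
                 quadrant_map = quadrant_map),
            class = "bs_recording")
}
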