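# Internal helpers shared across modules.

QUADRANTS <- c("RUQ", "LUQ", "RLQ", "LLQ")

#' Stable per-participant seed derived from a master seed
#'
#' Hashes `(master, id)` with a 31-bit polynomial rolling hash so that every
#' participant gets a reproducible, order-independent RNG stream.
#'
#' @param master integer master seed.
#' @param id character participant identifier.
#' @return integer in `[1, 2^31 - 2]`.
#' @keywords internal
stable_seed <- function(master, id) {
  stopifnot(length(master) == 1L, length(id) == 1L)
  bytes <- utf8ToInt(paste(format(master, scientific = FALSE), id, sep = ":"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(max(1, h))
}

# FNV-style hash of a config object, used to stamp pipeline artifacts.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  for (b in bytes) h <- ((bitwXor(as.integer(h %% 2^31), as.integer(b))) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

# Run code with a locally seeded RNG, restoring global state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Short-time RMS envelope
#'
#' Frame-based RMS with overlapping frames, computed in O(n) via cumulative
#' sums. Frame centres are reported in seconds.
#'
#' @param x numeric waveform.
#' @param sample_rate sampling rate in Hz.
#' @param frame frame length in seconds.
#' @param hop hop in seconds (default half a frame).
#' @return list with `t` (frame centres, s), `e` (RMS values), `hop`, `frame`.
#' @keywords internal
rms_envelope <- function(x, sample_rate, frame = 0.01, hop = frame / 2) {
  n <- length(x)
  w <- max(2L, as.integer(round(frame * sample_rate)))
  h <- max(1L, as.integer(round(hop * sample_rate)))
  if (n < w) {
    return(list(t = (n / 2) / sample_rate, e = sqrt(mean(x^2)),
                hop = h / sample_rate, frame = w / sample_rate))
  }
  cs <- c(0, cumsum(as.numeric(x)^2))
  starts <- seq.int(1L, n - w + 1L, by = h)
  e <- sqrt((cs[starts + w] - cs[starts]) / w)
  list(t = (starts - 1 + w / 2) / sample_rate, e = e,
       hop = h / sample_rate, frame = w / sample_rate)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)
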