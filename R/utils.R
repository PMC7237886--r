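# Internal numeric helpers shared across modules.

#' Zero-phase FIR low-pass filter
#'
#' Hamming-window FIR low-pass of the given order, applied forward-backward
#' (zero phase) after edge-reflection padding, so that constants and slow
#' trends survive the edges.  Used for the dF/F0 baseline smoothing (1 Hz
#' cutoff) and the locomotion speed criterion (0.25 Hz cutoff).
#'
#' @param x numeric vector.
#' @param sampling_rate sampling rate in Hz; cutoff must be below Nyquist.
#' @param cutoff_hz low-pass cutoff in Hz.
#' @param order FIR filter order (number of taps minus one).
#' @return filtered vector, same length as `x`.
#' @keywords internal
lowpass_zero_phase <- function(x, sampling_rate, cutoff_hz, order = 60L) {
  stopifnot(is.numeric(x), sampling_rate > 0)
  if (cutoff_hz >= sampling_rate / 2) {
    stop("low-pass cutoff (", cutoff_hz, " Hz) must be below Nyquist (",
         sampling_rate / 2, " Hz)")
  }
  n <- length(x)
  if (n == 0L) return(x)
  b <- signal::fir1(order, cutoff_hz / (sampling_rate / 2), type = "low")
  b <- as.numeric(b) / sum(b)   # exact unit DC gain
  # forward-backward application of a FIR filter equals a single centered
  # pass of its autocorrelation kernel (zero phase by symmetry)
  beff <- stats::convolve(b, b, type = "open")
  pad <- 3L * order
  idx <- reflect_index(seq.int(1L - pad, n + pad), n)
  xp <- x[idx]
  y <- stats::filter(xp, beff, method = "convolution", sides = 2)
  as.numeric(y)[(pad + 1L):(pad + n)]
}

# Reflect out-of-range 1-based indices back into 1..n (edge sample not
# repeated), as in "reflect" boundary handling of signal-processing edges.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  m <- 2L * (n - 1L)
  r <- (i - 1L) %% m
  ifelse(r >= n, m - r, r) + 1L
}

# Centered moving average with truncated (partial) windows at the edges.
rolling_mean_centered <- function(x, width) {
  n <- length(x)
  if (width <= 1L || n == 0L) return(x)
  half_lo <- (width - 1L) %/% 2L
  half_hi <- width %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - half_lo, 1L)
  hi <- pmin(i + half_hi, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Seconds -> frames, floor convention (deterministic, conservative).
sec_to_frames <- function(seconds, sampling_rate) {
  as.integer(floor(seconds * sampling_rate))
}

# FNV-1a 32-bit hash of an arbitrary R object (used for config logging only).
config_hash <- function(object) {
  bytes <- as.integer(serialize(object, connection = NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Wrap an angle difference in degrees onto (-90, 90] on the axial circle.
wrap_axial <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  ifelse(out == -90, 90, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
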