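# Shared numerical helpers: Welch spectra, analytic signal, peak utilities,
# seed derivation. All frequencies are kHz and all times ms unless a name
# says otherwise.

#' Welch power spectral density
#'
#' Averaged modified periodogram with a Hann window. Short inputs (shorter
#' than one segment) are zero-padded to at least twice their length and
#' estimated from the single padded segment, which is the convention used
#' here for single-cycle stimulus waveforms.
#'
#' @param x numeric trace.
#' @param sample_rate_khz sampling rate in kHz.
#' @param nperseg segment length in samples (default 4096).
#' @param overlap fractional overlap between segments (default 0.5).
#' @param detrend subtract the mean of each segment first.
#' @return list with `freq_khz` and `power` (one-sided).
#' @export
welch_psd <- function(x, sample_rate_khz, nperseg = 4096, overlap = 0.5,
                      detrend = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8) stop("trace too short for a spectral estimate")
  if (n < nperseg) {
    # single-segment mode with zero padding to >= 2x the wave length; no
    # taper: compact transients are already windowed by their own support,
    # and a Hann taper would bias the spectral peak of single-cycle waves
    nfft <- max(2L * n, 512L)
    nfft <- 2L^ceiling(log2(nfft))
    seg <- x
    if (detrend) seg <- seg - mean(seg)
    w <- rep(1, n)
    seg <- seg * w
    X <- fft(c(seg, numeric(nfft - n)))
    scale <- 1 / (sample_rate_khz * sum(w^2))
    p <- (Mod(X)^2) * scale
    half <- seq_len(nfft %/% 2 + 1L)
    p <- p[half]
    if (length(half) > 2) p[2:(length(half) - 1)] <- 2 * p[2:(length(half) - 1)]
    return(list(freq_khz = (half - 1) * sample_rate_khz / nfft, power = p))
  }
  step <- max(1L, floor(nperseg * (1 - overlap)))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- hann_window(nperseg)
  scale <- 1 / (sample_rate_khz * sum(w^2))
  acc <- numeric(nperseg %/% 2 + 1L)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(seg * w)
    p <- (Mod(X)^2) * scale
    half <- seq_len(nperseg %/% 2 + 1L)
    p <- p[half]
    p[2:(length(half) - 1)] <- 2 * p[2:(length(half) - 1)]
    acc <- acc + p
  }
  list(freq_khz = (seq_len(nperseg %/% 2 + 1L) - 1) * sample_rate_khz / nperseg,
       power = acc / length(starts))
}

hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x real-valued trace.
#' @return complex vector of the same length; `Mod()` is the amplitude
#'   envelope and `Arg()` the instantaneous phase.
#' @export
analytic_signal <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("trace too short for an analytic signal")
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Zero-phase band-pass by zeroing FFT bins outside [lo, hi] kHz.
fft_bandpass <- function(x, sample_rate_khz, lo_khz, hi_khz) {
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * sample_rate_khz / n
  f <- pmin(f, sample_rate_khz - f)  # two-sided frequency magnitude
  keep <- f >= lo_khz & f <= hi_khz
  X[!keep] <- 0
  Re(fft(X, inverse = TRUE) / n)
}

# Local maxima indices with a minimum separation (in samples). Of any run of
# candidates closer than min_sep, the largest survives.
local_maxima <- function(x, min_sep = 1L) {
  n <- length(x)
  if (n < 3) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(idx) == 0 || min_sep <= 1L) return(idx)
  keep <- integer(0)
  ord <- idx[order(-x[idx])]
  taken <- logical(n)
  for (i in ord) {
    lo <- max(1L, i - min_sep + 1L); hi <- min(n, i + min_sep - 1L)
    if (!any(taken[lo:hi])) {
      keep <- c(keep, i)
      taken[i] <- TRUE
    }
  }
  sort(keep)
}

# Sub-sample refinement of an extremum by parabolic interpolation.
# Returns position in (fractional) sample units and the interpolated value.
refine_extremum <- function(x, i) {
  n <- length(x)
  if (i <= 1 || i >= n) return(list(pos = i, value = x[i]))
  y1 <- x[i - 1]; y2 <- x[i]; y3 <- x[i + 1]
  denom <- (y1 - 2 * y2 + y3)
  if (denom == 0) return(list(pos = i, value = y2))
  d <- 0.5 * (y1 - y3) / denom
  d <- max(-0.5, min(0.5, d))
  list(pos = i + d, value = y2 - 0.25 * (y1 - y3) * d)
}

# Peak prominence for spectra: height above the highest of the two minima
# separating the peak from higher terrain on either side.
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(i) {
    left <- x[seq_len(i)]
    higher_l <- which(left > x[i])
    lmin <- if (length(higher_l)) min(left[max(higher_l):i]) else min(left)
    right <- x[i:length(x)]
    higher_r <- which(right > x[i])
    rmin <- if (length(higher_r)) min(right[1:min(higher_r)]) else min(right)
    x[i] - max(lmin, rmin)
  }, numeric(1))
}

# Deterministic child seeds below 2^31, derived from a user seed.
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647
  as.integer(max(1, s))
}

msamples <- function(ms, rate_khz) as.integer(round(ms * rate_khz))

check_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("%s must be finite", what))
  invisible(x)
}
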