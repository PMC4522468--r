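# Spontaneous-activity characterization: median filtering, alternating
# peak/trough detection, oscillation frequency/period/amplitude with the
# inclusion criterion, interspike intervals, and differential-recording
# spectra with beat detection.

#' Running-median filter of a voltage trace
#'
#' @param trace numeric trace.
#' @param sample_rate_khz sample rate.
#' @param width_ms filter width (default 0.1 ms); must span at least 3
#'   samples at the trace's rate.
#' @return filtered trace, same length (endrule keeps edges by median).
#' @export
median_filter_trace <- function(trace, sample_rate_khz, width_ms = 0.1) {
  k <- floor(width_ms * sample_rate_khz)
  if (k < 3) stop("filter width must span at least 3 samples")
  if (k %% 2 == 0) k <- k - 1L
  as.numeric(stats::runmed(trace, k, endrule = "median"))
}

#' Detect alternating oscillatory peaks and troughs
#'
#' Local extrema separated by at least `min_sep_ms`, pruned to strict
#' peak-trough alternation (of two consecutive same-type extrema the more
#' extreme one is kept). Peak/trough times are refined by parabolic
#' interpolation.
#'
#' @param trace filtered trace.
#' @param sample_rate_khz sample rate.
#' @param min_sep_ms minimum separation between like extrema (default
#'   0.2 ms, suited to 1-3 kHz oscillations).
#' @return data.frame with `time_ms`, `value_mv`, `type` ("peak"/"trough"),
#'   alternating; zero rows (with attribute `flagged = TRUE`) if none found.
#' @export
detect_peaks_troughs <- function(trace, sample_rate_khz, min_sep_ms = 0.2) {
  min_sep <- max(1L, msamples(min_sep_ms, sample_rate_khz))
  pk <- local_maxima(trace, min_sep)
  tr <- local_maxima(-trace, min_sep)
  if (length(pk) == 0 && length(tr) == 0) {
    out <- data.frame(time_ms = numeric(0), value_mv = numeric(0),
                      type = character(0))
    attr(out, "flagged") <- TRUE
    return(out)
  }
  ext <- rbind(
    data.frame(idx = pk, type = "peak"),
    data.frame(idx = tr, type = "trough"))
  ext <- ext[order(ext$idx), ]
  # enforce strict alternation: of two consecutive same-type extrema keep
  # the more extreme one, repeating until the sequence alternates
  repeat {
    if (nrow(ext) < 2) break
    same <- which(ext$type[-1] == ext$type[-nrow(ext)])
    if (length(same) == 0) break
    drop <- integer(0)
    for (s in same) {
      vi <- trace[ext$idx[s]]; vj <- trace[ext$idx[s + 1]]
      worse <- if (ext$type[s] == "peak") {
        if (vj > vi) s else s + 1
      } else {
        if (vj < vi) s else s + 1
      }
      drop <- c(drop, worse)
    }
    ext <- ext[-unique(drop), ]
  }
  ref <- lapply(ext$idx, function(i) {
    x <- if (ext$type[match(i, ext$idx)] == "trough") -trace else trace
    r <- refine_extremum(x, i)
    if (ext$type[match(i, ext$idx)] == "trough") r$value <- -r$value
    r
  })
  data.frame(time_ms = vapply(ref, `[[`, numeric(1), "pos") / sample_rate_khz -
               1 / sample_rate_khz,
             value_mv = vapply(ref, `[[`, numeric(1), "value"),
             type = ext$type, row.names = NULL)
}

#' Spontaneous oscillation statistics across repeated recordings
#'
#' The magnitude FFT is averaged across recordings (phase is random across
#' repetitions, so complex averaging would cancel) and its peak taken as the
#' spontaneous oscillation frequency; the period is its inverse. The
#' amplitude is each trough voltage subtracted from the preceding peak
#' voltage, averaged within and then across recordings. The inclusion
#' criterion is `amplitude >= max(2.5 * noise_floor, 0.1 mV)`.
#'
#' @param recordings list of equal-length traces (typically five 1-s
#'   recordings), or a matrix samples x recordings.
#' @param sample_rate_khz sample rate.
#' @param noise_floor_mv baseline noise level (robust SD of an
#'   oscillation-free segment).
#' @param n_expected expected number of recordings (default 5; fewer gives a
#'   warning, the statistics are computed anyway).
#' @param band_khz search band for the spectral peak (default 0.5-3.5 kHz).
#' @param min_sep_ms passed to [detect_peaks_troughs()].
#' @return list: `f_spont_khz`, `period_ms`, `amplitude_mv`,
#'   `passes_criterion`, `noise_floor_mv`, `n_recordings`.
#' @export
spontaneous_stats <- function(recordings, sample_rate_khz, noise_floor_mv,
                              n_expected = 5, band_khz = c(0.5, 3.5),
                              min_sep_ms = 0.2) {
  if (is.matrix(recordings))
    recordings <- lapply(seq_len(ncol(recordings)), function(i) recordings[, i])
  nrec <- length(recordings)
  if (nrec < n_expected)
    warning(sprintf("only %d of %d expected recordings supplied; computing anyway",
                    nrec, n_expected))
  len <- unique(vapply(recordings, length, integer(1)))
  if (length(len) != 1) stop("recordings must have equal length")
  # averaged magnitude spectrum
  spec <- Reduce(`+`, lapply(recordings, function(x) Mod(fft(x - mean(x)))))
  spec <- spec / nrec
  f <- (seq_len(len) - 1) * sample_rate_khz / len
  inband <- which(f >= band_khz[1] & f <= band_khz[2])
  f_spont <- f[inband[which.max(spec[inband])]]
  amps <- unlist(lapply(recordings, function(x) {
    xf <- median_filter_trace(x, sample_rate_khz)
    pt <- detect_peaks_troughs(xf, sample_rate_khz, min_sep_ms)
    if (nrow(pt) < 2) return(numeric(0))
    a <- numeric(0)
    for (i in seq_len(nrow(pt) - 1)) {
      if (pt$type[i] == "peak" && pt$type[i + 1] == "trough")
        a <- c(a, pt$value_mv[i] - pt$value_mv[i + 1])
    }
    a
  }))
  amplitude <- if (length(amps)) mean(amps) else 0
  list(f_spont_khz = f_spont, period_ms = 1 / f_spont,
       amplitude_mv = amplitude,
       passes_criterion = amplitude >= max(2.5 * noise_floor_mv, 0.1),
       noise_floor_mv = noise_floor_mv, n_recordings = nrec)
}

#' Interspike (interevent) intervals
#'
#' @param events an [event_train()] or numeric vector of times (ms).
#' @return numeric vector of successive differences (ms); empty for fewer
#'   than two events.
#' @export
interspike_intervals <- function(events) {
  t <- if (inherits(events, "event_train")) events$times_ms else as.numeric(events)
  if (length(t) < 2) return(numeric(0))
  diff(t)
}

#' Spectral peaks and beat report of a differential recording
#'
#' Welch spectrum restricted to `band_khz`; local maxima above a prominence
#' threshold (default 2 x robust noise of the in-band spectrum) are reported
#' together with an amplitude-envelope modulation index (quantile range of
#' the Hilbert envelope of the band-passed trace) and the dominant envelope
#' (beat) frequency.
#'
#' @param trace differential recording.
#' @param sample_rate_khz sample rate.
#' @param band_khz two-element frequency band (within Nyquist).
#' @param prominence_factor multiple of the spectrum's MAD-based noise used
#'   as the prominence threshold.
#' @return list: `peaks_khz`, `peak_power`, `modulation_index`,
#'   `envelope_freq_khz`.
#' @export
differential_psd_peaks <- function(trace, sample_rate_khz,
                                   band_khz = c(0.5, 3.5),
                                   prominence_factor = 2) {
  if (band_khz[2] <= band_khz[1]) stop("band is empty")
  if (band_khz[2] > sample_rate_khz / 2) stop("band exceeds Nyquist")
  ps <- welch_psd(trace, sample_rate_khz)
  sel <- which(ps$freq_khz >= band_khz[1] & ps$freq_khz <= band_khz[2])
  if (length(sel) < 5) stop("band too narrow for the spectral resolution")
  p <- ps$power[sel]
  pk <- local_maxima(p, min_sep = 2L)
  thr <- prominence_factor * mad(p, constant = 1.4826)
  if (length(pk)) {
    prom <- peak_prominences(p, pk)
    pk <- pk[prom > thr]
  }
  bp <- fft_bandpass(trace, sample_rate_khz, band_khz[1], band_khz[2])
  env <- Mod(analytic_signal(bp))
  # trim edges (5% each side) against transform edge effects
  m <- length(env)
  core <- env[max(1, floor(0.05 * m)):ceiling(0.95 * m)]
  qs <- quantile(core, c(0.05, 0.95), names = FALSE)
  mi <- (qs[2] - qs[1]) / (qs[2] + qs[1])
  env_f <- NA_real_
  ec <- core - mean(core)
  if (length(ec) > 16 && sd(ec) > 0) {
    es <- Mod(fft(ec))
    fe <- (seq_along(ec) - 1) * sample_rate_khz / length(ec)
    half <- 2:floor(length(ec) / 2)
    env_f <- fe[half][which.max(es[half])]
  }
  list(peaks_khz = ps$freq_khz[sel][pk], peak_power = p[pk],
       modulation_index = as.numeric(mi), envelope_freq_khz = env_f)
}
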