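# Frequency tuning: threshold-based curves for spiking receptors,
# vector-strength-based curves for oscillating receptors, stimulus
# peak-frequency determination, EOD spectra and total duration, and octave
# comparisons.

#' Spiking response criterion
#'
#' A receptor responded if it fired at least one more spike per sweep during
#' the stimulus window than during the equally long prestimulus window.
#'
#' @param ss a [sweep_set()] (spike events used if embedded, otherwise
#'   detected at `threshold_mv`).
#' @param window_ms window length (default 90 ms).
#' @param threshold_mv detection threshold when events are not embedded.
#' @return list: `responded`, `stim_rate`, `prestim_rate` (spikes/sweep).
#' @export
spiking_response_criterion <- function(ss, window_ms = 90,
                                       threshold_mv = NULL) {
  stopifnot(inherits(ss, "sweep_set"))
  t_on <- ss$t_stim_on_ms
  if (is.na(t_on)) stop("stimulus onset unknown")
  total_ms <- nrow(ss$sweeps) / ss$sample_rate_khz
  if (t_on - window_ms < 0 || t_on + window_ms > total_ms)
    stop("windows exceed sweep bounds")
  get_times <- function(i) {
    if (!is.null(ss$events)) ss$events[[i]]
    else detect_spike_peaks(ss$sweeps[, i], ss$sample_rate_khz, threshold_mv)
  }
  n_sweeps <- ncol(ss$sweeps)
  stim <- pre <- numeric(n_sweeps)
  for (i in seq_len(n_sweeps)) {
    tt <- get_times(i)
    stim[i] <- sum(tt >= t_on & tt < t_on + window_ms)
    pre[i] <- sum(tt >= t_on - window_ms & tt < t_on)
  }
  list(responded = mean(stim) - mean(pre) >= 1,
       stim_rate = mean(stim), prestim_rate = mean(pre))
}

#' Threshold tuning curve for a spiking receptor
#'
#' The threshold at each frequency is the lowest intensity that elicited a
#' spiking response; the best frequency is the frequency with the lowest
#' threshold, and the curve is expressed in dB (20 log10 of the intensity
#' ratio) relative to the threshold at the best frequency. Frequencies with
#' no responding intensity become open (NA) points.
#'
#' @param responses data.frame with columns `frequency_khz`, `intensity_na`,
#'   `responded` (logical).
#' @return object of class `tuning_curve` with `frequencies_khz`, `measure`
#'   (threshold dB), `threshold_na`, `best_frequency_khz`, `open` (logical),
#'   `mode = "threshold"`.
#' @export
spiking_threshold_curve <- function(responses) {
  need <- c("frequency_khz", "intensity_na", "responded")
  if (!all(need %in% names(responses))) stop("responses needs columns: ",
                                             paste(need, collapse = ", "))
  freqs <- sort(unique(responses$frequency_khz))
  thr <- vapply(freqs, function(f) {
    sub <- responses[responses$frequency_khz == f & responses$responded, ]
    if (nrow(sub) == 0) NA_real_ else min(sub$intensity_na)
  }, numeric(1))
  if (all(is.na(thr))) stop("no responding intensity at any frequency")
  bf_idx <- which(thr == min(thr, na.rm = TRUE))
  if (length(bf_idx) > 1)
    message("threshold tie across frequencies; lowest frequency chosen")
  bf_idx <- bf_idx[1]
  db <- 20 * log10(thr / thr[bf_idx])
  structure(list(frequencies_khz = freqs, measure = db, threshold_na = thr,
                 best_frequency_khz = freqs[bf_idx], open = is.na(thr),
                 mode = "threshold"),
            class = "tuning_curve")
}

#' Welch peak frequency of a stimulus waveform
#'
#' @param wv a `wave` or numeric vector.
#' @param sample_rate_khz required when `wv` is numeric.
#' @return peak-power frequency in kHz.
#' @export
stimulus_peak_frequency <- function(wv, sample_rate_khz = NULL) {
  if (inherits(wv, "wave")) {
    x <- wv$samples; rate <- wv$sample_rate_khz
  } else {
    x <- as.numeric(wv); rate <- sample_rate_khz
    if (is.null(rate)) stop("sample_rate_khz required for a numeric wave")
  }
  ps <- welch_psd(x, rate)
  pw <- ps$power[-1]  # exclude DC
  if (max(pw) <= 0 || diff(range(pw)) == 0) stop("flat spectrum")
  ps$freq_khz[-1][which.max(pw)]
}

#' Vector-strength tuning curve for an oscillating receptor
#'
#' Best frequency is the frequency eliciting the highest vector strength,
#' determined per polarity; when the polarities disagree the receptor's best
#' frequency is the mean of the two. Ties are broken toward the lower
#' frequency (and logged).
#'
#' @param vs_table data.frame with columns `frequency_khz`, `polarity`
#'   (+1/-1) and `vector_strength`.
#' @return object of class `tuning_curve` with per-polarity curves and the
#'   (possibly polarity-averaged) `best_frequency_khz`, `mode =
#'   "vector_strength"`.
#' @export
oscillating_tuning_curve <- function(vs_table) {
  need <- c("frequency_khz", "polarity", "vector_strength")
  if (!all(need %in% names(vs_table))) stop("vs_table needs columns: ",
                                            paste(need, collapse = ", "))
  pol_best <- vapply(sort(unique(vs_table$polarity)), function(p) {
    sub <- vs_table[vs_table$polarity == p, ]
    sub <- sub[order(sub$frequency_khz), ]
    best <- which(sub$vector_strength == max(sub$vector_strength))
    if (length(best) > 1)
      message(sprintf("vector-strength tie at polarity %+d; lowest frequency chosen", p))
    sub$frequency_khz[best[1]]
  }, numeric(1))
  structure(list(frequencies_khz = sort(unique(vs_table$frequency_khz)),
                 table = vs_table, per_polarity_best_khz = pol_best,
                 best_frequency_khz = mean(pol_best),
                 mode = "vector_strength"),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> mode=%s, best frequency = %.3g kHz\n",
              x$mode, x$best_frequency_khz))
  invisible(x)
}

#' EOD spectral peak and total duration
#'
#' Welch peak-power frequency, and total duration as the time between the
#' first and last points where the absolute waveform exceeds 0.5% of the
#' maximum peak-to-peak amplitude.
#'
#' @param wv a `wave` or numeric vector (zero-baseline padded).
#' @param sample_rate_khz required when `wv` is numeric.
#' @return list: `peak_power_freq_khz`, `total_duration_ms`.
#' @export
eod_spectrum_duration <- function(wv, sample_rate_khz = NULL) {
  if (inherits(wv, "wave")) {
    x <- wv$samples; rate <- wv$sample_rate_khz
  } else {
    x <- as.numeric(wv); rate <- sample_rate_khz
    if (is.null(rate)) stop("sample_rate_khz required for a numeric wave")
  }
  if (all(x == 0)) stop("all-zero waveform")
  di <- duration_05_idx(x)
  # inclusive sample count, so a rectangle of width w measures exactly w
  list(peak_power_freq_khz = stimulus_peak_frequency(x, rate),
       total_duration_ms = (di[2] - di[1] + 1) / rate)
}

#' Octave distance between two frequencies
#'
#' @param best_frequency_khz,peak_power_freq_khz positive frequencies.
#' @return `log2(best_frequency / peak_power_freq)` in octaves.
#' @export
octave_distance <- function(best_frequency_khz, peak_power_freq_khz) {
  if (best_frequency_khz <= 0 || peak_power_freq_khz <= 0)
    stop("frequencies must be positive")
  log2(best_frequency_khz / peak_power_freq_khz)
}
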