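# Stimulus construction: monopolar square pulses and pulse pairs,
# single-cycle bipolar sine waves, ramped sine bursts, synthetic EOD
# waveforms and constant-IPI EOD trains, plus residual stimulus artifacts.
#
# Stimulus amplitudes are constant-current intensities in nA. Stimuli are
# generated at 195.31 kHz by default and resampled onto the recording grid
# by linear interpolation when fed to a simulated receptor.

#' Stimulus specification
#'
#' @param kind one of `"square_pulse"`, `"pulse_pair"`, `"bipolar_sine"`,
#'   `"sine_burst"`, `"eod"`, `"eod_train"`.
#' @param duration_ms pulse (or single-cycle) duration in ms.
#' @param polarity `+1` or `-1`. For bipolar sines, positive polarity means
#'   the peak leads the trough.
#' @param intensity_na stimulus intensity in nA.
#' @param ipi_ms interpulse interval (onset-to-onset), required for
#'   `pulse_pair` and `eod_train`.
#' @param n_pulses number of pulses for `eod_train`.
#' @param frequency_khz frequency for `bipolar_sine` (alternative to
#'   `duration_ms`; exactly one must be given) and for `sine_burst`.
#' @param sample_rate_khz generation sample rate (default 195.31 kHz).
#' @param eod_wave sampled EOD waveform (a `wave`), for `eod`/`eod_train`.
#' @param ramp_ms cosine-squared on/off ramp for `sine_burst` (default 5 ms).
#' @return object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(kind, duration_ms = NULL, polarity = 1L,
                          intensity_na = 1, ipi_ms = NULL, n_pulses = NULL,
                          frequency_khz = NULL,
                          sample_rate_khz = .STIM_RATE_KHZ,
                          eod_wave = NULL, ramp_ms = 5) {
  kind <- match.arg(kind, c("square_pulse", "pulse_pair", "bipolar_sine",
                            "sine_burst", "eod", "eod_train"))
  if (!polarity %in% c(-1L, 1L, -1, 1)) stop("polarity must be +1 or -1")
  if (intensity_na < 0) stop("intensity_na must be >= 0")
  if (sample_rate_khz <= 0) stop("sample_rate_khz must be > 0")
  if (kind == "bipolar_sine") {
    if (is.null(duration_ms) == is.null(frequency_khz))
      stop("bipolar_sine needs exactly one of duration_ms or frequency_khz")
    if (is.null(duration_ms)) duration_ms <- 1 / frequency_khz
    if (is.null(frequency_khz)) frequency_khz <- 1 / duration_ms
  }
  if (kind == "sine_burst") {
    if (is.null(frequency_khz)) stop("sine_burst needs frequency_khz")
    if (is.null(duration_ms)) duration_ms <- 90
  }
  if (kind %in% c("square_pulse", "pulse_pair") && is.null(duration_ms))
    stop(sprintf("%s needs duration_ms", kind))
  if (kind == "pulse_pair" && is.null(ipi_ms))
    stop("pulse_pair needs ipi_ms")
  if (kind == "eod_train") {
    if (is.null(ipi_ms)) stop("eod_train needs ipi_ms")
    if (is.null(n_pulses)) n_pulses <- 10L
  }
  if (kind %in% c("eod", "eod_train") && is.null(eod_wave))
    stop(sprintf("%s needs eod_wave", kind))
  if (!is.null(duration_ms) && duration_ms <= 0) stop("duration_ms must be > 0")
  if (!is.null(ipi_ms) && ipi_ms <= 0) stop("ipi_ms must be > 0")
  structure(list(kind = kind, duration_ms = duration_ms,
                 polarity = as.integer(sign(polarity)),
                 intensity_na = intensity_na, ipi_ms = ipi_ms,
                 n_pulses = n_pulses, frequency_khz = frequency_khz,
                 sample_rate_khz = sample_rate_khz, eod_wave = eod_wave,
                 ramp_ms = ramp_ms),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$kind,
      sprintf("dur=%s ms", format(x$duration_ms)),
      sprintf("pol=%+d", x$polarity),
      sprintf("I=%g nA", x$intensity_na),
      if (!is.null(x$ipi_ms)) sprintf("ipi=%g ms", x$ipi_ms) else "",
      sprintf("@ %g kHz", x$sample_rate_khz), "\n")
  invisible(x)
}

wave <- function(samples, sample_rate_khz) {
  structure(list(samples = as.numeric(samples),
                 sample_rate_khz = sample_rate_khz), class = "wave")
}

#' Render a monopolar square pulse or pulse pair
#'
#' A pulse of duration `d` occupies `floor(d * sample_rate)` samples. For a
#' pair the second onset is `ipi_ms` (onset-to-onset) after the first.
#'
#' @param spec a [stimulus_spec()] of kind `square_pulse` or `pulse_pair`.
#' @return a `wave` (list of `samples` in nA and `sample_rate_khz`).
#' @export
make_pulse_stimulus <- function(spec) {
  if (!inherits(spec, "stimulus_spec")) stop("spec must be a stimulus_spec")
  if (!spec$kind %in% c("square_pulse", "pulse_pair"))
    stop("make_pulse_stimulus handles square_pulse and pulse_pair only")
  rate <- spec$sample_rate_khz
  n_on <- max(1L, floor(spec$duration_ms * rate))
  amp <- spec$polarity * spec$intensity_na
  if (spec$kind == "square_pulse") {
    x <- c(rep(amp, n_on), 0)
  } else {
    if (is.null(spec$ipi_ms)) stop("pulse_pair needs ipi_ms")
    gap <- msamples(spec$ipi_ms, rate)
    total <- gap + n_on + 1L
    x <- numeric(total)
    x[seq_len(n_on)] <- amp
    x[gap + seq_len(n_on)] <- amp
  }
  wave(x, rate)
}

#' Render a single-cycle bipolar sine wave
#'
#' One full sine cycle; with positive polarity the peak precedes the trough
#' (and the trace is inverted for negative polarity). Zero outside the cycle.
#'
#' @param frequency_khz,duration_ms exactly one must be given
#'   (`duration = 1/frequency`).
#' @param polarity +1 (peak leading trough) or -1.
#' @param intensity_na amplitude in nA.
#' @param sample_rate_khz sample rate (default 195.31 kHz).
#' @return a `wave`.
#' @export
make_bipolar_sine <- function(frequency_khz = NULL, duration_ms = NULL,
                              polarity = 1L, intensity_na = 1,
                              sample_rate_khz = .STIM_RATE_KHZ) {
  spec <- stimulus_spec("bipolar_sine", duration_ms = duration_ms,
                        frequency_khz = frequency_khz, polarity = polarity,
                        intensity_na = intensity_na,
                        sample_rate_khz = sample_rate_khz)
  d <- spec$duration_ms
  n <- max(4L, floor(d * sample_rate_khz))
  t <- (seq_len(n) - 1) / sample_rate_khz
  x <- spec$polarity * spec$intensity_na * sin(2 * pi * t / d)
  wave(c(x, 0), sample_rate_khz)
}

# cosine-squared-ramped sine burst, used for spiking-receptor tuning
make_sine_burst <- function(spec) {
  rate <- spec$sample_rate_khz
  n <- floor(spec$duration_ms * rate)
  t <- (seq_len(n) - 1) / rate
  env <- rep(1, n)
  nr <- msamples(spec$ramp_ms, rate)
  if (nr > 0 && 2 * nr < n) {
    ramp <- sin(seq(0, pi / 2, length.out = nr))^2
    env[seq_len(nr)] <- ramp
    env[n - nr + seq_len(nr)] <- rev(ramp)
  }
  x <- spec$polarity * spec$intensity_na * env *
    sin(2 * pi * spec$frequency_khz * t)
  wave(c(x, 0), rate)
}

# first/last 0.5 % peak-to-peak crossings, in sample indices
duration_05_idx <- function(x) {
  thr <- 0.005 * (max(x) - min(x))
  idx <- which(abs(x) > thr)
  if (length(idx) == 0) return(NULL)
  c(idx[1], idx[length(idx)])
}

#' Synthesize an EOD-like biphasic waveform
#'
#' A cosine-squared-windowed sine carrier, calibrated so that the Welch
#' spectral peak is within 10% of `peak_freq_khz` and the total duration by
#' the 0.5% peak-to-peak criterion is within 10% of `duration_ms`. Stands in
#' for a library of recorded conspecific EOD waveforms.
#'
#' @param duration_ms target total duration (0.5% criterion).
#' @param peak_freq_khz target Welch peak-power frequency.
#' @param sample_rate_khz sample rate (default 195.31 kHz).
#' @param amplitude peak amplitude scale (arbitrary units; head-positive).
#' @return a `wave`, zero-padded by half a duration on each side.
#' @export
synth_eod <- function(duration_ms, peak_freq_khz,
                      sample_rate_khz = .STIM_RATE_KHZ, amplitude = 1) {
  if (duration_ms <= 0 || peak_freq_khz <= 0)
    stop("duration_ms and peak_freq_khz must be > 0")
  if (peak_freq_khz * duration_ms < 0.5)
    stop("unattainable combination: peak_freq_khz * duration_ms < 0.5")
  build <- function(fc, width) {
    pad <- 0.5 * duration_ms
    n <- msamples(width + 2 * pad, sample_rate_khz)
    t <- (seq_len(n) - 1) / sample_rate_khz - pad - width / 2
    env <- ifelse(abs(t) < width / 2, cos(pi * t / width)^2, 0)
    x <- env * sin(2 * pi * fc * t)
    x / max(abs(x))
  }
  measure <- function(x) {
    ps <- welch_psd(x, sample_rate_khz)
    pk <- ps$freq_khz[which.max(ps$power)]
    di <- duration_05_idx(x)
    dur <- (di[2] - di[1] + 1) / sample_rate_khz
    c(pk, dur)
  }
  fc <- peak_freq_khz
  width <- duration_ms
  for (i in 1:15) {
    x <- build(fc, width)
    m <- measure(x)
    if (abs(m[1] - peak_freq_khz) / peak_freq_khz < 0.02 &&
        abs(m[2] - duration_ms) / duration_ms < 0.02) break
    fc <- fc * (peak_freq_khz / m[1])^0.8
    width <- width * (duration_ms / m[2])^0.8
    if (fc <= 0 || width <= 0) stop("EOD calibration diverged")
  }
  m <- measure(x)
  if (abs(m[1] - peak_freq_khz) / peak_freq_khz > 0.1 ||
      abs(m[2] - duration_ms) / duration_ms > 0.1)
    stop(sprintf(
      "unattainable combination: got peak %.3g kHz, duration %.3g ms",
      m[1], m[2]))
  wave(amplitude * x, sample_rate_khz)
}

#' Concatenate identical EODs into a constant-IPI train
#'
#' The EOD's start and end are located by the 0.5% peak-to-peak criterion and
#' the waveform trimmed to that support. Onsets are placed at multiples of
#' `ipi_ms`; when the EOD outlasts the IPI each copy is truncated at the IPI.
#'
#' @param eod a `wave` (e.g. from [synth_eod()]).
#' @param ipi_ms onset-to-onset interval in ms.
#' @param n_pulses number of EODs (default 10).
#' @return a `wave` containing the train.
#' @export
make_eod_train <- function(eod, ipi_ms, n_pulses = 10L) {
  if (!inherits(eod, "wave")) stop("eod must be a wave")
  if (n_pulses < 1) stop("n_pulses must be >= 1")
  if (ipi_ms <= 0) stop("ipi_ms must be > 0")
  rate <- eod$sample_rate_khz
  di <- duration_05_idx(eod$samples)
  if (is.null(di)) stop("EOD waveform is all zero")
  core <- eod$samples[di[1]:di[2]]
  gap <- msamples(ipi_ms, rate)
  if (length(core) > gap) core_t <- core[seq_len(gap)] else core_t <- core
  total <- (n_pulses - 1L) * gap + length(if (n_pulses > 1) core_t else core)
  # all but the last copy are truncated at the IPI; the last runs to its end
  x <- numeric((n_pulses - 1L) * gap + length(core))
  for (k in seq_len(n_pulses)) {
    seg <- if (k < n_pulses) core_t else core
    i0 <- (k - 1L) * gap
    x[i0 + seq_along(seg)] <- seg
  }
  wave(x, rate)
}

#' Add a residual stimulus artifact to a recording trace
#'
#' Models an imperfect bridge balance as `resistive_gain * s(t) +
#' capacitive_gain * ds/dt`, time-aligned with the trace.
#'
#' @param trace recorded trace (mV).
#' @param stimulus stimulus samples on the same time grid as `trace` (nA).
#' @param resistive_gain mV per nA.
#' @param capacitive_gain mV per (nA/ms).
#' @param sample_rate_khz shared sample rate.
#' @return trace with artifact added.
#' @export
add_artifact <- function(trace, stimulus, resistive_gain = 0,
                         capacitive_gain = 0,
                         sample_rate_khz = .REC_RATE_KHZ) {
  s <- if (inherits(stimulus, "wave")) stimulus$samples else as.numeric(stimulus)
  if (length(s) != length(trace))
    stop("trace and stimulus must be time-aligned (equal length)")
  dsdt <- c(0, diff(s)) * sample_rate_khz
  trace + resistive_gain * s + capacitive_gain * dsdt
}

# Resample a stimulus wave onto the recording grid by linear interpolation.
# Returns n_out samples starting at t_on_ms within the sweep.
resample_to_sweep <- function(wv, rec_rate_khz, n_out, t_on_ms) {
  t_rec <- (seq_len(n_out) - 1) / rec_rate_khz
  t_src <- (seq_along(wv$samples) - 1) / wv$sample_rate_khz + t_on_ms
  out <- approx(t_src, wv$samples, xout = t_rec, yleft = 0, yright = 0)$y
  out[!is.finite(out)] <- 0
  out
}
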