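# Stimulus-evoked measurements: oscillatory phase resets (phi, vector
# strength, delta-phi), evoked amplitudes and enhancement, oscillation- and
# spike-timing differences, interoscillation intervals, paired-pulse
# normalization, population synchrony, and spiking response measures.

avg_trace <- function(ss) rowMeans(ss$sweeps)

# First `n_peaks` oscillatory peaks after `after_ms` on a (single) trace:
# median filter, peak/trough detection, artifact rule. Returns the peak
# times/values, the designated peak index (1 or 2), latency and period.
post_peak_measure <- function(trace, sample_rate_khz, after_ms,
                              n_peaks = 7, min_sep_ms = 0.2,
                              median_width_ms = 0.1) {
  xf <- median_filter_trace(trace, sample_rate_khz, median_width_ms)
  pt <- detect_peaks_troughs(xf, sample_rate_khz, min_sep_ms)
  guard <- 1 / sample_rate_khz
  post <- pt[pt$time_ms > after_ms + guard, , drop = FALSE]
  pk <- post[post$type == "peak", , drop = FALSE]
  if (nrow(pk) == 0) stop("no poststimulus oscillatory peaks found")
  partial <- nrow(pk) < n_peaks
  pk <- head(pk, n_peaks)
  periods <- diff(pk$time_ms)
  used_second <- FALSE
  if (length(periods) >= 6) {
    ref <- mean(periods[2:6])
    if (periods[1] < 0.85 * ref || periods[1] > 1.15 * ref) used_second <- TRUE
  }
  d <- if (used_second) 2L else 1L
  if (nrow(pk) < d + 1)
    stop("too few peaks to measure a poststimulus period")
  lat <- pk$time_ms[d] - after_ms
  p <- pk$time_ms[d + 1] - pk$time_ms[d]
  # amplitude: mean of the designated and following peak voltages minus the
  # intervening trough voltage
  amp <- NA_real_
  tr_between <- post[post$type == "trough" &
                       post$time_ms > pk$time_ms[d] &
                       post$time_ms < pk$time_ms[d + 1], , drop = FALSE]
  if (nrow(tr_between) >= 1)
    amp <- mean(c(pk$value_mv[d], pk$value_mv[d + 1])) - tr_between$value_mv[1]
  list(peaks = pk, lat_ms = lat, p_ms = p, phi_rad = 2 * pi * (lat %% p) / p,
       used_second_peak = used_second, amplitude_mv = amp, partial = partial,
       extrema = pt)
}

# mean prestimulus oscillation amplitude (evoked definition applied to all
# peak-trough-peak triples before `before_ms`)
prestim_amplitude <- function(trace, sample_rate_khz, before_ms,
                              min_sep_ms = 0.2) {
  xf <- median_filter_trace(trace, sample_rate_khz)
  pt <- detect_peaks_troughs(xf, sample_rate_khz, min_sep_ms)
  pre <- pt[pt$time_ms < before_ms, , drop = FALSE]
  if (nrow(pre) < 3) return(NA_real_)
  a <- numeric(0)
  for (i in seq_len(nrow(pre) - 2)) {
    if (pre$type[i] == "peak" && pre$type[i + 1] == "trough" &&
        pre$type[i + 2] == "peak")
      a <- c(a, mean(c(pre$value_mv[i], pre$value_mv[i + 2])) -
               pre$value_mv[i + 1])
  }
  if (length(a)) mean(a) else NA_real_
}

#' Measure poststimulus oscillation resets across sweeps
#'
#' Each sweep is median filtered (0.1 ms), the first seven oscillatory peaks
#' after stimulus offset detected, and the first six poststimulus periods
#' measured. If the first period is less than 85% or more than 115% of the
#' average of the next five, the first peak is considered contaminated by
#' stimulus artifact and the second peak is used for all measurements. The
#' reset angle is `phi = 2*pi*(lat mod p)/p` where `lat` is the designated
#' peak's latency from stimulus offset and `p` the poststimulus period.
#'
#' @param ss a [sweep_set()].
#' @param offset_ms stimulus offset to reference latencies to (default the
#'   sweep set's `t_stim_off_ms`).
#' @param min_sep_ms minimum extremum separation for peak detection.
#' @param n_peaks number of poststimulus peaks to detect (default 7).
#' @return list with `per_sweep` (data.frame: `lat_ms`, `p_ms`, `phi_rad`,
#'   `used_second_peak`, `amp_mv`, `prestim_amp_mv`, `partial`) and
#'   `summary` (amplitude, prestimulus amplitude, normalized amplitude,
#'   vector strength, mean phase, n_sweeps).
#' @export
measure_poststimulus_oscillation <- function(ss, offset_ms = NULL,
                                             min_sep_ms = 0.2, n_peaks = 7) {
  stopifnot(inherits(ss, "sweep_set"))
  if (is.null(offset_ms)) offset_ms <- ss$t_stim_off_ms
  if (is.na(offset_ms)) stop("stimulus offset time unknown")
  rate <- ss$sample_rate_khz
  n_sweeps <- ncol(ss$sweeps)
  rows <- vector("list", n_sweeps)
  for (i in seq_len(n_sweeps)) {
    m <- post_peak_measure(ss$sweeps[, i], rate, offset_ms,
                           n_peaks = n_peaks, min_sep_ms = min_sep_ms)
    pre <- if (!is.na(ss$t_stim_on_ms))
      prestim_amplitude(ss$sweeps[, i], rate, ss$t_stim_on_ms, min_sep_ms)
    else NA_real_
    rows[[i]] <- data.frame(sweep = i, lat_ms = m$lat_ms, p_ms = m$p_ms,
                            phi_rad = m$phi_rad,
                            used_second_peak = m$used_second_peak,
                            amp_mv = m$amplitude_mv, prestim_amp_mv = pre,
                            partial = m$partial)
  }
  per_sweep <- do.call(rbind, rows)
  vs <- vector_strength(per_sweep$phi_rad)
  amp <- mean(per_sweep$amp_mv, na.rm = TRUE)
  pre <- mean(per_sweep$prestim_amp_mv, na.rm = TRUE)
  list(per_sweep = per_sweep,
       summary = list(amplitude_mv = amp, prestim_amplitude_mv = pre,
                      normalized_amplitude = amp / pre,
                      vector_strength = vs$r, mean_phase_rad = vs$mean_angle,
                      n_sweeps = n_sweeps))
}

#' Polarity-pair reset measurement from averaged traces
#'
#' Averages the sweeps of each polarity first, then measures the first
#' poststimulus peak latency and period on each averaged trace.
#'
#' @param pos,neg [sweep_set()]s for positive- and negative-polarity
#'   presentations of the same stimulus.
#' @param min_sep_ms extremum separation for peak detection.
#' @return object of class `polarity_pair`: `lat_P_ms`, `p_P_ms`,
#'   `lat_N_ms`, `p_N_ms`.
#' @export
measure_polarity_pair <- function(pos, neg, min_sep_ms = 0.2) {
  stopifnot(inherits(pos, "sweep_set"), inherits(neg, "sweep_set"))
  if (pos$stimulus$polarity <= 0 || neg$stimulus$polarity >= 0)
    stop("pos must be positive polarity and neg negative polarity")
  mp <- post_peak_measure(avg_trace(pos), pos$sample_rate_khz,
                          pos$t_stim_off_ms, min_sep_ms = min_sep_ms)
  mn <- post_peak_measure(avg_trace(neg), neg$sample_rate_khz,
                          neg$t_stim_off_ms, min_sep_ms = min_sep_ms)
  polarity_pair(lat_P_ms = mp$lat_ms, p_P_ms = mp$p_ms,
                lat_N_ms = mn$lat_ms, p_N_ms = mn$p_ms)
}

#' @rdname measure_polarity_pair
#' @param lat_P_ms,p_P_ms,lat_N_ms,p_N_ms latencies and first periods (ms)
#'   for the positive- and negative-polarity responses.
#' @export
polarity_pair <- function(lat_P_ms, p_P_ms, lat_N_ms, p_N_ms) {
  if (p_P_ms <= 0 || p_N_ms <= 0) stop("periods must be > 0")
  structure(list(lat_P_ms = lat_P_ms, p_P_ms = p_P_ms,
                 lat_N_ms = lat_N_ms, p_N_ms = p_N_ms),
            class = "polarity_pair")
}

#' Phase difference between opposite-polarity resets
#'
#' \deqn{\Delta\phi = \frac{lat_N - lat_P}{(p_N + p_P)/2} \times 360^\circ}
#'
#' @param pair a [polarity_pair()].
#' @return list with `raw_deg` and `deg` (reduced to `(-180, 180]`).
#' @export
delta_phase <- function(pair) {
  stopifnot(inherits(pair, "polarity_pair"))
  raw <- (pair$lat_N_ms - pair$lat_P_ms) /
    ((pair$p_N_ms + pair$p_P_ms) / 2) * 360
  red <- raw %% 360
  if (red > 180) red <- red - 360
  list(raw_deg = raw, deg = red)
}

#' Oscillation-timing difference between opposite polarities
#'
#' For pulse durations exceeding the receptors' intrinsic oscillation period
#' (> 0.5 ms), the average first-peak time after the negative pulse's offset
#' minus the average first-peak time after the positive pulse's onset. For
#' durations <= 0.5 ms, the difference of the average post-offset first-peak
#' times. Averaging across sweeps precedes differencing.
#'
#' @param pos,neg opposite-polarity [sweep_set()]s of matched duration.
#' @param min_sep_ms extremum separation.
#' @return timing difference in ms (negative minus positive).
#' @export
oscillation_timing_difference <- function(pos, neg, min_sep_ms = 0.2) {
  stopifnot(inherits(pos, "sweep_set"), inherits(neg, "sweep_set"))
  if (pos$stimulus$polarity <= 0 || neg$stimulus$polarity >= 0)
    stop("polarity mismatch: need one positive and one negative sweep set")
  dur <- pos$stimulus$duration_ms
  if (!isTRUE(all.equal(dur, neg$stimulus$duration_ms)))
    stop("pulse durations differ between polarities")
  rate <- pos$sample_rate_khz
  if (dur > 0.5) {
    tp <- post_peak_measure(avg_trace(pos), rate, pos$t_stim_on_ms,
                            min_sep_ms = min_sep_ms)
    tn <- post_peak_measure(avg_trace(neg), rate, neg$t_stim_off_ms,
                            min_sep_ms = min_sep_ms)
    t_pos <- pos$t_stim_on_ms + tp$lat_ms
    t_neg <- neg$t_stim_off_ms + tn$lat_ms
  } else {
    tp <- post_peak_measure(avg_trace(pos), rate, pos$t_stim_off_ms,
                            min_sep_ms = min_sep_ms)
    tn <- post_peak_measure(avg_trace(neg), rate, neg$t_stim_off_ms,
                            min_sep_ms = min_sep_ms)
    t_pos <- pos$t_stim_off_ms + tp$lat_ms
    t_neg <- neg$t_stim_off_ms + tn$lat_ms
  }
  t_neg - t_pos
}

#' Interoscillation interval from single-pulse and pulse-pair responses
#'
#' Measured on across-sweep averaged traces: the interval between the
#' designated first poststimulus peak evoked by the single pulse and the one
#' evoked by the second pulse of the pair (equivalent to the interval
#' between the peaks following each pulse of the pair, but immune to the
#' artifact of the second pulse obscuring the first response).
#'
#' @param single [sweep_set()] for the single pulse.
#' @param pair [sweep_set()] for the pulse pair (same polarity, duration and
#'   intensity).
#' @param min_sep_ms extremum separation.
#' @return interval in ms.
#' @export
interoscillation_interval <- function(single, pair, min_sep_ms = 0.2) {
  stopifnot(inherits(single, "sweep_set"), inherits(pair, "sweep_set"))
  ssp <- single$stimulus; pp <- pair$stimulus
  if (pp$kind != "pulse_pair") stop("pair must hold a pulse_pair stimulus")
  if (ssp$polarity != pp$polarity || !isTRUE(all.equal(ssp$duration_ms, pp$duration_ms)))
    stop("single and pair must share polarity and pulse duration")
  if (!isTRUE(all.equal(single$t_stim_on_ms, pair$t_stim_on_ms)))
    stop("sweep sets must share stimulus onset alignment")
  rate <- single$sample_rate_khz
  off_single <- single$t_stim_off_ms
  off_second <- pair$pulse_edges$offset_ms[2]
  ms <- post_peak_measure(avg_trace(single), rate, off_single,
                          min_sep_ms = min_sep_ms)
  mp <- post_peak_measure(avg_trace(pair), rate, off_second,
                          min_sep_ms = min_sep_ms)
  (off_second + mp$lat_ms) - (off_single + ms$lat_ms)
}

#' Paired-pulse oscillation amplitude normalized to the single-pulse response
#'
#' The mean poststimulus oscillation amplitude following the second pulse of
#' the pair divided by the mean amplitude following a single 0.2-ms pulse of
#' the same polarity.
#'
#' @param pair pulse-pair [sweep_set()].
#' @param single_ref single-pulse reference [sweep_set()] (0.2 ms, same
#'   polarity).
#' @param min_sep_ms extremum separation.
#' @return unitless amplitude ratio.
#' @export
paired_pulse_normalized_amplitude <- function(pair, single_ref,
                                              min_sep_ms = 0.2) {
  stopifnot(inherits(pair, "sweep_set"), inherits(single_ref, "sweep_set"))
  if (single_ref$stimulus$kind != "square_pulse" ||
      !isTRUE(all.equal(single_ref$stimulus$duration_ms, 0.2)))
    stop("single_ref must be a single 0.2-ms square pulse")
  if (single_ref$stimulus$polarity != pair$stimulus$polarity)
    stop("single_ref polarity must match the pair")
  m_pair <- measure_poststimulus_oscillation(
    pair, offset_ms = pair$pulse_edges$offset_ms[2], min_sep_ms = min_sep_ms)
  m_single <- measure_poststimulus_oscillation(single_ref,
                                               min_sep_ms = min_sep_ms)
  ref <- m_single$summary$amplitude_mv
  if (!is.finite(ref) || ref == 0) stop("zero single-pulse reference amplitude")
  m_pair$summary$amplitude_mv / ref
}

#' Evoked amplitude enhancement vs pulse duration
#'
#' Per duration, the mean poststimulus oscillation amplitude divided by the
#' mean prestimulus amplitude; also reports the duration of the curve's
#' maximum.
#'
#' @param sweep_sets list of [sweep_set()]s from the same receptor and
#'   intensity, one per pulse duration.
#' @return list with `curve` (data.frame `duration_ms`,
#'   `normalized_amplitude`) and `best_duration_ms`.
#' @export
duration_series_amplitude <- function(sweep_sets) {
  rows <- lapply(sweep_sets, function(ss) {
    m <- measure_poststimulus_oscillation(ss)
    data.frame(duration_ms = ss$stimulus$duration_ms,
               normalized_amplitude = m$summary$normalized_amplitude)
  })
  curve <- do.call(rbind, rows)
  curve <- curve[order(curve$duration_ms), ]
  list(curve = curve,
       best_duration_ms = curve$duration_ms[which.max(curve$normalized_amplitude)])
}

#' Population sum of amplitude-normalized responses
#'
#' Each receptor's across-sweep averaged trace is divided by its first
#' poststimulus oscillation amplitude (evoked definition), then the
#' normalized traces are summed sample-wise. Receptors with zero or
#' unmeasurable normalization amplitude are excluded with a warning.
#'
#' @param sweep_sets list of [sweep_set()]s, one per receptor, aligned to a
#'   common stimulus time.
#' @return list: `sum_trace`, `time_ms`, `n_used`, `excluded`,
#'   `t_stim_on_ms`, `t_stim_off_ms`, `sample_rate_khz`.
#' @export
population_sum <- function(sweep_sets) {
  if (length(sweep_sets) < 2) stop("need at least 2 receptors")
  rate <- sweep_sets[[1]]$sample_rate_khz
  n <- nrow(sweep_sets[[1]]$sweeps)
  acc <- numeric(n)
  used <- 0L; excluded <- integer(0)
  for (i in seq_along(sweep_sets)) {
    ss <- sweep_sets[[i]]
    tr <- avg_trace(ss)
    amp <- tryCatch(
      measure_poststimulus_oscillation(ss)$summary$amplitude_mv,
      error = function(e) NA_real_)
    if (!is.finite(amp) || amp == 0) {
      warning(sprintf("receptor %d excluded: zero normalization amplitude", i))
      excluded <- c(excluded, i)
      next
    }
    acc <- acc + tr / amp
    used <- used + 1L
  }
  list(sum_trace = acc, time_ms = (seq_len(n) - 1) / rate, n_used = used,
       excluded = excluded, t_stim_on_ms = sweep_sets[[1]]$t_stim_on_ms,
       t_stim_off_ms = sweep_sets[[1]]$t_stim_off_ms, sample_rate_khz = rate)
}

# threshold-crossing spike peak times on one trace
detect_spike_peaks <- function(trace, sample_rate_khz, threshold_mv,
                               min_sep_ms = 0.3) {
  idx <- local_maxima(trace, msamples(min_sep_ms, sample_rate_khz))
  idx <- idx[trace[idx] > threshold_mv]
  (idx - 1) / sample_rate_khz
}

#' Spike detection and response statistics for a sweep set
#'
#' Spikes are the peak voltages crossing `threshold_mv`. The response window
#' starts at the polarity-appropriate stimulus edge (onset for positive,
#' offset for negative polarity) and extends `window_ms` beyond it.
#'
#' @param ss a [sweep_set()] from a spiking receptor.
#' @param threshold_mv detection threshold; must exceed the baseline noise
#'   floor.
#' @param window_ms response-window length after the edge (default 5 ms).
#' @return list: `spike_times` (per sweep), `probability`,
#'   `mean_first_spike_ms` (absolute sweep time; NA and flagged if no
#'   spikes), `mean_latency_ms` (relative to the edge), `edge_ms`.
#' @export
measure_spike_response <- function(ss, threshold_mv, window_ms = 5) {
  stopifnot(inherits(ss, "sweep_set"))
  rate <- ss$sample_rate_khz
  pre_end <- if (!is.na(ss$t_stim_on_ms)) ss$t_stim_on_ms else
    nrow(ss$sweeps) / rate
  pre_idx <- seq_len(max(2, msamples(pre_end, rate) - 1))
  noise_floor <- stats::mad(ss$sweeps[pre_idx, 1], constant = 1.4826)
  if (threshold_mv <= 3 * noise_floor)
    stop(sprintf("threshold (%.3g mV) not above noise floor (3 x %.3g mV)",
                 threshold_mv, noise_floor))
  pol <- if (!is.null(ss$stimulus)) ss$stimulus$polarity else 1L
  edge <- if (pol > 0) ss$t_stim_on_ms else ss$t_stim_off_ms
  n_sweeps <- ncol(ss$sweeps)
  spikes <- lapply(seq_len(n_sweeps), function(i)
    detect_spike_peaks(ss$sweeps[, i], rate, threshold_mv))
  first <- vapply(spikes, function(tt) {
    tt <- tt[tt >= edge & tt <= edge + window_ms]
    if (length(tt)) tt[1] else NA_real_
  }, numeric(1))
  prob <- mean(!is.na(first))
  mfs <- if (any(!is.na(first))) mean(first, na.rm = TRUE) else NA_real_
  list(spike_times = spikes, probability = prob,
       mean_first_spike_ms = mfs,
       mean_latency_ms = if (is.na(mfs)) NA_real_ else mfs - edge,
       edge_ms = edge, no_response = is.na(mfs))
}

#' Spike-timing difference between opposite-polarity responses
#'
#' The mean first-spike time after the positive pulse's onset and after the
#' negative pulse's offset are averaged within each polarity first; the
#' difference (negative minus positive, on the common sweep clock) equals
#' the pulse duration in a receptor responding to inward current transients.
#'
#' @param pos,neg opposite-polarity [sweep_set()]s of matched duration and
#'   intensity.
#' @param threshold_mv spike threshold.
#' @param window_ms response window.
#' @return timing difference in ms.
#' @export
spike_timing_difference <- function(pos, neg, threshold_mv, window_ms = 5) {
  if (pos$stimulus$polarity <= 0 || neg$stimulus$polarity >= 0)
    stop("polarity mismatch")
  rp <- measure_spike_response(pos, threshold_mv, window_ms)
  rn <- measure_spike_response(neg, threshold_mv, window_ms)
  if (rp$no_response && rn$no_response)
    stop("no spikes detected in either sweep set")
  rn$mean_first_spike_ms - rp$mean_first_spike_ms
}

#' Paired-pulse spiking: probability of responding to both pulses and the
#' interspike interval
#'
#' Spikes are assigned to each pulse within a window after its
#' polarity-appropriate edge (onset for positive, offset for negative
#' polarity). The interval is measured between the edge-locked spikes when
#' both are present.
#'
#' @param ss pulse-pair [sweep_set()] from a spiking receptor.
#' @param threshold_mv spike threshold.
#' @param window_ms per-pulse assignment window (default `min(ipi, 5)` ms).
#' @return list: `both_pulse_probability`, `mean_interval_ms` (NA when no
#'   sweep has both spikes), `intervals_ms`.
#' @export
pair_interspike_interval <- function(ss, threshold_mv, window_ms = NULL) {
  stopifnot(inherits(ss, "sweep_set"))
  if (ss$stimulus$kind != "pulse_pair") stop("needs a pulse_pair stimulus")
  rate <- ss$sample_rate_khz
  pol <- ss$stimulus$polarity
  edges <- if (pol > 0) ss$pulse_edges$onset_ms else ss$pulse_edges$offset_ms
  ipi <- ss$stimulus$ipi_ms
  if (is.null(window_ms)) window_ms <- min(ipi, 5)
  n_sweeps <- ncol(ss$sweeps)
  intervals <- numeric(0)
  both <- logical(n_sweeps)
  for (i in seq_len(n_sweeps)) {
    tt <- detect_spike_peaks(ss$sweeps[, i], rate, threshold_mv)
    s1 <- tt[tt >= edges[1] & tt < edges[1] + window_ms]
    s2 <- tt[tt >= edges[2] & tt < edges[2] + window_ms]
    if (length(s1) && length(s2)) {
      both[i] <- TRUE
      intervals <- c(intervals, s2[1] - s1[1])
    }
  }
  list(both_pulse_probability = mean(both),
       mean_interval_ms = if (length(intervals)) mean(intervals) else NA_real_,
       intervals_ms = intervals)
}
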