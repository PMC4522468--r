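# EOD event detection, IPI statistics, and behavioral playback
# quantification via spike-density functions.

#' Detect EOD events by rectified threshold crossing
#'
#' Events are rising crossings of `threshold_mv` by the rectified
#' (absolute-value) trace; crossings within `dead_time_ms` of the previous
#' event are suppressed so multiphasic waveforms are not double counted.
#'
#' @param trace recorded trace (mV).
#' @param sample_rate_khz sample rate.
#' @param threshold_mv detection threshold (default 0.6 mV).
#' @param dead_time_ms suppression window after each event (default
#'   0.25 ms: short enough to pass sub-ms group IPIs).
#' @return an [event_train()].
#' @export
detect_eod_events <- function(trace, sample_rate_khz, threshold_mv = 0.6,
                              dead_time_ms = 0.25) {
  if (threshold_mv <= 0) stop("threshold_mv must be > 0")
  r <- abs(trace)
  if (mean(r >= 0.999 * max(r)) > 0.05)
    warning("trace appears saturated; event times may be unreliable")
  above <- r > threshold_mv
  rising <- which(above & !c(FALSE, above[-length(above)]))
  tt <- (rising - 1) / sample_rate_khz
  if (length(tt) > 1) {
    keep <- numeric(0); last <- -Inf
    for (t in tt) {
      if (t - last >= dead_time_ms) { keep <- c(keep, t); last <- t }
    }
    tt <- keep
  }
  event_train(tt, length(trace) / sample_rate_khz, label = "eod")
}

#' Interpulse-interval histogram
#'
#' @param events an [event_train()] (>= 2 events for a nonempty histogram).
#' @param breaks_ms bin edges in ms (default log-spaced 0.1-1000 ms).
#' @return list: `counts`, `breaks_ms`, `ipis_ms`, `fraction_below_1ms`,
#'   `n_events`.
#' @export
ipi_histogram <- function(events,
                          breaks_ms = 10^seq(-1, 3, length.out = 41)) {
  ipis <- interspike_intervals(events)
  if (length(ipis) == 0) {
    return(list(counts = integer(length(breaks_ms) - 1), breaks_ms = breaks_ms,
                ipis_ms = numeric(0), fraction_below_1ms = NA_real_,
                n_events = length(if (inherits(events, "event_train"))
                  events$times_ms else events)))
  }
  br <- breaks_ms
  if (min(ipis) < br[1]) br[1] <- min(ipis)
  if (max(ipis) > br[length(br)]) br[length(br)] <- max(ipis)
  h <- hist(ipis, breaks = br, plot = FALSE)
  list(counts = h$counts, breaks_ms = br, ipis_ms = ipis,
       fraction_below_1ms = mean(ipis < 1),
       n_events = length(ipis) + 1L)
}

#' Spike-density function
#'
#' Sum of unit-area Gaussian kernels (sigma = `width_ms`) centred on the
#' event times, evaluated on a regular grid, in events/s.
#'
#' @param events an [event_train()] or numeric times (ms).
#' @param width_ms Gaussian sigma (default 200 ms).
#' @param step_ms grid step (default 1 ms).
#' @param t_range_ms optional two-element grid range (default the train's
#'   `[0, duration]`).
#' @return list of class `sdf`: `time_s`, `rate_hz`, `kernel_width_ms`.
#' @export
spike_density_function <- function(events, width_ms = 200, step_ms = 1,
                                   t_range_ms = NULL) {
  if (width_ms <= 0) stop("width_ms must be > 0")
  tt <- if (inherits(events, "event_train")) events$times_ms else as.numeric(events)
  if (is.null(t_range_ms)) {
    t_range_ms <- c(0, if (inherits(events, "event_train")) events$duration_ms
                    else max(tt, 0))
  }
  grid <- seq(t_range_ms[1], t_range_ms[2], by = step_ms)
  rate <- numeric(length(grid))
  if (length(tt) > 0) {
    # evaluate each kernel only within +/- 6 sigma
    for (t0 in tt) {
      sel <- which(abs(grid - t0) <= 6 * width_ms)
      if (length(sel))
        rate[sel] <- rate[sel] +
          exp(-((grid[sel] - t0)^2) / (2 * width_ms^2)) /
          (sqrt(2 * pi) * width_ms)
    }
  }
  structure(list(time_s = grid / 1000, rate_hz = rate * 1000,
                 kernel_width_ms = width_ms),
            class = "sdf")
}

#' Baseline and extrema of stimulus-evoked EOD-rate modulation
#'
#' SDFs are averaged across stimulus repetitions first. The baseline is the
#' mean rate between 4.8 s and 0.2 s before stimulus onset; the maximum
#' increase and decrease are taken relative to the baseline within a window
#' from 0.2 s before onset to 1.2 s after stimulus offset.
#'
#' @param sdfs list of `sdf` objects (one per repetition) on a common grid,
#'   or a single `sdf`.
#' @param t_on_s,t_off_s stimulus onset/offset in seconds (grid time).
#' @param baseline_window_s window before onset (default `c(4.8, 0.2)` s).
#' @param response_window_s `c(before_onset, after_offset)` extension
#'   (default `c(0.2, 1.2)` s).
#' @return list of class `sdf_result`: `time_s`, `rate_hz` (averaged),
#'   `baseline_hz`, `max_increase_hz`, `max_decrease_hz`, windows used.
#' @export
behavioral_response_metrics <- function(sdfs, t_on_s, t_off_s,
                                        baseline_window_s = c(4.8, 0.2),
                                        response_window_s = c(0.2, 1.2)) {
  if (inherits(sdfs, "sdf")) sdfs <- list(sdfs)
  tg <- sdfs[[1]]$time_s
  for (s in sdfs) {
    if (length(s$time_s) != length(tg) || any(abs(s$time_s - tg) > 1e-9))
      stop("SDFs must share a common time grid")
  }
  if (t_on_s - tg[1] < baseline_window_s[1])
    stop(sprintf("insufficient prestimulus span: need >= %.1f s before onset",
                 baseline_window_s[1]))
  rate <- Reduce(`+`, lapply(sdfs, `[[`, "rate_hz")) / length(sdfs)
  bl_sel <- tg >= t_on_s - baseline_window_s[1] &
    tg <= t_on_s - baseline_window_s[2]
  baseline <- mean(rate[bl_sel])
  rs_sel <- tg >= t_on_s - response_window_s[1] &
    tg <= t_off_s + response_window_s[2]
  rr <- rate[rs_sel]
  structure(list(time_s = tg, rate_hz = rate, baseline_hz = baseline,
                 max_increase_hz = max(rr - baseline),
                 max_decrease_hz = max(baseline - rr),
                 baseline_window_s = baseline_window_s,
                 response_window_s = response_window_s,
                 t_on_s = t_on_s, t_off_s = t_off_s),
            class = "sdf_result")
}

#' Normalized behavioral response index
#'
#' `(r_ipi - r_single) / (r_ipi + r_single)`: the response to the IPI train
#' relative to the single-pulse response, bounded in `[-1, 1]` for
#' nonnegative inputs.
#'
#' @param r_ipi,r_single response magnitudes (same units).
#' @return unitless index.
#' @export
normalized_response <- function(r_ipi, r_single) {
  s <- r_ipi + r_single
  if (any(s == 0)) stop("zero denominator: r_ipi + r_single = 0")
  (r_ipi - r_single) / s
}

#' Species x IPI repeated-measures ANOVA
#'
#' Two-factor repeated-measures analysis (species between subjects, IPI
#' within) of normalized behavioral responses, delegated to `stats::aov`
#' with an error stratum for fish. Reports the species-by-IPI interaction.
#'
#' @param data data.frame with columns `fish` (subject id), `species`,
#'   `ipi_ms`, `response`. The IPI factor must be balanced within fish.
#' @return list: `table` (the within-stratum ANOVA table), `interaction_F`,
#'   `interaction_df`, `interaction_p`.
#' @export
species_comparison <- function(data) {
  need <- c("fish", "species", "ipi_ms", "response")
  if (!all(need %in% names(data))) stop("data needs columns: ",
                                        paste(need, collapse = ", "))
  data$fish <- factor(data$fish)
  data$species <- factor(data$species)
  data$ipi <- factor(data$ipi_ms)
  counts <- table(data$fish, data$ipi)
  if (length(unique(as.vector(counts))) != 1 || any(counts == 0))
    stop("unbalanced design: every fish needs every IPI equally often")
  fit <- aov(response ~ species * ipi + Error(fish / ipi), data = data)
  within <- summary(fit)[["Error: fish:ipi"]][[1]]
  ix <- grep("species:ipi", rownames(within))
  list(table = within,
       interaction_F = within[ix, "F value"],
       interaction_df = c(within[ix, "Df"],
                          within[nrow(within), "Df"]),
       interaction_p = within[ix, "Pr(>F)"])
}
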