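# Event trains (spikes or EODs) and generators for single-fish / group
# discharge sequences and behavioral playback sessions.

#' Ordered event-time series
#'
#' @param times_ms strictly increasing event times within `[0, duration_ms]`.
#' @param duration_ms recording duration.
#' @param label free-text label.
#' @return object of class `event_train`.
#' @export
event_train <- function(times_ms, duration_ms, label = "") {
  times_ms <- as.numeric(times_ms)
  if (length(times_ms) > 1 && any(diff(times_ms) <= 0))
    stop("event times must be strictly increasing")
  if (length(times_ms) > 0 &&
      (min(times_ms) < 0 || max(times_ms) > duration_ms))
    stop("event times must lie within [0, duration_ms]")
  structure(list(times_ms = times_ms, duration_ms = duration_ms,
                 label = label), class = "event_train")
}

#' @export
print.event_train <- function(x, ...) {
  cat(sprintf("<event_train> %d events over %.1f ms%s\n",
              length(x$times_ms), x$duration_ms,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Simulate EOD trains from one or several independently signaling fish
#'
#' Each fish is an independent renewal process whose interpulse intervals
#' follow a shifted gamma distribution, `IPI = min_ipi_ms + Gamma(shape,
#' scale)`, so a single fish never produces an IPI below its physiological
#' minimum (~8 ms), while the pooled train from a group contains much shorter
#' intervals from chance coincidences across fish.
#'
#' @param n_fish number of fish.
#' @param duration_ms recording duration.
#' @param min_ipi_ms minimum per-fish IPI (default 8 ms).
#' @param shape,scale gamma parameters of the IPI excess over the minimum
#'   (defaults give a mean per-fish IPI of 128 ms).
#' @param seed integer RNG seed.
#' @return list with `per_fish` (list of [event_train()]) and `pooled`
#'   (sorted merge across fish).
#' @export
generate_eod_population_train <- function(n_fish, duration_ms,
                                          min_ipi_ms = 8, shape = 2,
                                          scale = 60, seed = 1) {
  if (n_fish < 1) stop("n_fish must be >= 1")
  if (min_ipi_ms <= 0) stop("min_ipi_ms must be > 0")
  set.seed(seed)
  mean_ipi <- min_ipi_ms + shape * scale
  per_fish <- vector("list", n_fish)
  for (f in seq_len(n_fish)) {
    m <- ceiling(duration_ms / mean_ipi * 1.5) + 20
    tt <- runif(1, 0, mean_ipi) +
      cumsum(min_ipi_ms + rgamma(m, shape = shape, scale = scale))
    while (length(tt) > 0 && tt[length(tt)] < duration_ms) {
      tt <- c(tt, tt[length(tt)] +
                cumsum(min_ipi_ms + rgamma(m, shape = shape, scale = scale)))
    }
    tt <- tt[tt < duration_ms]
    per_fish[[f]] <- event_train(tt, duration_ms, label = sprintf("fish%02d", f))
  }
  pooled_t <- sort(unlist(lapply(per_fish, `[[`, "times_ms")))
  # pooled events from different fish can coincide on rare occasions; keep
  # strict ordering by nudging exact ties by a nanosecond
  if (length(pooled_t) > 1) {
    d <- diff(pooled_t)
    while (any(d <= 0)) {
      pooled_t[which(d <= 0) + 1L] <- pooled_t[which(d <= 0) + 1L] + 1e-6
      pooled_t <- sort(pooled_t)
      d <- diff(pooled_t)
    }
  }
  list(per_fish = per_fish,
       pooled = event_train(pooled_t, duration_ms, label = "pooled"))
}

# unit-peak alpha kernel, zero for t < 0
alpha_kernel <- function(t, tau_ms) {
  k <- (t / tau_ms) * exp(1 - t / tau_ms)
  k[t < 0] <- 0
  k
}

#' Simulate a behavioral EOD-rate session
#'
#' EOD times are drawn from an inhomogeneous renewal process whose rate is
#' `baseline + inc_amp * K+(t - t_stim) - dec_amp * K-(t - t_stim)`, floored
#' at zero. Kernels are unit-peak alpha functions (`shape = "alpha"`) or a
#' unit-height box of length `step_dur_s` (`shape = "step"`).
#'
#' @param baseline_rate_hz baseline EOD rate (events/s, > 0).
#' @param inc_amp_hz,dec_amp_hz peak rate increase / decrease (events/s).
#' @param stimulus_times_s stimulus onset times within the session (s).
#' @param duration_s session duration (s).
#' @param tau_inc_s,tau_dec_s alpha-kernel time constants (s).
#' @param delay_dec_s delay of the suppression kernel after onset (s).
#' @param shape `"alpha"` or `"step"`.
#' @param step_dur_s box length when `shape = "step"`.
#' @param regularity gamma shape of the renewal process (1 = Poisson).
#' @param seed integer RNG seed.
#' @return an [event_train()] (times in ms).
#' @export
simulate_behavioral_session <- function(baseline_rate_hz, inc_amp_hz = 0,
                                        dec_amp_hz = 0, stimulus_times_s = 5,
                                        duration_s = 12, tau_inc_s = 0.3,
                                        tau_dec_s = 0.5, delay_dec_s = 0,
                                        shape = c("alpha", "step"),
                                        step_dur_s = 1, regularity = 4,
                                        seed = 1) {
  if (baseline_rate_hz <= 0) stop("baseline_rate_hz must be > 0")
  shape <- match.arg(shape)
  set.seed(seed)
  dt <- 0.001
  tg <- seq(0, duration_s, by = dt)
  rate <- rep(baseline_rate_hz, length(tg))
  for (ts in stimulus_times_s) {
    if (shape == "alpha") {
      rate <- rate + inc_amp_hz * alpha_kernel(tg - ts, tau_inc_s) -
        dec_amp_hz * alpha_kernel(tg - ts - delay_dec_s, tau_dec_s)
    } else {
      box <- as.numeric(tg >= ts & tg < ts + step_dur_s)
      boxd <- as.numeric(tg >= ts + delay_dec_s &
                           tg < ts + delay_dec_s + step_dur_s)
      rate <- rate + inc_amp_hz * box - dec_amp_hz * boxd
    }
  }
  rate <- pmax(rate, 0)
  # time rescaling: events where the integrated rate crosses gamma-renewal
  # increments (shape = regularity, unit mean)
  L <- cumsum(rate) * dt
  events_s <- numeric(0)
  target <- rgamma(1, shape = regularity, rate = regularity)
  total <- L[length(L)]
  draws <- rgamma(ceiling(total) + 50, shape = regularity, rate = regularity)
  targets <- cumsum(c(target, draws))
  targets <- targets[targets < total]
  if (length(targets) > 0)
    events_s <- approx(L, tg, xout = targets, ties = "ordered")$y
  events_s <- events_s[!is.na(events_s)]
  events_s <- sort(unique(events_s))
  event_train(events_s * 1000, duration_s * 1000, label = "behavior")
}
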