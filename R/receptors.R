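# Simulated receptors. Oscillating receptors are forced, noisy
# Stuart-Landau limit cycles integrated in C++; spiking receptors emit
# single time-locked spikes to inward current transients (positive-pulse
# onsets and negative-pulse offsets) with a refractory period.

#' Generative parameters of a simulated receptor
#'
#' @param mode `"oscillating"` or `"spiking"`.
#' @param f0_khz intrinsic oscillation frequency (oscillating mode; must lie
#'   in (0.5, 3.5] kHz) or resonant frequency of the spiking front end.
#' @param mu limit-cycle growth rate (1/ms); the noise-free oscillation
#'   radius is `sqrt(mu)`.
#' @param kappa stimulus coupling gain, mV per nA*ms.
#' @param noise_sd process noise intensity, mV/sqrt(ms).
#' @param spont_amp_mv spontaneous peak-to-trough oscillation amplitude.
#' @param latency_ms spike latency after a qualifying transient (spiking).
#' @param refractory_ms absolute refractory period (spiking, > 0).
#' @param threshold_charge_nams transient charge at half-maximal spike
#'   probability (nA*ms).
#' @param jitter_sd_ms Gaussian spike-time jitter (0 for deterministic).
#' @param spont_rate_hz spontaneous spike rate (renewal process).
#' @param tau_rec_ms recovery time constant of the oscillating receptor's
#'   coupling depletion (ms). After a strong pulse the stimulus coupling is
#'   transiently depleted, so a second pulse arriving within ~1 ms cannot
#'   re-reset the phase (the interoscillation interval plateaus near the
#'   intrinsic period for submillisecond IPIs).
#' @param q_dep_nams stimulus charge that depletes the coupling by ~1/e
#'   (nA*ms); `Inf` disables depletion.
#' @param dep_threshold_na intensity below which the coupling does not
#'   deplete (nA); weak stimuli probe the intact resonance.
#' @param q_factor sharpness of the spiking front end's resonance.
#' @param meas_noise_mv additive measurement noise on the recorded trace.
#' @param spike_amp_mv amplitude of the cosmetic spike template.
#' @return object of class `receptor_params`.
#' @export
receptor_params <- function(mode = c("oscillating", "spiking"),
                            f0_khz = 2.0, mu = 1.0, kappa = 1.0,
                            noise_sd = 0.02, spont_amp_mv = 1.0,
                            latency_ms = 0.3, refractory_ms = 1.0,
                            threshold_charge_nams = 0.5, jitter_sd_ms = 0,
                            spont_rate_hz = 0, tau_rec_ms = 1.5,
                            q_dep_nams = 0.3, dep_threshold_na = 2,
                            q_factor = 2,
                            meas_noise_mv = 0.005, spike_amp_mv = 2.0) {
  mode <- match.arg(mode)
  if (mode == "oscillating") {
    if (!is.numeric(f0_khz) || f0_khz <= 0.5 || f0_khz > 3.5)
      stop("f0_khz must lie in (0.5, 3.5] kHz for oscillating receptors")
    if (mu <= 0) stop("mu must be > 0")
  } else {
    if (refractory_ms <= 0) stop("refractory_ms must be > 0")
    if (f0_khz <= 0) stop("f0_khz must be > 0")
  }
  if (noise_sd < 0 || jitter_sd_ms < 0) stop("noise/jitter must be >= 0")
  structure(list(mode = mode, f0_khz = f0_khz, mu = mu, kappa = kappa,
                 noise_sd = noise_sd, spont_amp_mv = spont_amp_mv,
                 latency_ms = latency_ms, refractory_ms = refractory_ms,
                 threshold_charge_nams = threshold_charge_nams,
                 jitter_sd_ms = jitter_sd_ms, spont_rate_hz = spont_rate_hz,
                 tau_rec_ms = tau_rec_ms, q_dep_nams = q_dep_nams,
                 dep_threshold_na = dep_threshold_na, q_factor = q_factor, meas_noise_mv = meas_noise_mv,
                 spike_amp_mv = spike_amp_mv),
            class = "receptor_params")
}

#' Stimulus-aligned set of recorded sweeps
#'
#' @param sweeps numeric matrix, samples x sweeps (mV).
#' @param sample_rate_khz recording sample rate.
#' @param stimulus the [stimulus_spec()] that evoked the sweeps (or NULL).
#' @param t_stim_on_ms,t_stim_off_ms stimulus on/off times within the sweep.
#' @param seed RNG seed used to generate the sweeps.
#' @param events optional list (one entry per sweep) of exact event times.
#' @param pulse_edges optional data.frame of per-pulse `onset_ms`/`offset_ms`.
#' @return object of class `sweep_set`.
#' @export
sweep_set <- function(sweeps, sample_rate_khz, stimulus = NULL,
                      t_stim_on_ms = NA_real_, t_stim_off_ms = NA_real_,
                      seed = NA_integer_, events = NULL, pulse_edges = NULL) {
  sweeps <- as.matrix(sweeps)
  if (!is.na(t_stim_on_ms) && !is.na(t_stim_off_ms) &&
      t_stim_off_ms < t_stim_on_ms)
    stop("t_stim_off_ms must be >= t_stim_on_ms")
  structure(list(sweeps = sweeps, sample_rate_khz = sample_rate_khz,
                 stimulus = stimulus, t_stim_on_ms = t_stim_on_ms,
                 t_stim_off_ms = t_stim_off_ms, seed = seed,
                 events = events, pulse_edges = pulse_edges),
            class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf("<sweep_set> %d sweeps x %d samples @ %g kHz (%.2f ms)\n",
              ncol(x$sweeps), nrow(x$sweeps), x$sample_rate_khz,
              nrow(x$sweeps) / x$sample_rate_khz))
  if (!is.null(x$stimulus)) print(x$stimulus)
  invisible(x)
}

sweep_times_ms <- function(ss) (seq_len(nrow(ss$sweeps)) - 1) / ss$sample_rate_khz

# Render a stimulus_spec to a wave at its own generation rate.
render_stimulus <- function(spec) {
  switch(spec$kind,
    square_pulse = ,
    pulse_pair = make_pulse_stimulus(spec),
    bipolar_sine = make_bipolar_sine(duration_ms = spec$duration_ms,
                                     polarity = spec$polarity,
                                     intensity_na = spec$intensity_na,
                                     sample_rate_khz = spec$sample_rate_khz),
    sine_burst = make_sine_burst(spec),
    eod = wave(spec$polarity * spec$intensity_na *
                 spec$eod_wave$samples / max(abs(spec$eod_wave$samples)),
               spec$eod_wave$sample_rate_khz),
    eod_train = {
      tr <- make_eod_train(spec$eod_wave, spec$ipi_ms, spec$n_pulses)
      wave(spec$polarity * spec$intensity_na * tr$samples /
             max(abs(tr$samples)), tr$sample_rate_khz)
    },
    stop("unsupported stimulus kind"))
}

# per-pulse onset/offset table for a spec placed at t_on
stimulus_edges <- function(spec, t_on_ms) {
  if (is.null(spec)) return(NULL)
  if (spec$kind == "square_pulse") {
    data.frame(onset_ms = t_on_ms, offset_ms = t_on_ms + spec$duration_ms)
  } else if (spec$kind == "pulse_pair") {
    data.frame(onset_ms = t_on_ms + c(0, spec$ipi_ms),
               offset_ms = t_on_ms + c(0, spec$ipi_ms) + spec$duration_ms)
  } else {
    dur <- stimulus_support_ms(spec)
    data.frame(onset_ms = t_on_ms, offset_ms = t_on_ms + dur)
  }
}

stimulus_support_ms <- function(spec) {
  wv <- render_stimulus(spec)
  length(wv$samples) / wv$sample_rate_khz
}

#' Simulate an oscillating receptor
#'
#' Integrates a stochastically perturbed, additively forced Stuart-Landau
#' oscillator per sweep and records `V = gain * Re(z)` plus measurement
#' noise. Sufficiently strong pulses entrain the oscillation phase (a phase
#' reset); opposite stimulus polarity flips the forcing sign and hence the
#' reset phase by ~180 degrees.
#'
#' @param params [receptor_params()] with `mode = "oscillating"`.
#' @param stimulus a [stimulus_spec()] or NULL for spontaneous activity.
#' @param n_sweeps number of stimulus repetitions.
#' @param seed integer RNG seed (required; simulations are reproducible).
#' @param total_ms sweep duration (default: stimulus span + 8 ms, min 10 ms).
#' @param t_on_ms stimulus onset within the sweep (default 3 ms).
#' @param sample_rate_khz recording rate (default 97.7 kHz).
#' @param resistive_gain,capacitive_gain residual artifact gains passed to
#'   [add_artifact()].
#' @return a [sweep_set()].
#' @export
simulate_oscillating_receptor <- function(params, stimulus = NULL,
                                          n_sweeps = 10, seed = 1,
                                          total_ms = NULL, t_on_ms = 3,
                                          sample_rate_khz = .REC_RATE_KHZ,
                                          resistive_gain = 0,
                                          capacitive_gain = 0) {
  stopifnot(inherits(params, "receptor_params"))
  if (params$mode != "oscillating") stop("params$mode must be 'oscillating'")
  if (params$f0_khz <= 0) stop("f0_khz must be positive")
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  stim_span <- if (is.null(stimulus)) 0 else stimulus_support_ms(stimulus)
  if (is.null(total_ms))
    total_ms <- max(10, t_on_ms + stim_span + 8)
  n <- msamples(total_ms, sample_rate_khz)
  dt <- 1 / sample_rate_khz
  gain <- params$spont_amp_mv / (2 * sqrt(params$mu))
  stim_samples <- numeric(n)
  if (!is.null(stimulus)) {
    wv <- render_stimulus(stimulus)
    stim_samples <- resample_to_sweep(wv, sample_rate_khz, n, t_on_ms)
  }
  if (is.finite(params$q_dep_nams) && any(stim_samples != 0)) {
    a <- .depletion_profile(stim_samples, dt, params$tau_rec_ms,
                            params$q_dep_nams, params$dep_threshold_na)
    stim_eff <- a * stim_samples
  } else stim_eff <- stim_samples
  force_z <- (params$kappa / gain) * stim_eff
  noise_amp <- (params$noise_sd / gain) * sqrt(dt)
  omega <- 2 * pi * params$f0_khz
  set.seed(seed)
  sweeps <- matrix(0, n, n_sweeps)
  for (i in seq_len(n_sweeps)) {
    phi0 <- runif(1, 0, 2 * pi)
    r0 <- sqrt(params$mu)
    zmat <- .sl_integrate(n, dt, params$mu, omega,
                          r0 * cos(phi0), r0 * sin(phi0),
                          force_z, rnorm(n), rnorm(n), noise_amp)
    v <- gain * zmat[, 1]
    if (params$meas_noise_mv > 0)
      v <- v + rnorm(n, sd = params$meas_noise_mv)
    if (resistive_gain != 0 || capacitive_gain != 0)
      v <- add_artifact(v, stim_samples, resistive_gain, capacitive_gain,
                        sample_rate_khz)
    sweeps[, i] <- v
  }
  sweep_set(sweeps, sample_rate_khz, stimulus,
            t_stim_on_ms = if (is.null(stimulus)) NA_real_ else t_on_ms,
            t_stim_off_ms = if (is.null(stimulus)) NA_real_ else
              t_on_ms + stim_span_effective(stimulus),
            seed = seed,
            pulse_edges = if (is.null(stimulus)) NULL else
              stimulus_edges(stimulus, t_on_ms))
}

# effective stimulus off time: end of the (last) pulse for pulse stimuli,
# end of rendered support otherwise
stim_span_effective <- function(spec) {
  if (spec$kind == "square_pulse") return(spec$duration_ms)
  if (spec$kind == "pulse_pair") return(spec$ipi_ms + spec$duration_ms)
  stimulus_support_ms(spec)
}

# biphasic 0.5-ms spike template, unit peak at offset 0
spike_template <- function(sample_rate_khz, amp_mv) {
  n <- max(5L, msamples(0.5, sample_rate_khz))
  t <- (seq_len(n) - 1) / (n - 1)
  w <- sin(2 * pi * t) * sin(pi * t)^2
  pk <- which.max(w)
  list(w = amp_mv * w / max(w), peak_offset = pk - 1L)
}

#' Simulate a spiking receptor
#'
#' Spiking receptors fire a single time-locked spike to inward current
#' transients, which occur at the onset of a positive-polarity square pulse
#' and at the offset of a negative-polarity pulse. A spike is emitted at
#' `transient + latency_ms + jitter` with probability given by a sigmoid of
#' the transient charge (intensity x min(duration, 0.1 ms) for pulse edges),
#' and suppressed within `refractory_ms` of the previous spike. Sine bursts
#' drive the receptor through a resonant gain centred on `f0_khz`, producing
#' one phase-locked spike candidate per stimulus cycle. Spontaneous spikes
#' arise from a gamma renewal process at `spont_rate_hz`.
#'
#' @inheritParams simulate_oscillating_receptor
#' @return a [sweep_set()] with exact spike times in `$events` and a
#'   cosmetic spike waveform written into the traces.
#' @export
simulate_spiking_receptor <- function(params, stimulus = NULL, n_sweeps = 10,
                                      seed = 1, total_ms = NULL, t_on_ms = 3,
                                      sample_rate_khz = .REC_RATE_KHZ) {
  stopifnot(inherits(params, "receptor_params"))
  if (params$mode != "spiking") stop("params$mode must be 'spiking'")
  if (params$refractory_ms <= 0) stop("refractory_ms must be > 0")
  stim_span <- if (is.null(stimulus)) 0 else stimulus_support_ms(stimulus)
  if (is.null(total_ms))
    total_ms <- max(10, t_on_ms + stim_span + 8)
  n <- msamples(total_ms, sample_rate_khz)
  tau_m <- 0.1  # ms, effective integration window of the transduction step
  # candidate transients: time and charge
  cands <- NULL
  if (!is.null(stimulus)) {
    if (stimulus$kind %in% c("square_pulse", "pulse_pair")) {
      edges <- stimulus_edges(stimulus, t_on_ms)
      q <- stimulus$intensity_na * min(stimulus$duration_ms, tau_m)
      tt <- if (stimulus$polarity > 0) edges$onset_ms else edges$offset_ms
      cands <- data.frame(time_ms = tt, charge = q)
    } else if (stimulus$kind == "sine_burst") {
      f <- stimulus$frequency_khz
      g <- 1 / sqrt(1 + params$q_factor^2 *
                      (f / params$f0_khz - params$f0_khz / f)^2)
      # one candidate per cycle at the inward-going phase
      per <- 1 / f
      tt <- seq(t_on_ms + per / 4, t_on_ms + stimulus$duration_ms, by = per)
      q <- stimulus$intensity_na * g * min(per / 2, tau_m)
      cands <- data.frame(time_ms = tt, charge = q)
    } else {
      # generic waveform: qualifying transients at strong positive jumps of
      # the rendered stimulus
      wv <- render_stimulus(stimulus)
      s <- resample_to_sweep(wv, sample_rate_khz, n, t_on_ms)
      ds <- diff(s)
      thr <- 0.5 * max(ds)
      if (is.finite(thr) && thr > 0) {
        idx <- which(ds > thr)
        idx <- idx[c(TRUE, diff(idx) > msamples(tau_m, sample_rate_khz))]
        cands <- data.frame(time_ms = idx / sample_rate_khz,
                            charge = ds[idx] / sample_rate_khz *
                          sample_rate_khz * tau_m)
      }
    }
  }
  slope <- 0.05 * max(params$threshold_charge_nams, 1e-9)
  set.seed(seed)
  tmpl <- spike_template(sample_rate_khz, params$spike_amp_mv)
  sweeps <- matrix(0, n, n_sweeps)
  events <- vector("list", n_sweeps)
  for (i in seq_len(n_sweeps)) {
    ev <- numeric(0)
    if (params$spont_rate_hz > 0) {
      mean_ipi_ms <- 1000 / params$spont_rate_hz
      m <- ceiling(total_ms / mean_ipi_ms) * 3 + 5
      gaps <- rgamma(m, shape = 2, scale = mean_ipi_ms / 2)
      tt <- cumsum(gaps) - runif(1, 0, mean_ipi_ms)
      ev <- tt[tt > 0 & tt < total_ms]
    }
    if (!is.null(cands) && nrow(cands) > 0) {
      p <- stats::plogis((cands$charge - params$threshold_charge_nams) / slope)
      fire <- runif(nrow(cands)) < p
      tt <- cands$time_ms[fire] + params$latency_ms
      if (params$jitter_sd_ms > 0)
        tt <- tt + rnorm(sum(fire), sd = params$jitter_sd_ms)
      ev <- c(ev, tt)
    }
    ev <- sort(ev[ev >= 0 & ev < total_ms])
    # absolute refractory period
    keep <- numeric(0)
    last <- -Inf
    for (t in ev) {
      if (t - last >= params$refractory_ms) {
        keep <- c(keep, t)
        last <- t
      }
    }
    v <- rnorm(n, sd = params$meas_noise_mv * 4)  # baseline noise
    for (t in keep) {
      i0 <- as.integer(round(t * sample_rate_khz)) + 1L - tmpl$peak_offset
      span <- seq_along(tmpl$w) + i0 - 1L
      ok <- span >= 1L & span <= n
      v[span[ok]] <- v[span[ok]] + tmpl$w[ok]
    }
    sweeps[, i] <- v
    events[[i]] <- keep
  }
  sweep_set(sweeps, sample_rate_khz, stimulus,
            t_stim_on_ms = if (is.null(stimulus)) NA_real_ else t_on_ms,
            t_stim_off_ms = if (is.null(stimulus)) NA_real_ else
              t_on_ms + stim_span_effective(stimulus),
            seed = seed, events = events,
            pulse_edges = if (is.null(stimulus)) NULL else
              stimulus_edges(stimulus, t_on_ms))
}
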