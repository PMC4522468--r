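# Canonical simulated receptors shared across tests.
#
# osc_reset_params: strong-reset regime (square-pulse experiments at 10 nA).
# osc_resonance_params: low-intensity paired-pulse resonance regime
#   (slower amplitude relaxation, ~ms-scale phase coherence).
# spiking_params: deterministic edge-triggered spiking receptor.

osc_reset_params <- function(f0_khz = 2) {
  receptor_params("oscillating", f0_khz = f0_khz, mu = 1, kappa = 7,
                  noise_sd = 0.15, spont_amp_mv = 1)
}

osc_resonance_params <- function(f0_khz = 2) {
  receptor_params("oscillating", f0_khz = f0_khz, mu = 0.35, kappa = 7,
                  noise_sd = 0.45, spont_amp_mv = 1)
}

spiking_params <- function(jitter_sd_ms = 0, spont_rate_hz = 0,
                           refractory_ms = 1) {
  receptor_params("spiking", latency_ms = 0.3, refractory_ms = refractory_ms,
                  threshold_charge_nams = 0.5, jitter_sd_ms = jitter_sd_ms,
                  spont_rate_hz = spont_rate_hz)
}

sim_pulse <- function(params, duration_ms, polarity = 1, intensity_na = 10,
                      seed = 1, n_sweeps = 10, ...) {
  st <- stimulus_spec("square_pulse", duration_ms = duration_ms,
                      polarity = polarity, intensity_na = intensity_na)
  if (params$mode == "oscillating")
    simulate_oscillating_receptor(params, st, n_sweeps = n_sweeps,
                                  seed = seed, ...)
  else simulate_spiking_receptor(params, st, n_sweeps = n_sweeps,
                                 seed = seed, ...)
}

sim_pair <- function(params, ipi_ms, duration_ms = 0.2, polarity = 1,
                     intensity_na = 10, seed = 1, n_sweeps = 10) {
  st <- stimulus_spec("pulse_pair", duration_ms = duration_ms,
                      polarity = polarity, ipi_ms = ipi_ms,
                      intensity_na = intensity_na)
  total <- max(10, 3 + ipi_ms + duration_ms + 8)
  if (params$mode == "oscillating")
    simulate_oscillating_receptor(params, st, n_sweeps = n_sweeps,
                                  seed = seed, total_ms = total)
  else simulate_spiking_receptor(params, st, n_sweeps = n_sweeps,
                                 seed = seed, total_ms = total)
}

# sweep set holding externally constructed traces with a nominal stimulus
fake_sweep_set <- function(traces, rate_khz, t_on, t_off, polarity = 1,
                           duration_ms = t_off - t_on) {
  st <- stimulus_spec("square_pulse", duration_ms = duration_ms,
                      polarity = polarity, intensity_na = 1)
  sweep_set(traces, rate_khz, stimulus = st, t_stim_on_ms = t_on,
            t_stim_off_ms = t_off,
            pulse_edges = data.frame(onset_ms = t_on, offset_ms = t_off))
}
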