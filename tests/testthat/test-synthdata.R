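# Synthetic-data generators: stimuli, receptors, trains, artifacts.

test_that("square pulses and pulse pairs sample correctly", {
  st <- stimulus_spec("square_pulse", duration_ms = 0.2, intensity_na = 5)
  w <- make_pulse_stimulus(st)
  expect_equal(sum(w$samples != 0), floor(0.2 * 195.31))  # 39 samples
  stn <- stimulus_spec("square_pulse", duration_ms = 0.2, polarity = -1,
                       intensity_na = 5)
  expect_equal(make_pulse_stimulus(stn)$samples, -w$samples)
  sp <- stimulus_spec("pulse_pair", duration_ms = 0.2, ipi_ms = 3,
                      intensity_na = 5)
  wp <- make_pulse_stimulus(sp)
  on <- which(wp$samples != 0)
  gap_samples <- on[which(diff(on) > 1) + 1] - on[1]
  expect_equal(gap_samples, round(3 * 195.31))
  expect_error(stimulus_spec("pulse_pair", duration_ms = 0.2), "ipi")
})

test_that("bipolar sine polarity and spectral peak conventions", {
  w <- make_bipolar_sine(duration_ms = 0.5)
  expect_lt(which.max(w$samples), which.min(w$samples))  # peak leads trough
  wn <- make_bipolar_sine(duration_ms = 0.5, polarity = -1)
  expect_equal(wn$samples, -w$samples)
  expect_lt(stimulus_peak_frequency(w), 1 / 0.5)
  expect_error(make_bipolar_sine(frequency_khz = 2, duration_ms = 0.5),
               "exactly one")
  expect_error(make_bipolar_sine(), "exactly one")
})

test_that("synthetic EODs meet their spectral and duration targets", {
  e <- synth_eod(0.5, 2.0)
  m <- eod_spectrum_duration(e)
  expect_equal(m$peak_power_freq_khz, 2.0, tolerance = 0.1)
  expect_equal(m$total_duration_ms, 0.5, tolerance = 0.1)
  m2 <- eod_spectrum_duration(wave(5 * e$samples, e$sample_rate_khz))
  expect_equal(m2$peak_power_freq_khz, m$peak_power_freq_khz)
  inv <- eod_spectrum_duration(wave(-e$samples, e$sample_rate_khz))
  expect_equal(inv$peak_power_freq_khz, m$peak_power_freq_khz)
  expect_error(synth_eod(0.2, 1), "unattainable")
})

test_that("EOD trains obey the 0.5% trim and IPI truncation rules", {
  e <- synth_eod(0.5, 2.0)
  rate <- e$sample_rate_khz
  core_n <- diff(oscreset:::duration_05_idx(e$samples)) + 1
  tr1 <- make_eod_train(e, ipi_ms = 5, n_pulses = 10)
  expect_equal(length(tr1$samples), 9 * round(5 * rate) + core_n)
  # EOD longer than the IPI: every inter-onset segment exactly ipi long
  tr2 <- make_eod_train(e, ipi_ms = 0.3, n_pulses = 10)
  gap <- round(0.3 * rate)
  for (k in 1:9) {
    seg <- tr2$samples[((k - 1) * gap + 1):(k * gap)]
    expect_true(any(seg != 0))
  }
  expect_equal(length(tr2$samples), 9 * gap + core_n)
  tr3 <- make_eod_train(e, ipi_ms = 5, n_pulses = 1)
  di <- oscreset:::duration_05_idx(e$samples)
  expect_equal(tr3$samples, e$samples[di[1]:di[2]])
})

test_that("oscillating receptor: spontaneous spectrum, reset, polarity flip", {
  p <- osc_reset_params()
  ss <- simulate_oscillating_receptor(p, NULL, n_sweeps = 5, seed = 2,
                                      total_ms = 200)
  st <- spontaneous_stats(ss$sweeps, ss$sample_rate_khz, 0.02)
  expect_equal(st$f_spont_khz, 2, tolerance = 0.05)
  pos <- sim_pulse(p, 0.2, 1, 10, seed = 5)
  vs <- measure_poststimulus_oscillation(pos)$summary$vector_strength
  expect_gt(vs, 0.9)
  neg <- sim_pulse(p, 0.2, -1, 10, seed = 6)
  dp <- delta_phase(measure_polarity_pair(pos, neg))
  expect_lt(abs(abs(dp$deg) - 180), 15)
  expect_error(
    receptor_params("oscillating", f0_khz = -1), "f0_khz")
})

test_that("simulators are seed-reproducible", {
  p <- osc_reset_params()
  a <- sim_pulse(p, 0.2, seed = 42)
  b <- sim_pulse(p, 0.2, seed = 42)
  expect_identical(a$sweeps, b$sweeps)
  c <- sim_pulse(p, 0.2, seed = 43)
  expect_false(identical(a$sweeps, c$sweeps))
  sp <- spiking_params(jitter_sd_ms = 0.05, spont_rate_hz = 20)
  s1 <- sim_pulse(sp, 0.2, seed = 7)
  s2 <- sim_pulse(sp, 0.2, seed = 7)
  expect_identical(s1$sweeps, s2$sweeps)
  expect_identical(s1$events, s2$events)
})

test_that("spontaneous amplitude grows with mu and saturates", {
  amp_at <- function(mu) {
    p <- receptor_params("oscillating", f0_khz = 2, mu = mu, noise_sd = 0.02,
                         spont_amp_mv = 2 * sqrt(mu))  # unit gain
    ss <- simulate_oscillating_receptor(p, NULL, n_sweeps = 3, seed = 9,
                                        total_ms = 100)
    suppressWarnings(  # 3 recordings instead of the conventional 5
      spontaneous_stats(ss$sweeps, ss$sample_rate_khz, 0.01)$amplitude_mv)
  }
  a1 <- amp_at(0.2); a2 <- amp_at(0.4)
  expect_gt(a2, a1)
  # saturation: amplitude tracks sqrt(mu), so doubling mu gives < 2x
  expect_lt(a2 / a1, 1.9)
})

test_that("spiking receptor obeys edge rules, refractoriness, and sigmoid", {
  sp <- spiking_params()
  pos <- sim_pulse(sp, 0.2, 1, 10, seed = 1)
  expect_true(all(vapply(pos$events, function(e)
    isTRUE(all.equal(e, 3 + 0.3)), logical(1))))
  neg <- sim_pulse(sp, 0.2, -1, 10, seed = 1)
  expect_true(all(vapply(neg$events, function(e)
    isTRUE(all.equal(e, 3.2 + 0.3)), logical(1))))
  # pair below the refractory period: one spike only
  pr <- sim_pair(sp, ipi_ms = 0.5)
  expect_true(all(vapply(pr$events, length, integer(1)) == 1L))
  # zero intensity: no evoked spikes
  quiet <- sim_pulse(sp, 0.2, 1, intensity_na = 0, seed = 3)
  expect_true(all(vapply(quiet$events, length, integer(1)) == 0L))
  expect_error(receptor_params("spiking", refractory_ms = 0), "refractory")
})

test_that("population EOD trains: single-fish floor, pooling, group sub-ms IPIs", {
  g1 <- generate_eod_population_train(1, 60000, seed = 4)
  expect_gte(min(interspike_intervals(g1$pooled)), 8)
  g <- generate_eod_population_train(24, 120000, seed = 5)
  expect_equal(length(g$pooled$times_ms),
               sum(vapply(g$per_fish, function(f) length(f$times_ms),
                          integer(1))))
  expect_gt(mean(interspike_intervals(g$pooled) < 1), 0)
  tiny <- generate_eod_population_train(2, 1, seed = 6)
  expect_equal(length(tiny$pooled$times_ms), 0)
})

test_that("behavioral sessions scale with baseline and respond to kernels", {
  base_est <- function(rate, seed) {
    tr <- simulate_behavioral_session(rate, stimulus_times_s = 6,
                                      duration_s = 12, seed = seed)
    s <- spike_density_function(tr, t_range_ms = c(0, 12000))
    behavioral_response_metrics(s, 6, 6.01)$baseline_hz
  }
  b8 <- mean(vapply(1:5, function(k) base_est(8, k), numeric(1)))
  b16 <- mean(vapply(1:5, function(k) base_est(16, 10 + k), numeric(1)))
  expect_equal(b16 / b8, 2, tolerance = 0.15)
  # zero-amplitude kernels: no measurable modulation beyond SDF noise
  sdfs <- lapply(1:10, function(k) {
    tr <- simulate_behavioral_session(10, 0, 0, 6, 12, seed = 50 + k)
    spike_density_function(tr, t_range_ms = c(0, 12000))
  })
  bm <- behavioral_response_metrics(sdfs, 6, 6.01)
  expect_lt(bm$max_increase_hz, 2)
  expect_error(simulate_behavioral_session(0), "baseline_rate")
})

test_that("residual artifacts are linear and edge-localized", {
  n <- 1000
  tr <- numeric(n)
  s <- c(rep(0, 100), rep(2, 50), rep(0, n - 150))
  expect_equal(add_artifact(tr, s, 0, 0), tr)
  cap <- add_artifact(tr, s, 0, 0.5)
  nz <- which(cap != 0)
  expect_true(all(nz %in% c(101, 151)))  # onset and offset only
  expect_equal(add_artifact(tr, 2 * s, 0.3, 0.5),
               2 * add_artifact(tr, s, 0.3, 0.5))
  expect_error(add_artifact(tr, s[-1], 1, 0), "equal length")
})
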