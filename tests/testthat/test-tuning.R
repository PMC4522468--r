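# Frequency tuning, stimulus spectra, octave comparisons.

REC <- 97.7

events_sweep_set <- function(events, t_on, window = 90, total = 200) {
  n <- as.integer(round(total * REC))
  ss <- sweep_set(matrix(0, n, length(events)), REC,
                  stimulus = stimulus_spec("sine_burst", frequency_khz = 5,
                                           duration_ms = window),
                  t_stim_on_ms = t_on, t_stim_off_ms = t_on + window,
                  events = events)
  ss
}

test_that("spiking response criterion is inclusive at +1 spike/sweep", {
  # 2 spikes/sweep during the stimulus, 0 before
  ev <- lapply(1:5, function(k) c(100, 150))
  cr <- spiking_response_criterion(events_sweep_set(ev, t_on = 95))
  expect_true(cr$responded)
  # equal counts: not a response
  ev2 <- lapply(1:5, function(k) c(50, 120))
  expect_false(spiking_response_criterion(events_sweep_set(ev2, 95))$responded)
  # exactly +1.0 spikes/sweep: boundary inclusive
  ev3 <- lapply(1:5, function(k) c(50, 100, 150))
  expect_true(spiking_response_criterion(events_sweep_set(ev3, 95))$responded)
  expect_error(spiking_response_criterion(events_sweep_set(ev, 10)),
               "exceed")
})

test_that("threshold curves: dB convention, open points, monotonicity", {
  resp <- expand.grid(frequency_khz = c(1, 2, 4, 8),
                      intensity_na = c(1, 2, 10, 20))
  thr_true <- c("1" = 2, "2" = 1, "4" = 10, "8" = Inf)
  resp$responded <- resp$intensity_na >= thr_true[as.character(resp$frequency_khz)]
  tc <- spiking_threshold_curve(resp)
  expect_equal(tc$best_frequency_khz, 2)
  expect_equal(tc$measure[tc$frequencies_khz == 2], 0)
  expect_equal(tc$measure[tc$frequencies_khz == 4], 20)  # 10x -> 20 dB
  expect_true(tc$open[tc$frequencies_khz == 8])
  # raising responses can only lower or keep thresholds
  resp2 <- resp
  resp2$responded <- resp2$responded | (resp2$frequency_khz == 1 &
                                          resp2$intensity_na >= 1)
  tc2 <- spiking_threshold_curve(resp2)
  expect_true(all(tc2$threshold_na <= tc$threshold_na, na.rm = TRUE))
  expect_error(spiking_threshold_curve(
    data.frame(frequency_khz = 1, intensity_na = 1, responded = FALSE)),
    "no responding")
})

test_that("a resonant simulated spiking receptor recovers its best frequency", {
  pk <- receptor_params("spiking", f0_khz = 5, q_factor = 2,
                        latency_ms = 0.3, threshold_charge_nams = 0.4,
                        jitter_sd_ms = 0.02, spont_rate_hz = 5)
  freqs <- 5 * 2^seq(-2, 2)
  rows <- list(); k <- 0
  for (f in freqs) for (I in c(1, 2, 4, 8, 16, 32)) {
    k <- k + 1
    st <- stimulus_spec("sine_burst", frequency_khz = f, intensity_na = I,
                        duration_ms = 90)
    ss <- simulate_spiking_receptor(pk, st, n_sweeps = 5, seed = 200 + k,
                                    t_on_ms = 95)
    rows[[k]] <- data.frame(frequency_khz = f, intensity_na = I,
                            responded = spiking_response_criterion(ss)$responded)
  }
  tc <- spiking_threshold_curve(do.call(rbind, rows))
  expect_lte(abs(log2(tc$best_frequency_khz / 5)), 1)  # within one grid step
})

test_that("stimulus peak frequency: tones, single cycles, scaling", {
  t <- (0:97699) / REC
  x <- sin(2 * pi * 2 * t)
  expect_equal(stimulus_peak_frequency(x, REC), 2, tolerance = 0.02)
  expect_equal(stimulus_peak_frequency(3 * x, REC),
               stimulus_peak_frequency(x, REC))
  w <- make_bipolar_sine(duration_ms = 0.5)
  expect_lt(stimulus_peak_frequency(w), 2)
  expect_error(stimulus_peak_frequency(rep(0, 1000), REC), "flat")
})

test_that("oscillating tuning curves: polarity averaging and tie rule", {
  tab <- expand.grid(frequency_khz = c(0.5, 1, 1.5, 2), polarity = c(1, -1))
  tab$vector_strength <- c(0.2, 0.9, 0.4, 0.3,   # positive: best at 1.0
                           0.2, 0.4, 0.9, 0.3)   # negative: best at 1.5
  tc <- oscillating_tuning_curve(tab)
  expect_equal(tc$per_polarity_best_khz, c(1.5, 1.0))
  expect_equal(tc$best_frequency_khz, 1.25)
  tie <- tab; tie$vector_strength <- 0.5
  expect_message(tc2 <- oscillating_tuning_curve(tie), "tie")
  expect_equal(tc2$best_frequency_khz, 0.5)
})

test_that("a simulated oscillator is tuned near its spontaneous frequency", {
  p <- osc_resonance_params()
  freqs <- 2 * 2^seq(-1.5, 1.5, 0.5)
  rows <- list(); k <- 0
  for (pol in c(1, -1)) for (f in freqs) {
    k <- k + 1
    st <- stimulus_spec("bipolar_sine", frequency_khz = f, polarity = pol,
                        intensity_na = 0.8)
    ss <- simulate_oscillating_receptor(p, st, n_sweeps = 10, seed = 500 + k)
    rows[[k]] <- data.frame(
      frequency_khz = f, polarity = pol,
      vector_strength = measure_poststimulus_oscillation(ss)$summary$vector_strength)
  }
  tc <- oscillating_tuning_curve(do.call(rbind, rows))
  expect_lte(abs(log2(tc$best_frequency_khz / 2)), 0.5)  # within half an octave
})

test_that("EOD spectrum/duration: rectangle width is exact, scaling is inert", {
  rate <- 195.31
  w <- round(0.4 * rate)  # 0.4 ms as an exact number of samples
  x <- c(numeric(100), rep(1, w), numeric(100))
  m <- eod_spectrum_duration(x, rate)
  expect_equal(m$total_duration_ms, w / rate, tolerance = 1e-12)
  m3 <- eod_spectrum_duration(3 * x, rate)
  expect_equal(m3$total_duration_ms, m$total_duration_ms)
  expect_equal(m3$peak_power_freq_khz, m$peak_power_freq_khz)
  expect_error(eod_spectrum_duration(rep(0, 100), rate), "all-zero")
})

test_that("octave distances", {
  expect_equal(octave_distance(2, 2), 0)
  expect_equal(octave_distance(0.5, 2), -2)
  expect_equal(octave_distance(4, 2), 1)
  set.seed(6)
  for (k in 1:10) {
    a <- runif(1, 0.1, 10); b <- runif(1, 0.1, 10)
    expect_equal(octave_distance(a, b), -octave_distance(b, a),
                 tolerance = 1e-12)
  }
  expect_error(octave_distance(-1, 2), "positive")
})
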