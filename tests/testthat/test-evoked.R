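# Evoked-response measurements.

REC <- 97.7

# trace whose poststimulus peaks sit at prescribed times: cos(2*pi*g(t))
# with g piecewise linear through g(t_k) = k (peaks exactly at t_k)
trace_with_peaks <- function(peak_times, total_ms, rate = REC) {
  p_first <- peak_times[2] - peak_times[1]
  pre <- peak_times[1] - p_first * (ceiling(peak_times[1] / p_first):1)
  pk <- c(pre[pre > 0], peak_times)
  t <- (0:(msamples(total_ms, rate) - 1)) / rate
  # knots at peaks (integer phase) and midpoint troughs (half-integer phase)
  mids <- (pk[-1] + pk[-length(pk)]) / 2
  knots <- c(0, sort(c(pk, mids)), total_ms)
  vals <- seq(0, by = 0.5, length.out = length(knots) - 2)
  vals <- c(vals[1] - 0.5, vals, vals[length(vals)] + 0.5)
  g <- approx(knots, vals, xout = t, rule = 2)$y
  cos(2 * pi * (g - vals[2]))  # peaks at integer phase offsets
}
msamples <- function(ms, rate) as.integer(round(ms * rate))

test_that("poststimulus measurement: geometry of a sine burst from offset", {
  off <- 3
  t <- (0:(msamples(10, REC) - 1)) / REC
  A <- 0.8; f <- 2
  x <- ifelse(t > off, A * sin(2 * pi * f * (t - off)), 0)
  ss <- fake_sweep_set(cbind(x, x), REC, t_on = 2.8, t_off = off)
  m <- measure_poststimulus_oscillation(ss)
  expect_equal(m$summary$amplitude_mv, 2 * A, tolerance = 0.05)
  expect_lt(abs(m$per_sweep$lat_ms[1] - 1 / (4 * f)), 0.025)
  expect_lt(abs(m$per_sweep$phi_rad[1] - pi / 2), 0.35)
  expect_equal(m$summary$vector_strength, 1, tolerance = 1e-6)
})

test_that("the 85%/115% artifact rule designates the correct peak", {
  off <- 3
  base <- 0.5
  mk <- function(p1) {
    pk <- off + c(0.3, 0.3 + p1, 0.3 + p1 + base * (1:5))
    trace_with_peaks(pk, 10)
  }
  # first period equal to the reference average: first peak used
  m_ok <- oscreset:::post_peak_measure(mk(base), REC, off)
  expect_false(m_ok$used_second_peak)
  expect_lt(abs(m_ok$lat_ms - 0.3), 0.03)
  expect_lt(abs(m_ok$p_ms - base), 0.03)
  # first period at 80% of the average: second peak used
  m_short <- oscreset:::post_peak_measure(mk(0.8 * base), REC, off)
  expect_true(m_short$used_second_peak)
  expect_lt(abs(m_short$lat_ms - (0.3 + 0.8 * base)), 0.03)
  # first period at 120%: second peak used as well
  m_long <- oscreset:::post_peak_measure(mk(1.2 * base), REC, off)
  expect_true(m_long$used_second_peak)
})

test_that("the artifact rule stays quiet on clean synthetic periods", {
  # periods i.i.d. within +/-5% of 0.5 ms never trip the 85/115% rule
  set.seed(123)
  trips <- vapply(1:200, function(k) {
    periods <- 0.5 * runif(6, 0.95, 1.05)
    pk <- 3 + 0.3 + cumsum(c(0, periods))
    m <- oscreset:::post_peak_measure(trace_with_peaks(pk, 10), REC, 3)
    m$used_second_peak
  }, logical(1))
  expect_false(any(trips))
})

test_that("delta-phi arithmetic and antisymmetry", {
  expect_equal(delta_phase(polarity_pair(0.25, 0.5, 0.5, 0.5))$deg, 180)
  expect_equal(delta_phase(polarity_pair(0.4, 0.5, 0.4, 0.5))$deg, 0)
  expect_equal(delta_phase(polarity_pair(0.2, 0.6, 0.3, 0.4))$raw_deg, 72)
  set.seed(2)
  for (k in 1:20) {
    lp <- runif(1, 0.1, 1); ln <- runif(1, 0.1, 1)
    p1 <- runif(1, 0.4, 0.6); p2 <- runif(1, 0.4, 0.6)
    d1 <- delta_phase(polarity_pair(lp, p1, ln, p2))$deg
    d2 <- delta_phase(polarity_pair(ln, p2, lp, p1))$deg
    expect_lt(abs(((d1 + d2 + 180) %% 360) - 180), 1e-9)
  }
})

test_that("phi and vector strength are invariant to trace scaling", {
  p <- osc_reset_params()
  ss <- sim_pulse(p, 0.2, seed = 33)
  m1 <- measure_poststimulus_oscillation(ss)
  ss2 <- ss; ss2$sweeps <- 5 * ss$sweeps
  m2 <- measure_poststimulus_oscillation(ss2)
  expect_equal(m2$per_sweep$phi_rad, m1$per_sweep$phi_rad, tolerance = 1e-9)
  expect_equal(m2$summary$vector_strength, m1$summary$vector_strength,
               tolerance = 1e-9)
  expect_equal(m2$summary$amplitude_mv, 5 * m1$summary$amplitude_mv,
               tolerance = 1e-9)
  expect_equal(m2$summary$normalized_amplitude,
               m1$summary$normalized_amplitude, tolerance = 1e-9)
})

test_that("oscillation timing difference: conventions and half-period offset", {
  # identical traces under opposite-polarity labels -> 0
  x <- trace_with_peaks(3.2 + 0.3 + 0.5 * (0:8), 12)
  pos <- fake_sweep_set(cbind(x, x), REC, 3, 3.2, polarity = 1)
  neg <- fake_sweep_set(cbind(x, x), REC, 3, 3.2, polarity = -1)
  expect_equal(oscillation_timing_difference(pos, neg), 0, tolerance = 1e-6)
  expect_error(oscillation_timing_difference(pos, pos), "polarity")
  # simulated 2-kHz receptor, 0.10-ms pulses: |difference| is about half the
  # intrinsic period, not the pulse duration
  p <- osc_reset_params()
  sp <- sim_pulse(p, 0.1, 1, 10, seed = 61)
  sn <- sim_pulse(p, 0.1, -1, 10, seed = 62)
  d <- oscillation_timing_difference(sp, sn)
  half_period_off <- abs(abs(d) %% 0.5 - 0.25)
  expect_lt(half_period_off, 0.08)
  expect_gt(abs(abs(d) - 0.1), 0.05)
  # 2-ms pulses: verified against directly measured first-peak times
  lp <- sim_pulse(p, 2, 1, 10, seed = 63)
  ln <- sim_pulse(p, 2, -1, 10, seed = 64)
  d2 <- oscillation_timing_difference(lp, ln)
  mpos <- oscreset:::post_peak_measure(rowMeans(lp$sweeps), REC, lp$t_stim_on_ms)
  mneg <- oscreset:::post_peak_measure(rowMeans(ln$sweeps), REC, ln$t_stim_off_ms)
  expect_equal(d2, (ln$t_stim_off_ms + mneg$lat_ms) -
                 (lp$t_stim_on_ms + mpos$lat_ms), tolerance = 1e-9)
})

test_that("interoscillation interval: exact for shifted responses", {
  p <- osc_reset_params()
  single <- sim_pulse(p, 0.2, seed = 71, total_ms = 16)
  ipi <- 2.5
  shift <- round(ipi * REC)
  shifted <- rbind(matrix(0, shift, ncol(single$sweeps)),
                   single$sweeps[1:(nrow(single$sweeps) - shift), ])
  fake_pair_stim <- stimulus_spec("pulse_pair", duration_ms = 0.2,
                                  ipi_ms = shift / REC, intensity_na = 10)
  pair <- sweep_set(single$sweeps * 0 + shifted, REC, fake_pair_stim,
                    t_stim_on_ms = 3, t_stim_off_ms = 3 + shift / REC + 0.2,
                    pulse_edges = data.frame(
                      onset_ms = 3 + c(0, shift / REC),
                      offset_ms = 3 + c(0, shift / REC) + 0.2))
  ii <- interoscillation_interval(single, pair)
  expect_equal(ii, shift / REC, tolerance = 1e-3)
  expect_error(interoscillation_interval(single, single), "pulse_pair")
})

test_that("paired-pulse amplitude normalization basics", {
  p <- osc_reset_params()
  single <- sim_pulse(p, 0.2, seed = 81)
  pair <- sim_pair(p, ipi_ms = 3, seed = 82)
  r1 <- paired_pulse_normalized_amplitude(pair, single)
  # doubling both responses leaves the ratio unchanged
  pair2 <- pair; pair2$sweeps <- 2 * pair$sweeps
  single2 <- single; single2$sweeps <- 2 * single$sweeps
  expect_equal(paired_pulse_normalized_amplitude(pair2, single2), r1,
               tolerance = 1e-9)
  # a pair response identical to the single reference gives 1 by construction
  fake <- single
  fake$stimulus <- stimulus_spec("pulse_pair", duration_ms = 0.2, ipi_ms = 1e-3,
                                 intensity_na = 10)
  fake$pulse_edges <- data.frame(onset_ms = c(3, 3), offset_ms = c(3.2, 3.2))
  expect_equal(paired_pulse_normalized_amplitude(fake, single), 1,
               tolerance = 1e-9)
  wrongpol <- sim_pulse(p, 0.2, polarity = -1, seed = 83)
  expect_error(paired_pulse_normalized_amplitude(pair, wrongpol), "polarity")
})

test_that("duration series: stimulus-free ratio near 1 and scale invariance", {
  p <- osc_reset_params()
  sets <- lapply(c(0.1, 0.25, 0.5), function(d)
    sim_pulse(p, d, intensity_na = 0.4, seed = round(100 * d)))
  ds <- duration_series_amplitude(sets)
  expect_true(all(is.finite(ds$curve$normalized_amplitude)))
  sets2 <- lapply(sets, function(s) { s$sweeps <- 3 * s$sweeps; s })
  ds2 <- duration_series_amplitude(sets2)
  expect_equal(ds2$curve$normalized_amplitude, ds$curve$normalized_amplitude,
               tolerance = 1e-9)
  # with a zero-intensity stimulus the post/pre ratio stays near 1
  quiet <- lapply(c(0.2, 0.5), function(d)
    sim_pulse(p, d, intensity_na = 0, seed = round(10 * d)))
  dq <- duration_series_amplitude(quiet)
  expect_equal(dq$curve$normalized_amplitude, c(1, 1), tolerance = 0.15)
})

test_that("population sum: identical receptors and exclusion rule", {
  p <- osc_reset_params()
  ss <- sim_pulse(p, 0.2, seed = 91, total_ms = 12)
  amp <- measure_poststimulus_oscillation(ss)$summary$amplitude_mv
  sets <- rep(list(ss), 5)
  ps <- population_sum(sets)
  expect_equal(ps$sum_trace, 5 * rowMeans(ss$sweeps) / amp, tolerance = 1e-9)
  expect_equal(ps$n_used, 5L)
  dead <- ss; dead$sweeps <- ss$sweeps * 0
  expect_warning(ps2 <- population_sum(list(ss, dead, ss)), "excluded")
  expect_equal(ps2$n_used, 2L)
  expect_error(population_sum(list(ss)), "at least 2")
})

test_that("spike responses: probability, latency, flags", {
  sp <- spiking_params()
  pos <- sim_pulse(sp, 0.2, 1, 10, seed = 7)
  r <- measure_spike_response(pos, threshold_mv = 1)
  expect_equal(r$probability, 1)
  expect_lt(abs(r$mean_latency_ms - 0.3), 1.5 / REC)
  quiet <- sim_pulse(sp, 0.2, 1, intensity_na = 0, seed = 8)
  r0 <- measure_spike_response(quiet, threshold_mv = 1)
  expect_equal(r0$probability, 0)
  expect_true(r0$no_response)
  expect_true(is.na(r0$mean_latency_ms))
  expect_error(measure_spike_response(pos, threshold_mv = 1e-6),
               "noise floor")
})

test_that("spike-timing differences equal the pulse duration", {
  sp <- spiking_params()
  for (d in c(0.1, 0.2)) {
    pos <- sim_pulse(sp, d, 1, 10, seed = 7)
    neg <- sim_pulse(sp, d, -1, 10, seed = 8)
    expect_lt(abs(spike_timing_difference(pos, neg, 1) - d), 2.5 / REC)
  }
  expect_error(spike_timing_difference(
    sim_pulse(sp, 0.1, 1, 10, seed = 1),
    sim_pulse(sp, 0.1, 1, 10, seed = 2), 1), "polarity")
})

test_that("paired-pulse spiking: interval matches IPI, refractoriness blocks", {
  sp <- spiking_params()
  pp3 <- sim_pair(sp, ipi_ms = 3)
  r3 <- pair_interspike_interval(pp3, 1)
  expect_equal(r3$both_pulse_probability, 1)
  expect_lt(abs(r3$mean_interval_ms - 3), 2 / REC)
  pp03 <- sim_pair(sp, ipi_ms = 0.3)
  r03 <- pair_interspike_interval(pp03, 1)
  expect_equal(r03$both_pulse_probability, 0)
  expect_true(is.na(r03$mean_interval_ms))
  pp8 <- sim_pair(sp, ipi_ms = 8)
  expect_equal(pair_interspike_interval(pp8, 1)$both_pulse_probability, 1)
})
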