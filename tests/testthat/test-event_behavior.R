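# EOD detection, IPI statistics, spike-density metrics, species comparison.

REC <- 97.7

pulse_trace <- function(times_ms, total_ms, amp = 1, rate = REC) {
  n <- as.integer(round(total_ms * rate))
  x <- numeric(n)
  for (t0 in times_ms) {
    i <- as.integer(round(t0 * rate)) + 1L
    w <- 0:as.integer(round(0.1 * rate))
    x[pmin(i + w, n)] <- amp
  }
  x
}

test_that("EOD event detection: threshold, dead time, round trip", {
  x <- pulse_trace(c(20, 30), 60)
  ev <- detect_eod_events(x, REC)
  expect_equal(length(ev$times_ms), 2)
  expect_equal(interspike_intervals(ev), 10, tolerance = 2 / REC)
  # 0.5 mV stays below the 0.6-mV threshold
  ev2 <- detect_eod_events(pulse_trace(20, 60, amp = 0.5), REC)
  expect_equal(length(ev2$times_ms), 0)
  # synthetic group train round trip
  set.seed(15)
  tt <- sort(runif(200, 1, 1990))
  tt <- tt[c(TRUE, diff(tt) > 0.5)]
  x3 <- pulse_trace(tt, 2000, amp = 1.2)
  ev3 <- detect_eod_events(x3, REC)
  expect_equal(length(ev3$times_ms), length(tt))
  expect_error(detect_eod_events(x, REC, threshold_mv = 0), "threshold")
  expect_warning(detect_eod_events(rep(2, 5000), REC), "saturated")
})

test_that("IPI histograms conserve counts and summarize sub-ms mass", {
  reg <- event_train(seq(0, 80, by = 8), 100)
  h <- ipi_histogram(reg)
  expect_equal(sum(h$counts), length(reg$times_ms) - 1)
  expect_equal(sum(h$counts > 0), 1)  # a single occupied bin
  expect_equal(h$fraction_below_1ms, 0)
  single <- generate_eod_population_train(1, 60000, seed = 18)
  expect_equal(ipi_histogram(single$pooled)$fraction_below_1ms, 0)
  group <- generate_eod_population_train(24, 120000, seed = 19)
  expect_gt(ipi_histogram(group$pooled)$fraction_below_1ms, 0)
  expect_equal(length(ipi_histogram(event_train(5, 10))$ipis_ms), 0)
})

test_that("spike-density functions: kernels, integral, stationary rate", {
  s0 <- spike_density_function(numeric(0), t_range_ms = c(0, 1000))
  expect_true(all(s0$rate_hz == 0))
  s1 <- spike_density_function(500, t_range_ms = c(-1000, 2000))
  expect_equal(s1$time_s[which.max(s1$rate_hz)], 0.5, tolerance = 1e-3)
  expect_equal(sum(s1$rate_hz) * 0.001, 1, tolerance = 1e-3)
  # homogeneous 10 events/s for 100 s
  set.seed(21)
  tt <- sort(runif(1000, 0, 1e5))
  tt <- tt[c(TRUE, diff(tt) > 1e-6)]
  s <- spike_density_function(event_train(tt, 1e5))
  core <- s$time_s > 5 & s$time_s < 95
  expect_equal(mean(s$rate_hz[core]), 10, tolerance = 0.5)
})

test_that("behavioral response metrics: windows, recovery, suppression", {
  flat_sdfs <- lapply(1:10, function(k) {
    tr <- simulate_behavioral_session(10, 0, 0, 6, 12, seed = 300 + k)
    spike_density_function(tr, t_range_ms = c(0, 12000))
  })
  bm <- behavioral_response_metrics(flat_sdfs, 6, 6.01)
  expect_lt(bm$max_increase_hz, 2)
  expect_lt(bm$max_decrease_hz, 2.5)
  expect_equal(bm$baseline_hz, 10, tolerance = 1)
  # +5 events/s step recovered within 20% over 20 repetitions
  step_sdfs <- lapply(1:20, function(k) {
    tr <- simulate_behavioral_session(8, inc_amp_hz = 5, stimulus_times_s = 6,
                                      duration_s = 12, shape = "step",
                                      step_dur_s = 1, seed = 400 + k)
    spike_density_function(tr, t_range_ms = c(0, 12000))
  })
  bs <- behavioral_response_metrics(step_sdfs, 6, 7)
  expect_equal(bs$max_increase_hz, 5, tolerance = 0.2 * 5)
  # pure suppression
  sup_sdfs <- lapply(1:20, function(k) {
    tr <- simulate_behavioral_session(10, dec_amp_hz = 6, stimulus_times_s = 6,
                                      duration_s = 12, shape = "step",
                                      step_dur_s = 1, seed = 500 + k)
    spike_density_function(tr, t_range_ms = c(0, 12000))
  })
  bd <- behavioral_response_metrics(sup_sdfs, 6, 7)
  expect_gt(bd$max_decrease_hz, 3)
  expect_lt(bd$max_increase_hz, 1.5)
  short <- spike_density_function(numeric(0), t_range_ms = c(3000, 9000))
  expect_error(behavioral_response_metrics(short, 6, 7), "prestimulus")
})

test_that("normalized response index", {
  expect_equal(normalized_response(2, 2), 0)
  expect_equal(normalized_response(3, 0), 1)
  expect_equal(normalized_response(3, 1), 0.5)
  set.seed(23)
  for (k in 1:10) {
    a <- runif(1, 0.1, 5); b <- runif(1, 0.1, 5)
    expect_equal(normalized_response(a, b), -normalized_response(b, a))
  }
  expect_error(normalized_response(1, -1), "denominator")
})

sim_species_data <- function(effect, seed, n_fish = 4, sd = 0.1) {
  ipis <- c(0.5, 1, 5, 10, 20, 50, 100)
  set.seed(seed)
  rows <- list()
  for (sp in c("A", "B")) for (f in seq_len(n_fish)) {
    shape <- if (sp == "A") effect * seq(-1, 1, length.out = length(ipis))
    else effect * seq(1, -1, length.out = length(ipis))
    rows[[paste(sp, f)]] <- data.frame(
      fish = paste0(sp, f), species = sp, ipi_ms = ipis,
      response = shape + rnorm(length(ipis), sd = sd))
  }
  do.call(rbind, rows)
}

test_that("species comparison: identical data, power, and type-I error", {
  # both species share the exact same per-fish values: interaction F = 0
  base <- sim_species_data(0.3, seed = 1)
  a_half <- base[base$species == "A", ]
  dup <- a_half
  dup$species <- "B"; dup$fish <- paste0("B", dup$fish)
  same <- rbind(a_half, dup)
  r0 <- species_comparison(same)
  expect_lt(r0$interaction_F, 1e-20)
  expect_equal(r0$interaction_p, 1, tolerance = 1e-6)
  # crossover effect: significant in >= 80% of 100 replicates
  hits <- vapply(1:100, function(k)
    species_comparison(sim_species_data(0.25, seed = 1000 + k))$interaction_p < 0.05,
    logical(1))
  expect_gte(mean(hits), 0.8)
  # permuted species labels: about 5% false positives
  fp <- vapply(1:100, function(k) {
    d <- sim_species_data(0, seed = 2000 + k)
    species_comparison(d)$interaction_p < 0.05
  }, logical(1))
  expect_lte(mean(fp), 0.12)
  bad <- sim_species_data(0.3, seed = 3)[-1, ]
  expect_error(species_comparison(bad), "unbalanced")
})
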