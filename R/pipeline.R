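# Orchestration: experiment configs (JSON), end-to-end runs
# (simulate -> analyze -> report), demo reproductions, and the CLI.

EXPERIMENT_KINDS <- c("spontaneous", "phase_independence", "duration_coding",
                      "tuning", "ipi_coding", "synchrony", "group_ipi",
                      "behavior")

#' Validate an experiment configuration
#'
#' Configs are nested key-value structures (JSON on disk). Physical
#' quantities carry explicit units in their key names (`*_ms`, `*_khz`,
#' `*_na`, `*_mv`, `*_hz`).
#'
#' @param config a named list or a path to a JSON config file.
#' @return validated config (class `experiment_config`).
#' @export
experiment_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  if (is.null(config$kind) || !config$kind %in% EXPERIMENT_KINDS)
    stop("config$kind must be one of: ", paste(EXPERIMENT_KINDS, collapse = ", "))
  if (is.null(config$seed)) stop("config$seed is required (explicit seeds only)")
  config$seed <- as.integer(config$seed)
  needs_receptor <- c("spontaneous", "duration_coding", "tuning",
                      "ipi_coding", "synchrony")
  if (config$kind %in% needs_receptor && is.null(config$receptor))
    stop(sprintf("missing receptor parameter set: config$receptor (kind '%s')",
                 config$kind))
  structure(config, class = c("experiment_config", "list"))
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config[order(names(config))], tf, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tf))
}

receptor_from_config <- function(rc) do.call(receptor_params, rc)

log_stage <- function(stage, seed, msg = "") {
  message(sprintf("[oscreset] stage=%s seed=%d %s", stage, seed, msg))
}

#' Run one experiment end to end
#'
#' Simulates the configured synthetic data, runs the corresponding analysis
#' modules, and writes CSV summaries plus a JSON run manifest (config hash,
#' seed, package version) to `out_dir`.
#'
#' @param config an [experiment_config()] (or list / JSON path).
#' @param out_dir output directory (default `config$out_dir`).
#' @return invisibly, a list with the result tables and output paths.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  config <- experiment_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("an output directory is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  seed <- config$seed
  log_stage(config$kind, seed, paste0("hash=", hash))
  res <- switch(config$kind,
    spontaneous = exp_spontaneous(config, out_dir, hash),
    phase_independence = exp_phase_independence(config, out_dir, hash),
    duration_coding = exp_duration_coding(config, out_dir, hash),
    tuning = exp_tuning(config, out_dir, hash),
    ipi_coding = exp_ipi_coding(config, out_dir, hash),
    synchrony = exp_synchrony(config, out_dir, hash),
    group_ipi = exp_group_ipi(config, out_dir, hash),
    behavior = exp_behavior(config, out_dir, hash))
  manifest <- list(kind = config$kind, seed = seed, config_hash = hash,
                   package_version = as.character(utils::packageVersion("oscreset")),
                   outputs = res$paths)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(res, list(manifest = manifest)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

exp_spontaneous <- function(config, out_dir, hash) {
  f0s <- config$f0_grid_khz %||% c(1.6, 2.0, 2.5)
  amps <- config$amp_grid_mv %||% c(0.09, 0.4, 1.9)
  dur_ms <- config$recording_ms %||% 300
  noise_floor <- config$noise_floor_mv %||% 0.04
  rows <- list()
  for (i in seq_along(f0s)) {
    rc <- config$receptor
    rc$f0_khz <- f0s[i]; rc$spont_amp_mv <- amps[min(i, length(amps))]
    params <- receptor_from_config(rc)
    ss <- simulate_oscillating_receptor(params, NULL, n_sweeps = 5,
                                        seed = derive_seed(config$seed, i),
                                        total_ms = dur_ms)
    st <- spontaneous_stats(ss$sweeps, ss$sample_rate_khz, noise_floor)
    rows[[i]] <- data.frame(receptor_id = i, f_spont_khz = st$f_spont_khz,
                            period_ms = st$period_ms,
                            amplitude_mv = st$amplitude_mv,
                            passes = st$passes_criterion)
  }
  tab <- do.call(rbind, rows)
  p <- file.path(out_dir, "spontaneous_stats.csv")
  write_report_csv(tab, p, hash)
  list(table = tab, paths = p)
}

exp_phase_independence <- function(config, out_dir, hash) {
  n_pairs <- config$n_pairs %||% 6
  seg_ms <- config$segment_ms %||% 150
  rate <- config$sample_rate_khz %||% (.REC_RATE_KHZ / 5)
  pairs <- simulate_receptor_pairs(n_pairs, seg_ms, rate, config$seed)
  study <- phase_coupling_test(pairs)
  tab <- data.frame(pair = seq_len(n_pairs),
                    r_simultaneous = study$r_simultaneous,
                    r_surrogate = study$r_surrogate)
  p1 <- file.path(out_dir, "phase_pairs.csv")
  write_report_csv(tab, p1, hash)
  summ <- data.frame(mean_r_simultaneous = study$mean_r_simultaneous,
                     mean_r_surrogate = study$mean_r_surrogate,
                     wilcoxon_p = study$p_value, n_pairs = n_pairs)
  p2 <- file.path(out_dir, "phase_summary.csv")
  write_report_csv(summ, p2, hash)
  list(table = tab, study = study, paths = c(p1, p2))
}

#' Simulate pairs of independently oscillating receptors
#'
#' Each receptor pair yields `n_segments` simultaneous spontaneous segments;
#' Hilbert phases are extracted per segment. Used by the phase-independence
#' pipeline and its null-calibration tests.
#'
#' @param n_pairs number of receptor pairs.
#' @param seg_ms segment duration (ms).
#' @param rate_khz simulation/recording rate.
#' @param seed integer seed.
#' @param n_segments segments per receptor (default 5).
#' @param f0_range_khz intrinsic-frequency range sampled per receptor.
#' @return list of pairs, each `list(a = , b = )` of phase-series lists.
#' @export
simulate_receptor_pairs <- function(n_pairs, seg_ms, rate_khz, seed,
                                    n_segments = 5,
                                    f0_range_khz = c(1.5, 2.5)) {
  pairs <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    f0s <- c(0, 0)
    set.seed(derive_seed(seed, 1000 + i))
    f0s <- runif(2, f0_range_khz[1], f0_range_khz[2])
    seg <- function(f0, k, who) {
      params <- receptor_params("oscillating", f0_khz = f0, mu = 1,
                                noise_sd = 0.15, spont_amp_mv = 1)
      ss <- simulate_oscillating_receptor(
        params, NULL, n_sweeps = 1, total_ms = seg_ms,
        sample_rate_khz = rate_khz,
        seed = derive_seed(seed, i * 97 + k * 13 + who))
      instantaneous_phase(ss$sweeps[, 1], rate_khz,
                          band_khz = c(0.5 * f0, 1.5 * f0))
    }
    pairs[[i]] <- list(a = lapply(seq_len(n_segments), function(k) seg(f0s[1], k, 1)),
                       b = lapply(seq_len(n_segments), function(k) seg(f0s[2], k, 2)))
  }
  pairs
}

exp_duration_coding <- function(config, out_dir, hash) {
  durations <- config$durations_ms %||% c(0.05, 0.1, 0.2, 0.5, 1, 2)
  intensity <- config$intensity_na %||% 18
  rc <- config$receptor
  params <- receptor_from_config(rc)
  thr <- config$spike_threshold_mv %||% 1
  rows <- list()
  for (i in seq_along(durations)) {
    d <- durations[i]
    mk <- function(pol, k) {
      st <- stimulus_spec("square_pulse", duration_ms = d, polarity = pol,
                          intensity_na = intensity)
      simulate_spiking_receptor(params, st, n_sweeps = 10,
                                seed = derive_seed(config$seed, i * 10 + k))
    }
    pos <- mk(1, 1); neg <- mk(-1, 2)
    dt <- spike_timing_difference(pos, neg, thr)
    pr <- measure_spike_response(pos, thr)$probability
    rows[[i]] <- data.frame(duration_ms = d, timing_diff_ms = dt,
                            spike_probability = pr)
  }
  tab <- do.call(rbind, rows)
  p <- file.path(out_dir, "spike_timing_difference.csv")
  write_report_csv(tab, p, hash)
  list(table = tab, paths = p)
}

exp_tuning <- function(config, out_dir, hash) {
  rc <- config$receptor
  params <- receptor_from_config(rc)
  paths <- character(0)
  out <- list()
  if (params$mode == "oscillating") {
    freqs <- config$frequencies_khz %||%
      (params$f0_khz * 2^seq(-1.5, 1.5, by = 0.5))
    intensity <- config$intensity_na %||% 0.8
    rows <- list()
    k <- 0
    for (pol in c(1, -1)) for (f in freqs) {
      k <- k + 1
      st <- stimulus_spec("bipolar_sine", frequency_khz = f, polarity = pol,
                          intensity_na = intensity)
      ss <- simulate_oscillating_receptor(params, st, n_sweeps = 10,
                                          seed = derive_seed(config$seed, k))
      m <- measure_poststimulus_oscillation(ss)
      rows[[k]] <- data.frame(frequency_khz = f, polarity = pol,
                              vector_strength = m$summary$vector_strength)
    }
    tab <- do.call(rbind, rows)
    tc <- oscillating_tuning_curve(tab)
    tab$best_frequency_khz <- tc$best_frequency_khz
    p <- file.path(out_dir, "oscillating_tuning.csv")
    write_report_csv(tab, p, hash)
    paths <- c(paths, p)
    out$oscillating <- tc
  } else {
    freqs <- config$frequencies_khz %||% (params$f0_khz * 2^seq(-2, 2))
    intens <- config$intensity_grid_na %||% c(1, 2, 4, 8, 16, 32)
    rows <- list(); k <- 0
    for (f in freqs) for (I in intens) {
      k <- k + 1
      st <- stimulus_spec("sine_burst", frequency_khz = f, intensity_na = I,
                          duration_ms = config$burst_ms %||% 90)
      ss <- simulate_spiking_receptor(params, st, n_sweeps = 5,
                                      seed = derive_seed(config$seed, k),
                                      t_on_ms = (config$burst_ms %||% 90) + 5)
      cr <- spiking_response_criterion(ss, window_ms = config$burst_ms %||% 90)
      rows[[k]] <- data.frame(frequency_khz = f, intensity_na = I,
                              responded = cr$responded)
    }
    tab <- do.call(rbind, rows)
    tc <- spiking_threshold_curve(tab)
    curve <- data.frame(frequency_khz = tc$frequencies_khz,
                        threshold_db = tc$measure,
                        threshold_na = tc$threshold_na,
                        best_frequency_khz = tc$best_frequency_khz)
    p <- file.path(out_dir, "spiking_tuning.csv")
    write_report_csv(curve, p, hash)
    paths <- c(paths, p)
    out$spiking <- tc
  }
  c(out, list(paths = paths))
}

exp_ipi_coding <- function(config, out_dir, hash) {
  rc <- config$receptor
  params <- receptor_from_config(rc)
  ipis <- config$ipis_ms %||% c(0.3, 0.5, 1, 2, 3, 5, 8, 13)
  intensity <- config$intensity_na %||% 10
  dur <- config$pulse_ms %||% 0.2
  rows <- list()
  if (params$mode == "oscillating") {
    st1 <- stimulus_spec("square_pulse", duration_ms = dur,
                         intensity_na = intensity)
    single <- simulate_oscillating_receptor(params, st1, n_sweeps = 10,
                                            seed = derive_seed(config$seed, 1))
    for (i in seq_along(ipis)) {
      st2 <- stimulus_spec("pulse_pair", duration_ms = dur, ipi_ms = ipis[i],
                           intensity_na = intensity)
      pair <- simulate_oscillating_receptor(
        params, st2, n_sweeps = 10, seed = derive_seed(config$seed, 1),
        total_ms = max(10, 3 + ipis[i] + dur + 8))
      # measure both on a common sweep span
      ii <- tryCatch(interoscillation_interval(single, pair),
                     error = function(e) NA_real_)
      na <- tryCatch(paired_pulse_normalized_amplitude(pair, single),
                     error = function(e) NA_real_)
      rows[[i]] <- data.frame(ipi_ms = ipis[i], interoscillation_ms = ii,
                              normalized_amplitude = na)
    }
    p <- file.path(out_dir, "interoscillation_intervals.csv")
  } else {
    thr <- config$spike_threshold_mv %||% 1
    for (i in seq_along(ipis)) {
      st2 <- stimulus_spec("pulse_pair", duration_ms = dur, ipi_ms = ipis[i],
                           intensity_na = intensity)
      ss <- simulate_spiking_receptor(params, st2, n_sweeps = 10,
                                      seed = derive_seed(config$seed, i))
      pi_ <- pair_interspike_interval(ss, thr)
      rows[[i]] <- data.frame(ipi_ms = ipis[i],
                              both_pulse_probability = pi_$both_pulse_probability,
                              interspike_ms = pi_$mean_interval_ms)
    }
    p <- file.path(out_dir, "pair_interspike_intervals.csv")
  }
  tab <- do.call(rbind, rows)
  write_report_csv(tab, p, hash)
  list(table = tab, paths = p)
}

exp_synchrony <- function(config, out_dir, hash) {
  n_rec <- config$n_receptors %||% 12
  f0s <- seq(config$f0_min_khz %||% 1.5, config$f0_max_khz %||% 2.0,
             length.out = n_rec)
  intensity <- config$intensity_na %||% 50
  st <- stimulus_spec("square_pulse", duration_ms = config$pulse_ms %||% 0.2,
                      intensity_na = intensity)
  rc <- config$receptor %||% list(mode = "oscillating")
  sets <- lapply(seq_len(n_rec), function(i) {
    rci <- rc; rci$f0_khz <- f0s[i]
    simulate_oscillating_receptor(receptor_from_config(rci), st,
                                  n_sweeps = 10,
                                  seed = derive_seed(config$seed, i),
                                  total_ms = 12)
  })
  ps <- population_sum(sets)
  env <- Mod(analytic_signal(ps$sum_trace))
  post <- ps$time_ms > ps$t_stim_off_ms
  pre <- ps$time_ms < ps$t_stim_on_ms - 0.5
  tab <- data.frame(n_receptors = ps$n_used,
                    peak_envelope = max(env[post]),
                    peak_time_ms = ps$time_ms[post][which.max(env[post])],
                    prestim_envelope = stats::quantile(env[pre], 0.95),
                    t_stim_off_ms = ps$t_stim_off_ms)
  p1 <- file.path(out_dir, "synchrony_summary.csv")
  write_report_csv(tab, p1, hash)
  p2 <- file.path(out_dir, "population_sum.csv")
  write_report_csv(data.frame(time_ms = ps$time_ms, sum = ps$sum_trace),
                   p2, hash)
  list(table = tab, population = ps, paths = c(p1, p2))
}

exp_group_ipi <- function(config, out_dir, hash) {
  dur_ms <- (config$duration_min %||% 2) * 60000
  n_group <- config$n_fish %||% 24
  single <- generate_eod_population_train(1, dur_ms,
                                          seed = derive_seed(config$seed, 1))
  group <- generate_eod_population_train(n_group, dur_ms,
                                         seed = derive_seed(config$seed, 2))
  h1 <- ipi_histogram(single$pooled)
  h2 <- ipi_histogram(group$pooled)
  tab <- data.frame(condition = c("single", "group"),
                    n_fish = c(1, n_group),
                    n_events = c(h1$n_events, h2$n_events),
                    min_ipi_ms = c(min(h1$ipis_ms), min(h2$ipis_ms)),
                    fraction_below_1ms = c(h1$fraction_below_1ms,
                                           h2$fraction_below_1ms))
  p1 <- file.path(out_dir, "ipi_summary.csv")
  write_report_csv(tab, p1, hash)
  hist_tab <- data.frame(bin_lo_ms = h1$breaks_ms[-length(h1$breaks_ms)],
                         bin_hi_ms = h1$breaks_ms[-1],
                         count_single = h1$counts, count_group = h2$counts)
  p2 <- file.path(out_dir, "ipi_histograms.csv")
  write_report_csv(hist_tab, p2, hash)
  list(table = tab, paths = c(p1, p2))
}

exp_behavior <- function(config, out_dir, hash) {
  ipis <- config$ipis_ms %||% c(0.5, 1, 5, 10, 20, 50, 100)
  n_reps <- config$n_reps %||% 5
  baseline <- config$baseline_rate_hz %||% 8
  inc_by_ipi <- config$inc_amp_hz %||% (6 * exp(-(log2(ipis) - log2(0.5))^2 / 8))
  single_amp <- config$single_inc_amp_hz %||% 2
  t_on_s <- 6; dur_s <- 12
  measure <- function(amp, k) {
    sdfs <- lapply(seq_len(n_reps), function(r) {
      tr <- simulate_behavioral_session(baseline, inc_amp_hz = amp,
                                        stimulus_times_s = t_on_s,
                                        duration_s = dur_s,
                                        seed = derive_seed(config$seed,
                                                           k * 100 + r))
      spike_density_function(tr, t_range_ms = c(0, dur_s * 1000))
    })
    behavioral_response_metrics(sdfs, t_on_s, t_on_s + 0.01)
  }
  r_single <- measure(single_amp, 1)$max_increase_hz
  rows <- list()
  for (i in seq_along(ipis)) {
    r_ipi <- measure(inc_by_ipi[i], i + 1)$max_increase_hz
    rows[[i]] <- data.frame(ipi_ms = ipis[i], max_increase_hz = r_ipi,
                            single_increase_hz = r_single,
                            norm_increase = normalized_response(r_ipi, r_single))
  }
  tab <- do.call(rbind, rows)
  p <- file.path(out_dir, "behavior_normalized_response.csv")
  write_report_csv(tab, p, hash)
  list(table = tab, paths = p)
}

#' Built-in demonstration configuration for an experiment kind
#'
#' @param kind one of the eight experiment kinds.
#' @param seed integer seed.
#' @return an [experiment_config()].
#' @export
demo_config <- function(kind, seed = 1) {
  base <- list(kind = kind, seed = seed)
  base$receptor <- switch(kind,
    duration_coding = list(mode = "spiking", latency_ms = 0.3,
                           refractory_ms = 1, jitter_sd_ms = 0.01,
                           threshold_charge_nams = 0.5),
    tuning = list(mode = "oscillating", f0_khz = 2, mu = 0.35, kappa = 7,
                  noise_sd = 0.45, spont_amp_mv = 1),
    ipi_coding = list(mode = "oscillating", f0_khz = 2, mu = 1, kappa = 7,
                      noise_sd = 0.15, spont_amp_mv = 1),
    spontaneous = list(mode = "oscillating", mu = 1, noise_sd = 0.05),
    synchrony = list(mode = "oscillating", mu = 1, kappa = 7,
                     noise_sd = 0.15, spont_amp_mv = 1),
    NULL)
  experiment_config(base)
}

#' Reproduce figure-style demo summaries for the experiment kinds
#'
#' Runs [run_experiment()] for each requested kind with its [demo_config()],
#' writing one subdirectory (CSV summaries plus a simple PNG figure) per
#' kind.
#'
#' @param out_dir parent output directory.
#' @param seed integer seed.
#' @param kinds experiment kinds to run (default all eight).
#' @param plots write PNG figures (default TRUE).
#' @return invisibly, named list of run results.
#' @export
reproduce_demo <- function(out_dir, seed = 1, kinds = EXPERIMENT_KINDS,
                           plots = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  for (kind in kinds) {
    sub <- file.path(out_dir, kind)
    cfg <- demo_config(kind, seed)
    t0 <- proc.time()[3]
    res <- run_experiment(cfg, sub)
    log_stage(kind, seed, sprintf("done in %.1f s", proc.time()[3] - t0))
    if (plots) demo_plot(kind, res, sub)
    results[[kind]] <- res
  }
  invisible(results)
}

demo_plot <- function(kind, res, out_dir) {
  fp <- file.path(out_dir, paste0(kind, ".png"))
  grDevices::png(fp, width = 700, height = 500)
  on.exit(grDevices::dev.off())
  tab <- res$table
  tryCatch({
    switch(kind,
      duration_coding = plot(tab$duration_ms, tab$timing_diff_ms, log = "x",
                             type = "b", xlab = "pulse duration (ms)",
                             ylab = "spike-timing difference (ms)"),
      ipi_coding = {
        ycol <- intersect(c("interoscillation_ms", "interspike_ms"), names(tab))[1]
        plot(tab$ipi_ms, tab[[ycol]], log = "x", type = "b",
             xlab = "IPI (ms)", ylab = ycol)
        abline(0, 1, lty = 2)
      },
      synchrony = plot(res$population$time_ms, res$population$sum_trace,
                       type = "l", xlab = "time (ms)", ylab = "summed response"),
      behavior = plot(tab$ipi_ms, tab$norm_increase, log = "x", type = "b",
                      xlab = "IPI (ms)", ylab = "normalized increase"),
      group_ipi = plot(seq_len(nrow(tab)), tab$fraction_below_1ms,
                       xlab = "condition", ylab = "fraction of IPIs < 1 ms"),
      phase_independence = plot(tab$r_simultaneous, tab$r_surrogate,
                                xlab = "simultaneous r", ylab = "surrogate r"),
      tuning = {
        if (!is.null(res$oscillating)) {
          t2 <- res$oscillating$table
          plot(t2$frequency_khz, t2$vector_strength, log = "x", type = "p",
               xlab = "stimulus frequency (kHz)", ylab = "vector strength")
        } else {
          plot(tab$f_spont_khz %||% seq_len(nrow(tab)), type = "b")
        }
      },
      spontaneous = plot(tab$receptor_id, tab$f_spont_khz, type = "h",
                         xlab = "receptor", ylab = "f_spont (kHz)"))
  }, error = function(e) plot.new())
  invisible(fp)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (persist synthetic raw data for a config),
#' `analyze` (full simulate-analyze-report run), `demo` (all or selected
#' demo kinds). Options: `--config <path>`, `--seed <int>`, `--out <dir>`,
#' `--kinds <comma-separated>` (demo only).
#'
#' @param args character vector (default `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
oscreset_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: oscreset (simulate|analyze|demo) [--config F] [--seed N] [--out D] [--kinds a,b]"
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(config = NULL, seed = 1L, out = "oscreset_out", kinds = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      message("unknown or incomplete option: ", args[i]); return(invisible(1L))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)
  status <- tryCatch({
    if (cmd == "demo") {
      kinds <- if (is.null(opt$kinds)) EXPERIMENT_KINDS else
        strsplit(opt$kinds, ",")[[1]]
      reproduce_demo(opt$out, seed = opt$seed, kinds = kinds)
    } else if (cmd %in% c("simulate", "analyze")) {
      if (is.null(opt$config)) stop("--config is required")
      cfg <- experiment_config(opt$config)
      cfg$seed <- opt$seed
      if (cmd == "analyze") {
        run_experiment(cfg, opt$out)
      } else {
        simulate_raw(cfg, opt$out)
      }
    } else stop("unknown subcommand: ", cmd)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

# persist raw synthetic data (sweep sets / event trains) without analysis
simulate_raw <- function(config, out_dir) {
  config <- experiment_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  if (config$kind == "group_ipi") {
    tr <- generate_eod_population_train(config$n_fish %||% 24,
                                        (config$duration_min %||% 2) * 60000,
                                        seed = seed)
    write_event_train(tr$pooled, file.path(out_dir, "pooled.csv"))
    for (i in seq_along(tr$per_fish))
      write_event_train(tr$per_fish[[i]],
                        file.path(out_dir, sprintf("fish%02d.csv", i)))
  } else if (config$kind == "behavior") {
    tr <- simulate_behavioral_session(config$baseline_rate_hz %||% 8,
                                      inc_amp_hz = config$inc_amp_hz %||% 5,
                                      seed = seed)
    write_event_train(tr, file.path(out_dir, "session.csv"))
  } else {
    rc <- config$receptor %||% list(mode = "oscillating")
    params <- receptor_from_config(rc)
    st <- stimulus_spec("square_pulse",
                        duration_ms = config$pulse_ms %||% 0.2,
                        intensity_na = config$intensity_na %||% 10)
    ss <- if (params$mode == "oscillating")
      simulate_oscillating_receptor(params, st, n_sweeps = 10, seed = seed)
    else simulate_spiking_receptor(params, st, n_sweeps = 10, seed = seed)
    write_sweep_set(ss, file.path(out_dir, "sweeps"))
  }
  invisible(out_dir)
}
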