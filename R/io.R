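# Plain-text persistence: event trains as CSV, sweep sets as a CSV sample
# matrix plus a JSON sidecar carrying the stimulus spec, rates and seed.

#' Write / read an event train as CSV
#'
#' Columns `time_ms`, `label`; the duration is stored in a header comment.
#'
#' @param train an [event_train()].
#' @param path output CSV path.
#' @export
write_event_train <- function(train, path) {
  stopifnot(inherits(train, "event_train"))
  con <- file(path, "w")
  writeLines(sprintf("# duration_ms: %.9g", train$duration_ms), con)
  writeLines("time_ms,label", con)
  if (length(train$times_ms))
    writeLines(sprintf("%.9g,%s", train$times_ms, train$label), con)
  close(con)
  invisible(path)
}

#' @rdname write_event_train
#' @export
read_event_train <- function(path) {
  hdr <- readLines(path, n = 1)
  dur <- as.numeric(sub("# duration_ms: ", "", hdr, fixed = TRUE))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  event_train(df$time_ms, dur,
              label = if (nrow(df)) df$label[1] else "")
}

#' Write / read a sweep set (CSV matrix + JSON sidecar)
#'
#' `<prefix>.csv` holds the samples-by-sweeps matrix; `<prefix>.json` the
#' stimulus specification, sample rate, stimulus timing and seed.
#'
#' @param ss a [sweep_set()].
#' @param prefix output path prefix (without extension).
#' @export
write_sweep_set <- function(ss, prefix) {
  stopifnot(inherits(ss, "sweep_set"))
  utils::write.table(ss$sweeps, paste0(prefix, ".csv"), sep = ",",
                     row.names = FALSE, col.names = FALSE)
  stim <- ss$stimulus
  if (!is.null(stim)) {
    stim <- unclass(stim)
    if (!is.null(stim$eod_wave)) {
      stim$eod_wave_samples <- stim$eod_wave$samples
      stim$eod_wave_rate_khz <- stim$eod_wave$sample_rate_khz
      stim$eod_wave <- NULL
    }
  }
  side <- list(sample_rate_khz = ss$sample_rate_khz,
               t_stim_on_ms = ss$t_stim_on_ms,
               t_stim_off_ms = ss$t_stim_off_ms,
               seed = ss$seed, stimulus = stim,
               events = ss$events, pulse_edges = ss$pulse_edges)
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(prefix)
}

#' @rdname write_sweep_set
#' @export
read_sweep_set <- function(prefix) {
  m <- as.matrix(read.csv(paste0(prefix, ".csv"), header = FALSE))
  dimnames(m) <- NULL
  side <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  stim <- side$stimulus
  if (!is.null(stim)) {
    ew <- NULL
    if (!is.null(stim$eod_wave_samples))
      ew <- wave(stim$eod_wave_samples, stim$eod_wave_rate_khz)
    stim <- stimulus_spec(kind = stim$kind, duration_ms = stim$duration_ms,
                          polarity = stim$polarity,
                          intensity_na = stim$intensity_na,
                          ipi_ms = stim$ipi_ms, n_pulses = stim$n_pulses,
                          frequency_khz = stim$frequency_khz,
                          sample_rate_khz = stim$sample_rate_khz,
                          eod_wave = ew,
                          ramp_ms = if (is.null(stim$ramp_ms)) 5 else stim$ramp_ms)
  }
  ev <- side$events
  if (!is.null(ev) && !is.list(ev)) ev <- as.list(as.data.frame(ev))
  sweep_set(m, side$sample_rate_khz, stimulus = stim,
            t_stim_on_ms = if (is.null(side$t_stim_on_ms)) NA_real_ else side$t_stim_on_ms,
            t_stim_off_ms = if (is.null(side$t_stim_off_ms)) NA_real_ else side$t_stim_off_ms,
            seed = if (is.null(side$seed)) NA_integer_ else side$seed,
            events = ev,
            pulse_edges = if (is.null(side$pulse_edges)) NULL else
              as.data.frame(side$pulse_edges))
}

# CSV with a config-hash comment line (read back with comment.char = "#")
write_report_csv <- function(df, path, config_hash = NULL) {
  con <- file(path, "w")
  if (!is.null(config_hash))
    writeLines(sprintf("# config_hash: %s", config_hash), con)
  close(con)
  suppressWarnings(utils::write.table(df, path, sep = ",", row.names = FALSE,
                                      append = !is.null(config_hash),
                                      qmethod = "double"))
  invisible(path)
}
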