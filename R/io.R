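# Plain-text file formats and flat configuration handling.
#
# Spike files are three-column CSV (time_seconds, electrode, label) with a
# leading metadata comment line carrying the recording duration; stimulus
# files are two-column CSV (onset_seconds, modality). Both round-trip
# losslessly through the readers.

#' Write a spike recording to CSV
#'
#' @param rec a [spike_recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(rec, path) {
  stopifnot(inherits(rec, "spike_recording"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_seconds=%.10g n_electrodes=%d",
                     rec$duration, rec$n_electrodes), con)
  writeLines("time_seconds,electrode,label", con)
  if (nrow(rec$events)) {
    writeLines(sprintf("%.10g,%d,%s", rec$events$time,
                       as.integer(rec$events$electrode), rec$events$label), con)
  }
  invisible(path)
}

#' Read a spike recording from CSV
#'
#' @param path spike CSV path (header line required; an optional leading
#'   `# duration_seconds=... n_electrodes=...` comment supplies metadata,
#'   otherwise the duration is the smallest 0.1-s multiple covering the last
#'   event).
#' @return A [spike_recording].
#' @export
read_spikes <- function(path) {
  lines <- readLines(path)
  assert_that(length(lines) >= 1L, "empty spike file")
  meta <- parse_meta(lines[1])
  body_start <- if (startsWith(lines[1], "#")) 2L else 1L
  assert_that(length(lines) >= body_start, "spike file has no header line")
  header <- strsplit(lines[body_start], ",")[[1]]
  assert_that(identical(header[1:2], c("time_seconds", "electrode")),
              "spike file header must start with time_seconds,electrode")
  n_el <- as.integer(meta["n_electrodes"] %||% MEA_N_ELECTRODES)
  if (is.na(n_el)) n_el <- MEA_N_ELECTRODES
  rows <- lines[-seq_len(body_start)]
  if (length(rows) == 0L) {
    dur <- as.numeric(meta["duration_seconds"])
    assert_that(!is.na(dur), "empty spike file without duration metadata")
    return(spike_recording(data.frame(time = numeric(0), electrode = integer(0),
                                      label = character(0)),
                           duration = dur, n_electrodes = n_el))
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed spike row at line %d: '%s'",
                 bad[1] + body_start, rows[bad[1]]), call. = FALSE)
  }
  time <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  electrode <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(time) | is.na(electrode))
  if (length(bad)) {
    stop(sprintf("malformed spike row at line %d: '%s'",
                 bad[1] + body_start, rows[bad[1]]), call. = FALSE)
  }
  bad <- which(electrode < 0L | electrode >= n_el)
  if (length(bad)) {
    stop(sprintf("electrode index out of range 0-%d at line %d",
                 n_el - 1L, bad[1] + body_start), call. = FALSE)
  }
  label <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "spike", "")
  dur <- as.numeric(meta["duration_seconds"])
  if (is.na(dur)) dur <- ceiling(max(time) / 0.1) * 0.1
  spike_recording(data.frame(time = time, electrode = electrode, label = label,
                             stringsAsFactors = FALSE),
                  duration = dur, n_electrodes = n_el)
}

parse_meta <- function(line) {
  if (!startsWith(line, "#")) return(character(0))
  kv <- regmatches(line, gregexpr("[A-Za-z_]+=[-0-9.eE+]+", line))[[1]]
  out <- vapply(strsplit(kv, "="), `[`, "", 2L)
  names(out) <- vapply(strsplit(kv, "="), `[`, "", 1L)
  out
}

#' Write a stimulus train to CSV
#'
#' @param train a [stimulus_train()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stimuli <- function(train, path) {
  stopifnot(inherits(train, "stimulus_train"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_seconds=%.10g", train$duration), con)
  writeLines("onset_seconds,modality", con)
  if (length(train$onset_times)) {
    writeLines(sprintf("%.10g,%s", train$onset_times, train$modality), con)
  }
  invisible(path)
}

#' Read a stimulus train from CSV
#'
#' @param path stimulus CSV path (columns `onset_seconds`, `modality`).
#' @param duration optional duration override in seconds.
#' @return A [stimulus_train()].
#' @export
read_stimuli <- function(path, duration = NULL) {
  lines <- readLines(path)
  meta <- parse_meta(lines[1])
  body_start <- if (startsWith(lines[1], "#")) 2L else 1L
  header <- strsplit(lines[body_start], ",")[[1]]
  assert_that(identical(header[1:2], c("onset_seconds", "modality")),
              "stimulus file header must be onset_seconds,modality")
  rows <- lines[-seq_len(body_start)]
  dur <- duration %||% as.numeric(meta["duration_seconds"])
  if (length(rows) == 0L) {
    return(stimulus_train(numeric(0), "focal", duration = dur))
  }
  parts <- strsplit(rows, ",", fixed = TRUE)
  onsets <- as.numeric(vapply(parts, `[`, "", 1L))
  modality <- vapply(parts, `[`, "", 2L)[1]
  if (is.na(dur) || is.null(dur)) dur <- ceiling(max(onsets)) + 1
  stimulus_train(onsets, modality, duration = dur)
}

#' Default experiment configuration
#'
#' Flat named list of every tunable of the generation-simulation-analysis
#' chain, keyed `module.parameter`. All stochastic stages derive their seeds
#' from `experiment.seed` plus a fixed per-stage label, so a configuration
#' fully determines an experiment.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    isi.self_transition = 0.9,
    isi.mean_target = 5.0,
    isi.mode_target = 1.1,
    mea.reliability = 0.8,
    mea.latency_focal = 0.0,
    mea.latency_global = 0.1,
    mea.response_duration = 0.2,
    mea.response_rate = 50,
    mea.hourly_reliability_decay = 0.025,
    raster.mask_follow = 3,
    infotheory.estimator = "dirichlet_bayes",
    pipeline.k_max = 5,
    bottleneck.cap_bins = 20,
    bottleneck.restarts = 5,
    bottleneck.beta_steps = 50,
    experiment.hours = 1,
    experiment.seed = 1
  )
}

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are parsed
#' as numbers or logicals where possible, strings otherwise.
#'
#' @param path configuration file path.
#' @return Named list; keys absent from the file keep their
#'   [default_config()] values.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  cfg <- default_config()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    assert_that(length(kv) == 2L, paste("malformed config line:", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
      else if (val %in% c("TRUE", "FALSE")) as.logical(val)
      else val
  }
  cfg
}

#' Write a configuration to a flat key-value file
#'
#' @param config named list as returned by [default_config()] /
#'   [read_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    if (is.numeric(v)) sprintf("%.10g", v) else as.character(v)
  }, "")
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}
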