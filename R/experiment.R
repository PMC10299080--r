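# End-to-end experiment driver: shared stimulus list -> focal-like and
# global-like simulated sessions -> per-hour MI analysis -> bottleneck
# efficiency -> tidy result files.

#' Run a complete simulated stimulation experiment
#'
#' Generates one shared interstimulus-interval list, applies it as a
#' focal-like (zero-latency) and a global-like (one-bin-latency) session to
#' independently simulated cultures, runs the per-hour MI analysis of both
#' sessions, and computes the memory-prediction bottleneck efficiency of
#' each. The canonical experiment layout is 20 h of stimulation framed by
#' spontaneous recording; the default here is a desk-scale 1-h stimulation
#' block, set `experiment.hours` for longer runs.
#'
#' Writes into `out_dir`: `stimuli.csv`, `curves.csv` (tidy table: modality,
#' hour, variant, shift_ms, mi_bits), `frontier.csv`, `summary.json`
#' (per-hour sums, fits, efficiencies, exclusions, seeds) and `log.txt`.
#' Stage failures are caught and recorded; the bundle is then marked partial.
#'
#' @param config named list, see [default_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return Invisibly, a list with `sessions`, `curves` (data frame),
#'   `bottleneck` (per modality), `partial`, `errors` and `config`.
#' @export
run_experiment <- function(config = default_config(), out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  seed <- as.integer(cfg$experiment.seed)
  hours <- cfg$experiment.hours
  duration <- hours * 3600
  errors <- list()
  note <- function(stage, e) errors[[stage]] <<- conditionMessage(e)

  model <- isi_model(self_transition = cfg$isi.self_transition,
                     mean_target = cfg$isi.mean_target,
                     mode_target = cfg$isi.mode_target)
  isis <- generate_isis(model, n = ceiling(duration / 4) + 50,
                        seed = derive_seed(seed, "isi"))
  trains <- list(
    focal = isis_to_train(isis, duration, "focal"),
    global = isis_to_train(isis, duration, "global")
  )
  latencies <- c(focal = cfg$mea.latency_focal, global = cfg$mea.latency_global)

  sessions <- list(); curves_rows <- list(); ib <- list()
  scfg <- session_config(estimator = cfg$infotheory.estimator,
                         k_max = as.integer(cfg$pipeline.k_max),
                         mask_follow = as.integer(cfg$raster.mask_follow))
  for (mod in names(trains)) {
    sess <- tryCatch({
      params <- network_params(reliability = cfg$mea.reliability,
                               response_latency = latencies[[mod]],
                               response_duration = cfg$mea.response_duration,
                               response_rate = cfg$mea.response_rate,
                               hourly_reliability_decay = cfg$mea.hourly_reliability_decay,
                               seed = derive_seed(seed, paste0("mea_", mod)))
      rec <- simulate_recording(params, trains[[mod]], duration)
      run_session(rec, trains[[mod]], scfg)
    }, error = function(e) { note(paste0("session_", mod), e); NULL })
    sessions[[mod]] <- sess
    if (!is.null(sess) && !sess$excluded) {
      for (h in seq_along(sess$curves)) {
        for (v in names(sess$curves[[h]])) {
          cv <- sess$curves[[h]][[v]]
          curves_rows[[length(curves_rows) + 1L]] <- data.frame(
            modality = mod, hour = h, variant = v,
            shift_ms = cv$shifts, mi_bits = cv$values)
        }
      }
      ib[[mod]] <- tryCatch({
        S <- encode_stimulus(trains[[mod]], duration)
        coding <- past_future_code(S, cap_bins = as.integer(cfg$bottleneck.cap_bins))
        X <- binarize(simulate_recording(
          network_params(reliability = cfg$mea.reliability,
                         response_latency = latencies[[mod]],
                         response_duration = cfg$mea.response_duration,
                         response_rate = cfg$mea.response_rate,
                         hourly_reliability_decay = cfg$mea.hourly_reliability_decay,
                         seed = derive_seed(seed, paste0("mea_", mod))),
          trains[[mod]], duration))
        el <- sess$selection[[1]]$electrodes
        pt <- measured_info(X, el, coding, estimator = cfg$infotheory.estimator)
        fr <- frontier(coding,
                       beta_grid = 10^seq(-1, 3, length.out = cfg$bottleneck.beta_steps),
                       restarts = as.integer(cfg$bottleneck.restarts),
                       seed = derive_seed(seed, "bottleneck"))
        list(point = pt, frontier = fr, efficiency = efficiency(pt, fr))
      }, error = function(e) { note(paste0("bottleneck_", mod), e); NULL })
    }
  }
  curves <- if (length(curves_rows)) do.call(rbind, curves_rows) else NULL

  bundle <- list(sessions = sessions, curves = curves, bottleneck = ib,
                 trains = trains, partial = length(errors) > 0,
                 errors = errors, config = cfg)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_stimuli(trains$focal, file.path(out_dir, "stimuli.csv"))
    if (!is.null(curves)) {
      utils::write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    }
    for (mod in names(ib)) {
      if (!is.null(ib[[mod]])) {
        utils::write.csv(ib[[mod]]$frontier$envelope,
                         file.path(out_dir, sprintf("frontier_%s.csv", mod)),
                         row.names = FALSE)
      }
    }
    summary <- list(
      seeds = list(experiment = seed,
                   isi = derive_seed(seed, "isi"),
                   mea_focal = derive_seed(seed, "mea_focal"),
                   mea_global = derive_seed(seed, "mea_global"),
                   bottleneck = derive_seed(seed, "bottleneck")),
      estimator = cfg$infotheory.estimator,
      hours = hours,
      n_stimuli = length(trains$focal$onset_times),
      sessions = lapply(sessions, function(s) {
        if (is.null(s)) return(list(status = "failed"))
        if (s$excluded) return(list(status = "excluded", reason = s$reason))
        list(status = "analysed", hours = s$hours, pred_mem_r = s$pred_mem_r)
      }),
      efficiency = lapply(ib, function(b) if (is.null(b)) NA else b$efficiency),
      partial = bundle$partial,
      errors = errors
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    writeLines(c(sprintf("stimpredict run at seed %d, %g h, estimator %s",
                         seed, hours, cfg$infotheory.estimator),
                 sprintf("stage errors: %d", length(errors))),
               file.path(out_dir, "log.txt"))
  }
  invisible(bundle)
}
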