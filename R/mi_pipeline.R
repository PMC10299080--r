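# Per-hour analysis pipeline: greedy electrode selection, time-shifted MI
# curves quantifying prediction (positive shifts) and short-term memory
# (nonpositive shifts), masked and self-information controls, curve sums,
# and the prediction-memory regression with its trend over hours.

SHIFTS_FUTURE <- seq(100, 2000, by = 100)
SHIFTS_PAST <- seq(-1000, 0, by = 100)

#' MI curve constructor
#'
#' @param shifts time shifts in ms (multiples of 100).
#' @param values MI in bits per shift (nonnegative).
#' @param variant one of `"future"`, `"past"`, `"masked_future"`,
#'   `"masked_past"`, `"self"`.
#' @param electrodes electrode subset the curve was computed on (0-based).
#' @param estimator entropy estimator used.
#' @export
mi_curve <- function(shifts, values,
                     variant = c("future", "past", "masked_future",
                                 "masked_past", "self"),
                     electrodes = integer(0), estimator = "dirichlet_bayes") {
  variant <- match.arg(variant)
  assert_that(length(shifts) == length(values), "shifts/values length mismatch")
  assert_that(all(values >= 0), "MI values must be nonnegative")
  if (variant %in% c("future", "masked_future")) {
    assert_that(all(shifts >= 100 & shifts <= 2000),
                "future shifts must lie in [100, 2000] ms")
  }
  if (variant %in% c("past", "masked_past")) {
    assert_that(all(shifts >= -1000 & shifts <= 0),
                "past shifts must lie in [-1000, 0] ms")
  }
  structure(
    list(shifts = as.numeric(shifts), values = as.numeric(values),
         variant = variant, electrodes = electrodes, estimator = estimator),
    class = "mi_curve"
  )
}

#' @export
print.mi_curve <- function(x, ...) {
  cat(sprintf("MI curve (%s, %s): %d shifts, max %.4f bits at %d ms\n",
              x$variant, x$estimator, length(x$shifts),
              max(x$values), as.integer(x$shifts[which.max(x$values)])))
  invisible(x)
}

#' @export
plot.mi_curve <- function(x, ...) {
  graphics::plot(x$shifts, x$values, type = "b", pch = 16,
                 xlab = expression(Delta * t ~ "(ms)"), ylab = "MI (bits)",
                 main = paste("MI vs shift:", x$variant), ...)
  invisible(x)
}

#' Greedy selection of the most informative electrodes
#'
#' Starting from the single electrode with the highest MI with the stimulus
#' vector, iteratively adds the electrode that maximises the joint MI of the
#' selected word with the stimulus, up to `k_max` electrodes (five by
#' default: the per-electrode information gain decays quickly and larger
#' words aggravate undersampling). Ties are broken towards the lowest
#' electrode index. Greedy selection can miss synergistic pairs (e.g.
#' XOR-coded stimuli), which is accepted: the result is a lower bound on the
#' full MI.
#'
#' @param X a [binary_raster].
#' @param S a [stimulus_vector][encode_stimulus] aligned with `X`.
#' @param k_max maximum number of electrodes (default 5).
#' @param estimator entropy estimator, see [entropy()].
#' @param candidates candidate electrode pool (0-based); default all raster
#'   columns.
#' @param align_shift nonnegative number of bins by which the activity word
#'   is taken *after* the stimulus bin during selection (0 pairs each
#'   stimulus bin with simultaneous activity). Sessions with one-bin response
#'   latency carry no zero-lag signal, so selection aligns at the response.
#' @return A list of class `greedy_selection`: `electrodes` (in selection
#'   order), `mi_trace` (joint MI after each addition), `align_shift`.
#' @export
greedy_select <- function(X, S, k_max = 5L, estimator = "dirichlet_bayes",
                          candidates = NULL, align_shift = 0L) {
  words <- raster_words(X)
  s <- stimulus_bins(S)
  N <- nrow(words)
  assert_that(length(s) == N, "raster and stimulus vector are not aligned")
  candidates <- candidates %||% (seq_len(ncol(words)) - 1L)
  assert_that(length(candidates) >= 1L, "no candidate electrodes")
  m <- as.integer(align_shift)
  assert_that(m >= 0L && m < N, "align_shift out of range")
  s_al <- if (m == 0L) s else s[seq_len(N - m)]
  rows <- if (m == 0L) seq_len(N) else seq_len(N - m) + m
  selected <- integer(0)
  trace <- numeric(0)
  base_code <- numeric(length(rows))
  for (step in seq_len(min(k_max, length(candidates)))) {
    pool <- setdiff(candidates, selected)
    best <- -Inf; best_e <- NA_integer_; best_code <- NULL
    for (e in sort(pool)) {
      code <- base_code + words[rows, e + 1L] * 2^(step - 1)
      mi <- mi_codes(s_al, code, 2L, 2^step, estimator)
      if (mi > best + 1e-12) { best <- mi; best_e <- e; best_code <- code }
    }
    selected <- c(selected, best_e)
    trace <- c(trace, best)
    base_code <- best_code
  }
  structure(list(electrodes = selected, mi_trace = trace, align_shift = m,
                 estimator = estimator),
            class = "greedy_selection")
}

#' @export
print.greedy_selection <- function(x, ...) {
  cat("greedy selection:", paste(x$electrodes, collapse = ", "),
      sprintf("(MI %.4f bits)\n", x$mi_trace[length(x$mi_trace)]))
  invisible(x)
}

#' MI between the stimulus and time-shifted activity
#'
#' For a positive shift `dt` (prediction), each stimulus bin `n` is paired
#' with the activity word `dt / 100` bins *before* it: activity preceding a
#' stimulus that carries information about it is predictive. For `dt <= 0`
#' (short-term memory), stimulus bin `n` is paired with the activity word
#' `|dt| / 100` bins *after* it: activity following a stimulus that retains
#' information about it is memory. The overlap is truncated at the sequence
#' edges and MI is computed per shift via the entropy identity.
#'
#' @inheritParams greedy_select
#' @param electrodes electrode subset defining the activity word (0-based).
#' @param shifts shift grid in ms, multiples of 100; either all positive
#'   (prediction, within `[100, 2000]`) or all nonpositive (memory, within
#'   `[-1000, 0]`).
#' @param variant curve variant label; default inferred from the shift signs
#'   (`"future"` or `"past"`); pass `"masked_future"` / `"masked_past"` when
#'   `X` is a masked raster.
#' @return An [mi_curve].
#' @export
mi_vs_shift <- function(X, S, electrodes, shifts, estimator = "dirichlet_bayes",
                        variant = NULL) {
  words <- raster_words(X)
  s <- stimulus_bins(S)
  N <- nrow(words)
  assert_that(length(s) == N, "raster and stimulus vector are not aligned")
  assert_that(all(shifts %% 100 == 0), "shifts must be multiples of 100 ms")
  future <- all(shifts > 0)
  past <- all(shifts <= 0)
  assert_that(future || past,
              "shifts must be all positive (future) or all nonpositive (past)")
  if (is.null(variant)) variant <- if (future) "future" else "past"
  cx <- word_codes(words, electrodes)
  Kx <- 2^length(electrodes)
  values <- vapply(shifts, function(dt) {
    d <- as.integer(abs(dt) / 100)
    assert_that(d < N, "empty overlap at this shift")
    if (d == 0L) {
      s_part <- s; x_part <- cx
    } else if (dt > 0) {
      s_part <- s[seq_len(N - d) + d]   # stimulus after the activity word
      x_part <- cx[seq_len(N - d)]
    } else {
      s_part <- s[seq_len(N - d)]       # activity word after the stimulus
      x_part <- cx[seq_len(N - d) + d]
    }
    mi_codes(s_part, x_part, 2L, Kx, estimator)
  }, numeric(1))
  mi_curve(shifts, values, variant = variant, electrodes = electrodes,
           estimator = estimator)
}

#' Sum an MI curve over its full shift range
#'
#' The scalar summaries of prediction and memory are the sums of the MI
#' curves over their complete grids: 20 shifts (100-2000 ms) for prediction,
#' 11 shifts (-1000-0 ms) for memory.
#'
#' @param curve an [mi_curve] covering the full grid for its variant.
#' @return Total MI in bits.
#' @export
sum_mi <- function(curve) {
  stopifnot(inherits(curve, "mi_curve"))
  expected <- switch(curve$variant,
                     future = , masked_future = SHIFTS_FUTURE,
                     past = , masked_past = SHIFTS_PAST,
                     stop("sum_mi is defined for future/past curves"))
  assert_that(length(curve$shifts) == length(expected) &&
                all(sort(curve$shifts) == expected),
              "curve does not cover its full shift range")
  sum(curve$values)
}

#' Linear fit of prediction against short-term memory
#'
#' Ordinary least squares of the prediction summary on the memory summary
#' across cultures (or segments), with the Pearson correlation and the
#' t-test of its significance.
#'
#' @param sum_past per-culture memory summaries (x).
#' @param sum_future per-culture prediction summaries (y).
#' @return A list: `slope`, `offset`, `r`, `p_value`, `n`.
#' @export
fit_pred_mem <- function(sum_past, sum_future) {
  assert_that(length(sum_past) == length(sum_future), "length mismatch")
  assert_that(length(sum_past) >= 3L, "need at least 3 points")
  assert_that(stats::var(sum_past) > 0, "zero variance in the memory summaries")
  fit <- stats::lm(sum_future ~ sum_past)
  ct <- stats::cor.test(sum_past, sum_future)
  list(slope = unname(stats::coef(fit)[2]),
       offset = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate),
       p_value = ct$p.value,
       n = length(sum_past))
}

#' Trend of a per-hour statistic over hours
#'
#' Ordinary least squares of a per-hour value (slope or offset of the
#' prediction-memory fit) against the hour index, with the two-sided t-test
#' of the regression slope.
#'
#' @param values per-hour statistic.
#' @param hours hour indices (default `seq_along(values)`).
#' @return A list: `trend` (change per hour), `t`, `p_value`, `n`.
#' @export
trend_over_hours <- function(values, hours = seq_along(values)) {
  assert_that(length(values) == length(hours), "length mismatch")
  assert_that(length(values) >= 5L, "need at least 5 hours")
  fit <- stats::lm(values ~ hours)
  # degenerate (zero-residual) fits are handled explicitly below
  smry <- suppressWarnings(summary(fit))
  sm <- smry$coefficients
  tt <- unname(sm[2, 3]); pv <- unname(sm[2, 4])
  scale <- mean(abs(values)) + 1e-300
  if (!is.finite(tt) || smry$sigma < 1e-10 * scale) {
    # zero residual variance: an exactly flat or exactly linear series
    if (abs(sm[2, 1]) < 1e-10 * scale) { tt <- 0; pv <- 1 }
    else { tt <- sign(sm[2, 1]) * Inf; pv <- 0 }
  }
  list(trend = unname(sm[2, 1]), t = tt, p_value = pv, n = length(values))
}

#' Session configuration for the per-hour analysis
#'
#' @param estimator entropy estimator used throughout.
#' @param k_max greedy selection cap.
#' @param mask_follow bins masked after each stimulus bin.
#' @param mask_seed seed for the masking donor draw.
#' @param align_max largest response-alignment shift (bins) tried when
#'   choosing the greedy-selection alignment.
#' @param active_min_spikes,active_min_electrodes activity inclusion rule.
#' @export
session_config <- function(estimator = "dirichlet_bayes", k_max = 5L,
                           mask_follow = 3L, mask_seed = 1000L,
                           align_max = 3L, active_min_spikes = 250L,
                           active_min_electrodes = 10L) {
  list(estimator = estimator, k_max = k_max, mask_follow = mask_follow,
       mask_seed = mask_seed, align_max = align_max,
       active_min_spikes = active_min_spikes,
       active_min_electrodes = active_min_electrodes)
}

segment_events <- function(rec, t_start, t_end) {
  ev <- rec$events
  ev <- ev[ev$time >= t_start & ev$time < t_end, , drop = FALSE]
  ev$time <- ev$time - t_start
  spike_recording(ev, duration = t_end - t_start,
                  n_electrodes = rec$n_electrodes)
}

segment_train <- function(train, t_start, t_end) {
  on <- train$onset_times
  on <- on[on >= t_start & on < t_end] - t_start
  stimulus_train(on, train$modality, duration = t_end - t_start)
}

#' Run the full per-hour MI analysis of one session
#'
#' Splits the recording into one-hour segments and, per segment: applies the
#' active-electrode filter, picks the response alignment and runs greedy
#' electrode selection, computes the prediction and memory MI curves, their
#' masked controls and the stimulus self-information, and the curve sums.
#' Sessions with fewer than ten active electrodes in the first hour or
#' without a clear PSTH response are flagged excluded, mirroring the culture
#' inclusion rules.
#'
#' @param rec a [spike_recording] spanning at least one hour.
#' @param train the [stimulus_train()] applied during the recording.
#' @param config a [session_config()].
#' @return An object of class `mi_session`: `excluded` (logical) with
#'   `reason`, per-hour data frame `hours` (`hour`, `n_active`,
#'   `align_shift`, `sum_future`, `sum_past`), nested `curves` (one list of
#'   `mi_curve`s per hour), `selection` per hour, and `pred_mem_r` (the
#'   across-hour correlation of the two sums, `NA` below 3 h).
#' @export
run_session <- function(rec, train, config = session_config()) {
  stopifnot(inherits(rec, "spike_recording"), inherits(train, "stimulus_train"))
  n_hours <- floor(rec$duration / 3600 + 1e-9)
  assert_that(n_hours >= 1, "recording must span at least one hour")
  first_hour <- segment_events(rec, 0, 3600)
  act0 <- active_electrodes(first_hour, window = 3600,
                            min_spikes = config$active_min_spikes)
  if (length(act0) < config$active_min_electrodes) {
    return(structure(list(excluded = TRUE,
                          reason = sprintf("only %d active electrodes", length(act0)),
                          hours = NULL, curves = NULL, selection = NULL,
                          pred_mem_r = NA_real_),
                     class = "mi_session"))
  }
  resp <- check_response(rec, train)
  if (!resp$responsive) {
    return(structure(list(excluded = TRUE, reason = "no clear PSTH response",
                          hours = NULL, curves = NULL, selection = NULL,
                          pred_mem_r = NA_real_),
                     class = "mi_session"))
  }
  hours <- data.frame(hour = seq_len(n_hours), n_active = NA_integer_,
                      align_shift = NA_integer_, sum_future = NA_real_,
                      sum_past = NA_real_)
  curves <- vector("list", n_hours)
  selections <- vector("list", n_hours)
  for (h in seq_len(n_hours)) {
    res <- analyse_segment(segment_events(rec, (h - 1) * 3600, h * 3600),
                           segment_train(train, (h - 1) * 3600, h * 3600),
                           config, mask_seed = config$mask_seed + h)
    hours$n_active[h] <- res$n_active
    hours$align_shift[h] <- res$align_shift
    hours$sum_future[h] <- res$sum_future
    hours$sum_past[h] <- res$sum_past
    curves[[h]] <- res$curves
    selections[[h]] <- res$selection
  }
  r <- if (n_hours >= 3 && stats::var(hours$sum_past) > 0)
    stats::cor(hours$sum_past, hours$sum_future) else NA_real_
  structure(list(excluded = FALSE, reason = NULL, hours = hours,
                 curves = curves, selection = selections, pred_mem_r = r),
            class = "mi_session")
}

# One-hour segment analysis: filter, align, select, curves, sums.
analyse_segment <- function(rec, train, config, mask_seed = 1000L) {
  act <- active_electrodes(rec, window = rec$duration,
                           min_spikes = config$active_min_spikes)
  if (length(act) == 0L) act <- seq_len(rec$n_electrodes) - 1L
  X <- binarize(rec)
  S <- encode_stimulus(train, duration = rec$duration)
  align <- choose_alignment(X, S, act, config)
  sel <- greedy_select(X, S, k_max = config$k_max,
                       estimator = config$estimator, candidates = act,
                       align_shift = align)
  el <- sel$electrodes
  fut <- mi_vs_shift(X, S, el, SHIFTS_FUTURE, config$estimator)
  pas <- mi_vs_shift(X, S, el, SHIFTS_PAST, config$estimator)
  msk <- mask_responses(X, S, n_follow = config$mask_follow, seed = mask_seed)
  mfut <- mi_vs_shift(msk$raster, S, el, SHIFTS_FUTURE, config$estimator,
                      variant = "masked_future")
  mpas <- mi_vs_shift(msk$raster, S, el, SHIFTS_PAST, config$estimator,
                      variant = "masked_past")
  slf <- mi_self(S, SHIFTS_FUTURE, estimator = config$estimator)
  list(n_active = length(act), align_shift = align,
       selection = sel,
       curves = list(future = fut, past = pas, masked_future = mfut,
                     masked_past = mpas, self = slf),
       sum_future = sum_mi(fut), sum_past = sum_mi(pas))
}

# Response alignment for greedy selection: the lag (0..align_max bins, i.e.
# activity 0-300 ms after the stimulus) at which the best single electrode
# is most informative about the stimulus.
choose_alignment <- function(X, S, candidates, config) {
  best_mi <- -Inf; best_m <- 0L
  for (m in 0:config$align_max) {
    sel <- greedy_select(X, S, k_max = 1L, estimator = config$estimator,
                         candidates = candidates, align_shift = m)
    if (sel$mi_trace[1] > best_mi + 1e-12) {
      best_mi <- sel$mi_trace[1]; best_m <- m
    }
  }
  best_m
}

#' @export
print.mi_session <- function(x, ...) {
  if (x$excluded) {
    cat("MI session: EXCLUDED (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("MI session: %d hour(s), across-hour r = %s\n",
                nrow(x$hours),
                ifelse(is.na(x$pred_mem_r), "NA", sprintf("%.2f", x$pred_mem_r))))
    print(x$hours)
  }
  invisible(x)
}
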