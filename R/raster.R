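# Rasterisation of spike recordings into binary words, the active-electrode
# inclusion filter, the PSTH clear-response criterion, and masking of
# stimulus-response bins.

#' Binary raster constructor
#'
#' @param words 0/1 integer matrix, time bins in rows (100-ms bins), one
#'   column per electrode (electrode `j` in column `j + 1`).
#' @param bin_width bin width in seconds (0.1).
#' @param t0 time of the first bin's left edge, seconds.
#' @export
binary_raster <- function(words, bin_width = 0.1, t0 = 0) {
  words <- as.matrix(words)
  assert_that(all(words %in% c(0L, 1L)), "raster entries must be 0 or 1")
  storage.mode(words) <- "integer"
  structure(list(words = words, bin_width = bin_width, t0 = t0),
            class = "binary_raster")
}

raster_words <- function(X) {
  if (inherits(X, "binary_raster")) X$words else as.matrix(X)
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf("binary raster: %d bins x %d electrodes (%.0f-ms bins, %.3f%% ones)\n",
              nrow(x$words), ncol(x$words), x$bin_width * 1000,
              100 * mean(x$words)))
  invisible(x)
}

#' Binarise a spike recording into 100-ms words
#'
#' Entry `[n, i]` of the word matrix is 1 iff electrode `i - 1` fired at
#' least once in the half-open bin `[(n-1) * 0.1, n * 0.1)` seconds.
#' Duplicate events within a bin are idempotent.
#'
#' @param rec a [spike_recording].
#' @param bin_width bin width in seconds, default 0.1.
#' @return A [binary_raster] with `ceiling(duration / bin_width)` rows.
#' @export
binarize <- function(rec, bin_width = 0.1) {
  stopifnot(inherits(rec, "spike_recording"))
  N <- as.integer(ceiling(rec$duration / bin_width - 1e-9))
  words <- matrix(0L, nrow = N, ncol = rec$n_electrodes)
  if (nrow(rec$events)) {
    bins <- time_to_bin(rec$events$time, bin_width) + 1L
    keep <- bins >= 1L & bins <= N
    words[cbind(bins[keep], rec$events$electrode[keep] + 1L)] <- 1L
  }
  binary_raster(words, bin_width = bin_width, t0 = 0)
}

#' Active-electrode inclusion filter
#'
#' Electrodes qualify as active when they recorded at least `min_spikes`
#' spikes (default 250) in the first `window` seconds (default the first
#' hour) of the recording. A culture is usable when at least ten electrodes
#' qualify.
#'
#' @param rec a [spike_recording] spanning at least `window` seconds.
#' @param window evaluation window in seconds from the recording start.
#' @param min_spikes spike-count threshold (inclusive).
#' @return Integer vector of active electrode indices (0-based), with an
#'   attribute `usable` that is `TRUE` when at least 10 electrodes qualify.
#' @export
active_electrodes <- function(rec, window = 3600, min_spikes = 250L) {
  stopifnot(inherits(rec, "spike_recording"))
  assert_that(rec$duration >= window - 1e-9,
              "recording shorter than the evaluation window")
  ev <- rec$events
  ev <- ev[ev$time < window, , drop = FALSE]
  counts <- tabulate(ev$electrode + 1L, nbins = rec$n_electrodes)
  act <- which(counts >= min_spikes) - 1L
  attr(act, "usable") <- length(act) >= 10L
  act
}

#' Clear-response criterion on the post-stimulus time histogram
#'
#' Pools spikes from all electrodes into 10-ms sub-bins around each stimulus
#' onset (`pre_window` seconds before, `post_window` after), averages over
#' stimuli, and declares the response clear when any post-stimulus PSTH value
#' strictly exceeds the pre-stimulus mean plus five times the pre-stimulus
#' standard deviation. A silent baseline (zero mean and variance) with any
#' post-stimulus spikes also counts as a clear response.
#'
#' @param rec a [spike_recording].
#' @param train a [stimulus_train()] with at least 10 onsets.
#' @param pre_window,post_window window sizes in seconds (default 0.5 each).
#' @param sub_bin PSTH resolution in seconds (default 0.01).
#' @return A list of class `psth_check`: `responsive` (logical), `psth`
#'   (data frame `time`, `value`), `threshold`, `n_stimuli`.
#' @export
check_response <- function(rec, train, pre_window = 0.5, post_window = 0.5,
                           sub_bin = 0.01) {
  stopifnot(inherits(rec, "spike_recording"), inherits(train, "stimulus_train"))
  onsets <- train$onset_times
  assert_that(length(onsets) >= 10L, "need at least 10 stimuli")
  n_pre <- as.integer(round(pre_window / sub_bin))
  n_post <- as.integer(round(post_window / sub_bin))
  counts <- numeric(n_pre + n_post)
  times <- sort(rec$events$time)
  for (on in onsets) {
    lo <- findInterval(on - pre_window, times) + 1L
    hi <- findInterval(on + post_window - 1e-12, times)
    if (hi >= lo) {
      rel <- times[lo:hi] - (on - pre_window)
      idx <- pmin(time_to_bin(rel, sub_bin) + 1L, n_pre + n_post)
      tab <- tabulate(idx, nbins = n_pre + n_post)
      counts <- counts + tab
    }
  }
  psth <- counts / length(onsets)
  pre <- psth[seq_len(n_pre)]
  post <- psth[n_pre + seq_len(n_post)]
  threshold <- mean(pre) + 5 * stats::sd(pre)
  responsive <- any(post > threshold)
  structure(
    list(responsive = responsive,
         psth = data.frame(
           time = (seq_len(n_pre + n_post) - 0.5) * sub_bin - pre_window,
           value = psth),
         threshold = threshold,
         n_stimuli = length(onsets)),
    class = "psth_check"
  )
}

#' @export
print.psth_check <- function(x, ...) {
  cat(sprintf("PSTH response check over %d stimuli: %s (threshold %.3f, max post %.3f)\n",
              x$n_stimuli, if (x$responsive) "clear response" else "no clear response",
              x$threshold, max(x$psth$value[x$psth$time > 0])))
  invisible(x)
}

#' Mask stimulus responses in a binary raster
#'
#' For every stimulus bin `b`, replaces the binary words in bins
#' `b, b+1, ..., b+n_follow` by words drawn uniformly with replacement
#' (seeded) from donor bins. Donor bins are stimulation-free periods: bins at
#' least `min_gap` bins (1 s) after every preceding stimulus bin, not
#' themselves stimulus or masked bins. Whole rows are substituted, which
#' preserves within-word correlations of the donor distribution.
#'
#' @param X a [binary_raster].
#' @param S a [stimulus_vector][encode_stimulus] aligned with `X`.
#' @param n_follow number of bins masked after each stimulus bin (default 3).
#' @param seed integer seed for the donor draw.
#' @param min_gap minimum distance (bins) from a preceding stimulus for a bin
#'   to qualify as a donor.
#' @return A list with `raster` (the masked [binary_raster]) and `mask` (a
#'   `mask_spec`: `masked_bins`, `donor_bins`, `seed`; 1-based bin indices).
#' @export
mask_responses <- function(X, S, n_follow = 3L, seed = NULL, min_gap = 10L) {
  words <- raster_words(X)
  s <- stimulus_bins(S)
  N <- nrow(words)
  assert_that(length(s) == N, "raster and stimulus vector are not aligned")
  stim_bins <- which(s == 1L)
  masked <- sort(unique(as.vector(outer(stim_bins, 0:n_follow, `+`))))
  masked <- masked[masked <= N]
  if (length(stim_bins) == 0L) {
    mask <- structure(list(masked_bins = integer(0), donor_bins = integer(0),
                           seed = seed), class = "mask_spec")
    return(list(raster = binary_raster(words, X$bin_width, X$t0), mask = mask))
  }
  # distance (in bins) since the most recent stimulus bin; Inf before the first
  last_idx <- findInterval(seq_len(N), stim_bins)
  dist_since <- ifelse(last_idx == 0L, Inf, seq_len(N) - stim_bins[pmax(last_idx, 1L)])
  donors <- setdiff(which(dist_since >= min_gap | is.infinite(dist_since)), masked)
  donors <- setdiff(donors, stim_bins)
  assert_that(length(donors) > 0, "donor pool is empty: stimulation too dense")
  out <- words
  draw <- with_seed(seed, sample(donors, length(masked), replace = TRUE))
  out[masked, ] <- words[draw, ]
  mask <- structure(list(masked_bins = masked, donor_bins = donors, seed = seed),
                    class = "mask_spec")
  list(raster = binary_raster(out, X$bin_width, X$t0), mask = mask)
}
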