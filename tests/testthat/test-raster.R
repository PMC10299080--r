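# Binarisation, activity filter, PSTH response criterion and masking.

test_that("binarise maps events into 0-based half-open 100-ms bins", {
  rec <- spike_recording(data.frame(time = numeric(0), electrode = integer(0)),
                         duration = 1)
  X <- binarize(rec)
  expect_equal(dim(X$words), c(10, 59))
  expect_true(all(X$words == 0))
  rec <- spike_recording(data.frame(time = 0.25, electrode = 3), duration = 1)
  X <- binarize(rec)
  expect_equal(sum(X$words), 1)
  expect_equal(X$words[3, 4], 1L)
  # duplicate events in one bin are idempotent
  rec2 <- spike_recording(data.frame(time = c(0.25, 0.26, 0.29),
                                     electrode = c(3, 3, 3)), duration = 1)
  expect_equal(binarize(rec2)$words, X$words)
})

test_that("binarise agrees with direct per-bin counting on random input", {
  set.seed(6)
  ev <- data.frame(time = runif(5000, 0, 60),
                   electrode = sample(0:58, 5000, replace = TRUE))
  rec <- spike_recording(ev, duration = 60)
  X <- binarize(rec)
  brute <- matrix(0L, 600, 59)
  for (i in seq_len(nrow(rec$events))) {
    b <- floor(rec$events$time[i] / 0.1) + 1
    brute[b, rec$events$electrode[i] + 1] <- 1L
  }
  expect_equal(X$words, brute)
})

test_that("active-electrode filter applies the 250-spike first-hour rule", {
  mk <- function(n, el) data.frame(time = seq(0, 3599, length.out = n),
                                   electrode = rep(el, n))
  rec <- spike_recording(rbind(mk(250, 0), mk(249, 1), mk(600, 2)),
                         duration = 3600)
  act <- active_electrodes(rec)
  expect_true(0 %in% act)     # exactly at threshold: included
  expect_false(1 %in% act)    # one below: excluded
  expect_true(2 %in% act)
  expect_false(attr(act, "usable"))
  silent <- spike_recording(data.frame(time = numeric(0), electrode = integer(0)),
                            duration = 3600)
  act <- active_electrodes(silent)
  expect_length(act, 0)
  expect_false(attr(act, "usable"))
  # spikes after the window do not count
  late <- spike_recording(data.frame(time = runif(400, 3600, 7200), electrode = 0),
                          duration = 7200)
  expect_length(active_electrodes(late), 0)
})

test_that("PSTH criterion detects constructed responses and respects the strict boundary", {
  fx <- responsive_recording(seed = 31, duration = 600, isi_seed = 13)
  expect_true(check_response(fx$rec, fx$train)$responsive)
  # silent baseline with any post-stimulus spikes: clear by the edge rule
  on <- seq(10, 100, by = 5)
  ev <- data.frame(time = on + 0.02, electrode = 0L)
  rec <- spike_recording(ev, duration = 120)
  expect_true(check_response(rec, stimulus_train(on, "focal", 120))$responsive)
  # every pre and post sub-bin holds exactly one spike: post equals the
  # threshold mean + 5 * 0 and the strict inequality rejects it
  on <- seq(10, 100, by = 5)
  ev <- do.call(rbind, lapply(on, function(t) {
    data.frame(time = t + seq(-0.495, 0.495, by = 0.01), electrode = 0L)
  }))
  rec <- spike_recording(ev, duration = 120)
  expect_false(check_response(rec, stimulus_train(on, "focal", 120))$responsive)
  expect_error(check_response(rec, stimulus_train(c(1, 3), "focal", 120)),
               "at least 10")
})

test_that("background-only recordings rarely pass the 5-SD criterion", {
  on <- seq(10, 290, by = 7)
  train <- stimulus_train(on, "focal", 300)
  fp <- vapply(1:400, function(s) {
    params <- network_params(reliability = 0, hourly_reliability_decay = 0,
                             seed = 5000 + s)
    rec <- simulate_recording(params, train, 300)
    check_response(rec, train)$responsive
  }, logical(1))
  expect_lt(mean(fp), 0.05)
})

test_that("masking replaces exactly the stimulation bin plus three followers", {
  set.seed(20)
  words <- matrix(rbinom(100 * 59, 1, 0.2), 100, 59)
  X <- binary_raster(words)
  s <- integer(100); s[40] <- 1L
  out <- mask_responses(X, stim_vec(s), seed = 1)
  expect_equal(out$mask$masked_bins, 40:43)
  changed <- which(rowSums(out$raster$words != words) > 0)
  expect_true(all(changed %in% 40:43))
  # donors keep their distance from the stimulus
  expect_true(all(out$mask$donor_bins < 40 | out$mask$donor_bins >= 50))
  # no stimuli: identity
  out0 <- mask_responses(X, stim_vec(integer(100)), seed = 1)
  expect_identical(out0$raster$words, words)
  # replacement rows are actual donor rows
  for (b in out$mask$masked_bins) {
    hit <- apply(words[out$mask$donor_bins, , drop = FALSE], 1,
                 function(r) all(r == out$raster$words[b, ]))
    expect_true(any(hit))
  }
  # dense stimulation exhausts the donor pool
  expect_error(mask_responses(X, stim_vec(rep(c(1L, rep(0L, 9)), 10)), seed = 1),
               "donor pool")
})

test_that("masked rows follow the stimulation-free word distribution", {
  set.seed(33)
  p_word <- c(0.5, 0.2, 0.2, 0.1)          # distribution over 2-bit words
  N <- 6000
  codes <- sample(0:3, N, replace = TRUE, prob = p_word)
  words <- cbind(codes %% 2L, codes %/% 2L)
  X <- raster_from(words)
  s <- rep(c(1L, rep(0L, 19)), N / 20)
  out <- mask_responses(X, stim_vec(s), seed = 2)
  got <- out$raster$words[out$mask$masked_bins, , drop = FALSE]
  got_codes <- got[, 1] + 2 * got[, 2]
  donor_codes <- codes[out$mask$donor_bins]
  expected <- tabulate(donor_codes + 1L, 4) / length(donor_codes)
  chi <- suppressWarnings(
    chisq.test(tabulate(got_codes + 1L, 4), p = expected))
  expect_gt(chi$p.value, 0.001)
})
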