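# Greedy electrode selection, shifted MI curves, curve summaries,
# prediction-memory fits and the per-hour session driver.

test_that("greedy selection finds the informative electrode and caps at five", {
  set.seed(2)
  s <- rbinom(3000, 1, 0.1)
  mat <- matrix(0L, 3000, 59)
  mat[, 8] <- s                       # electrode 7 copies the stimulus
  X <- binary_raster(mat)
  sel <- greedy_select(X, stim_vec(s), estimator = "plugin")
  expect_equal(sel$electrodes[1], 7)
  expect_length(sel$electrodes, 5)
  # silent additions gain essentially nothing
  expect_lt(sel$mi_trace[5] - sel$mi_trace[1], 1e-6)
  # all-informative raster still returns exactly five electrodes
  noisy <- mat
  for (j in 1:59) noisy[, j] <- as.integer(runif(3000) < 0.1 + 0.6 * s)
  sel2 <- greedy_select(binary_raster(noisy), stim_vec(s), estimator = "plugin")
  expect_length(sel2$electrodes, 5)
  # fewer candidates than the cap
  sel3 <- greedy_select(X, stim_vec(s), candidates = c(3, 7), estimator = "plugin")
  expect_length(sel3$electrodes, 2)
  expect_error(greedy_select(X, stim_vec(s), candidates = integer(0)))
})

test_that("greedy selection misses XOR synergy that exhaustive search finds", {
  set.seed(7)
  n <- 4000
  x1 <- rbinom(n, 1, 0.5); x2 <- rbinom(n, 1, 0.5)
  s <- as.integer(xor(x1, x2))
  x3 <- as.integer(xor(s, rbinom(n, 1, 0.1)))   # weak copy of S
  x4 <- rbinom(n, 1, 0.5)
  X <- raster_from(cbind(x1, x2, x3, x4))
  sel <- greedy_select(X, stim_vec(s), k_max = 2, estimator = "plugin",
                       candidates = 0:3)
  expect_equal(sel$electrodes[1], 2)            # greedy grabs the weak copy
  # exhaustive search over all subsets finds the synergistic pair
  subsets <- unlist(lapply(1:4, function(k) combn(0:3, k, simplify = FALSE)),
                    recursive = FALSE)
  mis <- vapply(subsets, function(el)
    mutual_information(X, el, stim_vec(s), "plugin"), numeric(1))
  sizes <- lengths(subsets)
  best2 <- subsets[sizes == 2][[which.max(mis[sizes == 2])]]
  expect_setequal(best2, c(0, 1))
  mi_greedy2 <- mutual_information(X, sel$electrodes, stim_vec(s), "plugin")
  expect_lt(mi_greedy2, max(mis[sizes == 2]))
})

test_that("shift pairing puts prediction before and memory after the stimulus", {
  # period 1.1 s, perfect immediate single-bin responses: x(n) = s(n)
  s <- rep(c(1L, rep(0L, 10)), 330)
  X <- raster_from(matrix(s, ncol = 1), n_electrodes = 59)
  fut <- mi_vs_shift(X, stim_vec(s), 0, seq(100, 2000, 100), "plugin")
  expect_equal(fut$shifts[which.max(fut$values)], 1100)
  pas <- mi_vs_shift(X, stim_vec(s), 0, seq(-1000, 0, 100), "plugin")
  expect_true(pas$shifts[which.max(pas$values)] %in% c(-100, 0))
  # stimulus-shuffled control: flat near zero at every shift
  set.seed(10)
  ssh <- sample(s)
  flat <- mi_vs_shift(X, stim_vec(ssh), 0, seq(100, 2000, 100), "plugin")
  expect_lt(max(flat$values), 0.002)
  expect_error(mi_vs_shift(X, stim_vec(s), 0, c(100, -100)), "all positive")
  expect_error(mi_vs_shift(X, stim_vec(s), 0, 250), "multiples")
})

test_that("MI values are unchanged under electrode relabelling", {
  set.seed(13)
  mat <- matrix(rbinom(2000 * 6, 1, 0.2), 2000, 6)
  s <- rbinom(2000, 1, 0.1)
  perm <- c(4, 2, 0, 5, 1, 3)
  mat_p <- mat[, perm + 1]
  mi1 <- mutual_information(raster_from(mat), c(0, 2, 5), stim_vec(s), "plugin")
  mi2 <- mutual_information(raster_from(mat_p), match(c(0, 2, 5), perm) - 1,
                            stim_vec(s), "plugin")
  expect_equal(mi1, mi2, tolerance = 1e-12)
})

test_that("curve sums cover the full shift ranges", {
  zero <- mi_curve(seq(100, 2000, 100), rep(0, 20), "future")
  expect_equal(sum_mi(zero), 0)
  const <- mi_curve(seq(100, 2000, 100), rep(0.1, 20), "future")
  expect_equal(sum_mi(const), 2.0)
  set.seed(1)
  v <- runif(11, 0, 0.2)
  past <- mi_curve(seq(-1000, 0, 100), v, "past")
  expect_equal(sum_mi(past), sum(v))
  expect_error(sum_mi(mi_curve(seq(100, 1000, 100), rep(0, 10), "future")),
               "full shift range")
  expect_error(sum_mi(mi_curve(c(100, 200), c(0, 0), "self")), "future/past")
})

test_that("prediction-memory fits recover lines and reject flat noise", {
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  fit <- fit_pred_mem(x, 2 * x + 1)
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$offset, 1, tolerance = 1e-9)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  set.seed(40)
  fit2 <- fit_pred_mem(runif(20), runif(20))
  expect_gt(fit2$p_value, 0.01)   # independent noise: not significant
  expect_error(fit_pred_mem(rep(1, 5), 1:5), "zero variance")
  expect_error(fit_pred_mem(1:2, 1:2), "at least 3")
})

test_that("hour trends detect monotone change and accept flat series", {
  set.seed(3)
  down <- seq(1, 0.5, length.out = 10) + rnorm(10, 0, 0.002)
  tr <- trend_over_hours(down)
  expect_lt(tr$trend, 0)
  expect_lt(tr$p_value, 0.001)
  flat <- trend_over_hours(rep(0.3, 8))
  expect_equal(flat$trend, 0)
  expect_equal(flat$p_value, 1)
  expect_error(trend_over_hours(1:3), "at least 5")
})

test_that("a two-hour responsive session yields two complete analysed hours", {
  fx <- responsive_recording(seed = 44, duration = 7200, isi_seed = 12)
  sess <- run_session(fx$rec, fx$train)
  expect_false(sess$excluded)
  expect_equal(nrow(sess$hours), 2)
  for (h in 1:2) {
    expect_named(sess$curves[[h]],
                 c("future", "past", "masked_future", "masked_past", "self"))
    expect_length(sess$selection[[h]]$electrodes, 5)
  }
  expect_true(all(sess$hours$sum_future >= 0))
  expect_true(all(sess$hours$sum_past >= 0))
  # masking control: masked curve maxima below unmasked maxima in every hour
  for (h in 1:2) {
    cv <- sess$curves[[h]]
    expect_lt(max(cv$masked_future$values), max(cv$future$values))
    expect_lt(max(cv$masked_past$values), max(cv$past$values))
  }
})

test_that("inactive and unresponsive sessions are excluded with a reason", {
  quiet <- spike_recording(
    data.frame(time = runif(300, 0, 3600), electrode = sample(0:58, 300, TRUE)),
    duration = 3600)
  tr <- periodic_train(5, 3600)
  sess <- run_session(quiet, tr)
  expect_true(sess$excluded)
  expect_match(sess$reason, "active electrodes")
  p <- network_params(spont_rates = rep(0.5, 59), reliability = 0,
                      hourly_reliability_decay = 0, seed = 61)
  rec <- simulate_recording(p, tr, 3600)
  sess2 <- run_session(rec, tr)
  expect_true(sess2$excluded)
  expect_match(sess2$reason, "response")
})
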