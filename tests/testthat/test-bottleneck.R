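# Past/future stimulus codes, measured information, the IB frontier and
# prediction efficiency.

test_that("past/future codes match hand computation and periodic structure", {
  pf <- past_future_code(stim_vec(c(1, 0, 0, 1)), cap_bins = 5)
  expect_equal(pf$s_plus, c(0L, 1L, 2L, 0L))
  expect_equal(pf$s_minus, c(0L, 2L, 1L, 0L))
  expect_equal(sum(pf$joint), 1, tolerance = 1e-12)
  # periodic train with period p: support is s_plus + s_minus = p or (0, 0)
  p <- 7
  pf <- past_future_code(stim_vec(rep(c(1, rep(0, p - 1)), 20)), cap_bins = 10)
  nz <- which(pf$joint > 0, arr.ind = TRUE) - 1L
  expect_true(all(nz[, 1] + nz[, 2] == p | (nz[, 1] == 0 & nz[, 2] == 0)))
  # stimulus bins carry the zero convention
  expect_true(all(pf$s_plus[stim_vec(rep(c(1, rep(0, p - 1)), 20))$bins == 1] == 0,
                  na.rm = TRUE))
  expect_error(past_future_code(stim_vec(c(0, 1, 0))), "two stimuli")
})

test_that("the default stimulus process carries predictive information", {
  isis <- generate_isis(default_model, 600, seed = 3)
  S <- encode_stimulus(isis_to_train(isis, 2400, "focal"), 2400)
  pf <- past_future_code(S)
  expect_gt(stimpredict:::joint_mi_bits(pf$joint), 0.1)
})

test_that("deterministic encodings attain the data-processing equalities", {
  isis <- generate_isis(default_model, 400, seed = 9)
  S <- encode_stimulus(isis_to_train(isis, 1800, "focal"), 1800)
  pf <- past_future_code(S)
  # five electrodes binary-encode s_plus exactly (injective map)
  sp <- pf$s_plus
  sp[is.na(sp)] <- 0L
  mat <- sapply(0:4, function(b) (sp %/% 2^b) %% 2L)
  X <- raster_from(mat, n_electrodes = 59)
  pt <- measured_info(X, 0:4, pf, estimator = "plugin")
  h_sp <- stimpredict:::entropy_probs_bits(rowSums(pf$joint))
  expect_equal(pt$i_mem, h_sp, tolerance = 1e-9)
  expect_equal(pt$i_pred, stimpredict:::joint_mi_bits(pf$joint), tolerance = 1e-9)
  # independent activity carries nothing
  set.seed(2)
  Xr <- raster_from(matrix(rbinom(length(sp) * 3, 1, 0.2), ncol = 3),
                    n_electrodes = 59)
  pt0 <- measured_info(Xr, 0:2, pf, estimator = "plugin")
  expect_lt(pt0$i_mem, 0.02)
  expect_lt(pt0$i_pred, 0.02)
})

test_that("the frontier matches exhaustive encoder search on a 2x2 joint", {
  P <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, byrow = TRUE)
  fr <- frontier(P, n_x = 2, seed = 3)
  g <- seq(0, 1, 0.005)
  psp <- rowSums(P); cond <- P / psp
  mems <- preds <- numeric(0)
  for (a in g) for (b in g) {
    Q <- rbind(c(1 - a, a), c(1 - b, b))
    Jm <- Q * psp
    mems <- c(mems, stimpredict:::joint_mi_bits(Jm))
    preds <- c(preds, stimpredict:::joint_mi_bits(crossprod(Jm, cond)))
  }
  ms <- seq(0, max(mems), length.out = 25)
  brute <- vapply(ms, function(m) max(preds[mems <= m + 1e-12]), numeric(1))
  ours <- approx(fr$envelope$R, fr$envelope$D, xout = ms, rule = 2)$y
  expect_lt(max(abs(brute - ours)), 0.005)
})

test_that("frontier envelopes are anchored, monotone, concave and capped", {
  isis <- generate_isis(default_model, 400, seed = 6)
  S <- encode_stimulus(isis_to_train(isis, 1800, "focal"), 1800)
  pf <- past_future_code(S)
  fr <- frontier(pf, beta_grid = 10^seq(-1, 3, length.out = 20), restarts = 3,
                 seed = 2)
  env <- fr$envelope
  expect_equal(env$R[1], 0)
  expect_equal(env$D[1], 0)
  expect_true(all(diff(env$D) >= -1e-12))          # nondecreasing
  expect_true(all(diff(env$R) > 0))                # strictly ordered memory
  slopes <- diff(env$D) / diff(env$R)
  expect_true(all(diff(slopes) <= 1e-6))           # concave
  expect_lt(abs(max(env$D) - fr$i_sps), 0.01)      # data-processing cap
  expect_true(all(fr$solutions$i_pred <= fr$i_sps + 1e-9))
})

test_that("the frontier is invariant to relabelling past categories", {
  P <- matrix(c(0.30, 0.05, 0.02, 0.05, 0.25, 0.03, 0.02, 0.03, 0.25),
              3, byrow = TRUE)
  fr1 <- frontier(P, seed = 4)
  perm <- c(3, 1, 2)
  fr2 <- frontier(P[perm, ], seed = 4)
  ms <- seq(0, min(max(fr1$envelope$R), max(fr2$envelope$R)), length.out = 15)
  d1 <- approx(fr1$envelope$R, fr1$envelope$D, xout = ms, rule = 2)$y
  d2 <- approx(fr2$envelope$R, fr2$envelope$D, xout = ms, rule = 2)$y
  expect_lt(max(abs(d1 - d2)), 0.005)
})

test_that("larger representation alphabets never lower the frontier", {
  P <- matrix(c(0.30, 0.05, 0.02, 0.05, 0.25, 0.03, 0.02, 0.03, 0.25),
              3, byrow = TRUE)
  maxd <- vapply(c(2, 3, 6), function(nx)
    max(frontier(P, n_x = nx, seed = 5)$envelope$D), numeric(1))
  expect_true(all(diff(maxd) >= -0.005))
})

test_that("measured points of simulations respect the frontier", {
  fx <- responsive_recording(seed = 3, isi_seed = 2)
  S <- encode_stimulus(fx$train, 3600)
  pf <- past_future_code(S)
  X <- binarize(fx$rec)
  sel <- greedy_select(X, S)
  pt <- measured_info(X, sel$electrodes, pf)
  fr <- frontier(pf, beta_grid = 10^seq(-1, 3, length.out = 25), restarts = 3,
                 seed = 8)
  d_star <- approx(fr$envelope$R, fr$envelope$D,
                   xout = min(max(pt$i_mem, 0), max(fr$envelope$R)),
                   rule = 2)$y
  expect_lte(pt$i_pred, d_star + 0.02)
  eff <- efficiency(pt, fr)
  expect_gt(eff, 0)
  expect_lte(eff, 102)
})

test_that("efficiency is 100% on the frontier, 0% without prediction, >=95% for the optimal deterministic code", {
  P <- matrix(c(0.4, 0.1, 0.1, 0.4), 2, byrow = TRUE)
  fr <- frontier(P, n_x = 2, seed = 3)
  env <- fr$envelope
  k <- nrow(env) - 1
  on_frontier <- structure(list(i_mem = env$R[k], i_pred = env$D[k]),
                           class = "info_point")
  expect_equal(efficiency(on_frontier, fr), 100, tolerance = 0.1)
  none <- structure(list(i_mem = 0.3, i_pred = 0), class = "info_point")
  expect_equal(efficiency(none, fr), 0)
  # identity encoding of s_plus: memory H(S+), prediction I[S+;S-]
  ident <- structure(list(i_mem = fr$h_sp, i_pred = fr$i_sps),
                     class = "info_point")
  expect_gte(efficiency(ident, fr), 95)
})
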