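# Predictive information bottleneck: time-since-last / time-to-next stimulus
# codes, the measured memory/prediction point of a recording, the
# theoretical memory-prediction frontier, and prediction efficiency.

#' Time-since-last and time-to-next stimulus codes
#'
#' Replaces the full stimulus past at each 100-ms bin by the time since the
#' last stimulus (`s_plus`, in bins) and the full future by the time to the
#' next stimulus (`s_minus`). Stimulus bins have `s_plus = s_minus = 0`.
#' Values above `cap_bins` collapse into one overflow category; bins before
#' the first or after the last stimulus are excluded. The empirical joint
#' distribution of `(s_plus, s_minus)` over included bins is attached.
#'
#' @param S a [stimulus_vector][encode_stimulus] with at least two stimuli.
#' @param cap_bins largest explicit count (default 20 bins = 2 s, the
#'   maximum shift of the prediction analysis).
#' @return An object of class `past_future_coding`: `s_plus`, `s_minus`
#'   (integer vectors, `NA` outside the included range, overflow coded as
#'   `cap_bins + 1`), `joint` (matrix over the `cap_bins + 2` categories of
#'   each margin, summing to 1), `cap_bins`, `included` (bin index range).
#' @export
past_future_code <- function(S, cap_bins = 20L) {
  s <- stimulus_bins(S)
  stim <- which(s == 1L)
  assert_that(length(stim) >= 2L, "need at least two stimuli")
  N <- length(s)
  idx <- seq_len(N)
  last <- findInterval(idx, stim)                 # index of last stim at/before bin
  nxt <- findInterval(idx - 0.5, stim) + 1L       # index of next stim at/after bin
  s_plus <- ifelse(last >= 1L, idx - stim[pmax(last, 1L)], NA_integer_)
  s_minus <- ifelse(nxt <= length(stim), stim[pmin(nxt, length(stim))] - idx,
                    NA_integer_)
  included <- !is.na(s_plus) & !is.na(s_minus)
  cap <- as.integer(cap_bins)
  s_plus <- ifelse(is.na(s_plus), NA_integer_, pmin(s_plus, cap + 1L))
  s_minus <- ifelse(is.na(s_minus), NA_integer_, pmin(s_minus, cap + 1L))
  K <- cap + 2L
  joint <- matrix(0, K, K, dimnames = list(0:(K - 1L), 0:(K - 1L)))
  tab <- table(factor(s_plus[included], levels = 0:(K - 1L)),
               factor(s_minus[included], levels = 0:(K - 1L)))
  joint[] <- tab / sum(tab)
  structure(
    list(s_plus = as.integer(s_plus), s_minus = as.integer(s_minus),
         joint = joint, cap_bins = cap, included = which(included)),
    class = "past_future_coding"
  )
}

#' @export
print.past_future_coding <- function(x, ...) {
  cat(sprintf("past/future stimulus coding: cap %d bins, %d included bins, I[S+;S-] = %.4f bits\n",
              x$cap_bins, length(x$included), joint_mi_bits(x$joint)))
  invisible(x)
}

# plug-in MI of a joint probability matrix, in bits
joint_mi_bits <- function(P) {
  p1 <- rowSums(P); p2 <- colSums(P)
  nz <- P > 0
  sum(P[nz] * log2(P[nz] / outer(p1, p2)[nz]))
}

entropy_probs_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Measured memory and prediction of a recording
#'
#' The memory a culture's activity carries about the recent stimulus past,
#' `Imem = I[S+; X]`, and its predictive power about the future,
#' `Ipred = I[S-; X]`, with `X` the binary word over the selected electrodes
#' and the MI estimated over the bins included in `coding`.
#'
#' @param X a [binary_raster] aligned with the stimulus vector that produced
#'   `coding`.
#' @param electrodes selected electrode subset (0-based).
#' @param coding a [past_future_code()] object.
#' @param estimator entropy estimator, see [entropy()].
#' @return An object of class `info_point` with fields `i_mem` and `i_pred`
#'   (bits).
#' @export
measured_info <- function(X, electrodes, coding, estimator = "dirichlet_bayes") {
  stopifnot(inherits(coding, "past_future_coding"))
  words <- raster_words(X)
  assert_that(nrow(words) == length(coding$s_plus),
              "raster and coding are not aligned")
  idx <- coding$included
  cx <- word_codes(words, electrodes)[idx]
  Kx <- 2^length(electrodes)
  Ks <- coding$cap_bins + 2L
  i_mem <- mi_codes(coding$s_plus[idx], cx, Ks, Kx, estimator)
  i_pred <- mi_codes(coding$s_minus[idx], cx, Ks, Kx, estimator)
  structure(list(i_mem = i_mem, i_pred = i_pred), class = "info_point")
}

#' @export
print.info_point <- function(x, ...) {
  cat(sprintf("Imem = %.4f bits, Ipred = %.4f bits\n", x$i_mem, x$i_pred))
  invisible(x)
}

#' Memory-prediction frontier of the stimulus process
#'
#' Solves the predictive information bottleneck for the joint distribution
#' of (time since last stimulus, time to next stimulus): over encoders
#' `p(x | s_plus)` with `n_x` representation states, the minimal memory
#' `I[X; S+]` needed to achieve predictive power `I[X; S-] >= D`. For each
#' trade-off parameter `beta` the self-consistent update of encoder,
#' representation marginal and decoder is iterated from several seeded random
#' initialisations; the best solution per `beta` (lowest objective
#' `I[X;S+] - beta I[X;S-]`) is kept, the deterministic identity encoder is
#' added as the high-memory endpoint, and the upper concave envelope of the
#' achieved (memory, prediction) pairs is returned.
#'
#' @param coding a [past_future_code()] object (or a joint probability
#'   matrix over the two codes).
#' @param n_x number of representation states; default the number of
#'   past-code categories with positive probability.
#' @param beta_grid trade-off parameters; default 50 log-spaced values in
#'   `[0.1, 1000]`.
#' @param restarts random initialisations per `beta` (default 5).
#' @param seed seed for the initialisations.
#' @param max_iter,tol convergence control of the self-consistent iteration.
#' @return An object of class `frontier_curve`: `solutions` (data frame
#'   `beta`, `i_mem`, `i_pred`, `converged`), `envelope` (data frame `R`
#'   memory, `D` predictive power; concave, nondecreasing, starting at
#'   (0, 0)), `i_sps` (`I[S+;S-]`, the data-processing cap on `D`), `n_x`.
#' @export
frontier <- function(coding, n_x = NULL,
                     beta_grid = 10^seq(log10(0.1), log10(1000), length.out = 50),
                     restarts = 5L, seed = 1L, max_iter = 2000L, tol = 1e-8) {
  P <- if (inherits(coding, "past_future_coding")) coding$joint else as.matrix(coding)
  assert_that(abs(sum(P) - 1) < 1e-9, "joint must sum to 1")
  keep_r <- rowSums(P) > 0
  keep_c <- colSums(P) > 0
  P <- P[keep_r, keep_c, drop = FALSE]
  p_sp <- rowSums(P)
  cond <- P / p_sp                       # p(s- | s+), rows
  n_sp <- nrow(P)
  n_x <- as.integer(n_x %||% n_sp)
  assert_that(n_x >= 1L, "n_x must be positive")
  i_sps <- joint_mi_bits(P)
  eps <- 1e-300

  evaluate <- function(Q) {              # Q: n_sp x n_x encoder
    qx <- as.vector(crossprod(Q, p_sp))
    j_xsp <- Q * p_sp                    # p(s+, x)
    i_mem <- joint_mi_bits(j_xsp)
    j_xsm <- crossprod(j_xsp, cond)      # p(x, s-)
    i_pred <- joint_mi_bits(j_xsm)
    list(qx = qx, i_mem = i_mem, i_pred = i_pred)
  }

  solve_beta <- function(beta, Q) {
    obj_old <- Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      qx <- pmax(as.vector(crossprod(Q, p_sp)), eps)
      dec <- crossprod(Q * p_sp, cond) / qx          # n_x x n_sm: q(s-|x)
      # KL(p(s-|s+) || q(s-|x)) for every (s+, x), in nats
      plogp <- rowSums(ifelse(cond > 0, cond * log(pmax(cond, eps)), 0))
      kl <- plogp - cond %*% t(log(pmax(dec, eps)))
      lq <- matrix(log(qx), n_sp, n_x, byrow = TRUE) - beta * kl
      lq <- lq - apply(lq, 1L, max)
      Q <- exp(lq)
      Q <- Q / rowSums(Q)
      ev <- evaluate(Q)
      obj <- ev$i_mem - beta * ev$i_pred
      if (is.finite(obj_old) && abs(obj - obj_old) < tol) {
        converged <- TRUE
        break
      }
      obj_old <- obj
    }
    ev <- evaluate(Q)
    list(Q = Q, i_mem = ev$i_mem, i_pred = ev$i_pred,
         obj = ev$i_mem - beta * ev$i_pred, converged = converged)
  }

  sols <- with_seed(seed, {
    out <- vector("list", length(beta_grid))
    for (b in seq_along(beta_grid)) {
      best <- NULL
      for (r in seq_len(restarts)) {
        Q0 <- matrix(stats::rexp(n_sp * n_x), n_sp, n_x)
        Q0 <- Q0 / rowSums(Q0)
        cand <- solve_beta(beta_grid[b], Q0)
        if (!cand$converged) next
        if (is.null(best) || cand$obj < best$obj) best <- cand
      }
      assert_that(!is.null(best),
                  sprintf("no restart converged at beta = %g", beta_grid[b]))
      out[[b]] <- data.frame(beta = beta_grid[b], i_mem = best$i_mem,
                             i_pred = best$i_pred, converged = best$converged)
    }
    do.call(rbind, out)
  })
  # deterministic identity encoder: the maximum-memory endpoint, which
  # attains the data-processing bound I[X;S-] = I[S+;S-]
  if (n_x >= n_sp) {
    Qid <- diag(1, n_sp, n_x)
    ev <- evaluate(Qid)
    sols <- rbind(sols, data.frame(beta = Inf, i_mem = ev$i_mem,
                                   i_pred = ev$i_pred, converged = TRUE))
  }
  env <- concave_envelope(sols$i_mem, sols$i_pred)
  structure(list(solutions = sols, envelope = env, i_sps = i_sps,
                 h_sp = entropy_probs_bits(p_sp), n_x = n_x,
                 beta_grid = beta_grid, restarts = restarts, seed = seed),
            class = "frontier_curve")
}

# Upper concave envelope of achieved (memory, prediction) points, anchored
# at (0, 0); returns a data frame with R (memory) increasing and D
# (prediction) nondecreasing and concave in R.
concave_envelope <- function(i_mem, i_pred) {
  pts <- data.frame(R = c(0, pmax(i_mem, 0)), D = c(0, pmax(i_pred, 0)))
  pts <- pts[order(pts$R, -pts$D), ]
  pts <- pts[!duplicated(round(pts$R, 12)), ]
  hull <- list()
  for (i in seq_len(nrow(pts))) {
    p <- pts[i, ]
    while (length(hull) >= 1L && p$D <= hull[[length(hull)]]$D) {
      if (p$R >= hull[[length(hull)]]$R) break
      hull[[length(hull)]] <- NULL
    }
    if (length(hull) >= 1L && p$D <= hull[[length(hull)]]$D) next
    while (length(hull) >= 2L) {
      a <- hull[[length(hull) - 1L]]; b <- hull[[length(hull)]]
      # drop b if it lies below segment a-p (concavity)
      if ((b$D - a$D) * (p$R - a$R) <= (p$D - a$D) * (b$R - a$R) + 1e-15) {
        hull[[length(hull)]] <- NULL
      } else break
    }
    hull[[length(hull) + 1L]] <- p
  }
  env <- do.call(rbind, hull)
  rownames(env) <- NULL
  env
}

#' @export
print.frontier_curve <- function(x, ...) {
  cat(sprintf("IB frontier: n_x = %d, %d beta values, max D = %.4f bits (I[S+;S-] = %.4f)\n",
              x$n_x, length(x$beta_grid), max(x$envelope$D), x$i_sps))
  invisible(x)
}

#' @export
plot.frontier_curve <- function(x, ...) {
  graphics::plot(x$envelope$R, x$envelope$D, type = "l", lwd = 2,
                 xlab = "memory I[X;S+] (bits)",
                 ylab = "prediction I[X;S-] (bits)",
                 main = "memory-prediction frontier", ...)
  graphics::points(x$solutions$i_mem, x$solutions$i_pred, pch = 16,
                   col = "grey50", cex = 0.6)
  invisible(x)
}

#' Prediction efficiency of a measured point against the frontier
#'
#' The achieved predictive power as a percentage of the frontier's maximal
#' predictive power at the measured memory:
#' `100 * i_pred / D*(i_mem)`, with `D*` linearly interpolated between
#' envelope points and `i_mem` clipped into the frontier's memory range.
#'
#' @param point an [info_point][measured_info].
#' @param curve a [frontier_curve][frontier].
#' @return Efficiency in percent.
#' @export
efficiency <- function(point, curve) {
  stopifnot(inherits(point, "info_point"), inherits(curve, "frontier_curve"))
  env <- curve$envelope
  assert_that(max(env$D) > 1e-12, "degenerate (all-zero) frontier")
  m <- min(max(point$i_mem, min(env$R)), max(env$R))
  d_star <- stats::approx(env$R, env$D, xout = m, rule = 2, ties = max)$y
  if (d_star <= 1e-12) {
    if (point$i_pred <= 1e-12) return(0)
    assert_that(FALSE, "frontier is zero at the measured memory")
  }
  100 * point$i_pred / d_star
}
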