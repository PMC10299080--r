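# Stimulus generation: a hidden-Markov interstimulus-interval (ISI) process
# with long-range temporal correlations, binary encoding of stimulus trains,
# and the stimulus self-information control.
#
# The experimental constraints the default model reproduces: ISIs live on a
# 100-ms grid with a hard floor of 1 s, the mean stimulation rate is 0.2 Hz
# (stationary mean ISI 5 s), the modal interval is 1.1 s, and consecutive
# ISIs are positively correlated through a sticky two-state hidden Markov
# chain.

#' Construct the default correlated-ISI hidden Markov model
#'
#' The ISI distribution is a two-component mixture on the 0.1-s grid: a sharp
#' log-normal "short" component whose mode sits at `mode_target` (1.1 s) and
#' a broader log-normal "long" component whose location is calibrated at
#' construction time (by root finding on the discretised grid) so that the
#' stationary mean ISI equals `mean_target` (5 s, i.e. a 0.2-Hz mean rate).
#' The two hidden states share these components but weight them differently
#' (`short_weights`); a sticky transition matrix (`self_transition`) then
#' produces slowly mixing regimes and hence positive long-range correlation
#' between consecutive ISIs, while keeping the marginal ISI distribution and
#' its sampling variance compatible with the 2% mean-rate calibration used
#' for quality control.
#'
#' Discretisation is by interval mass: grid point `k` (a multiple of 0.1 s)
#' carries the probability of `[k - 0.05, k + 0.05)`, with the first point
#' truncated on the left at exactly 1.0 s, which enforces the hard 1-s floor
#' between consecutive stimuli.
#'
#' @param self_transition probability of staying in the current hidden state
#'   per ISI (default 0.9).
#' @param mean_target stationary mean ISI in seconds (default 5.0).
#' @param mode_target modal ISI in seconds (default 1.1).
#' @param isi_max largest representable ISI in seconds (default 30).
#' @param short_sdlog,long_sdlog log-scale spreads of the two mixture
#'   components.
#' @param short_weights weight of the short component in each hidden state.
#' @param seed integer seed stored with the model (used as the default by
#'   [generate_isis()]).
#' @return An object of class `isi_model` with fields `n_states`,
#'   `transition_matrix`, `state_isi_pmfs` (states in rows, one column per
#'   grid point), `grid` and `seed`.
#' @export
isi_model <- function(self_transition = 0.9,
                      mean_target = 5.0,
                      mode_target = 1.1,
                      isi_max = 30,
                      short_sdlog = 0.12,
                      long_sdlog = 0.25,
                      short_weights = c(0.40, 0.10),
                      seed = 1L) {
  grid <- seq(1.0, isi_max, by = 0.1)
  disc <- function(mu, sig) {
    lo <- pmax(grid - 0.05, 1.0)
    hi <- grid + 0.05
    m <- stats::plnorm(hi, mu, sig) - stats::plnorm(lo, mu, sig)
    m / sum(m)
  }
  mu_short <- log(mode_target) + short_sdlog^2   # log-normal mode identity
  p_short <- disc(mu_short, short_sdlog)
  m_short <- sum(grid * p_short)
  w_bar <- mean(short_weights)                    # symmetric chain: stationary (1/2, 1/2)
  m_long_target <- (mean_target - w_bar * m_short) / (1 - w_bar)
  assert_that(m_long_target > 1 && m_long_target < isi_max,
              "mean_target unattainable with these components")
  f <- function(mu) sum(grid * disc(mu, long_sdlog)) - m_long_target
  mu_long <- stats::uniroot(f, interval = log(c(1.2, isi_max)), tol = 1e-12)$root
  p_long <- disc(mu_long, long_sdlog)
  pmfs <- rbind(short_weights[1] * p_short + (1 - short_weights[1]) * p_long,
                short_weights[2] * p_short + (1 - short_weights[2]) * p_long)
  s <- self_transition
  trans <- matrix(c(s, 1 - s, 1 - s, s), nrow = 2, byrow = TRUE)
  model <- new_isi_model(trans, pmfs, grid, seed = seed)
  model$mean_target <- mean_target
  model$mode_target <- mode_target
  model
}

#' Low-level ISI model constructor
#'
#' @param transition_matrix row-stochastic matrix over hidden states.
#' @param state_isi_pmfs matrix of per-state ISI probability mass functions
#'   (one row per state) over `grid`.
#' @param grid ISI support in seconds, multiples of 0.1 with minimum 1.0.
#' @param seed integer seed stored with the model.
#' @export
new_isi_model <- function(transition_matrix, state_isi_pmfs, grid, seed = 1L) {
  model <- structure(
    list(n_states = nrow(transition_matrix),
         transition_matrix = transition_matrix,
         state_isi_pmfs = state_isi_pmfs,
         grid = grid,
         seed = seed),
    class = "isi_model"
  )
  validate_isi_model(model)
  model
}

#' Validate an ISI model against its invariants
#'
#' Checks that transition rows are stochastic, that every state pmf sums to
#' one with zero mass below the 1-s floor, and that the stationary mean ISI
#' is within 1% of 5 s (0.2-Hz mean rate).
#'
#' @param model an `isi_model`.
#' @return The model, invisibly; errors otherwise.
#' @export
validate_isi_model <- function(model) {
  P <- model$transition_matrix
  assert_that(is.matrix(P) && nrow(P) == ncol(P) && all(P >= 0),
              "transition matrix must be square and nonnegative")
  assert_that(all(abs(rowSums(P) - 1) < 1e-12),
              "transition matrix rows must sum to 1")
  pm <- model$state_isi_pmfs
  assert_that(is.matrix(pm) && nrow(pm) == nrow(P),
              "state_isi_pmfs must have one row per hidden state")
  assert_that(all(abs(rowSums(pm) - 1) < 1e-12),
              "state ISI pmfs must sum to 1")
  assert_that(all(pm >= 0), "state ISI pmfs must be nonnegative")
  assert_that(all(model$grid >= 1.0 - 1e-9),
              "ISI pmfs must have zero mass below 1 s")
  pi0 <- stationary_distribution(P)
  mean_isi <- sum(as.vector(pi0 %*% pm) * model$grid)
  assert_that(abs(mean_isi - 5.0) / 5.0 < 0.01,
              "stationary mean ISI must equal 5 s within 1%")
  invisible(model)
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Draw interstimulus intervals from the hidden Markov ISI process
#'
#' Simulates the hidden state chain from its stationary distribution, then
#' draws one ISI per step from the active state's pmf.
#'
#' @param model an [isi_model()].
#' @param n number of ISIs to draw.
#' @param seed integer seed (defaults to the model's stored seed).
#' @return Numeric vector of `n` ISIs in seconds, each a multiple of 0.1 s
#'   and at least 1 s.
#' @export
generate_isis <- function(model, n, seed = model$seed) {
  validate_isi_model(model)
  assert_that(is.numeric(n) && length(n) == 1 && n >= 1, "n must be >= 1")
  n <- as.integer(n)
  P <- model$transition_matrix
  pi0 <- stationary_distribution(P)
  with_seed(seed, {
    states <- integer(n)
    states[1] <- sample.int(model$n_states, 1L, prob = pi0)
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      cumP <- t(apply(P, 1L, cumsum))
      for (i in 2:n) {
        states[i] <- findInterval(u[i - 1L], cumP[states[i - 1L], ]) + 1L
      }
    }
    isis <- numeric(n)
    for (k in seq_len(model$n_states)) {
      idx <- which(states == k)
      if (length(idx)) {
        isis[idx] <- sample(model$grid, length(idx), replace = TRUE,
                            prob = model$state_isi_pmfs[k, ])
      }
    }
    isis
  })
}

#' Build a stimulus train from a list of ISIs
#'
#' Onset times are the cumulative sums of the ISIs, truncated at `duration`;
#' the first onset falls at the first ISI.
#'
#' @param isis ISIs in seconds, all at least 1 s.
#' @param duration recording duration in seconds.
#' @param modality `"focal"` (electrical) or `"global"` (optogenetic).
#' @return A [stimulus_train()].
#' @export
isis_to_train <- function(isis, duration, modality = c("focal", "global")) {
  modality <- match.arg(modality)
  assert_that(length(isis) >= 1, "empty ISI list")
  assert_that(all(isis >= 1.0 - 1e-9), "all ISIs must be at least 1 s")
  onsets <- cumsum(isis)
  onsets <- onsets[onsets < duration]
  stimulus_train(onsets, modality, duration)
}

#' Stimulus train constructor
#'
#' @param onset_times stimulus onset times in seconds, strictly increasing,
#'   separated by at least 1 s, all inside `[0, duration)`.
#' @param modality `"focal"` or `"global"`.
#' @param duration recording duration in seconds.
#' @export
stimulus_train <- function(onset_times, modality = c("focal", "global"), duration) {
  modality <- match.arg(modality)
  onset_times <- as.numeric(onset_times)
  if (length(onset_times) > 1) {
    assert_that(all(diff(onset_times) >= 1.0 - 1e-9),
                "consecutive onsets must be at least 1 s apart")
  }
  assert_that(all(onset_times >= 0 & onset_times < duration),
              "onsets must lie in [0, duration)")
  structure(
    list(onset_times = onset_times, modality = modality, duration = duration),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus train: %d onsets over %.1f s (%s)\n",
              length(x$onset_times), x$duration, x$modality))
  invisible(x)
}

#' Encode a stimulus train as a binary 100-ms-bin vector
#'
#' Bin `n` (0-based) covers `[n * 0.1, (n + 1) * 0.1)` seconds; `s(n) = 1`
#' iff an onset falls in bin `n`.
#'
#' @param train a [stimulus_train()].
#' @param duration span to encode in seconds (default: the train duration);
#'   must cover the last onset.
#' @return A `stimulus_vector`: list with `bins` (0/1 integer vector of
#'   length `ceiling(duration / 0.1)`) and `bin_width` (0.1 s).
#' @export
encode_stimulus <- function(train, duration = train$duration) {
  stopifnot(inherits(train, "stimulus_train"))
  if (length(train$onset_times)) {
    assert_that(duration >= max(train$onset_times),
                "duration must cover the last onset")
  }
  N <- as.integer(ceiling(duration / 0.1 - 1e-9))
  bins <- integer(N)
  if (length(train$onset_times)) {
    idx <- time_to_bin(train$onset_times, 0.1) + 1L
    assert_that(!anyDuplicated(idx), "two onsets fall in one 100-ms bin")
    bins[idx] <- 1L
  }
  structure(list(bins = bins, bin_width = 0.1), class = "stimulus_vector")
}

stimulus_bins <- function(S) {
  if (inherits(S, "stimulus_vector")) S$bins else as.integer(S)
}

#' Self-information of the stimulus train across time shifts
#'
#' The intrinsic predictability of the stimulus: mutual information between
#' the binary stimulus vector and a time-shifted copy of itself,
#' `MIself(dt) = MI(s(n); s(n + dt / 0.1))`, evaluated on the overlapping
#' index range. On a train with a pronounced modal interval the curve peaks
#' at that interval.
#'
#' @param S a [stimulus_vector][encode_stimulus].
#' @param shifts time shifts in ms, multiples of 100.
#' @param estimator entropy estimator, see [entropy()].
#' @return An [mi_curve] with `variant = "self"`.
#' @export
mi_self <- function(S, shifts, estimator = "dirichlet_bayes") {
  s <- stimulus_bins(S)
  N <- length(s)
  assert_that(all(shifts %% 100 == 0), "shifts must be multiples of 100 ms")
  assert_that(all(abs(shifts) / 100 < N), "shift magnitude must be below N bins")
  values <- vapply(shifts, function(dt) {
    d <- as.integer(abs(dt) / 100)
    if (d == 0) {
      a <- s; b <- s
    } else {
      a <- s[seq_len(N - d)]
      b <- s[seq_len(N - d) + d]
    }
    if (dt < 0) { tmp <- a; a <- b; b <- tmp }
    mi_codes(a, b, 2L, 2L, estimator)
  }, numeric(1))
  mi_curve(shifts, values, variant = "self", electrodes = integer(0),
           estimator = estimator)
}
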