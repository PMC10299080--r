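# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Sets the R random seed, evaluates `code`, and restores the caller's RNG
#' state afterwards, so seeded simulation steps do not disturb each other or
#' the user's session.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed from a master seed and a stage label.
# Keeps the result well inside 32-bit integer range.
derive_seed <- function(seed, label) {
  offsets <- c(
    isi = 11L, train = 23L, mea_focal = 37L, mea_global = 41L,
    mask = 53L, bottleneck = 67L, params = 71L, cascade = 83L
  )
  off <- offsets[[label]]
  if (is.null(off)) stop("unknown seed label: ", label)
  (abs(as.integer(seed)) %% 20000000L) * 100L + off
}

# floor(t / width) robust to the representation error of decimal widths
time_to_bin <- function(t, width) {
  as.integer(floor(t / width + 1e-9))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
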