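#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for all printed values
#' (base R's \code{round} rounds half to even). A tiny guard absorbs binary
#' representation error so that e.g. 31.25 rounds up to 31.3 at one decimal.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed
#'
#' Counter-based scheme: sub-seeds depend only on (master seed, counter), so
#' cohort members are reproducible independently of generation order. All
#' arithmetic stays exact in double precision and the result fits a 32-bit
#' integer.
#'
#' @param seed master seed (integer).
#' @param counter non-negative integer counter.
#' @return integer sub-seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, counter) {
  m <- 2147483647
  x <- (abs(as.numeric(seed)) %% m) + 1
  for (i in seq_len(2)) {
    x <- (x * 48271 + as.numeric(counter) * 9973 + 12345) %% m
  }
  as.integer(x + 1)
}

# shared input checks
stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name))
}
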