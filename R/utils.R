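# Internal helpers shared across modules.

# Deterministic sub-seed derivation so that stages and planes can be
# re-generated individually.  Linear congruential hash over the integer
# components; result always a valid 32-bit seed.
derive_seed <- function(seed, ...) {
  parts <- c(seed, unlist(list(...)))
  h <- 0
  for (v in parts) {
    h <- (h * 69069 + as.numeric(v) + 12345) %% 2147483647
  }
  as.integer(h)
}

# Trapezoidal integral of y over x (x ascending).
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum(diff(x) * (y[-1L] + y[-n]) / 2)
}

# Degree-2 design matrix on the wavenumber axis rescaled to [0, 1].
# Rescaling keeps the normal equations well conditioned and makes baseline
# coefficients interpretable in counts.
poly2_design <- function(wavenumber) {
  u <- (wavenumber - wavenumber[1L]) / (wavenumber[length(wavenumber)] - wavenumber[1L])
  cbind(1, u, u * u)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
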