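# Internal helpers shared across modules.

mirdirect_abort <- function(message, class, ...) {
  abort(message, class = c(class, "mirdirect_error"), ...)
}

#' Conditions recognised in sample metadata
#' @keywords internal
#' @noRd
CONDITIONS <- c("tumor", "normal")

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state. A seed is mandatory for every stochastic operation in the package.
with_seed <- function(seed, expr) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    mirdirect_abort("a single integer `seed` is required for stochastic operations",
      class = "mirdirect_error_seed")
  }
  withr::with_seed(as.integer(seed), expr)
}

# Derive a stream of child seeds from one parent seed, kept within 32-bit
# integer range so they remain valid R seeds.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
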