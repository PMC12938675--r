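# Internal helpers shared across modules.

#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

# Derive a per-unit RNG stream seed from a master seed. Offsets are spaced by
# a prime so nested derivations (cohort -> subject -> channel) do not collide;
# result is kept inside the 32-bit signed range R requires of set.seed().
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 10007 * as.numeric(offset)) %% 2147483647L)
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a finite number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}

# Population variance (N denominator), used by Hjorth activity and the
# population moment conventions adopted throughout.
pop_var <- function(x) mean((x - mean(x))^2)

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a
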