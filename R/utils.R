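# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic child seed from a root seed and a stage/replicate offset,
# kept inside the 32-bit integer range R requires for set.seed().
derive_seed <- function(root, offset) {
  root <- as.numeric(root) %% 2147483647
  as.integer((root + 1000003 * as.numeric(offset)) %% 2147483647)
}

# Two-sided p-values, floored so they stay inside (0, 1].
p_from_z <- function(z) {
  pmax(2 * stats::pnorm(-abs(z)), 1e-300)
}

p_from_t <- function(t, df) {
  pmax(2 * stats::pt(-abs(t), df = df), 1e-300)
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(name, " must be a finite numeric scalar", call. = FALSE)
  }
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}
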