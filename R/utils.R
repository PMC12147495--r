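#' @keywords internal
"_PACKAGE"

# Abort with a classed condition so callers/tests can match on error class.
bv_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "bonevar_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

# Column-wise standardisation with training-set statistics only.
# Zero-variance columns are centred and left unscaled (scale set to 1) so
# constant features (e.g. empty LBP bins) do not produce NaN.
standardize_fit <- function(x) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  list(center = center, scale = scale)
}

standardize_apply <- function(x, st) {
  scale(x, center = st$center, scale = st$scale)[, , drop = FALSE]
}

# Derive a stream of child seeds from one root seed, kept inside 32-bit
# integer range so set.seed() never overflows.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(index)) %% 2147483587L) + 1L
}
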