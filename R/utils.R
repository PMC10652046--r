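# Small shared helpers.

# Deterministic 32-bit sub-seed derived from a base seed and an index path.
# Mixing stays within double-precision exact-integer range; results are in
# [1, 2^31 - 2] so they are always valid set.seed() inputs.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.numeric(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 69069 + (as.numeric(i) + 1) * 12345) %% 2147483647
  }
  as.integer(x %% 2147483646) + 1L
}
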