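# Internal helpers shared across modules.

# Deterministic polynomial hash of a non-negative integer vector, returned in
# [0, 2^31). All arithmetic stays below 2^53 so the result is exact in doubles
# and identical across platforms.
hash_ints <- function(x) {
  h <- 17
  for (v in x) {
    h <- (h * 31 + (as.numeric(v) %% 2147483647)) %% 2147483647
  }
  h
}

# Fold a hash to a fingerprint bit index in 1..nbits.
fold_bit <- function(h, nbits) (h %% nbits) + 1

# Derive a stream-specific child seed from a master seed; stays < 2^31.
child_seed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 48271 + hash_ints(utf8ToInt(tag))) %% 2147483647)
}

# round-half-up (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
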