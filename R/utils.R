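# Derive a reproducible child seed from a master seed and a counter.
# SplitMix-style integer hash, folded into [1, 2^31 - 2] so it is always a
# valid (32-bit) seed for set.seed().
derive_seed <- function(master, k) {
  stopifnot(is.numeric(master), is.numeric(k))
  z <- (as.double(master) * 2654435761 + as.double(k) * 40503 + 12345) %%
    2147483647
  as.integer(z %% 2147483645) + 1L
}

# Binomial sampler that tolerates sizes beyond .Machine$integer.max (R's
# rbinom returns NA there). Large sizes use the normal approximation to the
# binomial, whose error at such sizes is negligible next to sampling noise;
# results are clamped to [0, size] and rounded.
rbinom_large <- function(n, size, prob) {
  size <- as.double(size)
  out <- numeric(length(size))
  small <- size <= 2^31 - 1
  if (any(small))
    out[small] <- stats::rbinom(sum(small), size[small], prob)
  if (any(!small)) {
    m <- size[!small] * prob
    s <- sqrt(size[!small] * prob * (1 - prob))
    out[!small] <- pmin(pmax(round(stats::rnorm(sum(!small), m, s)), 0),
                        size[!small])
  }
  out
}
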