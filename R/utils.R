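# Internal numerical helpers shared across modules.

# Population standard deviation (divide by N, not N-1). Sample-entropy
# tolerances are defined against the series' own population sd.
pop_sd <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

# Count sign changes of a series, ignoring exact zeros: a crossing is a
# strict sign flip between consecutive non-zero samples.
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-1L] != s[-length(s)])
}

# Derive a reproducible substream seed from a base seed and a counter,
# kept within the 32-bit integer range.
derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) * 7919 + as.double(counter) * 104729) %% 2147483647)
}
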