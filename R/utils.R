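# Deterministic per-stage seed derivation from one top-level seed.
# Linear-congruential mixing, kept strictly below 2^31 - 1.
.deriveSeed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset) * 16807
  as.integer(s %% 2147483647) + 1L
}
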