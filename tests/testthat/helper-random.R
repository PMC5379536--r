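# Random profiles with controllable tie structure: rounding normal draws to
# `digits` decimals produces realistic tie multiplicities (heavier for fewer
# digits), mimicking saturated microarray intensities / zero-inflated counts.
random_tied_profile <- function(n, digits = sample(0:3, 1L)) {
  round(rnorm(n), digits)
}

# A random member-index set with 0 < n1 < N.
random_member_set <- function(n) {
  n1 <- sample(seq_len(n - 1L), 1L)
  sample(n, n1)
}
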