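# small shared fixtures, built in code at test time

uniform_volume <- function(value = 5, n = c(32L, 32L, 24L),
                           spacing = c(2.34, 2.34, 3.26)) {
  volume3d(array(value, dim = n), spacing)
}

gradient_volume <- function(n = c(32L, 32L, 24L),
                            spacing = c(2.34, 2.34, 3.26)) {
  a <- array(0, dim = n)
  for (k in seq_len(n[3])) a[, , k] <- 1 + 0.05 * (seq_len(n[1]) - 1) + 0.02 * (k - 1)
  volume3d(a, spacing)
}

table3_grids <- list(diq = c(2.34, 2.34, 3.26), dmi = c(2.34, 2.34, 2.8))
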