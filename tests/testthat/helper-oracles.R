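# Independent brute-force oracles and small fixture builders.

# Literal double-loop global Moran's I from a dense weight matrix.
brute_global_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    num <- num + W[i, j] * z[i] * z[j]
  (n / sum(W)) * num / sum(z^2)
}

# Literal per-cell local Moran's I (sample-variance denominator).
brute_local_moran <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  s2 <- sum(z^2) / (n - 1)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) acc <- acc + W[i, j] * z[j]
    out[i] <- z[i] / s2 * acc
  }
  out
}

# Dense weight matrix from a weight_matrix object (cells in w$cells order).
dense_weights <- function(w) {
  n <- length(w$cells)
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

# The 21-row published validation fixture.
validation_fixture <- function() aod_validation_data()

# A small LUT + geometry shared across inversion tests.
test_lut <- local({
  lut <- NULL
  function() {
    if (is.null(lut)) lut <<- build_lookup_table()
    lut
  }
})
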