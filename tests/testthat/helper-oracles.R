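# Independent brute-force oracles, deliberately written as plain double
# loops so they share no code with the package implementations.

brute_sorensen <- function(x, y) {
  num <- 0
  den <- 0
  for (i in seq_along(x)) {
    num <- num + abs(x[i] - y[i])
    den <- den + x[i] + y[i]
  }
  num / den
}

brute_morans_i <- function(values, w) {
  n <- length(values)
  z <- values - mean(values)
  num <- 0
  W <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      num <- num + w[i, j] * z[i] * z[j]
      W <- W + w[i, j]
    }
  }
  (n / W) * num / sum(z^2)
}

brute_mantel_r <- function(a, b) {
  va <- c()
  vb <- c()
  n <- nrow(a)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      va <- c(va, a[i, j])
      vb <- c(vb, b[i, j])
    }
  }
  cor(va, vb)
}

# Small random simplex compositions for property tests
random_composition <- function(n_rows, n_taxa) {
  m <- matrix(rexp(n_rows * n_taxa), n_rows)
  m / rowSums(m)
}
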