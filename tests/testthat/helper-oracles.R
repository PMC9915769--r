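# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain summation, enumeration, Monte-Carlo.

# Exact binomial upper tail P(X >= k) by direct summation.
binom_tail_oracle <- function(k, N, p) {
  if (k <= 0) return(1)
  i <- k:N
  sum(choose(N, i) * p^i * (1 - p)^(N - i))
}

# Exact hypergeometric upper tail by enumerating all draws of size n from a
# universe of size N with K marked elements (feasible for N <= 12).
hyper_tail_oracle <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}

# Monte-Carlo SASA: random points on each atom's expanded sphere, same
# boundary tie-break as the implementation (lower-indexed atom claims exact
# boundary points).
mc_sasa_oracle <- function(atoms, probe = 1.4, n_mc = 1e5) {
  n <- nrow(atoms)
  er <- atoms$radius + probe
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  eps <- 1e-9
  total <- 0
  for (i in seq_len(n)) {
    v <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    pts <- sweep(v * er[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_mc)
    for (j in seq_len(n)) {
      if (j == i) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
            (pts[, 3] - xyz[j, 3])^2
      lim <- er[j]^2
      exposed <- exposed & !(d2 < lim - eps | (abs(d2 - lim) <= eps & j < i))
    }
    total <- total + mean(exposed) * 4 * pi * er[i]^2
  }
  total
}

# Hamming distance between equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Random peptide of length n.
random_peptide <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
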