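# Independent oracles, coded without reference to the package internals.

# Score-only global alignment with affine gaps (Gotoh), gap of length L
# costing open + L * ext. Quadratic-space, plain R.
nw_score_oracle <- function(a, b, mat, open = 10, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + ext * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + ext * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             X[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Literal per-residue Markov substitution process: N ~ Poisson(lambda) jump
# events, each replacing the residue uniformly among the other 19.
# Returns the fraction of residues differing from the original.
markov_diff_fraction_oracle <- function(lambda, n_residues) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  orig <- sample(aa, n_residues, replace = TRUE)
  cur <- orig
  k <- rpois(n_residues, lambda)
  remaining <- k
  while (any(remaining > 0L)) {
    idx <- which(remaining > 0L)
    for (i in idx) cur[i] <- sample(setdiff(aa, cur[i]), 1L)
    remaining[idx] <- remaining[idx] - 1L
  }
  mean(cur != orig)
}

# Closed-form expected differing fraction of the 20-state uniform-replacement
# jump chain after Poisson(lambda) events (derived from the chain's
# eigenstructure: P(same) = 1/20 + (19/20) exp(-20 lambda / 19)).
expected_diff_fraction <- function(lambda) {
  (19 / 20) * (1 - exp(-20 * lambda / 19))
}

# Hypergeometric upper/lower tails by direct summation of choose() products.
hyper_tail_oracle <- function(k, K, N, n) {
  j_min <- max(0L, n + K - N)
  j_max <- min(n, K)
  pj <- function(j) choose(K, j) * choose(N - K, n - j) / choose(N, n)
  js <- j_min:j_max
  list(p_enrich = sum(vapply(js[js >= k], pj, numeric(1))),
       p_deplete = sum(vapply(js[js <= k], pj, numeric(1))))
}

# Brute-force enumeration of every size-n draw from a background of size N.
hyper_upper_enumeration <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  in_cat <- colSums(draws <= K)  # category = elements 1..K
  mean(in_cat >= k)
}
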