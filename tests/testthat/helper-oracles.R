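# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately share no code with the implementation.

# O(n^2) pairwise concordance count; ties score one half.
concordance_auc <- function(labels, scores) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# Straight-line evaluation of the sequence-order correlation factors
# theta_j = 1/(N-j) * sum_i mean_k (h_k(r_i) - h_k(r_{i+j}))^2 over the
# standardized property scales, for the de-padded residue string.
brute_theta <- function(residues, lambda) {
  props <- rbind(
    c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
      H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
      P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
      W = 0.81, Y = 0.26),
    c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0, H = -0.5,
      I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2, P = 0.0, Q = 0.2,
      R = 3.0, S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3),
    c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
      K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
      T = 45, V = 43, W = 130, Y = 107))
  for (k in 1:3) {
    v <- props[k, ]
    props[k, ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  }
  N <- length(residues)
  vapply(seq_len(lambda), function(j) {
    s <- 0
    for (i in seq_len(N - j)) {
      a <- residues[i]; b <- residues[i + j]
      s <- s + mean((props[, a] - props[, b])^2)
    }
    s / (N - j)
  }, numeric(1))
}

# Shannon entropy (bits) of a label vector, by direct counting.
brute_entropy <- function(y) {
  p <- table(y) / length(y)
  -sum(p * log2(p))
}

# All-pairs ungapped identity, X never matching; equal-length strings.
brute_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  sum(ca == cb & ca != "X") / length(ca)
}

# Random fragment with K center over the 20 standard residues.
random_fragment <- function(window) {
  n <- (window - 1L) %/% 2L
  aa <- sample(aa_standard(), 2L * n, replace = TRUE)
  paste(c(aa[seq_len(n)], "K", aa[n + seq_len(n)]), collapse = "")
}
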