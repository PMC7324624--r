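# Alphabet and physicochemical constants shared across encoders.

#' Standard amino-acid alphabets
#'
#' `aa_standard()` returns the 20 standard one-letter amino-acid codes in
#' alphabetical order; `aa_alphabet()` appends the padding symbol `"X"` used
#' for fragments that run past a protein terminus.
#'
#' @return Character vector of length 20 or 21.
#' @export
aa_standard <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' @rdname aa_standard
#' @export
aa_alphabet <- function() c(aa_standard(), "X")

# Classical property scales used by the pseudo-amino-acid composition
# descriptor: hydrophobicity, hydrophilicity (Hopp-Woods) and side-chain
# mass of the 20 standard residues.
paac_properties <- function() {
  aa <- aa_standard()
  hb <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19, G = 0.48,
          H = -0.40, I = 1.38, K = -1.50, L = 1.06, M = 0.64, N = -0.78,
          P = 0.12, Q = -0.85, R = -2.53, S = -0.18, T = -0.05, V = 1.08,
          W = 0.81, Y = 0.26)
  hl <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5, G = 0.0,
          H = -0.5, I = -1.8, K = 3.0, L = -1.8, M = -1.3, N = 0.2,
          P = 0.0, Q = 0.2, R = 3.0, S = 0.3, T = -0.4, V = -1.5,
          W = -3.4, Y = -2.3)
  sm <- c(A = 15, C = 47, D = 59, E = 73, F = 91, G = 1, H = 82, I = 57,
          K = 73, L = 57, M = 75, N = 58, P = 42, Q = 72, R = 101, S = 31,
          T = 45, V = 43, W = 130, Y = 107)
  rbind(hydrophobicity = hb[aa], hydrophilicity = hl[aa], sidechain_mass = sm[aa])
}

# Kyte-Doolittle hydropathy, used as a published anchor scale in the
# synthetic property table.
kyte_doolittle <- function() {
  c(A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
    I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
    R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)[aa_standard()]
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# split a peptide string into single characters
chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
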