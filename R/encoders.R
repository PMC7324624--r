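# Encoders: the five numeric representations of a lysine-centered fragment
# (AAC, one-hot, PAAC, AAindex property matrix, PSSM profile), plus
# information-gain property selection and PSSM parsing.
#
# Dimensional contracts for a window of size L = 2n + 1:
#   AAC      21-vector              (center excluded from the counts)
#   one-hot  (L-1) x 21 matrix      (center row dropped)
#   PAAC     (21 + lambda)-vector
#   AAindex  (L-1) x k matrix       (center row dropped)
#   PSSM     L x 20 matrix          (center included, fed "as is")

frag_check <- function(fragment) {
  r <- chars(fragment)
  L <- length(r)
  if (L < 3L || L %% 2L == 0L)
    stop("fragment length must be odd and >= 3, got ", L)
  if (r[(L + 1L) %/% 2L] != "K")
    stop("fragment center must be 'K'")
  bad <- setdiff(unique(r), aa_alphabet())
  if (length(bad)) stop("unknown residues: ", paste(bad, collapse = ", "))
  r
}

flank_residues <- function(fragment) {
  r <- frag_check(fragment)
  r[-((length(r) + 1L) %/% 2L)]
}

#' Amino-acid composition of the fragment flanks
#'
#' Residue frequencies over the 21-letter alphabet (20 standard amino acids
#' plus the padding symbol `"X"`), computed on the `2n` residues surrounding
#' the central lysine; the site itself is not counted. Entries sum to 1.
#'
#' @param fragment Lysine-centered fragment string of odd length.
#' @return Named numeric vector of length 21.
#' @export
encode_aac <- function(fragment) {
  fl <- flank_residues(fragment)
  counts <- table(factor(fl, levels = aa_alphabet()))
  v <- as.numeric(counts) / length(fl)
  names(v) <- aa_alphabet()
  v
}

#' One-hot encoding of the fragment flanks
#'
#' Binary matrix with one row per non-center position (in sequence order) and
#' one column per letter of the 21-letter alphabet; each row carries a single
#' 1 at its residue's column. The invariant central lysine is excluded.
#'
#' @inheritParams encode_aac
#' @return `(2n) x 21` binary matrix.
#' @export
encode_onehot <- function(fragment) {
  fl <- flank_residues(fragment)
  m <- matrix(0, nrow = length(fl), ncol = 21L,
              dimnames = list(NULL, aa_alphabet()))
  m[cbind(seq_along(fl), match(fl, aa_alphabet()))] <- 1
  m
}

#' Pseudo-amino-acid composition
#'
#' Composition over the 21-letter alphabet augmented with `lambda`
#' sequence-order correlation factors built from standardized hydrophobicity,
#' hydrophilicity and side-chain mass. Property scales are standardized over
#' the 20 standard residues; `"X"` carries no properties and is skipped in the
#' correlation sums (it still counts in the composition). The full vector is
#' normalized to sum to 1.
#'
#' The j-th correlation factor averages the mean squared property difference
#' between residues j apart along the de-padded fragment.
#'
#' @inheritParams encode_aac
#' @param lambda Number of sequence-order correlation tiers; default 13.
#' @param w Weight of the correlation block relative to composition;
#'   default 0.05.
#' @return Named numeric vector of length `21 + lambda`.
#' @export
encode_paac <- function(fragment, lambda = 13L, w = 0.05) {
  r <- frag_check(fragment)
  core <- r[r != "X"]
  if (length(core) < lambda + 1L)
    stop("PAAC with lambda = ", lambda, " needs at least ", lambda + 1L,
         " non-X residues (minimum window ", 2L * lambda + 1L,
         " for unpadded fragments); fragment has ", length(core))
  props <- paac_properties()
  zp <- t(apply(props, 1L, function(v) {
    (v - mean(v)) / sqrt(sum((v - mean(v))^2) / length(v))
  }))
  idx <- match(core, aa_standard())
  theta <- vapply(seq_len(lambda), function(j) {
    i <- seq_len(length(core) - j)
    d <- (zp[, idx[i], drop = FALSE] - zp[, idx[i + j], drop = FALSE])^2
    mean(colMeans(d))
  }, numeric(1))
  comp <- table(factor(r, levels = aa_alphabet()))
  f <- as.numeric(comp) / length(r)
  den <- sum(f) + w * sum(theta)
  out <- c(f / den, w * theta / den)
  names(out) <- c(aa_alphabet(), paste0("theta", seq_len(lambda)))
  out
}

#' Synthetic physicochemical property table
#'
#' A deterministic, self-contained stand-in for a catalogue of amino-acid
#' property scales: published anchor scales (Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, side-chain mass) followed by seeded synthetic
#' scales up to `n_properties` rows. Values are complete (no missing entries)
#' and stable across sessions, so property selection is reproducible. The
#' synthetic rows do not describe real biochemistry; they exist to exercise
#' the property-selection and encoding pathways at full catalogue scale.
#'
#' @param n_properties Number of property rows; default 531, the size of a
#'   post-filter property catalogue.
#' @return `n_properties x 20` numeric matrix; rows named by property ID,
#'   columns by residue.
#' @export
synthetic_aaindex <- function(n_properties = 531L) {
  anchors <- rbind(KYTJ820101 = kyte_doolittle(),
                   HOPT810101 = paac_properties()["hydrophilicity", ],
                   SCMASS0001 = paac_properties()["sidechain_mass", ])
  colnames(anchors) <- aa_standard()
  if (n_properties <= nrow(anchors))
    return(anchors[seq_len(n_properties), , drop = FALSE])
  n_syn <- n_properties - nrow(anchors)
  syn <- with_seed(531L, {
    matrix(round(stats::rnorm(n_syn * 20L), 3), nrow = n_syn, ncol = 20L)
  })
  rownames(syn) <- sprintf("SYN%07d", seq_len(n_syn))
  colnames(syn) <- aa_standard()
  rbind(anchors, syn)
}

#' Parse an AAindex1 flat file
#'
#' Reads `H`/`I` record blocks of the AAindex1 format: the `H` line names the
#' property, the `I` line is followed by two rows of ten values in the order
#' A R N D C Q E G H I / L K M F P S T W Y V. Entries with missing (`NA`)
#' values are dropped.
#'
#' @param path Path to an AAindex1-format text file.
#' @return Numeric matrix, one row per complete property, columns the 20
#'   standard residues in alphabetical order.
#' @export
parse_aaindex1 <- function(path) {
  lines <- readLines(path)
  order20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  ids <- character(0); rows <- list()
  i <- 1L; id <- NA_character_
  while (i <= length(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "H ")) id <- trimws(sub("^H ", "", ln))
    if (startsWith(ln, "I ")) {
      if (i + 2L > length(lines))
        stop("truncated I record at line ", i)
      vals <- suppressWarnings(as.numeric(unlist(
        strsplit(trimws(lines[i + 1:2]), "\\s+"))))
      if (length(vals) != 20L)
        stop("expected 20 values after I record at line ", i,
             ", got ", length(vals))
      if (!anyNA(vals)) {
        names(vals) <- order20
        ids <- c(ids, id)
        rows[[length(rows) + 1L]] <- vals[aa_standard()]
      }
      i <- i + 2L
    }
    i <- i + 1L
  }
  if (!length(rows)) stop("no complete property records found in ", path)
  m <- do.call(rbind, rows)
  rownames(m) <- ids
  m
}

#' Select physicochemical properties by summed information gain
#'
#' For every property in the table, the property value of the residue at each
#' non-center position is discretized (median split into `bins` quantile bins
#' by default) and the information gain of the class label given the bin,
#' `IG = H(label) - H(label | bin)` in bits, is computed per position and
#' summed over positions. The top `k` properties by summed gain are returned;
#' ties break by property ID. Padding residues carry no property value and are
#' excluded position-wise.
#'
#' @param fragments Character vector of equal-length fragments.
#' @param labels Binary labels, both classes present.
#' @param k Number of properties to retain.
#' @param table Property table as from [synthetic_aaindex()].
#' @param bins Number of quantile bins for discretization; default 2.
#' @return Object of class `property_selection`: list with `ids`, `gains`
#'   (summed IG, non-increasing), `k`, and `values` (the `k x 20` sub-table
#'   used by [encode_aaindex()]).
#' @export
select_properties_by_ig <- function(fragments, labels, k,
                                    table = synthetic_aaindex(), bins = 2L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (k > nrow(table))
    stop("k = ", k, " exceeds the ", nrow(table), " available properties")
  res <- t(vapply(fragments, flank_residues,
                  character(nchar(fragments[[1]]) - 1L)))
  ridx <- matrix(match(res, aa_standard()), nrow = nrow(res))  # X -> NA
  gains <- vapply(seq_len(nrow(table)), function(p) {
    vals <- matrix(table[p, ][ridx], nrow = nrow(ridx))
    sum(vapply(seq_len(ncol(vals)), function(pos) {
      v <- vals[, pos]; ok <- !is.na(v)
      if (!any(ok)) return(0)
      position_ig(v[ok], labels[ok], bins)
    }, numeric(1)))
  }, numeric(1))
  ord <- order(-gains, rownames(table))
  keep <- ord[seq_len(k)]
  structure(list(ids = rownames(table)[keep], gains = gains[keep], k = k,
                 values = table[keep, , drop = FALSE]),
            class = "property_selection")
}

entropy_bits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# IG of the label given a quantile-binned numeric feature at one position.
position_ig <- function(v, y, bins) {
  if (length(unique(y)) < 2L) return(0)
  qs <- unique(stats::quantile(v, probs = seq_len(bins - 1L) / bins,
                               names = FALSE, type = 1L))
  b <- findInterval(v, qs, left.open = TRUE)
  h_y <- entropy_bits(table(y))
  h_cond <- 0
  for (lev in unique(b)) {
    sel <- b == lev
    h_cond <- h_cond + mean(sel) * entropy_bits(table(y[sel]))
  }
  h_y - h_cond
}

#' @export
print.property_selection <- function(x, ...) {
  cat("property_selection: k =", x$k, "| top gains:",
      paste(sprintf("%s=%.3f", utils::head(x$ids, 3),
                    utils::head(x$gains, 3)), collapse = ", "), "\n")
  invisible(x)
}

#' Encode a fragment with selected physicochemical properties
#'
#' One row per non-center position, one column per selected property; entries
#' are the raw table values of the residue at that position. Padding (`"X"`)
#' rows are all zero. Optionally z-scales each property column over the 20
#' residues for training stability.
#'
#' @inheritParams encode_aac
#' @param selection A `property_selection` from [select_properties_by_ig()].
#' @param zscale If `TRUE`, per-property standardization before lookup.
#' @return `(2n) x k` numeric matrix.
#' @export
encode_aaindex <- function(fragment, selection, zscale = FALSE) {
  stopifnot(inherits(selection, "property_selection"))
  vals <- selection$values
  if (zscale) vals <- t(apply(vals, 1L, function(v) (v - mean(v)) / stats::sd(v)))
  fl <- flank_residues(fragment)
  idx <- match(fl, aa_standard())  # X -> NA
  m <- matrix(0, nrow = length(fl), ncol = nrow(vals),
              dimnames = list(NULL, rownames(vals)))
  ok <- !is.na(idx)
  m[ok, ] <- t(vals[, idx[ok], drop = FALSE])
  m
}

# Column order used by PSI-BLAST ASCII profiles.
pssm_col_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Parse a PSI-BLAST ASCII PSSM profile
#'
#' Reads the `-out_ascii_pssm` text format and extracts the first 20 score
#' columns (position-specific log-odds) per residue row. Columns are reordered
#' to the alphabetical residue order used throughout the package.
#'
#' @param path Path to the ASCII profile, or a character vector of its lines.
#' @param window_slice Optional integer vector of row (residue position)
#'   indices to keep, e.g. `5:35` for a 31-residue window.
#' @return `L x 20` integer matrix with a `residues` attribute giving the
#'   profile's residue column.
#' @export
parse_pssm_profile <- function(path, window_slice = NULL) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else path
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D\\s+C\\s+Q", lines)
  if (!length(hdr)) stop("no PSSM header line (A R N D C Q ...) found")
  hdr <- hdr[[1L]]
  rows <- list(); res <- character(0)
  for (i in seq(hdr + 1L, length(lines))) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) break
    tok <- strsplit(ln, "\\s+")[[1]]
    if (is.na(suppressWarnings(as.integer(tok[[1]])))) break
    if (length(tok) < 22L)
      stop("malformed PSSM row at line ", i, ": expected >= 22 fields, got ",
           length(tok))
    sc <- suppressWarnings(as.integer(tok[3:22]))
    if (anyNA(sc)) stop("non-integer score in PSSM row at line ", i)
    rows[[length(rows) + 1L]] <- sc
    res <- c(res, tok[[2]])
  }
  if (!length(rows)) stop("no PSSM data rows found after line ", hdr)
  m <- do.call(rbind, rows)
  colnames(m) <- pssm_col_order
  m <- m[, aa_standard(), drop = FALSE]
  if (!is.null(window_slice)) {
    if (any(window_slice < 1L) || any(window_slice > nrow(m)))
      stop("window_slice out of range: profile has ", nrow(m), " rows")
    res <- res[window_slice]
    m <- m[window_slice, , drop = FALSE]
  }
  attr(m, "residues") <- res
  m
}

#' Substitution-matrix surrogate profile
#'
#' When PSI-BLAST profiles are unavailable, builds an `L x 20` profile whose
#' row for residue `a` is the BLOSUM62 substitution row of `a`; padding rows
#' are zero. Marked as a surrogate via the `surrogate` attribute — it encodes
#' residue identity through substitution scores, not true evolutionary
#' conservation.
#'
#' @inheritParams encode_aac
#' @return `L x 20` numeric matrix (center row included).
#' @export
pseudo_pssm <- function(fragment) {
  r <- frag_check(fragment)
  b62 <- blosum62_20()
  m <- matrix(0, nrow = length(r), ncol = 20L,
              dimnames = list(NULL, aa_standard()))
  ok <- r != "X"
  m[ok, ] <- b62[r[ok], , drop = FALSE]
  attr(m, "surrogate") <- TRUE
  m
}

blosum62_env <- new.env(parent = emptyenv())
blosum62_20 <- function() {
  if (is.null(blosum62_env$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_env$m <- e$BLOSUM62[aa_standard(), aa_standard()]
  }
  blosum62_env$m
}

#' Encode many fragments with one feature
#'
#' Dispatcher over the five encoders. Vector features (`AAC`, `PAAC`) return a
#' samples-by-dimension matrix; matrix features (`ONEHOT`, `AAINDEX`, `PSSM`)
#' return a list of per-fragment matrices sharing one shape.
#'
#' @param fragments Character vector of equal-length fragments.
#' @param feature One of `"AAC"`, `"ONEHOT"`, `"PAAC"`, `"AAINDEX"`, `"PSSM"`.
#' @param selection `property_selection`, required for `AAINDEX`.
#' @param pssm_fun Function mapping a fragment to its `L x 20` profile;
#'   defaults to [pseudo_pssm()]. Supply a closure over parsed PSI-BLAST
#'   profiles to use real evolutionary information.
#' @param ... Extra arguments passed to the underlying encoder.
#' @return Matrix or list of matrices; see Details.
#' @export
encode_fragments <- function(fragments,
                             feature = c("AAC", "ONEHOT", "PAAC", "AAINDEX", "PSSM"),
                             selection = NULL, pssm_fun = pseudo_pssm, ...) {
  feature <- match.arg(feature)
  switch(feature,
    AAC = t(vapply(fragments, encode_aac, numeric(21L))),
    PAAC = {
      d <- length(encode_paac(fragments[[1]], ...))
      t(vapply(fragments, function(f) encode_paac(f, ...), numeric(d)))
    },
    ONEHOT = lapply(fragments, encode_onehot),
    AAINDEX = {
      if (is.null(selection)) stop("AAINDEX encoding needs a property_selection")
      lapply(fragments, encode_aaindex, selection = selection, ...)
    },
    PSSM = lapply(fragments, pssm_fun)
  )
}

#' Export an encoded feature to plain text
#'
#' Vectors are written as one-row CSV; matrices as whitespace-delimited dense
#' text with a shape comment, for inspection and interchange.
#'
#' @param x Numeric vector or matrix from an encoder.
#' @param path Output file path.
#' @export
export_feature <- function(x, path) {
  if (is.matrix(x)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("# shape %d %d", nrow(x), ncol(x)), con)
    utils::write.table(x, con, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(t(as.matrix(x)), path, sep = ",", row.names = FALSE,
                       col.names = names(x), quote = FALSE)
  }
  invisible(path)
}
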