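# Fragment construction: fixed-length lysine-centered peptide windows,
# redundancy reduction, and train/test splitting.

#' Extract a lysine-centered peptide fragment
#'
#' Cuts a window of `2n + 1` residues centered on `position` from a protein
#' sequence. Positions running past either terminus are filled with the dummy
#' residue `"X"`, so the returned fragment always has length `2n + 1` with the
#' annotated residue at its center.
#'
#' @param sequence Protein sequence as a single character string.
#' @param position 1-based index of the central residue.
#' @param n Half-width of the window; the fragment has `2n + 1` residues.
#' @param strict If `TRUE` (training mode) a non-lysine center is an error;
#'   if `FALSE` (scan mode) it produces a warning and `NA_character_`.
#' @return A character string of length `2n + 1`.
#' @examples
#' extract_fragment("MKSTE", 2, 2)    # "XMKST"
#' extract_fragment("AAAKAAA", 4, 3)  # "AAAKAAA"
#' @export
extract_fragment <- function(sequence, position, n, strict = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L, n >= 1L)
  len <- nchar(sequence)
  if (position < 1L || position > len)
    stop("position ", position, " out of range for sequence of length ", len)
  center <- substr(sequence, position, position)
  if (center != "K") {
    if (strict)
      stop("residue at position ", position, " is '", center,
           "', not 'K'; use strict = FALSE to skip")
    warning("skipping non-K center at position ", position)
    return(NA_character_)
  }
  lo <- position - n
  hi <- position + n
  pad_lo <- max(0L, 1L - lo)
  pad_hi <- max(0L, hi - len)
  core <- substr(sequence, max(1L, lo), min(len, hi))
  paste0(strrep("X", pad_lo), core, strrep("X", pad_hi))
}

#' Enumerate lysine positions in a protein
#'
#' @param sequence Protein sequence string.
#' @return Integer vector of 1-based positions of every `K`, ascending.
#' @export
enumerate_lysines <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  which(chars(sequence) == "K")
}

#' Pairwise ungapped sequence identity
#'
#' Positional identity between two sequences: matching positions divided by
#' the shorter length (equal to the common length for fragments). The padding
#' symbol `"X"` never counts as a match.
#'
#' @param a,b Sequence strings.
#' @return Identity fraction in `[0, 1]`.
#' @export
seq_identity <- function(a, b) {
  ca <- chars(a); cb <- chars(b)
  m <- min(length(ca), length(cb))
  if (m == 0L) return(0)
  ca <- ca[seq_len(m)]; cb <- cb[seq_len(m)]
  sum(ca == cb & ca != "X") / m
}

#' Greedy redundancy reduction at a sequence-identity threshold
#'
#' Scans sequences in input order and retains a sequence only if its identity
#' to every previously retained sequence is below `threshold`. This is the
#' built-in, alignment-free analogue of clustering at 40% identity used to
#' de-bias training sets.
#'
#' @param sequences Character vector of sequences (typically equal-length
#'   fragments).
#' @param threshold Identity threshold in `(0, 1]`; default 0.40.
#' @return Integer vector of retained (1-based) indices, in input order.
#' @export
reduce_redundancy <- function(sequences, threshold = 0.40) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(sequences) == 0L) return(integer(0))
  kept <- integer(0)
  for (i in seq_along(sequences)) {
    ok <- TRUE
    for (j in kept) {
      if (seq_identity(sequences[[i]], sequences[[j]]) >= threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  kept
}

#' Remove negatives resembling positives
#'
#' Drops every negative fragment whose identity to at least one positive
#' fragment reaches `threshold`; the positive set is never modified. Used to
#' eliminate cross-class redundancy between the two classes.
#'
#' @param positives,negatives Character vectors of equal-length fragments.
#' @param threshold Identity threshold, default 0.40.
#' @return Integer vector of retained negative indices.
#' @export
cross_class_filter <- function(positives, negatives, threshold = 0.40) {
  if (length(negatives) == 0L) return(integer(0))
  if (length(positives) == 0L) return(seq_along(negatives))
  keep <- vapply(negatives, function(ng) {
    !any(vapply(positives, function(ps) seq_identity(ng, ps) >= threshold,
                logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  which(keep)
}

#' Stratified train/test split
#'
#' Reproducibly partitions samples into train and test sets. The split is
#' stratified by label: each class is shuffled and divided at `ratio`
#' separately, so class proportions are preserved within one item.
#'
#' @param labels Binary (0/1) label vector; the split is over its indices.
#' @param ratio Training fraction in `(0, 1)`.
#' @param seed Integer seed; the same seed reproduces the same partition.
#' @return Object of class `dataset_split`: list with integer index vectors
#'   `$train` and `$test`, plus `$ratio` and `$seed`.
#' @export
split_dataset <- function(labels, ratio, seed) {
  stopifnot(ratio > 0, ratio < 1)
  labels <- as.integer(labels)
  tab <- table(labels)
  if (any(tab < 2L))
    stop("each class needs at least 2 members; got ",
         paste(names(tab), tab, sep = ":", collapse = ", "))
  train <- integer(0)
  with_seed(seed, {
    for (lv in names(tab)) {
      idx <- sample(which(labels == as.integer(lv)))
      n_tr <- round(length(idx) * ratio)
      n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
      train <- c(train, idx[seq_len(n_tr)])
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_along(labels), train),
                 ratio = ratio, seed = seed),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("dataset_split: ", length(x$train), " train / ", length(x$test),
      " test (ratio ", x$ratio, ", seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Read a protein FASTA file
#'
#' Multi-record FASTA with wrapped lines; terminal and internal `*` stop
#' symbols are stripped. Names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  seqs <- gsub("*", "", as.character(aas), fixed = TRUE)
  names(seqs) <- sub("\\s.*$", "", names(aas))
  seqs
}

#' Read a site annotation table
#'
#' CSV or TSV (sniffed from the header line) with columns `protein_id`,
#' `position` (1-based) and `label` (0/1).
#'
#' @param path Path to the table.
#' @return `data.frame` with the three columns, types enforced.
#' @export
read_site_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "label")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  df$position <- as.integer(df$position)
  df$label <- as.integer(df$label)
  if (!all(df$label %in% c(0L, 1L))) stop("labels must be 0/1")
  df[need]
}

#' Build a fragment table from sequences and site annotations
#'
#' Joins a site table against named sequences and extracts one lysine-centered
#' fragment per annotated site.
#'
#' @param sequences Named character vector of protein sequences.
#' @param sites Site table as from [read_site_table()].
#' @param n Window half-width.
#' @param strict Passed to [extract_fragment()].
#' @return `data.frame` with columns `protein_id`, `position`, `label`,
#'   `fragment`; scan-mode skips are dropped.
#' @export
build_fragments <- function(sequences, sites, n, strict = TRUE) {
  missing <- setdiff(unique(sites$protein_id), names(sequences))
  if (length(missing))
    stop("sequences missing for: ", paste(utils::head(missing, 5), collapse = ", "))
  frag <- mapply(function(id, pos) {
    extract_fragment(sequences[[id]], pos, n, strict = strict)
  }, sites$protein_id, sites$position, USE.NAMES = FALSE)
  out <- data.frame(protein_id = sites$protein_id, position = sites$position,
                    label = sites$label, fragment = frag,
                    stringsAsFactors = FALSE)
  out[!is.na(out$fragment), , drop = FALSE]
}
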