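# Synthetic data: labeled fragments and whole annotated proteomes with
# controllable position-specific residue enrichment, so the entire pipeline
# is trainable and testable with no external data.

#' Position-specific motif specification
#'
#' Describes how positive-class fragments deviate from the background
#' composition: for chosen center-relative offsets, named residues receive an
#' excess probability (negative values deplete). At each offset the specified
#' residues take `background + excess` (clipped at 0) and the unspecified
#' residues share the remaining mass in proportion to the background, so the
#' per-position distribution always sums to 1.
#'
#' @param offsets Named list: names are center-relative offsets (e.g. `"-1"`,
#'   `"1"`), values are named numeric vectors of per-residue excess
#'   probability. Empty list = no signal (null motif).
#' @param background Background composition over the 20 standard residues;
#'   default uniform.
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(offsets = list(), background = NULL) {
  if (is.null(background))
    background <- stats::setNames(rep(1 / 20, 20), aa_standard())
  stopifnot(abs(sum(background) - 1) < 1e-8,
            setequal(names(background), aa_standard()))
  for (off in names(offsets)) {
    ex <- offsets[[off]]
    if (!all(names(ex) %in% aa_standard()))
      stop("unknown residues in motif at offset ", off)
    # validity: adjusted specified mass must leave room for the rest
    if (sum(pmax(background[names(ex)] + ex, 0)) >= 1)
      stop("motif at offset ", off, " leaves no probability mass for ",
           "unspecified residues")
  }
  structure(list(offsets = offsets, background = background[aa_standard()]),
            class = "motif_spec")
}

#' Qualitative malonylation-flank motif
#'
#' Default positive-class signal emulating the mammalian pattern around
#' malonylated lysines: lysine enriched across many flank offsets, glutamate
#' enriched proximally, leucine depleted in the mid-flank. `effect` scales
#' all excesses linearly (0 = null motif).
#'
#' @param effect Effect scale; 1 is a moderate, qualitatively realistic
#'   signal, 2 a strong one.
#' @param background Passed to [motif_spec()].
#' @return A `motif_spec`.
#' @export
default_motif <- function(effect = 1, background = NULL) {
  if (effect == 0) return(motif_spec(background = background))
  off <- list()
  for (o in c(-(8:1), 1:8)) off[[as.character(o)]] <- c(K = 0.10 * effect)
  for (o in c(-(3:1), 1:3))
    off[[as.character(o)]] <- c(off[[as.character(o)]], E = 0.12 * effect)
  for (o in c(-(6:4), 4:6))
    off[[as.character(o)]] <- c(off[[as.character(o)]], L = -0.04 * effect)
  motif_spec(off, background = background)
}

# Per-position residue distribution after applying the motif at one offset.
position_probs <- function(motif, offset) {
  bg <- motif$background
  ex <- motif$offsets[[as.character(offset)]]
  if (is.null(ex)) return(bg)
  p <- bg
  p[names(ex)] <- pmax(bg[names(ex)] + ex, 0)
  rest <- setdiff(names(bg), names(ex))
  p[rest] <- bg[rest] / sum(bg[rest]) * (1 - sum(p[names(ex)]))
  p
}

#' Generate labeled lysine-centered fragments
#'
#' Positives draw each flank position from the motif-adjusted distribution at
#' that offset; negatives draw every position from the background. The center
#' is fixed to `K` in both classes. Deterministic given `seed`.
#'
#' @param n_pos,n_neg Class sizes (>= 1).
#' @param window Odd window size `2n + 1`.
#' @param motif A `motif_spec`; default [default_motif()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `fragment` and `label` (positives
#'   first).
#' @export
generate_fragments <- function(n_pos, n_neg, window, motif = default_motif(),
                               seed = 1L) {
  stopifnot(n_pos >= 1L, n_neg >= 1L, window %% 2L == 1L, window >= 3L,
            inherits(motif, "motif_spec"))
  n <- (window - 1L) %/% 2L
  offsets <- c(-(n:1), 1:n)
  with_seed(seed, {
    draw_class <- function(nsamp, probs_by_pos) {
      cols <- lapply(probs_by_pos, function(p)
        sample(aa_standard(), nsamp, replace = TRUE, prob = p))
      m <- do.call(cbind, cols)
      apply(cbind(m[, seq_len(n), drop = FALSE], "K",
                  m[, n + seq_len(n), drop = FALSE]), 1L, paste, collapse = "")
    }
    pos <- draw_class(n_pos, lapply(offsets, position_probs, motif = motif))
    neg <- draw_class(n_neg, rep(list(motif$background), 2L * n))
    data.frame(fragment = c(pos, neg),
               label = rep(c(1L, 0L), c(n_pos, n_neg)),
               stringsAsFactors = FALSE)
  })
}

#' Generate an annotated synthetic proteome
#'
#' Random background proteins with implanted, annotated lysine sites:
#' annotated positions are spaced at least one window apart, set to `K`, and
#' positive sites (at `site_rate`) have their flanks overwritten with
#' motif-adjusted draws. Emits exactly the containers the fragment module
#' reads.
#'
#' @param n_proteins Number of proteins.
#' @param length_range Two-element protein length range (>= `window`).
#' @param site_rate Probability an annotated site is positive; default 0.06,
#'   a realistic class imbalance for this modification.
#' @param motif A `motif_spec`.
#' @param window Window used to implant and report fragments.
#' @param seed Integer seed.
#' @return List with `sequences` (named character), `sites` (data.frame
#'   `protein_id`, `position`, `label`) and `fragments` (the implanted
#'   fragments, as re-extracted from the final sequences).
#' @export
generate_annotated_proteome <- function(n_proteins, length_range = c(200, 400),
                                        site_rate = 0.06,
                                        motif = default_motif(), window = 31L,
                                        seed = 1L) {
  stopifnot(length_range[1] >= window, inherits(motif, "motif_spec"))
  n <- (window - 1L) %/% 2L
  offsets <- c(-(n:1), 1:n)
  seqs <- character(n_proteins)
  sites <- list()
  with_seed(seed, {
    for (i in seq_len(n_proteins)) {
      len <- sample(length_range[1]:length_range[2], 1L)
      aa <- sample(aa_standard(), len, replace = TRUE,
                   prob = motif$background)
      # annotated sites, spaced >= window so motif implants never collide
      cand <- seq(n + 1L, len - n)
      pos_sel <- integer(0); avail <- cand
      while (length(avail)) {
        p <- avail[sample.int(length(avail), 1L)]
        pos_sel <- c(pos_sel, p)
        avail <- avail[abs(avail - p) >= window]
      }
      pos_sel <- sort(pos_sel)
      for (p in pos_sel) {
        aa[p] <- "K"
        lab <- stats::rbinom(1L, 1L, site_rate)
        if (lab == 1L) {
          for (j in seq_along(offsets)) {
            aa[p + offsets[j]] <- sample(
              aa_standard(), 1L, prob = position_probs(motif, offsets[j]))
          }
        }
        sites[[length(sites) + 1L]] <-
          data.frame(protein_id = sprintf("SYNP%04d", i), position = p,
                     label = lab, stringsAsFactors = FALSE)
      }
      seqs[i] <- paste(aa, collapse = "")
    }
  })
  names(seqs) <- sprintf("SYNP%04d", seq_len(n_proteins))
  sites <- do.call(rbind, sites)
  frags <- build_fragments(seqs, sites, n)
  list(sequences = seqs, sites = sites, fragments = frags$fragment)
}

#' Write a synthetic proteome to FASTA + site table
#'
#' @param proteome Result of [generate_annotated_proteome()].
#' @param fasta_path Output FASTA path.
#' @param sites_path Output CSV path.
#' @export
write_proteome <- function(proteome, fasta_path, sites_path) {
  con <- file(fasta_path, "w")
  for (nm in names(proteome$sequences)) {
    writeLines(paste0(">", nm), con)
    s <- proteome$sequences[[nm]]
    writeLines(substring(s, seq(1, nchar(s), 60),
                         pmin(seq(60, nchar(s) + 59, 60), nchar(s))), con)
  }
  close(con)
  utils::write.csv(proteome$sites, sites_path, row.names = FALSE)
  invisible(c(fasta_path, sites_path))
}

#' Write a profile in PSI-BLAST ASCII layout
#'
#' Emits a parseable `-out_ascii_pssm`-style text file for a given `L x 20`
#' profile (columns in alphabetical residue order internally, written in
#' PSI-BLAST column order). Useful for generating profile fixtures and for
#' exporting surrogate profiles.
#'
#' @param profile `L x 20` integer-valued matrix with columns named by
#'   residue.
#' @param residues Character vector of the residue at each row.
#' @param path Output path.
#' @export
write_pssm_ascii <- function(profile, residues, path) {
  stopifnot(nrow(profile) == length(residues), ncol(profile) == 20L)
  prof <- profile[, pssm_col_order, drop = FALSE]
  con <- file(path, "w"); on.exit(close(con))
  writeLines("Last position-specific scoring matrix computed", con)
  writeLines(paste0("            ",
                    paste(sprintf("%3s", pssm_col_order), collapse = " "), "  ",
                    paste(sprintf("%3s", pssm_col_order), collapse = " ")), con)
  for (i in seq_len(nrow(prof))) {
    writeLines(paste0(sprintf("%5d %s ", i, residues[i]),
                      paste(sprintf("%3d", prof[i, ]), collapse = " "), "  ",
                      paste(sprintf("%3d", prof[i, ]), collapse = " ")), con)
  }
  writeLines("", con)
  invisible(path)
}
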