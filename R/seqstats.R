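# Descriptive sequence statistics: class-wise amino-acid composition,
# two-sample-logo-style positional enrichment, and Pearson feature-label
# screening.

#' Class-wise amino-acid composition
#'
#' Mean flank composition (21-letter alphabet) of the positive and negative
#' fragment sets, with the per-residue difference vector for ranking. Each
#' composition vector equals the mean of the per-fragment [encode_aac()]
#' outputs and sums to 1.
#'
#' @param pos_fragments,neg_fragments Equal-window fragment vectors.
#' @return List with `pos`, `neg` (21-dim compositions) and
#'   `diff = pos - neg`.
#' @export
aac_by_class <- function(pos_fragments, neg_fragments) {
  stopifnot(length(pos_fragments) > 0, length(neg_fragments) > 0,
            nchar(pos_fragments[[1]]) == nchar(neg_fragments[[1]]))
  pos <- colMeans(t(vapply(pos_fragments, encode_aac, numeric(21L))))
  neg <- colMeans(t(vapply(neg_fragments, encode_aac, numeric(21L))))
  list(pos = pos, neg = neg, diff = pos - neg)
}

# Two-proportion test of residue frequency at one cell; pooled z-test when
# all expected counts reach 5, Fisher's exact test otherwise (symmetric in
# the two classes, so swapping the sets only flips the direction).
two_prop_p <- function(k1, n1, k2, n2) {
  p_hat <- (k1 + k2) / (n1 + n2)
  if (p_hat == 0 || p_hat == 1) return(1)
  e_min <- min(n1 * p_hat, n1 * (1 - p_hat), n2 * p_hat, n2 * (1 - p_hat))
  if (e_min >= 5) {
    z <- (k1 / n1 - k2 / n2) / sqrt(p_hat * (1 - p_hat) * (1 / n1 + 1 / n2))
    2 * stats::pnorm(-abs(z))
  } else {
    stats::fisher.test(matrix(c(k1, n1 - k1, k2, n2 - k2), 2L))$p.value
  }
}

#' Positional residue enrichment between two fragment classes
#'
#' For every flank position (center-relative offsets `-n..-1, +1..+n`) and
#' each of the 20 standard residues, compares the residue frequency in the
#' positive set against the negative set with a two-proportion test. Cells
#' with `p < alpha` are flagged `enriched` or `depleted` by the sign of the
#' frequency difference; padding (`"X"`) is excluded from testing but counts
#' toward the per-position totals.
#'
#' @param pos_fragments,neg_fragments Equal-window fragment vectors.
#' @param alpha Significance level; default 0.05.
#' @param correction `"none"` (default, mirroring two-sample logo practice)
#'   or `"bonferroni"` over the `2n x 20` cells.
#' @return `data.frame` of class `positional_enrichment` with columns
#'   `position` (offset), `residue`, `freq_pos`, `freq_neg`, `diff`, `p`,
#'   `flag`.
#' @export
positional_enrichment <- function(pos_fragments, neg_fragments, alpha = 0.05,
                                  correction = c("none", "bonferroni")) {
  correction <- match.arg(correction)
  stopifnot(length(pos_fragments) > 0, length(neg_fragments) > 0)
  L <- nchar(pos_fragments[[1]])
  stopifnot(L == nchar(neg_fragments[[1]]), L %% 2L == 1L)
  n <- (L - 1L) %/% 2L
  offsets <- c(-(n:1), 1:n)
  rp <- t(vapply(pos_fragments, chars, character(L)))[, -(n + 1L), drop = FALSE]
  rn <- t(vapply(neg_fragments, chars, character(L)))[, -(n + 1L), drop = FALSE]
  n1 <- length(pos_fragments); n2 <- length(neg_fragments)
  cells <- expand.grid(position = offsets, residue = aa_standard(),
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$position, cells$residue), ]
  col_of <- match(cells$position, offsets)
  k1 <- mapply(function(cl, r) sum(rp[, cl] == r), col_of, cells$residue)
  k2 <- mapply(function(cl, r) sum(rn[, cl] == r), col_of, cells$residue)
  p <- mapply(two_prop_p, k1, n1, k2, n2)
  thr <- if (correction == "bonferroni") alpha / nrow(cells) else alpha
  diff <- k1 / n1 - k2 / n2
  flag <- ifelse(p < thr & diff > 0, "enriched",
                 ifelse(p < thr & diff < 0, "depleted", "none"))
  out <- data.frame(position = cells$position, residue = cells$residue,
                    freq_pos = k1 / n1, freq_neg = k2 / n2, diff = diff,
                    p = p, flag = flag, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("positional_enrichment", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Pearson correlation between one feature and the class label
#'
#' Standard product-moment correlation of a numeric feature column against
#' the 0/1 label, used to screen encoder dimensions for class association.
#' Zero variance in either argument yields 0 with attribute
#' `undefined = TRUE`.
#'
#' @param feature Numeric vector (length >= 3).
#' @param labels Binary 0/1 labels.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_feature_label <- function(feature, labels) {
  stopifnot(length(feature) == length(labels), length(feature) >= 3L)
  if (stats::sd(feature) == 0 || stats::sd(labels) == 0)
    return(structure(0, undefined = TRUE))
  stats::cor(feature, as.numeric(labels))
}

#' Feature-label correlation screen over an encoded matrix
#'
#' @param x Samples-by-dimension feature matrix.
#' @param labels Binary labels.
#' @return `data.frame` of dimension name and PCC, ordered by `|PCC|`
#'   descending.
#' @export
pcc_screen <- function(x, labels) {
  pcc <- apply(x, 2L, pearson_feature_label, labels = labels)
  out <- data.frame(dimension = colnames(x) %||% as.character(seq_len(ncol(x))),
                    pcc = as.numeric(pcc), stringsAsFactors = FALSE)
  out[order(-abs(out$pcc)), ]
}

#' Write an enrichment table to CSV
#'
#' @param enrichment A `positional_enrichment` table.
#' @param path Output CSV path.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.csv(as.data.frame(enrichment), path, row.names = FALSE)
  invisible(path)
}
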