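#' Select contributor gene lists from WCA scores
#'
#' The genes with the most extreme first-component loadings: the
#' \code{n_down} most negative scores are the "downregulated contributors"
#' and the \code{n_up} most positive scores the "upregulated contributors"
#' (defaults 250 and 1000, the list sizes used on the 7,238-gene
#' universe). Only genes of the required sign are eligible; if fewer
#' exist the list is truncated with a warning. Ties at a boundary are
#' broken by gene id, so selection does not depend on input order.
#'
#' @param scores named numeric vector of WCA scores.
#' @param n_down,n_up list sizes (defaults 250 / 1000).
#' @return list of class \code{"contributor_sets"}: \code{down} and
#'   \code{up} (gene ids ordered most-extreme first), \code{n_down},
#'   \code{n_up}.
#' @export
select_contributors <- function(scores, n_down = 250, n_up = 1000) {
  stopifnot(!is.null(names(scores)))
  if (n_down + n_up > length(scores))
    stop("n_down + n_up exceeds the score universe (",
         length(scores), " genes)")
  neg <- scores[scores < 0]
  pos <- scores[scores > 0]
  ord_neg <- names(neg)[order(neg, names(neg))]          # most negative first
  ord_pos <- names(pos)[order(-pos, names(pos))]         # most positive first
  if (length(ord_neg) < n_down)
    warning("only ", length(ord_neg), " negative-score genes available ",
            "for n_down = ", n_down, "; list truncated")
  if (length(ord_pos) < n_up)
    warning("only ", length(ord_pos), " positive-score genes available ",
            "for n_up = ", n_up, "; list truncated")
  structure(list(down = utils::head(ord_neg, n_down),
                 up = utils::head(ord_pos, n_up),
                 n_down = n_down, n_up = n_up),
            class = "contributor_sets")
}

#' @export
print.contributor_sets <- function(x, ...) {
  cat(sprintf("contributor sets: %d down, %d up\n",
              length(x$down), length(x$up)))
  invisible(x)
}

#' Sign asymmetry of a score distribution
#'
#' Counts positive and negative scores and tests the split against 0.5
#' with an exact two-sided binomial test (zeros excluded). An excess of
#' positive scores indicates a global bias toward upregulation along the
#' path.
#'
#' @param scores numeric vector of scores.
#' @return list: \code{n_positive}, \code{n_negative}, \code{p_value}.
#' @export
score_asymmetry <- function(scores) {
  n_pos <- sum(scores > 0)
  n_neg <- sum(scores < 0)
  p <- if (n_pos + n_neg == 0) 1
       else stats::binom.test(n_pos, n_pos + n_neg, p = 0.5,
                              alternative = "two.sided")$p.value
  list(n_positive = n_pos, n_negative = n_neg, p_value = p)
}

#' Per-gene transgenerational trajectory classification
#'
#' For each requested gene and each lineage, the log2 change (difference of
#' log2(x+1) expression) of every non-reference state relative to that
#' lineage's P0, plus two flags:
#' \describe{
#'   \item{primed}{the P0 -> F2 changes are nonzero and share one sign in
#'     all lineages (early, pre-sterility misregulation).}
#'   \item{amplified}{in at least \code{quorum} lineages the F2 ->
#'     F4_sterile change is nonzero and goes strictly further in its own
#'     direction than the F2 -> F4_fertile change (further misregulation
#'     specifically toward sterility).}
#' }
#'
#' @param lm log-expression matrix, genes x samples.
#' @param design data.frame with \code{sample_id}, \code{lineage},
#'   \code{state}.
#' @param genes gene ids to classify.
#' @param states ordered state labels; the first is the reference.
#' @param quorum number of lineages in which the amplification inequality
#'   must hold (default: all lineages).
#' @return data.frame, one row per gene x lineage, with columns
#'   \code{gene_id}, \code{lineage}, \code{d_P0_F2}, \code{d_F2_F4fertile},
#'   \code{d_F2_F4sterile}, and per-gene logical columns \code{primed},
#'   \code{amplified} (repeated across the gene's rows).
#' @export
trajectory_table <- function(lm, design, genes,
                             states = c("P0", "F2", "F4_fertile",
                                        "F4_sterile"),
                             quorum = NULL) {
  missing <- setdiff(genes, rownames(lm))
  if (length(missing))
    stop("unknown gene(s): ", paste(utils::head(missing, 5), collapse = ", "))
  lineages <- unique(design$lineage)
  if (is.null(quorum)) quorum <- length(lineages)
  cell <- function(l, s) {
    ids <- design$sample_id[design$lineage == l & design$state == s]
    if (length(ids) == 0L)
      stop("design is missing the (", l, ", ", s, ") cell")
    rowMeans(lm[genes, ids, drop = FALSE])
  }
  rows <- list()
  for (l in lineages) {
    p0 <- cell(l, states[1L]); f2 <- cell(l, states[2L])
    f4f <- cell(l, states[3L]); f4s <- cell(l, states[4L])
    rows[[l]] <- data.frame(gene_id = genes, lineage = l,
                            d_P0_F2 = f2 - p0,
                            d_F2_F4fertile = f4f - f2,
                            d_F2_F4sterile = f4s - f2,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  flag <- function(g) {
    sub <- tab[tab$gene_id == g, , drop = FALSE]
    e <- sign(sub$d_P0_F2)
    primed <- all(e != 0) && length(unique(e)) == 1L
    d <- sign(sub$d_F2_F4sterile)
    amp_l <- d != 0 & d * sub$d_F2_F4sterile > d * sub$d_F2_F4fertile
    c(primed = primed, amplified = sum(amp_l) >= quorum)
  }
  fl <- t(vapply(genes, flag, c(primed = NA, amplified = NA)))
  tab$primed <- fl[match(tab$gene_id, genes), "primed"] > 0
  tab$amplified <- fl[match(tab$gene_id, genes), "amplified"] > 0
  tab
}

#' Tally priming / amplification flags over a gene list
#'
#' Summarizes a [trajectory_table()] (e.g. the top genes by |score|):
#' how many are primed, amplified, or both.
#'
#' @param records data.frame from [trajectory_table()].
#' @return list: \code{n_genes}, \code{n_primed}, \code{n_amplified},
#'   \code{n_both}.
#' @export
count_trajectory_classes <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    return(list(n_genes = 0L, n_primed = 0L, n_amplified = 0L, n_both = 0L))
  per_gene <- records[!duplicated(records$gene_id),
                      c("gene_id", "primed", "amplified")]
  list(n_genes = nrow(per_gene),
       n_primed = sum(per_gene$primed),
       n_amplified = sum(per_gene$amplified),
       n_both = sum(per_gene$primed & per_gene$amplified))
}
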