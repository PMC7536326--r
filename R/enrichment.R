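#' Exact hypergeometric tail probability
#'
#' Probability of drawing at least (\code{direction = "over"}) or at most
#' (\code{"under"}) \code{k} members of a \code{K}-sized set in an
#' \code{n}-sized draw without replacement from an \code{N}-sized universe.
#' Computed by summing log-density terms with a log-sum-exp reduction, so
#' extreme tails (p down to ~1e-300) keep full relative accuracy.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query (draw) size.
#' @param N universe size.
#' @param direction \code{"over"} for the upper tail \eqn{P(X \ge k)},
#'   \code{"under"} for the lower tail \eqn{P(X \le k)}.
#' @return tail probability.
#' @examples
#' hypergeom_tail(101, 389, 1250, 7238, "over")   # ~6e-06
#' @export
hypergeom_tail <- function(k, K, n, N, direction = c("over", "under")) {
  direction <- match.arg(direction)
  if (K < 0 || n < 0 || N < 0 || K > N || n > N)
    stop("require 0 <= K, n <= N")
  lo <- max(0, n + K - N); hi <- min(K, n)
  if (k < lo || k > hi)
    stop("impossible overlap k = ", k, " (support is [", lo, ", ", hi, "])")
  supp <- if (direction == "over") k:hi else lo:k
  logsumexp(stats::dhyper(supp, K, N - K, n, log = TRUE))
}

logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(exp(m))
  min(1, exp(m) * sum(exp(lx - m)))
}

#' Fold enrichment of an overlap
#'
#' Observed over expected overlap: \eqn{k N / (K n)}. Equals 1 exactly when
#' \code{k} matches the hypergeometric expectation \eqn{Kn/N}.
#'
#' @inheritParams hypergeom_tail
#' @return scalar fold enrichment.
#' @examples
#' fold_enrichment(101, 389, 1250, 7238)   # 1.50
#' @export
fold_enrichment <- function(k, K, n, N) {
  if (K <= 0 || n <= 0 || N <= 0)
    stop("fold enrichment undefined for zero K, n or N")
  k * N / (K * n)
}

enrichment_row <- function(set_name, query, set, universe) {
  N <- length(universe)
  K <- length(set)
  n <- length(query)
  k <- length(intersect(query, set))
  data.frame(set = set_name, N = N, K = K, n = n, k = k,
             fold = if (K > 0 && n > 0) fold_enrichment(k, K, n, N)
                    else NA_real_,
             p_over = hypergeom_tail(k, K, n, N, "over"),
             p_under = hypergeom_tail(k, K, n, N, "under"),
             stringsAsFactors = FALSE)
}

#' Hypergeometric enrichment of a query list against gene sets
#'
#' Each set is intersected with the universe before testing; query ids
#' outside the universe are dropped (with a message reporting how many).
#' Both tails are reported: \code{p_over} for over-representation and
#' \code{p_under} for depletion. P-values are raw (no multiple-testing
#' correction) unless \code{adjust = TRUE}, which adds BH-adjusted columns.
#'
#' @param query character vector of gene ids.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param universe character vector: the background gene universe
#'   (typically the expression-filtered analysis universe).
#' @param adjust add BH-adjusted \code{padj_over} / \code{padj_under}
#'   columns (default FALSE).
#' @return data.frame, one row per set, columns \code{set}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{fold}, \code{p_over},
#'   \code{p_under}.
#' @export
enrich_sets <- function(query, sets, universe, adjust = FALSE) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  dropped <- sum(!query %in% universe)
  if (dropped > 0)
    message(dropped, " query id(s) outside the universe dropped")
  query <- unique(intersect(query, universe))
  rows <- lapply(names(sets), function(nm) {
    enrichment_row(nm, query, unique(intersect(sets[[nm]], universe)),
                   universe)
  })
  out <- do.call(rbind, rows)
  if (adjust) {
    out$padj_over <- bh_adjust(out$p_over)
    out$padj_under <- bh_adjust(out$p_under)
  }
  out
}

#' Chromosome distribution of a gene list
#'
#' Per-chromosome hypergeometric test of the query against the universe,
#' plus a global chi-square goodness-of-fit of the query's chromosome
#' counts against the universe proportions. Both are reported because the
#' appropriate summary depends on the question (one chromosome of interest
#' vs overall distortion).
#'
#' @param query character vector of gene ids.
#' @param annotation data.frame with \code{gene_id}, \code{chromosome}.
#' @param universe background gene ids; every universe gene must be
#'   annotated.
#' @return list: \code{per_chromosome} (enrichment data.frame, one row per
#'   chromosome present in the universe), \code{chisq_statistic},
#'   \code{chisq_df}, \code{chisq_p}.
#' @export
chromosome_distribution <- function(query, annotation, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  chr <- annotation$chromosome[match(universe, annotation$gene_id)]
  if (anyNA(chr)) {
    off <- universe[is.na(chr)]
    stop("unannotated universe gene(s): ",
         paste(utils::head(off, 5), collapse = ", "),
         if (length(off) > 5) sprintf(" (and %d more)", length(off) - 5))
  }
  query <- unique(intersect(query, universe))
  qchr <- chr[match(query, universe)]
  chroms <- sort(unique(chr))
  rows <- lapply(chroms, function(cc) {
    enrichment_row(cc, query, universe[chr == cc], universe)
  })
  per_chr <- do.call(rbind, rows)
  ## global goodness of fit: query counts vs universe proportions
  obs <- vapply(chroms, function(cc) sum(qchr == cc), numeric(1))
  expd <- length(query) * vapply(chroms, function(cc) mean(chr == cc),
                                 numeric(1))
  ok <- expd > 0
  stat <- sum((obs[ok] - expd[ok])^2 / expd[ok])
  df <- sum(ok) - 1L
  list(per_chromosome = per_chr,
       chisq_statistic = stat, chisq_df = df,
       chisq_p = if (df > 0) stats::pchisq(stat, df, lower.tail = FALSE)
                 else NA_real_)
}

#' Compare score distributions between chromosome groups
#'
#' Two-sided Wilcoxon rank-sum comparison of WCA scores of X-linked versus
#' autosomal genes (or any two-group chromosome partition). A shifted X
#' distribution indicates that X-linked genes carry a distinct share of the
#' path-to-sterility signal.
#'
#' @param scores named numeric score vector.
#' @param annotation data.frame with \code{gene_id}, \code{chromosome}.
#' @param group_chromosomes chromosome labels forming the first group
#'   (default \code{"X"}); all other annotated genes form the second.
#' @return list: \code{statistic} (rank-sum W), \code{p_value},
#'   \code{median_group} (first group), \code{median_rest},
#'   \code{n_group}, \code{n_rest}.
#' @export
score_distribution_compare <- function(scores, annotation,
                                       group_chromosomes = "X") {
  chr <- annotation$chromosome[match(names(scores), annotation$gene_id)]
  g1 <- scores[!is.na(chr) & chr %in% group_chromosomes]
  g2 <- scores[!is.na(chr) & !(chr %in% group_chromosomes)]
  if (length(g1) == 0L || length(g2) == 0L)
    stop("both chromosome groups must be non-empty")
  wt <- stats::wilcox.test(g1, g2, alternative = "two.sided")
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       median_group = stats::median(g1), median_rest = stats::median(g2),
       n_group = length(g1), n_rest = length(g2))
}

#' Hypergeometric overlap test between two gene lists
#'
#' Tests \code{|A intersect B|} against the hypergeometric expectation in
#' the given universe (lists are intersected with the universe first).
#'
#' @param list_a,list_b character vectors of gene ids.
#' @param universe background gene ids.
#' @return single-row enrichment data.frame (\code{n} = |A|, \code{K} =
#'   |B|, \code{k} = overlap, both tails).
#' @export
overlap_test <- function(list_a, list_b, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  a <- unique(intersect(list_a, universe))
  b <- unique(intersect(list_b, universe))
  enrichment_row("overlap", a, b, universe)
}
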