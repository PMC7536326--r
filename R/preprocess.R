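#' Median-of-ratios size factors
#'
#' Per-sample scaling constants making libraries comparable: the reference
#' profile is the per-gene geometric mean over samples, computed over genes
#' with strictly positive counts in every sample; the size factor of sample
#' \eqn{j} is the median over those genes of \eqn{count_{gj} / ref_g}.
#' With this reference the factors of an exactly 2x-scaled pair come out as
#' \eqn{(2^{-1/2}, 2^{1/2})}.
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @return named numeric vector of positive size factors, one per sample.
#' @examples
#' m <- matrix(c(4L, 6L, 8L, 12L), 2, dimnames = list(c("a","b"), c("s1","s2")))
#' estimate_size_factors(m)   # (1/sqrt(2), sqrt(2))
#' @export
estimate_size_factors <- function(counts) {
  check_count_matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos))
    stop("size factors undefined: no gene has strictly positive counts ",
         "in every sample")
  lc <- log(counts[pos, , drop = FALSE])
  ref_log <- rowMeans(lc)                       # log geometric mean
  sf <- apply(exp(lc - ref_log), 2L, stats::median)
  names(sf) <- colnames(counts)
  sf
}

#' Normalize counts by size factors
#'
#' @param counts genes x samples matrix.
#' @param factors positive scalars, one per sample.
#' @return matrix of normalized expression \code{counts[, j] / factors[j]}.
#' @export
normalize_counts <- function(counts, factors) {
  check_count_matrix(counts)
  if (length(factors) != ncol(counts))
    stop("need one size factor per sample (got ", length(factors),
         " for ", ncol(counts), " samples)")
  if (any(factors <= 0)) stop("size factors must all be > 0")
  sweep(counts, 2L, factors, `/`)
}

#' log2(x + 1) transform
#'
#' @param m non-negative matrix of normalized expression.
#' @return matrix of the same shape, elementwise \code{log2(x + 1)}.
#' @export
log_transform <- function(m) {
  if (any(m < 0)) stop("log_transform requires non-negative values")
  log2(m + 1)
}

#' Per-gene max-expression and standard deviation summary
#'
#' The 2-D diagnostic used to pick an expression filter: per gene, the
#' maximal log-expression over samples and the standard deviation across
#' samples (n - 1 denominator). Low-expression genes show SD rising with
#' max (background variation); expressed genes do not.
#'
#' @param lm log-expression matrix, genes x samples (>= 2 samples).
#' @return data.frame with \code{gene_id}, \code{max_expression},
#'   \code{sd_expression}.
#' @export
expression_sd_summary <- function(lm) {
  if (ncol(lm) < 2L) stop("sd undefined with a single sample")
  data.frame(gene_id = rownames(lm),
             max_expression = apply(lm, 1L, max),
             sd_expression = apply(lm, 1L, stats::sd),
             stringsAsFactors = FALSE)
}

#' Expression filter defining the analysis universe
#'
#' Keeps genes whose maximum log2 expression over samples is strictly
#' greater than \code{threshold} (a gene peaking at exactly the threshold
#' is excluded), in stable input order.
#'
#' @param lm log-expression matrix, genes x samples.
#' @param threshold scalar cutoff (default 5, log2 scale).
#' @return character vector of gene ids (the universe).
#' @export
filter_expressed <- function(lm, threshold = 5) {
  rownames(lm)[apply(lm, 1L, max) > threshold]
}

#' Benjamini-Hochberg step-up adjustment
#'
#' \eqn{padj_{(i)} = \min_{j \ge i} \min(1, m\, p_{(j)} / j)} for ascending
#' order statistics, mapped back to input order.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed, passed
#'   through; m counts non-NA entries).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(out)
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

#' Surrogate differential-expression count versus P0
#'
#' A deliberately simple stand-in for a full NB-GLM differential test,
#' used only to reproduce the "number of deregulated genes per state"
#' counting behaviour on synthetic data. Per gene it compares the
#' normalized mean of the samples in \code{state} with the normalized mean
#' of the \code{p0_state} samples (lineages act as replicates): dispersion
#' is estimated by method of moments pooled over the two groups (the
#' across-gene median acting as a common dispersion), the Wald statistic
#' is the difference of log2 means over its delta-method standard error
#' with a two-sided normal reference, and BH adjustment is applied across
#' all tested genes. Mildly anti-conservative at 3 replicates per group
#' (null fraction of p < 0.05 is about 0.065); not a substitute for a
#' full NB-GLM when calibrated inference matters.
#'
#' @param counts genes x samples integer matrix.
#' @param design data.frame with \code{sample_id}, \code{state}.
#' @param state the state to compare against \code{p0_state}.
#' @param alpha adjusted-p threshold for the reported count (default 1e-5).
#' @param p0_state reference state label (default \code{"P0"}).
#' @param size_factors optional precomputed size factors (estimated from
#'   \code{counts} when \code{NULL}).
#' @return list with \code{table} (data.frame: \code{gene_id},
#'   \code{log2fc}, \code{pvalue}, \code{padj}) and \code{n_signif}
#'   (genes with \code{padj < alpha}).
#' @export
de_count_vs_p0 <- function(counts, design, state, alpha = 1e-5,
                           p0_state = "P0", size_factors = NULL) {
  check_count_matrix(counts)
  if (!state %in% design$state)
    stop("state '", state, "' absent from design")
  if (!p0_state %in% design$state)
    stop("reference state '", p0_state, "' absent from design")
  s1 <- design$sample_id[design$state == state]
  s0 <- design$sample_id[design$state == p0_state]
  if (length(s1) < 2L || length(s0) < 2L)
    stop("need >= 2 samples in each compared state")
  if (is.null(size_factors)) size_factors <- estimate_size_factors(counts)
  nm <- normalize_counts(counts, size_factors)
  x1 <- nm[, s1, drop = FALSE]; x0 <- nm[, s0, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  c1 <- mean(1 / size_factors[s1]); c0 <- mean(1 / size_factors[s0])

  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- apply(x1, 1L, stats::var); v0 <- apply(x0, 1L, stats::var)
  ## method-of-moments NB dispersion, pooled over the two groups:
  ## Var(K/sf) ~= mu * mean(1/sf) + alpha * mu^2  =>  per-gene alpha
  a1 <- ifelse(m1 > 0, (v1 - m1 * c1) / m1^2, NA_real_)
  a0 <- ifelse(m0 > 0, (v0 - m0 * c0) / m0^2, NA_real_)
  a_g <- rowMeans(cbind(a1, a0), na.rm = TRUE)
  ## per-gene moment estimates carry only ~4 df and are too noisy to use
  ## directly; the across-gene median serves as a common dispersion
  alpha_common <- stats::median(a_g[is.finite(a_g)], na.rm = TRUE)
  if (!is.finite(alpha_common)) alpha_common <- 0
  alpha_g <- rep(max(0, alpha_common), nrow(counts))

  tested <- (m1 + m0) > 0
  ## guard zero means for the log and variance terms
  m1g <- pmax(m1, 0.5 / n1); m0g <- pmax(m0, 0.5 / n0)
  var_mean1 <- (m1g * c1 + alpha_g * m1g^2) / n1
  var_mean0 <- (m0g * c0 + alpha_g * m0g^2) / n0
  lfc <- log2(m1g) - log2(m0g)
  se <- sqrt(var_mean1 / (m1g * log(2))^2 + var_mean0 / (m0g * log(2))^2)
  z <- ifelse(se > 0, lfc / se, 0)
  pv <- 2 * stats::pnorm(-abs(z))
  pv[!tested] <- NA_real_
  lfc[!tested] <- 0
  padj <- bh_adjust(pv)
  tab <- data.frame(gene_id = rownames(counts), log2fc = lfc,
                    pvalue = pv, padj = padj, stringsAsFactors = FALSE)
  list(table = tab, n_signif = sum(padj < alpha, na.rm = TRUE))
}

check_count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene and sample ids as dimnames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  invisible(counts)
}
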