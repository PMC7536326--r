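## Independent oracles: deliberately naive implementations used only to
## check the package's vectorized/log-space code paths.

## median-of-ratios size factors, plain loops
oracle_size_factors <- function(counts) {
  keep <- apply(counts, 1L, function(r) all(r > 0))
  ref <- apply(counts[keep, , drop = FALSE], 1L,
               function(r) prod(r)^(1 / length(r)))
  sapply(seq_len(ncol(counts)), function(j)
    median(counts[keep, j] / ref))
}

## BH by the defining formula: padj_(i) = min_{j >= i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    adj[o[i]] <- min(1, min(sapply(i:m, function(j) m * p[o[j]] / j)))
  }
  adj
}

## centered PCA by explicit covariance eigendecomposition (1/n weights)
oracle_pca <- function(x) {
  xc <- sweep(x, 2L, colMeans(x), `-`)
  cv <- crossprod(xc) / nrow(xc)
  e <- eigen(cv, symmetric = TRUE)
  list(eigenvalues = e$values, loadings = e$vectors)
}

## within-class analysis by explicit class-centering + covariance eigen
oracle_wca <- function(x, classes) {
  xc <- sweep(x, 2L, colMeans(x), `-`)
  for (cl in unique(classes)) {
    i <- classes == cl
    xc[i, ] <- sweep(xc[i, , drop = FALSE], 2L,
                     colMeans(xc[i, , drop = FALSE]), `-`)
  }
  e <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE)
  list(eigenvalues = e$values, loadings = e$vectors, centered = xc)
}

## hypergeometric tail by direct choose()-ratio summation (no dhyper)
oracle_hyper_tail <- function(k, K, n, N, direction) {
  lo <- max(0, n + K - N); hi <- min(K, n)
  supp <- if (direction == "over") k:hi else lo:k
  sum(choose(K, supp) * choose(N - K, n - supp)) / choose(N, n)
}

## hypergeometric upper tail by exhaustive enumeration of all draws
## (tiny N only)
oracle_hyper_enum <- function(k, K, n, N, direction) {
  draws <- combn(N, n)
  inset <- colSums(draws <= K)      # items 1..K form the set
  if (direction == "over") mean(inset >= k) else mean(inset <= k)
}

## absolute cosine between two vectors
abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))

## rank-based AUROC of score x for labels y (TRUE = positive)
auroc <- function(x, y) {
  r <- rank(x)
  n1 <- sum(y); n0 <- sum(!y)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## small standard pipeline: counts -> log matrix + universe + wca result
run_core <- function(sim, true_sf = FALSE) {
  sf <- if (true_sf) {
    stats::setNames(sim$size_factors, colnames(sim$counts))
  } else estimate_size_factors(sim$counts)
  lm <- log_transform(normalize_counts(sim$counts, sf))
  uni <- filter_expressed(lm)
  res <- wca(t(lm[uni, , drop = FALSE]), sim$design$lineage,
             state_rank = match(sim$design$state, sim$params$states))
  list(sf = sf, lm = lm, universe = uni, wca = res,
       scores = wca_scores(res))
}

truth_ids <- function(sim, lab) sim$truth$gene_id[sim$truth$label == lab]

## plumbing-scale simulation: planted content shrunk to fit tiny n_genes
tiny_sim <- function(n_genes, seed, ...) {
  simulate_counts(simulation_params(n_genes = n_genes, seed = seed,
                                    n_up_planted = 5, n_down_planted = 2,
                                    n_lineage_private = 3, ...))
}
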