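#' Principal component analysis under uniform row weights
#'
#' PCA written out explicitly rather than via \code{prcomp()}: variables
#' (columns) are centered, optionally scaled by their population standard
#' deviation, and the covariance under uniform row weights \eqn{1/n} is
#' eigendecomposed (via SVD). Eigenvalues are therefore the variances of
#' the row coordinates with the \eqn{1/n} convention, not \eqn{1/(n-1)}.
#' Component signs are fixed deterministically: the entry of largest
#' absolute loading is made positive.
#'
#' @param x numeric matrix, individuals x variables.
#' @param center center variables (default TRUE).
#' @param scale scale variables to unit population variance (default
#'   FALSE); an error names any zero-variance variable.
#' @return list of class \code{"wd_pca"}:
#'   \code{eigenvalues}, \code{percent_variance},
#'   \code{row_coordinates} (individuals x components),
#'   \code{variable_loadings} (variables x components, unit-norm columns).
#' @examples
#' r <- pca(matrix(rnorm(40), 8, 5))
#' sum(r$percent_variance)     # 100
#' @export
pca <- function(x, center = TRUE, scale = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("pca requires >= 2 individuals")
  if (any(!is.finite(x))) stop("pca requires finite values")
  if (center) x <- sweep(x, 2L, colMeans(x), `-`)
  if (scale) {
    sdev <- sqrt(colMeans(sweep(x, 2L, colMeans(x), `-`)^2))
    zero <- which(sdev == 0)
    if (length(zero))
      stop("cannot scale zero-variance variable(s): ",
           paste(if (is.null(colnames(x))) zero else colnames(x)[zero],
                 collapse = ", "))
    x <- sweep(x, 2L, sdev, `/`)
  }
  decomp_uniform(x)
}

## shared eigendecomposition of t(X) %*% X / n via SVD with deterministic
## sign fixing; ncomp_cap limits rank (n - n_classes for the class-centered
## case, n - 1 for plain centered PCA)
decomp_uniform <- function(x, ncomp_cap = nrow(x) - 1L) {
  n <- nrow(x)
  sv <- svd(x)
  eig <- sv$d^2 / n
  k <- min(ncomp_cap, ncol(x), length(eig))
  if (k > 0) {
    keep <- eig[seq_len(k)] > 1e-12 * max(eig[1L], .Machine$double.xmin)
    k <- sum(keep)
  }
  eig <- eig[seq_len(k)]
  load <- sv$v[, seq_len(k), drop = FALSE]
  ## sign: largest-|loading| entry positive, ties to the earlier variable
  for (j in seq_len(k)) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  coords <- x %*% load
  if (k > 0) {
    dimnames(load) <- list(colnames(x), paste0("PC", seq_len(k)))
    dimnames(coords) <- list(rownames(x), paste0("PC", seq_len(k)))
  }
  tot <- sum(sv$d^2) / n
  structure(list(eigenvalues = eig,
                 percent_variance = if (tot > 0) 100 * eig / tot
                                    else rep(NA_real_, k),
                 row_coordinates = coords,
                 variable_loadings = load,
                 total_variance = tot),
            class = "wd_pca")
}

#' Build the within-lineage expression-difference matrix
#'
#' For each lineage and each consecutive state transition (default
#' P0 -> F2, F2 -> F4_fertile, F4_fertile -> F4_sterile), one column holding
#' \code{LM[, later] - LM[, earlier]}. With 3 lineages and 4 states this is
#' the genes x 9 difference matrix whose column profiles are then examined
#' by PCA. Replicated cells are averaged before differencing.
#'
#' @param lm log-expression matrix, genes x samples.
#' @param design data.frame with \code{sample_id}, \code{lineage},
#'   \code{state}.
#' @param states ordered state labels (default the four-state design).
#' @return genes x (lineages * transitions) matrix; column names are
#'   \code{"<lineage>:<from>-><to>"}.
#' @export
build_diff_matrix <- function(lm, design,
                              states = c("P0", "F2", "F4_fertile",
                                         "F4_sterile")) {
  lineages <- unique(design$lineage)
  cell <- function(l, s) {
    ids <- design$sample_id[design$lineage == l & design$state == s]
    if (length(ids) == 0L)
      stop("design is missing the (", l, ", ", s, ") cell")
    rowMeans(lm[, ids, drop = FALSE])
  }
  cols <- list()
  for (l in lineages) {
    for (i in seq_len(length(states) - 1L)) {
      nm <- paste0(l, ":", states[i], "->", states[i + 1L])
      cols[[nm]] <- cell(l, states[i + 1L]) - cell(l, states[i])
    }
  }
  do.call(cbind, cols)
}

#' PCA on within-lineage difference profiles
#'
#' Treats each difference column of [build_diff_matrix()] as an individual
#' and genes as variables (the matrix is transposed internally). Clustering
#' of same-transition profiles across lineages on the leading components
#' indicates a shared two-step (priming then amplification) deregulation.
#'
#' @param dlm genes x differences matrix.
#' @return \code{"wd_pca"} object; row coordinates are the difference
#'   profiles.
#' @export
pca_on_differences <- function(dlm) {
  if (ncol(dlm) < 2L) stop("need >= 2 difference columns")
  pca(t(dlm), center = TRUE, scale = FALSE)
}

#' Within-class analysis (lineage-centered PCA)
#'
#' PCA after removing class (lineage) means, isolating the variation
#' shared across classes. Steps: (1) center each gene across all samples;
#' (2) subtract from every sample its class mean per gene; (3)
#' eigendecompose the class-centered matrix under uniform row weights
#' \eqn{1/n}. Class means of the centered matrix are exactly zero, so
#' between-class differences cannot leak into sample coordinates — this is
#' what lets replicate lineages overlay on the first component.
#'
#' The first component is oriented so that the Spearman correlation
#' between its sample coordinates and \code{state_rank} is positive (genes
#' upregulated along the path then carry positive loadings); without a
#' state ranking the largest-|loading| gene is made positive.
#'
#' @param x numeric matrix, samples x genes.
#' @param classes per-sample class labels (length \code{nrow(x)}).
#' @param state_rank optional per-sample numeric severity rank used for the
#'   sign convention of component 1.
#' @return list of class \code{"wd_wca"}:
#'   \code{classes}, \code{eigenvalues} (within-class), \code{pve}
#'   (percent of within-class variance per component, sums to 100),
#'   \code{sample_coordinates}, \code{gene_loadings} (unit-norm columns;
#'   column 1 holds the WCA scores), \code{within_total_ratio}
#'   (within-class variance over total variance), \code{total_variance},
#'   \code{within_variance}.
#' @export
wca <- function(x, classes, state_rank = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) stop("wca requires >= 2 samples")
  if (any(!is.finite(x))) stop("wca requires finite values")
  if (length(classes) != n)
    stop("need one class label per sample")
  if (any(is.na(classes))) stop("class label missing for some sample(s)")
  classes <- as.character(classes)
  cls <- unique(classes)
  if (length(cls) == 1L)
    warning("single class covers all samples: class centering reduces to ",
            "global centering and wca degenerates to plain PCA")
  if (length(cls) == n && n > 1L)
    warning("every class is a singleton: the class-centered matrix is ",
            "identically zero and all eigenvalues are 0")
  if (!is.null(state_rank) && length(state_rank) != n)
    stop("state_rank must have one entry per sample")

  xc <- sweep(x, 2L, colMeans(x), `-`)           # step 1: global centering
  total_var <- sum(colMeans(xc^2))
  w <- xc
  for (cl in cls) {                              # step 2: class centering
    i <- classes == cl
    w[i, ] <- sweep(w[i, , drop = FALSE], 2L,
                    colMeans(w[i, , drop = FALSE]), `-`)
  }
  within_var <- sum(colMeans(w^2))

  res <- decomp_uniform(w, ncomp_cap = n - length(cls))
  k <- length(res$eigenvalues)
  ## orient component 1 by state severity when available
  if (k >= 1L && !is.null(state_rank)) {
    rho <- suppressWarnings(
      stats::cor(res$row_coordinates[, 1L], rank(state_rank),
                 method = "spearman"))
    if (is.finite(rho) && rho < 0) {
      res$variable_loadings[, 1L] <- -res$variable_loadings[, 1L]
      res$row_coordinates[, 1L] <- -res$row_coordinates[, 1L]
    }
  }
  structure(list(classes = classes,
                 eigenvalues = res$eigenvalues,
                 pve = res$percent_variance,
                 sample_coordinates = res$row_coordinates,
                 gene_loadings = res$variable_loadings,
                 within_total_ratio = if (total_var > 0)
                   within_var / total_var else NA_real_,
                 total_variance = total_var,
                 within_variance = within_var),
            class = "wd_wca")
}

#' @export
print.wd_wca <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat(sprintf("within-class analysis: %d samples, %d classes, %d components\n",
              nrow(x$sample_coordinates), length(unique(x$classes)), k))
  if (k) cat(sprintf("PC1 pve: %.1f%% of within-class variance (within/total = %.2f)\n",
                     x$pve[1L], x$within_total_ratio))
  invisible(x)
}

#' Extract WCA scores
#'
#' The per-gene loadings on the first within-class component, as a named
#' unit-norm vector. Positive scores mark genes progressively upregulated
#' along the path to sterility, negative scores mark downregulation (given
#' the severity-based sign convention of [wca()]).
#'
#' @param result a \code{"wd_wca"} object with >= 1 component.
#' @return named numeric vector of scores (norm 1).
#' @export
wca_scores <- function(result) {
  stopifnot(inherits(result, "wd_wca"))
  if (length(result$eigenvalues) < 1L)
    stop("wca result has no component to extract scores from")
  scores <- result$gene_loadings[, 1L]
  names(scores) <- rownames(result$gene_loadings)
  scores
}

#' First-component pve of a within-class analysis on a gene subset
#'
#' Runs [wca()] on the column-subset matrix and returns the percent of
#' within-class variance captured by component 1 — used to ask how much of
#' the path-to-sterility signal a particular gene set (e.g. one chromosome)
#' carries on its own.
#'
#' @inheritParams wca
#' @param gene_subset non-empty character vector of column (gene) names.
#' @return scalar pve of component 1.
#' @export
subset_wca_pve <- function(x, classes, gene_subset, state_rank = NULL) {
  if (length(gene_subset) == 0L) stop("gene_subset must be non-empty")
  missing <- setdiff(gene_subset, colnames(x))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(utils::head(missing, 5),
                                          collapse = ", "))
  res <- wca(x[, gene_subset, drop = FALSE], classes, state_rank)
  if (length(res$pve) < 1L) return(NA_real_)
  res$pve[1L]
}
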