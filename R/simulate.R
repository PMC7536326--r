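#' Simulation parameters for a transgenerational count experiment
#'
#' Builds and validates the parameter set for [simulate_counts()]. The
#' defaults describe the design the downstream analysis assumes: three
#' independent mutant lineages, each sampled at four ordered generation
#' states (heterozygous parent \code{P0}, second-generation homozygote
#' \code{F2}, and fourth-generation \code{F4_fertile} / \code{F4_sterile}),
#' one library per (lineage, state) cell.
#'
#' Counts are negative binomial with mean
#' \deqn{\mu_{g,(l,s)} = sf_{(l,s)} \cdot 2^{\beta_g + \delta_g t(s) + \pi_{g,l} t(s)}}
#' where \eqn{\beta_g} is a per-gene baseline drawn from a two-component
#' log2 mixture (a low "background" component and a high "expressed"
#' component), \eqn{t(s)} the non-negative severity of state \eqn{s}
#' (0 at P0, increasing to sterility), \eqn{\delta_g} the planted global
#' effect (positive for up-contributors, negative for down-contributors,
#' zero otherwise) and \eqn{\pi_{g,l}} a lineage-private effect nonzero
#' only for (gene, lineage) pairs labelled \code{lineage_private}.
#' Variance is \eqn{\mu + \alpha\mu^2}; \code{dispersion = 0} degenerates
#' to Poisson.
#'
#' @param n_genes number of genes.
#' @param n_lineages number of independent lineages (classes).
#' @param states ordered character vector of generation-state labels.
#' @param severity named non-negative numeric vector \code{t(s)}, one entry
#'   per state; must be 0 at the first state and strictly increasing along
#'   the default four-state path.
#' @param n_up_planted,n_down_planted numbers of globally up-/down-regulated
#'   planted genes.
#' @param effect_size_log2 log2 fold change per unit severity for planted
#'   genes.
#' @param n_lineage_private number of genes with a lineage-specific effect.
#' @param private_effect_log2 magnitude (log2 per unit severity) of the
#'   lineage-private effect; sign is randomized per gene.
#' @param background_fraction fraction of genes drawn from the low-expression
#'   mixture component.
#' @param bg_mean_log2,expr_mean_log2,bg_sd_log2,expr_sd_log2 baseline
#'   mixture parameters (log2 scale). Chosen so the expression filter
#'   threshold of 5 bisects the two populations.
#' @param dispersion NB dispersion \eqn{\alpha} (variance
#'   \eqn{\mu + \alpha \mu^2}); 0 gives Poisson counts.
#' @param library_size_factors per-sample positive scalars, or \code{NULL}
#'   to draw lognormal factors (sdlog 0.15) normalized to geometric mean 1.
#' @param x_fraction_background probability that a non-planted gene is
#'   assigned to chromosome X.
#' @param x_fraction_up_planted probability that an up-planted gene is
#'   assigned to chromosome X (the X-desilencing signal).
#' @param n_replicates libraries per (lineage, state) cell.
#' @param seed integer seed; identical parameters and seed give
#'   bit-identical output.
#'
#' @return A validated list of class \code{"simulation_params"}.
#' @export
simulation_params <- function(n_genes = 8000,
                              n_lineages = 3,
                              states = c("P0", "F2", "F4_fertile", "F4_sterile"),
                              severity = c(P0 = 0, F2 = 1,
                                           F4_fertile = 1.5, F4_sterile = 3),
                              n_up_planted = 200,
                              n_down_planted = 50,
                              effect_size_log2 = 1.0,
                              n_lineage_private = 100,
                              private_effect_log2 = 1.0,
                              background_fraction = 0.6,
                              bg_mean_log2 = 2, expr_mean_log2 = 8,
                              bg_sd_log2 = 1, expr_sd_log2 = 1,
                              dispersion = 0.05,
                              library_size_factors = NULL,
                              x_fraction_background = 0.15,
                              x_fraction_up_planted = 0.5,
                              n_replicates = 1,
                              seed = 1L) {
  p <- list(n_genes = as.integer(n_genes), n_lineages = as.integer(n_lineages),
            states = as.character(states), severity = severity,
            n_up_planted = as.integer(n_up_planted),
            n_down_planted = as.integer(n_down_planted),
            effect_size_log2 = effect_size_log2,
            n_lineage_private = as.integer(n_lineage_private),
            private_effect_log2 = private_effect_log2,
            background_fraction = background_fraction,
            bg_mean_log2 = bg_mean_log2, expr_mean_log2 = expr_mean_log2,
            bg_sd_log2 = bg_sd_log2, expr_sd_log2 = expr_sd_log2,
            dispersion = dispersion,
            library_size_factors = library_size_factors,
            x_fraction_background = x_fraction_background,
            x_fraction_up_planted = x_fraction_up_planted,
            n_replicates = as.integer(n_replicates), seed = as.integer(seed))
  class(p) <- "simulation_params"
  validate_simulation_params(p)
  p
}

validate_simulation_params <- function(p) {
  stopifnot(is.list(p))
  if (p$n_genes < 1L) stop("invalid params: n_genes must be >= 1")
  if (p$n_lineages < 1L) stop("invalid params: n_lineages must be >= 1")
  if (anyDuplicated(p$states))
    stop("invalid params: states must be distinct (strictly ordered labels)")
  if (length(p$states) < 2L) stop("invalid params: need >= 2 states")
  if (!all(p$states %in% names(p$severity)))
    stop("invalid params: severity must name every state")
  sev <- p$severity[p$states]
  if (any(!is.finite(sev)) || any(sev < 0))
    stop("invalid params: all severity values must be finite and non-negative")
  if (sev[[1]] != 0)
    stop("invalid params: severity of the first state must be 0")
  if (p$n_up_planted + p$n_down_planted + p$n_lineage_private > p$n_genes)
    stop("invalid params: n_up_planted + n_down_planted + n_lineage_private ",
         "exceeds n_genes")
  if (p$dispersion < 0) stop("invalid params: dispersion must be >= 0")
  if (!is.null(p$library_size_factors)) {
    n_samp <- p$n_lineages * length(p$states) * p$n_replicates
    if (length(p$library_size_factors) != n_samp)
      stop("invalid params: library_size_factors must have one entry per sample")
    if (any(p$library_size_factors <= 0))
      stop("invalid params: all library_size_factors must be > 0")
  }
  for (f in c("background_fraction", "x_fraction_background",
              "x_fraction_up_planted")) {
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("invalid params: ", f, " must lie in [0, 1]")
  }
  if (p$effect_size_log2 <= 0)
    stop("invalid params: effect_size_log2 must be positive")
  if (p$n_replicates < 1L) stop("invalid params: n_replicates must be >= 1")
  invisible(p)
}

#' Simulate a transgenerational count experiment
#'
#' Draws a gene-by-sample integer count matrix with the statistical
#' structure described in [simulation_params()]: a baseline expression
#' mixture, planted global up/down deregulation growing linearly (in log2)
#' with state severity, lineage-private deregulation, library-size
#' variation and NB sampling noise. Chromosome labels are assigned so that
#' up-planted genes can be X-enriched relative to the background.
#'
#' @param params a \code{"simulation_params"} object.
#' @return A list of class \code{"synthetic_experiment"} with elements
#'   \describe{
#'     \item{counts}{integer matrix, genes x samples, dimnames set.}
#'     \item{design}{data.frame with \code{sample_id}, \code{lineage},
#'       \code{state} (and \code{replicate}).}
#'     \item{annotation}{data.frame with \code{gene_id}, \code{chromosome}.}
#'     \item{truth}{data.frame with per-gene \code{label} (one of
#'       \code{up_contributor}, \code{down_contributor},
#'       \code{lineage_private}, \code{background}), \code{baseline_log2},
#'       signed effect \code{delta}, and \code{private_lineage}.}
#'     \item{params}{the input parameters.}
#'   }
#' @examples
#' sim <- simulate_counts(simulation_params(n_genes = 200, seed = 7))
#' dim(sim$counts)      # 200 x 12
#' table(sim$truth$label)
#' @export
simulate_counts <- function(params) {
  validate_simulation_params(params)
  p <- params
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)

  n_states <- length(p$states)
  genes <- sprintf("gene_%05d", seq_len(p$n_genes))

  ## design: one row per lineage x state x replicate, lineage-major
  design <- expand.grid(replicate = seq_len(p$n_replicates),
                        state = p$states, lineage = seq_len(p$n_lineages),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[, c("lineage", "state", "replicate")]
  design$lineage <- paste0("L", design$lineage)
  design$sample_id <- if (p$n_replicates == 1L)
    paste(design$lineage, design$state, sep = "_")
  else
    paste(design$lineage, design$state, paste0("r", design$replicate), sep = "_")
  design <- design[, c("sample_id", "lineage", "state", "replicate")]
  n_samp <- nrow(design)

  ## gene labels: planted first, then private, rest background
  label <- rep("background", p$n_genes)
  i_up <- seq_len(p$n_up_planted)
  i_down <- seq_len(p$n_down_planted) + p$n_up_planted
  i_priv <- seq_len(p$n_lineage_private) + p$n_up_planted + p$n_down_planted
  label[i_up] <- "up_contributor"
  label[i_down] <- "down_contributor"
  label[i_priv] <- "lineage_private"

  ## baseline mixture; planted and private genes use the expressed component
  ## so that they survive the max-expression filter (they must be members of
  ## the analysis universe for recovery to be defined)
  is_bg_component <- stats::runif(p$n_genes) < p$background_fraction
  is_bg_component[label != "background"] <- FALSE
  beta <- ifelse(is_bg_component,
                 stats::rnorm(p$n_genes, p$bg_mean_log2, p$bg_sd_log2),
                 stats::rnorm(p$n_genes, p$expr_mean_log2, p$expr_sd_log2))

  delta <- numeric(p$n_genes)
  delta[i_up] <- p$effect_size_log2
  delta[i_down] <- -p$effect_size_log2

  private_lineage <- rep(NA_character_, p$n_genes)
  private_sign <- numeric(p$n_genes)
  if (p$n_lineage_private > 0L) {
    private_lineage[i_priv] <-
      paste0("L", sample.int(p$n_lineages, p$n_lineage_private, replace = TRUE))
    private_sign[i_priv] <- sample(c(-1, 1), p$n_lineage_private, replace = TRUE)
  }

  ## chromosomes: X with configured probabilities, autosomes uniform I..V
  autosomes <- c("I", "II", "III", "IV", "V")
  p_x <- ifelse(label == "up_contributor",
                p$x_fraction_up_planted, p$x_fraction_background)
  on_x <- stats::runif(p$n_genes) < p_x
  chrom <- ifelse(on_x, "X",
                  autosomes[sample.int(5L, p$n_genes, replace = TRUE)])

  sf <- p$library_size_factors
  if (is.null(sf)) {
    sf <- exp(stats::rnorm(n_samp, 0, 0.15))
    sf <- sf / exp(mean(log(sf)))
  }

  sev <- p$severity[design$state]
  ## log2 mean matrix: beta + delta * t(s) + pi_{g,l} * t(s)
  log2mu <- outer(beta, rep(1, n_samp)) + outer(delta, sev)
  if (p$n_lineage_private > 0L) {
    for (g in i_priv) {
      l_hit <- design$lineage == private_lineage[g]
      log2mu[g, l_hit] <- log2mu[g, l_hit] +
        private_sign[g] * p$private_effect_log2 * sev[l_hit]
    }
  }
  mu <- sweep(2^log2mu, 2L, sf, `*`)

  counts <- if (p$dispersion == 0) {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = p$n_genes)
  } else {
    matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / p$dispersion),
           nrow = p$n_genes)
  }
  dimnames(counts) <- list(genes, design$sample_id)
  storage.mode(counts) <- "integer"

  truth <- data.frame(gene_id = genes, label = label,
                      baseline_log2 = beta,
                      delta = delta * ifelse(label %in%
                        c("up_contributor", "down_contributor"), 1, 0),
                      private_lineage = private_lineage,
                      private_effect = private_sign * p$private_effect_log2,
                      stringsAsFactors = FALSE)

  out <- list(counts = counts, design = design,
              annotation = data.frame(gene_id = genes, chromosome = chrom,
                                      stringsAsFactors = FALSE),
              truth = truth, size_factors = sf, params = p)
  class(out) <- "synthetic_experiment"
  out
}

#' @export
print.synthetic_experiment <- function(x, ...) {
  cat(sprintf("synthetic_experiment: %d genes x %d samples (%d lineages x %d states x %d reps)\n",
              nrow(x$counts), ncol(x$counts), x$params$n_lineages,
              length(x$params$states), x$params$n_replicates))
  print(table(x$truth$label))
  invisible(x)
}

## save/restore the RNG state so simulate_counts() is a pure function of its
## seed and does not perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Write a synthetic experiment to disk
#'
#' Serializes counts, design and annotation as TSV, the planted truth sets
#' as GMT, and the parameters (with seed) as a JSON sidecar, so a run can
#' be reproduced from files alone.
#'
#' @param sim a \code{"synthetic_experiment"}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             design = file.path(dir, "design.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             truth_sets = file.path(dir, "truth_sets.gmt"),
             truth = file.path(dir, "truth.tsv"),
             params = file.path(dir, "params.json"))
  write_matrix_tsv(sim$counts, paths[["counts"]])
  write_tsv(sim$design, paths[["design"]])
  write_tsv(sim$annotation, paths[["annotation"]])
  write_tsv(sim$truth, paths[["truth"]])
  sets <- list(
    planted_up = sim$truth$gene_id[sim$truth$label == "up_contributor"],
    planted_down = sim$truth$gene_id[sim$truth$label == "down_contributor"])
  write_gmt(sets, paths[["truth_sets"]],
            descriptions = c("planted up-contributors",
                             "planted down-contributors"))
  par <- sim$params
  class(par) <- NULL
  jsonlite::write_json(par, paths[["params"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(paths)
}
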