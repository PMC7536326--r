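#' Pipeline configuration
#'
#' Bundles paths, thresholds and options for [run_all()]. Inputs may be
#' file paths (TSV/GMT) or in-memory objects; when \code{sim} is supplied
#' the counts/design/annotation inputs are generated by the simulator
#' instead and written alongside the results.
#'
#' @param counts path to a counts TSV or a genes x samples integer matrix.
#' @param design path to a design TSV or a data.frame
#'   (\code{sample_id}, \code{lineage}, \code{state}).
#' @param annotation path to an annotation TSV or a data.frame
#'   (\code{gene_id}, \code{chromosome}); optional.
#' @param gene_sets path to a GMT file or a named list of gene sets;
#'   optional.
#' @param out_dir output directory.
#' @param filter_threshold expression-filter cutoff (log2 scale,
#'   default 5).
#' @param de_alpha adjusted-p threshold for the DE counting stage
#'   (default 1e-5; the printed "10e-6" read literally).
#' @param n_down,n_up contributor list sizes (defaults 250 / 1000).
#' @param quorum amplification lineage quorum (default: all lineages).
#' @param states ordered generation-state labels.
#' @param sim optional \code{"simulation_params"} object.
#' @param seed integer seed (propagated to the simulator).
#' @return list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(counts = NULL, design = NULL, annotation = NULL,
                            gene_sets = NULL, out_dir,
                            filter_threshold = 5, de_alpha = 1e-5,
                            n_down = 250, n_up = 1000, quorum = NULL,
                            states = c("P0", "F2", "F4_fertile",
                                       "F4_sterile"),
                            sim = NULL, seed = 1L) {
  if (filter_threshold <= 0 || de_alpha <= 0 || n_down <= 0 || n_up <= 0)
    stop("all thresholds must be positive")
  if (is.null(sim) && is.null(counts))
    stop("either counts or a sim block must be provided")
  structure(list(counts = counts, design = design, annotation = annotation,
                 gene_sets = gene_sets, out_dir = out_dir,
                 filter_threshold = filter_threshold, de_alpha = de_alpha,
                 n_down = n_down, n_up = n_up, quorum = quorum,
                 states = states, sim = sim, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: (optional) simulation, normalization, log
#' transform, expression filtering, PCA on samples, PCA on
#' within-lineage differences, within-class analysis, WCA-score
#' extraction, contributor selection, trajectory classification,
#' DE counting versus P0, and (when inputs allow) gene-set and chromosome
#' enrichment. Every stage writes its outputs under \code{out_dir} and is
#' recorded, with MD5 checksums, in a JSON run manifest; re-running with
#' an identical configuration and inputs reproduces identical checksums.
#' A stage failure aborts with the stage name and marks the manifest
#' incomplete.
#'
#' @param config a \code{"pipeline_config"}.
#' @return invisibly, the manifest list (also written to
#'   \code{out_dir/manifest.json}).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "wcadrift",
    version = as.character(utils::packageVersion("wcadrift")),
    seed = cfg$seed,
    config = serialize_config(cfg),
    stages = list(), complete = FALSE)
  log_msg <- function(...) message("[wcadrift] ", ...)

  record <- function(stage, files) {
    files <- unlist(files, use.names = FALSE)
    sums <- as.list(tools::md5sum(files))
    manifest$stages[[stage]] <<- list(outputs = sums)
    log_msg("stage '", stage, "' wrote ", length(files), " file(s)")
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e) {
      write_manifest(manifest, cfg$out_dir)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out <- function(...) file.path(cfg$out_dir, ...)

  ## -- inputs (simulated or loaded) ---------------------------------------
  if (!is.null(cfg$sim)) {
    run_stage("simulate", function() {
      sim_par <- cfg$sim
      sim_par$seed <- cfg$seed
      sim <- simulate_counts(sim_par)
      paths <- write_synthetic(sim, out("sim"))
      cfg$counts <<- sim$counts
      cfg$design <<- sim$design
      cfg$annotation <<- sim$annotation
      cfg$gene_sets <<- read_gmt(paths[["truth_sets"]])
      record("simulate", paths)
    })
  }
  counts <- if (is.character(cfg$counts)) read_matrix_tsv(cfg$counts)
            else cfg$counts
  storage.mode(counts) <- "double"
  design <- if (is.character(cfg$design)) read_design(cfg$design)
            else cfg$design
  annotation <- if (is.character(cfg$annotation))
    read_annotation(cfg$annotation) else cfg$annotation
  gene_sets <- if (is.character(cfg$gene_sets)) read_gmt(cfg$gene_sets)
               else cfg$gene_sets
  if (!setequal(design$sample_id, colnames(counts)))
    stop("design does not cover the count matrix samples")
  design <- design[match(colnames(counts), design$sample_id), ]

  ## -- preprocess ----------------------------------------------------------
  env <- new.env()
  run_stage("normalize", function() {
    sf <- estimate_size_factors(counts)
    nm <- normalize_counts(counts, sf)
    lm <- log_transform(nm)
    write_tsv(data.frame(sample_id = names(sf), size_factor = sf),
              out("size_factors.tsv"))
    write_matrix_tsv(nm, out("normalized.tsv"))
    write_matrix_tsv(lm, out("log_expression.tsv"))
    env$lm <- lm; env$sf <- sf
    record("normalize", c(out("size_factors.tsv"), out("normalized.tsv"),
                          out("log_expression.tsv")))
  })
  run_stage("filter", function() {
    summ <- expression_sd_summary(env$lm)
    env$universe <- filter_expressed(env$lm, cfg$filter_threshold)
    write_tsv(summ, out("max_sd_summary.tsv"))
    writeLines(env$universe, out("universe.txt"))
    record("filter", c(out("max_sd_summary.tsv"), out("universe.txt")))
  })
  run_stage("de_counts", function() {
    other <- setdiff(cfg$states, cfg$states[1L])
    cnt <- vapply(other, function(s) {
      res <- de_count_vs_p0(counts, design, s, alpha = cfg$de_alpha,
                            p0_state = cfg$states[1L], size_factors = env$sf)
      write_tsv(res$table, out(paste0("de_", s, "_vs_", cfg$states[1L], ".tsv")))
      res$n_signif
    }, numeric(1))
    write_tsv(data.frame(state = other, n_signif = as.integer(cnt)),
              out("de_counts.tsv"))
    record("de_counts", c(out("de_counts.tsv"),
                          out(paste0("de_", other, "_vs_", cfg$states[1L],
                                     ".tsv"))))
  })

  ## -- multivariate --------------------------------------------------------
  run_stage("sample_pca", function() {
    res <- pca(t(env$lm))
    write_pca_tables(res, out, "sample_pca")
    record("sample_pca", c(out("sample_pca_eigenvalues.tsv"),
                           out("sample_pca_coordinates.tsv")))
  })
  run_stage("difference_pca", function() {
    dlm <- build_diff_matrix(env$lm, design, cfg$states)
    write_matrix_tsv(dlm, out("difference_matrix.tsv"))
    res <- pca_on_differences(dlm)
    write_pca_tables(res, out, "difference_pca")
    record("difference_pca", c(out("difference_matrix.tsv"),
                               out("difference_pca_eigenvalues.tsv"),
                               out("difference_pca_coordinates.tsv")))
  })
  run_stage("wca", function() {
    xs <- t(env$lm[env$universe, , drop = FALSE])
    env$wca <- wca(xs, design$lineage,
                   state_rank = match(design$state, cfg$states))
    env$scores <- wca_scores(env$wca)
    k <- length(env$wca$eigenvalues)
    write_tsv(data.frame(component = seq_len(k),
                         eigenvalue = env$wca$eigenvalues,
                         pve = env$wca$pve),
              out("wca_eigenvalues.tsv"))
    write_tsv(data.frame(sample_id = rownames(env$wca$sample_coordinates),
                         lineage = design$lineage, state = design$state,
                         env$wca$sample_coordinates, check.names = FALSE),
              out("wca_coordinates.tsv"))
    sc <- sort(env$scores, decreasing = TRUE)
    write_tsv(data.frame(gene_id = names(sc), wca_score = sc,
                         rank = seq_along(sc)),
              out("wca_scores.tsv"))
    record("wca", c(out("wca_eigenvalues.tsv"), out("wca_coordinates.tsv"),
                    out("wca_scores.tsv")))
  })

  ## -- contributors --------------------------------------------------------
  run_stage("contributors", function() {
    env$sets <- select_contributors(env$scores, cfg$n_down, cfg$n_up)
    writeLines(env$sets$down, out("contributors_down.txt"))
    writeLines(env$sets$up, out("contributors_up.txt"))
    write_gmt(list(upregulated_contributors = env$sets$up,
                   downregulated_contributors = env$sets$down),
              out("contributors.gmt"))
    asym <- score_asymmetry(env$scores)
    write_tsv(data.frame(n_positive = asym$n_positive,
                         n_negative = asym$n_negative,
                         p_value = asym$p_value),
              out("score_asymmetry.tsv"))
    record("contributors", c(out("contributors_down.txt"),
                             out("contributors_up.txt"),
                             out("contributors.gmt"),
                             out("score_asymmetry.tsv")))
  })
  run_stage("trajectories", function() {
    genes <- c(env$sets$down, env$sets$up)
    tab <- trajectory_table(env$lm, design, genes, cfg$states,
                            quorum = cfg$quorum)
    write_tsv(tab, out("trajectories.tsv"))
    record("trajectories", out("trajectories.tsv"))
  })

  ## -- enrichment ----------------------------------------------------------
  if (!is.null(gene_sets)) {
    run_stage("enrichment", function() {
      files <- character(0)
      for (side in c("up", "down")) {
        res <- enrich_sets(env$sets[[side]], gene_sets, env$universe)
        f <- out(paste0("enrichment_", side, ".tsv"))
        write_tsv(res, f); files <- c(files, f)
      }
      record("enrichment", files)
    })
  }
  if (!is.null(annotation)) {
    run_stage("chromosomes", function() {
      files <- character(0)
      for (side in c("up", "down")) {
        cd <- chromosome_distribution(env$sets[[side]], annotation,
                                      env$universe)
        f <- out(paste0("chromosome_", side, ".tsv"))
        tab <- cd$per_chromosome
        tab$chisq_statistic <- cd$chisq_statistic
        tab$chisq_p <- cd$chisq_p
        write_tsv(tab, f); files <- c(files, f)
      }
      cmp <- score_distribution_compare(env$scores, annotation)
      f <- out("x_vs_autosome_scores.tsv")
      write_tsv(as.data.frame(cmp), f); files <- c(files, f)
      record("chromosomes", files)
    })
  }

  manifest$complete <- TRUE
  write_manifest(manifest, cfg$out_dir)
  invisible(manifest)
}

write_pca_tables <- function(res, out, prefix) {
  k <- length(res$eigenvalues)
  write_tsv(data.frame(component = seq_len(k), eigenvalue = res$eigenvalues,
                       pve = res$percent_variance),
            out(paste0(prefix, "_eigenvalues.tsv")))
  write_tsv(data.frame(id = rownames(res$row_coordinates),
                       res$row_coordinates, check.names = FALSE),
            out(paste0(prefix, "_coordinates.tsv")))
}

serialize_config <- function(cfg) {
  s <- unclass(cfg)
  for (f in c("counts", "design", "annotation", "gene_sets"))
    if (!is.null(s[[f]]) && !is.character(s[[f]]))
      s[[f]] <- paste0("<in-memory ", class(s[[f]])[1L], ">")
  if (!is.null(s$sim)) s$sim <- unclass(s$sim)
  s
}

write_manifest <- function(manifest, out_dir) {
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}
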