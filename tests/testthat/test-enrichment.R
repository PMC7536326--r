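test_that("hypergeometric tails: bounds, brute force, invariants", {
  expect_equal(hypergeom_tail(5, 5, 5, 5, "over"), 1)
  expect_error(hypergeom_tail(6, 4, 5, 10), "impossible overlap")
  expect_error(hypergeom_tail(1, 11, 5, 10), "<= N")

  ## exhaustive enumeration over all C(10,5) draws
  expect_equal(hypergeom_tail(3, 4, 5, 10, "over"),
               oracle_hyper_enum(3, 4, 5, 10, "over"), tolerance = 1e-12)
  expect_equal(hypergeom_tail(1, 4, 5, 10, "under"),
               oracle_hyper_enum(1, 4, 5, 10, "under"), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:40) {
    N <- sample(5:60, 1)
    K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n + K - N); hi <- min(K, n)
    k <- if (lo == hi) lo else sample(lo:hi, 1)
    for (dir in c("over", "under")) {
      p <- hypergeom_tail(k, K, n, N, dir)
      o <- oracle_hyper_tail(k, K, n, N, dir)
      expect_lt(abs(p - o) / max(o, .Machine$double.xmin), 1e-10)
      ## symmetry under swapping K and n
      expect_equal(p, hypergeom_tail(k, n, K, N, dir), tolerance = 1e-12)
    }
    ## tail complementarity: p_over + p_under - P(X = k) = 1
    pmf <- dhyper(k, K, N - K, n)
    expect_equal(hypergeom_tail(k, K, n, N, "over") +
                 hypergeom_tail(k, K, n, N, "under") - pmf, 1,
                 tolerance = 1e-12)
  }

  ## log-space summation keeps relative accuracy at extreme tails
  p_far <- hypergeom_tail(120, 600, 700, 20000, "over")
  expect_lt(p_far, 1e-50)
  expect_equal(p_far, phyper(119, 600, 19400, 700, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("fold enrichment: expectation gives 1, oracle on random counts", {
  expect_equal(fold_enrichment(6, 30, 20, 100), 1)   # k = K n / N exactly
  expect_error(fold_enrichment(0, 0, 5, 10), "undefined")
  set.seed(8)
  for (i in 1:10) {
    N <- sample(50:500, 1); K <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(fold_enrichment(k, K, n, N), (k / n) / (K / N),
                 tolerance = 1e-12)
  }
})

test_that("enrich_sets: toy fixture with hand-counted overlaps", {
  universe <- paste0("g", 1:20)
  sets <- list(s1 = paste0("g", 1:5),              # K = 5
               s2 = paste0("g", c(4:8, 99)),        # K = 5 after intersection
               s3 = paste0("g", 16:20))             # K = 5
  query <- paste0("g", c(1, 2, 3, 6, 17))           # n = 5
  res <- enrich_sets(query, sets, universe)
  expect_equal(res$k, c(3, 1, 1))
  expect_equal(res$K, c(5, 5, 5))
  expect_equal(res$N, rep(20, 3))
  expect_equal(res$fold, c(3, 1, 1) * 20 / (5 * 5))
  for (i in 1:3) {
    expect_equal(res$p_over[i],
                 oracle_hyper_tail(res$k[i], 5, 5, 20, "over"),
                 tolerance = 1e-12)
    expect_equal(res$p_under[i],
                 oracle_hyper_tail(res$k[i], 5, 5, 20, "under"),
                 tolerance = 1e-12)
  }
  ## query = universe -> k = K, fold = 1 at n = N
  r2 <- enrich_sets(universe, sets["s1"], universe)
  expect_equal(r2$k, r2$K)
  expect_equal(r2$fold, 1)
  ## out-of-universe query ids dropped with a message
  expect_message(enrich_sets(c(query, "zz"), sets, universe), "dropped")
  expect_error(enrich_sets(query, sets, character(0)), "empty universe")
})

test_that("planted truth sets are detected in recovered contributors", {
  sim <- simulate_counts(simulation_params(n_genes = 2000, seed = 19))
  core <- run_core(sim)
  sets <- select_contributors(core$scores, n_down = 50, n_up = 200)
  truth_sets <- list(planted_up = truth_ids(sim, "up_contributor"),
                     planted_down = truth_ids(sim, "down_contributor"))
  r_up <- enrich_sets(sets$up, truth_sets, core$universe)
  expect_lt(r_up$p_over[r_up$set == "planted_up"], 1e-6)
  r_dn <- enrich_sets(sets$down, truth_sets, core$universe)
  expect_lt(r_dn$p_over[r_dn$set == "planted_down"], 1e-6)
})

test_that("chromosome distribution: degenerate and null behaviour", {
  ann <- data.frame(gene_id = paste0("g", 1:30),
                    chromosome = rep("I", 30))
  cd <- chromosome_distribution(paste0("g", 1:4), ann, paste0("g", 1:30))
  expect_equal(cd$per_chromosome$k, 4)
  expect_equal(cd$per_chromosome$p_over, 1)

  expect_error(
    chromosome_distribution("g1", ann[1:10, ], paste0("g", 1:30)),
    "unannotated")

  ## uniform null queries: no chromosome should light up
  set.seed(41)
  universe <- paste0("g", 1:2000)
  ann2 <- data.frame(gene_id = universe,
                     chromosome = sample(c("I", "II", "III", "IV", "V", "X"),
                                         2000, replace = TRUE,
                                         prob = c(rep(0.17, 5), 0.15)))
  hits <- vapply(1:20, function(i) {
    q <- sample(universe, 150)
    any(chromosome_distribution(q, ann2, universe)$per_chromosome$p_over
        < 0.001)
  }, logical(1))
  expect_gte(mean(!hits), 0.95)
})

test_that("planted X-enrichment of up contributors is detected", {
  sim <- simulate_counts(simulation_params(n_genes = 2000, seed = 19))
  core <- run_core(sim)
  sets <- select_contributors(core$scores, n_down = 50, n_up = 200)
  cd <- chromosome_distribution(sets$up, sim$annotation, core$universe)
  px <- cd$per_chromosome$p_over[cd$per_chromosome$set == "X"]
  expect_lt(px, 1e-3)
  expect_lt(cd$chisq_p, 1e-3)
})

test_that("score comparison: identical groups null, power, exact oracle", {
  ann <- data.frame(gene_id = paste0("g", 1:40),
                    chromosome = rep(c("X", "I"), each = 20))
  sc <- setNames(rep(c(1, 2, 3, 4), 10), paste0("g", 1:40))
  r <- suppressWarnings(score_distribution_compare(sc, ann))  # tied toy data
  expect_gt(r$p_value, 0.5)                     # same distribution
  expect_equal(r$median_group, r$median_rest)

  ## exact permutation-enumeration oracle at n1 = n2 = 5 (no ties)
  set.seed(3)
  vals <- sample(seq(0.1, 1, by = 0.1))
  ann5 <- data.frame(gene_id = paste0("g", 1:10),
                     chromosome = rep(c("X", "II"), each = 5))
  sc5 <- setNames(vals, paste0("g", 1:10))
  r5 <- score_distribution_compare(sc5, ann5)
  combs <- combn(10, 5)
  wstat <- apply(combs, 2, function(i) sum(rank(vals)[i]) - 15)
  obs <- sum(rank(vals)[1:5]) - 15
  p_enum <- mean(abs(wstat - 12.5) >= abs(obs - 12.5))
  expect_equal(r5$p_value, p_enum, tolerance = 1e-12)

  ## shifted X scores (n >= 200 per group) are detected
  detected <- vapply(1:5, function(seed) {
    set.seed(seed + 500)
    scn <- setNames(c(rnorm(250, 0.02, 0.05), rnorm(250, 0, 0.05)),
                    paste0("g", 1:500))
    annn <- data.frame(gene_id = paste0("g", 1:500),
                       chromosome = rep(c("X", "III"), each = 250))
    score_distribution_compare(scn, annn)$p_value < 0.01
  }, logical(1))
  expect_gte(mean(detected), 0.9)

  expect_error(score_distribution_compare(sc, ann, group_chromosomes = "V"),
               "non-empty")
})

test_that("overlap test: disjoint, identical, and singleton-set consistency", {
  universe <- paste0("g", 1:50)
  a <- paste0("g", 1:10); b <- paste0("g", 11:25)
  r <- overlap_test(a, b, universe)
  expect_equal(r$k, 0)
  expect_lte(r$p_under, r$p_over)
  r2 <- overlap_test(a, a, universe)
  expect_equal(r2$k, 10)
  expect_equal(r2$p_over, oracle_hyper_tail(10, 10, 10, 50, "over"),
               tolerance = 1e-12)
  ## internal consistency with enrich_sets on a singleton set
  r3 <- overlap_test(a, b, universe)
  r4 <- enrich_sets(a, list(b = b), universe)
  expect_equal(r3[, -1], r4[, -1], ignore_attr = TRUE)
})
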