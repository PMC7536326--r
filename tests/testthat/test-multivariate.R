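rand_mat <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(p))))
}

test_that("pca basics: degenerate inputs and the 2x2 hand case", {
  m <- matrix(rep(c(1, 2, 3), each = 4), 4, 3)
  expect_length(pca(m)$eigenvalues, 0)           # identical rows -> no variance

  ## rows (0,0) and (2,0): one component along variable 1, eigenvalue 1
  ## under 1/n weighting (centered values +-1, mean square = 1)
  r <- pca(matrix(c(0, 0, 2, 0), 2, 2, byrow = TRUE))
  expect_length(r$eigenvalues, 1)
  expect_equal(r$eigenvalues, 1)
  expect_equal(abs(r$variable_loadings[, 1]), c(1, 0))
  expect_equal(r$percent_variance, 100)

  expect_error(pca(matrix(1, 1, 3)), ">= 2 individuals")
  expect_error(pca(matrix(c(1, 2, NA, 3), 2, 2)), "finite")
  m2 <- rand_mat(5, 3, 1); m2[, 2] <- 7
  expect_error(pca(m2, scale = TRUE), "g2")
})

test_that("pca matches the explicit-covariance oracle on random matrices", {
  for (seed in 1:5) {
    x <- rand_mat(8, 5, seed)
    r <- pca(x)
    o <- oracle_pca(x)
    k <- length(r$eigenvalues)
    expect_equal(r$eigenvalues, o$eigenvalues[seq_len(k)], tolerance = 1e-10)
    for (j in seq_len(k))
      expect_equal(abs_cosine(r$variable_loadings[, j], o$loadings[, j]), 1,
                   tolerance = 1e-10)
    ## contract invariants
    expect_equal(sum(r$percent_variance), 100, tolerance = 1e-9)
    expect_false(is.unsorted(rev(r$eigenvalues)))
    g <- crossprod(r$variable_loadings)
    expect_equal(g, diag(k), tolerance = 1e-9, ignore_attr = TRUE)
    ## row coordinates = centered matrix projected on loadings
    xc <- sweep(x, 2, colMeans(x), `-`)
    expect_equal(r$row_coordinates, xc %*% r$variable_loadings,
                 tolerance = 1e-10)
  }
})

test_that("difference matrix has lineage x transition columns in order", {
  sim <- tiny_sim(40, seed = 2)
  lm <- log_transform(normalize_counts(sim$counts, rep(1, 12)))
  dlm <- build_diff_matrix(lm, sim$design)
  expect_equal(dim(dlm), c(40L, 9L))              # 3 lineages x 3 transitions
  expect_equal(colnames(dlm)[1:3],
               c("L1:P0->F2", "L1:F2->F4_fertile",
                 "L1:F4_fertile->F4_sterile"))
  ## hand subtraction on a toy matrix
  d <- sim$design
  expect_equal(dlm[, "L2:P0->F2"],
               lm[, d$sample_id[d$lineage == "L2" & d$state == "F2"]] -
               lm[, d$sample_id[d$lineage == "L2" & d$state == "P0"]])
  ## equal columns -> zero difference column
  lm2 <- lm
  lm2[, "L1_F2"] <- lm2[, "L1_P0"]
  expect_true(all(build_diff_matrix(lm2, d)[, "L1:P0->F2"] == 0))
  ## missing cell is identified
  expect_error(build_diff_matrix(lm, d[d$sample_id != "L3_F2", ]),
               "L3, F2")
})

test_that("difference PCA clusters same-transition profiles (two-step signal)", {
  ## planted two-step deregulation, no lineage-private effects
  sim <- simulate_counts(simulation_params(
    n_genes = 2000, n_lineage_private = 0, seed = 31))
  core <- run_core(sim)
  dlm <- build_diff_matrix(core$lm, sim$design)
  r <- pca_on_differences(dlm)
  co <- r$row_coordinates
  grp <- sub("^L[0-9]+:", "", rownames(co))
  ## PC1: all P0->F2 profiles on one side-consistent sign, all
  ## F4_fertile->F4_sterile profiles consistent sign
  expect_equal(length(unique(sign(co[grp == "P0->F2", 1]))), 1L)
  expect_equal(length(unique(sign(co[grp == "F4_fertile->F4_sterile", 1]))),
               1L)
  ## same-transition distances smaller than different-transition distances
  dm <- as.matrix(dist(co))
  same <- outer(grp, grp, "==") & upper.tri(dm)
  diff_ <- outer(grp, grp, "!=") & upper.tri(dm)
  expect_lt(mean(dm[same]), mean(dm[diff_]))

  expect_error(pca_on_differences(dlm[, 1, drop = FALSE]), ">= 2")
})

test_that("wca matches the explicit class-centered oracle (12x40, 3 classes)", {
  classes <- rep(c("a", "b", "c"), each = 4)
  for (seed in 1:5) {
    x <- rand_mat(12, 40, seed + 100)
    r <- wca(x, classes)
    o <- oracle_wca(x, classes)
    k <- length(r$eigenvalues)
    expect_equal(k, 9L)                            # min(12 - 3, 40)
    expect_equal(r$eigenvalues, o$eigenvalues[seq_len(k)], tolerance = 1e-10)
    for (j in seq_len(k))
      expect_equal(abs_cosine(r$gene_loadings[, j], o$loadings[, j]), 1,
                   tolerance = 1e-10)
    expect_equal(sum(r$pve), 100, tolerance = 1e-9)
    ## class means of the class-centered matrix are exactly zero
    for (cl in unique(classes))
      expect_lt(max(abs(colMeans(o$centered[classes == cl, ]))), 1e-10)
    ## conservation: sum of eigenvalues = within-class variance
    expect_equal(sum(r$eigenvalues), r$within_variance,
                 tolerance = 1e-9 * r$within_variance)
    ## between + within = total
    xc <- sweep(x, 2, colMeans(x), `-`)
    between <- sum(colMeans((xc - o$centered)^2))
    expect_equal(between + r$within_variance, r$total_variance,
                 tolerance = 1e-9 * r$total_variance)
  }
})

test_that("wca degenerate limits: one class equals pca, singletons vanish", {
  x <- rand_mat(10, 25, 9)
  expect_warning(r1 <- wca(x, rep("all", 10)), "single class")
  rp <- pca(x)
  expect_equal(r1$eigenvalues, rp$eigenvalues, tolerance = 1e-10)
  expect_gte(abs_cosine(r1$gene_loadings[, 1], rp$variable_loadings[, 1]),
             0.999)

  expect_warning(r2 <- wca(x, paste0("s", 1:10)), "singleton")
  expect_true(length(r2$eigenvalues) == 0 || all(r2$eigenvalues == 0))

  expect_error(wca(x, rep(c("a", NA), 5)), "missing")
  expect_error(wca(x, c("a", "b")), "one class label per sample")
})

test_that("eigenvalues are invariant to gene permutation; loadings permute", {
  x <- rand_mat(12, 30, 55)
  classes <- rep(c("a", "b", "c"), each = 4)
  perm <- sample(30)
  r1 <- wca(x, classes)
  r2 <- wca(x[, perm], classes)
  expect_equal(r1$eigenvalues, r2$eigenvalues, tolerance = 1e-10)
  for (j in seq_len(3))
    expect_equal(abs_cosine(r1$gene_loadings[perm, j],
                            r2$gene_loadings[, j]), 1, tolerance = 1e-10)
})

test_that("wca scores: unit norm, orientation, degenerate dominance", {
  classes <- rep(c("a", "b", "c"), each = 4)
  x <- rand_mat(12, 30, 71)
  r <- wca(x, classes)
  sc <- wca_scores(r)
  expect_equal(sqrt(sum(sc^2)), 1, tolerance = 1e-12)
  expect_named(sc)

  ## a single gene carrying all within-class variance takes |score| -> 1
  x0 <- matrix(0, 12, 30,
               dimnames = list(paste0("s", 1:12), paste0("g", 1:30)))
  x0[, 5] <- rep(c(-1, -0.5, 0.5, 1), 3)
  sc0 <- wca_scores(wca(x0 + rand_mat(12, 30, 3) * 1e-6, classes))
  expect_gt(abs(sc0[5]), 0.999)
  expect_lt(max(abs(sc0[-5])), 0.01)

  ## severity orientation: planted up genes load positive
  sim <- simulate_counts(simulation_params(n_genes = 1500, seed = 17))
  core <- run_core(sim)
  up <- intersect(truth_ids(sim, "up_contributor"), core$universe)
  bg <- intersect(truth_ids(sim, "background"), core$universe)
  expect_gt(mean(core$scores[up]), 0)
  expect_gt(mean(core$scores[up]), mean(core$scores[bg]))
})

test_that("no-lineage-effect limit: wca scores align with plain PCA loadings", {
  sim <- simulate_counts(simulation_params(
    n_genes = 1500, n_lineage_private = 0, seed = 23))
  core <- run_core(sim)
  rp <- pca(t(core$lm[core$universe, ]))
  expect_gte(abs_cosine(core$scores, rp$variable_loadings[, 1]), 0.99)
})

test_that("subset pve: consistency, single gene, oracle on sliced matrix", {
  classes <- rep(c("a", "b", "c"), each = 4)
  x <- rand_mat(12, 30, 88)
  r <- wca(x, classes)
  expect_equal(subset_wca_pve(x, classes, colnames(x)), r$pve[1])
  expect_equal(subset_wca_pve(x, classes, "g7"), 100)
  sub <- c("g2", "g9", "g15", "g30")
  o <- oracle_wca(x[, sub], classes)
  ev <- o$eigenvalues[o$eigenvalues > 1e-12 * o$eigenvalues[1]]
  expect_equal(subset_wca_pve(x, classes, sub), 100 * ev[1] / sum(ev),
               tolerance = 1e-9)
  expect_error(subset_wca_pve(x, classes, character(0)), "non-empty")
  expect_error(subset_wca_pve(x, classes, "nope"), "not in matrix")
})
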