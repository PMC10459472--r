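test_that("CV filter keeps variable DEGs and drops stable ones", {
  x <- rbind(hi = c(7, 13, 10, 16, 4, 10),    # mean 10, sd 3 -> CV > 0.2
             flat = rep(10, 6),               # CV 0 -> removed
             lo = c(9.5, 10.5, 10, 10, 9.8, 10.2))
  colnames(x) <- paste0("s", 1:6)
  em <- expression_matrix(x, "ctf_cpm")
  kept <- select_variable_genes(em, c("hi", "flat", "lo"), 0.2)
  expect_equal(kept, "hi")
  expect_gt(sd(x["hi", ]) / mean(x["hi", ]), 0.2)

  # genes with non-positive mean are excluded with a warning
  x2 <- rbind(x, neg = c(-5, 5, -5, 5, -5, 5))
  em2 <- expression_matrix(x2, "ctf_cpm")
  expect_warning(kept2 <- select_variable_genes(em2, rownames(x2), 0.2),
                 "non-positive")
  expect_false("neg" %in% kept2)
})

test_that("correlation distance matches the sum-formula oracle", {
  set.seed(31)
  x <- matrix(rnorm(6 * 10), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  em <- expression_matrix(x, "scaled")
  dm <- correlation_distance(em)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(dm$d[i, j], 1 - oracle_pearson(x[i, ], x[j, ]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(diag(dm$d)), rep(0, 6))
  expect_equal(dm$d, t(dm$d))
  expect_true(all(dm$d >= -1e-12 & dm$d <= 2 + 1e-12))

  # identical and exactly opposite profiles
  y <- rbind(a = 1:10, b = 1:10, c = 10:1)
  colnames(y) <- paste0("s", 1:10)
  dm2 <- correlation_distance(expression_matrix(y, "scaled"))
  expect_equal(dm2$d["a", "b"], 0, tolerance = 1e-12)
  expect_equal(dm2$d["a", "c"], 2, tolerance = 1e-12)

  # Euclidean-embedding variant is sqrt(2 d)
  dm3 <- correlation_distance(expression_matrix(y, "scaled"), type = "euclid")
  expect_equal(dm3$d["a", "c"], 2, tolerance = 1e-12)
  expect_equal(dm3$d["a", "b"], 0, tolerance = 1e-6)
})

test_that("AHC recovers planted modules and collapses unstructured data", {
  mp <- module_profiles(c(15, 15), loading = 0.97, seed = 41)
  dm <- correlation_distance(mp$em)
  cfg <- pipeline_config(min_cluster_size = 10)
  sol <- cluster_ahc(dm, cfg)
  expect_equal(sol$k, 2)
  expect_equal(rand_index(sol$assignment, mp$truth), 1)
  ac <- sol$selection_evidence$agglomerative_coefficients
  expect_true(all(ac >= 0 & ac <= 1))

  # one tight blob -> a single cluster
  one <- module_profiles(30, loading = 0.995, seed = 42)
  sol1 <- cluster_ahc(correlation_distance(one$em), cfg)
  expect_equal(sol1$k, 1)
  expect_equal(unname(unique(sol1$assignment)), 1L)

  expect_error(cluster_ahc(correlation_distance(module_profiles(6, 0.9)$em),
                           cfg), "too few genes")
})

test_that("k-means validity vote selects the planted k and ties break low", {
  mp <- module_profiles(c(20, 20, 20), loading = 0.95, seed = 43)
  cfg <- pipeline_config(min_cluster_size = 10, k_max = 6, seed = 43)
  sol <- cluster_kmeans_vote(mp$em, cfg)
  expect_equal(sol$k, 3)
  expect_gte(rand_index(sol$assignment, mp$truth), 0.95)
  expect_equal(sum(sol$selection_evidence$tally), 10)  # ten indices voted

  # tie rule: most-voted k, ties toward the smaller k
  expect_equal(vote_k(c(2, 2, 3, 3, 4)), 2)
  expect_equal(vote_k(c(5, 3, 3, 5)), 3)
  expect_equal(vote_k(c(4L)), 4)

  expect_error(cluster_kmeans_vote(
    expression_matrix(matrix(1, 30, 5,
                             dimnames = list(paste0("g", 1:30),
                                             paste0("s", 1:5))), "scaled"),
    cfg), "degenerate|identical")
})

test_that("Gaussian-mixture BIC selects planted structure", {
  # two well-separated Gaussian clusters in profile space
  set.seed(44)
  x <- rbind(matrix(rnorm(25 * 4, -2, 0.4), 25, 4),
             matrix(rnorm(25 * 4, 2, 0.8), 25, 4))
  rownames(x) <- paste0("g", 1:50); colnames(x) <- paste0("s", 1:4)
  em <- expression_matrix(x, "scaled")
  cfg <- pipeline_config(k_min = 1, k_max = 5, min_cluster_size = 5, seed = 44)
  sol <- cluster_gmm_bic(em, cfg)
  expect_equal(sol$k, 2)
  expect_equal(rand_index(sol$assignment, rep(1:2, each = 25)), 1)
  # posterior responsibilities sum to one per gene
  expect_equal(unname(rowSums(sol$z)), rep(1, 50), tolerance = 1e-10)

  # a single Gaussian cloud prefers k = 1 in nearly every seeded run
  ok <- 0
  for (s in 1:20) {
    set.seed(s)
    x1 <- matrix(rnorm(40 * 4), 40, 4,
                 dimnames = list(paste0("g", 1:40), paste0("s", 1:4)))
    s1 <- cluster_gmm_bic(expression_matrix(x1, "scaled"),
                          pipeline_config(k_min = 1, k_max = 3,
                                          min_cluster_size = 2, seed = s))
    if (s1$k == 1) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("minimum-size enforcement reassigns to the nearest centroid", {
  set.seed(45)
  x <- rbind(matrix(rnorm(15 * 3, 0), 15, 3),
             matrix(rnorm(12 * 3, 6), 12, 3),
             matrix(rnorm(4 * 3, 5.4), 4, 3))
  rownames(x) <- paste0("g", 1:31); colnames(x) <- paste0("s", 1:3)
  sol <- structure(list(algorithm = "KMEANS", k = 3L,
                        assignment = setNames(rep(1:3, c(15, 12, 4)),
                                              rownames(x)),
                        selection_evidence = NULL),
                   class = "cluster_solution")
  cfg <- pipeline_config(min_cluster_size = 10)
  out <- enforce_min_size(sol, x, cfg)
  expect_equal(out$k, 2)
  expect_true(all(out$assignment > 0))
  # brute-force check: each moved gene went to its closest retained centroid
  cent <- rbind(colMeans(x[1:15, ]), colMeans(x[16:27, ]))
  for (g in paste0("g", 28:31)) {
    d <- sqrt(rowSums(sweep(cent, 2, x[g, ])^2))
    keep_label <- out$assignment[paste0("g", c(1, 16))][which.min(d)]
    expect_equal(unname(out$assignment[g]), unname(keep_label))
  }
  # all clusters already large enough -> identity
  sol2 <- sol; sol2$assignment <- setNames(rep(1:2, c(16, 15)), rownames(x))
  expect_identical(enforce_min_size(sol2, x, cfg)$assignment,
                   sol2$assignment)
})

test_that("cluster profiles aggregate medians and are order-invariant", {
  x <- rbind(g1 = c(1, 4), g2 = c(2, 5), g3 = c(3, 9))
  colnames(x) <- c("s1", "s2")
  em <- expression_matrix(x, "scaled")
  emc <- expression_matrix(10 * x, "ctf_cpm")
  sol <- structure(list(algorithm = "AHC", k = 1L,
                        assignment = setNames(c(1L, 1L, 1L), rownames(x))),
                   class = "cluster_solution")
  pr <- profile_clusters(sol, em, emc)
  expect_equal(pr$median_scaled[pr$sample == "s1"], 2)
  expect_equal(pr$sd_scaled[pr$sample == "s1"], 1)
  expect_equal(pr$median_cpm[pr$sample == "s2"], 50)
  expect_equal(unique(pr$n_genes), 3)

  # permuting gene order leaves the aggregate unchanged
  perm <- c("g3", "g1", "g2")
  em_p <- expression_matrix(x[perm, ], "scaled")
  emc_p <- expression_matrix(10 * x[perm, ], "ctf_cpm")
  sol_p <- sol; sol_p$assignment <- sol$assignment[perm]
  expect_equal(profile_clusters(sol_p, em_p, emc_p)$median_scaled,
               pr$median_scaled)

  # singleton cluster -> sd 0
  sol1 <- sol; sol1$assignment <- setNames(c(1L, 2L, 2L), rownames(x))
  sol1$k <- 2L
  pr1 <- profile_clusters(sol1, em, emc)
  expect_equal(pr1$sd_scaled[pr1$cluster == 1], c(0, 0))
})

test_that("solution comparison ranks the planted truth first", {
  mp <- module_profiles(c(20, 20, 20), loading = 0.9, seed = 46)
  dm <- correlation_distance(mp$em)
  truth_sol <- structure(list(algorithm = "TRUTH", k = 3L,
                              assignment = setNames(mp$truth,
                                                    mp$em$gene_ids)),
                         class = "cluster_solution")
  set.seed(46)
  scrambled <- structure(list(algorithm = "RANDOM", k = 3L,
                              assignment = setNames(sample(mp$truth),
                                                    mp$em$gene_ids)),
                         class = "cluster_solution")
  cmp <- compare_solutions(list(truth = truth_sol, random = scrambled),
                           dm, mp$em$values)
  expect_equal(rownames(cmp$quality)[1], "truth")
  expect_true(all(abs(cmp$quality$avg_silhouette) <= 1, na.rm = TRUE))
  expect_equal(cmp$rand["truth", "truth"], 1)
  # identical partitions -> Rand 1
  cmp2 <- compare_solutions(list(a = truth_sol, b = truth_sol), dm,
                            mp$em$values)
  expect_equal(cmp2$rand["a", "b"], 1)
})

test_that("rand_index matches its definition and the adjusted variant", {
  a <- c(1, 1, 2, 2, 3, 3); b <- c(1, 1, 1, 2, 2, 2)
  # brute force over all pairs
  n <- length(a); agree <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
  }
  expect_equal(rand_index(a, b), agree / tot)
  expect_equal(rand_index(a, a), 1)
  expect_equal(rand_index(a, b, adjusted = TRUE),
               mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
})

test_that("all three algorithms recover a planted 3-module design", {
  mp <- module_profiles(c(20, 20, 20), loading = 0.95, seed = 47)
  cfg <- pipeline_config(min_cluster_size = 10, k_max = 6, seed = 47)
  dm <- correlation_distance(mp$em)
  sols <- list(AHC = cluster_ahc(dm, cfg),
               KMEANS = cluster_kmeans_vote(mp$em, cfg),
               MBC = cluster_gmm_bic(mp$em, cfg))
  for (nm in names(sols)) {
    expect_gte(rand_index(sols[[nm]]$assignment, mp$truth), 0.9)
  }
  # seeded determinism: same config and seed -> identical assignments
  sols2 <- list(AHC = cluster_ahc(dm, cfg),
                KMEANS = cluster_kmeans_vote(mp$em, cfg),
                MBC = cluster_gmm_bic(mp$em, cfg))
  for (nm in names(sols)) {
    expect_identical(sols[[nm]]$assignment, sols2[[nm]]$assignment)
  }
})
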