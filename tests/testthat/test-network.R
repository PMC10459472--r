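# Profiles engineered to a chosen pairwise correlation: y = r*x + e with x
# and e exactly orthogonal standardized vectors gives cor(x, y) == r.
exact_r_pair <- function(r, n = 12) {
  x <- scale(seq_len(n))[, 1]
  e <- scale(resid(lm(rnorm(n) ~ x)))[, 1]
  y <- r * x + sqrt(1 - r^2) * e
  rbind(a = x, b = y)
}

test_that("edge filter applies strict |r| and adjusted-p thresholds", {
  set.seed(51)
  pr_hi <- exact_r_pair(0.80)
  pr_at <- exact_r_pair(0.75)
  x <- rbind(hi1 = pr_hi["a", ], hi2 = pr_hi["b", ],
             at1 = pr_at["a", ], at2 = pr_at["b", ])
  colnames(x) <- paste0("s", 1:12)
  em <- expression_matrix(x, "scaled")
  # a pair whose correlation equals the cutoff exactly is excluded
  # (strict >): set the cutoff to that pair's realized correlation
  r_at <- cor(x["at1", ], x["at2", ])
  net <- build_network(em, rownames(x), pipeline_config(r_cutoff = r_at))
  pairs <- paste(net$edges$gene_a, net$edges$gene_b)
  expect_true("hi1 hi2" %in% pairs)
  expect_false("at1 at2" %in% pairs)
  net75 <- build_network(em, rownames(x), pipeline_config())
  expect_true(all(abs(net75$edges$r) > 0.75))
  expect_true(all(net75$edges$p_adj < 0.05))
  net <- net75
  # raw p follows the t transform with n-2 df
  r <- net$edges$r[1]
  tt <- r * sqrt((12 - 2) / (1 - r^2))
  expect_equal(net$edges$p_raw[1], 2 * pt(-abs(tt), 10), tolerance = 1e-12)
})

test_that("a tight planted module yields the complete subgraph", {
  mp <- module_profiles(12, loading = 0.985, seed = 52)
  net <- build_network(mp$em, mp$em$gene_ids, pipeline_config())
  expect_equal(nrow(net$edges), choose(12, 2))  # all 66 pairs
  expect_equal(net$n_pairs_tested, 66)
})

test_that("edge sets shrink as cutoffs tighten and ignore orderings", {
  mp <- module_profiles(c(10, 10), loading = 0.9, seed = 53, n_noise = 5)
  em <- mp$em
  n1 <- build_network(em, em$gene_ids, pipeline_config(r_cutoff = 0.6))
  n2 <- build_network(em, em$gene_ids, pipeline_config(r_cutoff = 0.8))
  n3 <- build_network(em, em$gene_ids,
                      pipeline_config(r_cutoff = 0.6, edge_alpha = 0.001))
  key <- function(net) paste(net$edges$gene_a, net$edges$gene_b)
  expect_true(all(key(n2) %in% key(n1)))
  expect_true(all(key(n3) %in% key(n1)))
  expect_lte(nrow(n2$edges), nrow(n1$edges))
  expect_lte(nrow(n3$edges), nrow(n1$edges))

  # permuting genes and samples leaves the edge set unchanged
  perm_g <- sample(em$gene_ids)
  perm_s <- sample(em$sample_ids)
  em_p <- expression_matrix(em$values[perm_g, perm_s], "scaled")
  n1p <- build_network(em_p, perm_g, pipeline_config(r_cutoff = 0.6))
  canon <- function(net) {
    e <- net$edges
    sort(paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b)))
  }
  expect_equal(canon(n1p), canon(n1))
})

test_that("node metrics match closed forms and the power-iteration oracle", {
  # star with 11 leaves: center degree 11 and hub score 1, leaves degree 1
  edges <- data.frame(gene_a = "hub", gene_b = paste0("leaf", 1:11),
                      r = 0.9, p_raw = 1e-6, p_adj = 1e-5)
  net <- structure(list(nodes = c("hub", paste0("leaf", 1:11), "isolated"),
                        edges = edges, scope = "star", n_samples = 12,
                        n_pairs_tested = 78),
                   class = "gene_network")
  m <- compute_node_metrics(net)
  rownames(m) <- m$gene_id
  expect_equal(m["hub", "degree"], 11L)
  expect_equal(m["hub", "kleinberg_score"], 1)
  expect_true(all(m[paste0("leaf", 1:11), "degree"] == 1L))
  expect_equal(m["isolated", "degree"], 0L)
  expect_equal(m["isolated", "betweenness"], 0)
  expect_equal(m["isolated", "kleinberg_score"], 0)
  expect_equal(m["hub", "betweenness"], choose(11, 2))

  # random graphs: hub score equals plain power iteration to 1e-8
  for (s in 1:3) {
    set.seed(60 + s)
    n <- 30
    adj <- matrix(0, n, n)
    pick <- which(upper.tri(adj))
    on <- sample(pick, 80)
    adj[on] <- 1
    adj <- adj + t(adj)
    ids <- paste0("g", 1:n)
    pairs <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    net_r <- structure(list(nodes = ids,
                            edges = data.frame(gene_a = ids[pairs[, 1]],
                                               gene_b = ids[pairs[, 2]],
                                               r = 0.9, p_raw = 0, p_adj = 0),
                            scope = "rand", n_samples = 12,
                            n_pairs_tested = choose(n, 2)),
                       class = "gene_network")
    mr <- compute_node_metrics(net_r)
    oracle <- oracle_hub_power(adj)
    connected <- rowSums(adj) > 0
    expect_equal(mr$kleinberg_score[connected][order(mr$gene_id[connected])],
                 oracle[connected][order(ids[connected])], tolerance = 1e-8)
  }
})

test_that("communities split bridged cliques and cover every node", {
  clique_edges <- function(ids) {
    p <- t(combn(ids, 2))
    data.frame(gene_a = p[, 1], gene_b = p[, 2], r = 0.9,
               p_raw = 0, p_adj = 0)
  }
  a <- paste0("a", 1:6); b <- paste0("b", 1:6)
  edges <- rbind(clique_edges(a), clique_edges(b),
                 data.frame(gene_a = "a1", gene_b = "b1", r = 0.8,
                            p_raw = 0, p_adj = 0))
  net <- structure(list(nodes = c(a, b), edges = edges, scope = "x",
                        n_samples = 12, n_pairs_tested = 66),
                   class = "gene_network")
  comm <- detect_communities(net, seed = 1)
  expect_length(unique(comm), 2)
  expect_length(unique(comm[a]), 1)
  expect_length(unique(comm[b]), 1)
  expect_true(all(names(comm) == net$nodes))  # a full partition

  net1 <- structure(list(nodes = a, edges = clique_edges(a), scope = "x",
                         n_samples = 12, n_pairs_tested = 15),
                    class = "gene_network")
  expect_length(unique(detect_communities(net1)), 1)
})

test_that("hub rule is strict on both thresholds and deterministic", {
  m <- data.frame(gene_id = c("center", "border", "leaf"),
                  degree = c(11L, 10L, 1L),
                  betweenness = c(55, 10, 0),
                  kleinberg_score = c(1, 0.95, 0.2))
  hs <- select_hubs(list(c1 = m), ubiquitous = "ubi1", pipeline_config())
  expect_equal(hs$outstanding$gene_id, "center")
  # degree exactly at the threshold is rejected
  expect_false("border" %in% hs$outstanding$gene_id)
  expect_true("ubi1" %in% hs$table$gene_id)
  expect_true(hs$table$ubiquitous[hs$table$gene_id == "ubi1"])
  # deterministic given a fixed metrics table
  hs2 <- select_hubs(list(c1 = m), ubiquitous = "ubi1", pipeline_config())
  expect_identical(hs$table, hs2$table)
})

test_that("a planted hub dominates centrality across seeded runs", {
  wins <- 0; passes <- 0
  for (s in 1:20) {
    # a well-expressed star module (correlation estimates for low-count
    # genes are too unstable to probe centrality behaviour)
    sc <- simulation_scenario(n_genes = 16, group_labels = c("A", "B"),
                              n_replicates = 12, de_fraction = 0,
                              de_logfc = 0, dispersion = 0.05,
                              baseline_meanlog = 6, baseline_sdlog = 0.5,
                              module_factor_sd = 2, seed = 500 + s)
    sc <- plant_hub_module(sc, 16, hub_loading = 0.95,
                           satellite_loading = 0.8)
    sim <- simulate_counts(sc)
    ctf <- ctf_normalize(sim$counts, tmm_factors(sim$counts))
    em <- scale_rows(ctf)
    net <- build_network(em, em$gene_ids, pipeline_config())
    m <- compute_node_metrics(net)
    hub_id <- sim$truth$genes$gene_id[sim$truth$genes$hub]
    sc_hub <- m$kleinberg_score[m$gene_id == hub_id]
    if (sc_hub >= max(m$kleinberg_score) - 1e-9) wins <- wins + 1
    if (sc_hub > 0.9 && m$degree[m$gene_id == hub_id] > 10) passes <- passes + 1
  }
  expect_gte(wins, 18)
  expect_gte(passes, 18)
})
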