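# Co-expression networks: significance-filtered correlation edges, node
# centralities (degree, betweenness, Kleinberg hub score), communities and
# rule-based hub gene selection.

#' Build a correlation network over a set of genes
#'
#' All pairwise Pearson correlations of the gene profiles are tested with
#' the t transform (t = r * sqrt((n-2)/(1-r^2)), n-2 df, two-sided) and
#' Benjamini-Hochberg adjusted over all pairs in scope; an edge is kept
#' when |r| strictly exceeds \code{r_cutoff} (so that shared variance
#' r^2 > 50\% at the 0.75 default) and its adjusted p is below
#' \code{edge_alpha}. Pairs are processed in blocks so the full gene-pair
#' matrix is never materialized beyond the block size.
#'
#' @param em Scaled CTF [expression_matrix()] (profiles used for
#'   clustering).
#' @param genes Gene IDs in scope (e.g. one cluster's members).
#' @param cfg A [pipeline_config()].
#' @param scope Label recorded on the network (cluster id or
#'   \code{"global"}).
#' @param block Genes per block for the pairwise computation, default 512.
#' @return A \code{gene_network}: list with \code{nodes}, \code{edges}
#'   (data frame \code{gene_a, gene_b, r, p_raw, p_adj}), \code{scope}
#'   and \code{n_samples}.
#' @export
build_network <- function(em, genes, cfg = pipeline_config(),
                          scope = "global", block = 512L) {
  stopifnot(all(genes %in% em$gene_ids))
  x <- em$values[genes, , drop = FALSE]
  n <- ncol(x)
  if (length(genes) < 2) stop("need at least 2 genes")
  if (n <= 2) stop("correlation test undefined for <= 2 samples")

  xt <- t(x)
  p_genes <- length(genes)
  starts <- seq(1, p_genes, by = block)
  ga <- gb <- character(0); rr <- numeric(0)
  for (si in starts) {
    ia <- seq(si, min(si + block - 1, p_genes))
    ra <- cor(xt[, ia, drop = FALSE], xt)
    for (row in seq_along(ia)) {
      i <- ia[row]
      if (i >= p_genes) next
      js <- seq(i + 1, p_genes)
      ga <- c(ga, rep(genes[i], length(js)))
      gb <- c(gb, genes[js])
      rr <- c(rr, ra[row, js])
    }
  }
  r_clip <- pmin(pmax(rr, -1 + 1e-15), 1 - 1e-15)
  tstat <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p_raw <- 2 * pt(-abs(tstat), df = n - 2)
  p_adj <- p.adjust(p_raw, method = "BH")
  keep <- abs(rr) > cfg$r_cutoff & p_adj < cfg$edge_alpha
  edges <- data.frame(gene_a = ga[keep], gene_b = gb[keep],
                      r = rr[keep], p_raw = p_raw[keep], p_adj = p_adj[keep],
                      stringsAsFactors = FALSE)
  structure(list(nodes = genes, edges = edges, scope = scope,
                 n_samples = n, n_pairs_tested = length(rr)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network [", x$scope, "]: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges (", x$n_pairs_tested, " pairs tested)\n", sep = "")
  invisible(x)
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = net$nodes))
  igraph::E(g)$r <- net$edges$r
  g
}

#' Node centralities of a gene network
#'
#' Degree (incident edge count), shortest-path betweenness on the
#' unweighted graph (or with 1/|r| edge lengths when \code{weighted}),
#' and the Kleinberg hub score: the principal eigenvector of the
#' adjacency matrix, sign-fixed to non-negative entries and normalized so
#' the maximum is 1 (for an undirected graph the hub and authority scores
#' coincide). Isolated nodes score 0.
#'
#' @param net A [build_network()] result.
#' @param weighted Use |r| as connection strength for betweenness,
#'   default FALSE.
#' @return Data frame with \code{gene_id, degree, betweenness,
#'   kleinberg_score}.
#' @export
compute_node_metrics <- function(net, weighted = FALSE) {
  if (length(net$nodes) == 0) stop("empty network")
  g <- .as_igraph(net)
  deg <- igraph::degree(g)
  wts <- if (weighted && nrow(net$edges) > 0) 1 / abs(igraph::E(g)$r) else NA
  btw <- igraph::betweenness(g, directed = FALSE,
                             weights = if (weighted) wts else NULL)
  hub <- .kleinberg_score(net)
  data.frame(gene_id = net$nodes,
             degree = as.integer(deg[net$nodes]),
             betweenness = as.numeric(btw[net$nodes]),
             kleinberg_score = as.numeric(hub[net$nodes]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Kleinberg hub score: principal eigenvector of the (unweighted, symmetric)
# adjacency, sign-fixed to non-negative entries, max normalized to 1.
# On an undirected graph the hub and authority scores coincide.
.kleinberg_score <- function(net, tol = 1e-10) {
  nodes <- net$nodes
  score <- setNames(rep(0, length(nodes)), nodes)
  if (nrow(net$edges) == 0) return(score)
  adj <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[cbind(net$edges$gene_a, net$edges$gene_b)] <- 1
  adj[cbind(net$edges$gene_b, net$edges$gene_a)] <- 1
  ev <- eigen(adj, symmetric = TRUE)
  v <- ev$vectors[, 1]
  v <- v * sign(v[which.max(abs(v))])
  v[abs(v) < tol] <- 0
  v <- pmax(v, 0)
  score[nodes] <- v / max(v)
  score
}

#' Modularity communities of a gene network
#'
#' Louvain modularity maximization on the undirected graph (seeded for
#' reproducibility). Isolated nodes form singleton communities.
#'
#' @param net A [build_network()] result.
#' @param seed Integer seed, default 1.
#' @return Named integer vector of community labels per node.
#' @export
detect_communities <- function(net, seed = 1L) {
  if (length(net$nodes) == 0) stop("empty network")
  g <- .as_igraph(net)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g)
  mem <- igraph::membership(comm)
  setNames(as.integer(mem[net$nodes]), net$nodes)
}

#' Select candidate hub genes
#'
#' Outstanding genes are nodes whose Kleinberg score strictly exceeds
#' \code{hub_score_min} and whose degree strictly exceeds
#' \code{hub_degree_min}, evaluated within each cluster's network and
#' unioned with per-cluster provenance; ubiquitous DEGs (differentially
#' expressed in every contrast) are appended with their own flag.
#'
#' @param metrics Named list (by cluster) of [compute_node_metrics()]
#'   data frames, or a single data frame.
#' @param ubiquitous Character vector of ubiquitous DEG IDs.
#' @param cfg A [pipeline_config()].
#' @return A \code{hub_set}: list with \code{outstanding} (data frame
#'   gene_id, cluster, degree, kleinberg_score), \code{ubiquitous}, and
#'   \code{table} (union with provenance flags).
#' @export
select_hubs <- function(metrics, ubiquitous = character(0),
                        cfg = pipeline_config()) {
  if (is.data.frame(metrics)) metrics <- list(global = metrics)
  out <- do.call(rbind, lapply(names(metrics), function(cl) {
    m <- metrics[[cl]]
    hit <- m$kleinberg_score > cfg$hub_score_min & m$degree > cfg$hub_degree_min
    if (!any(hit)) return(NULL)
    data.frame(gene_id = m$gene_id[hit], cluster = cl,
               degree = m$degree[hit],
               kleinberg_score = m$kleinberg_score[hit],
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(gene_id = character(0), cluster = character(0),
                      degree = integer(0), kleinberg_score = numeric(0),
                      stringsAsFactors = FALSE)
  all_genes <- union(out$gene_id, ubiquitous)
  tab <- data.frame(gene_id = all_genes,
                    outstanding = all_genes %in% out$gene_id,
                    ubiquitous = all_genes %in% ubiquitous,
                    stringsAsFactors = FALSE)
  structure(list(outstanding = out, ubiquitous = ubiquitous, table = tab),
            class = "hub_set")
}

#' Per-algorithm hub sets and their intersection
#'
#' Runs per-cluster network construction, node metrics and the hub rule
#' for each clustering solution, then reports per-algorithm hub gene sets
#' and the genes common to all algorithms.
#'
#' @param solutions Named list of \code{cluster_solution} objects.
#' @param em Scaled [expression_matrix()] of the clustered genes.
#' @param ubiquitous Ubiquitous DEG IDs.
#' @param cfg A [pipeline_config()].
#' @return List with per-algorithm results (\code{networks},
#'   \code{metrics}, \code{hubs}), \code{hub_sets} (gene IDs per
#'   algorithm), \code{hub_union} and \code{hub_common}.
#' @export
hub_analysis <- function(solutions, em, ubiquitous = character(0),
                         cfg = pipeline_config()) {
  per_alg <- lapply(solutions, function(sol) {
    cl <- sol$assignment
    clusters <- sort(unique(cl[cl > 0]))
    nets <- list(); mets <- list()
    for (c1 in clusters) {
      genes <- names(cl)[cl == c1]
      if (length(genes) < 2) next
      nm <- as.character(c1)
      net <- build_network(em, genes, cfg, scope = nm)
      nets[[nm]] <- net
      m <- compute_node_metrics(net)
      if (nrow(net$edges) > 0)
        m$community <- detect_communities(net, seed = cfg$seed)[m$gene_id]
      else m$community <- seq_len(nrow(m))
      mets[[nm]] <- m
    }
    hubs <- select_hubs(mets, ubiquitous, cfg)
    list(networks = nets, metrics = mets, hubs = hubs)
  })
  hub_sets <- lapply(per_alg, function(a) unique(a$hubs$outstanding$gene_id))
  list(per_algorithm = per_alg,
       hub_sets = hub_sets,
       hub_union = Reduce(union, hub_sets, character(0)),
       hub_common = if (length(hub_sets) > 0) Reduce(intersect, hub_sets) else character(0))
}
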