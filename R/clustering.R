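# Co-expression clustering: variable-gene selection, 1-r dissimilarity,
# three algorithms (AHC with an adaptive dendrogram cut, k-means with a
# validity-index vote for k, Gaussian mixtures selected by BIC), minimum
# cluster size enforcement, aggregated profiles and solution comparison.

#' Keep DEGs with variable expression profiles
#'
#' Genes whose coefficient of variation (sd/mean of the CTF-adjusted
#' values across all samples) strictly exceeds the threshold. Stable genes
#' carry no profile shape worth clustering and only add computational
#' load when genes far outnumber samples.
#'
#' @param em CTF-normalized [expression_matrix()].
#' @param degs Character vector of DEG IDs (subset of the matrix genes).
#' @param cv_threshold Strict lower bound on CV, default 0.2.
#' @return Character vector of retained gene IDs.
#' @export
select_variable_genes <- function(em, degs, cv_threshold = 0.2) {
  stopifnot(all(degs %in% em$gene_ids))
  x <- em$values[degs, , drop = FALSE]
  mu <- rowMeans(x)
  nonpos <- mu <= 0
  if (any(nonpos)) {
    warning(sum(nonpos), " gene(s) with non-positive mean excluded from CV filter")
  }
  cv <- rep(0, nrow(x))
  cv[!nonpos] <- apply(x[!nonpos, , drop = FALSE], 1, sd) / mu[!nonpos]
  degs[!nonpos & cv > cv_threshold]
}

#' Pearson correlation dissimilarity (1 - r) between gene profiles
#'
#' @param em [expression_matrix()] of profiles (typically scaled CTF).
#' @param genes Optional subset of gene IDs.
#' @param type \code{"one_minus_r"} (the default, d = 1 - r) or
#'   \code{"euclid"} (d = sqrt(2(1 - r)), which is the Euclidean distance
#'   between standardized profiles up to a constant).
#' @return A \code{distance_matrix}: list with \code{gene_ids} and the
#'   symmetric matrix \code{d}.
#' @export
correlation_distance <- function(em, genes = NULL,
                                 type = c("one_minus_r", "euclid")) {
  type <- match.arg(type)
  x <- em$values
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  if (nrow(x) < 2) stop("need at least 2 genes")
  if (ncol(x) < 3) stop("need at least 3 samples")
  if (any(apply(x, 1, sd) == 0))
    stop("zero-variance gene profile; filter constant genes first")
  r <- cor(t(x))
  d <- 1 - r
  if (type == "euclid") d <- sqrt(pmax(2 * d, 0))
  diag(d) <- 0
  structure(list(gene_ids = rownames(x), d = d, type = type),
            class = "distance_matrix")
}

.new_solution <- function(algorithm, k, assignment, evidence) {
  structure(list(algorithm = algorithm, k = as.integer(k),
                 assignment = assignment, selection_evidence = evidence),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  tab <- table(x$assignment[x$assignment > 0])
  cat("cluster_solution [", x$algorithm, "]: k = ", x$k, "; sizes: ",
      paste(tab, collapse = ", "),
      if (any(x$assignment == 0)) paste0("; unassigned: ", sum(x$assignment == 0)),
      "\n", sep = "")
  invisible(x)
}

# relabel clusters 1..k by decreasing size (0 stays 0)
.relabel_by_size <- function(cl) {
  pos <- cl[cl > 0]
  if (length(pos) == 0) return(cl)
  sizes <- sort(table(pos), decreasing = TRUE)
  map <- setNames(seq_along(sizes), names(sizes))
  cl[cl > 0] <- map[as.character(pos)]
  cl
}

#' Agglomerative hierarchical clustering with linkage selection and an
#' adaptive dendrogram cut
#'
#' The linkage (average, single, complete, Ward) with the highest
#' agglomerative coefficient is selected; the dendrogram is then cut at
#' the number of branches maximizing the average silhouette width over
#' candidate k, so the cut height adapts to the dendrogram shape rather
#' than being fixed. When even the best cut shows no substantial structure
#' (average silhouette <= 0.25, the usual rule of thumb) a single cluster
#' is returned. Clusters smaller than \code{min_cluster_size} are
#' dissolved to the unassigned label 0.
#'
#' @param dm A [correlation_distance()] result.
#' @param cfg A [pipeline_config()].
#' @return A \code{cluster_solution} (algorithm \code{"AHC"}); the
#'   selection evidence records the agglomerative coefficient per linkage
#'   and the silhouette profile over candidate k.
#' @export
cluster_ahc <- function(dm, cfg = pipeline_config()) {
  n <- length(dm$gene_ids)
  if (n < 2 * cfg$min_cluster_size)
    stop("too few genes for clustering: ", n)
  dd <- as.dist(dm$d)
  linkages <- c("average", "single", "complete", "ward")
  ac <- vapply(linkages, function(l)
    cluster::agnes(dd, diss = TRUE, method = l)$ac, numeric(1))
  best_link <- linkages[which.max(ac)]
  ag <- cluster::agnes(dd, diss = TRUE, method = best_link)
  hc <- as.hclust(ag)

  kcap <- min(n - 1, max(cfg$k_max, floor(n / max(1, cfg$min_cluster_size))))
  ks <- seq(2, max(2, kcap))
  sil <- vapply(ks, function(k) {
    cl <- cutree(hc, k = k)
    mean(cluster::silhouette(cl, dd)[, "sil_width"])
  }, numeric(1))
  if (max(sil) <= 0.25) {
    assignment <- setNames(rep(1L, n), dm$gene_ids)
    k <- 1L
  } else {
    k <- ks[which.max(sil)]
    assignment <- cutree(hc, k = k)
    names(assignment) <- dm$gene_ids
  }
  sizes <- table(assignment)
  small <- as.integer(names(sizes)[sizes < cfg$min_cluster_size])
  assignment[assignment %in% small] <- 0L
  if (all(assignment == 0)) {
    # no cut produced a retained cluster: no substantial structure
    assignment[] <- 1L
  }
  assignment <- .relabel_by_size(assignment)
  k <- length(unique(assignment[assignment > 0]))
  .new_solution("AHC", max(k, 1L), assignment,
                list(linkage = best_link,
                     agglomerative_coefficients = ac,
                     candidate_k = ks, avg_silhouette = sil))
}

# ---------------------------------------------------------------------------
# Cluster validity indices for the k-means vote
# ---------------------------------------------------------------------------

.wss_total <- function(x, cl) {
  sum(vapply(split(seq_len(nrow(x)), cl), function(idx) {
    xm <- x[idx, , drop = FALSE]
    sum(sweep(xm, 2, colMeans(xm))^2)
  }, numeric(1)))
}

# per-k scores of the index battery; D is the Euclidean dist object on x
.validity_scores <- function(x, D, fits, ks, seed, gap_B = 20) {
  n <- nrow(x); d <- ncol(x)
  Dm <- as.matrix(D)
  tot_ss <- sum(sweep(x, 2, colMeans(x))^2)
  W <- vapply(fits, function(f) f$tot.withinss, numeric(1))
  B <- tot_ss - W

  per_cluster_stats <- lapply(fits, function(f) {
    cl <- f$cluster
    cent <- f$centers
    list(cl = cl, cent = cent)
  })

  ch <- mapply(function(w, b, k) (b / (k - 1)) / (w / (n - k)), W, B, ks)

  silh <- vapply(seq_along(ks), function(i)
    mean(cluster::silhouette(fits[[i]]$cluster, D)[, "sil_width"]), numeric(1))

  db <- vapply(seq_along(ks), function(i) {
    cl <- fits[[i]]$cluster; cent <- fits[[i]]$centers; k <- ks[i]
    S <- vapply(seq_len(k), function(c1) {
      idx <- which(cl == c1)
      mean(sqrt(rowSums(sweep(x[idx, , drop = FALSE], 2, cent[c1, ])^2)))
    }, numeric(1))
    M <- as.matrix(dist(cent))
    mean(vapply(seq_len(k), function(c1)
      max((S[c1] + S[-c1]) / M[c1, -c1]), numeric(1)))
  }, numeric(1))

  dunn <- vapply(seq_along(ks), function(i) {
    cl <- fits[[i]]$cluster
    same <- outer(cl, cl, "==")
    diam <- max(Dm[same & upper.tri(Dm)])
    sep <- min(Dm[!same & upper.tri(Dm)])
    sep / diam
  }, numeric(1))

  d_up <- Dm[upper.tri(Dm)]
  d_sorted <- sort(d_up)
  cindex <- vapply(seq_along(ks), function(i) {
    cl <- fits[[i]]$cluster
    within <- outer(cl, cl, "==")[upper.tri(Dm)]
    l <- sum(within)
    S <- sum(d_up[within])
    smin <- sum(d_sorted[seq_len(l)])
    smax <- sum(d_sorted[seq(length(d_sorted) - l + 1, length(d_sorted))])
    (S - smin) / (smax - smin)
  }, numeric(1))

  mcclain <- vapply(seq_along(ks), function(i) {
    cl <- fits[[i]]$cluster
    within <- outer(cl, cl, "==")[upper.tri(Dm)]
    mean(d_up[within]) / mean(d_up[!within])
  }, numeric(1))

  # Ratkowsky-Lance: mean over variables of sqrt(between-SS fraction) / sqrt(k)
  col_tss <- colSums(sweep(x, 2, colMeans(x))^2)
  rl <- vapply(seq_along(ks), function(i) {
    cl <- fits[[i]]$cluster; k <- ks[i]
    sizes <- table(cl)
    cent <- fits[[i]]$centers
    bgss_j <- colSums(sweep(cent, 2, colMeans(x))^2 * as.numeric(sizes))
    mean(sqrt(bgss_j / col_tss)) / sqrt(k)
  }, numeric(1))

  list(W = W, calinski_harabasz = ch, silhouette = silh,
       davies_bouldin = db, dunn = dunn, c_index = cindex,
       mcclain_rao = mcclain, ratkowsky_lance = rl)
}

.seeded_kmeans <- function(x, k, seed, nstart = 25) {
  set.seed(seed + k)
  if (k == 1) {
    cent <- matrix(colMeans(x), 1, ncol(x))
    list(cluster = rep(1L, nrow(x)), centers = cent,
         tot.withinss = sum(sweep(x, 2, cent[1, ])^2))
  } else {
    kmeans(x, centers = k, nstart = nstart, iter.max = 100)
  }
}

#' k-means with the number of clusters chosen by a validity-index vote
#'
#' k-means (25 restarts per candidate k, seeded) is fitted over the
#' candidate range and ten cluster-validity indices each vote for their
#' preferred k: Calinski-Harabasz, average silhouette, Davies-Bouldin,
#' Dunn, C-index, McClain-Rao, Ratkowsky-Lance, Hartigan's rule,
#' Krzanowski-Lai and the gap statistic. The final k is the most voted
#' value (ties break toward the smaller k) and the solution is refitted
#' at that k.
#'
#' @param em Scaled [expression_matrix()] of the selected genes (or any
#'   numeric profile matrix wrapped in one).
#' @param cfg A [pipeline_config()] (k range, min cluster size, seed).
#' @param genes Optional subset of gene IDs.
#' @param gap_B Bootstrap replicates for the gap statistic, default 20.
#' @return A \code{cluster_solution} (algorithm \code{"KMEANS"}) whose
#'   selection evidence holds the per-index scores and the vote tally.
#' @export
cluster_kmeans_vote <- function(em, cfg = pipeline_config(), genes = NULL,
                                gap_B = 20) {
  x <- em$values
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  n <- nrow(x)
  k_max <- min(cfg$k_max, floor(n / max(1, cfg$min_cluster_size)), n - 1)
  if (k_max < max(2, cfg$k_min)) stop("too few genes for the requested k range")
  ks <- seq(max(2, cfg$k_min), k_max)
  if (nrow(unique(x)) < 2) stop("degenerate data: all profiles identical")

  seed <- cfg$seed
  fits <- lapply(ks, function(k) .seeded_kmeans(x, k, seed))
  D <- dist(x)
  sc <- .validity_scores(x, D, fits, ks, seed, gap_B)

  # extended within-SS curve for Hartigan / Krzanowski-Lai / gap
  k_ext <- c(min(ks) - 1, ks, max(ks) + 1)
  k_ext <- k_ext[k_ext >= 1 & k_ext <= n - 1]
  W_ext <- setNames(vapply(k_ext, function(k) {
    if (k %in% ks) sc$W[match(k, ks)] else .seeded_kmeans(x, k, seed)$tot.withinss
  }, numeric(1)), k_ext)

  hart <- vapply(ks, function(k) {
    if (!as.character(k + 1) %in% names(W_ext)) return(NA_real_)
    (W_ext[as.character(k)] / W_ext[as.character(k + 1)] - 1) * (n - k - 1)
  }, numeric(1))
  hart_ok <- ks[!is.na(hart) & hart <= 10]
  hart_k <- if (length(hart_ok) > 0) min(hart_ok) else max(ks)

  d <- ncol(x)
  diff_k <- function(k) {
    (k - 1)^(2 / d) * W_ext[as.character(k - 1)] - k^(2 / d) * W_ext[as.character(k)]
  }
  kl <- vapply(ks, function(k) {
    if (!all(as.character(c(k - 1, k, k + 1)) %in% names(W_ext))) return(NA_real_)
    denom <- diff_k(k + 1)
    if (abs(denom) < .Machine$double.eps) return(NA_real_)
    abs(diff_k(k) / denom)
  }, numeric(1))

  # gap statistic vs uniform reference over the bounding box
  set.seed(seed + 104729L)
  rngs <- apply(x, 2, range)
  logW_ref <- matrix(NA_real_, gap_B, length(k_ext),
                     dimnames = list(NULL, k_ext))
  for (b in seq_len(gap_B)) {
    xb <- vapply(seq_len(d), function(j)
      runif(n, rngs[1, j], rngs[2, j]), numeric(n))
    for (k in k_ext) {
      f <- if (k == 1) .seeded_kmeans(xb, 1, seed)
           else kmeans(xb, centers = k, nstart = 5, iter.max = 50)
      logW_ref[b, as.character(k)] <- log(f$tot.withinss)
    }
  }
  gap <- colMeans(logW_ref) - log(W_ext[colnames(logW_ref)])
  s_k <- apply(logW_ref, 2, sd) * sqrt(1 + 1 / gap_B)
  gap_k <- max(ks)
  for (k in ks) {
    k1 <- as.character(k + 1)
    if (k1 %in% names(gap) && gap[as.character(k)] >= gap[k1] - s_k[k1]) {
      gap_k <- k; break
    }
  }

  votes <- c(calinski_harabasz = ks[which.max(sc$calinski_harabasz)],
             silhouette = ks[which.max(sc$silhouette)],
             davies_bouldin = ks[which.min(sc$davies_bouldin)],
             dunn = ks[which.max(sc$dunn)],
             c_index = ks[which.min(sc$c_index)],
             mcclain_rao = ks[which.min(sc$mcclain_rao)],
             ratkowsky_lance = ks[which.max(sc$ratkowsky_lance)],
             hartigan = hart_k,
             krzanowski_lai = if (all(is.na(kl))) NA_integer_ else ks[which.max(kl)],
             gap = gap_k)
  votes <- votes[!is.na(votes)]
  k_final <- vote_k(votes)

  fit <- fits[[match(k_final, ks)]]
  assignment <- setNames(fit$cluster, rownames(x))
  assignment <- .relabel_by_size(assignment)
  .new_solution("KMEANS", k_final, assignment,
                list(candidate_k = ks, votes = votes,
                     tally = table(factor(votes, levels = ks)),
                     scores = sc, gap = gap, hartigan = hart,
                     krzanowski_lai = kl))
}

#' Most-voted k with ties broken toward the smaller k
#' @param votes Integer vector of per-index preferred k.
#' @return The winning k.
#' @export
vote_k <- function(votes) {
  tab <- table(votes)
  winners <- as.integer(names(tab)[tab == max(tab)])
  min(winners)
}

#' Model-based clustering: Gaussian mixtures selected by BIC
#'
#' Fits Gaussian-mixture models by EM over the candidate k range and six
#' covariance families (spherical/diagonal/full, shared or varying) and
#' keeps the (k, family) pair maximizing the Bayesian information
#' criterion; genes are assigned by maximum posterior responsibility.
#'
#' @param em Scaled [expression_matrix()] of selected genes.
#' @param cfg A [pipeline_config()].
#' @param genes Optional subset of gene IDs.
#' @return A \code{cluster_solution} (algorithm \code{"MBC"}); the
#'   selection evidence is the BIC table, and element \code{z} holds the
#'   posterior responsibilities.
#' @export
cluster_gmm_bic <- function(em, cfg = pipeline_config(), genes = NULL) {
  x <- em$values
  if (!is.null(genes)) x <- x[genes, , drop = FALSE]
  n <- nrow(x)
  models <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
  if (n <= ncol(x)) models <- c("EII", "VII", "EEI", "VVI")
  G <- seq(cfg$k_min, min(cfg$k_max, n - 1))
  set.seed(cfg$seed)
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this name in the caller
  mc <- mclust::Mclust(x, G = G, modelNames = models, verbose = FALSE)
  if (is.null(mc)) stop("model-based clustering did not converge for any model")
  assignment <- setNames(as.integer(mc$classification), rownames(x))
  assignment <- .relabel_by_size(assignment)
  sol <- .new_solution("MBC", mc$G, assignment,
                       list(model = mc$modelName, bic = mc$BIC,
                            best_bic = as.numeric(mc$bic)))
  sol$z <- mc$z
  sol
}

#' Dissolve undersized clusters and reassign their genes
#'
#' Clusters below \code{min_cluster_size} are dissolved; their genes move
#' to the nearest retained cluster centroid (Euclidean distance in the
#' profile space), or to the unassigned label 0 when no cluster survives.
#'
#' @param sol A \code{cluster_solution}.
#' @param profiles Numeric matrix (genes x samples) of the profiles the
#'   solution was computed on (scaled values).
#' @param cfg A [pipeline_config()].
#' @return The adjusted \code{cluster_solution}.
#' @export
enforce_min_size <- function(sol, profiles, cfg = pipeline_config()) {
  cl <- sol$assignment
  stopifnot(all(names(cl) %in% rownames(profiles)))
  sizes <- table(cl[cl > 0])
  keep <- as.integer(names(sizes)[sizes >= cfg$min_cluster_size])
  drop <- setdiff(as.integer(names(sizes)), keep)
  if (length(drop) == 0) return(sol)
  moved <- names(cl)[cl %in% drop]
  if (length(keep) == 0) {
    cl[moved] <- 0L
  } else {
    cent <- t(vapply(keep, function(c1)
      colMeans(profiles[names(cl)[cl == c1], , drop = FALSE]),
      numeric(ncol(profiles))))
    for (g in moved) {
      dd <- sqrt(rowSums(sweep(cent, 2, profiles[g, ])^2))
      cl[g] <- keep[which.min(dd)]
    }
  }
  cl <- .relabel_by_size(cl)
  sol$assignment <- cl
  sol$k <- length(unique(cl[cl > 0]))
  sol
}

#' Aggregated cluster expression profiles
#'
#' Per cluster and sample: the median profile with the standard deviation
#' as error bar, on both the scaled and the CPM-scale matrices, plus the
#' number of genes aggregated.
#'
#' @param sol A \code{cluster_solution}.
#' @param em_scaled,em_cpm [expression_matrix()] objects covering the
#'   clustered genes.
#' @return Data frame with columns \code{cluster, sample, n_genes,
#'   median_scaled, sd_scaled, median_cpm, sd_cpm}.
#' @export
profile_clusters <- function(sol, em_scaled, em_cpm) {
  cl <- sol$assignment
  genes <- names(cl)[cl > 0]
  if (length(genes) == 0) stop("no assigned genes to profile")
  stopifnot(all(genes %in% em_scaled$gene_ids), all(genes %in% em_cpm$gene_ids))
  out <- do.call(rbind, lapply(sort(unique(cl[genes])), function(c1) {
    g <- names(cl)[cl == c1]
    xs <- em_scaled$values[g, , drop = FALSE]
    xc <- em_cpm$values[g, , drop = FALSE]
    sd0 <- function(v) if (length(v) < 2) 0 else sd(v)  # singleton: sd 0
    data.frame(cluster = c1, sample = colnames(xs), n_genes = length(g),
               median_scaled = apply(xs, 2, median),
               sd_scaled = apply(xs, 2, sd0),
               median_cpm = apply(xc, 2, median),
               sd_cpm = apply(xc, 2, sd0),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  out
}

#' Rand index (plain or adjusted) between two partitions
#' @param a,b Integer/character cluster labels over the same elements.
#' @param adjusted Return the chance-adjusted version, default FALSE.
#' @return A scalar in [0, 1] (adjusted version can be negative).
#' @export
rand_index <- function(a, b, adjusted = FALSE) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  total <- comb2(n)
  if (!adjusted) {
    (total + 2 * sum_ij - sum_i - sum_j) / total
  } else {
    exp_ij <- sum_i * sum_j / total
    (sum_ij - exp_ij) / ((sum_i + sum_j) / 2 - exp_ij)
  }
}

.cluster_quality <- function(cl, D, x) {
  assigned <- cl > 0
  cl <- cl[assigned]
  idx <- which(assigned)
  k <- length(unique(cl))
  n <- length(cl)
  if (k < 2 || n < 3)
    return(c(avg_silhouette = NA_real_, calinski_harabasz = NA_real_,
             wb_ratio = NA_real_))
  Dm <- as.matrix(D)[idx, idx]
  sil <- mean(cluster::silhouette(cl, as.dist(Dm))[, "sil_width"])
  xm <- x[idx, , drop = FALSE]
  tot <- sum(sweep(xm, 2, colMeans(xm))^2)
  W <- .wss_total(xm, cl)
  B <- tot - W
  ch <- (B / (k - 1)) / (W / (n - k))
  c(avg_silhouette = sil, calinski_harabasz = ch, wb_ratio = W / B)
}

#' Compare clustering solutions on shared genes
#'
#' Per solution: average silhouette width (on the correlation
#' dissimilarity), Calinski-Harabasz and within/between sum-of-squares
#' ratio, ranked by average silhouette; plus pairwise (plain) Rand
#' indices between the solutions.
#'
#' @param solutions Named list of \code{cluster_solution} objects on the
#'   same genes.
#' @param dm The [correlation_distance()] they were built from.
#' @param profiles Numeric matrix (genes x samples) of the clustered
#'   profiles.
#' @return List with \code{quality} (data frame, ranked) and \code{rand}
#'   (pairwise Rand index matrix).
#' @export
compare_solutions <- function(solutions, dm, profiles) {
  stopifnot(length(solutions) >= 2)
  genes <- dm$gene_ids
  D <- as.dist(dm$d)
  qual <- t(vapply(solutions, function(s)
    .cluster_quality(s$assignment[genes], D, profiles[genes, , drop = FALSE]),
    numeric(3)))
  qual <- data.frame(algorithm = vapply(solutions, `[[`, "", "algorithm"),
                     k = vapply(solutions, `[[`, 0L, "k"),
                     qual, row.names = names(solutions))
  qual <- qual[order(-qual$avg_silhouette), , drop = FALSE]
  m <- length(solutions)
  rand <- matrix(1, m, m, dimnames = list(names(solutions), names(solutions)))
  for (i in seq_len(m - 1)) for (j in seq(i + 1, m)) {
    rand[i, j] <- rand[j, i] <-
      rand_index(solutions[[i]]$assignment[genes], solutions[[j]]$assignment[genes])
  }
  list(quality = qual, rand = rand)
}
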