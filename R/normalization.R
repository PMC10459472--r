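# Normalization: CPM, reliability filtering, TMM, CTF, scaling, BCV,
# sample ordination.

#' Construct an expression matrix tagged with its normalization scheme
#' @param values Numeric matrix (genes x samples) with dimnames.
#' @param scheme One of \code{raw_cpm}, \code{tmm_cpm}, \code{ctf_cpm},
#'   \code{log_cpm}, \code{scaled}.
#' @param library_sizes Per-sample raw totals.
#' @param norm_factors Per-sample TMM factors (1 when unused).
#' @return An \code{expression_matrix} object.
#' @export
expression_matrix <- function(values, scheme,
                              library_sizes = colSums(values),
                              norm_factors = rep(1, ncol(values))) {
  scheme <- match.arg(scheme, c("raw_cpm", "tmm_cpm", "ctf_cpm", "log_cpm", "scaled"))
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = colnames(values),
                 scheme = scheme,
                 library_sizes = library_sizes,
                 norm_factors = norm_factors),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix [", x$scheme, "]: ", nrow(x$values), " genes x ",
      ncol(x$values), " samples\n", sep = "")
  invisible(x)
}

#' Counts per million, optionally with normalization factors
#'
#' \code{value[g,s] = count[g,s] / (library_size[s] * factor[s]) * 1e6}.
#' With all factors 1 this is the plain CPM used for the reliability filter;
#' with TMM factors it yields TMM-normalized CPM.
#'
#' @param cm A [count_matrix()].
#' @param factors Optional per-sample scaling factors (default all 1).
#' @return An [expression_matrix()] with scheme \code{raw_cpm} or
#'   \code{tmm_cpm}.
#' @export
compute_cpm <- function(cm, factors = NULL) {
  lib <- colSums(cm$counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(cm$sample_ids[lib <= 0], collapse = ", "))
  if (is.null(factors)) {
    f <- rep(1, ncol(cm$counts))
    scheme <- "raw_cpm"
  } else {
    f <- factors
    if (any(f <= 0)) stop("normalization factors must be positive")
    scheme <- "tmm_cpm"
  }
  vals <- sweep(cm$counts, 2, lib * f, "/") * 1e6
  expression_matrix(vals, scheme, library_sizes = lib, norm_factors = f)
}

#' Keep reliably expressed genes (CPM above threshold in enough samples)
#'
#' A gene is reliable when its CPM strictly exceeds \code{cfg$cpm_threshold}
#' in at least \code{cfg$min_samples} samples (counted over all samples by
#' default, or within some single group when
#' \code{cfg$reliable_within_group}). The report splits the input three
#' ways: never expressed (zero counts everywhere), expressed but unreliable,
#' and reliable.
#'
#' @param em Raw-CPM [expression_matrix()] derived from \code{cm}.
#' @param cm The matching [count_matrix()].
#' @param cfg A [pipeline_config()].
#' @return List with the filtered \code{count_matrix} and a \code{report}
#'   (counts and gene ID lists of the three classes).
#' @export
filter_reliable <- function(em, cm, cfg = pipeline_config()) {
  stopifnot(identical(em$gene_ids, cm$gene_ids))
  above <- em$values > cfg$cpm_threshold
  if (cfg$reliable_within_group) {
    per_group <- vapply(levels(cm$groups), function(g)
      rowSums(above[, cm$groups == g, drop = FALSE]), numeric(nrow(above)))
    n_ok <- apply(per_group, 1, max)
  } else {
    n_ok <- rowSums(above)
  }
  reliable <- n_ok >= cfg$min_samples
  never <- rowSums(cm$counts) == 0
  unreliable <- !reliable & !never
  if (!any(reliable)) warning("no gene passed the reliability filter")
  filtered <- cm
  filtered$counts <- cm$counts[reliable, , drop = FALSE]
  filtered$gene_ids <- rownames(filtered$counts)
  report <- list(n_input = nrow(cm$counts),
                 n_never = sum(never),
                 n_unreliable = sum(unreliable),
                 n_reliable = sum(reliable),
                 never = cm$gene_ids[never],
                 unreliable = cm$gene_ids[unreliable],
                 reliable = cm$gene_ids[reliable])
  list(counts = filtered, report = report)
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Per-sample factors from the TMM procedure: the reference sample is the
#' one whose upper-quartile CPM is closest to the mean upper-quartile;
#' gene-wise log2 ratios (M) and mean log2 abundances (A) against the
#' reference are doubly trimmed (30\% of the M tails, 5\% of the A tails)
#' and the factor is 2 to the precision-weighted mean of the surviving M
#' values, rescaled so the factors have geometric mean 1.
#'
#' @param cm A [count_matrix()] (ideally already reliability-filtered).
#' @return Named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(cm) {
  if (ncol(cm$counts) < 2) stop("TMM needs at least 2 samples")
  if (any(colSums(cm$counts > 0) == 0)) stop("sample with no nonzero gene")
  f <- edgeR::calcNormFactors(cm$counts, method = "TMM")
  setNames(as.numeric(f), cm$sample_ids)
}

#' Count adjustment with TMM factors (CTF)
#'
#' Counts are divided by the sample's TMM factor only — deliberately not by
#' the library size — which is the adjustment recommended for correlation
#' and co-expression work. With all factors equal to 1 the values are the
#' raw counts.
#'
#' @param cm A [count_matrix()].
#' @param factors TMM factors from [tmm_factors()].
#' @return An [expression_matrix()] with scheme \code{ctf_cpm}.
#' @export
ctf_normalize <- function(cm, factors) {
  if (any(factors <= 0)) stop("non-positive normalization factor")
  vals <- sweep(cm$counts, 2, factors, "/")
  expression_matrix(vals, "ctf_cpm", library_sizes = colSums(cm$counts),
                    norm_factors = factors)
}

#' Standardize each gene profile to mean 0, sd 1
#'
#' Row-wise centering and scaling by the sample standard deviation, the
#' usual preparation before correlation clustering so profile shape, not
#' expression level, drives similarity. Constant rows become all zero with
#' a warning.
#'
#' @param em An [expression_matrix()].
#' @return An [expression_matrix()] with scheme \code{scaled}.
#' @export
scale_rows <- function(em) {
  sc <- t(scale(t(em$values)))
  const <- !is.finite(sc[, 1])
  if (any(const)) {
    warning(sum(const), " constant gene profile(s) set to zero after scaling")
    sc[const, ] <- 0
  }
  dimnames(sc) <- dimnames(em$values)
  out <- expression_matrix(sc, "scaled", library_sizes = em$library_sizes,
                           norm_factors = em$norm_factors)
  out
}

#' Common negative-binomial dispersion and its BCV
#'
#' Estimates the single dispersion maximizing the adjusted profile
#' likelihood over all genes given the group-means design. The biological
#' coefficient of variation is its square root; a drop in BCV after
#' filtering/normalization indicates cleaner data.
#'
#' @param cm A [count_matrix()].
#' @param factors Optional TMM factors applied to the library sizes.
#' @return List with \code{common_dispersion} and \code{bcv}.
#' @export
estimate_bcv <- function(cm, factors = NULL) {
  if (all(table(cm$groups) < 2)) stop("need at least one group with replicates")
  design <- model.matrix(~ 0 + cm$groups)
  y <- edgeR::DGEList(counts = cm$counts, group = cm$groups)
  if (!is.null(factors)) y$samples$norm.factors <- factors
  y <- edgeR::estimateGLMCommonDisp(y, design)
  disp <- y$common.dispersion
  list(common_dispersion = disp, bcv = sqrt(disp))
}

#' Two-dimensional sample ordination: MDS on leading fold changes and PCA
#'
#' MDS uses classical scaling of pairwise leading-fold-change distances
#' (root-mean-square of the top \code{top} absolute log fold-changes per
#' sample pair), the standard similarity display for RNA-seq replicates;
#' PCA is computed on the gene-standardized log-scale matrix.
#'
#' @param em A log-scale [expression_matrix()] (or any matrix-like em).
#' @param top Number of top genes per pair for the MDS distance, default 500.
#' @return List with \code{mds_coords} (samples x 2), \code{pca_coords}
#'   (samples x 2) and \code{pca_variance_fractions}.
#' @export
sample_ordination <- function(em, top = 500) {
  x <- em$values
  if (ncol(x) < 3) stop("ordination needs at least 3 samples")
  mds <- limma::plotMDS(x, top = min(top, nrow(x)), plot = FALSE)
  lam <- pmax(mds$eigen.values, 0)
  coords <- mds$eigen.vectors[, 1:2, drop = FALSE] %*% diag(sqrt(lam[1:2]), 2)
  rownames(coords) <- colnames(x)
  colnames(coords) <- c("dim1", "dim2")

  xs <- x[apply(x, 1, sd) > 0, , drop = FALSE]
  pca <- prcomp(t(xs), center = TRUE, scale. = TRUE)
  fr <- pca$sdev^2 / sum(pca$sdev^2)
  pc <- pca$x[, 1:2, drop = FALSE]
  colnames(pc) <- c("PC1", "PC2")
  list(mds_coords = coords, pca_coords = pc, pca_variance_fractions = fr)
}
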