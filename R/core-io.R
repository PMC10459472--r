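#' coexflow: from read counts to candidate hub genes
#'
#' An automated analysis chain for ordered multi-group (time-course) RNA-seq
#' designs: reliability filtering on CPM, TMM/CTF normalization, precision
#' weights with moderated testing (empirical Bayes and fold-change-threshold
#' schemes), multi-algorithm co-expression clustering, correlation networks
#' and rule-based hub gene selection, plus a negative-binomial simulator
#' with planted ground truth.
#'
#' @importFrom stats aggregate cor cutree dist kmeans median model.matrix
#'   p.adjust pnorm prcomp pt quantile rlnorm rnbinom rnorm rpois runif sd
#'   setNames var as.dist as.hclust
#' @importFrom utils read.delim write.table capture.output packageVersion
#' @keywords internal
"_PACKAGE"

# ---------------------------------------------------------------------------
# Count matrix container
# ---------------------------------------------------------------------------

#' Construct and validate a count matrix with sample grouping
#'
#' The basic container of the workflow: a non-negative integer matrix of
#' read counts (rows = transcripts/genes, columns = samples) together with
#' an ordered group assignment for every sample (e.g. incubation times
#' \code{0h < 1h < 3h < 6h}).
#'
#' @param counts Numeric matrix of non-negative integer counts with row
#'   names (gene IDs) and column names (sample IDs).
#' @param groups Factor or character vector of group labels, one per sample,
#'   named by sample ID or in column order. If not already a factor, levels
#'   are taken in order of first appearance; supply a factor with explicit
#'   levels to control the stage ordering.
#' @param check_replicates Require at least 2 groups with at least 2
#'   replicates each (needed for model fitting). Default \code{TRUE}.
#'
#' @return An object of class \code{count_matrix}: a list with elements
#'   \code{counts}, \code{gene_ids}, \code{sample_ids}, \code{groups}
#'   (ordered factor indexed by sample).
#' @export
count_matrix <- function(counts, groups, check_replicates = TRUE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene IDs as row names and sample IDs as column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample IDs: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count for gene '%s', sample '%s': %s",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
                 format(counts[bad[1, , drop = FALSE]])))
  storage.mode(counts) <- "double"

  if (!is.null(names(groups))) {
    missing <- setdiff(colnames(counts), names(groups))
    if (length(missing) > 0)
      stop("samples missing from group assignment: ",
           paste(missing, collapse = ", "))
    groups <- groups[colnames(counts)]
  } else if (length(groups) != ncol(counts)) {
    stop("groups must name every sample (got ", length(groups),
         " labels for ", ncol(counts), " samples)")
  }
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  names(groups) <- colnames(counts)
  if (check_replicates) {
    tab <- table(groups)
    if (length(tab) < 2 || any(tab < 2))
      stop("need >= 2 groups with >= 2 replicates each; got sizes: ",
           paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  structure(list(counts = counts,
                 gene_ids = rownames(counts),
                 sample_ids = colnames(counts),
                 groups = groups),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  tab <- table(x$groups)
  cat("groups:", paste(sprintf("%s(n=%d)", names(tab), tab), collapse = " < "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a count matrix and its sample-group table from TSV files
#'
#' The counts file is tab-separated with a header row of sample IDs and the
#' gene ID in the first column (header \code{gene_id}). The groups file has
#' columns \code{sample_id}, \code{group} and \code{order} (an integer
#' giving the position of the group in the stage ordering, so that labels
#' like \code{0h, 1h, 3h, 6h} are never ordered lexically).
#'
#' @param counts_path Path to the counts TSV.
#' @param groups_path Path to the sample-group TSV.
#' @param check_replicates Passed to [count_matrix()].
#' @return A validated [count_matrix()].
#' @export
read_count_matrix <- function(counts_path, groups_path, check_replicates = TRUE) {
  raw <- read.delim(counts_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("counts file needs a gene_id column plus >=1 sample")
  gene_ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  if (!is.numeric(mat)) {
    num <- suppressWarnings(apply(raw[, -1, drop = FALSE], 2,
                                  function(z) as.numeric(as.character(z))))
    bad <- which(is.na(num) & !is.na(as.matrix(raw[, -1, drop = FALSE])),
                 arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop(sprintf("non-numeric count for gene '%s', sample '%s'",
                   gene_ids[bad[1, 1]], colnames(raw)[-1][bad[1, 2]]))
    mat <- num
  }
  rownames(mat) <- gene_ids

  grp <- read.delim(groups_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% colnames(grp)))
    stop("groups file must have columns 'sample_id' and 'group' (optional 'order')")
  missing <- setdiff(colnames(mat), grp$sample_id)
  if (length(missing) > 0)
    stop("samples in counts header absent from groups file: ",
         paste(missing, collapse = ", "))
  grp <- grp[match(colnames(mat), grp$sample_id), , drop = FALSE]
  if ("order" %in% colnames(grp)) {
    lev <- unique(grp$group[order(grp$order)])
  } else {
    lev <- unique(grp$group)
  }
  groups <- factor(grp$group, levels = lev)
  names(groups) <- grp$sample_id
  count_matrix(mat, groups, check_replicates = check_replicates)
}

# ---------------------------------------------------------------------------
# Pipeline configuration
# ---------------------------------------------------------------------------

#' Workflow configuration with the standard thresholds
#'
#' All tunable thresholds of the workflow with their defaults: genes are
#' reliable when CPM exceeds \code{cpm_threshold} in at least
#' \code{min_samples} samples; DEGs are called at adjusted p below
#' \code{p_cutoff} with the fold-change-threshold test at \code{fc_threshold};
#' clustering uses DEGs with coefficient of variation above
#' \code{cv_threshold}; network edges need \code{|r| > r_cutoff} and
#' adjusted p below \code{edge_alpha}; hubs need a Kleinberg score above
#' \code{hub_score_min} and degree above \code{hub_degree_min}.
#'
#' @param cpm_threshold CPM reliability threshold (strict >), default 1.
#' @param min_samples Minimum number of samples above the CPM threshold,
#'   default 3 (the replicate count per group of the reference design).
#' @param fc_threshold Minimal biologically meaningful fold change for the
#'   treat-style test, default 1.2 (must be >= 1).
#' @param p_cutoff Adjusted-p cutoff for DEG calling (strict <), default 0.1.
#' @param cv_threshold Coefficient-of-variation filter before clustering
#'   (strict >), default 0.2.
#' @param r_cutoff Absolute Pearson correlation needed for a network edge
#'   (strict >), default 0.75 so that shared variance exceeds 50\%.
#' @param edge_alpha Adjusted-p cutoff for network edges, default 0.05.
#' @param hub_score_min Minimal Kleinberg hub score (strict >), default 0.9.
#' @param hub_degree_min Minimal node degree (strict >), default 10.
#' @param min_cluster_size Minimal genes per retained cluster, default 10.
#' @param k_min,k_max Candidate range for the number of clusters, default 2..15.
#' @param reliable_within_group Count the CPM filter within a single group
#'   rather than over all samples; default \code{FALSE} (over all samples).
#' @param seed Integer seed driving every stochastic step, default 1.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(cpm_threshold = 1, min_samples = 3,
                            fc_threshold = 1.2, p_cutoff = 0.1,
                            cv_threshold = 0.2, r_cutoff = 0.75,
                            edge_alpha = 0.05, hub_score_min = 0.9,
                            hub_degree_min = 10, min_cluster_size = 10,
                            k_min = 2, k_max = 15,
                            reliable_within_group = FALSE, seed = 1L) {
  cfg <- list(cpm_threshold = cpm_threshold, min_samples = as.integer(min_samples),
              fc_threshold = fc_threshold, p_cutoff = p_cutoff,
              cv_threshold = cv_threshold, r_cutoff = r_cutoff,
              edge_alpha = edge_alpha, hub_score_min = hub_score_min,
              hub_degree_min = as.integer(hub_degree_min),
              min_cluster_size = as.integer(min_cluster_size),
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              reliable_within_group = isTRUE(reliable_within_group),
              seed = as.integer(seed))
  stopifnot(cfg$cpm_threshold > 0,
            cfg$p_cutoff > 0, cfg$p_cutoff <= 1,
            cfg$fc_threshold >= 1,
            cfg$r_cutoff > 0, cfg$r_cutoff < 1,
            cfg$edge_alpha > 0, cfg$edge_alpha <= 1,
            cfg$cv_threshold >= 0,
            cfg$min_samples >= 0, cfg$hub_degree_min >= 0,
            cfg$min_cluster_size >= 0,
            cfg$k_min >= 1, cfg$k_max >= cfg$k_min)
  class(cfg) <- "pipeline_config"
  cfg
}

# ---------------------------------------------------------------------------
# Contrasts for ordered stage designs
# ---------------------------------------------------------------------------

#' Build all later-vs-earlier contrasts of an ordered design
#'
#' Every pair of stages is compared with the later stage relative to the
#' earlier one, so a positive log fold-change always reads as an increase
#' of expression over time. Adjacent transitions come first, then pairs of
#' increasing span: for stages \code{0h,1h,3h,6h} the order is
#' 1v0, 3v1, 6v3, 3v0, 6v1, 6v0.
#'
#' @param groups Character vector or factor of ordered group labels (the
#'   order of levels/appearance is the stage order).
#' @return A \code{contrast_set}: data frame with columns \code{name},
#'   \code{later}, \code{earlier}.
#' @export
build_contrasts <- function(groups) {
  if (is.factor(groups)) lev <- levels(droplevels(groups)) else lev <- unique(as.character(groups))
  g <- length(lev)
  if (g < 2) stop("need at least 2 groups to form contrasts, got ", g)
  later <- earlier <- character(0)
  for (lag in seq_len(g - 1)) {
    for (i in seq_len(g - lag)) {
      earlier <- c(earlier, lev[i])
      later <- c(later, lev[i + lag])
    }
  }
  out <- data.frame(name = paste0(later, "_vs_", earlier),
                    later = later, earlier = earlier,
                    stringsAsFactors = FALSE)
  structure(out, class = c("contrast_set", "data.frame"), levels = lev)
}

#' Numeric contrast matrix (groups x contrasts) for model fitting
#' @param contrasts A [build_contrasts()] result.
#' @return Matrix with +1 at the later group, -1 at the earlier.
#' @export
contrast_matrix <- function(contrasts) {
  lev <- attr(contrasts, "levels")
  cm <- matrix(0, length(lev), nrow(contrasts),
               dimnames = list(lev, contrasts$name))
  for (j in seq_len(nrow(contrasts))) {
    cm[contrasts$later[j], j] <- 1
    cm[contrasts$earlier[j], j] <- -1
  }
  cm
}

# ---------------------------------------------------------------------------
# Timestamped TSV artifacts
# ---------------------------------------------------------------------------

#' Format a run timestamp for output file names
#' @param time A POSIXct; defaults to now.
#' @return String \code{YYYYMMDD_HHMMSS}.
#' @export
run_datetime <- function(time = Sys.time()) format(time, "%Y%m%d_%H%M%S")

#' Write a tabular result as \code{<stem>-<DATETIME>.tsv}
#'
#' All persistent artifacts of a run share one timestamp so files from the
#' same execution sort together and runs never overwrite each other.
#' Matrices are written with their row names in a leading \code{gene_id}
#' column; data frames are written as-is.
#'
#' @param table Matrix or data frame.
#' @param stem File-name stem, e.g. \code{"filteredData"}.
#' @param run_time Timestamp string from [run_datetime()].
#' @param out_dir Output directory (created if missing).
#' @param id_col Header for the row-name column when \code{table} is a
#'   matrix. Default \code{"gene_id"}.
#' @return The path written, invisibly.
#' @export
write_timestamped_table <- function(table, stem, run_time = run_datetime(),
                                    out_dir = ".", id_col = "gene_id") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  path <- file.path(out_dir, paste0(stem, "-", run_time, ".tsv"))
  if (is.matrix(table)) {
    df <- data.frame(rownames(table), table, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1] <- id_col
    table <- df
  }
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, dec = ".", fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a count matrix (and its groups) to the TSV dialect read back by
#' [read_count_matrix()]
#' @param cm A [count_matrix()].
#' @param counts_path,groups_path Destination paths.
#' @return \code{counts_path}, invisibly.
#' @export
write_count_matrix <- function(cm, counts_path, groups_path = NULL) {
  df <- data.frame(gene_id = cm$gene_ids, cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path)) {
    gdf <- data.frame(sample_id = cm$sample_ids,
                      group = as.character(cm$groups),
                      order = as.integer(cm$groups))
    write.table(gdf, groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(counts_path)
}
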