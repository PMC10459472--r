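# Differential expression: precision weights, weighted linear fits over all
# stage contrasts, empirical-Bayes and fold-change-threshold moderation,
# DEG calling and ubiquitous DEGs.

#' Mean-variance precision weights (voom transform)
#'
#' Log2-CPM with the canonical small offsets (0.5 on counts, 1 on the
#' factor-adjusted library size), per-gene linear fits, and a locally
#' weighted regression of the square-root residual standard deviation on
#' average log count; each observation receives weight predicted-sd^(-4)
#' at its fitted log count, removing the count mean-variance trend so the
#' downstream linear model is approximately homoscedastic.
#'
#' @param cm Filtered [count_matrix()].
#' @param factors TMM factors from [tmm_factors()].
#' @param span Span of the locally weighted trend regression, default 0.5.
#' @return List of class \code{mean_variance_model}: \code{log_cpm},
#'   \code{weights}, \code{design}, and the underlying \code{elist}.
#' @export
voom_weights <- function(cm, factors = NULL, span = 0.5) {
  design <- model.matrix(~ 0 + groups, data = list(groups = cm$groups))
  colnames(design) <- levels(cm$groups)
  if (qr(design)$rank < ncol(design)) stop("design matrix is not full rank")
  if (ncol(cm$counts) < ncol(design)) stop("fewer samples than design columns")
  lib <- colSums(cm$counts)
  if (is.null(factors)) factors <- rep(1, ncol(cm$counts))
  v <- limma::voom(cm$counts, design, lib.size = lib * factors, span = span)
  structure(list(log_cpm = v$E, weights = v$weights, design = design,
                 elist = v),
            class = "mean_variance_model")
}

#' Weighted linear fits for all later-vs-earlier contrasts
#'
#' Per-gene weighted least squares on the group-means design followed by
#' re-parametrization to the requested contrasts (later minus earlier), so
#' every coefficient is a log2 fold-change that is positive when expression
#' rises over time.
#'
#' @param mv A [voom_weights()] result.
#' @param contrasts A [build_contrasts()] result.
#' @return A \code{contrast_fit}: the underlying \code{MArrayLM} plus the
#'   contrast definitions.
#' @export
fit_contrasts <- function(mv, contrasts) {
  fit <- limma::lmFit(mv$elist, mv$design)
  if (any(fit$df.residual < 1)) stop("zero residual degrees of freedom")
  cmat <- contrast_matrix(contrasts)[colnames(mv$design), , drop = FALSE]
  cfit <- limma::contrasts.fit(fit, cmat)
  structure(list(fit = cfit, contrasts = contrasts), class = "contrast_fit")
}

.contrast_tables <- function(efit, contrasts, method, p_cutoff) {
  res <- lapply(seq_len(nrow(contrasts)), function(j) {
    tt <- limma::topTable(efit, coef = j, number = Inf, sort.by = "none",
                          adjust.method = "BH", confint = FALSE)
    df <- data.frame(gene_id = rownames(tt),
                     logFC = tt$logFC,
                     avg_expr = tt$AveExpr,
                     t = tt$t,
                     p_value = tt$P.Value,
                     p_adj = tt$adj.P.Val,
                     stringsAsFactors = FALSE)
    df$direction <- ifelse(df$p_adj < p_cutoff,
                           ifelse(df$logFC > 0, "up", "down"), "ns")
    df
  })
  names(res) <- contrasts$name
  structure(list(tables = res, method = method, p_cutoff = p_cutoff,
                 contrasts = contrasts),
            class = "contrast_result")
}

#' Empirical-Bayes moderated tests for every contrast
#'
#' Per-gene residual variances are squeezed toward a common prior whose
#' degrees of freedom are estimated by moment matching on the
#' log-variances; the moderated t uses the posterior standard deviation and
#' pooled degrees of freedom, with Benjamini-Hochberg adjustment within
#' each contrast.
#'
#' @param cfit A [fit_contrasts()] result.
#' @param p_cutoff Adjusted-p cutoff used for the direction call,
#'   default 0.1.
#' @return A \code{contrast_result}: per-contrast tables with columns
#'   \code{gene_id, logFC, avg_expr, t, p_value, p_adj, direction}, plus
#'   the moderation prior (\code{prior_df}, \code{prior_var}).
#' @export
moderate_ebayes <- function(cfit, p_cutoff = 0.1) {
  if (nrow(cfit$fit$coefficients) < 10)
    stop("empirical-Bayes prior estimation needs at least 10 genes")
  eb <- limma::eBayes(cfit$fit)
  out <- .contrast_tables(eb, cfit$contrasts, "ebayes", p_cutoff)
  out$prior_df <- eb$df.prior
  out$prior_var <- eb$s2.prior
  out$efit <- eb
  out
}

#' Fold-change-threshold moderated tests (treat) for every contrast
#'
#' Tests the composite null |true log2FC| <= log2(fc_threshold) instead of
#' zero: with tau the log2 threshold and posterior standard errors,
#' p = P(T > (|logFC|-tau)/se) + P(T > (|logFC|+tau)/se), capped at 1.
#' More conservative than the empirical-Bayes point null, hence fewer but
#' more biologically meaningful DEGs. With \code{fc_threshold = 1} it
#' reduces exactly to the empirical-Bayes two-sided p.
#'
#' @param cfit A [fit_contrasts()] result.
#' @param fc_threshold Fold-change threshold >= 1, default 1.2.
#' @param p_cutoff Adjusted-p cutoff used for the direction call.
#' @return A \code{contrast_result} (see [moderate_ebayes()]).
#' @export
moderate_treat <- function(cfit, fc_threshold = 1.2, p_cutoff = 0.1) {
  if (fc_threshold < 1) stop("fc_threshold must be >= 1")
  tr <- limma::treat(cfit$fit, fc = fc_threshold)
  out <- .contrast_tables(tr, cfit$contrasts, "treat", p_cutoff)
  out$fc_threshold <- fc_threshold
  out$prior_df <- tr$df.prior
  out$prior_var <- tr$s2.prior
  out$efit <- tr
  out
}

#' Call DEGs per contrast and summarize in the up/down table layout
#'
#' A gene is a DEG in a contrast when its adjusted p is strictly below the
#' cutoff; direction follows the sign of the log fold-change. The summary
#' gives, per contrast, total/down/up counts for each supplied method and
#' the count ratio between the first and second method.
#'
#' @param results Named list of \code{contrast_result} objects (e.g.
#'   \code{list(ebayes = ..., treat = ...)}).
#' @param cfg A [pipeline_config()] supplying \code{p_cutoff}.
#' @return List with \code{degs} (per method, per contrast: data frame of
#'   DEGs split by direction) and \code{summary} (the per-contrast count
#'   table).
#' @export
call_degs <- function(results, cfg = pipeline_config()) {
  degs <- lapply(results, function(res) {
    lapply(res$tables, function(df) {
      hit <- df$p_adj < cfg$p_cutoff
      out <- df[hit, , drop = FALSE]
      out$direction <- ifelse(out$logFC > 0, "up", "down")
      out[order(out$p_adj, out$p_value), , drop = FALSE]
    })
  })
  cn <- results[[1]]$contrasts$name
  rows <- lapply(cn, function(nm) {
    counts <- lapply(names(results), function(m) {
      d <- degs[[m]][[nm]]
      c(total = nrow(d), down = sum(d$direction == "down"),
        up = sum(d$direction == "up"))
    })
    names(counts) <- names(results)
    row <- data.frame(contrast = nm, stringsAsFactors = FALSE)
    for (m in names(counts)) {
      row[[paste0(m, "_total")]] <- counts[[m]]["total"]
      row[[paste0(m, "_down")]] <- counts[[m]]["down"]
      row[[paste0(m, "_up")]] <- counts[[m]]["up"]
    }
    if (length(results) >= 2) {
      a <- counts[[1]]["total"]; b <- counts[[2]]["total"]
      row$ratio <- if (b > 0) unname(a / b) else NA_real_
    }
    row
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(degs = degs, summary = summary)
}

#' Genes differentially expressed in every contrast
#'
#' The intersection of DEG sets across all contrasts under the primary
#' (fold-change-threshold) method; when that intersection is empty the
#' fallback (empirical Bayes) method is used instead, and the method that
#' produced the list is recorded.
#'
#' @param degs The \code{degs} element of [call_degs()], a list keyed by
#'   method then contrast.
#' @param method_order Methods to try in order, default
#'   \code{c("treat", "ebayes")}.
#' @return List with \code{genes}, \code{method} (the method that yielded
#'   a non-empty list, or the primary method when all are empty) and
#'   \code{table} (per-gene mean logFC and max adjusted p over contrasts).
#' @export
ubiquitous_degs <- function(degs, method_order = c("treat", "ebayes")) {
  method_order <- intersect(method_order, names(degs))
  if (length(degs[[method_order[1]]]) < 2)
    stop("ubiquitous DEGs need at least 2 contrasts")
  pick <- function(m) Reduce(intersect, lapply(degs[[m]], function(d) d$gene_id))
  genes <- character(0); used <- method_order[1]
  for (m in method_order) {
    genes <- pick(m)
    used <- m
    if (length(genes) > 0) break
  }
  if (length(genes) == 0) used <- method_order[1]
  tab <- NULL
  if (length(genes) > 0) {
    lf <- sapply(degs[[used]], function(d) d$logFC[match(genes, d$gene_id)])
    pa <- sapply(degs[[used]], function(d) d$p_adj[match(genes, d$gene_id)])
    if (length(genes) == 1) { lf <- matrix(lf, 1); pa <- matrix(pa, 1) }
    tab <- data.frame(gene_id = genes,
                      mean_logFC = rowMeans(lf),
                      max_p_adj = apply(pa, 1, max),
                      method = used,
                      stringsAsFactors = FALSE)
  }
  list(genes = genes, method = used, table = tab)
}
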