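# End-to-end orchestration: filtering -> normalization -> differential
# expression -> clustering -> networks -> hub genes, with timestamped TSV
# artifacts and a machine-readable run summary.

.fmt_num <- function(x) sub("\\.?0+$", "", format(x, trim = TRUE))

#' Run the complete workflow on a count matrix
#'
#' Executes, in order: CPM reliability filtering, TMM factors, dispersion
#' (BCV) before and after normalization, precision weights, weighted
#' linear fits over all later-vs-earlier contrasts, empirical-Bayes and
#' fold-change-threshold moderation, DEG calling and ubiquitous DEGs, CTF
#' normalization, row scaling, CV-based variable-gene selection, the three
#' clustering algorithms with minimum-size enforcement, aggregated cluster
#' profiles, solution comparison, per-cluster correlation networks with
#' node metrics and communities, and rule-based hub selection. All stage
#' outputs are written as \code{<stem>-<DATETIME>.tsv} files plus a run
#' summary JSON.
#'
#' @param cm A [count_matrix()], or a counts TSV path (then
#'   \code{groups} must be the groups TSV path).
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory for artifacts; NULL disables writing.
#' @param groups Groups TSV path when \code{cm} is a path.
#' @param run_time Timestamp string shared by all artifacts of the run.
#' @return Invisibly, a list with the run \code{summary}, the
#'   intermediate results (\code{filter}, \code{factors}, \code{bcv},
#'   \code{degs}, \code{ubiquitous}, \code{solutions}, \code{profiles},
#'   \code{comparison}, \code{hub}) and the file \code{manifest}.
#' @export
run_pipeline <- function(cm, cfg = pipeline_config(), out_dir = NULL,
                         groups = NULL, run_time = run_datetime()) {
  if (is.character(cm)) {
    stopifnot(!is.null(groups))
    cm <- read_count_matrix(cm, groups)
  }
  set.seed(cfg$seed)
  manifest <- character(0)
  emit <- function(tab, stem, id_col = "gene_id") {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- write_timestamped_table(tab, stem, run_time, out_dir, id_col = id_col)
    manifest <<- c(manifest, p)
    invisible(p)
  }
  say <- function(...) message("[coexflow] ", ...)

  # --- filtering ----------------------------------------------------------
  say("filtering: CPM > ", cfg$cpm_threshold, " in >= ", cfg$min_samples,
      " samples")
  raw_cpm <- compute_cpm(cm)
  flt <- filter_reliable(raw_cpm, cm, cfg)
  fcm <- flt$counts
  if (nrow(fcm$counts) == 0) stop("filtering removed every gene")
  emit(fcm$counts, "filteredData")

  # --- normalization ------------------------------------------------------
  factors <- tmm_factors(fcm)
  say("TMM factors: ", paste(sprintf("%.3f", factors), collapse = " "))
  bcv_raw <- estimate_bcv(fcm)
  bcv_norm <- estimate_bcv(fcm, factors = factors)
  say(sprintf("BCV raw %.4f -> normalised %.4f", bcv_raw$bcv, bcv_norm$bcv))
  lib <- colSums(fcm$counts)
  eff <- lib * factors
  tmm_counts <- sweep(fcm$counts, 2, eff, "/") * exp(mean(log(lib)))
  emit(tmm_counts, "TMMnormalisedCounts")
  tmm_cpm <- compute_cpm(fcm, factors)
  emit(tmm_cpm$values, "TMMnormalisedCPMs")

  # --- differential expression -------------------------------------------
  contrasts <- build_contrasts(fcm$groups)
  mv <- voom_weights(fcm, factors)
  emit(mv$log_cpm, "normHomoscedCPM")
  cfit <- fit_contrasts(mv, contrasts)
  res_eb <- moderate_ebayes(cfit, p_cutoff = cfg$p_cutoff)
  res_tr <- moderate_treat(cfit, fc_threshold = cfg$fc_threshold,
                           p_cutoff = cfg$p_cutoff)
  tag <- paste0(.fmt_num(cfg$p_cutoff), "_", .fmt_num(cfg$fc_threshold))
  long <- function(res) do.call(rbind, lapply(names(res$tables), function(nm) {
    cbind(contrast = nm, res$tables[[nm]])
  }))
  emit(long(res_tr), paste0("AllGenes_allContrast_TREAT_", tag))
  emit(long(res_eb), paste0("AllGenes_allContrast_eB_", tag))
  called <- call_degs(list(ebayes = res_eb, treat = res_tr), cfg)
  for (m in names(called$degs)) for (nm in names(called$degs[[m]])) {
    emit(called$degs[[m]][[nm]],
         paste0("DEGs_", nm, "_", m, "_", tag))
  }
  say("DEG summary:\n", paste(capture.output(print(called$summary)), collapse = "\n"))
  ubi <- ubiquitous_degs(called$degs)
  if (!is.null(ubi$table)) emit(ubi$table, "ubiquitousDEGs")
  say(length(ubi$genes), " ubiquitous DEG(s) [", ubi$method, "]")

  # --- clustering input ---------------------------------------------------
  deg_union <- unique(unlist(lapply(called$degs$treat, function(d) d$gene_id)))
  deg_method <- "treat"
  if (length(deg_union) == 0) {
    deg_union <- unique(unlist(lapply(called$degs$ebayes, function(d) d$gene_id)))
    deg_method <- "ebayes"
  }
  ctf <- ctf_normalize(fcm, factors)
  emit(ctf$values, "CTFnormalisedCPMs")

  solutions <- NULL; profiles <- NULL; comparison <- NULL; hub <- NULL
  var_genes <- character(0)
  if (length(deg_union) == 0) {
    say("no DEG found under either method; skipping clustering and networks")
  } else {
    var_genes <- select_variable_genes(ctf, deg_union, cfg$cv_threshold)
    say(length(deg_union), " DEGs (", deg_method, "), ",
        length(var_genes), " with CV > ", cfg$cv_threshold)
    if (length(var_genes) < 2 * cfg$min_cluster_size) {
      say("too few variable DEGs for clustering (need >= ",
          2 * cfg$min_cluster_size, "); skipping clustering and networks")
    } else {
      sub <- fcm
      sub$counts <- fcm$counts[var_genes, , drop = FALSE]
      sub$gene_ids <- var_genes
      ctf_sub <- ctf_normalize(sub, factors)
      scaled <- scale_rows(ctf_sub)
      dm <- correlation_distance(scaled)
      sol_ahc <- cluster_ahc(dm, cfg)
      sol_km <- cluster_kmeans_vote(scaled, cfg)
      sol_mbc <- cluster_gmm_bic(scaled, cfg)
      solutions <- list(AHC = sol_ahc, KMEANS = sol_km, MBC = sol_mbc)
      solutions <- lapply(solutions, enforce_min_size,
                          profiles = scaled$values, cfg = cfg)
      assign_tab <- data.frame(
        gene_id = var_genes,
        ahc_cluster = solutions$AHC$assignment[var_genes],
        kmeans_cluster = solutions$KMEANS$assignment[var_genes],
        mbc_cluster = solutions$MBC$assignment[var_genes],
        stringsAsFactors = FALSE)
      emit(assign_tab, "ClustersCTF")
      profiles <- lapply(solutions, function(s)
        profile_clusters(s, scaled, ctf_sub))
      emit(do.call(rbind, lapply(names(profiles), function(a)
        cbind(algorithm = a, profiles[[a]]))), "ClusterProfilesCTF")
      comparison <- compare_solutions(solutions, dm, scaled$values)
      say("clustering quality (ranked by silhouette):\n",
          paste(capture.output(print(comparison$quality)), collapse = "\n"))

      # --- networks and hubs ---------------------------------------------
      hub <- hub_analysis(solutions, scaled, ubi$genes, cfg)
      for (alg in names(hub$per_algorithm)) {
        pa <- hub$per_algorithm[[alg]]
        for (nm in names(pa$networks)) {
          net <- pa$networks[[nm]]
          if (nrow(net$edges) > 0)
            emit(net$edges, paste0("BestCorrelations_", alg, nm))
        }
      }
      outst <- do.call(rbind, lapply(names(hub$per_algorithm), function(alg) {
        pa <- hub$per_algorithm[[alg]]
        do.call(rbind, lapply(names(pa$metrics), function(nm) {
          m <- pa$metrics[[nm]]
          m$cluster <- nm
          m$algorithm <- alg
          m$hub_flag <- m$gene_id %in% pa$hubs$outstanding$gene_id
          m[, c("gene_id", "cluster", "algorithm", "degree", "betweenness",
                "kleinberg_score", "community", "hub_flag")]
        }))
      }))
      if (!is.null(outst)) emit(outst, "OutstandingGenes")
      say("hubs per algorithm: ",
          paste(sprintf("%s=%d", names(hub$hub_sets),
                        vapply(hub$hub_sets, length, 0L)), collapse = ", "),
          "; unique ", length(hub$hub_union),
          ", common ", length(hub$hub_common))
      if (!is.null(out_dir)) {
        net_json <- lapply(hub$per_algorithm, function(pa)
          lapply(pa$networks, function(net)
            list(nodes = net$nodes, edges = net$edges, scope = net$scope)))
        p <- file.path(out_dir, paste0("Networks-", run_time, ".json"))
        jsonlite::write_json(net_json, p, auto_unbox = TRUE, digits = NA,
                             dataframe = "rows")
        manifest <- c(manifest, p)
      }
    }
  }

  # --- run summary --------------------------------------------------------
  summary <- list(
    config = unclass(cfg),
    seed = cfg$seed,
    datetime = run_time,
    versions = list(package = as.character(utils::packageVersion("coexflow")),
                    r = paste(R.version$major, R.version$minor, sep = ".")),
    genes = list(input = flt$report$n_input, never = flt$report$n_never,
                 unreliable = flt$report$n_unreliable,
                 reliable = flt$report$n_reliable),
    bcv = list(raw = bcv_raw$bcv, normalised = bcv_norm$bcv),
    deg_summary = called$summary,
    ubiquitous = list(n = length(ubi$genes), method = ubi$method),
    deg_union = list(n = length(deg_union), method = deg_method),
    variable_genes = length(var_genes),
    clusters = if (!is.null(solutions)) lapply(solutions, function(s)
      list(k = s$k, sizes = as.integer(table(s$assignment[s$assignment > 0])),
           unassigned = sum(s$assignment == 0))) else NULL,
    edges = if (!is.null(hub)) lapply(hub$per_algorithm, function(pa)
      sum(vapply(pa$networks, function(n) nrow(n$edges), 0L))) else NULL,
    hubs = if (!is.null(hub)) list(
      per_algorithm = lapply(hub$hub_sets, length),
      unique = length(hub$hub_union),
      common = length(hub$hub_common)) else NULL,
    manifest = basename(manifest))
  if (!is.null(out_dir)) {
    p <- file.path(out_dir, paste0("runSummary-", run_time, ".json"))
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", force = TRUE)
    manifest <- c(manifest, p)
    summary$manifest <- basename(manifest)
  }
  invisible(list(summary = summary, filter = flt, factors = factors,
                 bcv = list(raw = bcv_raw, normalised = bcv_norm),
                 contrasts = contrasts,
                 results = list(ebayes = res_eb, treat = res_tr),
                 degs = called, ubiquitous = ubi, deg_union = deg_union,
                 variable_genes = var_genes, solutions = solutions,
                 profiles = profiles, comparison = comparison, hub = hub,
                 manifest = manifest))
}
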