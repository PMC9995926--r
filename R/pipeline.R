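#' Pipeline configuration
#'
#' All thresholds of the end-to-end flow, with the conventional defaults:
#' the expression screen `|log2FC| > 1` at raw `p < 0.05`, the methylation
#' screen `p < 0.01`, detection filter at 0.01, the network cutoff
#' `|r| >= 0.95`, hub screening at the top 41 nodes with minimum degree 25,
#' and the tighter visualization screen (top 13, minimum degree 30).
#'
#' @param lfc_threshold Absolute log2 fold-change bound for the mRNA screen.
#' @param mrna_p Raw p bound for the mRNA screen.
#' @param mrna_fdr Optional additional FDR bound (NULL = off).
#' @param meth_p Raw p bound for the methylation screen.
#' @param detection_p Detection-p filter threshold.
#' @param r_threshold Network |r| cutoff, in (0, 1].
#' @param hub_min_degree,hub_top_n Hub-screen knobs.
#' @param viz_min_degree,viz_top_n Visualization-screen knobs.
#' @param dm_scale Test scale for methylation: "m_value" or "beta".
#' @param network_scale Methylation scale for the correlation network.
#' @param normalize_beta Apply between-sample quantile normalization to
#'   betas before testing?
#' @param pseudocount Pseudocount for the expression log transform.
#' @param seed Integer seed used by the stochastic stages (simulation,
#'   duplicate-name deletion).
#' @return A validated `coexmeth_config` list.
#' @export
pipeline_config <- function(lfc_threshold = 1.0, mrna_p = 0.05,
                            mrna_fdr = NULL, meth_p = 0.01,
                            detection_p = 0.01, r_threshold = 0.95,
                            hub_min_degree = 25, hub_top_n = 41,
                            viz_min_degree = 30, viz_top_n = 13,
                            dm_scale = "m_value", network_scale = "m_value",
                            normalize_beta = TRUE, pseudocount = 0.5,
                            seed = 1) {
  cfg <- list(lfc_threshold = lfc_threshold, mrna_p = mrna_p,
              mrna_fdr = mrna_fdr, meth_p = meth_p,
              detection_p = detection_p, r_threshold = r_threshold,
              hub_min_degree = hub_min_degree, hub_top_n = hub_top_n,
              viz_min_degree = viz_min_degree, viz_top_n = viz_top_n,
              dm_scale = dm_scale, network_scale = network_scale,
              normalize_beta = normalize_beta, pseudocount = pseudocount,
              seed = seed)
  class(cfg) <- "coexmeth_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param cfg A `coexmeth_config` or plain list of config fields.
#' @return Invisibly, the validated config (classed).
#' @export
validate_config <- function(cfg) {
  err <- function(...) stop("config: ", ..., call. = FALSE)
  num_pos <- c("lfc_threshold", "mrna_p", "meth_p", "detection_p",
               "hub_min_degree", "hub_top_n", "viz_min_degree", "viz_top_n",
               "pseudocount")
  for (f in num_pos) {
    v <- cfg[[f]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0) {
      err("`", f, "` must be a positive number")
    }
  }
  r <- cfg$r_threshold
  if (is.null(r) || !is.numeric(r) || length(r) != 1 || is.na(r) ||
      r <= 0 || r > 1) {
    err("`r_threshold` must lie in (0, 1]")
  }
  if (!is.null(cfg$mrna_fdr) && (!is.numeric(cfg$mrna_fdr) || cfg$mrna_fdr <= 0)) {
    err("`mrna_fdr` must be NULL or a positive number")
  }
  if (!cfg$dm_scale %in% c("m_value", "beta")) {
    err("`dm_scale` must be 'm_value' or 'beta'")
  }
  if (!cfg$network_scale %in% c("m_value", "beta")) {
    err("`network_scale` must be 'm_value' or 'beta'")
  }
  s <- cfg$seed
  if (is.null(s) || !is.numeric(s) || length(s) != 1 || is.na(s) ||
      s != round(s)) {
    err("`seed` must be an integer")
  }
  if (!inherits(cfg, "coexmeth_config")) class(cfg) <- "coexmeth_config"
  invisible(cfg)
}

#' Read a YAML pipeline configuration
#'
#' Fields present in the file override [pipeline_config()] defaults; the
#' result is validated before any compute.
#'
#' @param path YAML file path.
#' @return A `coexmeth_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("config: unknown field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, raw)
}

#' Write a pipeline configuration to YAML
#' @param cfg A `coexmeth_config`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full integrative pipeline
#'
#' Fixed stage order: differential expression -> differential methylation
#' (detection filter, optional quantile normalization, moderated test) ->
#' duplicate-name deletion -> bipartite correlation network between the
#' screened methylation positions and mRNAs -> degree-based hub screen and
#' hub-gene roster -> gene-level overlap -> optional gene-set enrichment.
#' A machine-readable report records row counts at every stage together
#' with all thresholds.
#'
#' @param counts Counts `feature_matrix`.
#' @param betas Beta `feature_matrix` with `gene_name` annotation.
#' @param groups Group assignment data.frame.
#' @param detection_p Optional detection-p `feature_matrix`.
#' @param config A `coexmeth_config` (default [pipeline_config()]).
#' @param gmt Optional gene-set collection (see [read_gmt()]) for enrichment
#'   of the overlapping genes.
#' @param outdir Optional output directory; when given, every stage table,
#'   the network exports and the JSON run report are written there.
#' @return A list with elements `de_table`, `de_filtered`, `dm_table`,
#'   `dm_filtered`, `network`, `degrees`, `hubs`, `viz_hubs`,
#'   `hub_gene_table`, `overlap`, `enrichment` (or NULL), and `report`.
#' @export
run_pipeline <- function(counts, betas, groups, detection_p = NULL,
                         config = pipeline_config(), gmt = NULL,
                         outdir = NULL) {
  config <- validate_config(config)

  ## expression layer
  de_table <- de_test(counts, groups, pseudocount = config$pseudocount)
  de_filtered <- apply_de_filter(de_table, config$lfc_threshold,
                                 config$mrna_p, config$mrna_fdr)
  de_filtered <- dedup_random(de_filtered, seed = config$seed)

  ## methylation layer: filter -> normalize -> test (fixed order)
  betas_f <- betas
  n_det_dropped <- 0
  if (!is.null(detection_p)) {
    betas_f <- detection_filter(betas, detection_p, config$detection_p)
    n_det_dropped <- attr(betas_f, "n_dropped")
  }
  if (isTRUE(config$normalize_beta)) {
    betas_f <- quantile_normalize_beta(betas_f)
  }
  dm_table <- dm_test(betas_f, groups, scale = config$dm_scale)
  dm_filtered <- apply_dm_filter(dm_table, config$meth_p)
  dm_filtered_dedup <- dedup_random(dm_filtered, seed = config$seed)

  ## network between screened positions and screened mRNAs
  bmat <- fm_values(betas_f)
  meth_vals <- bmat[dm_filtered$feature_id, , drop = FALSE]
  if (config$network_scale == "m_value") meth_vals <- beta_to_m(meth_vals)
  sf <- size_factors(counts)
  norm <- sweep(fm_values(counts), 2, sf, "/")
  rna_vals <- log2(norm + config$pseudocount)[de_filtered$feature_id, ,
                                              drop = FALSE]
  net <- if (nrow(meth_vals) && nrow(rna_vals)) {
    suppressWarnings(build_network(meth_vals, rna_vals, config$r_threshold))
  } else {
    structure(list(edges = data.frame(probe_id = character(),
                                      gene_id = character(), r = numeric(),
                                      stringsAsFactors = FALSE),
                   meth_nodes = rownames(meth_vals),
                   rna_nodes = rownames(rna_vals),
                   threshold = config$r_threshold, n_undefined = 0L),
              class = "bipartite_network")
  }
  degrees <- node_degrees(net)
  hubs <- screen_hubs(net, config$hub_min_degree, config$hub_top_n)
  viz_hubs <- screen_hubs(net, config$viz_min_degree, config$viz_top_n)
  hub_gene_table <- hub_genes(hubs, dm_filtered)

  ## gene-level overlap of the two layers
  overlap <- overlap_genes(de_filtered$gene_name, dm_filtered_dedup$gene_name)

  enrichment <- NULL
  if (!is.null(gmt) && length(overlap$intersection)) {
    universe <- unique(c(de_table$gene_name, dm_table$gene_name))
    enrichment <- enrich_sets(overlap$intersection, gmt, universe)
  }

  report <- list(
    parameters = unclass(config),
    counts = list(
      genes_tested = nrow(de_table),
      de_screened = nrow(de_filtered),
      de_up = attr(de_filtered, "n_up"),
      de_down = attr(de_filtered, "n_down"),
      probes_input = nrow(fm_values(betas)),
      probes_detection_dropped = n_det_dropped,
      probes_tested = nrow(dm_table),
      dm_screened = nrow(dm_filtered),
      dm_hyper = attr(dm_filtered, "n_hyper"),
      dm_hypo = attr(dm_filtered, "n_hypo"),
      correlated_pairs = count_pairs(net),
      undefined_pairs_skipped = net$n_undefined,
      hubs_screened = nrow(hubs),
      hub_genes = nrow(hub_gene_table),
      overlap_genes = unname(overlap$counts["both"]),
      enrichment_sets = if (is.null(enrichment)) 0L else nrow(enrichment)))

  result <- list(de_table = de_table, de_filtered = de_filtered,
                 dm_table = dm_table, dm_filtered = dm_filtered,
                 network = net, degrees = degrees, hubs = hubs,
                 viz_hubs = viz_hubs, hub_gene_table = hub_gene_table,
                 overlap = overlap, enrichment = enrichment, report = report)

  if (!is.null(outdir)) .write_pipeline_outputs(result, outdir)
  result
}

.write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_diff_table(result$de_filtered, file.path(outdir, "de_table.tsv"),
                   effect_name = "log2FoldChange")
  write_diff_table(result$dm_filtered, file.path(outdir, "dm_table.tsv"),
                   effect_name = "deltaBeta")
  write_network(result$network, file.path(outdir, "edges.tsv"), "tsv")
  write_network(result$network, file.path(outdir, "network.sif"), "sif")
  hg <- result$hub_gene_table
  writeLines(c("probe_id\tgene_name\tdegree\tpvalue",
               if (nrow(hg)) paste(hg$probe_id, hg$gene_name, hg$degree,
                                   sprintf("%.6e", hg$p), sep = "\t")),
             file.path(outdir, "hubs.tsv"), useBytes = TRUE)
  writeLines(result$overlap$intersection,
             file.path(outdir, "overlap_genes.txt"), useBytes = TRUE)
  if (!is.null(result$enrichment)) {
    utils::write.table(result$enrichment,
                       file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(result$report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' One-command demo on a simulated cohort
#'
#' Simulates a paired cohort with planted structure ([simulate_cohort()]),
#' runs the full pipeline, and appends the truth-recovery report.
#'
#' @param seed Integer seed (drives both the simulation and the pipeline's
#'   stochastic stages).
#' @param sim Optional [sim_config()] override (its seed is replaced by
#'   `seed`).
#' @param config Optional [pipeline_config()] override (seed replaced too).
#' @param outdir Optional output directory.
#' @return The [run_pipeline()] result list, plus `sim` (the simulated
#'   data) and `recovery` (the [truth_recovery_report()]).
#' @export
run_demo <- function(seed = 1, sim = NULL, config = NULL, outdir = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed) else sim$seed <- seed
  if (is.null(config)) config <- pipeline_config(seed = seed)
  else config$seed <- seed
  cohort <- simulate_cohort(sim)
  res <- run_pipeline(cohort$counts, cohort$betas, cohort$groups,
                      detection_p = cohort$detection_p,
                      config = config, outdir = outdir)
  res$sim <- cohort
  res$recovery <- truth_recovery_report(cohort$truth,
                                        de_table = res$de_filtered,
                                        dm_table = res$dm_filtered,
                                        hubs = res$hubs)
  if (!is.null(outdir)) {
    jsonlite::write_json(res$recovery, file.path(outdir, "recovery.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}
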