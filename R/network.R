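#' Build the bipartite methylation-mRNA co-expression network
#'
#' Computes the Pearson correlation across samples for every
#' (methylation position, mRNA) pair and keeps an edge when `|r| >=
#' r_threshold` (non-strict, both signs). Pairs with undefined correlation
#' (a zero-variance vector) are skipped and counted. With fewer than 10
#' samples a stringency warning is emitted: at n = 9 the default |r| >= 0.95
#' cutoff is extremely selective.
#'
#' @param meth_values Probe-by-sample numeric matrix (typically M-values of
#'   the differentially methylated positions).
#' @param rna_values Gene-by-sample numeric matrix (typically log2 normalized
#'   expression of the differential mRNAs). Must share the sample columns of
#'   `meth_values`, same order.
#' @param r_threshold Absolute-correlation cutoff (default 0.95).
#' @return A `bipartite_network`: list with `edges` (data.frame `probe_id`,
#'   `gene_id`, `r`, in lexicographic (probe, gene) order), `meth_nodes`,
#'   `rna_nodes` (all candidate ids, including degree-0 nodes),
#'   `threshold`, and `n_undefined` (skipped pairs).
#' @export
build_network <- function(meth_values, rna_values, r_threshold = 0.95) {
  mm <- fm_values(meth_values)
  rm_ <- fm_values(rna_values)
  if (!identical(colnames(mm), colnames(rm_))) {
    only_m <- setdiff(colnames(mm), colnames(rm_))
    only_r <- setdiff(colnames(rm_), colnames(mm))
    stop("sample columns differ between the two matrices",
         if (length(only_m)) paste0("; only in methylation: ",
                                    paste(only_m, collapse = ", ")),
         if (length(only_r)) paste0("; only in mRNA: ",
                                    paste(only_r, collapse = ", ")),
         if (!length(only_m) && !length(only_r)) "; same samples, different order",
         call. = FALSE)
  }
  if (ncol(mm) < 3) {
    stop("at least 3 shared samples are required", call. = FALSE)
  }
  if (ncol(mm) < 10) {
    warning("only ", ncol(mm), " samples: the |r| >= ", r_threshold,
            " cutoff is very stringent at this size", call. = FALSE)
  }
  r_mat <- suppressWarnings(stats::cor(t(mm), t(rm_)))
  undef <- is.na(r_mat)
  hit <- which(!undef & abs(r_mat) >= r_threshold, arr.ind = TRUE)
  edges <- data.frame(
    probe_id = rownames(mm)[hit[, 1]],
    gene_id = rownames(rm_)[hit[, 2]],
    r = r_mat[hit],
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$probe_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 meth_nodes = rownames(mm),
                 rna_nodes = rownames(rm_),
                 threshold = r_threshold,
                 n_undefined = sum(undef)),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf(paste0("bipartite_network: %d methylation x %d mRNA nodes, ",
                     "%d edges (|r| >= %g)\n"),
              length(x$meth_nodes), length(x$rna_nodes), nrow(x$edges),
              x$threshold))
  invisible(x)
}

#' Node degrees of a bipartite network
#'
#' Exact edge-count degrees for every candidate node on both sides; nodes
#' absent from all edges have degree 0.
#'
#' @param net A `bipartite_network`.
#' @return A data.frame with columns `node`, `side` ("meth"/"rna"),
#'   `degree`.
#' @export
node_degrees <- function(net) {
  meth_deg <- table(factor(net$edges$probe_id, levels = net$meth_nodes))
  rna_deg <- table(factor(net$edges$gene_id, levels = net$rna_nodes))
  data.frame(
    node = c(net$meth_nodes, net$rna_nodes),
    side = c(rep("meth", length(net$meth_nodes)),
             rep("rna", length(net$rna_nodes))),
    degree = as.integer(c(meth_deg, rna_deg)),
    stringsAsFactors = FALSE)
}

#' Degree-based hub screening
#'
#' Keeps nodes with degree >= `min_degree`, sorts by degree descending with
#' ties broken by node id ascending (a documented deterministic rule), and
#' truncates to the `top_n` highest. The screened fraction of all candidate
#' nodes is attached as attribute `fraction_of_nodes`.
#'
#' @param net A `bipartite_network`.
#' @param min_degree Minimum degree (default 25).
#' @param top_n Maximum number of hubs returned (default 41).
#' @return Data.frame of hub nodes (`node`, `side`, `degree`).
#' @export
screen_hubs <- function(net, min_degree = 25, top_n = 41) {
  deg <- node_degrees(net)
  deg <- deg[deg$degree >= min_degree, , drop = FALSE]
  deg <- deg[order(-deg$degree, deg$node), , drop = FALSE]
  out <- utils::head(deg, top_n)
  rownames(out) <- NULL
  n_total <- length(net$meth_nodes) + length(net$rna_nodes)
  attr(out, "fraction_of_nodes") <- if (n_total) nrow(out) / n_total else NA_real_
  out
}

#' Restrict hubs to differentially methylated positions (hub genes)
#'
#' Keeps methylation-side hub nodes present in the (filtered) differential-
#' methylation table and attaches each probe's gene name and differential
#' p-value; the hub-gene roster of the pipeline. Probes missing from the
#' table are excluded with a warning.
#'
#' @param hub_nodes Data.frame from [screen_hubs()].
#' @param dm_table Filtered table from [dm_test()] / [apply_dm_filter()].
#' @return Data.frame with columns `probe_id`, `gene_name`, `degree`, `p`,
#'   sorted by degree descending.
#' @export
hub_genes <- function(hub_nodes, dm_table) {
  meth_hubs <- hub_nodes[hub_nodes$side == "meth", , drop = FALSE]
  idx <- match(meth_hubs$node, dm_table$feature_id)
  if (any(is.na(idx)) && nrow(meth_hubs)) {
    warning("hub probes absent from the differential-methylation table ",
            "were excluded: ",
            paste(meth_hubs$node[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  keep <- !is.na(idx)
  out <- data.frame(
    probe_id = meth_hubs$node[keep],
    gene_name = dm_table$gene_name[idx[keep]],
    degree = meth_hubs$degree[keep],
    p = dm_table$p[idx[keep]],
    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$probe_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total number of correlated pairs
#' @param net A `bipartite_network`.
#' @return The edge count.
#' @export
count_pairs <- function(net) {
  nrow(net$edges)
}
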