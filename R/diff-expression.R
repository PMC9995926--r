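#' Median-of-ratios size factors
#'
#' Per-sample scale factors by the median-of-ratios construction: for every
#' gene with positive counts in all samples, divide each sample's count by
#' the gene's geometric mean, then take the per-sample median of those
#' ratios. Factors are not rescaled further.
#'
#' @param counts A `feature_matrix` of counts or a numeric count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- fm_values(counts)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; pre-filter the matrix ",
         "before computing size factors", call. = FALSE)
  }
  logm <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(logm)
  apply(logm, 2, function(lc) exp(stats::median(lc - geo)))
}

#' Fragments per kilobase per million (FPKM)
#'
#' `FPKM_gj = 1e9 * K_gj / (L_g * N_j)` with `K` the count, `L` the
#' transcript length in bp and `N` the sample's total count.
#'
#' @param counts A `feature_matrix` of counts with a `length` annotation
#'   column, or a count matrix if `lengths` is supplied.
#' @param lengths Optional positive lengths in bp, one per feature.
#' @return FPKM matrix with the input dimnames.
#' @export
fpkm <- function(counts, lengths = NULL) {
  m <- fm_values(counts)
  if (is.null(lengths)) {
    if (inherits(counts, "feature_matrix") && !is.null(counts$annotation$length)) {
      lengths <- counts$annotation$length
    } else {
      stop("gene lengths are required (annotation column `length` or the ",
           "`lengths` argument)", call. = FALSE)
    }
  }
  if (length(lengths) != nrow(m)) {
    stop("`lengths` must have one entry per feature", call. = FALSE)
  }
  if (anyNA(lengths) || any(lengths <= 0)) {
    stop("all lengths must be positive", call. = FALSE)
  }
  n <- colSums(m)
  if (any(n <= 0)) {
    stop("every sample must have a positive total count", call. = FALSE)
  }
  1e9 * sweep(m / lengths, 2, n, "/")
}

#' Two-group differential expression test
#'
#' Counts are normalized by [size_factors()]; the reported effect is
#' `log2((mean normalized case + c) / (mean normalized control + c))` with
#' pseudocount `c = 0.5`, and p-values come from the moderated t test on
#' `log2(normalized + c)` values with the empirical-Bayes variance prior
#' fitted across all genes ([eb_shrink_variances()]). FDR is the
#' Benjamini-Hochberg adjustment of the raw p-values. The engine is a
#' moderated t on the log scale (not a negative-binomial GLM), recorded in
#' the table's `engine` attribute.
#'
#' @param counts A counts `feature_matrix` (gene_name annotation used if
#'   present).
#' @param groups Group assignment data.frame (`sample_id`, `group`), at least
#'   2 samples per group.
#' @param pseudocount Pseudocount on the normalized scale (default 0.5).
#' @return A data.frame with columns `feature_id`, `gene_name`, `effect`
#'   (log2 fold change, case vs control), `direction` (`up`/`down`/`none`),
#'   `p`, `fdr`, sorted by |effect| descending. Attributes: `engine`,
#'   `d0`, `s0_sq`.
#' @export
de_test <- function(counts, groups, pseudocount = 0.5) {
  m <- fm_values(counts)
  is_case <- .match_groups(m, groups)
  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  logs <- log2(norm + pseudocount)
  st <- .row_two_group_stats(logs, is_case)
  prior <- .fit_prior(st$s2, st$df)
  mod <- .row_moderated_p(st, prior$d0, prior$s0_sq)
  mean_case <- rowMeans(norm[, is_case, drop = FALSE])
  mean_ctrl <- rowMeans(norm[, !is_case, drop = FALSE])
  effect <- log2((mean_case + pseudocount) / (mean_ctrl + pseudocount))
  tab <- data.frame(
    feature_id = rownames(m),
    gene_name = .gene_names(counts),
    effect = effect,
    direction = ifelse(effect > 0, "up", ifelse(effect < 0, "down", "none")),
    p = mod$p,
    fdr = bh_adjust(mod$p),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-abs(tab$effect), tab$feature_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "engine") <- "moderated_t_log2_normalized"
  attr(tab, "d0") <- prior$d0
  attr(tab, "s0_sq") <- prior$s0_sq
  tab
}

.gene_names <- function(fm) {
  m <- fm_values(fm)
  if (inherits(fm, "feature_matrix") && !is.null(fm$annotation$gene_name)) {
    fm$annotation$gene_name
  } else {
    rownames(m)
  }
}

.match_groups <- function(m, groups) {
  validate_groups(groups, require_two = TRUE)
  missing <- setdiff(colnames(m), groups$sample_id)
  if (length(missing)) {
    stop("samples missing from the group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lab <- groups$group[match(colnames(m), groups$sample_id)]
  if (sum(lab == "case") < 2 || sum(lab == "control") < 2) {
    stop("each group needs at least 2 samples among the matrix columns",
         call. = FALSE)
  }
  lab == "case"
}

#' Apply the differential-expression screen
#'
#' Keeps rows with `|effect| > lfc_threshold` and `p < p_threshold` (both
#' strict). Raw p drives the screen; an optional FDR cap can be added.
#' Up/down counts are attached as attributes `n_up` / `n_down`.
#'
#' @param table A table from [de_test()].
#' @param lfc_threshold Absolute log2 fold-change bound (default 1).
#' @param p_threshold Raw p-value bound (default 0.05).
#' @param fdr_threshold Optional additional FDR bound (default `NULL`, off).
#' @return The filtered table (a subset of the input, order preserved).
#' @export
apply_de_filter <- function(table, lfc_threshold = 1.0, p_threshold = 0.05,
                            fdr_threshold = NULL) {
  keep <- abs(table$effect) > lfc_threshold & table$p < p_threshold
  if (!is.null(fdr_threshold)) keep <- keep & table$fdr < fdr_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  out
}

#' Random deletion of duplicate gene names
#'
#' For every gene name appearing more than once, exactly one row is retained,
#' chosen uniformly at random from the seeded generator; row order is
#' otherwise preserved. The number of dropped rows is attached as attribute
#' `n_dropped`.
#'
#' @param table A differential table with a `gene_name` column.
#' @param seed Integer seed for the random choice (NULL uses the current RNG
#'   state).
#' @return The deduplicated table.
#' @export
dedup_random <- function(table, seed = NULL) {
  pick <- function() {
    keep <- rep(TRUE, nrow(table))
    for (nm in unique(table$gene_name[duplicated(table$gene_name)])) {
      idx <- which(table$gene_name == nm)
      chosen <- idx[sample.int(length(idx), 1)]
      keep[setdiff(idx, chosen)] <- FALSE
    }
    keep
  }
  keep <- if (is.null(seed)) pick() else .with_seed(seed, pick())
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!keep)
  out
}
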