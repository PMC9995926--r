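#' Overlap between two gene lists
#'
#' Case-sensitive exact-match intersection after whitespace trimming;
#' duplicates are collapsed before counting. The counts are the Venn-diagram
#' triple (a-only, b-only, both).
#'
#' @param list_a,list_b Character vectors of gene names.
#' @return A list with `intersection` (sorted), `a_only`, `b_only`, and
#'   `counts` (named integer vector `a_only`, `b_only`, `both`).
#' @export
overlap_genes <- function(list_a, list_b) {
  a <- unique(trimws(as.character(list_a)))
  b <- unique(trimws(as.character(list_b)))
  a <- a[nzchar(a)]
  b <- b[nzchar(b)]
  both <- sort(intersect(a, b))
  list(intersection = both,
       a_only = sort(setdiff(a, b)),
       b_only = sort(setdiff(b, a)),
       counts = c(a_only = length(setdiff(a, b)),
                  b_only = length(setdiff(b, a)),
                  both = length(both)))
}

#' Cross-study gene intersection
#'
#' Intersection of two study-level gene lists (e.g. an adolescent cohort's
#' overlapping genes against an adult reanalysis), reported as a one-column
#' table for export.
#'
#' @param study_a_genes,study_b_genes Character vectors of gene names.
#' @return A data.frame with column `gene_name` (sorted intersection).
#' @export
cross_study_intersect <- function(study_a_genes, study_b_genes) {
  ov <- overlap_genes(study_a_genes, study_b_genes)
  data.frame(gene_name = ov$intersection, stringsAsFactors = FALSE)
}

#' Fisher-exact gene-set enrichment over a GMT collection
#'
#' One-sided hypergeometric over-representation test ([enrich_p()]) of a
#' selected gene list against every set in the collection, with
#' Benjamini-Hochberg adjustment across sets. Every set is intersected with
#' the universe first; selected genes outside the universe are dropped with
#' a warning.
#'
#' @param selected_genes Character vector of selected gene names.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector naming the tested universe (defaults
#'   should be all features tested in the corresponding differential stage).
#' @return A data.frame with columns `set_name`, `overlap_k`, `set_size_K`,
#'   `selected_n`, `universe_N`, `p`, `fdr`, sorted by `p` ascending.
#' @export
enrich_sets <- function(selected_genes, collection, universe) {
  universe <- unique(trimws(as.character(universe)))
  universe <- universe[nzchar(universe)]
  if (!length(universe)) stop("the universe is empty", call. = FALSE)
  selected <- unique(trimws(as.character(selected_genes)))
  outside <- setdiff(selected, universe)
  if (length(outside)) {
    warning(length(outside), " selected gene(s) outside the universe were ",
            "dropped", call. = FALSE)
    selected <- intersect(selected, universe)
  }
  n <- length(selected)
  N <- length(universe)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(unique(collection[[nm]]), universe)
    k <- length(intersect(selected, members))
    data.frame(set_name = nm, overlap_k = k, set_size_K = length(members),
               selected_n = n, universe_N = N,
               p = enrich_p(k, length(members), n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-way hierarchical clustering leaf orders
#'
#' Agglomerative clustering with distance `1 - Pearson r` and average
#' linkage, applied independently to rows (features) and columns (samples);
#' the ordering used for heatmap display of the differential features.
#' Constant rows/columns have undefined correlation and are placed last with
#' a warning.
#'
#' @param values Feature-by-sample numeric matrix (>= 2 rows and columns, no
#'   missing values).
#' @return A list with `row_order` and `col_order` (character vectors of
#'   row/column names in leaf order, constant features appended last).
#' @export
two_way_cluster <- function(values) {
  m <- fm_values(values)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("at least 2 rows and 2 columns are required", call. = FALSE)
  }
  if (anyNA(m)) stop("missing values are not allowed", call. = FALSE)
  order_side <- function(x, ids) {
    const <- apply(x, 1, stats::var) == 0
    if (any(const)) {
      warning(sum(const), " constant feature(s) with undefined correlation ",
              "placed last", call. = FALSE)
    }
    act <- which(!const)
    ord <- if (length(act) >= 2) {
      d <- stats::as.dist(1 - stats::cor(t(x[act, , drop = FALSE])))
      act[stats::hclust(d, method = "average")$order]
    } else act
    c(ids[ord], ids[const])
  }
  list(row_order = order_side(m, rownames(m)),
       col_order = order_side(t(m), colnames(m)))
}
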