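#' Feature-by-sample matrix with optional feature annotation
#'
#' Lightweight container for count, beta-value and detection-p matrices:
#' a numeric matrix with feature ids as rownames and unique sample ids as
#' colnames, plus an optional annotation data.frame carrying `gene_name`
#' and/or `length` columns. Gene names always travel as annotation, never
#' parsed out of feature ids, so probe ids (cg...) and symbols can coexist.
#'
#' @param values Numeric matrix, rownames = feature ids, colnames = sample ids.
#' @param annotation Optional data.frame with one row per feature; recognised
#'   columns are `gene_name` (character) and `length` (positive bp).
#' @param kind One of "counts", "beta", "detection_p", "numeric"; triggers the
#'   matching domain validation (nonnegative integers / values in \[0,1\]).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, annotation = NULL,
                           kind = c("numeric", "counts", "beta", "detection_p")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry feature ids (rownames) and sample ids (colnames)",
         call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample id: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "), call. = FALSE)
  }
  .check_domain(values, kind)
  if (!is.null(annotation)) {
    if (nrow(annotation) != nrow(values)) {
      stop("`annotation` must have one row per feature", call. = FALSE)
    }
    if (!is.null(annotation$length) &&
        any(!is.na(annotation$length) & annotation$length <= 0)) {
      stop("annotation `length` values must be positive", call. = FALSE)
    }
    rownames(annotation) <- rownames(values)
  }
  structure(list(values = values, annotation = annotation, kind = kind),
            class = "feature_matrix")
}

.check_domain <- function(values, kind, where = "value") {
  bad <- which(is.na(values))
  if (length(bad)) {
    stop("missing ", where, " at row ", rownames(values)[row(values)[bad[1]]],
         ", column ", colnames(values)[col(values)[bad[1]]], call. = FALSE)
  }
  if (kind == "counts") {
    bad <- which(values < 0 | values != round(values))
    if (length(bad)) {
      stop("counts must be nonnegative integers; offending value ",
           values[bad[1]], " at row ", rownames(values)[row(values)[bad[1]]],
           ", column ", colnames(values)[col(values)[bad[1]]], call. = FALSE)
    }
  } else if (kind %in% c("beta", "detection_p")) {
    bad <- which(values < 0 | values > 1)
    if (length(bad)) {
      stop(kind, " values must lie in the domain [0, 1]; offending value ",
           values[bad[1]], " at row ", rownames(values)[row(values)[bad[1]]],
           ", column ", colnames(values)[col(values)[bad[1]]], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("feature_matrix [%s]: %d features x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$annotation)) {
    cat("annotation columns:", paste(names(x$annotation), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the numeric matrix from a feature_matrix (or pass a matrix through)
#' @param x A `feature_matrix` or numeric matrix.
#' @return The underlying numeric matrix.
#' @export
fm_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else x
}

#' Read a feature-by-sample TSV matrix
#'
#' The single on-disk matrix dialect is tab-delimited UTF-8 with a header row:
#' first column the feature id, then any annotation columns named `gene_name`
#' or `length`, then one numeric column per sample. Duplicate feature ids are
#' permitted on read (deduplication is a pipeline stage); duplicate sample ids
#' and out-of-domain values are rejected with location information.
#'
#' @param path File path.
#' @param kind Matrix domain; see [feature_matrix()].
#' @return A `feature_matrix`.
#' @export
read_matrix <- function(path, kind = c("numeric", "counts", "beta", "detection_p")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs a feature id column and at least one sample", call. = FALSE)
  feature_ids <- df[[1]]
  ann_cols <- intersect(c("gene_name", "length"), names(df)[-1])
  sample_cols <- names(df)[-1]
  sample_cols <- sample_cols[!sample_cols %in% ann_cols] # keep duplicates visible
  if (anyDuplicated(sample_cols)) {
    stop("duplicate sample id in header: ",
         paste(unique(sample_cols[duplicated(sample_cols)]), collapse = ", "),
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow(df), length(sample_cols),
                   dimnames = list(feature_ids, sample_cols))
  for (j in seq_along(sample_cols)) {
    raw <- df[[sample_cols[j]]]
    num <- suppressWarnings(as.numeric(raw))
    if (anyNA(num)) {
      i <- which(is.na(num))[1]
      stop("malformed number '", raw[i], "' at row ", feature_ids[i],
           ", column ", sample_cols[j], call. = FALSE)
    }
    values[, j] <- num
  }
  annotation <- NULL
  if (length(ann_cols)) {
    annotation <- df[ann_cols]
    if ("length" %in% ann_cols) {
      annotation$length <- suppressWarnings(as.numeric(annotation$length))
    }
  }
  # feature ids may repeat; bypass the constructor's rowname uniqueness by design
  fm <- feature_matrix(values, annotation = annotation, kind = kind)
  fm
}

#' Write a feature-by-sample TSV matrix
#'
#' Deterministic writer for the dialect read by [read_matrix()]: feature rows
#' in their current order, annotation columns (if any) between the id and the
#' sample columns, full-precision numeric formatting.
#'
#' @param fm A `feature_matrix`.
#' @param path Output path.
#' @param id_col Header name for the feature id column.
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(fm, path, id_col = "feature_id") {
  values <- fm_values(fm)
  header <- c(id_col,
              if (!is.null(fm$annotation)) names(fm$annotation),
              colnames(values))
  body <- cbind(rownames(values),
                if (!is.null(fm$annotation))
                  do.call(cbind, lapply(fm$annotation, .fmt_num)),
                .fmt_num(values))
  lines <- c(paste(header, collapse = "\t"),
             apply(body, 1, paste, collapse = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

.fmt_num <- function(x) {
  if (is.numeric(x)) {
    out <- sprintf("%.15g", x)
    dim(out) <- dim(x)
    out
  } else {
    as.matrix(as.character(x))
  }
}

#' Read a sample-to-group assignment table
#'
#' TSV with columns `sample_id` and `group`; group labels must be `case` or
#' `control` and every sample id unique.
#'
#' @param path File path.
#' @return A data.frame with columns `sample_id` and `group`.
#' @export
read_groups <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% names(df))) {
    stop("groups file needs `sample_id` and `group` columns", call. = FALSE)
  }
  validate_groups(df)
  df[c("sample_id", "group")]
}

#' Validate a group assignment data.frame
#' @param groups Data.frame with `sample_id` and `group` columns.
#' @param require_two Require at least 2 samples per group (the testing-stage
#'   precondition)?
#' @return Invisibly, `groups`.
#' @export
validate_groups <- function(groups, require_two = FALSE) {
  if (anyDuplicated(groups$sample_id)) {
    stop("duplicate sample id in group assignment", call. = FALSE)
  }
  if (!all(nzchar(groups$group)) || !all(groups$group %in% c("case", "control"))) {
    stop("group labels must be 'case' or 'control'", call. = FALSE)
  }
  if (require_two && any(table(factor(groups$group, c("case", "control"))) < 2)) {
    stop("each group needs at least 2 samples for testing stages", call. = FALSE)
  }
  invisible(groups)
}

#' Write a group assignment table
#' @param groups Data.frame with `sample_id` and `group`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_groups <- function(groups, path) {
  writeLines(c("sample_id\tgroup",
               paste(groups$sample_id, groups$group, sep = "\t")),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#' File order is preserved; empty members (trailing tabs) are dropped with a
#' warning; duplicate set names and lines with fewer than 3 fields are errors.
#'
#' @param path File path.
#' @return A named list of character member vectors, with a `description`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT line ", i, " has fewer than 3 fields", call. = FALSE)
    }
    name <- fields[1]
    if (name %in% names(sets)) {
      stop("duplicate gene-set name '", name, "' (line ", i, ")", call. = FALSE)
    }
    members <- fields[-(1:2)]
    if (any(!nzchar(members))) {
      warning("empty member ignored in set '", name, "' (line ", i, ")",
              call. = FALSE)
      members <- members[nzchar(members)]
    }
    if (!length(members)) {
      stop("gene set '", name, "' has no members (line ", i, ")", call. = FALSE)
    }
    sets[[name]] <- members
    desc[name] <- fields[2]
  }
  attr(sets, "description") <- desc
  sets
}

#' Export a bipartite network
#'
#' Deterministic writers in three dialects, edges ordered lexicographically by
#' (methylation id, mRNA id): `sif` emits `meth TAB coexpr TAB rna` lines for
#' Cytoscape; `tsv` adds the Pearson r as a column; `graphml` carries the
#' bipartite node class (`meth` / `rna`) and the edge `r` attribute.
#'
#' @param net A `bipartite_network` from [build_network()].
#' @param path Output path.
#' @param dialect One of "tsv", "sif", "graphml".
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif", "graphml")) {
  dialect <- match.arg(dialect)
  edges <- net$edges[order(net$edges$probe_id, net$edges$gene_id), , drop = FALSE]
  if (dialect == "sif") {
    writeLines(paste(edges$probe_id, "coexpr", edges$gene_id, sep = "\t"),
               path, useBytes = TRUE)
  } else if (dialect == "tsv") {
    writeLines(c("probe_id\tgene_id\tr",
                 if (nrow(edges))
                   paste(edges$probe_id, edges$gene_id,
                         sprintf("%.15g", edges$r), sep = "\t")),
               path, useBytes = TRUE)
  } else {
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$probe_id, to = edges$gene_id, r = edges$r),
      directed = FALSE,
      vertices = data.frame(
        name = c(net$meth_nodes, net$rna_nodes),
        class = c(rep("meth", length(net$meth_nodes)),
                  rep("rna", length(net$rna_nodes)))))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Reload a TSV network export
#' @param path Path written by [write_network()] with `dialect = "tsv"`.
#' @return A data.frame with columns `probe_id`, `gene_id`, `r`.
#' @export
read_network_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "numeric"))
}

#' Write a differential-feature table
#'
#' TSV with the conventional column names (`log2FoldChange` or `deltaBeta`
#' for the effect, `pvalue`, `FDR`), scientific notation for p-values.
#'
#' @param table A differential table from [de_test()] or [dm_test()].
#' @param path Output path.
#' @param effect_name Header for the effect column.
#' @return Invisibly, `path`.
#' @export
write_diff_table <- function(table, path, effect_name = "log2FoldChange") {
  header <- paste(c("feature_id", "gene_name", effect_name, "direction",
                    "pvalue", "FDR"), collapse = "\t")
  body <- if (nrow(table)) {
    paste(table$feature_id, table$gene_name,
          sprintf("%.15g", table$effect), table$direction,
          sprintf("%.6e", table$p), sprintf("%.6e", table$fdr), sep = "\t")
  } else character()
  writeLines(c(header, body), path, useBytes = TRUE)
  invisible(path)
}
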