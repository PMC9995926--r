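# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately naive re-derivations from definitions, kept
# separate from the implementation paths they check.

# O(m^2) step-up BH from the definition: q_i = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) m * p[ord[j]] / j, numeric(1))
    q[ord[i]] <- min(1, min(cand))
  }
  q
}

# Definitional Pearson correlation evaluated term by term.
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Upper-tail hypergeometric P(X >= k) by full enumeration of the pmf.
hyper_oracle <- function(k, K, n, N) {
  kk <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, kk) * choose(N - K, n - kk) / choose(N, n)
  sum(pmf[kk >= k])
}

# Small paired-cohort matrices with named dims for network tests.
random_bipartite_instance <- function(n_probes, n_genes, n_samples = 9) {
  meth <- matrix(rnorm(n_probes * n_samples), n_probes, n_samples,
                 dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                                 sprintf("s%02d", seq_len(n_samples))))
  rna <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                colnames(meth)))
  list(meth = meth, rna = rna)
}

# Naive edge set: loop over all pairs with the definitional correlation.
edges_oracle <- function(meth, rna, threshold) {
  out <- list()
  for (i in seq_len(nrow(meth))) {
    for (j in seq_len(nrow(rna))) {
      if (var(meth[i, ]) == 0 || var(rna[j, ]) == 0) next
      r <- pearson_oracle(meth[i, ], rna[j, ])
      if (abs(r) >= threshold) {
        out[[length(out) + 1]] <- data.frame(
          probe_id = rownames(meth)[i], gene_id = rownames(rna)[j], r = r,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(probe_id = character(), gene_id = character(),
                      r = numeric(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$probe_id, df$gene_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

tiny_groups <- function(n_case = 4, n_control = 5) {
  data.frame(
    sample_id = c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("ctrl_%02d", seq_len(n_control))),
    group = c(rep("case", n_case), rep("control", n_control)),
    stringsAsFactors = FALSE)
}

tiny_counts <- function(values, n_case = 4, n_control = 5, lengths = NULL) {
  g <- tiny_groups(n_case, n_control)
  m <- matrix(as.numeric(values), ncol = n_case + n_control,
              dimnames = list(sprintf("g%02d", seq_len(length(values) /
                                                         (n_case + n_control))),
                              g$sample_id))
  ann <- if (!is.null(lengths)) data.frame(length = lengths)
  feature_matrix(m, annotation = ann, kind = "counts")
}

top20_mrna <- function() {
  utils::read.delim(system.file("extdata", "adolescent_mdd_top20_mrna.tsv",
                                package = "coexmeth"),
                    stringsAsFactors = FALSE)
}

top20_dmp <- function() {
  utils::read.delim(system.file("extdata", "adolescent_mdd_top20_dmp.tsv",
                                package = "coexmeth"),
                    stringsAsFactors = FALSE)
}

# Shape a printed screen table into the internal differential-table layout.
as_diff_table <- function(df, effect_col) {
  data.frame(feature_id = df$gene_name, gene_name = df$gene_name,
             effect = df[[effect_col]], direction = df$direction,
             p = df$pvalue,
             fdr = if ("FDR" %in% names(df)) df$FDR else NA_real_,
             stringsAsFactors = FALSE)
}
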