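#' Detection-p probe filter
#'
#' Drops every probe whose detection p-value exceeds the threshold in any
#' sample; the array QC convention for unreliably measured positions.
#'
#' @param betas Beta-value `feature_matrix`.
#' @param detection_p Detection-p `feature_matrix` aligned to `betas`
#'   (identical probes and samples).
#' @param threshold Detection p-value bound (default 0.01).
#' @return The filtered beta `feature_matrix`, with attribute `n_dropped`.
#' @export
detection_filter <- function(betas, detection_p, threshold = 0.01) {
  b <- fm_values(betas)
  d <- fm_values(detection_p)
  if (!identical(dim(b), dim(d)) ||
      !identical(rownames(b), rownames(d)) ||
      !identical(colnames(b), colnames(d))) {
    stop("`betas` and `detection_p` must share probes and samples in the ",
         "same order", call. = FALSE)
  }
  keep <- rowSums(d > threshold) == 0
  out <- .subset_fm(betas, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

.subset_fm <- function(fm, keep) {
  if (inherits(fm, "feature_matrix")) {
    feature_matrix(fm$values[keep, , drop = FALSE],
                   annotation = if (!is.null(fm$annotation))
                     fm$annotation[keep, , drop = FALSE],
                   kind = fm$kind)
  } else {
    fm[keep, , drop = FALSE]
  }
}

#' Between-sample quantile normalization of beta values
#'
#' Classical quantile normalization on the beta scale: per-sample sorted
#' values at each rank are replaced by the across-sample mean at that rank;
#' tied values share the mean of their tied ranks (average ranks are mapped
#' by linear interpolation between adjacent rank means). Output stays in
#' \[0, 1\]. Provided as the normalization stage for array betas (a plain
#' alternative to mixture-based probe-type corrections, which are out of
#' scope).
#'
#' @param betas Beta-value `feature_matrix` or matrix.
#' @return Normalized object of the same class.
#' @export
quantile_normalize_beta <- function(betas) {
  b <- fm_values(betas)
  n <- nrow(b)
  sorted <- apply(b, 2, sort)
  target <- rowMeans(sorted)
  rk <- apply(b, 2, rank, ties.method = "average")
  lo <- floor(rk)
  hi <- ceiling(rk)
  out <- target[lo] + (rk - lo) * (target[hi] - target[lo])
  dim(out) <- dim(b)
  dimnames(out) <- dimnames(b)
  if (inherits(betas, "feature_matrix")) {
    feature_matrix(out, annotation = betas$annotation, kind = betas$kind)
  } else {
    out
  }
}

#' Beta to M-value transform
#'
#' `M = log2(beta / (1 - beta))` with beta clipped to
#' `[1e-3, 1 - 1e-3]` before the transform; the variance-stabilized scale
#' conventionally used for testing array methylation.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @return M-values of the same shape.
#' @export
beta_to_m <- function(beta) {
  b <- pmin(pmax(beta, 1e-3), 1 - 1e-3)
  log2(b / (1 - b))
}

#' Two-group differential methylation test
#'
#' The effect is always deltaBeta = mean beta(case) - mean beta(control) on
#' the beta scale, regardless of the test scale. P-values come from the
#' moderated t test ([moderated_t_test()] machinery) on either M-values
#' (default; variance stabilization matters with 4-vs-5 samples) or raw
#' betas, with the variance prior fitted across probes. Direction `up`
#' (hyper-methylated in cases) is defined as deltaBeta > 0.
#'
#' @param betas Beta-value `feature_matrix`.
#' @param groups Group assignment data.frame, >= 2 samples per group.
#' @param scale Test scale: "m_value" (default) or "beta".
#' @return A data.frame with columns `feature_id`, `gene_name`, `effect`
#'   (deltaBeta), `direction`, `p`, `fdr`, sorted by |effect| descending;
#'   attributes `engine`, `scale`, `d0`, `s0_sq`.
#' @export
dm_test <- function(betas, groups, scale = c("m_value", "beta")) {
  scale <- match.arg(scale)
  b <- fm_values(betas)
  is_case <- .match_groups(b, groups)
  test_vals <- if (scale == "m_value") beta_to_m(b) else b
  st <- .row_two_group_stats(test_vals, is_case)
  prior <- .fit_prior(st$s2, st$df)
  mod <- .row_moderated_p(st, prior$d0, prior$s0_sq)
  effect <- rowMeans(b[, is_case, drop = FALSE]) -
    rowMeans(b[, !is_case, drop = FALSE])
  tab <- data.frame(
    feature_id = rownames(b),
    gene_name = .gene_names(betas),
    effect = effect,
    direction = ifelse(effect > 0, "up", ifelse(effect < 0, "down", "none")),
    p = mod$p,
    fdr = bh_adjust(mod$p),
    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(-abs(tab$effect), tab$feature_id), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "engine") <- "moderated_t"
  attr(tab, "scale") <- scale
  attr(tab, "d0") <- prior$d0
  attr(tab, "s0_sq") <- prior$s0_sq
  tab
}

#' Apply the differential-methylation screen
#'
#' Keeps rows with `p < p_threshold` (strict). Hyper/hypo counts (sign of
#' deltaBeta) are attached as attributes `n_hyper` / `n_hypo`.
#'
#' @param table A table from [dm_test()].
#' @param p_threshold Raw p-value bound (default 0.01).
#' @return The filtered table.
#' @export
apply_dm_filter <- function(table, p_threshold = 0.01) {
  out <- table[table$p < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_hyper") <- sum(out$effect > 0)
  attr(out, "n_hypo") <- sum(out$effect < 0)
  out
}
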