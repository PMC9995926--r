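#' Pearson correlation with explicit undefined sentinel
#'
#' Sample Pearson correlation of two paired numeric vectors. With very small
#' cohorts (here 4 cases vs 5 controls) constant vectors are a realistic
#' occurrence; instead of propagating `NaN`, a zero-variance input yields the
#' sentinel `NA_real_`, which downstream network construction skips and counts.
#'
#' @param x,y Numeric vectors of equal length (at least 3), no missing values.
#' @return A correlation in \[-1, 1\], or `NA_real_` when either vector has
#'   zero variance (undefined correlation).
#' @examples
#' pearson_r(c(1, 2, 3), c(2, 4, 6))   # 1
#' pearson_r(c(1, 2, 3), c(5, 5, 5))   # NA (undefined)
#' @export
pearson_r <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) {
    stop("`x` and `y` must be numeric vectors", call. = FALSE)
  }
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length (got ", length(x), " and ",
         length(y), ")", call. = FALSE)
  }
  if (length(x) < 3) {
    stop("at least 3 paired observations are required", call. = FALSE)
  }
  if (anyNA(x) || anyNA(y)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate adjustment: with `m` p-values sorted
#' ascending, the adjusted value at rank `i` is `min_{j >= i} (m * p_j / j)`,
#' clipped at 1, returned in the original input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\], length >= 1.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || length(p) < 1) {
    stop("`p` must be a numeric vector of length >= 1", call. = FALSE)
  }
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop("all p-values must lie in [0, 1] with no missing values",
         call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' One-sided over-representation p-value
#'
#' Upper-tail hypergeometric probability P(X >= k) for X ~ Hypergeom(N, K, n):
#' the chance of drawing at least `overlap_k` members of a size-`set_size_K`
#' gene set when selecting `selected_n` genes from a universe of
#' `universe_N`. Identical to the one-sided Fisher exact test of the 2x2
#' overlap table.
#'
#' @param overlap_k Observed overlap (integer >= 0).
#' @param set_size_K Gene-set size within the universe.
#' @param selected_n Number of selected genes.
#' @param universe_N Universe size.
#' @return One-sided enrichment p-value in \[0, 1\].
#' @examples
#' enrich_p(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
enrich_p <- function(overlap_k, set_size_K, selected_n, universe_N) {
  vals <- c(overlap_k, set_size_K, selected_n, universe_N)
  if (anyNA(vals) || any(vals != round(vals)) || any(vals < 0)) {
    stop("all arguments must be nonnegative integers", call. = FALSE)
  }
  if (set_size_K > universe_N || selected_n > universe_N) {
    stop("set size and selection must not exceed the universe size",
         call. = FALSE)
  }
  if (overlap_k > min(set_size_K, selected_n)) {
    stop("`overlap_k` cannot exceed min(set_size_K, selected_n)",
         call. = FALSE)
  }
  stats::phyper(overlap_k - 1, set_size_K, universe_N - set_size_K,
                selected_n, lower.tail = FALSE)
}

#' Classical pooled-variance two-sample t test
#'
#' Equal-variance two-sided t test with `nA + nB - 2` degrees of freedom.
#' Equivalent to [moderated_t_test()] with prior degrees of freedom 0.
#' The effect is the group-mean difference `mean(xA) - mean(xB)` (cases minus
#' controls in pipeline use).
#'
#' @param xA,xB Numeric vectors, each of length >= 2.
#' @return A list with components `effect`, `t_stat`, `df`, `p`, and
#'   `degenerate` (TRUE when the pooled variance is exactly 0 with unequal
#'   means, in which case `p` is the smallest representable positive value).
#' @export
pooled_t_test <- function(xA, xB) {
  moderated_t_test(xA, xB, d0 = 0, s0_sq = 0)
}

#' Moderated two-sample t test with empirical-Bayes shrunk variance
#'
#' Two-group linear-model test whose residual variance is shrunk towards a
#' prior: the posterior variance is `(d0 * s0_sq + df * s2) / (d0 + df)` with
#' residual degrees of freedom `df = nA + nB - 2`, and the statistic is
#' referred to a t distribution on `df + d0` degrees of freedom (normal when
#' `d0` is infinite, i.e. complete shrinkage). At `d0 = 0` this reduces
#' exactly to [pooled_t_test()].
#'
#' @param xA,xB Numeric vectors, each of length >= 2.
#' @param d0 Prior degrees of freedom (>= 0, possibly `Inf`).
#' @param s0_sq Prior variance (>= 0); ignored when `d0 = 0`.
#' @return A list with components `effect`, `t_stat`, `df` (total degrees of
#'   freedom used for the reference distribution), `p`, and `degenerate`.
#' @seealso [eb_shrink_variances()] for estimating `d0` and `s0_sq`.
#' @export
moderated_t_test <- function(xA, xB, d0 = 0, s0_sq = 0) {
  if (length(xA) < 2 || length(xB) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (anyNA(xA) || anyNA(xB)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  if (is.na(d0) || d0 < 0) stop("`d0` must be >= 0 or Inf", call. = FALSE)
  nA <- length(xA)
  nB <- length(xB)
  df <- nA + nB - 2
  effect <- mean(xA) - mean(xB)
  s2 <- (sum((xA - mean(xA))^2) + sum((xB - mean(xB))^2)) / df
  if (is.infinite(d0)) {
    s2_post <- s0_sq
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
    df_total <- df + d0
  }
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  degenerate <- FALSE
  if (se == 0) {
    if (effect == 0) {
      t_stat <- 0
      p <- 1
    } else {
      t_stat <- sign(effect) * Inf
      p <- .Machine$double.xmin
      degenerate <- TRUE
    }
  } else {
    t_stat <- effect / se
    p <- 2 * stats::pt(-abs(t_stat), df = df_total)
  }
  list(effect = effect, t_stat = t_stat, df = df_total, p = p,
       degenerate = degenerate)
}

#' Empirical-Bayes variance shrinkage hyperparameters
#'
#' Moment-matching fit of the scaled inverse-chi-square prior used by
#' [moderated_t_test()]. Writing `e_g = log(s2_g) - digamma(df/2) +
#' log(df/2)`, the prior degrees of freedom `d0` solve
#' `trigamma(d0/2) = max(var(e) - trigamma(df/2), 0)` (trigamma is strictly
#' decreasing, so bisection on (1e-6, 1e6) is safe), and the prior variance is
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the between-
#' feature spread of `e` does not exceed its sampling noise the fit returns
#' `d0 = Inf` (complete shrinkage) with `s0_sq = exp(mean(e))`.
#'
#' @param s2 Per-feature residual variances (at least 2 positive entries).
#' @param df Residual degrees of freedom, identical for every feature in the
#'   two-group design (scalar, >= 1).
#' @return A list with components `d0` (possibly `Inf`) and `s0_sq`.
#' @export
eb_shrink_variances <- function(s2, df) {
  if (length(df) > 1) {
    if (length(unique(df)) != 1) {
      stop("`df` must be identical across features", call. = FALSE)
    }
    df <- df[1]
  }
  if (is.na(df) || df < 1) stop("`df` must be >= 1", call. = FALSE)
  ok <- !is.na(s2) & s2 > 0
  if (sum(ok) < 2) {
    stop("need at least 2 features with positive residual variance",
         call. = FALSE)
  }
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  target <- stats::var(e) - trigamma(df / 2)
  e_mean <- mean(e)
  if (!is.finite(target) || target <= 0) {
    return(list(d0 = Inf, s0_sq = exp(e_mean)))
  }
  f <- function(d0) trigamma(d0 / 2) - target
  lo <- 1e-6
  hi <- 1e6
  if (f(hi) > 0) {
    # spread below what is resolvable on the bisection interval
    return(list(d0 = Inf, s0_sq = exp(e_mean)))
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < 1e-10) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  d0 <- mid
  list(d0 = d0, s0_sq = exp(e_mean + digamma(d0 / 2) - log(d0 / 2)))
}

# Prior fit tolerant of degenerate panels: with fewer than 2 positive
# residual variances there is nothing to pool, so fall back to no shrinkage
# (d0 = 0) and let the per-feature degenerate rules apply.
.fit_prior <- function(s2, df) {
  if (sum(!is.na(s2) & s2 > 0) < 2) {
    list(d0 = 0, s0_sq = 0)
  } else {
    eb_shrink_variances(s2, df)
  }
}

# Row-wise two-group summaries for a feature-by-sample matrix.
# `is_case` is a logical vector over columns. Returns effect (case - control),
# pooled residual variance, and design constants shared by all rows.
.row_two_group_stats <- function(mat, is_case) {
  A <- mat[, is_case, drop = FALSE]
  B <- mat[, !is_case, drop = FALSE]
  nA <- ncol(A)
  nB <- ncol(B)
  if (nA < 2 || nB < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  mA <- rowMeans(A)
  mB <- rowMeans(B)
  ss <- rowSums((A - mA)^2) + rowSums((B - mB)^2)
  df <- nA + nB - 2
  list(effect = mA - mB, mean_case = mA, mean_control = mB,
       s2 = ss / df, df = df, nA = nA, nB = nB)
}

# Vectorized moderated-t p-values from .row_two_group_stats output.
# Mirrors moderated_t_test() exactly, including the degenerate rules.
.row_moderated_p <- function(st, d0, s0_sq) {
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0_sq, length(st$s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + st$df * st$s2) / (d0 + st$df)
    df_total <- st$df + d0
  }
  se <- sqrt(s2_post * (1 / st$nA + 1 / st$nB))
  t_stat <- ifelse(se > 0, st$effect / se,
                   ifelse(st$effect == 0, 0, sign(st$effect) * Inf))
  p <- ifelse(se > 0, 2 * stats::pt(-abs(t_stat), df = df_total),
              ifelse(st$effect == 0, 1, .Machine$double.xmin))
  list(t_stat = t_stat, p = p, df = df_total)
}
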