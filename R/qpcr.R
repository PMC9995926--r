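#' Relative quantification by the 2^-ddCt method
#'
#' Per-sample delta Ct against the reference gene (replicates averaged on
#' the Ct scale first), group delta-delta Ct, and the fold change:
#' `dCt_s = Ct_target,s - Ct_ref,s`; `ddCt = mean(case dCt) - mean(control
#' dCt)`; `fold = 2^-ddCt`; `log2_fold = -ddCt`. Positive `log2_fold` means
#' higher expression in cases, matching the differential-expression
#' direction convention.
#'
#' @param ct Data.frame with columns `sample_id`, `gene`, `ct` (cycles > 0)
#'   and optionally `replicate`.
#' @param target Target gene name.
#' @param reference Reference (housekeeping) gene name, e.g. beta-actin.
#' @param groups Group assignment data.frame (`sample_id`, `group`).
#' @return A list with `fold`, `log2_fold`, `ddct`, and `dct` (named
#'   per-sample delta-Ct vector).
#' @export
ddct_fold_change <- function(ct, target, reference, groups) {
  if (!all(c("sample_id", "gene", "ct") %in% names(ct))) {
    stop("`ct` needs columns sample_id, gene, ct", call. = FALSE)
  }
  if (any(is.na(ct$ct)) || any(ct$ct <= 0)) {
    stop("all Ct values must be positive", call. = FALSE)
  }
  validate_groups(groups)
  samples <- groups$sample_id
  mean_ct <- function(gene) {
    sub <- ct[ct$gene == gene, , drop = FALSE]
    vapply(samples, function(s) {
      v <- sub$ct[sub$sample_id == s]
      if (!length(v)) NA_real_ else mean(v)
    }, numeric(1))
  }
  ref_ct <- mean_ct(reference)
  if (anyNA(ref_ct)) {
    stop("reference gene '", reference, "' missing for sample(s): ",
         paste(samples[is.na(ref_ct)], collapse = ", "), call. = FALSE)
  }
  tgt_ct <- mean_ct(target)
  if (anyNA(tgt_ct)) {
    stop("target gene '", target, "' missing for sample(s): ",
         paste(samples[is.na(tgt_ct)], collapse = ", "), call. = FALSE)
  }
  dct <- tgt_ct - ref_ct
  is_case <- groups$group == "case"
  ddct <- mean(dct[is_case]) - mean(dct[!is_case])
  list(fold = 2^(-ddct), log2_fold = -ddct, ddct = ddct, dct = dct)
}
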