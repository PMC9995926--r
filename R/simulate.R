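#' Configuration for the synthetic paired cohort
#'
#' Defaults emulate the study design the pipeline targets: 4 case vs 5
#' control subjects, negative-binomial RNA-seq counts with planted log2 fold
#' changes up to ~8, beta-distributed array methylation with planted group
#' mean shifts (deltaBeta) up to ~0.55, and planted methylation-hub -> mRNA
#' driver links that the co-expression network stage must recover.
#'
#' @param n_case,n_control Samples per group (defaults 4 and 5).
#' @param n_genes,n_probes Panel sizes.
#' @param frac_de Fraction of genes with a planted log2 fold change.
#' @param de_lfc_range Magnitude range of planted |log2FC| (default 1.5-8).
#' @param nb_dispersion Shared negative-binomial dispersion (>0).
#' @param base_mean_log_range Range of per-gene log2 base mean counts.
#' @param frac_dm Fraction of probes with a planted beta shift.
#' @param dm_delta_range Magnitude range of planted |deltaBeta| (default
#'   0.15-0.55).
#' @param beta_precision Concentration of the beta noise (larger = tighter).
#' @param n_hubs Number of planted hub probes (each a DM probe).
#' @param links_per_hub Genes driven per hub (driven genes are DE genes).
#' @param hub_noise_sd Gaussian noise sd (log2 expression units) on the
#'   hub-driven genes; 0 gives the deterministic linear-coupling limit.
#' @param frac_detect_fail Fraction of probes given one failing detection
#'   p-value (> 0.01).
#' @param frac_dup_name Fraction of genes whose symbol duplicates another
#'   gene's (exercises the duplicate-name random-deletion stage).
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_case = 4, n_control = 5,
                       n_genes = 2000, n_probes = 2000,
                       frac_de = 0.10, de_lfc_range = c(1.5, 8),
                       nb_dispersion = 0.05, base_mean_log_range = c(4, 10),
                       frac_dm = 0.05, dm_delta_range = c(0.15, 0.55),
                       beta_precision = 30,
                       n_hubs = 5, links_per_hub = 30, hub_noise_sd = 0.25,
                       frac_detect_fail = 0.01, frac_dup_name = 0.01,
                       seed = 1) {
  cfg <- list(n_case = n_case, n_control = n_control, n_genes = n_genes,
              n_probes = n_probes, frac_de = frac_de,
              de_lfc_range = de_lfc_range, nb_dispersion = nb_dispersion,
              base_mean_log_range = base_mean_log_range, frac_dm = frac_dm,
              dm_delta_range = dm_delta_range, beta_precision = beta_precision,
              n_hubs = n_hubs, links_per_hub = links_per_hub,
              hub_noise_sd = hub_noise_sd, frac_detect_fail = frac_detect_fail,
              frac_dup_name = frac_dup_name, seed = seed)
  stopifnot(n_case >= 1, n_control >= 1, n_genes >= 1, n_probes >= 1,
            frac_de >= 0, frac_de <= 1, frac_dm >= 0, frac_dm <= 1,
            diff(de_lfc_range) >= 0, diff(dm_delta_range) >= 0,
            nb_dispersion > 0, beta_precision > 0, n_hubs >= 0,
            links_per_hub >= 0, hub_noise_sd >= 0,
            frac_detect_fail >= 0, frac_detect_fail <= 1)
  n_de <- round(frac_de * n_genes)
  if (n_hubs * links_per_hub > n_de) {
    stop("planted hub links (n_hubs * links_per_hub) must not exceed the ",
         "number of planted DE genes", call. = FALSE)
  }
  if (n_hubs > round(frac_dm * n_probes)) {
    stop("`n_hubs` must not exceed the number of planted DM probes",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Run `expr` under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a paired expression + methylation cohort with planted truth
#'
#' Counts are negative binomial around per-gene base means, with case-group
#' means scaled by `2^lfc` for planted DE genes. Betas are Beta-distributed
#' around group means shifted by the planted deltaBeta for DM probes, clipped
#' to (0.01, 0.99). Each hub probe's realised per-sample M-value drives its
#' linked genes' log2 expression linearly (slope chosen so the implied group
#' fold change matches the gene's planted log2FC) plus Gaussian noise of sd
#' `hub_noise_sd`, so planted links attain high |Pearson r| across the
#' samples. Detection p-values are well below 0.01 except for a configurable
#' fraction of failing probes.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `counts`, `betas`, `detection_p`
#'   (`feature_matrix` objects), `groups` (data.frame, cases first), and
#'   `truth` (list with `de_genes`, `dm_probes` as named effect vectors and
#'   `hub_links` as a named list probe -> driven gene ids).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n_s <- cfg$n_case + cfg$n_control
    samples <- c(sprintf("case_%02d", seq_len(cfg$n_case)),
                 sprintf("ctrl_%02d", seq_len(cfg$n_control)))
    is_case <- c(rep(TRUE, cfg$n_case), rep(FALSE, cfg$n_control))
    groups <- data.frame(sample_id = samples,
                         group = ifelse(is_case, "case", "control"),
                         stringsAsFactors = FALSE)

    ## --- gene layer -----------------------------------------------------
    gene_ids <- sprintf("tx%05d", seq_len(cfg$n_genes))
    gene_names <- sprintf("GENE%05d", seq_len(cfg$n_genes))
    n_dup <- round(cfg$frac_dup_name * cfg$n_genes)
    if (n_dup > 0 && cfg$n_genes >= 2) {
      dup_idx <- sample(cfg$n_genes, n_dup)
      for (i in dup_idx) {
        gene_names[i] <- gene_names[sample(setdiff(seq_len(cfg$n_genes), i), 1)]
      }
    }
    gene_len <- round(exp(stats::runif(cfg$n_genes, log(300), log(10000))))
    mu_log2 <- stats::runif(cfg$n_genes, cfg$base_mean_log_range[1],
                            cfg$base_mean_log_range[2])
    n_de <- round(cfg$frac_de * cfg$n_genes)
    de_idx <- if (n_de > 0) sort(sample(cfg$n_genes, n_de)) else integer()
    lfc <- numeric(cfg$n_genes)
    if (n_de > 0) {
      lfc[de_idx] <- sample(c(-1, 1), n_de, replace = TRUE) *
        stats::runif(n_de, cfg$de_lfc_range[1], cfg$de_lfc_range[2])
    }

    ## --- methylation layer ---------------------------------------------
    probe_ids <- sprintf("cg%08d", seq_len(cfg$n_probes))
    probe_gene <- sample(gene_names, cfg$n_probes, replace = TRUE)
    base_beta <- stats::runif(cfg$n_probes, 0.10, 0.90)
    n_dm <- round(cfg$frac_dm * cfg$n_probes)
    dm_idx <- if (n_dm > 0) sort(sample(cfg$n_probes, n_dm)) else integer()
    delta <- numeric(cfg$n_probes)
    if (n_dm > 0) {
      mag <- stats::runif(n_dm, cfg$dm_delta_range[1], cfg$dm_delta_range[2])
      sgn <- sample(c(-1, 1), n_dm, replace = TRUE)
      # keep the shifted group mean inside (0.05, 0.95): flip infeasible signs
      sgn <- ifelse(base_beta[dm_idx] + sgn * mag > 0.95, -1,
                    ifelse(base_beta[dm_idx] + sgn * mag < 0.05, 1, sgn))
      delta[dm_idx] <- sgn * mag
    }
    mean_beta <- matrix(base_beta, cfg$n_probes, n_s)
    mean_beta[, is_case] <- mean_beta[, is_case] + delta
    mean_beta <- pmin(pmax(mean_beta, 0.02), 0.98)
    betas <- matrix(stats::rbeta(cfg$n_probes * n_s,
                                 shape1 = mean_beta * cfg$beta_precision,
                                 shape2 = (1 - mean_beta) * cfg$beta_precision),
                    cfg$n_probes, n_s,
                    dimnames = list(probe_ids, samples))
    betas <- pmin(pmax(betas, 0.01), 0.99)
    m_vals <- log2(betas / (1 - betas))

    ## --- hub coupling ----------------------------------------------------
    hub_probes <- integer()
    hub_links <- list()
    driven <- integer()
    if (cfg$n_hubs > 0 && cfg$links_per_hub > 0) {
      hub_probes <- dm_idx[sample.int(length(dm_idx), cfg$n_hubs)]
      driven <- de_idx[sample.int(length(de_idx), cfg$n_hubs * cfg$links_per_hub)]
      hub_links <- split(gene_ids[driven],
                         rep(probe_ids[hub_probes], each = cfg$links_per_hub))
      hub_links <- hub_links[probe_ids[hub_probes]]
    }

    ## --- counts ----------------------------------------------------------
    mean_counts <- matrix(2^mu_log2, cfg$n_genes, n_s)
    mean_counts[, is_case] <- mean_counts[, is_case] * 2^lfc
    counts <- matrix(stats::rnbinom(cfg$n_genes * n_s,
                                    mu = mean_counts,
                                    size = 1 / cfg$nb_dispersion),
                     cfg$n_genes, n_s,
                     dimnames = list(gene_ids, samples))
    storage.mode(counts) <- "double"
    if (length(driven)) {
      logit2 <- function(b) log2(b / (1 - b))
      hub_of <- rep(hub_probes, each = cfg$links_per_hub)
      for (k in seq_along(driven)) {
        g <- driven[k]
        p <- hub_of[k]
        # expected case-minus-control M shift for this probe
        cb <- pmin(pmax(base_beta[p] + delta[p], 0.02), 0.98)
        d_m <- logit2(cb) - logit2(base_beta[p])
        slope <- lfc[g] / d_m
        intercept <- mu_log2[g] - slope * logit2(base_beta[p])
        log_expr <- intercept + slope * m_vals[p, ] +
          stats::rnorm(n_s, sd = cfg$hub_noise_sd)
        counts[g, ] <- pmax(0, round(2^log_expr))
      }
    }

    ## --- detection p ------------------------------------------------------
    det <- matrix(stats::runif(cfg$n_probes * n_s, 0, 0.005),
                  cfg$n_probes, n_s, dimnames = list(probe_ids, samples))
    n_fail <- round(cfg$frac_detect_fail * cfg$n_probes)
    if (n_fail > 0) {
      fail_p <- sample(cfg$n_probes, n_fail)
      fail_s <- sample(n_s, n_fail, replace = TRUE)
      det[cbind(fail_p, fail_s)] <- stats::runif(n_fail, 0.02, 0.30)
    }

    truth <- list(
      de_genes = stats::setNames(lfc[de_idx], gene_ids[de_idx]),
      dm_probes = stats::setNames(delta[dm_idx], probe_ids[dm_idx]),
      hub_links = hub_links)

    list(
      counts = feature_matrix(counts,
                              annotation = data.frame(gene_name = gene_names,
                                                      length = gene_len,
                                                      stringsAsFactors = FALSE),
                              kind = "counts"),
      betas = feature_matrix(betas,
                             annotation = data.frame(gene_name = probe_gene,
                                                     stringsAsFactors = FALSE),
                             kind = "beta"),
      detection_p = feature_matrix(det, kind = "detection_p"),
      groups = groups,
      truth = truth)
  })
}

#' Sensitivity/precision of the pipeline against the planted truth
#'
#' Confusion summaries per molecular layer plus hub recovery: the fraction of
#' planted hub probes appearing in the screened hub list. Precision is the
#' `NA` undefined sentinel when nothing was called.
#'
#' @param truth The `truth` element from [simulate_cohort()].
#' @param de_table Filtered differential-expression table (or NULL to skip).
#' @param dm_table Filtered differential-methylation table (or NULL).
#' @param hubs Screened hub data.frame from [screen_hubs()] (or NULL).
#' @return A list of per-layer lists with `tp`, `called`, `planted`,
#'   `sensitivity`, `precision` (and `recovery` for hubs).
#' @export
truth_recovery_report <- function(truth, de_table = NULL, dm_table = NULL,
                                  hubs = NULL) {
  layer <- function(called_ids, planted_ids) {
    tp <- length(intersect(called_ids, planted_ids))
    list(tp = tp, called = length(called_ids), planted = length(planted_ids),
         sensitivity = if (length(planted_ids)) tp / length(planted_ids) else NA_real_,
         precision = if (length(called_ids)) tp / length(called_ids) else NA_real_)
  }
  out <- list()
  if (!is.null(de_table)) {
    out$de <- layer(unique(de_table$feature_id), names(truth$de_genes))
  }
  if (!is.null(dm_table)) {
    out$dm <- layer(unique(dm_table$feature_id), names(truth$dm_probes))
  }
  if (!is.null(hubs)) {
    planted <- names(truth$hub_links)
    found <- intersect(hubs$node, planted)
    out$hubs <- list(tp = length(found), called = nrow(hubs),
                     planted = length(planted),
                     recovery = if (length(planted))
                       length(found) / length(planted) else NA_real_)
  }
  out
}
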