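test_that("size factors match the median-of-ratios hand derivation", {
  # two genes, two samples, counts [[2,4],[2,4]]: geometric mean sqrt(8),
  # ratios 2/sqrt(8) and 4/sqrt(8) -> factors (1/sqrt(2), sqrt(2))
  m <- matrix(c(2, 2, 4, 4), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(unname(size_factors(m)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  # identical columns -> all factors 1
  m2 <- matrix(c(3, 7, 3, 7, 3, 7), 2, 3,
               dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
  # single gene, equal counts
  m3 <- matrix(c(3, 3), 1, 2, dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(size_factors(m3)), c(1, 1))
  # columns that are scalar multiples recover the scalars up to a constant
  base <- matrix(rpois(40, 50) + 1, 10, 4,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  scaled <- sweep(base[, c(1, 1, 1, 1)], 2, c(1, 2, 4, 0.5), "*")
  colnames(scaled) <- paste0("s", 1:4)
  sf <- size_factors(scaled)
  expect_equal(unname(sf / sf[1]), c(1, 2, 4, 0.5), tolerance = 1e-9)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2,
                                   dimnames = list(c("a", "b"), c("x", "y")))),
               "pre-filter")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(3)
  m <- matrix(rnbinom(300 * 6, mu = 100, size = 10), 300, 6,
              dimnames = list(paste0("g", 1:300), paste0("s", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("FPKM follows its formula and is depth-invariant", {
  m <- matrix(c(10, 999990), 2, 1,
              dimnames = list(c("g1", "g2"), "s1"))
  f <- fpkm(m, lengths = c(1000, 2000))
  expect_equal(f["g1", "s1"], 10) # 1e9 * 10 / (1000 * 1e6)
  expect_equal(fpkm(matrix(c(0, 10), 2, 1, dimnames = dimnames(m)),
                    lengths = c(1000, 1000))["g1", 1], 0)
  expect_equal(fpkm(2 * m, lengths = c(1000, 2000)), f) # N doubles with K
  expect_error(fpkm(m, lengths = c(-5, 100)), "positive")
})

test_that("de_test estimates planted effects and is antisymmetric in labels", {
  # low-noise regime so the estimate concentrates tightly around the truth
  sim <- simulate_cohort(sim_config(n_genes = 500, frac_de = 0.2,
                                    de_lfc_range = c(3, 3), n_hubs = 0,
                                    links_per_hub = 0, nb_dispersion = 0.01,
                                    base_mean_log_range = c(8, 12), seed = 13))
  de <- de_test(sim$counts, sim$groups)
  planted <- sim$truth$de_genes
  est <- de$effect[match(names(planted), de$feature_id)]
  expect_true(all(abs(est - planted) < 0.5))

  flipped <- sim$groups
  flipped$group <- ifelse(flipped$group == "case", "control", "case")
  de2 <- de_test(sim$counts, flipped)
  m <- match(de$feature_id, de2$feature_id)
  expect_equal(de2$effect[m], -de$effect, tolerance = 1e-9)
  expect_equal(de2$p[m], de$p, tolerance = 1e-9)
})

test_that("zero-effect rows get direction 'none'", {
  m <- matrix(rep(c(8, 6), each = 9), 2, 9, byrow = TRUE,
              dimnames = list(c("g1", "g2"), tiny_groups()$sample_id))
  de <- de_test(feature_matrix(m, kind = "counts"), tiny_groups())
  expect_true(all(de$direction == "none"))
})

test_that("the expression screen keeps printed exemplar rows and is idempotent", {
  tab <- as_diff_table(top20_mrna(), "log2FoldChange")
  kept <- apply_de_filter(tab)
  expect_equal(nrow(kept), nrow(tab)) # every printed row passes the screen
  expect_true("LPIN1" %in% kept$gene_name[kept$effect == 8.26])
  expect_true("PPP1R16B" %in% kept$gene_name[kept$effect == -7.95 &
                                               kept$direction == "down"])
  # below the fold-change bound -> dropped
  weak <- tab[1, ]
  weak$effect <- 0.5
  weak$p <- 0.001
  expect_equal(nrow(apply_de_filter(weak)), 0)
  # idempotence and subset property
  again <- apply_de_filter(kept)
  expect_identical(again$feature_id, kept$feature_id)
  expect_true(all(kept$feature_id %in% tab$feature_id))
  expect_equal(attr(kept, "n_up") + attr(kept, "n_down"), nrow(kept))
})

test_that("duplicate-name deletion is seeded, uniform and order-preserving", {
  tab <- data.frame(feature_id = paste0("t", 1:5),
                    gene_name = c("A", "B", "B", "C", "D"),
                    effect = 1:5, direction = "up", p = 0.01, fdr = 0.05,
                    stringsAsFactors = FALSE)
  out <- dedup_random(tab, seed = 1)
  expect_equal(nrow(out), 4)
  expect_equal(attr(out, "n_dropped"), 1)
  expect_identical(out, dedup_random(tab, seed = 1)) # same seed, same pick
  expect_identical(out$feature_id, sort(out$feature_id)) # order preserved

  # uniformity over seeds: each duplicate copy kept about half the time
  picks <- vapply(1:2000, function(s) {
    dedup_random(tab, seed = s)$feature_id[2]
  }, character(1))
  frac_t2 <- mean(picks == "t2")
  half_width <- 2.576 * sqrt(0.25 / 2000)
  expect_lt(abs(frac_t2 - 0.5), half_width)
})
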