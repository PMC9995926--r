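test_that("build_network keeps exact-correlation pairs and validates samples", {
  meth <- matrix(c(1, 2, 3), 1, 3, dimnames = list("p1", c("s1", "s2", "s3")))
  rna <- matrix(c(2, 4, 6, 1, 0, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  net <- suppressWarnings(build_network(meth, rna, 0.95))
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$gene_id, "g1")
  expect_equal(net$edges$r, 1)
  # non-strict threshold keeps |r| exactly at the cutoff
  rna2 <- rbind(rna, g3 = -2 * rna[1, ] + 7)
  net2 <- suppressWarnings(build_network(meth, rna2, 1))
  expect_setequal(net2$edges$gene_id, c("g1", "g3"))
  # sample mismatch names the difference
  bad <- rna
  colnames(bad) <- c("s1", "s2", "sX")
  expect_error(suppressWarnings(build_network(meth, bad)), "sX")
  # undefined pairs skipped and counted
  rna3 <- rbind(rna, g4 = c(5, 5, 5))
  net3 <- suppressWarnings(build_network(meth, rna3, 0.95))
  expect_equal(net3$n_undefined, 1)
  expect_false("g4" %in% net3$edges$gene_id)
})

test_that("edge sets match a brute-force oracle on random instances", {
  set.seed(47)
  for (trial in 1:25) {
    inst <- random_bipartite_instance(sample(5:50, 1), sample(5:50, 1))
    thr <- runif(1, 0.2, 0.8)
    net <- suppressWarnings(build_network(inst$meth, inst$rna, thr))
    oracle <- edges_oracle(inst$meth, inst$rna, thr)
    expect_identical(net$edges$probe_id, oracle$probe_id)
    expect_identical(net$edges$gene_id, oracle$gene_id)
    expect_equal(net$edges$r, oracle$r, tolerance = 1e-12)
  }
})

test_that("degrees satisfy hand counts and the handshake identity", {
  net <- structure(list(
    edges = data.frame(probe_id = c("m1", "m1", "m1", "m2"),
                       gene_id = c("g1", "g2", "g3", "g1"),
                       r = c(1, 1, 1, 1), stringsAsFactors = FALSE),
    meth_nodes = c("m1", "m2", "m3"), rna_nodes = c("g1", "g2", "g3"),
    threshold = 0.95, n_undefined = 0L), class = "bipartite_network")
  deg <- node_degrees(net)
  lookup <- setNames(deg$degree, deg$node)
  expect_equal(unname(lookup[c("m1", "m2", "m3")]), c(3, 1, 0))
  expect_equal(unname(lookup[c("g1", "g2", "g3")]), c(2, 1, 1))
  expect_equal(sum(deg$degree[deg$side == "meth"]),
               sum(deg$degree[deg$side == "rna"]))
  expect_equal(sum(deg$degree[deg$side == "meth"]), count_pairs(net))
})

test_that("hub screening sorts, truncates, breaks ties deterministically", {
  net <- structure(list(
    edges = data.frame(
      probe_id = c(rep("a", 30), rep("b", 26), rep("c", 10), rep("d", 26)),
      gene_id = paste0("g", c(1:30, 1:26, 1:10, 1:26)),
      r = 1, stringsAsFactors = FALSE),
    meth_nodes = c("a", "b", "c", "d"),
    rna_nodes = paste0("g", 1:30), threshold = 0.95, n_undefined = 0L),
    class = "bipartite_network")
  hubs <- screen_hubs(net, min_degree = 25, top_n = 41)
  expect_identical(hubs$node, c("a", "b", "d")) # c below min degree
  # tie at the cut: one slot for two degree-26 nodes -> lexicographic winner
  hubs2 <- screen_hubs(net, min_degree = 25, top_n = 2)
  expect_identical(hubs2$node, c("a", "b"))
  expect_equal(attr(hubs2, "fraction_of_nodes"), 2 / 34)
})

test_that("thresholds are monotone: lower r adds edges, higher degree removes hubs", {
  set.seed(53)
  inst <- random_bipartite_instance(30, 30)
  thrs <- c(0.9, 0.7, 0.5, 0.3)
  sizes <- vapply(thrs, function(t) {
    count_pairs(suppressWarnings(build_network(inst$meth, inst$rna, t)))
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  net <- suppressWarnings(build_network(inst$meth, inst$rna, 0.3))
  hub_sizes <- vapply(c(1, 3, 5, 8), function(d) {
    nrow(screen_hubs(net, min_degree = d, top_n = 1e6))
  }, numeric(1))
  expect_true(all(diff(hub_sizes) <= 0))
})

test_that("network is invariant under joint sample permutation", {
  set.seed(59)
  inst <- random_bipartite_instance(12, 12)
  perm <- sample(ncol(inst$meth))
  a <- suppressWarnings(build_network(inst$meth, inst$rna, 0.5))
  b <- suppressWarnings(build_network(inst$meth[, perm], inst$rna[, perm], 0.5))
  expect_equal(a$edges, b$edges, tolerance = 1e-12)
})

test_that("planted links all become edges in the zero-noise limit", {
  # moderate fold changes over well-expressed genes: keeps every driven
  # gene's counts away from zero, so count rounding cannot erode the
  # perfect linear coupling below the edge threshold
  cfg <- sim_config(n_genes = 300, n_probes = 300, frac_de = 0.5,
                    frac_dm = 0.1, n_hubs = 5, links_per_hub = 30,
                    de_lfc_range = c(1.5, 3), base_mean_log_range = c(6, 10),
                    hub_noise_sd = 0, seed = 61)
  sim <- simulate_cohort(cfg)
  m <- beta_to_m(fm_values(sim$betas))
  sf <- size_factors(sim$counts)
  rna <- log2(sweep(fm_values(sim$counts), 2, sf, "/") + 0.5)
  net <- suppressWarnings(build_network(m, rna, 0.95))
  keyed <- paste(net$edges$probe_id, net$edges$gene_id)
  planted <- unlist(lapply(names(sim$truth$hub_links), function(p) {
    paste(p, sim$truth$hub_links[[p]])
  }))
  expect_length(planted, 150)
  expect_equal(sum(planted %in% keyed), 150) # exactly the 150 planted pairs
})

test_that("hub_genes restricts to screened methylation probes with annotation", {
  hubs <- data.frame(node = c("cg1", "cg2", "g9"),
                     side = c("meth", "meth", "rna"),
                     degree = c(30, 28, 40), stringsAsFactors = FALSE)
  dm <- data.frame(feature_id = "cg1", gene_name = "SLC6A6", effect = 0.4,
                   direction = "up", p = 0.0073, fdr = 0.1,
                   stringsAsFactors = FALSE)
  expect_warning(out <- hub_genes(hubs, dm), "cg2")
  expect_equal(nrow(out), 1)
  expect_identical(out$gene_name, "SLC6A6")
  expect_identical(out$probe_id, "cg1")
  expect_equal(out$p, 0.0073)
  # empty hub list -> empty roster
  expect_equal(nrow(hub_genes(hubs[0, ], dm)), 0)
})
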