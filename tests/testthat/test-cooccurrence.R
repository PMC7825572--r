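test_that("Spearman score matrix handles monotone, antitone, tied cases", {
  m <- rbind(a = c(1, 2, 3, 4, 5), b = c(2, 4, 6, 8, 10),
             c = c(5, 4, 3, 2, 1), d = c(7, 7, 7, 7, 7))
  colnames(m) <- paste0("s", 1:5)
  s <- spearman_score_matrix(m)
  expect_equal(s["a", "b"], 1)
  expect_equal(s["a", "c"], -1)
  expect_true(is.na(s["a", "d"]))  # constant row -> missing, not error
  expect_equal(s, t(s))
  expect_true(all(diag(s) == 1))
  m2 <- rbind(a = c(1, 2, 3), b = c(1, 3, 2)); colnames(m2) <- paste0("s", 1:3)
  expect_equal(spearman_score_matrix(m2)["a", "b"], 0.5)
  expect_error(spearman_score_matrix(m[, 1:2]), "3 samples")
})

test_that("candidate threshold is inclusive and two-sided", {
  s <- diag(4)
  s[1, 2] <- s[2, 1] <- 0.70
  s[1, 3] <- s[3, 1] <- -0.85
  s[2, 3] <- s[3, 2] <- 0.69
  s[3, 4] <- s[4, 3] <- NA
  cand <- candidate_edges(s, 0.7)
  expect_identical(nrow(cand), 2L)
  expect_true(any(cand$i == 1 & cand$j == 2 & cand$score == 0.70))
  expect_true(any(cand$i == 1 & cand$j == 3 & cand$score == -0.85))
})

test_that("sampled permutation null is centred for independent rows", {
  tab <- independent_table(50, 40, seed = 21)
  rel <- to_relative_abundance(tab)
  # without renormalization the row-shuffle null is centred at zero
  plain <- permutation_null(rel, c(1, 2), n_iter = 1000, renormalize = FALSE,
                            seed = 5)
  expect_false(attr(plain, "exact"))
  expect_lt(abs(mean(plain)), 0.05)
  # the renormalized null keeps the (small, pair-share-dependent)
  # compositional bias; for a pair holding a few percent of the total it
  # stays close to zero
  nul <- permutation_null(rel, c(1, 2), n_iter = 1000, seed = 5)
  expect_lt(abs(mean(nul)), 0.1)
  expect_true(all(nul >= -1 & nul <= 1))
  n1 <- permutation_null(rel, c(1, 2), n_iter = 1, seed = 6)
  expect_length(as.numeric(n1), 1L)
})

test_that("exact enumeration matches the sampled null (oracle equivalence)", {
  tab <- independent_table(6, 5, depth = 5000, seed = 22)
  rel <- to_relative_abundance(tab)
  ex <- permutation_null(rel, c(1, 2), renormalize = TRUE, exact_max_n = 6)
  expect_true(attr(ex, "exact"))
  expect_length(as.numeric(ex), factorial(5)^2)
  sam <- permutation_null(rel, c(1, 2), n_iter = 20000, renormalize = TRUE,
                          exact_max_n = 0, seed = 7)
  expect_lt(abs(mean(ex) - mean(sam)), 0.02)  # Monte-Carlo error at 20k draws
  # unrenormalized exact mode reduces to single-row orders
  ex2 <- permutation_null(rel, c(1, 2), renormalize = FALSE, exact_max_n = 6)
  expect_length(as.numeric(ex2), factorial(5))
  sam2 <- permutation_null(rel, c(1, 2), n_iter = 20000, renormalize = FALSE,
                           exact_max_n = 0, seed = 8)
  expect_lt(abs(mean(ex2) - mean(sam2)), 0.02)
})

test_that("renormalization on a 2-taxon table equals direct recomputation", {
  # with only two taxa the renormalized values are xi/(xi+xj'); verify the
  # null against a direct per-iteration recomputation oracle
  m <- rbind(a = c(.1, .3, .2, .25, .15), b = c(.9, .7, .8, .75, .85))
  colnames(m) <- paste0("s", 1:5)
  got <- permutation_null(m, c(1, 2), renormalize = TRUE, exact_max_n = 5)
  P <- ncoocnet:::.all_perms(5)
  oracle <- c()
  for (ai in seq_len(nrow(P))) for (bi in seq_len(nrow(P))) {
    xa <- m[1, P[ai, ]]; xb <- m[2, P[bi, ]]
    s <- xa + xb
    oracle <- c(oracle, suppressWarnings(
      cor(xa / s, xb / s, method = "spearman")))
  }
  expect_equal(sort(as.numeric(got)), sort(oracle))
})

test_that("bootstrap distribution tracks the observed score", {
  m <- rbind(a = 1:10, b = (1:10)^2)  # perfectly rank-correlated
  colnames(m) <- paste0("s", 1:10)
  bo <- bootstrap_distribution(m, c(1, 2), n_iter = 200, seed = 1)
  expect_true(all(abs(bo - 1) < 1e-12, na.rm = TRUE))
  pe <- data.frame(taxon_i = 1L, taxon_j = 2L, target_spearman = 0.9)
  lat <- plant_copula_correlations(2, 40, pe, seed = 3)
  obs <- cor(lat[1, ], lat[2, ], method = "spearman")
  bo2 <- bootstrap_distribution(lat, c(1, 2), n_iter = 1000, seed = 4)
  expect_lt(abs(mean(bo2, na.rm = TRUE) - obs), 0.05)
  expect_error(bootstrap_distribution(m, c(1, 2), n_iter = 0), "n_iter")
  expect_error(bootstrap_distribution(m[, 1:2], c(1, 2)), "3 samples")
})

test_that("ReBoot p-value follows the Gaussian tail of the z statistic", {
  nul <- rnorm(1000, 0, 0.05); nul <- nul - mean(nul)          # mean 0
  bo <- rnorm(1000, 0.8, 0.1); bo <- bo - mean(bo) + 0.8       # mean .8
  bo <- 0.8 + (bo - 0.8) * 0.1 / sd(bo)                        # sd .1
  p <- reboot_pvalue(nul, bo)
  expect_equal(p, 2 * pnorm(-8), tolerance = 1e-6)
  expect_lt(p, 1e-10)
  x <- rnorm(500)
  expect_equal(reboot_pvalue(x, x), 1)  # identical distributions -> z = 0
  expect_error(reboot_pvalue(NA_real_, NA_real_), "defined")
})

test_that("stability filter compares the null mean to the bootstrap interval", {
  bo <- seq(0.6, 0.9, length.out = 100)
  expect_true(is_stable(bo, 0.0))                    # null well outside
  sym <- c(seq(-1, 1, length.out = 101))
  expect_false(is_stable(sym, 0.0))                  # null dead centre
  # ci = 0 collapses the interval to the median
  expect_true(is_stable(sym, 0.5, ci = 0))
  expect_false(is_stable(sym, stats::median(sym), ci = 0))
})

test_that("p-value merging: identity, dependent collapse, Fisher", {
  expect_identical(merge_pvalues(0.03), 0.03)
  # perfectly dependent measures collapse to the single test
  set.seed(1)
  s <- rnorm(500)
  for (p in c(0.01, 0.2, 0.7))
    expect_equal(merge_pvalues(c(p, p), "brown", cbind(s, s)), p,
                 tolerance = 0.05)
  # independent p = (0.5, 0.5): chi^2_4 tail of -2(2 log 0.5) = 0.5966
  expect_equal(merge_pvalues(c(0.5, 0.5), "fisher"),
               pchisq(-2 * 2 * log(0.5), 4, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(merge_pvalues(c(0.5, 0.5), "fisher"), 0.5966, tolerance = 1e-4)
  expect_error(merge_pvalues(numeric(0)), "empty")
})

test_that("BH adjustment matches the step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(1), 1)
  expect_equal(bh_adjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(2)
  for (k in 1:5) {
    p <- runif(20)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
})

test_that("build_network recovers a planted edge and is deterministic", {
  spec <- synthetic_spec(n_taxa = 12, n_groups = 1, n_replicates = 40,
                         depth = 10000, group_labels = "CK",
                         planted_edges = data.frame(taxon_i = 1L, taxon_j = 2L,
                                                    target_spearman = 0.95),
                         seed = 31)
  tab <- generate_dataset(spec)$table
  filt <- filter_otus(tab, "CK")
  cfg <- cooc_config(n_permutations = 500, n_bootstraps = 500, seed = 32)
  net <- build_network(filt, "CK", cfg)
  expect_true(any(net$edges$from == "OTU_001" & net$edges$to == "OTU_002"))
  expect_true(all(net$edges$q <= 0.05))
  expect_true(all(abs(net$edges$score) >= 0.7))
  net2 <- build_network(filt, "CK", cfg)
  expect_identical(net$edges, net2$edges)
})

test_that("planted co-exclusion yields a negative-sign edge", {
  spec <- synthetic_spec(n_taxa = 10, n_groups = 1, n_replicates = 40,
                         depth = 10000, group_labels = "CK",
                         planted_edges = data.frame(taxon_i = 3L, taxon_j = 7L,
                                                    target_spearman = -0.95),
                         seed = 33)
  tab <- generate_dataset(spec)$table
  net <- build_network(filter_otus(tab, "CK"), "CK",
                       cooc_config(n_permutations = 500, n_bootstraps = 500,
                                   seed = 34))
  hit <- net$edges[net$edges$from == "OTU_003" & net$edges$to == "OTU_007", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$sign, "negative")
})

test_that("edge set is invariant under taxon relabeling (symmetry)", {
  spec <- synthetic_spec(n_taxa = 8, n_groups = 1, n_replicates = 30,
                         depth = 8000, group_labels = "CK",
                         planted_edges = data.frame(taxon_i = 1L, taxon_j = 5L,
                                                    target_spearman = 0.95),
                         seed = 35)
  tab <- generate_dataset(spec)$table
  cfg <- cooc_config(n_permutations = 300, n_bootstraps = 300, seed = 36)
  net <- build_network(filter_otus(tab, "CK"), "CK", cfg)
  # relabel: reverse row order with renamed ids
  perm <- rev(seq_len(nrow(tab$counts)))
  relab <- paste0("X_", rownames(tab$counts)[perm])
  m <- tab$counts[perm, ]; rownames(m) <- relab
  tab2 <- abundance_table(m, tab$taxonomy[perm], tab$group)
  net2 <- build_network(filter_otus(tab2, "CK"), "CK", cfg)
  key <- function(net, strip = FALSE) {
    f <- net$edges$from; t <- net$edges$to
    if (strip) { f <- sub("^X_", "", f); t <- sub("^X_", "", t) }
    sort(paste(pmin(f, t), pmax(f, t)))
  }
  expect_identical(key(net), key(net2, strip = TRUE))
})

test_that("metadata networks recover planted links and tag node classes", {
  spec <- synthetic_spec(n_taxa = 10, n_groups = 1, n_replicates = 40,
                         depth = 10000, group_labels = "CK",
                         metadata_spec = data.frame(
                           variable = c("pH", "flat"),
                           linked_taxon = c(4L, NA),
                           target_pearson = c(0.95, 0),
                           mean = c(5, 1), sd = c(0.3, 0)),
                         seed = 41)
  ds <- generate_dataset(spec)
  filt <- filter_otus(ds$table, "CK")
  cfg <- cooc_config(n_permutations = 500, n_bootstraps = 500, seed = 42)
  expect_warning(net <- build_metadata_network(filt, ds$metadata, "CK", cfg),
                 "constant metadata")
  hit <- net$edges[(net$edges$from == "OTU_004" & net$edges$to == "pH") |
                   (net$edges$from == "pH" & net$edges$to == "OTU_004"), ]
  expect_identical(nrow(hit), 1L)
  expect_identical(net$nodes$node_class[net$nodes$id == "pH"], "metadata")
  expect_false("flat" %in% c(net$edges$from, net$edges$to))
  # no metadata -> reduces to build_network under the same seed
  netA <- suppressWarnings(build_metadata_network(filt, NULL, "CK", cfg))
  netB <- suppressWarnings(build_network(filt, "CK", cfg))
  expect_identical(netA$edges, netB$edges)
})

test_that("every reported edge satisfies the joint significance contract", {
  spec <- synthetic_spec(n_taxa = 15, n_groups = 1, n_replicates = 40,
                         depth = 10000, group_labels = "CK",
                         planted_edges = data.frame(
                           taxon_i = c(1L, 3L), taxon_j = c(2L, 4L),
                           target_spearman = c(0.9, 0.85)),
                         seed = 51)
  tab <- generate_dataset(spec)$table
  net <- build_network(filter_otus(tab, "CK"), "CK",
                       cooc_config(n_permutations = 400, n_bootstraps = 400,
                                   seed = 52))
  et <- net$edge_tests
  kept <- paste(net$edges$from, net$edges$to)
  for (k in seq_len(nrow(et))) {
    in_net <- paste(et$from[k], et$to[k]) %in% kept
    ok <- et$stable[k] && !is.na(et$q_bh[k]) && et$q_bh[k] <= 0.05 &&
      abs(et$observed_score[k]) >= 0.7
    expect_identical(in_net, ok)
  }
})
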