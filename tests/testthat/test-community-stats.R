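test_that("alpha diversity matches hand-computed toy values", {
  m <- matrix(c(6, 2, 2), 3, 1, dimnames = list(c("A", "B", "C"), "s1"))
  a <- alpha_diversity(m)
  expect_identical(a$observed_otus, 3)
  expect_equal(a$gini_simpson, 1 - (0.36 + 0.04 + 0.04))
  expect_equal(a$shannon, -sum(c(.6, .2, .2) * log(c(.6, .2, .2))))
  expect_equal(a$evenness, a$shannon / log(3))

  # chao1: S=10, F1=4, F2=2 -> 10 + 16/4 = 14
  x <- c(rep(1, 4), rep(2, 2), rep(5, 4))
  m2 <- matrix(x, length(x), 1,
               dimnames = list(paste0("o", seq_along(x)), "s1"))
  expect_equal(alpha_diversity(m2)$chao1, 14)
  # F2 = 0 -> bias-corrected form
  x3 <- c(rep(1, 3), rep(5, 2))
  m3 <- matrix(x3, 5, 1, dimnames = list(paste0("o", 1:5), "s1"))
  expect_equal(alpha_diversity(m3)$chao1, 5 + 3 * 2 / 2)

  single <- matrix(9, 1, 1, dimnames = list("o1", "s1"))
  a1 <- alpha_diversity(single)
  expect_equal(a1$shannon, 0)
  expect_equal(a1$gini_simpson, 0)
  expect_true(is.na(a1$evenness))
})

test_that("chao1 >= observed, equality iff no singletons (property)", {
  set.seed(3)
  for (k in 1:20) {
    x <- rpois(50, 2)
    if (sum(x) == 0) next
    m <- matrix(x, 50, 1, dimnames = list(paste0("o", 1:50), "s1"))
    a <- alpha_diversity(m)
    expect_gte(a$chao1, a$observed_otus)
    if (sum(x == 1) == 0) expect_equal(a$chao1, a$observed_otus)
    else expect_gt(a$chao1, a$observed_otus)
  }
})

test_that("faith_pd sums the rooted spanning subtree", {
  tree <- ape::read.tree(text = "((A:1,B:2):3,(C:4,D:5):6);")
  expect_equal(faith_pd(c("A", "B"), tree), 1 + 2 + 3)
  expect_equal(faith_pd("C", tree), 4 + 6)
  expect_equal(faith_pd(c("A", "B", "C", "D"), tree), 21)
  expect_equal(faith_pd(character(0), tree), 0)
  m <- matrix(c(3, 0, 1, 2), 4, 1,
              dimnames = list(c("A", "B", "C", "E"), "s1"))
  expect_error(alpha_diversity(m, tree = tree), "E")
})

test_that("Bray-Curtis matches the 1 - sum(min) oracle", {
  p <- cbind(s1 = c(0.5, 0.5, 0), s2 = c(0.5, 0, 0.5))
  expect_equal(bray_curtis(p)["s1", "s2"], 0.5)
  expect_equal(bray_curtis(cbind(a = c(.3, .7), b = c(.3, .7)))["a", "b"], 0)
  expect_equal(bray_curtis(cbind(a = c(1, 0), b = c(0, 1)))["a", "b"], 1)
  set.seed(5)
  m <- matrix(rexp(60), 6, 10, dimnames = list(NULL, paste0("s", 1:10)))
  m <- sweep(m, 2, colSums(m), "/")
  d <- bray_curtis(m)
  oracle <- outer(seq_len(10), seq_len(10), Vectorize(function(i, j)
    1 - sum(pmin(m[, i], m[, j]))))
  dimnames(oracle) <- dimnames(d)
  expect_equal(d, oracle, tolerance = 1e-12)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  if (requireNamespace("vegan", quietly = TRUE))
    expect_equal(unname(d), unname(as.matrix(vegan::vegdist(t(m)))),
                 tolerance = 1e-12)
})

test_that("PCoA is classical scaling: line geometry, degeneracy, Euclidean", {
  x <- c(0, 1, 3, 7)
  D <- as.matrix(dist(x)); dimnames(D) <- list(letters[1:4], letters[1:4])
  ord <- pcoa(D)
  # first axis recovers inter-point distances exactly
  expect_equal(as.matrix(dist(ord$coordinates[, 1])), D,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(ord$eigenvalues >= -1e-9))
  cms <- cmdscale(D, k = 1)
  expect_equal(abs(ord$coordinates[, 1]), abs(cms[, 1]), ignore_attr = TRUE)

  D0 <- matrix(0, 3, 3)
  expect_true(all(abs(pcoa(D0)$coordinates) < 1e-12) ||
                ncol(pcoa(D0)$coordinates) == 0)
  expect_error(pcoa(matrix(0, 2, 2)), "3 samples")
})

test_that("PERMANOVA agrees with the vegan oracle and is label-invariant", {
  set.seed(8)
  m <- matrix(rexp(12 * 20), 20, 12, dimnames = list(NULL, paste0("s", 1:12)))
  m <- sweep(m, 2, colSums(m), "/")
  d <- bray_curtis(m)
  g <- rep(c("CK", "AR"), each = 6)
  res <- permanova(d, g, n_perm = 99, seed = 1)
  expect_true(res$p >= 0 && res$p <= 1)
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::adonis2(as.dist(d) ~ grp,
                         data = data.frame(grp = g), permutations = 99)
    expect_equal(res$pseudo_F, vg$F[1], tolerance = 1e-10)
    expect_equal(res$R2, vg$R2[1], tolerance = 1e-10)
  }
  # permuting sample order leaves F unchanged
  o <- sample(12)
  res2 <- permanova(d[o, o], g[o], n_perm = 9, seed = 2)
  expect_equal(res2$pseudo_F, res$pseudo_F)
  expect_error(permanova(d, rep("CK", 12)), "2 groups")
  expect_error(permanova(d, c("A", rep("B", 11))), "2 samples")
})

test_that("PERMANOVA detects a planted group shift (power)", {
  hits <- 0L
  for (s in 1:8) {
    spec <- synthetic_spec(n_taxa = 20, n_groups = 2, n_replicates = 10,
                           depth = 5000,
                           group_effects = data.frame(group = "AR",
                                                      taxon = 1:5,
                                                      multiplier = 6),
                           seed = 200 + s)
    ds <- generate_dataset(spec)
    d <- bray_curtis(ds$table)
    res <- permanova(d, ds$table$group, n_perm = 199, seed = s)
    if (res$p <= 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 7L)
})

test_that("Mantel statistic is rank-invariant and matches vegan", {
  set.seed(9)
  x <- matrix(rnorm(10 * 5), 10)
  A <- as.matrix(dist(x)); dimnames(A) <- list(letters[1:10], letters[1:10])
  expect_equal(mantel_test(A, A, n_perm = 9, seed = 1)$r, 1)
  B <- sqrt(A)  # monotone transform
  expect_equal(mantel_test(A, B, n_perm = 9, seed = 1)$r, 1)
  C <- as.matrix(dist(matrix(rnorm(10 * 5), 10)))
  dimnames(C) <- dimnames(A)
  mt <- mantel_test(A, C, n_perm = 99, seed = 2)
  if (requireNamespace("vegan", quietly = TRUE)) {
    vg <- vegan::mantel(as.dist(A), as.dist(C), method = "spearman",
                        permutations = 99)
    expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-10)
  }
  bad <- C; dimnames(bad) <- list(LETTERS[1:10], LETTERS[1:10])
  expect_error(mantel_test(A, bad), "different samples")
})

test_that("diversity-environment correlations: exact and independent cases", {
  set.seed(10)
  n <- 1000
  alpha <- data.frame(shannon = rnorm(n), chao1 = rnorm(n))
  rownames(alpha) <- paste0("s", 1:n)
  md <- data.frame(pH = alpha$shannon,            # identical -> r = 1
                   AP = -alpha$chao1,             # negated  -> r = -1
                   AK = rnorm(n))                 # independent
  rownames(md) <- rownames(alpha)
  res <- diversity_env_correlations(alpha, md)
  expect_equal(res$r["shannon", "pH"], 1)
  expect_equal(res$r["chao1", "AP"], -1)
  expect_lt(abs(res$r["shannon", "AK"]), 0.1)
  expect_identical(res$stars["shannon", "pH"], "**")
  expect_error(diversity_env_correlations(alpha[1:2, ], md[1:2, ]),
               "3 shared")
})
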