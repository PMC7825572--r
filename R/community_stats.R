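#' Per-sample alpha diversity indices
#'
#' observed = number of OTUs with count > 0; chao1 = S + F1^2 / (2 F2)
#' (bias-corrected S + F1 (F1 - 1) / (2 (F2 + 1)) when F2 = 0, with F1 and
#' F2 the singleton and doubleton counts); shannon = -sum p log p (natural
#' log by default); gini_simpson = 1 - sum p^2; evenness = shannon /
#' log(S) (undefined, NA, for S <= 1); faith_pd = total branch length of
#' the rooted subtree spanning the observed OTUs (only when a tree is
#' supplied).
#'
#' @param table an `abundance_table` (or bare count matrix).
#' @param tree optional rooted `ape::phylo` tree whose tip labels cover the
#'   table's OTU ids; OTUs absent from the tree raise an error listing
#'   them.
#' @param base logarithm base for Shannon (default `exp(1)`).
#' @return data.frame with one row per sample.
#' @export
alpha_diversity <- function(table, tree = NULL, base = exp(1)) {
  m <- if (inherits(table, "abundance_table")) table$counts else
    as.matrix(table)
  if (any(colSums(m) <= 0)) stop("sample(s) with zero total count")
  if (!is.null(tree)) {
    missing <- setdiff(rownames(m), tree$tip.label)
    if (length(missing))
      stop("tree is missing taxa: ", paste(missing, collapse = ", "))
  }
  one <- function(x) {
    S <- sum(x > 0)
    F1 <- sum(x == 1); F2 <- sum(x == 2)
    chao1 <- if (F2 > 0) S + F1^2 / (2 * F2) else
      S + F1 * (F1 - 1) / (2 * (F2 + 1))
    p <- x[x > 0] / sum(x)
    sh <- -sum(p * log(p, base = base))
    c(observed_otus = S, chao1 = chao1, shannon = sh,
      gini_simpson = 1 - sum(p^2),
      evenness = if (S > 1) sh / log(S, base = base) else NA_real_)
  }
  out <- as.data.frame(t(apply(m, 2, one)))
  if (!is.null(tree))
    out$faith_pd <- apply(m, 2, function(x) faith_pd(rownames(m)[x > 0], tree))
  out
}

#' Faith's phylogenetic diversity of a set of tips
#'
#' Sum of branch lengths on the paths from each observed tip to the root
#' (each branch counted once), i.e. the rooted spanning subtree.
#'
#' @param tips character vector of tip labels present in the sample.
#' @param tree a rooted `ape::phylo` with branch lengths.
#' @return total branch length (0 for an empty tip set).
#' @export
faith_pd <- function(tips, tree) {
  stopifnot(inherits(tree, "phylo"))
  tips <- intersect(tips, tree$tip.label)
  if (length(tips) == 0L) return(0)
  tipidx <- match(tips, tree$tip.label)
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- numeric(max(tree$edge))
  elen[tree$edge[, 2]] <- tree$edge.length
  used <- logical(max(tree$edge))
  root <- ape::Ntip(tree) + 1L
  for (t in tipidx) {
    v <- t
    while (v != root && !used[v]) {
      used[v] <- TRUE
      v <- parent[v]
    }
  }
  sum(elen[used])
}

#' Bray-Curtis distance matrix
#'
#' d(s, t) = 1 - sum_i min(p_is, p_it) on column-normalized relative
#' abundances.
#'
#' @param relabund taxa x samples matrix with columns summing to 1 (a
#'   count matrix or `abundance_table` is normalized first).
#' @return symmetric distance matrix (samples x samples) with zero
#'   diagonal, entries in [0, 1].
#' @export
bray_curtis <- function(relabund) {
  m <- if (inherits(relabund, "abundance_table"))
    to_relative_abundance(relabund) else as.matrix(relabund)
  if (max(abs(colSums(m) - 1)) > 1e-6) m <- sweep(m, 2, colSums(m), "/")
  n <- ncol(m)
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    d[s, t] <- d[t, s] <- 1 - sum(pmin(m[, s], m[, t]))
  }
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Eigen-decomposition of the double-centered -D^2/2 matrix.  Negative
#' eigenvalues are reported, not corrected; coordinates span the
#' positive-eigenvalue axes only.
#'
#' @param dist square symmetric distance matrix (n >= 3).
#' @return list with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, decreasing), `proportion_explained` (relative to
#'   the positive eigenvalue total).
#' @export
pcoa <- function(dist) {
  D <- as.matrix(dist)
  n <- nrow(D)
  if (n < 3) stop("need >= 3 samples for ordination")
  stopifnot(isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > 1e-9 * max(abs(e$values), 1)
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(D)
  if (sum(pos)) colnames(coords) <- paste0("PCo", seq_len(sum(pos)))
  list(coordinates = coords, eigenvalues = e$values,
       proportion_explained = if (any(pos))
         pmax(e$values, 0) / sum(e$values[pos]) else rep(0, n))
}

#' One-way PERMANOVA on a distance matrix
#'
#' Pseudo-F from among/within sums of squared distances (raw, not ranked);
#' the p-value counts label permutations with F at least as large as
#' observed, with the add-one correction.  Deterministic given `seed`.
#'
#' @param dist square symmetric distance matrix.
#' @param groups per-sample group labels (>= 2 groups, each >= 2 samples).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed or NULL.
#' @return list with `pseudo_F`, `R2`, `p`.
#' @export
permanova <- function(dist, groups, n_perm = 999L, seed = NULL) {
  D <- as.matrix(dist)
  groups <- as.character(groups)
  n <- nrow(D)
  stopifnot(length(groups) == n)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples")
  D2 <- D^2
  sst <- sum(D2[upper.tri(D2)]) / n
  a <- length(tab)
  fstat <- function(g) {
    ssw <- 0
    for (lv in unique(g)) {
      idx <- which(g == lv)
      ssw <- ssw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
    }
    ssa <- sst - ssw
    (ssa / (a - 1)) / (ssw / (n - a))
  }
  F_obs <- fstat(groups)
  ssw <- 0
  for (lv in unique(groups)) {
    idx <- which(groups == lv)
    ssw <- ssw + sum(D2[idx, idx][upper.tri(D2[idx, idx])]) / length(idx)
  }
  R2 <- (sst - ssw) / sst
  p <- with_seed(seed, {
    hits <- 0L
    for (k in seq_len(n_perm)) {
      if (fstat(sample(groups)) >= F_obs) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(pseudo_F = F_obs, R2 = R2, p = p)
}

#' Mantel test between two distance matrices
#'
#' r = correlation (Spearman by default) of the corresponding
#' upper-triangle entries; p by permuting one matrix's sample labels.
#' One-tailed (r_perm >= r_obs) by default, matching common ecological
#' usage; `tail = "two"` available.
#'
#' @param dist_a,dist_b square symmetric distance matrices over the same
#'   samples (matching dimnames required when present).
#' @param method `"spearman"` or `"pearson"`.
#' @param n_perm permutations (default 999).
#' @param tail `"one"` or `"two"`.
#' @param seed integer seed or NULL.
#' @return list with `r`, `p`.
#' @export
mantel_test <- function(dist_a, dist_b, method = c("spearman", "pearson"),
                        n_perm = 999L, tail = c("one", "two"), seed = NULL) {
  method <- match.arg(method); tail <- match.arg(tail)
  A <- as.matrix(dist_a); B <- as.matrix(dist_b)
  if (!all(dim(A) == dim(B))) stop("distance matrices differ in size")
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    if (!setequal(rownames(A), rownames(B)))
      stop("distance matrices cover different samples")
    B <- B[rownames(A), rownames(A)]
  }
  ut <- upper.tri(A)
  r_obs <- stats::cor(A[ut], B[ut], method = method)
  p <- with_seed(seed, {
    n <- nrow(A)
    hits <- 0L
    for (k in seq_len(n_perm)) {
      pidx <- sample.int(n)
      rp <- stats::cor(A[ut], B[pidx, pidx][ut], method = method)
      if (tail == "one") {
        if (rp >= r_obs) hits <- hits + 1L
      } else if (abs(rp) >= abs(r_obs)) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  })
  list(r = r_obs, p = p)
}

#' Pearson correlations between alpha diversity indices and soil variables
#'
#' Pairwise-complete Pearson r with a two-tailed t-test p per (index,
#' variable) pair; cells with fewer than 3 complete pairs are left missing
#' with a warning.  Stars: "*" for p < 0.05, "**" for p < 0.01.
#'
#' @param alpha data.frame of per-sample diversity indices (rownames =
#'   sample ids).
#' @param metadata data.frame of per-sample soil variables (rownames =
#'   sample ids).
#' @return list of matrices `r`, `p`, `stars` (indices x variables).
#' @export
diversity_env_correlations <- function(alpha, metadata) {
  shared <- intersect(rownames(alpha), rownames(metadata))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  a <- alpha[shared, , drop = FALSE]
  m <- metadata[shared, , drop = FALSE]
  r <- p <- matrix(NA_real_, ncol(a), ncol(m),
                   dimnames = list(colnames(a), colnames(m)))
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(m))) {
    x <- a[[i]]; y <- m[[j]]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3) {
      warning(sprintf("fewer than 3 complete pairs for (%s, %s)",
                      colnames(a)[i], colnames(m)[j]))
      next
    }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**",
                                       ifelse(p < 0.05, "*", "")))
  list(r = r, p = p, stars = stars)
}
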