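#' Configuration for network inference
#'
#' Defaults mirror the standard CoNet-style setup: Spearman threshold 0.7
#' (two-sided, inclusive), 1000 permutations and 1000 bootstraps per
#' candidate edge, renormalized permutation null, unstable-edge filter at
#' the central 95% bootstrap interval, Brown p-value merging (identity for
#' the single Spearman measure), and Benjamini-Hochberg correction at 0.05.
#'
#' @param threshold absolute Spearman threshold for candidate edges.
#' @param n_permutations,n_bootstraps iterations per candidate edge.
#' @param ci central bootstrap interval mass for the stability filter.
#' @param alpha significance level applied to BH-adjusted p-values.
#' @param renormalize renormalize samples inside the permutation null
#'   (compositionality correction); metadata rows are never renormalized.
#' @param exact_enumeration_max_n sample-size cap below which the
#'   permutation null is enumerated exactly instead of sampled.  With
#'   renormalization the null lives on pairs of row orders (n!^2 states),
#'   so exact mode engages only when n!^2 is tractable (n <= 5); without
#'   renormalization the null reduces to single-row orders (n! states) and
#'   the cap applies directly.
#' @param p_method `"gaussian"` (z against the bootstrap spread, the CoNet
#'   reading) or `"empirical"` (two-sided tail of the null at the bootstrap
#'   mean).
#' @param merge_method `"brown"` or `"fisher"` for multi-measure merging.
#' @param seed integer root seed for the stochastic stages.
#' @return a `cooc_config` list.
#' @export
cooc_config <- function(threshold = 0.7, n_permutations = 1000L,
                        n_bootstraps = 1000L, ci = 0.95, alpha = 0.05,
                        renormalize = TRUE, exact_enumeration_max_n = 6L,
                        p_method = c("gaussian", "empirical"),
                        merge_method = c("brown", "fisher"), seed = 1L) {
  stopifnot(threshold > 0, threshold <= 1, n_permutations >= 1,
            n_bootstraps >= 1, ci >= 0, ci <= 1, alpha > 0, alpha <= 1)
  structure(list(threshold = threshold,
                 n_permutations = as.integer(n_permutations),
                 n_bootstraps = as.integer(n_bootstraps), ci = ci,
                 alpha = alpha, renormalize = isTRUE(renormalize),
                 exact_enumeration_max_n = as.integer(exact_enumeration_max_n),
                 p_method = match.arg(p_method),
                 merge_method = match.arg(merge_method),
                 seed = as.integer(seed)),
            class = "cooc_config")
}

# rowwise Spearman between two n_iter x n matrices (ties -> average ranks)
.row_spearman <- function(A, B) {
  ra <- t(apply(A, 1, rank))
  rb <- t(apply(B, 1, rank))
  ra <- ra - rowMeans(ra)
  rb <- rb - rowMeans(rb)
  num <- rowSums(ra * rb)
  den <- sqrt(rowSums(ra^2) * rowSums(rb^2))
  out <- rep(NA_real_, nrow(A))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# all permutations of 1:n as an n! x n matrix (n small)
.all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman score matrix over all OTU (and metadata) rows
#'
#' @param relabund numeric matrix, rows = features, columns = samples (>= 3).
#'   Ties receive average ranks.  Constant rows get `NA` scores (recorded
#'   as missing rather than erroring).
#' @return symmetric matrix with unit diagonal.
#' @export
spearman_score_matrix <- function(relabund) {
  m <- as.matrix(relabund)
  if (ncol(m) < 3) stop("need >= 3 samples for correlation scoring")
  const <- apply(m, 1, function(x) stats::sd(x) == 0 || !all(is.finite(x)))
  s <- suppressWarnings(stats::cor(t(m), method = "spearman"))
  s[const, ] <- NA_real_
  s[, const] <- NA_real_
  diag(s) <- 1
  s
}

#' Candidate edges above the correlation threshold
#'
#' Returns each unordered pair once, with `|r| >= threshold` (inclusive,
#' two-sided: both co-occurrence and co-exclusion candidates).
#'
#' @param scores symmetric score matrix (from [spearman_score_matrix()]).
#' @param threshold in (0, 1].
#' @return data.frame with columns `i`, `j` (row indices, i < j), `score`.
#' @export
candidate_edges <- function(scores, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  s <- as.matrix(scores)
  idx <- which(upper.tri(s) & !is.na(s) & abs(s) >= threshold, arr.ind = TRUE)
  data.frame(i = idx[, 1], j = idx[, 2],
             score = s[cbind(idx[, 1], idx[, 2])])
}

#' Permutation null distribution for one edge score
#'
#' Each iteration independently permutes the two member rows across
#' samples; with `renormalize = TRUE`, every sample column is then
#' renormalized over all taxon rows (the compositionality correction) before
#' the pair's Spearman score is recomputed.  Metadata rows are permuted but
#' never enter the renormalization.  When the sample size is small enough
#' the null is enumerated exactly over the permutation space instead of
#' sampled (see [cooc_config()]).
#'
#' @param relabund taxa x samples relative-abundance matrix (rows of
#'   metadata, if any, are indicated via `meta_rows`).
#' @param pair length-2 integer vector of row indices.
#' @param n_iter number of sampled iterations (ignored in exact mode).
#' @param renormalize logical.
#' @param meta_rows integer indices of metadata rows (excluded from column
#'   sums and never renormalized).
#' @param exact_max_n sample-size cap for exact enumeration.
#' @param seed integer seed or NULL.
#' @return numeric vector of null scores, with attribute `"exact"`.
#' @export
permutation_null <- function(relabund, pair, n_iter = 1000L,
                             renormalize = TRUE, meta_rows = integer(0),
                             exact_max_n = 6L, seed = NULL) {
  m <- as.matrix(relabund)
  n <- ncol(m)
  stopifnot(length(pair) == 2L, n_iter >= 1)
  i <- pair[1]; j <- pair[2]
  xi <- m[i, ]; xj <- m[j, ]
  if (stats::sd(xi) == 0 || stats::sd(xj) == 0)
    stop("constant row in pair; no defined permutation null")
  i_meta <- i %in% meta_rows; j_meta <- j %in% meta_rows
  taxa_rows <- setdiff(seq_len(nrow(m)), meta_rows)
  base <- colSums(m[taxa_rows, , drop = FALSE])
  renorm <- renormalize && !(i_meta && j_meta)

  # exact-enumeration feasibility: renormalized nulls live on (sigma, tau)
  # pairs unless one member is untouched by renormalization
  nf <- factorial(n)
  pairs_needed <- renorm && !(i_meta || j_meta)
  exact <- if (pairs_needed) (n <= exact_max_n && nf^2 <= 20000)
           else n <= exact_max_n

  if (exact) {
    P <- .all_perms(n)
    if (!renorm) {
      # distribution of cor(x_sigma, y_tau) == distribution over sigma alone
      A <- matrix(xi[P], nrow(P))
      B <- matrix(rep(xj, each = nrow(P)), nrow(P))
      out <- .row_spearman(A, B)
    } else if (pairs_needed) {
      g <- expand.grid(a = seq_len(nrow(P)), b = seq_len(nrow(P)))
      nr <- nrow(g)
      A0 <- matrix(xi[P[g$a, , drop = FALSE]], nr)
      B0 <- matrix(xj[P[g$b, , drop = FALSE]], nr)
      S <- matrix(rep(base, each = nr), nr) -
        matrix(rep(xi + xj, each = nr), nr) + A0 + B0
      out <- .row_spearman(A0 / S, B0 / S)
    } else {
      # exactly one taxon row renormalized; the metadata row's rank order is
      # fixed, so enumerating the taxon row's orders suffices
      tx <- if (i_meta) xj else xi
      mt <- if (i_meta) xi else xj
      A0 <- matrix(tx[P], nrow(P))
      S <- matrix(rep(base, each = nrow(P)), nrow(P)) -
        matrix(rep(tx, each = nrow(P)), nrow(P)) + A0
      out <- .row_spearman(A0 / S, matrix(rep(mt, each = nrow(P)), nrow(P)))
    }
    attr(out, "exact") <- TRUE
    return(out)
  }

  with_seed(seed, {
    sig <- t(vapply(seq_len(n_iter), function(k) sample.int(n), integer(n)))
    tau <- t(vapply(seq_len(n_iter), function(k) sample.int(n), integer(n)))
    A <- matrix(xi[sig], n_iter)
    B <- matrix(xj[tau], n_iter)
    if (renorm) {
      S <- matrix(rep(base, each = n_iter), n_iter)
      if (!i_meta) S <- S - matrix(rep(xi, each = n_iter), n_iter) + A
      if (!j_meta) S <- S - matrix(rep(xj, each = n_iter), n_iter) + B
      if (!i_meta) A <- A / S
      if (!j_meta) B <- B / S
    }
    out <- .row_spearman(A, B)
    attr(out, "exact") <- FALSE
    out
  })
}

#' Bootstrap distribution of one edge score
#'
#' Each iteration resamples sample columns with replacement (same n) and
#' recomputes the pair's Spearman score.  Resamples in which either row
#' becomes constant are redrawn up to a retry cap and recorded missing
#' afterwards; if more than half the iterations end up missing the sample
#' size is too small to bootstrap and an error is raised.
#'
#' @inheritParams permutation_null
#' @param retry_cap redraw attempts per degenerate resample.
#' @return numeric vector of bootstrap scores (may contain NA).
#' @export
bootstrap_distribution <- function(relabund, pair, n_iter = 1000L,
                                   retry_cap = 10L, seed = NULL) {
  m <- as.matrix(relabund)
  n <- ncol(m)
  if (n < 3) stop("need >= 3 samples to bootstrap")
  if (n_iter < 1) stop("n_iter must be >= 1")
  xi <- m[pair[1], ]; xj <- m[pair[2], ]
  with_seed(seed, {
    out <- rep(NA_real_, n_iter)
    for (k in seq_len(n_iter)) {
      for (try in seq_len(retry_cap + 1L)) {
        idx <- sample.int(n, n, replace = TRUE)
        a <- xi[idx]; b <- xj[idx]
        if (stats::sd(a) > 0 && stats::sd(b) > 0) {
          out[k] <- stats::cor(a, b, method = "spearman")
          break
        }
      }
    }
    if (mean(is.na(out)) > 0.5)
      stop("bootstrap degenerate for > 50% of iterations; increase sample size")
    out
  })
}

#' ReBoot edge p-value
#'
#' Gaussian reading of the ReBoot comparison: z = (mean(null) - mean(boot))
#' / sd(boot), two-tailed standard-normal p.  The `"empirical"` alternative
#' uses the two-sided tail of the permutation null at the bootstrap mean
#' (add-one corrected).
#'
#' @param null_scores permutation null scores.
#' @param boot_scores bootstrap scores.
#' @param method `"gaussian"` or `"empirical"`.
#' @return p-value in [0, 1].
#' @export
reboot_pvalue <- function(null_scores, boot_scores,
                          method = c("gaussian", "empirical")) {
  method <- match.arg(method)
  nu <- null_scores[is.finite(null_scores)]
  bo <- boot_scores[is.finite(boot_scores)]
  if (length(nu) < 2 || length(bo) < 2) stop("need >= 2 defined scores in each")
  if (method == "gaussian") {
    s <- stats::sd(bo)
    # degenerate bootstrap: p by indicator of equality of the two means
    if (s == 0)
      return(if (isTRUE(all.equal(mean(nu), mean(bo)))) 1 else 0)
    z <- (mean(nu) - mean(bo)) / s
    min(1, 2 * stats::pnorm(-abs(z)))
  } else {
    mb <- mean(bo)
    (1 + sum(abs(nu - mean(nu)) >= abs(mb - mean(nu)))) / (1 + length(nu))
  }
}

#' Unstable-edge filter
#'
#' An edge is unstable iff the permutation-null mean lies inside the
#' central `ci` interval of its bootstrap score distribution, i.e. the
#' resampled edge cannot be told apart from its null location.  Unstable
#' edges are discarded before multiple-testing correction.
#'
#' @param boot_scores bootstrap scores (>= 2 defined values).
#' @param null_mean mean of the permutation null.
#' @param ci central interval mass (default 0.95).
#' @return TRUE if stable.
#' @export
is_stable <- function(boot_scores, null_mean, ci = 0.95) {
  bo <- boot_scores[is.finite(boot_scores)]
  stopifnot(length(bo) >= 2)
  qq <- stats::quantile(bo, c((1 - ci) / 2, 1 - (1 - ci) / 2), names = FALSE)
  !(null_mean >= qq[1] && null_mean <= qq[2])
}

#' Merge per-measure p-values (Brown / Fisher)
#'
#' With the single Spearman measure used here the merge is the identity.
#' For multiple measures, Brown's method rescales Fisher's -2*sum(log p)
#' statistic by the empirical covariance of the per-measure evidence,
#' estimated from per-measure permutation score vectors when supplied
#' (columns of `perm_scores`); Fisher assumes independence.
#'
#' @param p_list numeric vector of p-values in [0, 1].
#' @param method `"brown"` or `"fisher"`.
#' @param perm_scores optional matrix (iterations x measures) of permutation
#'   scores used to estimate the dependence between measures for Brown's
#'   method; without it measures are treated as independent.
#' @return merged p-value.
#' @export
merge_pvalues <- function(p_list, method = c("brown", "fisher"),
                          perm_scores = NULL) {
  method <- match.arg(method)
  p <- as.numeric(p_list)
  if (length(p) == 0L) stop("empty p-value list")
  stopifnot(all(p >= 0 & p <= 1))
  if (length(p) == 1L) return(p)
  p <- pmax(p, .Machine$double.xmin)
  X <- -2 * sum(log(p))
  k <- length(p)
  EX <- 2 * k
  if (method == "fisher" || is.null(perm_scores)) {
    VX <- 4 * k
    if (method == "brown" && is.null(perm_scores)) {
      # no dependence information: Brown degrades to Fisher
    }
  } else {
    # empirical p per measure per permutation iteration, then cov of -2 log p
    ps <- apply(perm_scores, 2, function(s) {
      s <- s[is.finite(s)]
      r <- rank(-abs(s - mean(s)))
      r / (length(s) + 1)
    })
    lp <- -2 * log(pmax(as.matrix(ps), .Machine$double.xmin))
    C <- stats::cov(lp)
    VX <- sum(C)
  }
  c_scale <- VX / (2 * EX)
  df <- 2 * EX^2 / VX
  stats::pchisq(X / c_scale, df = df, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_vector p-values in [0, 1] (NA passed through).
#' @return adjusted q-values (monotone, capped at 1).
#' @export
bh_adjust <- function(p_vector) {
  p <- as.numeric(p_vector)
  ok <- !is.na(p)
  stopifnot(all(p[ok] >= 0 & p[ok] <= 1))
  q <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(pp[o] * m / (m - seq_len(m) + 1)))[ro]
  }
  q
}

new_cooc_network <- function(treatment, nodes, edges, edge_tests = NULL,
                             n_samples = NA_integer_) {
  structure(list(treatment = treatment, nodes = nodes, edges = edges,
                 edge_tests = edge_tests, n_samples = n_samples),
            class = "cooc_network")
}

#' @export
print.cooc_network <- function(x, ...) {
  cat(sprintf("cooc_network '%s': %d nodes, %d edges (%d positive, %d negative)\n",
              x$treatment, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative")))
  invisible(x)
}

#' Convert a `cooc_network` to an igraph graph
#' @param network a `cooc_network`.
#' @return an undirected igraph graph with node/edge attributes.
#' @export
network_igraph <- function(network) {
  stopifnot(inherits(network, "cooc_network"))
  g <- igraph::graph_from_data_frame(
    network$edges[, c("from", "to",
                      intersect(c("sign", "score", "q"),
                                colnames(network$edges)))],
    directed = FALSE, vertices = network$nodes)
  if (!is.na(network$treatment))
    g <- igraph::set_graph_attr(g, "treatment", network$treatment)
  g
}

# shared machinery behind build_network / build_metadata_network
.build_network_impl <- function(table, metadata, group, config) {
  stopifnot(inherits(table, "abundance_table"), inherits(config, "cooc_config"))
  samp <- names(table$group)[table$group == group]
  if (length(samp) == 0L) stop("no samples in group '", group, "'")
  sub <- subset_table(table, samples = samp)
  rel <- to_relative_abundance(sub)
  n_taxa <- nrow(rel)
  meta_rows <- integer(0)
  if (!is.null(metadata)) {
    md <- metadata[samp, , drop = FALSE]
    const <- vapply(md, function(v) stats::sd(v, na.rm = TRUE) == 0 ||
                      all(is.na(v)), logical(1))
    if (any(const))
      warning("constant metadata variable(s) excluded: ",
              paste(colnames(md)[const], collapse = ", "))
    md <- md[, !const, drop = FALSE]
    if (ncol(md)) {
      rel <- rbind(rel, t(as.matrix(md)))
      meta_rows <- n_taxa + seq_len(ncol(md))
    }
  }
  scores <- spearman_score_matrix(rel)
  cand <- candidate_edges(scores, config$threshold)
  # metadata-metadata pairs are not candidates
  if (length(meta_rows) && nrow(cand))
    cand <- cand[!(cand$i %in% meta_rows & cand$j %in% meta_rows), ,
                 drop = FALSE]
  ids <- rownames(rel)
  empty_net <- function() {
    warning("no significant edges for group '", group, "'")
    new_cooc_network(group,
                     nodes = data.frame(id = character(0), genus = character(0),
                                        node_class = character(0),
                                        mean_relabund = numeric(0)),
                     edges = data.frame(from = character(0), to = character(0),
                                        sign = character(0), score = numeric(0),
                                        q = numeric(0)),
                     edge_tests = NULL, n_samples = length(samp))
  }
  if (nrow(cand) == 0L) return(empty_net())

  tests <- lapply(seq_len(nrow(cand)), function(k) {
    pr <- c(cand$i[k], cand$j[k])
    sk <- derive_seed(config$seed, paste0("edge/", group, "/", ids[pr[1]],
                                          "|", ids[pr[2]]))
    nul <- permutation_null(rel, pr, n_iter = config$n_permutations,
                            renormalize = config$renormalize,
                            meta_rows = meta_rows,
                            exact_max_n = config$exact_enumeration_max_n,
                            seed = derive_seed(sk, "perm"))
    boo <- bootstrap_distribution(rel, pr, n_iter = config$n_bootstraps,
                                  seed = derive_seed(sk, "boot"))
    nm <- mean(nul, na.rm = TRUE)
    stable <- is_stable(boo, nm, config$ci)
    p_raw <- if (stable) reboot_pvalue(nul, boo, config$p_method) else NA_real_
    list(i = pr[1], j = pr[2], observed = cand$score[k],
         null_mean = nm, null_sd = stats::sd(nul, na.rm = TRUE),
         boot_mean = mean(boo, na.rm = TRUE),
         boot_sd = stats::sd(boo, na.rm = TRUE),
         boot_q025 = stats::quantile(boo, 0.025, na.rm = TRUE, names = FALSE),
         boot_q975 = stats::quantile(boo, 0.975, na.rm = TRUE, names = FALSE),
         stable = stable, p_raw = p_raw,
         p_merged = if (stable) merge_pvalues(p_raw, config$merge_method)
                    else NA_real_)
  })
  et <- data.frame(
    from = ids[vapply(tests, `[[`, 0, "i")],
    to = ids[vapply(tests, `[[`, 0, "j")],
    observed_score = vapply(tests, `[[`, 0, "observed"),
    null_mean = vapply(tests, `[[`, 0, "null_mean"),
    null_sd = vapply(tests, `[[`, 0, "null_sd"),
    boot_mean = vapply(tests, `[[`, 0, "boot_mean"),
    boot_sd = vapply(tests, `[[`, 0, "boot_sd"),
    boot_q025 = vapply(tests, `[[`, 0, "boot_q025"),
    boot_q975 = vapply(tests, `[[`, 0, "boot_q975"),
    stable = vapply(tests, `[[`, NA, "stable"),
    p_raw = vapply(tests, `[[`, 0, "p_raw"),
    p_merged = vapply(tests, `[[`, 0, "p_merged"),
    stringsAsFactors = FALSE)
  et$sign <- ifelse(et$observed_score >= 0, "positive", "negative")
  # BH over the stable candidates of this one network run
  et$q_bh <- NA_real_
  et$q_bh[et$stable] <- bh_adjust(et$p_merged[et$stable])
  keep <- which(et$stable & !is.na(et$q_bh) & et$q_bh <= config$alpha)
  if (length(keep) == 0L) return(empty_net())

  edges <- data.frame(from = et$from[keep], to = et$to[keep],
                      sign = et$sign[keep], score = et$observed_score[keep],
                      q = et$q_bh[keep], stringsAsFactors = FALSE)
  node_ids <- unique(c(edges$from, edges$to))
  node_class <- ifelse(match(node_ids, ids) %in% meta_rows, "metadata", "taxon")
  mean_rel <- vapply(node_ids, function(id) {
    r <- match(id, ids)
    if (r %in% meta_rows) NA_real_ else mean(rel[r, ])
  }, numeric(1))
  genus <- vapply(node_ids, function(id) {
    if (id %in% rownames(sub$counts)) extract_genus(sub$taxonomy[[id]])
    else NA_character_
  }, character(1))
  nodes <- data.frame(id = node_ids, genus = genus, node_class = node_class,
                      mean_relabund = unname(mean_rel),
                      stringsAsFactors = FALSE)
  new_cooc_network(group, nodes = nodes, edges = edges, edge_tests = et,
                   n_samples = length(samp))
}

#' Infer a significant co-occurrence network for one treatment
#'
#' Full pipeline for one group's (already filtered) table: relative
#' abundance -> Spearman score matrix -> |r| >= threshold candidates ->
#' per-candidate renormalized permutation null + bootstrap -> unstable-edge
#' filter -> ReBoot p-value -> merge -> Benjamini-Hochberg over the stable
#' candidates -> keep q <= alpha.  Nodes are the endpoints of kept edges.
#' Deterministic given `config$seed`.
#'
#' @param table an `abundance_table` already filtered (see [filter_otus()]).
#' @param group treatment label (selects the table's samples).
#' @param config a [cooc_config()].
#' @return a `cooc_network`.
#' @export
build_network <- function(table, group, config = cooc_config()) {
  .build_network_impl(table, metadata = NULL, group = group, config = config)
}

#' Infer a network augmented with soil metadata nodes
#'
#' Candidate pairs include taxon-taxon and taxon-metadata pairs
#' (metadata-metadata pairs are excluded).  Metadata rows are permuted in
#' the null but never renormalized, and metadata nodes carry
#' `node_class = "metadata"`.  With `metadata = NULL` this reduces exactly
#' to [build_network()].
#'
#' @param table an `abundance_table` already filtered for the group.
#' @param metadata data.frame of numeric soil variables, rownames = sample
#'   ids (see [read_soil_metadata()]); or NULL.
#' @param group treatment label.
#' @param config a [cooc_config()].
#' @return a `cooc_network`.
#' @export
build_metadata_network <- function(table, metadata, group,
                                   config = cooc_config()) {
  .build_network_impl(table, metadata = metadata, group = group,
                      config = config)
}
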