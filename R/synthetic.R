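#' Specify a synthetic community dataset
#'
#' Captures everything needed to generate a compositional OTU table with
#' known ground truth: the study layout (two treatment groups of five
#' replicate samples by default), planted monotone taxon-taxon associations
#' (target Spearman correlations realized through a Gaussian copula over
#' log-normal marginals), per-group multiplicative abundance shifts, and
#' soil covariates optionally linked to taxa.
#'
#' @param n_taxa number of taxa (OTUs).
#' @param n_groups number of treatment groups (default 2).
#' @param n_replicates replicate samples per group (default 5).
#' @param depth mean sequencing depth per sample (Poisson-jittered).
#' @param planted_edges data.frame with columns `taxon_i`, `taxon_j`
#'   (1-based indices), `target_spearman` in [-1, 1]; or NULL.
#' @param group_effects data.frame with columns `group` (label or 1-based
#'   index), `taxon` (1-based index), `multiplier` (> 0); or NULL.
#' @param metadata_spec data.frame with columns `variable`, `linked_taxon`
#'   (1-based index or NA for pure noise), `target_pearson`, `mean`, `sd`;
#'   or NULL.
#' @param meanlog,sdlog log-normal marginal parameters (defaults 0 and 1).
#' @param group_labels optional character vector of group names (defaults
#'   "G1", "G2", ...; with two groups, "CK" and "AR").
#' @param seed integer seed; every stochastic sub-operation derives its own
#'   named substream from it.
#' @return a `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_taxa, n_groups = 2L, n_replicates = 5L,
                           depth = 10000L, planted_edges = NULL,
                           group_effects = NULL, metadata_spec = NULL,
                           meanlog = 0, sdlog = 1, group_labels = NULL,
                           seed = 1L) {
  stopifnot(n_taxa >= 1, n_groups >= 1, n_replicates >= 1, depth >= 1)
  if (is.null(planted_edges))
    planted_edges <- data.frame(taxon_i = integer(0), taxon_j = integer(0),
                                target_spearman = numeric(0))
  planted_edges <- as.data.frame(planted_edges)
  stopifnot(all(c("taxon_i", "taxon_j", "target_spearman") %in%
                  colnames(planted_edges)))
  if (nrow(planted_edges)) {
    with(planted_edges, {
      if (any(taxon_i == taxon_j)) stop("planted edge with identical endpoints")
      if (any(taxon_i < 1 | taxon_i > n_taxa | taxon_j < 1 | taxon_j > n_taxa))
        stop("planted edge references out-of-range taxon")
      if (any(abs(target_spearman) > 1)) stop("|target_spearman| must be <= 1")
    })
    key <- apply(planted_edges[, c("taxon_i", "taxon_j")], 1,
                 function(r) paste(sort(r), collapse = "-"))
    if (anyDuplicated(key)) stop("duplicate planted pair: ",
                                 key[duplicated(key)][1])
  }
  if (is.null(group_labels)) {
    group_labels <- if (n_groups == 2L) c("CK", "AR")
      else paste0("G", seq_len(n_groups))
  }
  stopifnot(length(group_labels) == n_groups)
  structure(list(n_taxa = as.integer(n_taxa), n_groups = as.integer(n_groups),
                 n_replicates = as.integer(n_replicates),
                 depth = as.integer(depth), planted_edges = planted_edges,
                 group_effects = group_effects, metadata_spec = metadata_spec,
                 meanlog = meanlog, sdlog = sdlog,
                 group_labels = group_labels, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Latent abundances coupled by a Gaussian copula with planted Spearman
#' correlations
#'
#' Target Spearman correlations are converted to the latent normal Pearson
#' scale by the bivariate-normal identity r = 2 sin(pi * rho / 6); the
#' resulting pairwise correlation matrix (identity off the planted pairs)
#' is Cholesky-factored and, if it is not positive definite, repaired to
#' the nearest positive-definite matrix (reported via a warning naming the
#' offending pairs).  Log-normal marginals are applied by the monotone map
#' exp(meanlog + sdlog * z), which preserves Spearman correlations exactly.
#'
#' @param n_taxa number of taxa.
#' @param n_samples number of samples to draw.
#' @param planted_edges data.frame (`taxon_i`, `taxon_j`, `target_spearman`).
#' @param meanlog,sdlog log-normal marginal parameters.
#' @param seed integer seed or NULL.
#' @return a strictly positive `n_taxa` x `n_samples` matrix.
#' @export
plant_copula_correlations <- function(n_taxa, n_samples, planted_edges = NULL,
                                      meanlog = 0, sdlog = 1, seed = NULL) {
  if (is.null(planted_edges))
    planted_edges <- data.frame(taxon_i = integer(0), taxon_j = integer(0),
                                target_spearman = numeric(0))
  R <- diag(n_taxa)
  if (nrow(planted_edges)) {
    r <- 2 * sin(pi * planted_edges$target_spearman / 6)
    for (k in seq_len(nrow(planted_edges))) {
      i <- planted_edges$taxon_i[k]; j <- planted_edges$taxon_j[k]
      R[i, j] <- R[j, i] <- r[k]
    }
  }
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    pairs <- paste(planted_edges$taxon_i, planted_edges$taxon_j, sep = "-")
    rep <- tryCatch(
      as.matrix(Matrix::nearPD(R, corr = TRUE)$mat),
      error = function(e) stop("correlation matrix for planted pairs (",
                               paste(pairs, collapse = ", "),
                               ") is not positive definite and could not be repaired"))
    if (max(abs(rep - R)) > 0.05)
      stop("planted correlations are not jointly positive definite and lie ",
           "beyond repair tolerance; offending pairs: ",
           paste(pairs, collapse = ", "))
    warning("planted correlation matrix repaired to nearest PD; pairs: ",
            paste(pairs, collapse = ", "))
    R <- rep
    ed <- eigen(R, symmetric = TRUE)
  }
  # eigen square root handles the positive-semidefinite boundary (e.g. a
  # comonotone pair at target 1) that a Cholesky factor would reject
  L <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), n_taxa) %*% t(ed$vectors)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_taxa * n_samples), nrow = n_samples)
    X <- Z %*% L                     # samples x taxa, correlated normals
    t(exp(meanlog + sdlog * X))      # taxa x samples, log-normal marginals
  })
}

#' Draw multinomial counts from latent abundances
#'
#' Each sample's total depth is Poisson-jittered around `depth` (floored at
#' 1 read) and its counts drawn multinomially with probabilities equal to
#' the sample's latent column after closure.  Sparsity thus arises from
#' finite depth, not from structural zeros, so planted associations stay
#' exact at the population level.
#'
#' @param latent strictly positive taxa x samples matrix.
#' @param depth mean total reads per sample (>= 1).
#' @param seed integer seed or NULL.
#' @return integer count matrix, same dimnames as `latent`.
#' @export
draw_counts <- function(latent, depth, seed = NULL) {
  latent <- as.matrix(latent)
  if (any(!is.finite(latent))) stop("non-finite latent abundance")
  if (any(latent <= 0)) stop("latent abundances must be strictly positive")
  if (depth < 1) stop("depth must be >= 1")
  with_seed(seed, {
    n <- ncol(latent)
    totals <- pmax(1L, stats::rpois(n, depth))
    cnt <- vapply(seq_len(n), function(s) {
      p <- latent[, s] / sum(latent[, s])
      as.numeric(stats::rmultinom(1, totals[s], p))
    }, numeric(nrow(latent)))
    cnt <- matrix(cnt, nrow = nrow(latent), dimnames = dimnames(latent))
    storage.mode(cnt) <- "integer"
    cnt
  })
}

#' Generate soil covariates, optionally correlated with taxa
#'
#' A variable linked to a taxon with target Pearson correlation rho is
#' built as rho * standardized relative abundance + sqrt(1 - rho^2) * noise,
#' rescaled to the requested mean and sd; unlinked variables are independent
#' Gaussian noise.  A variable with sd = 0 is emitted as a constant column
#' and flagged via attribute `"constant_variables"` (its correlation with
#' anything is undefined).
#'
#' @param table an `abundance_table` (relative abundances are computed from
#'   its counts).
#' @param metadata_spec data.frame with columns `variable`, `linked_taxon`
#'   (1-based row index into the table or NA), `target_pearson`, `mean`,
#'   `sd`.
#' @param seed integer seed or NULL.
#' @return data.frame of per-sample variables (rownames = sample ids).
#' @export
generate_soil_metadata <- function(table, metadata_spec, seed = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  ms <- as.data.frame(metadata_spec)
  stopifnot(all(c("variable", "linked_taxon", "target_pearson", "mean", "sd")
                %in% colnames(ms)))
  if (any(abs(ms$target_pearson) > 1, na.rm = TRUE))
    stop("|target_pearson| must be <= 1")
  linked <- ms$linked_taxon[!is.na(ms$linked_taxon)]
  if (any(linked < 1 | linked > nrow(table$counts)))
    stop("linked taxon out of range")
  rel <- to_relative_abundance(table)
  n <- ncol(rel)
  with_seed(seed, {
    cols <- lapply(seq_len(nrow(ms)), function(k) {
      if (ms$sd[k] == 0) return(rep(ms$mean[k], n))
      z <- stats::rnorm(n)
      if (is.na(ms$linked_taxon[k])) {
        y <- z
      } else {
        x <- rel[ms$linked_taxon[k], ]
        sx <- stats::sd(x)
        xs <- if (sx > 0) (x - mean(x)) / sx else rep(0, n)
        rho <- ms$target_pearson[k]
        y <- rho * xs + sqrt(1 - rho^2) * z
      }
      ms$mean[k] + ms$sd[k] * y
    })
    out <- as.data.frame(stats::setNames(cols, ms$variable))
    rownames(out) <- colnames(table$counts)
    attr(out, "constant_variables") <- ms$variable[ms$sd == 0]
    out
  })
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws the latent copula-coupled abundances, applies per-group
#' multiplicative effects, samples multinomial counts per sample, and
#' generates linked soil covariates.  The same spec (including seed) is
#' guaranteed to reproduce identical output.
#'
#' @param spec a [synthetic_spec()].
#' @return a list with elements `table` (an `abundance_table`), `metadata`
#'   (data.frame or NULL), and `truth` (a `ground_truth`: planted edges,
#'   latent matrix, group labels).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_samples <- spec$n_groups * spec$n_replicates
  latent <- plant_copula_correlations(
    spec$n_taxa, n_samples, spec$planted_edges,
    meanlog = spec$meanlog, sdlog = spec$sdlog,
    seed = derive_seed(spec$seed, "copula"))
  otu_ids <- sprintf("OTU_%03d", seq_len(spec$n_taxa))
  grp <- rep(spec$group_labels, each = spec$n_replicates)
  sample_ids <- paste0(grp, ".", rep(seq_len(spec$n_replicates),
                                     times = spec$n_groups))
  dimnames(latent) <- list(otu_ids, sample_ids)
  if (!is.null(spec$group_effects)) {
    ge <- as.data.frame(spec$group_effects)
    stopifnot(all(c("group", "taxon", "multiplier") %in% colnames(ge)))
    for (k in seq_len(nrow(ge))) {
      g <- ge$group[k]
      if (is.numeric(g)) g <- spec$group_labels[g]
      latent[ge$taxon[k], grp == g] <- latent[ge$taxon[k], grp == g] *
        ge$multiplier[k]
    }
  }
  counts <- draw_counts(latent, spec$depth,
                        seed = derive_seed(spec$seed, "counts"))
  taxonomy <- paste0("k__Bacteria;g__Genus", seq_len(spec$n_taxa))
  tab <- abundance_table(counts, taxonomy, grp)
  md <- NULL
  if (!is.null(spec$metadata_spec))
    md <- generate_soil_metadata(tab, spec$metadata_spec,
                                 seed = derive_seed(spec$seed, "metadata"))
  truth <- structure(list(planted_edges = spec$planted_edges,
                          latent = latent,
                          group = stats::setNames(grp, sample_ids)),
                     class = "ground_truth")
  list(table = tab, metadata = md, truth = truth)
}
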