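#' Convert counts to relative abundances (per-sample closure)
#'
#' Each sample column is divided by its total so that columns sum to one.
#' This is the "renormalization" applied before correlation scoring and
#' inside the permutation null.
#'
#' @param table an `abundance_table`, or a bare numeric matrix
#'   (taxa x samples).
#' @return a matrix of the same shape with columns summing to 1, with
#'   attribute `"table"` carrying the source `abundance_table` when one was
#'   given.
#' @export
to_relative_abundance <- function(table) {
  m <- if (inherits(table, "abundance_table")) table$counts else as.matrix(table)
  tot <- colSums(m)
  if (any(tot <= 0)) {
    bad <- colnames(m)[which(tot <= 0)]
    stop("zero-depth sample(s): ", paste(bad, collapse = ", "))
  }
  rel <- sweep(m, 2, tot, "/")
  if (inherits(table, "abundance_table")) attr(rel, "table") <- table
  rel
}

#' Apply the per-treatment OTU retention filters
#'
#' Restricted to the given group's samples, an OTU is retained iff
#' (a) its count is positive in every sample of the group (presence in all
#' replicates), and (b) its summed per-sample relative abundance across the
#' group's samples exceeds `min_sum_relabund` (default 1e-4, i.e. 0.01%).
#' Relative abundances are computed on the group's samples over all OTUs
#' before subsetting.  `mode = "mean"` replaces the sum in (b) by the mean.
#'
#' @param table an `abundance_table`.
#' @param group group label to filter for.
#' @param min_sum_relabund strict lower threshold for rule (b).
#' @param mode `"sum"` (default) or `"mean"` aggregation for rule (b).
#' @return an `abundance_table` restricted to the group's samples and the
#'   retained OTUs (possibly zero rows, with a warning).
#' @export
filter_otus <- function(table, group, min_sum_relabund = 1e-4,
                        mode = c("sum", "mean")) {
  stopifnot(inherits(table, "abundance_table"))
  mode <- match.arg(mode)
  samp <- names(table$group)[table$group == group]
  if (length(samp) == 0L) stop("no samples in group '", group, "'")
  if (length(samp) < 2L) stop("group '", group, "' has fewer than 2 samples")
  sub <- subset_table(table, samples = samp)
  rel <- to_relative_abundance(sub)
  present_all <- rowSums(sub$counts > 0) == length(samp)
  agg <- if (mode == "sum") rowSums(rel) else rowMeans(rel)
  keep <- present_all & (agg > min_sum_relabund)
  if (!any(keep)) {
    warning("filter removed all OTUs for group '", group, "'")
  }
  subset_table(sub, otus = rownames(sub$counts)[keep])
}
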