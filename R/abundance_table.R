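#' Construct an OTU-by-sample abundance table
#'
#' The central container of the pipeline: a non-negative integer count matrix
#' with one row per OTU and one column per sample, a taxonomy lineage string
#' per OTU, and a treatment/group label per sample.
#'
#' @param counts numeric matrix (OTUs x samples), non-negative and finite.
#'   Row names are OTU ids, column names sample ids; both must be unique.
#' @param taxonomy character vector of lineage strings, one per OTU.  Ranks
#'   separated by ";"; "g__"-style prefixes are accepted but not required.
#'   Missing annotation should be spelled "unclassified".
#' @param group character (or factor) vector of per-sample treatment labels.
#' @return an object of class `abundance_table` with elements `counts`,
#'   `taxonomy`, `group`.
#' @export
abundance_table <- function(counts, taxonomy, group) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0L && is.null(rownames(counts))) ||
      (ncol(counts) > 0L && is.null(colnames(counts))))
    stop("counts must have OTU row names and sample column names")
  if (is.null(rownames(counts))) dimnames(counts) <-
    list(character(0), colnames(counts))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts) || any(!is.finite(counts)))
    stop("counts must be finite numeric")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at OTU '%s', sample '%s'",
                 rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
  }
  if (length(taxonomy) != nrow(counts))
    stop("taxonomy must have one entry per OTU")
  taxonomy <- as.character(taxonomy)
  taxonomy[is.na(taxonomy) | !nzchar(trimws(taxonomy))] <- "unclassified"
  group <- as.character(group)
  if (length(group) != ncol(counts))
    stop("group must have one label per sample")
  structure(list(counts = counts,
                 taxonomy = stats::setNames(taxonomy, rownames(counts)),
                 group = stats::setNames(group, colnames(counts))),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d OTUs x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$group)),
                            as.integer(table(x$group))), collapse = ", ")))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Extract the genus from a taxonomy lineage string
#'
#' The genus is taken as the last non-empty rank of the ";"-separated
#' lineage, with any "g__"-style rank prefix stripped.  An empty or
#' unparseable lineage yields "unclassified".
#'
#' @param lineage character vector of lineage strings.
#' @return character vector of genus names.
#' @export
extract_genus <- function(lineage) {
  vapply(as.character(lineage), function(s) {
    parts <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
    parts <- sub("^[a-zA-Z]__", "", parts)
    parts <- parts[nzchar(parts)]
    if (length(parts) == 0L) "unclassified" else parts[length(parts)]
  }, character(1), USE.NAMES = FALSE)
}

#' Subset an abundance table by OTUs and/or samples
#'
#' @param table an `abundance_table`.
#' @param otus OTU ids or indices (default: all).
#' @param samples sample ids or indices (default: all).
#' @return a new `abundance_table`.
#' @export
subset_table <- function(table, otus = NULL, samples = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  if (is.null(otus)) otus <- rownames(table$counts)
  if (is.null(samples)) samples <- colnames(table$counts)
  abundance_table(table$counts[otus, samples, drop = FALSE],
                  table$taxonomy[otus],
                  table$group[samples])
}
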