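#' Read a tab-delimited OTU table with taxonomy annotation
#'
#' Expected layout: first column OTU id, one column per sample, and a final
#' column named `taxonomy` holding the lineage string.  An optional second
#' header line / sidecar is not supported; group labels are supplied via
#' `group` or default to a single group.
#'
#' @param path file path.
#' @param group optional named character vector of per-sample group labels
#'   (names = sample ids); unnamed vectors are matched by column order.
#'   Defaults to `"all"` for every sample.
#' @return an [abundance_table()].
#' @export
read_abundance_table <- function(path, group = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  hdr <- colnames(df)
  if (tolower(hdr[length(hdr)]) != "taxonomy")
    stop("last column must be named 'taxonomy', found '", hdr[length(hdr)], "'")
  sample_ids <- hdr[-c(1L, length(hdr))]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  otu_ids <- as.character(df[[1]])
  if (anyDuplicated(otu_ids))
    stop("duplicated OTU id: ",
         paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", "))
  cnt <- df[, sample_ids, drop = FALSE]
  for (j in seq_along(cnt)) {
    v <- suppressWarnings(as.numeric(cnt[[j]]))
    if (any(is.na(v) & !is.na(cnt[[j]])))
      stop(sprintf("non-numeric count in column '%s', row %d",
                   sample_ids[j], which(is.na(v) & !is.na(cnt[[j]]))[1]))
    if (any(v < 0, na.rm = TRUE))
      stop(sprintf("negative count at OTU '%s', sample '%s'",
                   otu_ids[which(v < 0)[1]], sample_ids[j]))
    cnt[[j]] <- v
  }
  m <- as.matrix(cnt)
  rownames(m) <- otu_ids
  if (is.null(group)) {
    group <- rep("all", length(sample_ids))
  } else if (!is.null(names(group))) {
    missing <- setdiff(sample_ids, names(group))
    if (length(missing))
      stop("group labels missing for samples: ", paste(missing, collapse = ", "))
    group <- unname(group[sample_ids])
  }
  abundance_table(m, df$taxonomy, group)
}

#' Write an abundance table in the tab-delimited layout read by
#' [read_abundance_table()]
#'
#' @param table an `abundance_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path) {
  stopifnot(inherits(table, "abundance_table"))
  df <- data.frame(`#OTU ID` = rownames(table$counts), table$counts,
                   taxonomy = unname(table$taxonomy),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("#OTU ID", colnames(table$counts), "taxonomy")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table of soil physicochemical variables
#'
#' Samples are rows (first column = sample id), variables are numeric
#' columns (pH, AP, AK, AN, NH4, NO3, TC, TN, C/N, moisture, EC,
#' temperature, ...).  Rows are reordered to the abundance table's sample
#' order; metadata samples absent from the table are dropped with a
#' warning.  Missing values are encoded "NA".
#'
#' @param path file path.
#' @param table the matching `abundance_table`.
#' @return a data.frame with rownames = the table's sample ids and one
#'   numeric column per variable.
#' @export
read_soil_metadata <- function(path, table) {
  if (!file.exists(path)) stop("no such file: ", path)
  stopifnot(inherits(table, "abundance_table"))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicated metadata sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  want <- colnames(table$counts)
  if (!any(want %in% ids)) stop("no metadata samples overlap the table")
  extra <- setdiff(ids, want)
  if (length(extra))
    warning("dropping metadata samples absent from table: ",
            paste(extra, collapse = ", "))
  absent <- setdiff(want, ids)
  if (length(absent))
    warning("table samples without metadata (filled NA): ",
            paste(absent, collapse = ", "))
  vars <- df[, -1, drop = FALSE]
  vars[] <- lapply(vars, function(v) suppressWarnings(as.numeric(v)))
  rownames(vars) <- ids
  out <- vars[match(want, ids), , drop = FALSE]
  rownames(out) <- want
  out
}

#' Write soil metadata in the layout read by [read_soil_metadata()]
#' @param metadata data.frame, rownames = sample ids.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_soil_metadata <- function(metadata, path) {
  df <- data.frame(sample = rownames(metadata), metadata,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a co-occurrence network for external viewers
#'
#' GraphML carries node attributes `name` (OTU/variable id), `genus`,
#' `node_class` ("taxon" or "metadata") and `mean_relabund`, and edge
#' attributes `sign`, `score` (observed Spearman) and `q` (BH-adjusted
#' p-value), so the file drops straight into Cytoscape.  The edge-list TSV
#' mirrors the edge attributes.
#'
#' @param network a `cooc_network` (see [build_network()]).
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path, format = c("graphml", "edgelist")) {
  stopifnot(inherits(network, "cooc_network"))
  format <- match.arg(format)
  if (format == "graphml") {
    g <- network_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    e <- network$edges
    utils::write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [write_network()] (GraphML)
#'
#' @param path GraphML file.
#' @return a `cooc_network` with the node and edge attributes restored.
#' @export
read_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- data.frame(
    id = igraph::V(g)$name,
    genus = if ("genus" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$genus else NA_character_,
    node_class = if ("node_class" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$node_class else "taxon",
    mean_relabund = if ("mean_relabund" %in% igraph::vertex_attr_names(g))
      igraph::V(g)$mean_relabund else NA_real_,
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  edges <- data.frame(
    from = el[, 1], to = el[, 2],
    sign = if (igraph::ecount(g) && "sign" %in% igraph::edge_attr_names(g))
      igraph::E(g)$sign else character(0),
    score = if (igraph::ecount(g) && "score" %in% igraph::edge_attr_names(g))
      igraph::E(g)$score else numeric(0),
    q = if (igraph::ecount(g) && "q" %in% igraph::edge_attr_names(g))
      igraph::E(g)$q else numeric(0),
    stringsAsFactors = FALSE)
  new_cooc_network(treatment = if ("treatment" %in% igraph::graph_attr_names(g))
    igraph::graph_attr(g, "treatment") else NA_character_,
    nodes = nodes, edges = edges)
}

#' Write per-network topology and keystone reports
#'
#' One tab-delimited report row per network with the seven standard topology
#' columns (nodes, edges, clustering coefficient, network diameter, shortest
#' paths, average number of neighbors, graph density), and a keystone table
#' with per-node centralities.
#'
#' @param topology_reports named list of `topology_report` objects (names =
#'   treatment labels).
#' @param keystones named list of keystone data.frames (as returned by
#'   [keystone_taxa()]); may be empty.
#' @param path output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_reports <- function(topology_reports, keystones = list(), path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  topo_file <- file.path(path, "topology_report.tsv")
  rows <- lapply(names(topology_reports), function(nm) {
    r <- topology_reports[[nm]]
    data.frame(treatment = nm, nodes = r$nodes, edges = r$edges,
               clustering_coefficient = r$clustering_coefficient,
               network_diameter = r$network_diameter,
               shortest_paths = r$shortest_paths,
               avg_neighbors = r$avg_neighbors,
               graph_density = r$graph_density,
               stringsAsFactors = FALSE)
  })
  topo <- if (length(rows)) do.call(rbind, rows) else
    data.frame(treatment = character(0), nodes = integer(0),
               edges = integer(0), clustering_coefficient = numeric(0),
               network_diameter = numeric(0), shortest_paths = numeric(0),
               avg_neighbors = numeric(0), graph_density = numeric(0))
  utils::write.table(topo, topo_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  key_file <- file.path(path, "keystone_taxa.tsv")
  krows <- lapply(names(keystones), function(nm) {
    k <- keystones[[nm]]
    if (is.null(k) || nrow(k) == 0L) return(NULL)
    cbind(data.frame(treatment = nm, stringsAsFactors = FALSE), k)
  })
  krows <- Filter(Negate(is.null), krows)
  kd <- if (length(krows)) do.call(rbind, krows) else
    data.frame(treatment = character(0), id = character(0),
               degree = integer(0), closeness = numeric(0),
               betweenness = numeric(0))
  utils::write.table(kd, key_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(topo_file, key_file))
}

#' Write a ground-truth planted edge list
#' @param truth a `ground_truth` (see [generate_dataset()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.table(truth$planted_edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
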