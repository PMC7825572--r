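# Brute-force graph oracle, independent of igraph: Floyd-Warshall distances,
# explicit enumeration of all shortest paths for betweenness, and direct
# neighborhood counting for local clustering.  Only meant for graphs <= ~8
# nodes.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# all shortest paths between s and t as list of vertex sequences
oracle_shortest_paths <- function(adj, D, s, t) {
  if (!is.finite(D[s, t]) || s == t) return(list())
  grow <- function(path) {
    v <- path[length(path)]
    if (v == t) return(list(path))
    nxt <- which(adj[v, ] == 1 & D[, t] == D[v, t] - 1)
    unlist(lapply(nxt, function(w) grow(c(path, w))), recursive = FALSE)
  }
  grow(s)
}

oracle_graph_stats <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  E <- sum(adj) / 2
  D <- oracle_distances(adj)
  finite_off <- is.finite(D) & row(D) != col(D)
  # local clustering
  loc <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] == 1)
    if (length(nb) < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    2 * links / (length(nb) * (length(nb) - 1))
  }, numeric(1))
  # betweenness with equal split among shortest paths
  btw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    paths <- oracle_shortest_paths(adj, D, s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      inner <- setdiff(p, c(s, t))
      btw[inner] <- btw[inner] + 1 / length(paths)
    }
  }
  # component sizes
  comp <- rep(NA_integer_, n); cid <- 0
  for (v in seq_len(n)) if (is.na(comp[v])) {
    cid <- cid + 1
    comp[is.finite(D[v, ])] <- cid
  }
  csize <- as.integer(table(comp))[comp]
  btw_norm <- ifelse(csize > 2, btw * 2 / ((csize - 1) * (csize - 2)), 0)
  reach <- rowSums(finite_off)
  dsum <- vapply(seq_len(n), function(v) sum(D[v, ][finite_off[v, ]]),
                 numeric(1))
  clo <- ifelse(dsum > 0, reach / dsum, 0)
  list(nodes = n, edges = E,
       clustering = if (any(deg >= 2)) mean(loc[deg >= 2]) else 0,
       diameter = if (any(finite_off)) max(D[finite_off]) else 0,
       shortest_paths = sum(finite_off),
       degree = deg, closeness = clo, betweenness = btw_norm)
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  up <- upper.tri(adj)
  adj[up] <- rbinom(sum(up), 1, p)
  adj + t(adj)
}

adj_to_igraph <- function(adj) {
  dimnames(adj) <- list(paste0("v", seq_len(nrow(adj))),
                        paste0("v", seq_len(nrow(adj))))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# convenience builders -------------------------------------------------------

make_table <- function(counts, taxonomy = NULL, group = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("OTU", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("S", seq_len(ncol(counts)))
  if (is.null(taxonomy))
    taxonomy <- paste0("k__Bacteria;g__Genus", seq_len(nrow(counts)))
  if (is.null(group)) group <- rep("all", ncol(counts))
  abundance_table(counts, taxonomy, group)
}

# a single-group synthetic table of independent taxa
independent_table <- function(n_taxa, n_samples, depth = 10000, seed = 1) {
  spec <- synthetic_spec(n_taxa = n_taxa, n_groups = 1,
                         n_replicates = n_samples, depth = depth,
                         group_labels = "CK", seed = seed)
  generate_dataset(spec)$table
}
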