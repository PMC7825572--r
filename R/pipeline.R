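#' Assemble a run configuration
#'
#' Collects paths, the groups to analyze, network-inference settings,
#' keystone criteria and the root seed for a full per-treatment run.
#' `config_file` accepts a flat `key: value` / `key=value` text file whose
#' keys override the defaults (recognized keys: threshold, n_permutations,
#' n_bootstraps, ci, alpha, renormalize, exact_enumeration_max_n, seed,
#' min_nodes, keystone_preset).
#'
#' @param table_path path to the OTU table (see [read_abundance_table()]).
#' @param metadata_path optional soil metadata path.
#' @param tree_path optional newick tree path.
#' @param out_dir output directory.
#' @param groups group labels to analyze (NULL = all in the table).
#' @param group per-sample group labels passed to the reader (named
#'   character vector), or NULL.
#' @param cooc a [cooc_config()].
#' @param keystone a [keystone_criteria()], preset name, or NULL to skip.
#' @param min_nodes size gate threshold (default 10).
#' @param seed root seed (overrides `cooc$seed`).
#' @param config_file optional flat text config file.
#' @return a `run_config` list.
#' @export
run_config <- function(table_path, metadata_path = NULL, tree_path = NULL,
                       out_dir = ".", groups = NULL, group = NULL,
                       cooc = cooc_config(), keystone = "nirS",
                       min_nodes = 10L, seed = 1L, config_file = NULL) {
  if (!is.null(config_file)) {
    kv <- read_flat_config(config_file)
    num <- function(k, d) if (k %in% names(kv)) as.numeric(kv[[k]]) else d
    cooc <- cooc_config(
      threshold = num("threshold", cooc$threshold),
      n_permutations = num("n_permutations", cooc$n_permutations),
      n_bootstraps = num("n_bootstraps", cooc$n_bootstraps),
      ci = num("ci", cooc$ci), alpha = num("alpha", cooc$alpha),
      renormalize = if ("renormalize" %in% names(kv))
        tolower(kv$renormalize) %in% c("true", "yes", "1") else cooc$renormalize,
      exact_enumeration_max_n = num("exact_enumeration_max_n",
                                    cooc$exact_enumeration_max_n),
      seed = num("seed", cooc$seed))
    if ("min_nodes" %in% names(kv)) min_nodes <- as.integer(kv$min_nodes)
    if ("keystone_preset" %in% names(kv)) keystone <- kv$keystone_preset
    if ("seed" %in% names(kv)) seed <- as.integer(kv$seed)
  }
  stopifnot(file.exists(table_path))
  if (!is.null(metadata_path)) stopifnot(file.exists(metadata_path))
  if (!is.null(tree_path)) stopifnot(file.exists(tree_path))
  structure(list(table_path = table_path, metadata_path = metadata_path,
                 tree_path = tree_path, out_dir = out_dir, groups = groups,
                 group = group, cooc = cooc, keystone = keystone,
                 min_nodes = as.integer(min_nodes), seed = as.integer(seed)),
            class = "run_config")
}

#' Parse a flat `key: value` / `key=value` configuration file
#' @param path text file; `#` starts a comment; blank lines ignored.
#' @return named list of character values.
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^:=]+)[:=](.*)$", ln))[[1]]
    if (length(m) != 3) stop("unparseable config line: ", ln)
    kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv
}

#' Run the per-treatment network analysis end to end
#'
#' For each group: OTU retention filter -> network inference (with metadata
#' nodes when metadata is given) -> size gate -> topology report ->
#' keystone taxa -> GraphML/edge-list/report outputs.  A JSON run manifest
#' records the configuration, seed, per-group audit counts (retained OTUs,
#' candidate edges, unstable discards, final edges) and any size-gate
#' exclusions.  A failing group is logged and skipped; other groups
#' proceed.
#'
#' @param config a [run_config()].
#' @return (invisibly) named list per group with elements `network`,
#'   `topology`, `keystones`, `gate`, plus `manifest`.
#' @export
run_network_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_abundance_table(config$table_path, group = config$group)
  md <- if (!is.null(config$metadata_path))
    read_soil_metadata(config$metadata_path, tab) else NULL
  groups <- if (is.null(config$groups)) unique(unname(tab$group))
            else config$groups
  results <- list()
  manifest <- list(seed = config$seed,
                   config = unclass(config$cooc),
                   groups = list(),
                   package_version = as.character(utils::packageVersion("ncoocnet")))
  topo_reports <- list(); keystones <- list()
  for (g in groups) {
    res <- tryCatch({
      cfg <- config$cooc
      cfg$seed <- derive_seed(config$seed, paste0("network/", g))
      filt <- filter_otus(tab, g)
      net <- if (is.null(md)) build_network(filt, g, cfg)
             else build_metadata_network(filt, md, g, cfg)
      gate <- size_gate(net, config$min_nodes)
      topo <- NULL; keys <- NULL
      if (gate) {
        topo <- topology_report(net)
        if (!is.null(config$keystone))
          keys <- keystone_taxa(net, config$keystone)
      }
      write_network(net, file.path(config$out_dir,
                                   paste0("network_", g, ".graphml")),
                    "graphml")
      write_network(net, file.path(config$out_dir,
                                   paste0("network_", g, ".edges.tsv")),
                    "edgelist")
      list(network = net, topology = topo, keystones = keys, gate = gate,
           audit = list(retained_otus = nrow(filt$counts),
                        candidates = if (is.null(net$edge_tests)) 0L
                                     else nrow(net$edge_tests),
                        unstable_discarded = if (is.null(net$edge_tests)) 0L
                                     else sum(!net$edge_tests$stable),
                        edges = nrow(net$edges)))
    }, error = function(e) {
      warning("group '", g, "' failed: ", conditionMessage(e))
      list(network = NULL, topology = NULL, keystones = NULL, gate = NA,
           audit = list(error = conditionMessage(e)))
    })
    results[[g]] <- res
    manifest$groups[[g]] <- c(res$audit,
      list(size_gate = if (is.logical(res$gate) && length(res$gate))
        attr(res$gate, "reason") else "error"))
    if (!is.null(res$topology)) topo_reports[[g]] <- res$topology
    if (!is.null(res$keystones)) keystones[[g]] <- res$keystones
  }
  write_reports(topo_reports, keystones, config$out_dir)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(results, list(manifest = manifest)))
}

#' Run the community-statistics analysis
#'
#' Alpha diversity per sample, Bray-Curtis distances, PCoA, PERMANOVA
#' across groups, Mantel tests of the community distance against each soil
#' variable's Euclidean distance, and the Pearson diversity-environment
#' matrix.  All results are written as tab-delimited reports; stages that
#' need metadata are skipped with a warning when none is given.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `alpha`, `bray`, `pcoa`, `permanova`,
#'   `mantel`, `env_cor`.
#' @export
run_community_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tab <- read_abundance_table(config$table_path, group = config$group)
  md <- if (!is.null(config$metadata_path))
    read_soil_metadata(config$metadata_path, tab) else NULL
  tree <- if (!is.null(config$tree_path)) ape::read.tree(config$tree_path)
          else NULL
  alpha <- alpha_diversity(tab, tree = tree)
  utils::write.table(data.frame(sample = rownames(alpha), alpha),
                     file.path(config$out_dir, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bc <- bray_curtis(tab)
  utils::write.table(bc, file.path(config$out_dir, "bray_curtis.tsv"),
                     sep = "\t", quote = FALSE)
  ord <- pcoa(bc)
  utils::write.table(data.frame(sample = rownames(ord$coordinates),
                                ord$coordinates),
                     file.path(config$out_dir, "pcoa_coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  perm <- NULL
  tabg <- table(tab$group)
  if (length(tabg) >= 2 && all(tabg >= 2)) {
    perm <- permanova(bc, tab$group,
                      seed = derive_seed(config$seed, "permanova"))
    utils::write.table(data.frame(pseudo_F = perm$pseudo_F, R2 = perm$R2,
                                  p = perm$p),
                       file.path(config$out_dir, "permanova.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    warning("PERMANOVA skipped: need >= 2 groups with >= 2 samples each")
  }
  mant <- NULL; envc <- NULL
  if (is.null(md)) {
    warning("no metadata: Mantel and diversity-environment stages skipped")
  } else {
    rows <- lapply(colnames(md), function(v) {
      x <- md[[v]]
      if (all(is.na(x)) || stats::sd(x, na.rm = TRUE) == 0) return(NULL)
      dv <- as.matrix(stats::dist(x))
      dimnames(dv) <- list(rownames(md), rownames(md))
      mt <- mantel_test(bc, dv,
                        seed = derive_seed(config$seed, paste0("mantel/", v)))
      data.frame(variable = v, r = mt$r, p = mt$p)
    })
    rows <- Filter(Negate(is.null), rows)
    mant <- if (length(rows)) do.call(rbind, rows) else
      data.frame(variable = character(0), r = numeric(0), p = numeric(0))
    utils::write.table(mant, file.path(config$out_dir, "mantel.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    envc <- diversity_env_correlations(alpha, md)
    utils::write.table(data.frame(index = rownames(envc$r), envc$r),
                       file.path(config$out_dir, "diversity_env_r.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(index = rownames(envc$p), envc$p),
                       file.path(config$out_dir, "diversity_env_p.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(alpha = alpha, bray = bc, pcoa = ord, permanova = perm,
                 mantel = mant, env_cor = envc))
}
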