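# Readers and writers for the tab-separated table formats, Newick trees and
# network exchange formats. All text is UTF-8, tab-delimited, "." decimal.

read_tsv_checked <- function(path) {
  if (!file.exists(path)) abort_input("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
}

#' Read an OTU count table from a TSV file
#'
#' The first column holds identifiers for one axis and the header row for the
#' other. The canonical on-disk orientation is OTUs x samples; a transposed
#' file is accepted with `orientation = "samples_by_otus"` and normalized on
#' read, so both orientations yield the identical `otu_table`.
#'
#' @param path path to a tab-separated file
#' @param orientation `"otus_by_samples"` (default; rows are OTUs) or
#'   `"samples_by_otus"`
#' @return a validated [otu_table]
#' @export
read_otu_table <- function(path,
                           orientation = c("otus_by_samples",
                                           "samples_by_otus")) {
  orientation <- match.arg(orientation)
  df <- read_tsv_checked(path)
  if (ncol(df) < 2) abort_input("OTU table needs an id column plus >=1 data column: ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    cellrow <- if (length(bad)) ids[bad[1]] else ids[1]
    abort_input(sprintf("non-numeric count in row '%s' of %s", cellrow, path))
  }
  rownames(m) <- ids
  if (orientation == "samples_by_otus") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to TSV (OTUs x samples)
#' @param table an [otu_table]
#' @param path output path
#' @export
write_otu_table <- function(table, path) {
  df <- data.frame(otu_id = table$otu_ids, table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}

# ---- taxonomy ---------------------------------------------------------------

#' Construct a taxonomy table
#'
#' Seven-rank lineages per OTU (domain..species); empty string means
#' unassigned. An assigned rank below an unassigned one is rejected as a
#' malformed lineage.
#'
#' @param df data.frame with columns `otu_id` and the seven ranks in
#'   [TAX_RANKS]
#' @return object of class `taxonomy_table`
#' @export
taxonomy_table <- function(df) {
  need <- c("otu_id", TAX_RANKS)
  if (!all(need %in% names(df)))
    abort_input("taxonomy needs columns: ", paste(need, collapse = ", "))
  df <- df[, need]
  for (r in TAX_RANKS) {
    df[[r]] <- trimws(as.character(df[[r]]))
    df[[r]][is.na(df[[r]])] <- ""
    # strip greengenes-style "k__" / "g__" prefixes
    df[[r]] <- sub("^[a-zA-Z]__", "", df[[r]])
  }
  if (anyDuplicated(df$otu_id))
    abort_input("duplicate otu_id in taxonomy")
  lin <- as.matrix(df[, TAX_RANKS])
  assigned <- lin != ""
  # once a rank is unassigned, all lower ranks must be unassigned too
  for (i in seq_len(nrow(lin))) {
    a <- assigned[i, ]
    if (any(a) && any(diff(a) > 0))
      abort_input("OTU '", df$otu_id[i],
                  "': assigned rank below an unassigned rank")
  }
  rownames(df) <- df$otu_id
  class(df) <- c("taxonomy_table", "data.frame")
  df
}

#' Read a taxonomy table from TSV
#'
#' Columns: `otu_id` then the seven ranks. Greengenes-style `k__` prefixes are
#' stripped on read.
#'
#' @param path tab-separated file
#' @return a `taxonomy_table`
#' @export
read_taxonomy <- function(path) taxonomy_table(read_tsv_checked(path))

#' @export
write_taxonomy <- function(tax, path) write_tsv(as.data.frame(tax), path)

# ---- trait database ---------------------------------------------------------

#' Construct an rrnDB-style trait database
#'
#' Records of (rank, lineage, rrn copy number), where `lineage` is the
#' semicolon-separated path from domain down to the named taxon. A
#' parent-to-children index is derived from the lineages. Copy numbers must be
#' >= 1; duplicate taxon names within a rank (homonyms) are rejected.
#'
#' @param df data.frame with columns `rank`, `lineage`, `copies`
#' @return object of class `trait_db`
#' @export
trait_db <- function(df) {
  need <- c("rank", "lineage", "copies")
  if (!all(need %in% names(df)))
    abort_input("trait db needs columns: ", paste(need, collapse = ", "))
  df$rank <- as.character(df$rank)
  bad_rank <- setdiff(unique(df$rank), TAX_RANKS)
  if (length(bad_rank))
    abort_input("unknown rank(s) in trait db: ", paste(bad_rank, collapse = ", "))
  df$copies <- suppressWarnings(as.numeric(df$copies))
  if (anyNA(df$copies) || any(df$copies < 1))
    abort_input("rrn copy numbers must be numeric and >= 1")
  parts <- strsplit(as.character(df$lineage), ";", fixed = TRUE)
  parts <- lapply(parts, trimws)
  depth <- match(df$rank, TAX_RANKS)
  if (any(lengths(parts) != depth))
    abort_input("lineage depth must equal the record's rank (domain;...;name)")
  df$name <- vapply(parts, function(p) p[length(p)], character(1))
  df$parent <- vapply(parts, function(p)
    if (length(p) > 1) p[length(p) - 1] else NA_character_, character(1))
  key <- paste(df$rank, df$name)
  if (anyDuplicated(key))
    abort_input("homonym taxon name(s) within a rank: ",
                paste(unique(key[duplicated(key)]), collapse = ", "))
  df <- df[, c("rank", "lineage", "name", "parent", "copies")]
  # Node index: every taxon appearing anywhere in a record's lineage path,
  # so that a genus known only through its species still resolves at genus
  # rank. Homonyms among derived nodes (same rank+name, different parents)
  # are ambiguous and rejected.
  nodes <- unique(do.call(rbind, lapply(parts, function(p) {
    data.frame(rank_idx = seq_along(p), name = p,
               parent = c(NA_character_, p[-length(p)]),
               stringsAsFactors = FALSE)
  })))
  nk <- paste(nodes$rank_idx, nodes$name)
  if (anyDuplicated(nk))
    abort_input("ambiguous lineages: taxon name(s) appear under multiple ",
                "parents at the same rank: ",
                paste(unique(nk[duplicated(nk)]), collapse = ", "))
  attr(df, "nodes") <- nodes
  class(df) <- c("trait_db", "data.frame")
  df
}

#' Read a trait database from TSV
#' @param path tab-separated file with columns `rank`, `lineage`, `copies`
#' @return a `trait_db`
#' @export
read_trait_db <- function(path) trait_db(read_tsv_checked(path))

#' @export
write_trait_db <- function(db, path)
  write_tsv(as.data.frame(db)[, c("rank", "lineage", "copies")], path)

#' Child taxa of a taxon in a trait database
#'
#' Children are derived from record lineage paths, so a genus represented only
#' through its species records still lists those species as children.
#'
#' @param db a `trait_db`
#' @param rank rank of the parent taxon
#' @param name parent taxon name
#' @return character vector of child taxon names at the next-lower rank
#' @export
trait_db_children <- function(db, rank, name) {
  ri <- match(rank, TAX_RANKS)
  if (is.na(ri)) abort_input("unknown rank: ", rank)
  if (ri == length(TAX_RANKS)) return(character(0))
  nodes <- attr(db, "nodes")
  nodes$name[nodes$rank_idx == ri + 1L & !is.na(nodes$parent) &
               nodes$parent == name]
}

# TRUE when (rank, name) names a taxon known to the db, either as a record or
# as an ancestor on some record's lineage path
trait_db_has <- function(db, rank_idx, name) {
  nodes <- attr(db, "nodes")
  any(nodes$rank_idx == rank_idx & nodes$name == name)
}

# ---- environment table ------------------------------------------------------

#' Construct a sample metadata table of numeric covariates
#'
#' @param df data.frame with a `sample_id` column and numeric covariates
#'   (e.g., `NH4_N_mgL`, `TP_mgL`). Missing values are allowed and flagged.
#' @return object of class `env_table`
#' @export
env_table <- function(df) {
  if (!"sample_id" %in% names(df))
    abort_input("environment table needs a `sample_id` column")
  if (anyDuplicated(df$sample_id)) abort_input("duplicate sample_id")
  for (nm in setdiff(names(df), "sample_id")) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    if (all(is.na(v)) && !all(is.na(df[[nm]])))
      abort_input("covariate '", nm, "' is not numeric")
    df[[nm]] <- v
  }
  rownames(df) <- df$sample_id
  class(df) <- c("env_table", "data.frame")
  df
}

#' Read sample metadata (numeric covariates) from TSV
#' @param path tab-separated file, first column `sample_id`
#' @return an `env_table`
#' @export
read_env_table <- function(path) env_table(read_tsv_checked(path))

#' @export
write_env_table <- function(env, path) write_tsv(as.data.frame(env), path)

# ---- phylogenetic tree ------------------------------------------------------

#' Read and validate a rooted phylogeny whose tips are OTU ids
#'
#' Thin wrapper over [ape::read.tree] enforcing unique tip labels and
#' non-negative branch lengths.
#'
#' @param path Newick file
#' @return an `ape::phylo` object
#' @export
read_phylo_tree <- function(path) {
  tr <- ape::read.tree(path)
  validate_phylo(tr)
}

validate_phylo <- function(tr) {
  if (is.null(tr)) abort_input("could not parse tree")
  if (anyDuplicated(tr$tip.label)) abort_input("duplicate tree tip labels")
  if (is.null(tr$edge.length)) abort_input("tree has no branch lengths")
  if (any(tr$edge.length < 0)) abort_input("negative branch length in tree")
  tr
}

# ---- network exchange -------------------------------------------------------

#' Write an association network to disk
#'
#' `edge_list_tsv` writes one row per edge with columns
#' (otu_a, otu_b, sign, correlation, module_id); `graphml` writes the full
#' graph with node attributes (biosphere label, degree, module) via igraph and
#' round-trips them.
#'
#' @param net an `assoc_network` (see [build_network])
#' @param path output file
#' @param format `"edge_list_tsv"` or `"graphml"`
#' @export
write_network <- function(net, path, format = c("edge_list_tsv", "graphml")) {
  if (!inherits(net, "assoc_network")) abort_input("`net` must be an assoc_network")
  format <- match.arg(format)
  if (format == "edge_list_tsv") {
    ed <- net$edges
    mod <- net$nodes$module[match(ed$otu_a, net$nodes$otu_id)]
    out <- data.frame(otu_a = ed$otu_a, otu_b = ed$otu_b, sign = ed$sign,
                      correlation = ed$rho,
                      module_id = if (nrow(ed)) mod else integer(0),
                      stringsAsFactors = FALSE)
    write_tsv(out, path)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(NULL)
}

#' Read a network written by [write_network]
#' @param path file written by `write_network`
#' @param format `"edge_list_tsv"` or `"graphml"`
#' @return an `assoc_network`
#' @export
read_network <- function(path, format = c("edge_list_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_list_tsv") {
    df <- read_tsv_checked(path)
    ids <- unique(c(df$otu_a, df$otu_b))
    edges <- data.frame(otu_a = as.character(df$otu_a),
                        otu_b = as.character(df$otu_b),
                        sign = as.character(df$sign),
                        rho = as.numeric(df$correlation),
                        stringsAsFactors = FALSE)
    nodes <- data.frame(otu_id = ids, label = rep(NA_character_, length(ids)),
                        degree = tabulate(match(c(edges$otu_a, edges$otu_b), ids),
                                          nbins = length(ids)),
                        module = df$module_id[match(ids, df$otu_a)],
                        stringsAsFactors = FALSE)
    new_assoc_network(nodes, edges, s_t = NA_real_)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(otu_id = igraph::V(g)$name,
                        label = igraph::V(g)$label %||% NA_character_,
                        degree = igraph::degree(g),
                        module = igraph::V(g)$module %||% NA_integer_,
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(otu_a = el[, 1], otu_b = el[, 2],
                        sign = igraph::E(g)$sign %||% NA_character_,
                        rho = igraph::E(g)$rho %||% NA_real_,
                        stringsAsFactors = FALSE)
    new_assoc_network(nodes, edges, s_t = (igraph::graph_attr(g, "s_t") %||% NA_real_))
  }
}
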