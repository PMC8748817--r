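# Signed co-occurrence network construction, modules, null models, and
# biosphere-level summaries.

#' Discard low-occurrence OTUs before correlation analysis
#'
#' OTUs detected in less than `min_fraction` of samples are removed ("less
#' than" is strict: an OTU at exactly the cutoff is retained) and relative
#' abundances are re-closed per sample.
#'
#' @param table an [otu_table]
#' @param min_fraction minimum occurrence fraction (default 0.3)
#' @return a filtered [otu_table]
#' @export
occurrence_filter <- function(table, min_fraction = 0.3) {
  stopifnot(inherits(table, "otu_table"))
  stopifnot_scalar_fraction(min_fraction, "min_fraction", 0, 1, FALSE, FALSE)
  keep <- table$otu_ids[table$occurrence >= min_fraction]
  if (length(keep) == 0)
    abort_input("occurrence filter at ", min_fraction, " removes every OTU")
  ct_log("occurrence_filter: ", length(table$otu_ids) - length(keep),
         " of ", length(table$otu_ids), " OTUs removed")
  subset_otus(table, keep)
}

#' Pairwise Spearman correlation matrix over OTUs
#'
#' Rank correlation (average ranks for ties) of relative abundances across
#' samples. Pairs involving a constant OTU vector have undefined rho and are
#' set to 0 with a warning, keeping the matrix aligned with the OTU set.
#'
#' @param table an [otu_table] with >= 4 samples
#' @return symmetric matrix of rho with unit diagonal, OTU ids as dimnames
#' @export
spearman_matrix <- function(table) {
  stopifnot(inherits(table, "otu_table"))
  if (n_samples(table) < 4)
    abort_input("need >= 4 samples for rank correlation")
  x <- t(table$rel_abund)
  const <- apply(x, 2, function(v) max(v) == min(v))
  rho <- suppressWarnings(stats::cor(x, method = "spearman"))
  if (any(const)) {
    warning(sum(const), " constant OTU vector(s): undefined rho set to 0",
            call. = FALSE)
    rho[const, ] <- 0
    rho[, const] <- 0
  }
  rho[is.na(rho)] <- 0
  diag(rho) <- 1
  rho
}

new_assoc_network <- function(nodes, edges, s_t) {
  structure(list(nodes = nodes, edges = edges, s_t = s_t),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("assoc_network: %d nodes, %d edges (%d negative), s_t = %s\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$sign == "-"),
              format(x$s_t)))
  invisible(x)
}

#' Build a signed association network from a thresholded correlation matrix
#'
#' An undirected edge joins every OTU pair with |rho| >= `s_t`; the edge sign
#' is the sign of rho. Isolated OTUs (no super-threshold partner) are dropped
#' from the network but counted in the `n_isolated` diagnostic.
#'
#' @param corr symmetric correlation matrix with OTU dimnames
#' @param s_t correlation threshold (from [rmt_threshold] or user override)
#' @param labels optional `biosphere_labels` supplying node labels
#' @return an `assoc_network`: `nodes` (otu_id, label, degree, module),
#'   `edges` (otu_a, otu_b, sign, rho), and the threshold `s_t`
#' @export
build_network <- function(corr, s_t, labels = NULL) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  ids <- rownames(corr)
  adj <- abs(corr) >= s_t
  diag(adj) <- FALSE
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- data.frame(otu_a = ids[idx[, 1]], otu_b = ids[idx[, 2]],
                      sign = ifelse(corr[idx] >= 0, "+", "-"),
                      rho = corr[idx], stringsAsFactors = FALSE)
  deg <- tabulate(match(c(edges$otu_a, edges$otu_b), ids), nbins = length(ids))
  keep <- deg > 0
  nodes <- data.frame(otu_id = ids[keep],
                      label = rep(NA_character_, sum(keep)),
                      degree = deg[keep],
                      module = rep(NA_integer_, sum(keep)),
                      stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    stopifnot(inherits(labels, "biosphere_labels"))
    nodes$label <- labels$label[match(nodes$otu_id, labels$otu_id)]
  }
  net <- new_assoc_network(nodes, edges, s_t)
  net$n_isolated <- sum(!keep)
  net
}

#' Convert an association network to an igraph graph
#'
#' Unsigned, undirected topology; sign and rho carried as edge attributes,
#' biosphere label / degree / module as node attributes.
#'
#' @param net an `assoc_network`
#' @return an `igraph` graph
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$otu_a, to = net$edges$otu_b,
                   sign = net$edges$sign, rho = net$edges$rho,
                   stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$otu_id,
                          label = ifelse(is.na(net$nodes$label), "",
                                         net$nodes$label),
                          module = ifelse(is.na(net$nodes$module), -1L,
                                          net$nodes$module),
                          stringsAsFactors = FALSE))
  if (!is.na(net$s_t)) g <- igraph::set_graph_attr(g, "s_t", net$s_t)
  g
}

#' Fast-greedy module detection
#'
#' Runs fast greedy modularity optimization on the unsigned topology and
#' writes the module id of every non-isolated node back into the network.
#'
#' @param net an `assoc_network` with >= 1 edge
#' @return the network with `nodes$module` filled and `modularity` attached
#' @export
greedy_modularity <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  if (nrow(net$edges) == 0) abort_input("empty network: no edges to cluster")
  g <- as_igraph(net)
  cm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  net$nodes$module <- as.integer(igraph::membership(cm)[net$nodes$otu_id])
  net$modularity <- igraph::modularity(cm)
  net
}

#' Topological indices of a network
#'
#' Node count, link count, average degree, average (local) clustering
#' coefficient with isolates counted as zero, average path length on the
#' largest connected component, and fast-greedy modularity — all on the
#' unsigned graph.
#'
#' @param net an `assoc_network`
#' @return named numeric vector of indices
#' @export
network_topology <- function(net) {
  g <- as_igraph(net)
  topology_from_igraph(g)
}

topology_from_igraph <- function(g) {
  n <- igraph::vcount(g)
  m <- igraph::ecount(g)
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  q <- if (m > 0)
    igraph::modularity(igraph::cluster_fast_greedy(igraph::simplify(g)))
  else NA_real_
  c(nodes = n,
    links = m,
    avg_degree = if (n > 0) 2 * m / n else NA_real_,
    avg_clustering = igraph::transitivity(g, type = "localaverage",
                                          isolates = "zero"),
    avg_path_length = igraph::mean_distance(giant, directed = FALSE),
    modularity = q)
}

#' Degree-preserving rewired null models
#'
#' Generates `n_nulls` randomizations of the unsigned topology by
#' double-edge swaps that keep the node set, link count and the exact degree
#' sequence, then summarizes each topological index over the nulls and the
#' Z-score of the observed value. Graphs that admit no valid swap (the
#' rewiring returns the original edge set every time) are flagged.
#'
#' @param net an `assoc_network` with >= 2 edges
#' @param n_nulls number of null networks (default 100)
#' @param seed integer RNG seed (required)
#' @param swaps_per_edge double-edge swaps attempted per link (default 10)
#' @return list with `observed` (named indices), `null_mean`, `null_sd`, `z`,
#'   `null_values` (matrix nulls x indices), and `degenerate` flag
#' @export
rewire_null <- function(net, n_nulls = 100, seed, swaps_per_edge = 10) {
  stopifnot(inherits(net, "assoc_network"))
  if (missing(seed)) abort_input("`seed` is required")
  if (nrow(net$edges) < 2) abort_input("need >= 2 edges to rewire")
  g <- as_igraph(net)
  observed <- topology_from_igraph(g)
  niter <- swaps_per_edge * igraph::ecount(g)
  set.seed(seed)
  changed <- FALSE
  vals <- matrix(NA_real_, nrow = n_nulls, ncol = length(observed),
                 dimnames = list(NULL, names(observed)))
  obs_el <- igraph::as_edgelist(g)
  obs_key <- sort(paste(pmin(obs_el[, 1], obs_el[, 2]),
                        pmax(obs_el[, 1], obs_el[, 2])))
  for (k in seq_len(n_nulls)) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    el <- igraph::as_edgelist(gr)
    key <- sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
    if (!identical(key, obs_key)) changed <- TRUE
    vals[k, ] <- topology_from_igraph(gr)
  }
  null_mean <- colMeans(vals)
  null_sd <- apply(vals, 2, stats::sd)
  z <- (observed - null_mean) / null_sd
  if (!changed)
    warning("graph admits no valid double-edge swap; nulls equal the original",
            call. = FALSE)
  list(observed = observed, null_mean = null_mean, null_sd = null_sd, z = z,
       null_values = vals, degenerate = !changed)
}

#' Link-sign summary by biosphere category
#'
#' Counts and proportions of positive and negative links within and between
#' the abundant (A), intermediate (I) and rare (R) biospheres — categories
#' AA, AI, AR, II, IR, RR — plus the overall totals.
#'
#' @param net an `assoc_network` whose nodes carry biosphere labels
#' @return data.frame with one row per category and an "overall" row:
#'   columns category, n_links, n_positive, n_negative, prop_positive,
#'   prop_negative
#' @export
link_sign_summary <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  lab <- net$nodes$label[match(c(net$edges$otu_a, net$edges$otu_b),
                               net$nodes$otu_id)]
  if (anyNA(lab) || any(lab == ""))
    abort_input("every node must carry a biosphere label")
  nm <- c(abundant = "A", intermediate = "I", rare = "R")
  half <- nrow(net$edges)
  la <- nm[lab[seq_len(half)]]
  lb <- nm[lab[half + seq_len(half)]]
  cat_ <- paste0(pmin(la, lb), pmax(la, lb))
  cats <- c("AA", "AI", "AR", "II", "IR", "RR")
  rows <- lapply(c(cats, "overall"), function(cg) {
    sel <- if (cg == "overall") rep(TRUE, half) else cat_ == cg
    np <- sum(net$edges$sign[sel] == "+")
    nn <- sum(net$edges$sign[sel] == "-")
    tot <- np + nn
    data.frame(category = cg, n_links = tot, n_positive = np, n_negative = nn,
               prop_positive = if (tot > 0) np / tot else NA_real_,
               prop_negative = if (tot > 0) nn / tot else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Node-degree distributions per biosphere label
#'
#' @param net a labeled `assoc_network`
#' @return list with `degrees` (named list of per-label degree vectors) and
#'   `summary` (data.frame of n, min, q25, median, q75, max per label)
#' @export
degree_by_category <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  lv <- c("abundant", "intermediate", "rare")
  degs <- lapply(lv, function(lb)
    net$nodes$degree[!is.na(net$nodes$label) & net$nodes$label == lb])
  names(degs) <- lv
  summ <- do.call(rbind, lapply(lv, function(lb) {
    d <- degs[[lb]]
    if (length(d) == 0)
      return(data.frame(label = lb, n = 0L, min = NA_real_, q25 = NA_real_,
                        median = NA_real_, q75 = NA_real_, max = NA_real_))
    q <- stats::quantile(d, c(0, .25, .5, .75, 1), names = FALSE)
    data.frame(label = lb, n = length(d), min = q[1], q25 = q[2],
               median = q[3], q75 = q[4], max = q[5])
  }))
  list(degrees = degs, summary = summ)
}
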