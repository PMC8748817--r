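# Phylogenetic diversity and community distance statistics, plus the
# trait-nutrient correlation machinery: weighted MPD, normalized weighted
# UniFrac, Euclidean nutrient distance, Pearson correlation, partial Mantel.

#' Abundance-weighted mean pairwise phylogenetic distance (MPD)
#'
#' Mean patristic distance over all unordered pairs of distinct OTUs detected
#' in the sample, each pair weighted proportionally to the product of the two
#' relative abundances (the usual abundance-weighted MPD convention).
#'
#' @param table an [otu_table]; detected OTUs must be tree tips
#' @param tree rooted `phylo` with branch lengths; tip labels are OTU ids
#' @param sample sample id
#' @return numeric scalar; NA with a warning when < 2 OTUs are detected
#' @export
weighted_mpd <- function(table, tree, sample) {
  stopifnot(inherits(table, "otu_table"), inherits(tree, "phylo"))
  if (!sample %in% table$sample_ids) abort_input("unknown sample: ", sample)
  p <- table$rel_abund[, sample]
  det <- names(p)[p > 0]
  missing <- setdiff(det, tree$tip.label)
  if (length(missing) > 0)
    abort_input("detected OTU(s) not in tree: ",
                paste(utils::head(missing, 3), collapse = ", "))
  if (length(det) < 2) {
    warning("fewer than 2 detected OTUs in sample ", sample,
            "; MPD undefined", call. = FALSE)
    return(NA_real_)
  }
  sub <- ape::keep.tip(tree, det)
  D <- stats::cophenetic(sub)[det, det]
  w <- p[det] %o% p[det]
  lt <- lower.tri(D)
  sum(w[lt] * D[lt]) / sum(w[lt])
}

# per-branch subtree relative-abundance sums; tree reordered postorder
branch_abundance <- function(tree, p) {
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  acc <- numeric(ntip + tr$Nnode)
  acc[seq_len(ntip)] <- p[tr$tip.label]
  for (k in seq_len(nrow(tr$edge)))
    acc[tr$edge[k, 1]] <- acc[tr$edge[k, 1]] + acc[tr$edge[k, 2]]
  list(weight = acc[tr$edge[, 2]], length = tr$edge.length)
}

#' Normalized weighted UniFrac dissimilarity between two samples
#'
#' \deqn{\sum_b l_b |A_b - B_b| \; / \; \sum_b l_b (A_b + B_b)}
#' where the sum runs over tree branches, \eqn{l_b} is the branch length and
#' \eqn{A_b, B_b} are the summed relative abundances of the taxa descending
#' from the branch in the two samples. Ranges over [0, 1]; 0 for identical
#' abundance vectors, 1 for phylogenetically disjoint communities.
#'
#' @param table an [otu_table]
#' @param tree rooted `phylo`; all detected OTUs must be tips
#' @param sample_a,sample_b sample ids
#' @return numeric scalar in [0, 1]
#' @export
weighted_unifrac <- function(table, tree, sample_a, sample_b) {
  stopifnot(inherits(table, "otu_table"), inherits(tree, "phylo"))
  for (sm in c(sample_a, sample_b))
    if (!sm %in% table$sample_ids) abort_input("unknown sample: ", sm)
  pa <- table$rel_abund[, sample_a]
  pb <- table$rel_abund[, sample_b]
  det <- names(pa)[pa > 0 | pb > 0]
  missing <- setdiff(det, tree$tip.label)
  if (length(missing) > 0)
    abort_input("detected OTU(s) not in tree: ",
                paste(utils::head(missing, 3), collapse = ", "))
  fill <- function(p) {
    v <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
    v[names(p)] <- p
    v
  }
  A <- branch_abundance(tree, fill(pa))
  B <- branch_abundance(tree, fill(pb))
  num <- sum(A$length * abs(A$weight - B$weight))
  den <- sum(A$length * (A$weight + B$weight))
  if (den == 0) abort_input("zero total branch abundance; degenerate input")
  num / den
}

new_distance_matrix <- function(m, sample_ids, metric) {
  dimnames(m) <- list(sample_ids, sample_ids)
  if (max(abs(m - t(m))) > 1e-12) abort_input("distance matrix not symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  structure(m, metric = metric, class = c("distance_matrix", "matrix"))
}

#' Pairwise distance matrices over samples
#'
#' `env_distance` is the Euclidean distance over (optionally scaled) nutrient
#' covariates; `unifrac_matrix` applies [weighted_unifrac] to every sample
#' pair; `trait_distance` is the absolute difference of a per-sample trait
#' value (e.g., the community-level rrn copy number).
#'
#' @param env an `env_table`
#' @param variables covariate names to use (default: all numeric columns)
#' @param scale standardize covariates to unit variance first (default TRUE)
#' @return a `distance_matrix` (symmetric, zero diagonal, metric tag attached)
#' @export
env_distance <- function(env, variables = NULL, scale = TRUE) {
  stopifnot(inherits(env, "env_table"))
  variables <- variables %||% setdiff(names(env), "sample_id")
  x <- as.matrix(as.data.frame(env)[, variables, drop = FALSE])
  if (anyNA(x)) {
    keep <- stats::complete.cases(x)
    ct_log("env_distance: dropping ", sum(!keep), " sample(s) with missing values")
    x <- x[keep, , drop = FALSE]
    env <- env[keep, ]
  }
  if (scale) x <- base::scale(x)
  new_distance_matrix(as.matrix(stats::dist(x)), env$sample_id, "euclidean_env")
}

#' @rdname env_distance
#' @param table an [otu_table]
#' @param tree rooted `phylo`
#' @export
unifrac_matrix <- function(table, tree) {
  ids <- table$sample_ids
  missing <- setdiff(table$otu_ids[rowSums(table$counts) > 0], tree$tip.label)
  if (length(missing) > 0)
    abort_input("detected OTU(s) not in tree: ",
                paste(utils::head(missing, 3), collapse = ", "))
  # accumulate per-branch subtree abundances for all samples in one postorder
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  acc <- matrix(0, ntip + tr$Nnode, length(ids))
  hit <- match(tr$tip.label, table$otu_ids)
  ok <- !is.na(hit)
  acc[which(ok), ] <- table$rel_abund[hit[ok], , drop = FALSE]
  for (k in seq_len(nrow(tr$edge)))
    acc[tr$edge[k, 1], ] <- acc[tr$edge[k, 1], ] + acc[tr$edge[k, 2], ]
  W <- acc[tr$edge[, 2], , drop = FALSE]
  l <- tr$edge.length
  m <- matrix(0, length(ids), length(ids))
  for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
    num <- sum(l * abs(W[, i] - W[, j]))
    den <- sum(l * (W[, i] + W[, j]))
    m[i, j] <- m[j, i] <- num / den
  }
  new_distance_matrix(m, ids, "weighted_unifrac")
}

#' @rdname env_distance
#' @param values named per-sample numeric vector
#' @export
trait_distance <- function(values) {
  m <- abs(outer(values, values, `-`))
  new_distance_matrix(m, names(values), "trait_euclidean")
}

new_correlation_result <- function(r, p, n, method, permutations = NA_integer_) {
  structure(list(r = r, p = p, n = n, method = method,
                 permutations = permutations),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: r = %.4f, p = %.4g, n = %d\n", x$method, x$r, x$p, x$n))
  invisible(x)
}

#' Pearson correlation between a per-sample trait and a nutrient covariate
#'
#' Two-sided test; pairs with missing values are dropped (pairwise-complete)
#' and the n actually used is reported.
#'
#' @param trait_values named per-sample numeric vector (e.g., community-level
#'   rrn copy numbers)
#' @param env an `env_table`
#' @param variable covariate name
#' @return a `correlation_result`
#' @export
pearson_trait_env <- function(trait_values, env, variable) {
  stopifnot(inherits(env, "env_table"))
  if (!variable %in% names(env)) abort_input("unknown covariate: ", variable)
  common <- intersect(names(trait_values), env$sample_id)
  x <- trait_values[common]
  y <- env[[variable]][match(common, env$sample_id)]
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < length(common))
    ct_log("pearson_trait_env: dropped ", length(common) - sum(keep),
           " incomplete pair(s)")
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort_input("need >= 3 paired complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    abort_input("zero variance in trait or covariate vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  new_correlation_result(unname(ct$estimate), ct$p.value, length(x), "pearson")
}

lower_vec <- function(m) m[lower.tri(m)]

#' Partial Mantel test between two distance matrices controlling for a third
#'
#' The statistic is the partial correlation of the off-diagonal entries of A
#' and B given C. Significance is assessed by permuting the sample order of A
#' (rows and columns jointly) and recomputing the statistic; the p-value is
#' one-sided ("greater"): \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\}) /
#' (1 + permutations)}.
#'
#' @param A,B,C `distance_matrix` objects (or plain symmetric matrices) with
#'   identical sample ids in identical order
#' @param permutations number of permutations (>= 99; default 999)
#' @param seed integer RNG seed (required, for reproducible p-values)
#' @return a `correlation_result` (`n` is the number of samples)
#' @export
partial_mantel <- function(A, B, C, permutations = 999, seed) {
  if (missing(seed)) abort_input("`seed` is required")
  if (permutations < 99) abort_input("permutations must be >= 99")
  ids <- rownames(A)
  if (is.null(ids) || !identical(ids, rownames(B)) ||
      !identical(ids, rownames(C)))
    abort_input("A, B, C must share identical sample ids in identical order")
  n <- nrow(A)
  a <- lower_vec(A); b <- lower_vec(B); cc <- lower_vec(C)
  if (stats::sd(b) == 0 || stats::sd(cc) == 0 || stats::sd(a) == 0)
    abort_input("degenerate distance matrix (zero off-diagonal variance)")
  pr <- function(rab, rac, rbc) {
    den <- sqrt((1 - rac^2) * (1 - rbc^2))
    if (den == 0) abort_input("degenerate partial correlation (|r| = 1 with control)")
    (rab - rac * rbc) / den
  }
  r_bc <- stats::cor(b, cc)
  r_obs <- pr(stats::cor(a, b), stats::cor(a, cc), r_bc)
  lt <- which(lower.tri(A), arr.ind = TRUE)
  bc <- cbind(b, cc)
  set.seed(seed)
  r_perm <- numeric(permutations)
  for (k in seq_len(permutations)) {
    p <- sample.int(n)
    ap <- A[cbind(p[lt[, 1]], p[lt[, 2]])]
    rr <- stats::cor(ap, bc)
    r_perm[k] <- pr(rr[1], rr[2], r_bc)
  }
  pval <- (1 + sum(r_perm >= r_obs)) / (1 + permutations)
  out <- new_correlation_result(r_obs, pval, n, "partial_mantel", permutations)
  out$r_perm <- r_perm
  out
}
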