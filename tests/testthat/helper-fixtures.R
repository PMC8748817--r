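# Fixture builders and independent brute-force oracles. Oracles here are
# written directly from the definitions (loops over raw records / pairs) and
# never call the code paths they check.

make_counts <- function(values, n_otu, n_sample) {
  matrix(values, nrow = n_otu, ncol = n_sample,
         dimnames = list(sprintf("OTU%02d", seq_len(n_otu)),
                         sprintf("s%02d", seq_len(n_sample))))
}

make_table <- function(values, n_otu, n_sample)
  otu_table(make_counts(values, n_otu, n_sample))

random_table <- function(n_otu, n_sample, lambda = 20) {
  repeat {
    m <- make_counts(stats::rpois(n_otu * n_sample, lambda), n_otu, n_sample)
    if (all(colSums(m) > 0)) return(otu_table(m))
  }
}

# hand-rolled trait assignment for fixtures
make_traits <- function(otu_ids, n) {
  structure(data.frame(otu_id = otu_ids, n = n,
                       matched_rank = ifelse(is.na(n), NA, "species"),
                       matched_name = NA_character_, missing = is.na(n),
                       reason = NA_character_, stringsAsFactors = FALSE),
            class = c("trait_assignment", "data.frame"))
}

make_labels <- function(otu_ids, labels) {
  out <- data.frame(otu_id = otu_ids, label = labels,
                    max_relabund = NA_real_, freq_above_cutoff = NA_real_,
                    occurrence = NA_real_, boundary_tie = FALSE,
                    stringsAsFactors = FALSE)
  attr(out, "thresholds") <- c(a = 0.001, f1 = 0.5, f2 = 0.8)
  class(out) <- c("biosphere_labels", "data.frame")
  out
}

star_tree <- function(n_leaves, branch = 1) {
  labs <- sprintf("OTU%02d", seq_len(n_leaves))
  txt <- paste0("(", paste0(labs, ":", branch, collapse = ","), ");")
  ape::read.tree(text = txt)
}

# --- brute-force classification oracle: per-clause loop over OTUs ----------
oracle_classify <- function(table, a = 0.001, f1 = 0.5, f2 = 0.8) {
  rel <- sweep(table$counts, 2, colSums(table$counts), `/`)
  S <- ncol(rel)
  out <- character(nrow(rel))
  for (i in seq_len(nrow(rel))) {
    n_above <- 0L; n_present <- 0L; all_below <- TRUE
    for (j in seq_len(S)) {
      if (rel[i, j] >= a) { n_above <- n_above + 1L; all_below <- FALSE }
      if (table$counts[i, j] > 0) n_present <- n_present + 1L
    }
    out[i] <- if (n_above / S > f1 && n_present / S > f2) "abundant"
      else if (all_below) "rare" else "intermediate"
  }
  stats::setNames(out, rownames(rel))
}

# --- brute-force Eq. 1 oracle: explicit loop over OTUs ----------------------
oracle_community_rrn <- function(S, n) {
  num <- 0; den <- 0
  for (i in seq_along(S)) {
    num <- num + S[i]
    den <- den + S[i] / n[i]
  }
  unname(num / den)
}

# --- brute-force hierarchical db search oracle ------------------------------
# Operates on the raw record data.frame (rank, lineage, copies): a taxon at
# rank r is known when its name appears at position r on some record's
# lineage; its value is the recursive unweighted mean over the distinct names
# at position r+1 among records passing through it, falling back to the exact
# record's copy number at the leaf of the known subtree.
oracle_db_value <- function(records, rank_idx, name) {
  parts <- strsplit(records$lineage, ";", fixed = TRUE)
  through <- vapply(parts, function(p)
    length(p) >= rank_idx && p[rank_idx] == name, logical(1))
  kids <- unique(vapply(parts[through & lengths(parts) > rank_idx],
                        function(p) p[rank_idx + 1L], character(1)))
  if (length(kids) == 0) {
    exact <- through & lengths(parts) == rank_idx
    return(records$copies[exact][1])
  }
  mean(vapply(kids, function(k) oracle_db_value(records, rank_idx + 1L, k),
              numeric(1)))
}

oracle_assign <- function(lineage, records) {
  parts <- strsplit(records$lineage, ";", fixed = TRUE)
  for (ri in rev(seq_along(lineage))) {
    nm <- lineage[ri]
    if (nm == "") next
    known <- any(vapply(parts, function(p)
      length(p) >= ri && p[ri] == nm, logical(1)))
    if (known)
      return(list(n = oracle_db_value(records, ri, nm), rank_idx = ri))
  }
  list(n = NA_real_, rank_idx = NA_integer_)
}

# --- brute-force weighted MPD: double loop over distinct pairs --------------
oracle_wmpd <- function(dist_mat, p) {
  ids <- names(p)[p > 0]
  num <- 0; den <- 0
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (j <= i) next
    w <- p[ids[i]] * p[ids[j]]
    num <- num + w * dist_mat[ids[i], ids[j]]
    den <- den + w
  }
  unname(num / den)
}

# GOE-style random symmetric matrix with unit diagonal
goe_matrix <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  M <- (A + t(A)) / sqrt(2 * n)
  diag(M) <- 1
  M
}

block_matrix <- function(n, n_blocks = 10) {
  M <- matrix(0, n, n)
  bs <- n %/% n_blocks
  for (b in seq_len(n_blocks)) {
    idx <- (b - 1L) * bs + seq_len(bs)
    M[idx, idx] <- goe_matrix(bs)
  }
  diag(M) <- 1
  M
}
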