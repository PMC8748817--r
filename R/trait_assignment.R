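# Hierarchical rrn copy-number assignment against an rrnDB-style trait table,
# and the community-level rrn copy number: the abundance-weighted harmonic
# mean  sum_i S_i / sum_i (S_i / n_i)  over detected, trait-assigned OTUs.

# Resolved value of a taxon: unweighted mean over its immediate child taxa
# when the db knows children (recursing down to records); else the taxon's
# own record.
trait_db_value <- function(db, rank, name) {
  kids <- trait_db_children(db, rank, name)
  if (length(kids) > 0) {
    ri <- match(rank, TAX_RANKS)
    mean(vapply(kids, function(k)
      trait_db_value(db, TAX_RANKS[ri + 1L], k), numeric(1)))
  } else {
    own <- db$copies[db$rank == rank & db$name == name]
    if (length(own) == 0)
      abort_input("taxon not in db: ", rank, " ", name)
    own
  }
}

#' Assign rrn copy numbers to OTUs by hierarchical taxonomic matching
#'
#' Each OTU's lineage is searched from the lowest assigned rank upward
#' (species, genus, ..., domain). At the first rank whose taxon name exists in
#' the database, the OTU's copy number is the database value for that taxon:
#' the unweighted mean over its child taxa when children are recorded
#' (recursively), otherwise the taxon's own record. OTUs matching at no rank
#' are carried with an explicit missing flag and excluded downstream.
#'
#' @param tax a `taxonomy_table`
#' @param db a `trait_db`
#' @return object of class `trait_assignment`: data.frame with columns
#'   `otu_id`, `n` (copy number, NA when missing), `matched_rank`,
#'   `matched_name`, `missing`, `reason`
#' @export
assign_rrn <- function(tax, db) {
  stopifnot(inherits(tax, "taxonomy_table"), inherits(db, "trait_db"))
  nodes <- attr(db, "nodes")
  key <- paste(nodes$rank_idx, nodes$name)
  # cache resolved values so repeated lineages are O(1)
  cache <- new.env(parent = emptyenv())
  resolve <- function(rank, name) {
    k <- paste(rank, name)
    if (!is.null(cache[[k]])) return(cache[[k]])
    v <- trait_db_value(db, rank, name)
    cache[[k]] <- v
    v
  }
  n_otu <- nrow(tax)
  n <- rep(NA_real_, n_otu)
  mrank <- rep(NA_character_, n_otu)
  mname <- rep(NA_character_, n_otu)
  reason <- rep(NA_character_, n_otu)
  lin <- as.matrix(as.data.frame(tax)[, TAX_RANKS])
  for (i in seq_len(n_otu)) {
    ranks_assigned <- which(lin[i, ] != "")
    if (length(ranks_assigned) == 0) {
      reason[i] <- "empty lineage"
      next
    }
    hit <- FALSE
    for (ri in rev(ranks_assigned)) {
      nm <- lin[i, ri]
      if (paste(ri, nm) %in% key) {
        n[i] <- resolve(TAX_RANKS[ri], nm)
        mrank[i] <- TAX_RANKS[ri]
        mname[i] <- nm
        hit <- TRUE
        break
      }
    }
    if (!hit) reason[i] <- "no database match at any rank"
  }
  out <- data.frame(otu_id = tax$otu_id, n = n, matched_rank = mrank,
                    matched_name = mname, missing = is.na(n),
                    reason = reason, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("trait_assignment", "data.frame")
  out
}

# shared core: abundances and copy numbers of detected, assigned OTUs
detected_assigned <- function(table, traits, sample) {
  stopifnot(inherits(table, "otu_table"), inherits(traits, "trait_assignment"))
  if (!sample %in% table$sample_ids)
    abort_input("unknown sample: ", sample)
  s <- table$counts[, sample]
  n <- traits$n[match(table$otu_ids, traits$otu_id)]
  detected <- s > 0
  use <- detected & !is.na(n)
  list(S = s[use], n = n[use],
       coverage = if (any(detected)) sum(s[use]) / sum(s[detected]) else NA_real_)
}

#' Community-level rrn copy number (abundance-weighted)
#'
#' The abundance-weighted harmonic-style aggregate
#' \deqn{\sum_i S_i / \sum_i (S_i / n_i)}
#' over OTUs detected in the sample that carry an assigned copy number.
#' Invariant to rescaling all abundances, and bounded by the min and max
#' copy number among contributing OTUs. The fraction of detected reads covered
#' by trait-assigned OTUs is attached as attribute `coverage` so the exclusion
#' of unassigned OTUs is auditable.
#'
#' @param table an [otu_table]
#' @param traits a `trait_assignment` from [assign_rrn]
#' @param sample sample id
#' @return numeric scalar with attribute `coverage`
#' @export
community_rrn <- function(table, traits, sample) {
  d <- detected_assigned(table, traits, sample)
  if (length(d$S) == 0)
    abort_input("no detected, trait-assigned OTU in sample ", sample)
  structure(sum(d$S) / sum(d$S / d$n), coverage = d$coverage)
}

#' Unweighted community-level rrn copy number
#'
#' Arithmetic mean copy number over OTUs detected in the sample, ignoring
#' abundance. Always >= the weighted statistic would be under equal weights
#' (arithmetic-harmonic mean inequality).
#'
#' @inheritParams community_rrn
#' @return numeric scalar with attribute `coverage`
#' @export
community_rrn_unweighted <- function(table, traits, sample) {
  d <- detected_assigned(table, traits, sample)
  if (length(d$S) == 0)
    abort_input("no detected, trait-assigned OTU in sample ", sample)
  structure(mean(d$n), coverage = d$coverage)
}

#' Community-level rrn copy number of one biosphere
#'
#' The weighted statistic restricted to the OTUs carrying a given biosphere
#' label, using the subset's abundances. Returns NA (with a logged note) when
#' no detected, assigned OTU in the sample carries the label.
#'
#' @inheritParams community_rrn
#' @param labels a `biosphere_labels` object
#' @param label one of "abundant", "intermediate", "rare"
#' @return numeric scalar (NA when the subset is empty)
#' @export
biosphere_rrn <- function(table, traits, labels, label, sample) {
  stopifnot(inherits(labels, "biosphere_labels"))
  label <- match.arg(label, c("abundant", "intermediate", "rare"))
  keep <- labels$otu_id[labels$label == label]
  s <- table$counts[, sample]
  n <- traits$n[match(table$otu_ids, traits$otu_id)]
  use <- (table$otu_ids %in% keep) & s > 0 & !is.na(n)
  if (!any(use)) {
    ct_log("sample ", sample, ": no detected, assigned '", label,
           "' OTU; returning NA")
    return(NA_real_)
  }
  sum(s[use]) / sum(s[use] / n[use])
}

#' Per-sample community rrn profile
#'
#' Convenience table over all samples: weighted and unweighted community-level
#' rrn copy number, the assigned-abundance coverage, and (when labels are
#' given) the per-biosphere weighted values.
#'
#' @inheritParams community_rrn
#' @param labels optional `biosphere_labels`
#' @return data.frame, one row per sample
#' @export
community_rrn_profile <- function(table, traits, labels = NULL) {
  res <- lapply(table$sample_ids, function(sm) {
    w <- community_rrn(table, traits, sm)
    row <- data.frame(sample_id = sm, rrn_weighted = as.numeric(w),
                      rrn_unweighted = as.numeric(
                        community_rrn_unweighted(table, traits, sm)),
                      coverage = attr(w, "coverage"),
                      stringsAsFactors = FALSE)
    if (!is.null(labels)) {
      for (lb in c("abundant", "intermediate", "rare"))
        row[[paste0("rrn_", lb)]] <-
          suppressMessages(biosphere_rrn(table, traits, labels, lb, sm))
    }
    row
  })
  do.call(rbind, res)
}
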