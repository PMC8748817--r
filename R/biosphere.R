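# Partition of OTUs into the abundant, intermediate and rare biospheres from
# relative abundance and occurrence frequency.

#' Classify OTUs into abundant, intermediate and rare biospheres
#'
#' An OTU is *abundant* when its relative abundance is >= `a` in a fraction of
#' samples strictly greater than `f1` AND it occurs (count > 0) in a fraction
#' of samples strictly greater than `f2`. An OTU is *rare* when its relative
#' abundance is < `a` in every sample. Everything else is *intermediate*.
#' The ">" clauses are strict and the ">= a" clause inclusive, exactly as the
#' classification criteria are usually printed; boundary ties are reported in
#' the output so they can be audited.
#'
#' @param table an [otu_table]
#' @param a relative-abundance cutoff (default 0.001, i.e. 0.1%)
#' @param f1 fraction-of-samples cutoff for the abundance clause (default 0.5)
#' @param f2 occurrence cutoff (default 0.8)
#' @return object of class `biosphere_labels`: a data.frame with columns
#'   `otu_id`, `label`, `max_relabund`, `freq_above_cutoff`, `occurrence`,
#'   `boundary_tie`; thresholds kept as attributes.
#' @export
classify_biospheres <- function(table, a = 0.001, f1 = 0.5, f2 = 0.8) {
  stopifnot(inherits(table, "otu_table"))
  stopifnot_scalar_fraction(a, "a", 0, 1, TRUE, TRUE)
  stopifnot_scalar_fraction(f1, "f1")
  stopifnot_scalar_fraction(f2, "f2")
  if (n_samples(table) == 1L)
    warning("single-sample table: occurrence criteria are degenerate",
            call. = FALSE)
  rel <- table$rel_abund
  freq_above <- rowMeans(rel >= a)
  occ <- table$occurrence
  max_rel <- apply(rel, 1, max)
  abundant <- freq_above > f1 & occ > f2
  rare <- max_rel < a
  label <- ifelse(abundant, "abundant", ifelse(rare, "rare", "intermediate"))
  tie <- (abs(freq_above - f1) < 1e-12) | (abs(occ - f2) < 1e-12) |
    apply(abs(rel - a) < 1e-12, 1, any)
  out <- data.frame(otu_id = table$otu_ids, label = label,
                    max_relabund = max_rel, freq_above_cutoff = freq_above,
                    occurrence = occ, boundary_tie = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "thresholds") <- c(a = a, f1 = f1, f2 = f2)
  class(out) <- c("biosphere_labels", "data.frame")
  out
}

#' Summarize a biosphere partition
#'
#' Per-label OTU counts, percentage of OTUs, and the summed relative abundance
#' of each label in every sample.
#'
#' @param labels a `biosphere_labels` object
#' @param table the [otu_table] the labels were derived from (same OTU set)
#' @return list with `counts` (named integer), `percent` (named, sums to 100)
#'   and `rel_abund_by_sample` (labels x samples matrix; columns sum to 1)
#' @export
biosphere_summary <- function(labels, table) {
  stopifnot(inherits(labels, "biosphere_labels"), inherits(table, "otu_table"))
  if (!setequal(labels$otu_id, table$otu_ids) ||
      length(labels$otu_id) != length(table$otu_ids))
    abort_input("labels and table do not share the same OTU set")
  lv <- c("abundant", "intermediate", "rare")
  lab <- factor(labels$label[match(table$otu_ids, labels$otu_id)], levels = lv)
  counts <- table(lab)
  pct <- 100 * as.numeric(counts) / length(table$otu_ids)
  names(pct) <- lv
  agg <- rowsum(table$rel_abund, group = lab)
  m <- matrix(0, nrow = 3, ncol = n_samples(table),
              dimnames = list(lv, table$sample_ids))
  m[rownames(agg), ] <- agg
  list(counts = stats::setNames(as.integer(counts), lv), percent = pct,
       rel_abund_by_sample = m)
}
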