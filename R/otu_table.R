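# OTU count table container: counts plus derived relative abundances and
# occurrence frequencies. Canonical orientation is OTUs x samples.

#' Construct an OTU table
#'
#' Validates a non-negative count matrix (OTUs in rows, samples in columns)
#' and derives per-sample relative abundances and per-OTU occurrence
#' frequencies. Pre-normalized tables (every column summing to 1 within 1e-6)
#' are accepted and re-closed per sample.
#'
#' @param counts numeric matrix, OTUs x samples, with unique row and column
#'   names. Entries must be non-negative; unless the table is pre-normalized,
#'   they must be whole numbers (read counts).
#' @return An object of class `otu_table`: a list with elements `counts`,
#'   `rel_abund` (columns sum to 1), `occurrence` (fraction of samples with
#'   count > 0 per OTU), `otu_ids`, `sample_ids`.
#' @examples
#' m <- matrix(c(10, 0, 5, 5, 85, 95), nrow = 3, byrow = TRUE,
#'             dimnames = list(paste0("OTU", 1:3), c("s1", "s2")))
#' tab <- otu_table(m)
#' colSums(tab$rel_abund)
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort_input("`counts` must be a numeric matrix (OTUs x samples)")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort_input("`counts` must have OTU row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    abort_input("duplicate OTU identifiers: ",
                paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                      collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    abort_input("duplicate sample identifiers: ",
                paste(unique(colnames(counts)[duplicated(colnames(counts))]),
                      collapse = ", "))
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort_input(sprintf(
      "negative or non-numeric count at OTU '%s', sample '%s'",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  cs <- colSums(counts)
  if (any(cs == 0))
    abort_input("sample column(s) with zero total counts: ",
                paste(colnames(counts)[cs == 0], collapse = ", "))
  normalized <- all(abs(cs - 1) <= 1e-6)
  if (!normalized) {
    off <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)
    if (nrow(off) > 0)
      abort_input(sprintf(
        "non-integer count at OTU '%s', sample '%s' (columns do not sum to 1, so the table is not pre-normalized)",
        rownames(counts)[off[1, 1]], colnames(counts)[off[1, 2]]))
  }
  storage.mode(counts) <- "double"
  rel <- sweep(counts, 2, cs, `/`)
  structure(
    list(counts = counts,
         rel_abund = rel,
         occurrence = rowMeans(counts > 0),
         otu_ids = rownames(counts),
         sample_ids = colnames(counts)),
    class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d OTUs x %d samples (total reads %.6g)\n",
              length(x$otu_ids), length(x$sample_ids), sum(x$counts)))
  invisible(x)
}

#' Number of OTUs / samples in an OTU table
#' @param table an `otu_table`
#' @return integer count
#' @export
n_otus <- function(table) length(table$otu_ids)

#' @rdname n_otus
#' @export
n_samples <- function(table) length(table$sample_ids)

#' Subset an OTU table to a set of OTUs
#'
#' Relative abundances are re-closed per sample over the retained OTUs.
#' Samples in which no retained OTU was counted keep a zero column in
#' `counts` only if `allow_empty_samples` is TRUE; otherwise an error is
#' raised (the default, since downstream statistics assume positive totals).
#'
#' @param table an `otu_table`
#' @param otus character vector of OTU ids to keep
#' @param allow_empty_samples keep samples whose retained counts are all zero
#' @return an `otu_table` over the retained OTUs
#' @export
subset_otus <- function(table, otus, allow_empty_samples = FALSE) {
  missing <- setdiff(otus, table$otu_ids)
  if (length(missing) > 0)
    abort_input("unknown OTU id(s): ", paste(missing, collapse = ", "))
  m <- table$counts[otus, , drop = FALSE]
  cs <- colSums(m)
  if (any(cs == 0)) {
    if (!allow_empty_samples)
      abort_input("subsetting leaves sample(s) with zero totals: ",
                  paste(colnames(m)[cs == 0], collapse = ", "))
    m <- m[, cs > 0, drop = FALSE]
  }
  otu_table(m)
}
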