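# Internal helpers shared across modules.

#' Taxonomic ranks recognized by the package, highest to lowest
#'
#' Lineages are seven-rank (domain through species); an empty string marks an
#' unassigned rank.
#'
#' @export
TAX_RANKS <- c("domain", "phylum", "class", "order", "family", "genus",
               "species")

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_input <- function(...) stop(..., call. = FALSE)

# message() wrapper so diagnostic logging is grep-able and suppressible
ct_log <- function(...) message("[commtrait] ", ...)

stopifnot_scalar_fraction <- function(x, name, lo = 0, hi = 1,
                                      lo_open = TRUE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) abort_input(sprintf("`%s` must be a single number in %s%g, %g%s",
                               name, if (lo_open) "(" else "[", lo, hi,
                               if (hi_open) ")" else "]"))
  invisible(x)
}
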