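# Random-matrix-theory threshold selection for correlation networks.
#
# Rationale: the eigenvalue nearest-neighbour spacing distribution (NNSD) of
# a noise-dominated symmetric matrix follows the Gaussian orthogonal ensemble
# (Wigner-Dyson) law, while a matrix reduced to system-specific modular
# structure has (near-)independent blocks whose superposed spectra show
# Poisson spacing P(s) = exp(-s). Scanning the hard threshold upward, the
# transition from GOE-like to Poisson-like spacing marks the cutoff at which
# surviving correlations reflect structure rather than noise.

# Unfold a sorted eigenvalue spectrum to unit mean spacing: fit a monotone
# cubic spline to the empirical spectral CDF on `knots` knots and map each
# eigenvalue through n * F_smooth(lambda).
unfold_eigenvalues <- function(ev, knots = 15) {
  ev <- sort(ev)
  # merge numerically duplicate eigenvalues (e.g., repeated unit diagonal)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]
  n <- length(ev)
  if (n < 3) return(numeric(0))
  k <- max(3L, min(as.integer(knots), n))
  idx <- unique(round(seq(1L, n, length.out = k)))
  xk <- ev[idx]
  yk <- (idx - 0.5) / n
  keep <- c(TRUE, diff(xk) > 1e-10)
  xk <- xk[keep]; yk <- yk[keep]
  if (length(xk) < 3) return(numeric(0))
  f <- stats::splinefun(xk, yk, method = "hyman")
  e <- n * f(ev)
  diff(e)
}

# Chi-square goodness of fit of spacings against Exponential(1), using
# equal-probability bins. Returns NA p-value when too few spacings remain to
# test (consistent-with-Poisson by default: the test cannot reject).
nnsd_poisson_gof <- function(spacings, min_spacings = 20) {
  s <- spacings[is.finite(spacings) & spacings >= 0]
  if (length(s) < min_spacings)
    return(list(statistic = NA_real_, p = NA_real_, df = NA_integer_,
                n_spacings = length(s)))
  s <- s / mean(s)
  k <- max(5L, length(s) %/% 10L)
  edges <- stats::qexp(seq(0, 1, length.out = k + 1))
  obs <- graphics::hist(pmin(s, edges[k] + 1), breaks = c(edges[-(k + 1)], Inf),
                        plot = FALSE, right = FALSE)$counts
  expd <- length(s) / k
  stat <- sum((obs - expd)^2 / expd)
  list(statistic = stat, p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE),
       df = k - 1L, n_spacings = length(s))
}

# NNSD Poisson test of one thresholded correlation matrix. Isolated rows
# (no surviving off-diagonal entry) are excluded before the eigendecomposition
# since each contributes only a trivial unit eigenvalue.
nnsd_test_matrix <- function(m, threshold = NULL, knots = 15) {
  if (!is.null(threshold)) {
    m[abs(m) < threshold] <- 0
    diag(m) <- 1
  }
  off <- m
  diag(off) <- 0
  keep <- rowSums(off != 0) > 0
  res <- list(n_nodes = sum(keep))
  if (sum(keep) < 10)
    return(c(res, list(statistic = NA_real_, p = NA_real_, n_spacings = 0L,
                       too_small = TRUE)))
  ev <- eigen(m[keep, keep], symmetric = TRUE, only.values = TRUE)$values
  sp <- unfold_eigenvalues(ev, knots = knots)
  c(res, nnsd_poisson_gof(sp), list(too_small = FALSE))
}

#' RMT-based correlation threshold scan
#'
#' Scans candidate hard thresholds in ascending order. At each candidate,
#' entries with |rho| below it are zeroed (diagonal kept at 1), the spectrum
#' of the non-isolated submatrix is unfolded with a monotone cubic spline, and
#' the nearest-neighbour spacing distribution is tested against the Poisson
#' law P(s) = exp(-s) by a chi-square goodness-of-fit on equal-probability
#' bins. The chosen threshold is the smallest candidate whose Poisson fit is
#' not rejected (p > alpha) and which persists for at least two consecutive
#' steps. Candidates whose thresholded matrix keeps fewer than 10 connected
#' nodes end the scan with a diagnostic; thresholds where too few distinct
#' spacings remain to test are treated as consistent with Poisson (the test
#' cannot reject) and flagged.
#'
#' @param corr symmetric Spearman correlation matrix (unit diagonal), e.g.
#'   from [spearman_matrix]
#' @param scan_min,scan_max,step candidate threshold grid (defaults 0.30,
#'   0.99, 0.01)
#' @param alpha significance level of the Poisson GOF test (default 0.05)
#' @param knots knot count of the unfolding spline (default 15)
#' @return object of class `rmt_scan`: list with `threshold` (chosen s_t) and
#'   `scan` (data.frame: threshold, n_nodes, n_spacings, chisq, p, pass)
#' @export
rmt_threshold <- function(corr, scan_min = 0.30, scan_max = 0.99, step = 0.01,
                          alpha = 0.05, knots = 15) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    abort_input("`corr` must be a square correlation matrix")
  if (nrow(corr) < 30)
    warning("fewer than ~30 OTUs: eigenvalue spacing statistics are unstable",
            call. = FALSE)
  thresholds <- seq(scan_min, scan_max, by = step)
  rows <- vector("list", length(thresholds))
  for (i in seq_along(thresholds)) {
    t_i <- thresholds[i]
    r <- nnsd_test_matrix(corr, threshold = t_i, knots = knots)
    if (r$too_small) {
      ct_log(sprintf(
        "rmt scan stopped at s_t = %.2f: fewer than 10 connected nodes", t_i))
      break
    }
    rows[[i]] <- data.frame(threshold = t_i, n_nodes = r$n_nodes,
                            n_spacings = r$n_spacings,
                            chisq = r$statistic, p = r$p,
                            pass = is.na(r$p) || r$p > alpha)
  }
  scan <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(scan) || nrow(scan) == 0)
    abort_input("RMT scan produced no testable threshold; widen the scan range")
  chosen <- NA_real_
  for (i in seq_len(nrow(scan) - 1L)) {
    if (scan$pass[i] && scan$pass[i + 1L] &&
        abs(scan$threshold[i + 1L] - scan$threshold[i] - step) < 1e-9) {
      chosen <- scan$threshold[i]
      break
    }
  }
  if (is.na(chosen) && nrow(scan) == 1L && scan$pass[1L])
    chosen <- scan$threshold[1L]
  if (is.na(chosen))
    abort_input("no threshold in [", scan_min, ", ", scan_max,
                "] passes the Poisson spacing test for two consecutive steps; ",
                "widen the scan range or inspect the scan table")
  structure(list(threshold = chosen, scan = scan, alpha = alpha,
                 knots = knots), class = "rmt_scan")
}

#' @export
print.rmt_scan <- function(x, ...) {
  cat(sprintf("rmt_scan: chosen s_t = %.2f over %d candidates (alpha = %g)\n",
              x$threshold, nrow(x$scan), x$alpha))
  invisible(x)
}
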