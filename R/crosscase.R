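#' Genome-wide correlation of expression with tumor purity
#'
#' Pearson correlation of every gene with the per-section purity vector,
#' with t-distribution p-values and BH q-values. Constant genes get `NA`.
#'
#' @param X Genes x sections expression matrix (>= 4 sections).
#' @param purity Numeric purity vector aligned to the columns of `X`.
#' @return Tibble: `gene`, `r`, `p`, `q`, `n`.
#' @export
purity_correlations <- function(X, purity) {
  n <- ncol(X)
  if (n < 4) stop("need at least 4 sections")
  stopifnot(length(purity) == n)
  r <- suppressWarnings(drop(stats::cor(t(X), purity)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(gene = rownames(X) %||% paste0("g", seq_len(nrow(X))),
                 r = r, p = p, q = stats::p.adjust(p, method = "BH"), n = n)
}

#' Combine correlations across cases by Fisher's z
#'
#' Each correlation is Fisher-transformed (`z = atanh(r)`) and averaged with
#' weights `n - 3`; the combined estimate is the inverse transform of the
#' weighted mean, and the test statistic divides the weighted mean by its
#' joint standard error `1 / sqrt(sum(n - 3))`, giving a standard normal
#' under the null.
#'
#' @param r1,n1 Correlation(s) and sample size for case 1 (vectorized over
#'   genes).
#' @param r2,n2 Optional second case; with a single case the input
#'   correlation is returned unchanged.
#' @return Tibble: `r` (combined), `z` (test statistic), `p` (two-sided).
#' @export
fisher_combine <- function(r1, n1, r2 = NULL, n2 = NULL) {
  check <- function(r, n) {
    if (any(abs(r) >= 1, na.rm = TRUE)) stop("|r| must be < 1 for Fisher's z")
    if (any(n <= 3)) stop("need n > 3")
  }
  check(r1, n1)
  if (is.null(r2)) {
    zbar <- atanh(r1)
    wsum <- n1 - 3
  } else {
    check(r2, n2)
    w1 <- n1 - 3; w2 <- n2 - 3
    zbar <- (w1 * atanh(r1) + w2 * atanh(r2)) / (w1 + w2)
    wsum <- w1 + w2
  }
  z <- zbar * sqrt(wsum)
  tibble::tibble(r = tanh(zbar), z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Select genes consistently correlated with purity across cases
#'
#' On the shared gene universe, keeps genes whose correlation exceeds
#' `r_min` (or falls below `-r_min`) with the *same sign in every case* and
#' whose Fisher-combined q-value clears `q_max`; sign-discordant genes are
#' excluded.
#'
#' @param case_results List of [purity_correlations()] tibbles (columns
#'   `gene`, `r`, `n`), one per case.
#' @param r_min Minimum absolute per-case correlation.
#' @param q_max Maximum BH q on the combined p-value.
#' @return Tibble: `gene`, `sign` (+1/-1), per-case `r_1`, `r_2`, ...,
#'   `combined_r`, `q`.
#' @export
select_consistent_genes <- function(case_results, r_min = 0.3, q_max = 0.05) {
  stopifnot(length(case_results) >= 2)
  shared <- Reduce(intersect, lapply(case_results, function(d) d$gene))
  if (!length(shared)) stop("empty gene intersection across cases")
  rs <- vapply(case_results, function(d) d$r[match(shared, d$gene)],
               numeric(length(shared)))
  ns <- vapply(case_results, function(d) d$n[match(shared, d$gene)],
               numeric(length(shared)))
  ok <- rowSums(is.na(rs)) == 0 & rowSums(abs(rs) >= 1) == 0
  w <- ns - 3
  zbar <- rowSums(atanh(rs * ok) * w) / rowSums(w)
  z <- zbar * sqrt(rowSums(w))
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  pos <- ok & rowSums(rs > r_min) == ncol(rs) & q < q_max
  neg <- ok & rowSums(rs < -r_min) == ncol(rs) & q < q_max
  keep <- pos | neg
  out <- tibble::tibble(gene = shared[keep], sign = ifelse(pos[keep], 1, -1))
  for (j in seq_len(ncol(rs))) out[[paste0("r_", j)]] <- rs[keep, j]
  out$combined_r <- tanh(zbar[keep])
  out$q <- q[keep]
  out
}

#' Power of the two-sided Pearson correlation test
#'
#' Fisher-z approximation with the small-sample bias term: the critical
#' correlation at level `alpha` comes from the exact t cutoff,
#' `r_crit = t / sqrt(t^2 + n - 2)`, and
#' `power = Phi((atanh(r) + r / (2(n-1)) - atanh(r_crit)) * sqrt(n - 3))`
#' plus the (usually negligible) opposite tail.
#'
#' @param n Sample size (> 3).
#' @param r True correlation in (0, 1).
#' @param alpha Significance level.
#' @param sided 1 or 2.
#' @return Power in `[0, 1]`.
#' @export
power_correlation <- function(n, r, alpha = 0.05, sided = 2) {
  if (any(n <= 3)) stop("need n > 3")
  if (any(r <= 0) || any(r >= 1)) stop("r must lie in (0, 1)")
  if (!sided %in% c(1, 2)) stop("sided must be 1 or 2")
  tcrit <- stats::qt(1 - alpha / sided, df = n - 2)
  zcrit <- atanh(tcrit / sqrt(tcrit^2 + n - 2))
  zr <- atanh(r) + r / (2 * (n - 1))
  stats::pnorm((zr - zcrit) * sqrt(n - 3)) +
    if (sided == 2) stats::pnorm((-zr - zcrit) * sqrt(n - 3)) else 0
}
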