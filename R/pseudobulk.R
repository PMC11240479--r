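#' Pseudobulk samples from single-cell counts
#'
#' Each pseudobulk sample sums the counts of an independent uniform random
#' sample (without replacement) of `ceiling(frac * N)` cells; the true
#' malignant fraction of each sample is tracked from the cell labels.
#'
#' @param sc_counts Genes x cells matrix.
#' @param malignant Logical vector per cell (TRUE = malignant).
#' @param frac Fraction of cells per sample.
#' @param n_samples Number of pseudobulk samples.
#' @param seed Optional seed.
#' @return List: `pseudobulk` (genes x samples), `malignant_fraction`
#'   (per-sample), `cells` (list of sampled cell indices).
#' @export
make_pseudobulk <- function(sc_counts, malignant, frac = 0.10, n_samples = 100,
                            seed = NULL) {
  N <- ncol(sc_counts)
  stopifnot(length(malignant) == N)
  n_cells <- ceiling(frac * N)
  if (n_cells < 10) stop("frac * N = ", n_cells, " cells per sample; need at least 10")
  with_seed(seed, {
    cells <- lapply(seq_len(n_samples), function(i) sample.int(N, n_cells))
    pb <- vapply(cells, function(idx) rowSums(sc_counts[, idx, drop = FALSE]),
                 numeric(nrow(sc_counts)))
    colnames(pb) <- paste0("pb", seq_len(n_samples))
    rownames(pb) <- rownames(sc_counts)
    mf <- vapply(cells, function(idx) mean(malignant[idx]), numeric(1))
    cs_log("make_pseudobulk", cells_per_sample = n_cells, samples = n_samples)
    list(pseudobulk = pb, malignant_fraction = mf, cells = cells)
  })
}

#' Single-cell differential expression: malignant versus nonmalignant
#'
#' Per-gene two-sided t-test comparing malignant to nonmalignant cells.
#' Positive t means higher expression in malignant cells. Genes with zero
#' variance in both classes get `t = 0` and are flagged.
#'
#' @param sc_counts Genes x cells matrix.
#' @param malignant Logical vector per cell.
#' @param var_equal Use the pooled-variance t (default Welch).
#' @return Tibble: `gene`, `t`, `p`, `df`, `flat` (zero-variance flag).
#' @export
sc_differential_expression <- function(sc_counts, malignant, var_equal = FALSE) {
  stopifnot(sum(malignant) >= 2, sum(!malignant) >= 2)
  x <- sc_counts[, malignant, drop = FALSE]
  y <- sc_counts[, !malignant, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  flat <- v1 == 0 & v2 == 0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      (pmax((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1), 1e-300))
  }
  tstat <- ifelse(flat, 0, (m1 - m2) / ifelse(se == 0, Inf, se))
  p <- ifelse(flat, 1, 2 * stats::pt(-abs(tstat), df = df))
  tibble::tibble(gene = rownames(sc_counts) %||% paste0("g", seq_along(m1)),
                 t = tstat, p = p, df = df, flat = flat)
}

#' Recover the malignant-abundance module from pseudobulk samples
#'
#' Runs the coexpression stack on the pseudobulk matrix (top 1 percent of
#' bicor values, merge threshold 0.85, minimum size 10), selects the module
#' whose eigengene correlates most strongly (in absolute value) with the
#' true malignant fraction, and returns genome-wide kME to that eigengene —
#' the quantity that recapitulates single-cell differential expression.
#'
#' @param pseudobulk Genes x samples pseudobulk matrix.
#' @param malignant_fraction Per-sample true malignant fraction.
#' @param top_frac,merge_threshold,min_size Module-detection settings.
#' @return List: `module`, `r` (eigengene vs fraction), `kme` (named vector),
#'   `modules` (the full `module_set`).
#' @export
malignant_module_recovery <- function(pseudobulk, malignant_fraction,
                                      top_frac = 0.01, merge_threshold = 0.85,
                                      min_size = 10) {
  ms <- coexpr_modules(pseudobulk, top_frac = top_frac, min_size = min_size,
                       merge_threshold = merge_threshold)
  if (!nrow(ms$eigengenes)) stop("no coexpression module found in pseudobulk data; ",
                                 "check top_frac/min_size against the matrix size")
  rs <- apply(ms$eigengenes, 1, function(me) stats::cor(me, malignant_fraction))
  best <- names(rs)[which.max(abs(rs))]
  me <- ms$eigengenes[best, ]
  if (rs[best] < 0) me <- -me  # orient toward malignant abundance
  kvec <- drop(stats::cor(t(pseudobulk), me))
  names(kvec) <- rownames(pseudobulk)
  cs_log("malignant_module_recovery", module = best, r = round(abs(rs[best]), 3))
  list(module = best, r = unname(abs(rs[best])), kme = kvec, modules = ms)
}
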