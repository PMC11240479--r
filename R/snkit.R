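#' Per-locus genotype call from single-nucleus amplicon reads
#'
#' A locus is called mutant when it has at least `min_reads` alternate reads
#' at a variant fraction of at least `min_vaf`; wildtype when total coverage
#' reaches `min_reads` with fewer than `min_alt_for_mutant` alternate reads;
#' otherwise indeterminate (insufficient or ambiguous reads).
#'
#' @param alt,ref Nonnegative read counts (vectorized).
#' @param min_reads Minimum reads supporting a call.
#' @param min_vaf Minimum variant fraction for a mutant call.
#' @param min_alt_for_mutant Alternate reads at or above which a wildtype
#'   call is withheld (defaults to `min_reads`).
#' @return Character vector in `{"mutant", "wildtype", "indeterminate"}`.
#' @export
call_locus <- function(alt, ref, min_reads = 10, min_vaf = 0.1,
                       min_alt_for_mutant = min_reads) {
  if (any(alt < 0) || any(ref < 0)) stop("read counts must be nonnegative")
  depth <- alt + ref
  vaf <- ifelse(depth > 0, alt / depth, 0)
  out <- rep("indeterminate", length(alt))
  out[alt >= min_reads & vaf >= min_vaf] <- "mutant"
  out[out == "indeterminate" & depth >= min_reads & alt < min_alt_for_mutant] <- "wildtype"
  out
}

#' Per-nucleus genotype category from locus calls
#'
#' Applies, in order: *insufficient* when two or more loci are
#' indeterminate; *discrepant* for the exact two-wildtype-plus-one-mutant
#' pattern (a single mutant call against two confident wildtype calls);
#' *called* when two or more loci agree (two or more mutant, or two or more
#' wildtype) with at most one indeterminate — malignant if the agreement is
#' mutant (allele dropout explains a lone wildtype), nonmalignant if
#' wildtype; any remaining ambiguous pattern (e.g. one of each call) is
#' *insufficient*. The three categories partition all call combinations.
#'
#' @param locus_calls Character vector of per-locus calls for one nucleus
#'   (length = number of genotyped truncal loci, default 3).
#' @param n_loci Expected number of loci.
#' @return List: `category` in `{"called", "discrepant", "insufficient"}`,
#'   `malignant` (`TRUE`/`FALSE`/`NA`).
#' @export
call_nucleus <- function(locus_calls, n_loci = 3) {
  if (length(locus_calls) != n_loci) {
    stop("expected ", n_loci, " locus calls, got ", length(locus_calls))
  }
  bad <- setdiff(locus_calls, c("mutant", "wildtype", "indeterminate"))
  if (length(bad)) stop("unknown locus call: ", paste(bad, collapse = ", "))
  n_mut <- sum(locus_calls == "mutant")
  n_wt <- sum(locus_calls == "wildtype")
  n_ind <- sum(locus_calls == "indeterminate")
  if (n_ind >= 2) return(list(category = "insufficient", malignant = NA))
  if (n_wt == 2 && n_mut == 1) return(list(category = "discrepant", malignant = NA))
  if (n_mut >= 2) return(list(category = "called", malignant = TRUE))
  if (n_wt >= 2) return(list(category = "called", malignant = FALSE))
  list(category = "insufficient", malignant = NA)
}

#' Genotype all nuclei from an amplicon read table
#'
#' Applies [call_locus()] then [call_nucleus()] per nucleus.
#'
#' @param genotype Tibble with columns `nucleus`, `locus`, `alt`, `ref`.
#' @param min_reads,min_vaf Passed to [call_locus()].
#' @return Tibble: `nucleus`, `category`, `malignant`.
#' @export
call_nuclei <- function(genotype, min_reads = 10, min_vaf = 0.1) {
  genotype$call <- call_locus(genotype$alt, genotype$ref,
                              min_reads = min_reads, min_vaf = min_vaf)
  n_loci <- length(unique(genotype$locus))
  out <- dplyr::group_by(genotype, .data$nucleus)
  out <- dplyr::summarise(out, res = list(call_nucleus(.data$call, n_loci = n_loci)),
                          .groups = "drop")
  tibble::tibble(
    nucleus = out$nucleus,
    category = vapply(out$res, `[[`, "", "category"),
    malignant = vapply(out$res, function(r) {
      if (is.na(r$malignant)) NA else r$malignant
    }, logical(1))
  )
}

#' Cluster nuclei by expression profile
#'
#' Depth-normalizes counts per nucleus (scaled to the median library size),
#' log-transforms (`log1p`), and hierarchically clusters nuclei with Ward
#' linkage on the 1 - Pearson-correlation distance. The number of clusters
#' comes from [consensus_cluster_count()] when not given.
#'
#' @param counts Genes x nuclei count matrix.
#' @param k Optional cluster count.
#' @param kmax Screening bound when `k` is `NULL`.
#' @return Tibble: `nucleus`, `cluster`.
#' @export
cluster_nuclei <- function(counts, k = NULL, kmax = 8) {
  if (ncol(counts) < 2) stop("need at least 2 nuclei")
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  norm <- log1p(t(t(counts) / lib * stats::median(lib)))
  cc <- stats::cor(norm)
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  if (is.null(k)) k <- consensus_cluster_count(d, kmax = min(kmax, ncol(counts) - 1L))
  hc <- stats::hclust(d, method = "ward.D")
  cl <- stats::cutree(hc, k = k)
  tibble::tibble(nucleus = colnames(counts) %||% paste0("nuc", seq_len(ncol(counts))),
                 cluster = unname(cl))
}

#' One-sided upregulation test of a module in a nucleus cluster
#'
#' Tests whether the cluster-versus-rest t-values of a module's genes exceed
#' those of all other genes, with a one-sided Wilcoxon rank-sum test.
#'
#' @param t_values Named numeric vector of per-gene t-values (cluster vs
#'   rest).
#' @param module_genes Character vector of module member genes.
#' @return One-sided p-value.
#' @export
module_upregulation_test <- function(t_values, module_genes) {
  module_genes <- intersect(module_genes, names(t_values))
  if (!length(module_genes)) stop("empty module (no genes in the t-value universe)")
  inmod <- names(t_values) %in% module_genes
  # wilcox.test switches to the exact distribution on small tie-free inputs
  stats::wilcox.test(t_values[inmod], t_values[!inmod],
                     alternative = "greater")$p.value
}

#' Map nucleus clusters to clone/cell-type modules
#'
#' BH-corrects the cluster x module upregulation p-values and assigns each
#' cluster the module with the smallest q-value when it clears `alpha`;
#' several clusters may map to the same module; clusters with no q below
#' `alpha` stay unassigned.
#'
#' @param p_matrix Clusters x modules matrix of one-sided p-values.
#' @param alpha Significance level on BH q-values.
#' @return Tibble: `cluster`, `module` (`NA` if unassigned), `q`.
#' @export
map_clusters_to_populations <- function(p_matrix, alpha = 0.05) {
  q <- matrix(stats::p.adjust(p_matrix, method = "BH"),
              nrow(p_matrix), ncol(p_matrix), dimnames = dimnames(p_matrix))
  rows <- rownames(q) %||% paste0("cluster", seq_len(nrow(q)))
  best <- apply(q, 1, which.min)
  qbest <- q[cbind(seq_len(nrow(q)), best)]
  tibble::tibble(
    cluster = rows,
    module = ifelse(qbest < alpha, colnames(q)[best], NA_character_),
    q = qbest
  )
}

#' Evaluate per-nucleus malignancy calls against genotype ground truth
#'
#' Confusion-matrix metrics for an expression-based CNV caller's
#' malignant/nonmalignant calls, using amplicon genotypes as truth. Nuclei
#' with unknown truth (discrepant or insufficient genotypes) are excluded.
#'
#' @param predicted Tibble with columns `nucleus`, `predicted`
#'   (`"malignant"`/`"nonmalignant"` or logical).
#' @param truth Tibble with columns `nucleus`, `malignant`
#'   (`TRUE`/`FALSE`/`NA`), e.g. from [call_nuclei()].
#' @return Tibble: `sensitivity`, `specificity`, `accuracy`, `tp`, `fp`,
#'   `tn`, `fn`, `n`.
#' @export
cnv_caller_metrics <- function(predicted, truth) {
  pr <- predicted$predicted
  if (!is.logical(pr)) pr <- pr == "malignant"
  df <- merge(data.frame(nucleus = predicted$nucleus, pred = pr),
              data.frame(nucleus = truth$nucleus, truth = truth$malignant),
              by = "nucleus")
  df <- df[!is.na(df$truth), ]
  if (!nrow(df)) stop("no nuclei with known truth shared between calls and genotypes")
  tp <- sum(df$pred & df$truth)
  fp <- sum(df$pred & !df$truth)
  tn <- sum(!df$pred & !df$truth)
  fn <- sum(!df$pred & df$truth)
  tibble::tibble(
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / (tp + fp + tn + fn),
    tp = tp, fp = fp, tn = tn, fn = fn, n = nrow(df)
  )
}

#' Concordance of bulk and single-nucleus population composition
#'
#' Pearson correlation between a section's bulk population fractions and the
#' composition of nuclei sampled from an adjacent section.
#'
#' @param bulk_fractions Named numeric vector of population fractions.
#' @param sn_fractions Named numeric vector over (a superset of) the same
#'   populations.
#' @return Pearson r.
#' @export
abundance_concordance <- function(bulk_fractions, sn_fractions) {
  shared <- intersect(names(bulk_fractions), names(sn_fractions))
  if (length(shared) < 3) stop("need at least 3 shared populations")
  stats::cor(bulk_fractions[shared], sn_fractions[shared])
}
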