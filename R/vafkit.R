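#' Variant allele frequencies from read counts
#'
#' `vaf = alt / (alt + ref)`, with explicit `NA` wherever depth is zero.
#'
#' @param alt,ref Nonnegative integer matrices, mutations x sections.
#' @return Numeric matrix of VAFs in `[0, 1]` with `NA` at zero depth.
#' @export
compute_vaf <- function(alt, ref) {
  stopifnot(identical(dim(alt), dim(ref)))
  if (any(alt < 0) || any(ref < 0)) stop("read counts must be nonnegative")
  depth <- alt + ref
  vaf <- ifelse(depth > 0, alt / depth, NA_real_)
  dimnames(vaf) <- dimnames(alt)
  vaf
}

#' Read-depth downsampling stability of VAF estimates
#'
#' For each target depth, reads at every mutation x section are repeatedly
#' subsampled without replacement (hypergeometric draws of alternate reads
#' among the finite observed reads), VAFs recomputed, and compared to the
#' full-coverage VAFs by root-mean-square error and Pearson correlation over
#' sections. Entries whose observed depth falls below the target are kept at
#' full coverage and logged (the subsample cannot exceed the data).
#'
#' @param alt,ref Observed read-count matrices, mutations x sections.
#' @param depths Integer vector of target depths.
#' @param n_rep Random subsamples per depth.
#' @param seed Optional seed.
#' @return A tibble of class `stability_curve` with columns `depth`,
#'   `mutation`, `rmse`, `pearson_r`, `n_rep` (mean over replicates).
#' @export
downsample_stability <- function(alt, ref, depths, n_rep = 1000, seed = NULL) {
  if (n_rep < 1) stop("n_rep must be at least 1")
  full <- compute_vaf(alt, ref)
  depth_obs <- alt + ref
  muts <- rownames(alt)
  if (is.null(muts)) muts <- paste0("m", seq_len(nrow(alt)))
  with_seed(seed, {
    rows <- list()
    for (d in depths) {
      skipped <- sum(depth_obs < d)
      if (skipped) cs_log("downsample_stability", depth = d, below_target = skipped)
      for (i in seq_len(nrow(alt))) {
        n_draw <- pmin(d, depth_obs[i, ])
        rmse_r <- vapply(seq_len(n_rep), function(rep) {
          sub_alt <- stats::rhyper(ncol(alt), alt[i, ], ref[i, ], n_draw)
          v <- ifelse(n_draw > 0, sub_alt / n_draw, NA_real_)
          ok <- !is.na(v) & !is.na(full[i, ])
          c(sqrt(mean((v[ok] - full[i, ok])^2)),
            suppressWarnings(stats::cor(v[ok], full[i, ok])))
        }, numeric(2))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          depth = d, mutation = muts[i],
          rmse = mean(rmse_r[1, ]), pearson_r = mean(rmse_r[2, ], na.rm = TRUE),
          n_rep = n_rep
        )
      }
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("stability_curve", class(out))
    out
  })
}

#' Cluster mutations by their VAF profile across sections
#'
#' Hierarchical clustering with Ward linkage (`"ward.D"`) on the
#' 1 - Pearson-correlation dissimilarity of VAF profiles; missing VAFs are
#' excluded pairwise. When `k` is not given it is chosen by
#' [consensus_cluster_count()].
#'
#' @param vaf Mutations x sections matrix (may contain `NA`).
#' @param k Optional number of clusters.
#' @param linkage Ward variant, `"ward.D"` (default, the stated method) or
#'   `"ward.D2"`.
#' @param kmax Largest `k` screened when `k` is `NULL`.
#' @param distance `"pearson"` (1 - Pearson over sections, the stated VAF
#'   dissimilarity) or `"euclidean"` (used for cellular-prevalence profiles,
#'   whose absolute level is meaningful: a subclone's prevalence can track
#'   its parent's in shape while sitting strictly below it).
#' @return Tibble with columns `mutation`, `cluster` (integer).
#' @export
cluster_mutations <- function(vaf, k = NULL, linkage = c("ward.D", "ward.D2"), kmax = 8,
                              distance = c("pearson", "euclidean")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (nrow(vaf) < 2) stop("need at least 2 mutations")
  if (ncol(vaf) < 3) stop("need at least 3 sections")
  all_missing <- rowSums(!is.na(vaf)) == 0
  if (any(all_missing)) {
    warning("excluding ", sum(all_missing), " mutation(s) with all-missing VAFs")
    vaf <- vaf[!all_missing, , drop = FALSE]
  }
  muts <- rownames(vaf)
  if (is.null(muts)) muts <- paste0("m", seq_len(nrow(vaf)))
  if (distance == "pearson") {
    cmat <- row_cor(vaf)
    cmat[is.na(cmat)] <- 0
    d <- stats::as.dist(1 - cmat)
  } else {
    d <- stats::dist(vaf)
  }
  if (is.null(k)) k <- consensus_cluster_count(d, kmax = min(kmax, nrow(vaf) - 1L), linkage = linkage)
  hc <- stats::hclust(d, method = linkage)
  cl <- stats::cutree(hc, k = k)
  tibble::tibble(mutation = muts, cluster = unname(cl))
}

#' Consensus number of clusters from elbow and silhouette criteria
#'
#' Screens `k = 1..kmax` on a Ward dendrogram of the supplied dissimilarity.
#' The elbow `k` maximizes the second difference of `log W(k)` (the kink in
#' the scree of total within-cluster dissimilarity); the silhouette `k`
#' maximizes the mean silhouette width. When the two agree within 1, the
#' larger (finer) of the two is returned: the mean silhouette is biased
#' toward coarse solutions on nested clusters (merging an adjacent
#' parent/child pair raises the average), so when the scree kink supports
#' one more cluster that structure is real. When they disagree by more than
#' 1 the estimate is unstable and the smaller of the two is returned, with a
#' log note. Degenerate input (all points effectively identical) returns
#' `k = 1`.
#'
#' @param dissimilarity A `dist` object or symmetric matrix.
#' @param kmax Largest number of clusters screened (>= 2).
#' @param linkage Ward variant passed to [stats::hclust()].
#' @param tol Dissimilarity level below which points count as identical.
#' @return Integer `k`.
#' @export
consensus_cluster_count <- function(dissimilarity, kmax = 8, linkage = "ward.D",
                                    tol = 1e-10) {
  if (kmax < 2) stop("kmax must be at least 2")
  d <- stats::as.dist(dissimilarity)
  n <- attr(d, "Size")
  if (n < 2 || max(d) < tol) return(1L)
  kmax <- min(kmax, n - 1L)
  hc <- stats::hclust(d, method = linkage)
  dm <- as.matrix(d)
  ks <- seq_len(min(kmax + 1L, n))  # one past kmax for the second difference
  W <- vapply(ks, function(k) {
    cl <- stats::cutree(hc, k = k)
    sum(vapply(split(seq_len(n), cl), function(idx) {
      if (length(idx) < 2) 0 else sum(dm[idx, idx]) / 2
    }, numeric(1)))
  }, numeric(1))
  sil <- vapply(2:kmax, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, dmatrix = dm)[, "sil_width"])
  }, numeric(1))
  k_sil <- (2:kmax)[which.max(sil)]
  # elbow: sharpest kink in the scree of W(k). The second difference is taken
  # on log(W): W typically drops by orders of magnitude until the true k and
  # flattens after, so the kink only shows on the log scale (on the raw scale
  # the k = 2 drop from W(1) dominates every fixture).
  if (length(W) >= 3) {
    Wl <- log(pmax(W, W[1] * 1e-12))
    second_diff <- Wl[seq_len(length(Wl) - 2L)] - 2 * Wl[2:(length(Wl) - 1L)] + Wl[3:length(Wl)]
    cand <- ks[2:(length(W) - 1L)]
    keep <- cand <= kmax
    k_elbow <- cand[keep][which.max(second_diff[keep])]
  } else {
    k_elbow <- k_sil
  }
  if (abs(k_elbow - k_sil) <= 1L) {
    k <- max(k_elbow, k_sil)
  } else {
    k <- min(k_elbow, k_sil)
    cs_log("consensus_cluster_count", elbow = k_elbow, silhouette = k_sil, consensus = k)
  }
  as.integer(k)
}

#' Event fraction from major-allele B-allele frequency under copy-neutral LOH
#'
#' In a mixture where a fraction `f` of cells carries copy-neutral LOH (two
#' copies of the major allele) and the rest are heterozygous diploid, the
#' major-allele BAF is `(1 + f) / 2`; inverting gives `f = 2 * BAF - 1`,
#' clipped to `[0, 1]`.
#'
#' @param baf_major Numeric vector of per-section major-allele BAFs in
#'   `[0.5, 1]`.
#' @return Numeric vector of per-section LOH cell fractions.
#' @export
loh_fraction_from_baf <- function(baf_major) {
  if (any(baf_major < 0.5, na.rm = TRUE)) {
    stop("baf_major must be oriented to the major allele (values >= 0.5)")
  }
  if (any(baf_major > 1, na.rm = TRUE)) stop("BAF cannot exceed 1")
  pmin(pmax(2 * baf_major - 1, 0), 1)
}
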