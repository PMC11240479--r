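#' Scale a correlation matrix to the unit interval
#'
#' The affine map `s = (1 + cor) / 2` sends `[-1, 1]` to `[0, 1]`, so that
#' correlation matrices from different tissues can be subtracted on a common
#' nonnegative scale.
#'
#' @param cormat Matrix with values in `[-1, 1]`.
#' @return Matrix of the same shape with values in `[0, 1]`.
#' @export
scale_correlations <- function(cormat) {
  if (any(cormat < -1 - 1e-9, na.rm = TRUE) || any(cormat > 1 + 1e-9, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  (1 + cormat) / 2
}

#' Tumor-minus-normal subtraction matrix
#'
#' Elementwise difference of two scaled correlation matrices on their shared
#' gene universe (the intersection is taken and logged). Entries are positive
#' where gene pairs co-vary more strongly in tumor than in the normal
#' reference.
#'
#' @param tumor_scaled,normal_scaled Scaled (`[0, 1]`) correlation matrices
#'   with gene dimnames.
#' @param min_shared Minimum shared genes required.
#' @return Symmetric matrix (genes x genes) over the shared universe, zero
#'   diagonal.
#' @export
subtraction_matrix <- function(tumor_scaled, normal_scaled, min_shared = 100) {
  shared <- intersect(rownames(tumor_scaled), rownames(normal_scaled))
  if (length(shared) < min_shared) {
    stop("only ", length(shared), " shared genes (need >= ", min_shared, ")")
  }
  if (length(shared) < nrow(tumor_scaled) || length(shared) < nrow(normal_scaled)) {
    cs_log("subtraction_matrix", shared = length(shared))
  }
  tumor_scaled[shared, shared] - normal_scaled[shared, shared]
}

#' Consensus of subtraction matrices
#'
#' Elementwise minimum across tumor-minus-normal subtraction matrices: a gene
#' pair scores high only when its coexpression exceeds that of *every*
#' normal reference.
#'
#' @param submats List of subtraction matrices over an identical gene
#'   universe.
#' @return Matrix of elementwise minima.
#' @export
consensus_submat <- function(submats) {
  if (!length(submats)) stop("need at least one subtraction matrix")
  g <- rownames(submats[[1]])
  for (m in submats) {
    if (!identical(rownames(m), g)) stop("subtraction matrices have misaligned gene universes")
  }
  Reduce(pmin, submats)
}

#' Tumor-specific coexpression modules from a consensus subtraction matrix
#'
#' Runs the standard module machinery with distance `1 - consensus` and cut
#' height set by the top fraction of consensus values; eigengenes and kME
#' are computed back on the tumor expression matrix, since the consensus
#' matrix itself has no sample dimension.
#'
#' @param consensus Consensus subtraction matrix.
#' @param tumor_expr Genes x sections tumor expression matrix covering the
#'   consensus universe.
#' @param top_frac Fraction of consensus values above the cut (default the
#'   stated 2 percent).
#' @param min_size Minimum module size.
#' @param merge_threshold Eigengene merge correlation.
#' @return A `module_set` (see [coexpr_modules()]).
#' @export
tumor_specific_modules <- function(consensus, tumor_expr, top_frac = 0.02,
                                   min_size = 10, merge_threshold = 0.85) {
  g <- intersect(rownames(consensus), rownames(tumor_expr))
  cons <- consensus[g, g]
  # gene pairs with nonpositive consensus carry no tumor-specific excess and
  # must never be joined, so the cut height is capped below distance 1
  height <- min(cut_height_from_top_fraction(cons, top_frac), 1 - 1e-9)
  labels <- detect_modules(cons, height, min_size = min_size)
  merged <- merge_modules(labels, tumor_expr[g, , drop = FALSE],
                          threshold = merge_threshold)
  km <- if (nrow(merged$eigengenes)) {
    kme(tumor_expr[g, , drop = FALSE], merged$eigengenes)
  } else {
    list(kme = NULL, q = NULL,
         membership = tibble::tibble(gene = character(), module = character(),
                                     kme = numeric(), q = numeric()))
  }
  structure(list(labels = merged$labels, eigengenes = merged$eigengenes,
                 kme = km$kme, q = km$q, membership = km$membership,
                 height = height, cormat_source = "consensus submat"),
            class = "module_set")
}

#' Differential coexpression pipeline
#'
#' Builds the scaled bicor matrix for the tumor and each normal series,
#' subtracts each normal from the tumor, forms the consensus (elementwise
#' minimum) and detects tumor-specific modules on it.
#'
#' @param tumor_expr Genes x sections tumor expression matrix.
#' @param normal_exprs List of genes x sections normal expression matrices.
#' @param top_frac,min_size,merge_threshold Passed to
#'   [tumor_specific_modules()].
#' @return A `module_set` with an extra `consensus` field.
#' @export
diffcoexpr_modules <- function(tumor_expr, normal_exprs, top_frac = 0.02,
                               min_size = 10, merge_threshold = 0.85) {
  ts <- scale_correlations(bicor_matrix(tumor_expr))
  subs <- lapply(normal_exprs, function(nx) {
    subtraction_matrix(ts, scale_correlations(bicor_matrix(nx)))
  })
  shared <- Reduce(intersect, lapply(subs, rownames))
  subs <- lapply(subs, function(m) m[shared, shared])
  cons <- consensus_submat(subs)
  ms <- tumor_specific_modules(cons, tumor_expr, top_frac = top_frac,
                               min_size = min_size, merge_threshold = merge_threshold)
  ms$consensus <- cons
  cs_log("diffcoexpr_modules", genes = length(shared), normals = length(normal_exprs),
         modules = nrow(ms$eigengenes))
  ms
}
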