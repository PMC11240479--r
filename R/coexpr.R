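#' Biweight midcorrelation matrix of gene expression profiles
#'
#' Outlier-robust correlation between all pairs of genes (rows). Each
#' observation is weighted by `w_i = (1 - u_i^2)^2 * 1[|u_i| < 1]` with
#' `u_i = (x_i - med(x)) / (9 * MAD(x))` (raw median absolute deviation).
#' Rows with zero MAD cannot be weighted and fall back to the Pearson
#' correlation (logged). When no observation lies beyond `9 * MAD`, all
#' weights are strictly positive and bicor closely tracks Pearson.
#'
#' @param X Genes x samples numeric matrix, at least 4 samples.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
bicor_matrix <- function(X) {
  if (ncol(X) < 4) stop("need at least 4 samples for correlation")
  G <- bicor_transform(X)
  out <- tcrossprod(G)
  diag(out) <- 1
  out[out > 1] <- 1; out[out < -1] <- -1
  dimnames(out) <- list(rownames(X), rownames(X))
  out
}

# rows transformed so that tcrossprod() gives bicor (Pearson for zero-MAD rows)
bicor_transform <- function(X) {
  med <- apply(X, 1, stats::median)
  madr <- apply(abs(X - med), 1, stats::median)
  fallback <- madr == 0
  if (any(fallback)) {
    cs_log("bicor_matrix", pearson_fallback_rows = sum(fallback))
  }
  G <- matrix(0, nrow(X), ncol(X))
  if (any(!fallback)) {
    idx <- which(!fallback)
    u <- (X[idx, , drop = FALSE] - med[idx]) / (9 * madr[idx])
    w <- (1 - u^2)^2 * (abs(u) < 1)
    G[idx, ] <- (X[idx, , drop = FALSE] - med[idx]) * w
  }
  if (any(fallback)) {
    idx <- which(fallback)
    G[idx, ] <- X[idx, , drop = FALSE] - rowMeans(X[idx, , drop = FALSE])
  }
  nrm <- sqrt(rowSums(G^2))
  nrm[nrm == 0] <- 1  # constant rows correlate at 0 with everything
  G / nrm
}

#' Dendrogram cut height matching a top fraction of correlations
#'
#' With distance `1 - cor`, cutting at height `1 - q` joins exactly the gene
#' pairs whose correlation exceeds `q`; taking `q` as the `(1 - top_frac)`
#' quantile of the off-diagonal correlations makes the cut correspond to the
#' top `top_frac` of values of the correlation matrix.
#'
#' @param cormat Symmetric correlation-like matrix.
#' @param top_frac Fraction of off-diagonal values above the cut, in (0, 1).
#' @return Cut height (scalar).
#' @export
cut_height_from_top_fraction <- function(cormat, top_frac) {
  stopifnot(top_frac > 0, top_frac < 1)
  off <- cormat[upper.tri(cormat)]
  1 - unname(stats::quantile(off, 1 - top_frac))
}

#' Detect coexpression modules by a static-height dendrogram cut
#'
#' Complete-linkage hierarchical clustering on `1 - cor`, cut at a fixed
#' height; clusters smaller than `min_size` are left unassigned (`NA`).
#' Modules are labeled `M1`, `M2`, ... by decreasing size.
#'
#' @param cormat Symmetric correlation-like matrix with gene dimnames.
#' @param height Static cut height on the `1 - cor` distance scale.
#' @param min_size Minimum module size (>= 2).
#' @return Tibble with columns `gene`, `module` (`NA` = unassigned).
#' @export
detect_modules <- function(cormat, height, min_size = 15) {
  stopifnot(min_size >= 2)
  genes <- rownames(cormat) %||% paste0("g", seq_len(nrow(cormat)))
  hc <- stats::hclust(stats::as.dist(1 - cormat), method = "complete")
  cl <- stats::cutree(hc, h = height)
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_size]
  module <- rep(NA_character_, length(cl))
  if (length(keep)) {
    keep <- keep[order(sizes[keep], decreasing = TRUE)]
    for (i in seq_along(keep)) module[cl == as.integer(keep[i])] <- paste0("M", i)
  }
  tibble::tibble(gene = genes, module = module)
}

#' Module eigengene
#'
#' Standardizes each member gene across samples and takes the first right
#' singular vector of the standardized matrix (the first principal component
#' over samples). The sign is fixed so the mean correlation with member
#' genes is nonnegative; the eigengene has unit norm.
#'
#' @param X Genes x samples matrix restricted to one module's genes (>= 2).
#' @return Numeric eigengene of length `ncol(X)`.
#' @export
module_eigengene <- function(X) {
  if (nrow(X) < 2) stop("a module needs at least 2 genes")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant gene(s) from eigengene computation")
    X <- X[sds > 0, , drop = FALSE]
    if (nrow(X) < 2) stop("fewer than 2 non-constant genes in module")
  }
  Z <- t(scale(t(X)))
  sv <- svd(Z, nu = 0, nv = 1)
  me <- sv$v[, 1]
  if (mean(stats::cor(t(Z), me)) < 0) me <- -me
  me
}

# eigengenes for a label tibble: modules x samples matrix
eigengene_matrix <- function(X, labels) {
  mods <- sort(unique(stats::na.omit(labels$module)))
  if (!length(mods)) return(matrix(numeric(), 0, ncol(X), dimnames = list(NULL, colnames(X))))
  me <- t(vapply(mods, function(m) {
    module_eigengene(X[labels$gene[!is.na(labels$module) & labels$module == m], , drop = FALSE])
  }, numeric(ncol(X))))
  dimnames(me) <- list(mods, colnames(X))
  me
}

#' Iteratively merge highly correlated modules
#'
#' Repeatedly merges the single pair of modules with the highest eigengene
#' Pearson correlation above `threshold`, recomputing all eigengenes and
#' correlations after each merge, until no pair exceeds the threshold.
#' Terminates in at most (initial module count - 1) merges.
#'
#' @param labels Tibble `gene`, `module` from [detect_modules()].
#' @param X Genes x samples expression matrix covering the labeled genes.
#' @param threshold Eigengene correlation above which modules merge.
#' @return List with `labels` (relabeled `M1..` by size) and `eigengenes`
#'   (modules x samples).
#' @export
merge_modules <- function(labels, X, threshold = 0.80) {
  stopifnot(threshold > 0, threshold < 1)
  repeat {
    me <- eigengene_matrix(X, labels)
    if (nrow(me) < 2) break
    cc <- stats::cor(t(me))
    diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] <= threshold) break
    from <- rownames(me)[mx[2]]; into <- rownames(me)[mx[1]]
    labels$module[!is.na(labels$module) & labels$module == from] <- into
  }
  # relabel by decreasing size
  sizes <- sort(table(labels$module), decreasing = TRUE)
  map <- stats::setNames(paste0("M", seq_along(sizes)), names(sizes))
  labels$module <- ifelse(is.na(labels$module), NA_character_, map[labels$module])
  list(labels = labels, eigengenes = eigengene_matrix(X, labels))
}

#' Genome-wide kME and FDR-expanded module membership
#'
#' kME is the Pearson correlation of each gene with each module eigengene.
#' Correlation p-values come from the exact t distribution; q-values are
#' Benjamini-Hochberg within each module. Genes significant for at least one
#' module are assigned to the module of their largest kME among the
#' significant ones.
#'
#' @param X Genes x samples expression matrix (>= 4 samples).
#' @param eigengenes Modules x samples matrix.
#' @param alpha FDR level for expanded membership.
#' @return List: `kme` (genes x modules), `q` (matching BH q-values),
#'   `membership` (tibble: gene, module, kme, q for significant genes).
#' @export
kme <- function(X, eigengenes, alpha = 0.05) {
  if (ncol(X) < 4) stop("need at least 4 samples")
  n <- ncol(X)
  km <- stats::cor(t(X), t(eigengenes))
  tstat <- km * sqrt((n - 2) / pmax(1 - km^2, 1e-300))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  q <- apply(p, 2, stats::p.adjust, method = "BH")
  if (is.null(dim(q))) q <- matrix(q, ncol = ncol(km), dimnames = dimnames(km))
  sig <- q < alpha
  genes <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  rows <- which(rowSums(sig, na.rm = TRUE) > 0)
  membership <- dplyr::bind_rows(lapply(rows, function(i) {
    cand <- which(sig[i, ])
    best <- cand[which.max(km[i, cand])]
    tibble::tibble(gene = genes[i], module = colnames(km)[best],
                   kme = km[i, best], q = q[i, best])
  }))
  if (!nrow(membership)) {
    membership <- tibble::tibble(gene = character(), module = character(),
                                 kme = numeric(), q = numeric())
  }
  list(kme = km, q = q, membership = membership)
}

#' One-sided Fisher enrichment of gene lists in gene sets
#'
#' For every (list, set) pair, tests over-representation of the set in the
#' list against the universe with a one-sided (greater) Fisher exact test;
#' the odds ratio is the cross-product ratio of the 2x2 table. q-values are
#' Benjamini-Hochberg across all tested pairs.
#'
#' @param gene_lists Named list of character vectors (e.g. module members).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector containing all tested genes.
#' @return Tibble: `list`, `set`, `overlap`, `list_size`, `set_size`,
#'   `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(gene_lists, gene_sets, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!is.list(gene_lists)) gene_lists <- list(list1 = gene_lists)
  if (!is.list(gene_sets)) gene_sets <- list(set1 = gene_sets)
  rows <- list()
  for (ln in names(gene_lists)) {
    gl <- intersect(gene_lists[[ln]], universe)
    for (sn in names(gene_sets)) {
      gs <- intersect(gene_sets[[sn]], universe)
      a <- length(intersect(gl, gs))
      b <- length(gl) - a
      cc <- length(gs) - a
      d <- length(universe) - a - b - cc
      p <- stats::fisher.test(matrix(c(a, b, cc, d), 2), alternative = "greater")$p.value
      or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        list = ln, set = sn, overlap = a, list_size = length(gl),
        set_size = length(gs), odds_ratio = or, p = p
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Correlate module eigengenes with cumulative clone abundance
#'
#' Pearson correlation of each eigengene with each clone's cumulative
#' abundance (clone plus descendants; for the truncal clone this is tumor
#' purity) across shared sections, with t-distribution p-values and BH
#' q-values; the top module per clone maximizes `|r|`.
#'
#' @param eigengenes Modules x sections matrix.
#' @param fractions Clones x sections exact-genotype fraction matrix.
#' @param tree A [clone_tree()] or named parent vector (for cumulation).
#' @return Tibble: `module`, `clone`, `r`, `p`, `q`, `top` (logical, best
#'   module for that clone).
#' @export
module_clone_correlation <- function(eigengenes, fractions, tree) {
  shared <- intersect(colnames(eigengenes), colnames(fractions))
  if (length(shared) < 4) stop("need at least 4 shared sections")
  cum <- cumulative_fractions(fractions[, shared, drop = FALSE], tree)
  me <- eigengenes[, shared, drop = FALSE]
  n <- length(shared)
  out <- tidyr::expand_grid(module = rownames(me), clone = rownames(cum))
  out$r <- mapply(function(m, cl) stats::cor(me[m, ], cum[cl, ]), out$module, out$clone)
  tstat <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, 1e-300))
  out$p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- dplyr::group_by(out, .data$clone)
  out <- dplyr::mutate(out, top = abs(.data$r) == max(abs(.data$r)))
  dplyr::ungroup(out)
}

#' Full coexpression module pipeline
#'
#' bicor, static-height cut at the top fraction of correlations, size
#' filter, eigengenes, iterative merging, and FDR-expanded kME membership —
#' the standard bulk coexpression stack of this package.
#'
#' @param X Genes x samples expression matrix.
#' @param top_frac Fraction of correlations above the cut (0.30 and 0.20 are
#'   the bulk defaults for the two case studies; 0.02 for differential
#'   coexpression; 0.01 for pseudobulk).
#' @param min_size Minimum module size.
#' @param merge_threshold Eigengene correlation for merging (0.80 bulk, 0.85
#'   pseudobulk/differential).
#' @param alpha FDR for expanded membership.
#' @param cormat Optional precomputed correlation-like matrix (used by the
#'   differential-coexpression stage); defaults to `bicor_matrix(X)`.
#' @return Object of class `module_set`: `labels`, `eigengenes`, `kme`, `q`,
#'   `membership`, `height`, `cormat_source`.
#' @export
coexpr_modules <- function(X, top_frac = 0.30, min_size = 15,
                           merge_threshold = 0.80, alpha = 0.05, cormat = NULL) {
  src <- if (is.null(cormat)) "bicor" else "supplied"
  if (is.null(cormat)) cormat <- bicor_matrix(X)
  height <- cut_height_from_top_fraction(cormat, top_frac)
  labels <- detect_modules(cormat, height, min_size = min_size)
  merged <- merge_modules(labels, X, threshold = merge_threshold)
  km <- if (nrow(merged$eigengenes)) kme(X, merged$eigengenes, alpha = alpha) else {
    list(kme = NULL, q = NULL,
         membership = tibble::tibble(gene = character(), module = character(),
                                     kme = numeric(), q = numeric()))
  }
  cs_log("coexpr_modules", genes = nrow(X), samples = ncol(X),
         modules = nrow(merged$eigengenes), height = round(height, 4))
  structure(list(labels = merged$labels, eigengenes = merged$eigengenes,
                 kme = km$kme, q = km$q, membership = km$membership,
                 height = height, cormat_source = src),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat("<module_set> ", sum(!is.na(x$labels$module)), "/", nrow(x$labels),
      " genes in ", nrow(x$eigengenes), " modules (cut height ",
      format(x$height, digits = 3), ", ", x$cormat_source, " correlations)\n", sep = "")
  invisible(x)
}
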