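#' Design matrix of cumulative clone abundances
#'
#' Builds the predictor matrix for per-gene lasso models: one standardized
#' column per clone holding its cumulative abundance across sections. In
#' `"group-lasso"` mode the truncal clone forms its own (unpenalized) group
#' and all remaining clones a second, penalized group — the truncal column
#' is the tumor-purity vector, the dominant source of expression variation,
#' and leaving it unpenalized stops it from absorbing subclonal signal.
#'
#' @param fractions Clones x sections exact-genotype fraction matrix.
#' @param tree A [clone_tree()] or named parent vector.
#' @param mode `"lasso"` (all clones penalized) or `"group-lasso"` (truncal
#'   unpenalized).
#' @param exclude Clone ids to drop (e.g. very low-frequency clones or clones
#'   defined by a single CNV).
#' @return List: `x` (sections x clones, columns standardized), `penalty`
#'   (0/1 penalty factors), `truncal`, `mode`.
#' @export
build_design <- function(fractions, tree, mode = c("lasso", "group-lasso"),
                         exclude = character()) {
  mode <- match.arg(mode)
  cum <- cumulative_fractions(fractions, tree)
  keep <- setdiff(rownames(cum), exclude)
  if (length(keep) < 2) stop("need at least 2 clones after exclusions")
  x <- t(cum[keep, , drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant clone-abundance column(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) stop("need at least 2 clones after exclusions")
  }
  x <- scale(x)
  root <- tree_root(tree)
  penalty <- rep(1, ncol(x))
  names(penalty) <- colnames(x)
  if (mode == "group-lasso" && root %in% colnames(x)) penalty[root] <- 0
  list(x = x, penalty = penalty, truncal = root, mode = mode)
}

#' Sole-survivor selection along the lasso regularization path
#'
#' Fits the full L1 path (100 log-spaced penalties, strongest first) and
#' returns the penalized predictor that is the only penalized predictor with
#' a nonzero coefficient at the first path point where exactly one survives;
#' `NA` if no such point exists. Unpenalized (truncal-group) membership is
#' allowed throughout.
#'
#' @param y Response vector (one gene's expression across sections).
#' @param design A [build_design()] result.
#' @return List: `predictor` (clone id or `NA`), `sign` (+1/-1 or `NA`).
#' @export
path_select <- function(y, design) {
  if (length(y) < 10) stop("need at least 10 samples")
  fit <- glmnet::glmnet(design$x, y, family = "gaussian", alpha = 1,
                        penalty.factor = design$penalty, nlambda = 100,
                        lambda.min.ratio = 1e-3, standardize = FALSE)
  beta <- as.matrix(fit$beta)
  pen <- names(design$penalty)[design$penalty > 0]
  bp <- beta[pen, , drop = FALSE]
  nz <- colSums(bp != 0)
  hit <- which(nz == 1L)
  if (!length(hit)) return(list(predictor = NA_character_, sign = NA_real_))
  j <- hit[1]
  i <- which(bp[, j] != 0)
  list(predictor = pen[i], sign = sign(bp[i, j]))
}

#' Bootstrap stability of sole-survivor selection
#'
#' Resamples sections with replacement `n_boot` times, reruns
#' [path_select()], and counts how often the modal surviving predictor is
#' the sole survivor; the coefficient sign is the modal sign over those
#' bootstraps.
#'
#' @param y Response vector.
#' @param design A [build_design()] result.
#' @param n_boot Number of bootstrap resamples.
#' @param seed Optional seed.
#' @return Tibble: `predictor`, `stability` (0..n_boot), `sign`.
#' @export
stability_score <- function(y, design, n_boot = 100, seed = NULL) {
  with_seed(seed, {
    n <- length(y)
    picks <- character(n_boot)
    signs <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      d_b <- design
      d_b$x <- design$x[idx, , drop = FALSE]
      sel <- tryCatch(path_select(y[idx], d_b),
                      error = function(e) list(predictor = NA_character_, sign = NA_real_))
      picks[b] <- sel$predictor
      signs[b] <- sel$sign
    }
    ok <- !is.na(picks)
    if (!any(ok)) {
      return(tibble::tibble(predictor = NA_character_, stability = 0L, sign = NA_real_))
    }
    tab <- sort(table(picks[ok]), decreasing = TRUE)
    modal <- names(tab)[1]
    won <- ok & picks == modal
    sgn_tab <- table(signs[won])
    tibble::tibble(predictor = modal, stability = as.integer(sum(won)),
                   sign = as.numeric(names(sgn_tab)[which.max(sgn_tab)]))
  })
}

#' Permutation FDR threshold on stability values
#'
#' The threshold is the smallest integer `s` such that among all models with
#' stability at least `s`, the fraction that are permuted models is at most
#' `fdr`. If no `s <= n_boot` satisfies the bound the threshold is
#' `n_boot + 1` (nothing passes), which is logged.
#'
#' @param real,permuted Integer stability values for real and permuted
#'   models.
#' @param fdr Target false-discovery proportion.
#' @param n_boot Number of bootstraps (upper bound on stability).
#' @return Integer threshold.
#' @export
permutation_fdr_threshold <- function(real, permuted, fdr = 0.05, n_boot = 100) {
  if (!length(real) || !length(permuted)) stop("need nonempty real and permuted stabilities")
  for (s in 0:n_boot) {
    np <- sum(permuted >= s)
    nr <- sum(real >= s)
    if (np + nr == 0) next
    if (np / (np + nr) <= fdr) return(as.integer(s))
  }
  cs_log("permutation_fdr_threshold", result = "none", threshold = n_boot + 1L)
  as.integer(n_boot + 1L)
}

#' Gene-wise lasso stability selection against clonal abundance
#'
#' Models every gene's expression on the cumulative clone-abundance design,
#' bootstrapping sole-survivor selection for the real profile and for a
#' permuted copy of the profile (the empirical null), then applies the
#' permutation FDR threshold to call genes significantly tied to one clone.
#'
#' @param X Genes x sections expression matrix.
#' @param fractions Clones x sections fraction matrix.
#' @param tree A [clone_tree()] or named parent vector.
#' @param mode,exclude Passed to [build_design()].
#' @param n_boot Bootstraps per model.
#' @param fdr FDR level for the stability threshold.
#' @param seed Seed (drives bootstraps and permutations).
#' @return Object of class `stability_result`: tibble with `gene`, `clone`,
#'   `stability`, `sign`, `permuted` (flag), `significant`; attributes
#'   `threshold`, `n_boot`.
#' @export
clone_lasso <- function(X, fractions, tree, mode = c("lasso", "group-lasso"),
                        exclude = character(), n_boot = 100, fdr = 0.05,
                        seed = NULL) {
  mode <- match.arg(mode)
  design <- build_design(fractions, tree, mode = mode, exclude = exclude)
  sections <- rownames(design$x)
  if (!is.null(sections) && !is.null(colnames(X))) {
    X <- X[, sections, drop = FALSE]
  }
  genes <- rownames(X) %||% paste0("g", seq_len(nrow(X)))
  with_seed(seed, {
    run <- function(y, flag) {
      st <- stability_score(y, design, n_boot = n_boot)
      st$permuted <- flag
      st
    }
    real <- dplyr::bind_rows(lapply(seq_len(nrow(X)), function(i) run(X[i, ], FALSE)))
    perm <- dplyr::bind_rows(lapply(seq_len(nrow(X)), function(i) {
      run(sample(X[i, ]), TRUE)
    }))
    real$gene <- genes
    perm$gene <- genes
    thr <- permutation_fdr_threshold(real$stability, perm$stability,
                                     fdr = fdr, n_boot = n_boot)
    out <- dplyr::bind_rows(real, perm)
    out$significant <- !out$permuted & out$stability >= thr
    out <- dplyr::select(dplyr::rename(out, clone = "predictor"),
                         "gene", "clone", "stability", "sign", "permuted", "significant")
    cs_log("clone_lasso", genes = nrow(X), mode = mode, threshold = thr,
           significant = sum(out$significant))
    structure(out, threshold = thr, n_boot = n_boot,
              class = c("stability_result", class(out)))
  })
}
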