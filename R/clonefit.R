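#' Expected VAF of a mutation in a mixed cell population
#'
#' With population fractions `f` (summing to at most 1; the remainder plus
#' any explicit nonmalignant entry carries `m = 0, t = 2`), mutant copy
#' numbers `m` and total copy numbers `t` per population, the expected
#' variant allele frequency is the copy-number-weighted mixture
#' `VAF = sum(f * m) / sum(f * t)`. A zero denominator yields `NA`.
#'
#' @param fractions Numeric vector of population fractions for one section;
#'   if it sums to less than 1 the remainder is treated as nonmalignant
#'   diploid wildtype.
#' @param m,t Mutant and total copies per population, aligned to `fractions`.
#' @return Expected VAF (scalar).
#' @export
expected_vaf <- function(fractions, m, t) {
  stopifnot(length(fractions) == length(m), length(m) == length(t))
  if (any(fractions < -1e-12) || sum(fractions) > 1 + 1e-9) {
    stop("fractions must be nonnegative with sum <= 1")
  }
  rest <- max(0, 1 - sum(fractions))
  num <- sum(fractions * m)
  den <- sum(fractions * t) + 2 * rest
  if (den <= 0) return(NA_real_)
  num / den
}

#' Expected VAF matrix for a clone tree over sections
#'
#' Applies the mixture model of [expected_vaf()] to every mutation and
#' section given exact-genotype clone fractions; the nonmalignant remainder
#' is diploid wildtype.
#'
#' @param tree A [clone_tree()].
#' @param fractions Clones x sections exact-genotype fraction matrix.
#' @return Mutations x sections matrix of expected VAFs.
#' @export
expected_vaf_matrix <- function(tree, fractions) {
  ids <- rownames(fractions)
  muts <- unique(tree$allele_state$mutation_id)
  rest <- pmax(0, 1 - colSums(fractions))
  out <- matrix(NA_real_, length(muts), ncol(fractions),
                dimnames = list(muts, colnames(fractions)))
  st <- tree$allele_state
  for (i in seq_along(muts)) {
    sti <- st[st$mutation_id == muts[i], ]
    m <- stats::setNames(sti$m, sti$clone)[ids]
    t_ <- stats::setNames(sti$t, sti$clone)[ids]
    m[is.na(m)] <- 0; t_[is.na(t_)] <- 2
    num <- as.vector(m %*% fractions)
    den <- as.vector(t_ %*% fractions) + 2 * rest
    out[i, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  out
}

#' Cellular prevalence from VAF under a known allele context
#'
#' Inverts the linear mixture model of [expected_vaf()] for the fraction
#' `phi` of all cells carrying an event, given the allele state `(m, t)` in
#' carrying cells and the background total copy number `t_bg` elsewhere:
#' `VAF = phi * m / (phi * t + (1 - phi) * t_bg)`, hence
#' `phi = VAF * t_bg / (m - VAF * (t - t_bg))`, clipped to `[0, 1]`.
#' When read counts are supplied, a binomial normal-approximation confidence
#' interval on the VAF is propagated through the (monotone) inversion.
#'
#' @param vaf Numeric vector of observed VAFs.
#' @param m,t Mutant and total copies in carrying cells (scalars).
#' @param t_bg Total copies in non-carrying cells (default diploid, 2).
#' @param alt,depth Optional read counts matching `vaf` for the CI.
#' @param conf Confidence level.
#' @return Tibble with columns `phi`, `lo`, `hi` (the last two `NA` without
#'   counts).
#' @export
cellular_prevalence <- function(vaf, m, t, t_bg = 2, alt = NULL, depth = NULL,
                                conf = 0.95) {
  if (m <= 0) stop("event with m = 0 mutant copies is not observable in VAF")
  inv <- function(v) {
    den <- m - v * (t - t_bg)
    phi <- ifelse(is.na(v), NA_real_, ifelse(den <= 0, 1, v * t_bg / den))
    pmin(pmax(phi, 0), 1)
  }
  lo <- hi <- rep(NA_real_, length(vaf))
  if (!is.null(alt) && !is.null(depth)) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    se <- sqrt(pmax(vaf * (1 - vaf), 0) / pmax(depth, 1))
    lo <- inv(pmax(vaf - z * se, 0))
    hi <- inv(pmin(vaf + z * se, 1))
  }
  tibble::tibble(phi = inv(vaf), lo = lo, hi = hi)
}

#' Cluster SNV/CNV events by their cellular-prevalence profile
#'
#' Reuses the VAF-profile clustering machinery ([cluster_mutations()]) on
#' prevalence profiles; each cluster's prevalence per section is the
#' precision-weighted mean of its members (weights `1 / variance` when
#' per-observation variances are given, equal weights otherwise).
#'
#' @param phi Events x sections matrix of cellular prevalences.
#' @param variances Optional matching matrix of per-observation variances.
#' @param k Optional cluster count; chosen by [consensus_cluster_count()]
#'   when `NULL`.
#' @param kmax Screening bound when `k` is `NULL`.
#' @return List of class `prevalence_clusters`: `membership` (tibble: event,
#'   cluster), `prevalence` (clusters x sections matrix, rows ordered by
#'   decreasing mean prevalence and named `c1`, `c2`, ...).
#' @export
cluster_events <- function(phi, variances = NULL, k = NULL, kmax = 8) {
  if (nrow(phi) < 1) stop("need at least one event")
  if (nrow(phi) == 1) {
    memb <- tibble::tibble(event = rownames(phi) %||% "e1", cluster = 1L)
    prev <- phi
    rownames(prev) <- "c1"
  } else {
    cl <- cluster_mutations(phi, k = k, kmax = kmax, distance = "euclidean")
    memb <- tibble::tibble(event = cl$mutation, cluster = cl$cluster)
    w <- if (is.null(variances)) matrix(1, nrow(phi), ncol(phi)) else 1 / pmax(variances, 1e-12)
    ks <- sort(unique(memb$cluster))
    prev <- t(vapply(ks, function(kk) {
      idx <- which(memb$cluster == kk)
      colSums(phi[idx, , drop = FALSE] * w[idx, , drop = FALSE]) /
        colSums(w[idx, , drop = FALSE])
    }, numeric(ncol(phi))))
  }
  ord <- order(rowMeans(prev), decreasing = TRUE)
  prev <- prev[ord, , drop = FALSE]
  relabel <- match(seq_len(nrow(prev)), ord)
  memb$cluster <- relabel[memb$cluster]
  rownames(prev) <- paste0("c", seq_len(nrow(prev)))
  colnames(prev) <- colnames(phi)
  structure(list(membership = memb, prevalence = prev), class = "prevalence_clusters")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Enumerate all rooted trees over k labeled clusters
#'
#' Returns every parent map over `k` labeled clusters with a fixed root
#' (cluster 1 by convention, the truncal cluster). The count equals Cayley's
#' formula `k^(k-2)` for `k >= 2` and 1 for `k = 1`. Enumeration is guarded
#' at `k <= 7`.
#'
#' @param k Number of clusters.
#' @return List of integer parent vectors (`NA` at the root).
#' @export
enumerate_trees <- function(k) {
  if (k > 7) stop("tree enumeration is k^(k-2); k > 7 not supported, use a heuristic search")
  if (k < 1) stop("k must be positive")
  if (k == 1) return(list(c(NA_integer_)))
  choices <- lapply(2:k, function(i) setdiff(seq_len(k), i))
  grid <- do.call(expand.grid, choices)
  keep <- apply(grid, 1, function(par) {
    parent <- c(NA_integer_, as.integer(par))
    for (i in 2:k) {  # walk up; must reach the root without revisiting
      seen <- logical(k)
      cur <- i
      while (!is.na(parent[cur])) {
        if (seen[cur]) return(FALSE)
        seen[cur] <- TRUE
        cur <- parent[cur]
      }
      if (cur != 1L) return(FALSE)
    }
    TRUE
  })
  lapply(which(keep), function(r) c(NA_integer_, as.integer(grid[r, ])))
}

# subtree indicator for an integer parent vector (root has NA)
subtree_matrix_int <- function(parent) {
  k <- length(parent)
  A <- matrix(0, k, k)
  for (d in seq_len(k)) {
    cur <- d
    repeat {
      A[cur, d] <- 1
      if (is.na(parent[cur])) break
      cur <- parent[cur]
    }
  }
  A
}

# Exact solution of: min ||phi - A f||^2  s.t.  f >= 0, sum(f) <= 1,
# simultaneously for every column of `phi`, by enumerating KKT active sets
# (k <= 7 so at most 2^(k+1) equality-constrained solves, each shared by all
# sections). The subset achieving the optimum is feasible and attains the
# global minimum of the convex program, so the feasible minimum over all
# subsets is exact.
solve_tree_nnls <- function(A, phi, tol = 1e-9) {
  k <- nrow(A)
  S <- ncol(phi)
  best_obj <- rep(Inf, S)
  best_f <- matrix(0, k, S)
  phi2 <- colSums(phi^2)
  for (mask in 0:(2^k - 1)) {
    R <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)  # free coordinates
    for (eq in c(FALSE, TRUE)) {
      if (!length(R)) {
        if (eq) next
        f <- matrix(0, k, S)
        obj <- phi2
      } else {
        AR <- A[, R, drop = FALSE]
        M <- crossprod(AR)
        rhs <- crossprod(AR, phi)
        fR <- if (!eq) {
          sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
          if (is.null(sol)) next
          sol
        } else {
          KKT <- rbind(cbind(2 * M, rep(1, length(R))), c(rep(1, length(R)), 0))
          sol <- tryCatch(solve(KKT, rbind(2 * rhs, rep(1, S))), error = function(e) NULL)
          if (is.null(sol)) next
          sol[seq_along(R), , drop = FALSE]
        }
        feas <- colSums(fR < -tol) == 0 & colSums(fR) <= 1 + tol
        if (!any(feas)) next
        f <- matrix(0, k, S)
        f[R, ] <- fR
        res <- phi - AR %*% fR
        obj <- colSums(res^2)
        obj[!feas] <- Inf
      }
      upd <- obj < best_obj - 0
      if (any(upd)) {
        best_obj[upd] <- obj[upd]
        best_f[, upd] <- f[, upd]
      }
    }
  }
  best_f[best_f < 0] <- 0
  list(f = best_f, objective = best_obj)
}

#' Fit per-section clone frequencies for a fixed tree topology
#'
#' For each section, solves the constrained least-squares problem
#' `min sum_c (phi_obs[c] - cumulative(f)[c])^2` over exact-genotype
#' fractions `f >= 0` with column sum at most 1, where `cumulative` is the
#' subtree-sum linear map fixed by the tree. The solution automatically
#' satisfies the subclone-sum constraint. The fit objective is the sum over
#' sections of squared prevalence residuals.
#'
#' @param parent Integer parent vector over clusters (root = index 1, `NA`
#'   parent) as produced by [enumerate_trees()], or a named character parent
#'   map.
#' @param prevalence Clusters x sections matrix of observed cellular
#'   prevalences (rows in parent order).
#' @return Object of class `tree_fit`: `parent`, `fractions` (clusters x
#'   sections), `cumulative`, `objective`, `objective_per_section`.
#' @export
fit_tree_frequencies <- function(parent, prevalence) {
  ids <- rownames(prevalence) %||% paste0("c", seq_len(nrow(prevalence)))
  if (is.character(parent) || all(is.na(parent))) {
    if (!is.null(names(parent))) parent <- parent[ids]
    parent_int <- match(parent, ids)
  } else {
    parent_int <- as.integer(parent)
  }
  A <- subtree_matrix_int(parent_int)
  sol <- solve_tree_nnls(A, prevalence)
  f <- sol$f
  dimnames(f) <- dimnames(prevalence)
  cum <- A %*% f
  dimnames(cum) <- dimnames(prevalence)
  structure(list(
    parent = stats::setNames(ifelse(is.na(parent_int), NA_character_, ids[parent_int]), ids),
    fractions = f,
    cumulative = cum,
    objective = sum(sol$objective),
    objective_per_section = sol$objective
  ), class = "tree_fit")
}

#' @export
print.tree_fit <- function(x, ...) {
  cat("<tree_fit> ", length(x$parent), " clusters x ", ncol(x$fractions),
      " sections; objective ", format(x$objective, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Select the minimum-objective clonal tree
#'
#' Enumerates all rooted trees over the prevalence clusters (root = the
#' cluster with maximal mean prevalence, i.e. the truncal cluster), fits
#' frequencies for each by constrained least squares, and returns the tree
#' with the minimum objective. Trees whose objectives fall within a relative
#' tolerance of the best are reported as a ranked candidate list with a tie
#' flag, leaving the final choice to the analyst.
#'
#' @param clusters A [cluster_events()] result (rows of `$prevalence` are
#'   already ordered by decreasing mean prevalence, so row 1 is the root).
#' @param tie_tol Relative objective tolerance for reporting near-ties.
#' @return The best `tree_fit`, with extra fields `candidates` (tibble:
#'   rank, parent string, objective) and `tie` (logical).
#' @export
select_best_tree <- function(clusters, tie_tol = 0.01) {
  prev <- clusters$prevalence
  k <- nrow(prev)
  fits <- lapply(enumerate_trees(k), fit_tree_frequencies, prevalence = prev)
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  ord <- order(objs)
  best <- fits[[ord[1]]]
  thr <- objs[ord[1]] * (1 + tie_tol) + 1e-12
  near <- ord[objs[ord] <= thr]
  best$candidates <- tibble::tibble(
    rank = seq_along(near),
    parent = vapply(fits[near], function(f) {
      paste(ifelse(is.na(f$parent), "-", f$parent), collapse = ",")
    }, ""),
    objective = objs[near]
  )
  best$tie <- length(near) > 1L
  if (best$tie) cs_log("select_best_tree", near_ties = length(near) - 1L)
  best
}

#' Per-section tumor purity from a fitted tree
#'
#' Purity is the cumulative frequency of the truncal (root) cluster.
#'
#' @param fit A `tree_fit`.
#' @return Named numeric vector over sections.
#' @export
purity_per_section <- function(fit) {
  root <- names(fit$parent)[is.na(fit$parent)]
  fit$cumulative[root, ]
}

#' Relative copy number from qPCR means
#'
#' Ratio of target to reference mean quantities, multiplied by two so that a
#' diploid target reports 2 copies.
#'
#' @param target_qpcr_mean,reference_qpcr_mean Positive means.
#' @return `2 * target / reference`.
#' @export
relative_copy_number <- function(target_qpcr_mean, reference_qpcr_mean) {
  if (any(reference_qpcr_mean <= 0)) stop("reference qPCR mean must be positive")
  2 * target_qpcr_mean / reference_qpcr_mean
}

#' Reconstruct clonal architecture from amplicon read counts
#'
#' End-to-end convenience wrapper: computes VAFs, inverts them to cellular
#' prevalences under the supplied allele context (default heterozygous
#' diploid), clusters events by prevalence profile, and selects the
#' minimum-objective tree with per-section clone frequencies and purity.
#'
#' @param alt,ref Read-count matrices, mutations x sections.
#' @param m,t,t_bg Allele context of the mutations (scalars or per-mutation
#'   vectors); defaults to heterozygous diploid in carriers, diploid
#'   background.
#' @param k Optional number of prevalence clusters.
#' @param kmax Screening bound for the consensus cluster count.
#' @return A `tree_fit` with extra fields `clusters` (the
#'   [cluster_events()] result) and `purity`.
#' @export
reconstruct_clones <- function(alt, ref, m = 1, t = 2, t_bg = 2, k = NULL, kmax = 7) {
  vaf <- compute_vaf(alt, ref)
  n <- nrow(vaf)
  m <- rep_len(m, n); t <- rep_len(t, n); t_bg <- rep_len(t_bg, n)
  phi <- t(vapply(seq_len(n), function(i) {
    cellular_prevalence(vaf[i, ], m = m[i], t = t[i], t_bg = t_bg[i])$phi
  }, numeric(ncol(vaf))))
  dimnames(phi) <- dimnames(vaf)
  clusters <- cluster_events(phi, k = k, kmax = kmax)
  fit <- select_best_tree(clusters)
  fit$clusters <- clusters
  fit$purity <- purity_per_section(fit)
  cs_log("reconstruct_clones", mutations = n, sections = ncol(vaf),
         clusters = nrow(clusters$prevalence), objective = fit$objective)
  fit
}
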