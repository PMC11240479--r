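#' Construct a clone tree
#'
#' A `clone_tree` is the central genetic description of a tumor: a rooted
#' phylogeny of malignant clones, with somatic SNVs and copy-number events
#' assigned to the branch on which they arose, and a per-(mutation, clone)
#' allele state giving the number of mutant copies `m` out of `t` total copies
#' at that locus in cells of that clone. The root is the truncal clone (its
#' conceptual parent is the nonmalignant compartment, encoded as `NA`).
#'
#' @param parent Named character vector mapping each clone id to its parent
#'   clone id; the single root has `NA`.
#' @param mutations Data frame with columns `mutation_id`, `clone` (clone of
#'   origin) and optionally `chrom`, `start`, `end` (0-based half-open).
#' @param cnv_segments Data frame with columns `chrom`, `start`, `end`
#'   (0-based half-open), `clone` (clone of origin), `total_copies`, `event`
#'   (one of `"gain"`, `"loss"`, `"cn-LOH"`), or `NULL`.
#' @param allele_state Data frame with columns `mutation_id`, `clone`, `m`,
#'   `t`: mutant and total copy number of each mutation locus in each clone.
#'   Clones absent for a mutation default to `m = 0, t = 2`.
#'
#' @return An object of class `clone_tree`.
#' @export
clone_tree <- function(parent, mutations, cnv_segments = NULL, allele_state) {
  stopifnot(is.character(parent) || all(is.na(parent)), !is.null(names(parent)))
  mutations <- tibble::as_tibble(mutations)
  allele_state <- tibble::as_tibble(allele_state)
  if (is.null(cnv_segments)) {
    cnv_segments <- tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      clone = character(), total_copies = integer(), event = character()
    )
  }
  cnv_segments <- tibble::as_tibble(cnv_segments)
  tree <- structure(
    list(
      clone_ids = names(parent),
      parent = parent,
      mutations = mutations,
      cnv_segments = cnv_segments,
      allele_state = allele_state
    ),
    class = "clone_tree"
  )
  validate_clone_tree(tree)
  tree
}

#' Validate clone-tree invariants
#'
#' Checks: exactly one root, acyclic parent relation reaching the root from
#' every clone, `0 <= m <= t` in every allele state, and mutation clones /
#' allele-state clones known to the tree.
#'
#' @param tree A [clone_tree()].
#' @return `tree`, invisibly; errors on violation.
#' @export
validate_clone_tree <- function(tree) {
  p <- tree$parent
  ids <- tree$clone_ids
  if (anyDuplicated(ids)) stop("duplicated clone ids")
  roots <- ids[is.na(p)]
  if (length(roots) != 1L) stop("clone tree must have exactly one root, found ", length(roots))
  for (cl in ids) {
    seen <- character()
    cur <- cl
    while (!is.na(p[[cur]])) {
      if (cur %in% seen) stop("cycle in parent relation at clone ", cl)
      seen <- c(seen, cur)
      cur <- p[[cur]]
      if (!cur %in% ids) stop("unknown parent clone ", cur)
    }
  }
  if (nrow(tree$allele_state)) {
    with(tree$allele_state, {
      if (any(t < 0) || any(m < 0) || any(m > t)) {
        stop("allele_state must satisfy 0 <= m <= t")
      }
    })
    bad <- setdiff(tree$allele_state$clone, ids)
    if (length(bad)) stop("allele_state references unknown clones: ", paste(bad, collapse = ", "))
  }
  if (nrow(tree$mutations)) {
    bad <- setdiff(tree$mutations$clone, ids)
    if (length(bad)) stop("mutations reference unknown clones: ", paste(bad, collapse = ", "))
  }
  invisible(tree)
}

#' @export
print.clone_tree <- function(x, ...) {
  cat("<clone_tree> ", length(x$clone_ids), " clones, ",
      nrow(x$mutations), " mutations, ", nrow(x$cnv_segments), " CNV segments\n", sep = "")
  cat("  root: ", tree_root(x), "\n", sep = "")
  invisible(x)
}

#' Root clone of a tree
#' @param tree A [clone_tree()] or a named parent vector.
#' @return The root clone id.
#' @export
tree_root <- function(tree) {
  p <- if (inherits(tree, "clone_tree")) tree$parent else tree
  names(p)[is.na(p)]
}

#' Children of each clone
#' @param tree A [clone_tree()] or named parent vector.
#' @return Named list mapping clone id to character vector of children.
#' @export
clone_children <- function(tree) {
  p <- if (inherits(tree, "clone_tree")) tree$parent else tree
  ids <- names(p)
  out <- lapply(ids, function(cl) ids[!is.na(p) & p == cl])
  names(out) <- ids
  out
}

#' Subtree (self + descendants) indicator matrix
#'
#' Row `c`, column `d` is 1 when clone `d` lies in the subtree rooted at `c`.
#' Cumulative clone abundance is then `A %*% fractions` for exact-genotype
#' fraction matrices, and tumor purity is the root's row of that product.
#'
#' @param tree A [clone_tree()] or named parent vector.
#' @return A 0/1 matrix with clone ids as dimnames.
#' @export
subtree_matrix <- function(tree) {
  p <- if (inherits(tree, "clone_tree")) tree$parent else tree
  ids <- names(p)
  k <- length(ids)
  A <- matrix(0, k, k, dimnames = list(ids, ids))
  for (d in ids) {
    cur <- d
    repeat {
      A[cur, d] <- 1
      if (is.na(p[[cur]])) break
      cur <- p[[cur]]
    }
  }
  A
}

#' Cumulative clone abundance and purity
#'
#' `cumulative_fractions()` converts exact-genotype clone fractions (each cell
#' counted once, under the most derived clone whose genotype it carries) into
#' cumulative abundances (a clone plus all of its descendants).
#' `purity_from_fractions()` returns the truncal cumulative abundance, i.e.
#' the malignant fraction of each section.
#'
#' @param fractions Numeric matrix, clones x sections, exact-genotype
#'   fractions; rownames are clone ids.
#' @param tree A [clone_tree()] or named parent vector covering the rows.
#' @return A matrix of the same shape (cumulative), or a named numeric vector
#'   of per-section purities.
#' @export
cumulative_fractions <- function(fractions, tree) {
  A <- subtree_matrix(tree)
  stopifnot(all(rownames(fractions) %in% rownames(A)))
  A <- A[rownames(fractions), rownames(fractions), drop = FALSE]
  A %*% fractions
}

#' @rdname cumulative_fractions
#' @export
purity_from_fractions <- function(fractions, tree) {
  cumulative_fractions(fractions, tree)[tree_root(tree), ]
}

#' Validate a clone-fraction matrix
#'
#' Exact-genotype fractions must lie in `[0, 1]` with column sums at most 1
#' (the remainder is the nonmalignant compartment). The subclone-sum
#' constraint — a parent's cumulative abundance is at least the sum of its
#' children's — holds automatically for nonnegative exact-genotype fractions
#' and is re-checked here for safety.
#'
#' @inheritParams cumulative_fractions
#' @param tol Numerical slack on the constraints.
#' @return `fractions`, invisibly; errors on violation.
#' @export
validate_fractions <- function(fractions, tree, tol = 1e-8) {
  if (any(fractions < -tol) || any(fractions > 1 + tol)) {
    stop("clone fractions must lie in [0, 1]")
  }
  if (any(colSums(fractions) > 1 + tol)) stop("column sums of clone fractions exceed 1")
  cum <- cumulative_fractions(fractions, tree)
  kids <- clone_children(tree)
  for (cl in rownames(fractions)) {
    ch <- intersect(kids[[cl]], rownames(fractions))
    if (length(ch)) {
      viol <- colSums(cum[ch, , drop = FALSE]) - cum[cl, ] > tol
      if (any(viol)) stop("subclone-sum constraint violated at clone ", cl)
    }
  }
  invisible(fractions)
}
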