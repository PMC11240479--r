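#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted clonal tree
#'
#' One row per (clone, section) with exact-genotype and cumulative
#' frequencies.
#'
#' @param x A `tree_fit`.
#' @param ... Unused.
#' @return A tibble: `clone`, `section`, `fraction`, `cumulative`.
#' @export
tidy.tree_fit <- function(x, ...) {
  sections <- colnames(x$fractions) %||% paste0("s", seq_len(ncol(x$fractions)))
  tibble::tibble(
    clone = rep(rownames(x$fractions), times = ncol(x$fractions)),
    section = rep(sections, each = nrow(x$fractions)),
    fraction = as.vector(x$fractions),
    cumulative = as.vector(x$cumulative)
  )
}

#' @describeIn tidy.tree_fit One-row model summary: clusters, sections,
#'   objective, purity range, tie flag.
#' @export
glance.tree_fit <- function(x, ...) {
  pur <- purity_per_section(x)
  tibble::tibble(
    n_clones = nrow(x$fractions),
    n_sections = ncol(x$fractions),
    objective = x$objective,
    purity_min = min(pur),
    purity_max = max(pur),
    tie = isTRUE(x$tie)
  )
}

#' Tidy a module set
#'
#' One row per gene with its (merged) module label and, when available, the
#' FDR-expanded membership (kME and q of the assigned module).
#'
#' @param x A `module_set`.
#' @param ... Unused.
#' @return A tibble: `gene`, `module`, `expanded_module`, `kme`, `q`.
#' @export
tidy.module_set <- function(x, ...) {
  out <- x$labels
  m <- x$membership
  out$expanded_module <- m$module[match(out$gene, m$gene)]
  out$kme <- m$kme[match(out$gene, m$gene)]
  out$q <- m$q[match(out$gene, m$gene)]
  out
}

#' @describeIn tidy.module_set One-row summary: module count, assigned and
#'   expanded gene counts, cut height.
#' @export
glance.module_set <- function(x, ...) {
  tibble::tibble(
    n_modules = nrow(x$eigengenes),
    n_assigned = sum(!is.na(x$labels$module)),
    n_expanded = nrow(x$membership),
    n_genes = nrow(x$labels),
    height = x$height
  )
}

#' Tidy lasso stability results
#'
#' The real (non-permuted) rows of a `stability_result`.
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return A tibble: `gene`, `clone`, `stability`, `sign`, `significant`.
#' @export
tidy.stability_result <- function(x, ...) {
  out <- tibble::as_tibble(x)
  out[!out$permuted, c("gene", "clone", "stability", "sign", "significant")]
}

#' @describeIn tidy.stability_result One-row summary: threshold, counts.
#' @export
glance.stability_result <- function(x, ...) {
  real <- x[!x$permuted, ]
  tibble::tibble(
    threshold = attr(x, "threshold"),
    n_boot = attr(x, "n_boot"),
    n_genes = nrow(real),
    n_significant = sum(real$significant)
  )
}

#' Plot fitted clone frequencies along the section axis
#'
#' @param object A `tree_fit`.
#' @param cumulative Plot cumulative abundance instead of exact-genotype
#'   fractions.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tree_fit <- function(object, cumulative = FALSE, ...) {
  df <- tidy(object)
  df$section_index <- rep(seq_len(ncol(object$fractions)), each = nrow(object$fractions))
  yvar <- if (cumulative) "cumulative" else "fraction"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$section_index, y = .data[[yvar]],
                                   colour = .data$clone)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "section", y = if (cumulative) "cumulative abundance" else
      "exact-genotype fraction", colour = "clone") +
    ggplot2::theme_minimal()
}

#' Plot module eigengenes across samples
#'
#' @param object A `module_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.module_set <- function(object, ...) {
  me <- object$eigengenes
  df <- tibble::tibble(
    module = rep(rownames(me), times = ncol(me)),
    sample_index = rep(seq_len(ncol(me)), each = nrow(me)),
    eigengene = as.vector(me)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_index, y = .data$eigengene)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~module) +
    ggplot2::labs(x = "sample", y = "module eigengene") +
    ggplot2::theme_minimal()
}

#' Plot a downsampling stability curve
#'
#' RMSE of downsampled VAFs against target depth, one line per mutation.
#'
#' @param object A `stability_curve` tibble from [downsample_stability()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$depth, y = .data$rmse,
                                       colour = .data$mutation)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "target depth (reads)", y = "VAF RMSE vs full coverage",
                  colour = "mutation") +
    ggplot2::theme_minimal()
}
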