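# Internal helpers shared across stages.

# Evaluate `code` under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# One structured log line per stage: key=value pairs via message(), silenced
# unless options(clonesect.verbose = TRUE).
cs_log <- function(stage, ...) {
  if (!isTRUE(getOption("clonesect.verbose", FALSE))) return(invisible(NULL))
  kv <- list(...)
  msg <- paste0("[clonesect:", stage, "] ",
                paste(names(kv), unname(vapply(kv, function(v) paste(format(v), collapse = ","),
                                               character(1))),
                      sep = "=", collapse = " "))
  message(msg)
  invisible(NULL)
}

# >= 1 bp overlap of 0-based half-open intervals.
intervals_overlap <- function(start1, end1, start2, end2) {
  pmax(start1, start2) < pmin(end1, end2)
}

#' Genes overlapping a genomic segment
#'
#' A gene belongs to a segment when its interval overlaps the segment by at
#' least one base pair (0-based half-open coordinates on the same chromosome).
#'
#' @param gene_meta Data frame with columns `gene`, `chrom`, `start`, `end`.
#' @param segment One-row data frame (or list) with `chrom`, `start`, `end`.
#' @return Character vector of gene ids.
#' @export
genes_in_segment <- function(gene_meta, segment) {
  hit <- gene_meta$chrom == segment$chrom &
    intervals_overlap(gene_meta$start, gene_meta$end, segment$start, segment$end)
  gene_meta$gene[hit]
}

# Pairwise-complete Pearson correlation of matrix rows, tolerant of NAs.
row_cor <- function(x) {
  stats::cor(t(x), use = "pairwise.complete.obs")
}
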