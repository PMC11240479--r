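#' Read a genes-by-samples expression matrix from TSV
#'
#' First column holds gene ids, remaining columns one sample each (header row
#' of sample ids). Sample order is preserved exactly as in the file.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus at least one sample column")
  genes <- df[[1]]
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicated gene id(s): ", paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric value '", vals[bad[1, 1], bad[1, 2]], "' at gene row ",
         bad[1, 1], " (", genes[bad[1, 1]], "), sample column ", bad[1, 2],
         " (", colnames(df)[-1][bad[1, 2]], ")")
  }
  dimnames(num) <- list(genes, colnames(df)[-1])
  cs_log("read_expression_tsv", path = path, genes = nrow(num), samples = ncol(num))
  num
}

#' Write a genes-by-samples matrix to TSV
#'
#' Inverse of [read_expression_tsv()]; the pair round-trips losslessly
#' (values are written with full precision, 15 significant digits).
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Header for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(x, path, id_col = "gene") {
  df <- tibble::as_tibble(x, rownames = id_col)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read somatic mutations from a VCF file
#'
#' Accepts a minimal VCF (meta lines `##`, header `#CHROM`, one record per
#' somatic mutation). Coordinates are converted from VCF's 1-based convention
#' to the package-internal 0-based half-open convention at this boundary.
#' Mutation ids are `CHROM:POS:REF>ALT` with the 1-based position as printed
#' in the file.
#'
#' @param path Path to an (uncompressed) VCF.
#' @return Tibble with columns `mutation_id`, `chrom`, `pos` (1-based),
#'   `start`, `end` (0-based half-open), `ref`, `alt`.
#' @export
read_mutations_vcf <- function(path) {
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  empty <- tibble::tibble(
    mutation_id = character(), chrom = character(), pos = integer(),
    start = integer(), end = integer(), ref = character(), alt = character()
  )
  if (!length(body_idx)) return(empty)
  recs <- lapply(body_idx, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed VCF record at line ", i, ": fewer than 5 fields")
    pos <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos)) stop("malformed VCF record at line ", i, ": non-integer POS '", f[2], "'")
    ref <- f[4]; alt <- f[5]
    if (!nzchar(ref) || !nzchar(alt) || grepl("[^ACGTNacgtn]", ref)) {
      stop("malformed VCF record at line ", i, ": bad REF/ALT")
    }
    if (identical(ref, alt)) stop("malformed VCF record at line ", i, ": REF equals ALT")
    tibble::tibble(
      mutation_id = paste0(f[1], ":", pos, ":", ref, ">", alt),
      chrom = f[1], pos = pos,
      start = pos - 1L, end = pos - 1L + nchar(ref),
      ref = ref, alt = alt
    )
  })
  out <- dplyr::bind_rows(recs)
  cs_log("read_mutations_vcf", path = path, n = nrow(out))
  out
}

#' Read clone-assigned CNV segments from a BED-like file
#'
#' Columns: chrom, start (0-based), end (half-open), event, clone,
#' total_copies. Events must be one of `gain`, `loss`, `cn-LOH`. Segments are
#' validated and returned sorted by (chrom, start); overlapping segments
#' assigned to the same clone are kept with a warning.
#'
#' @param path Path to a tab- or whitespace-separated file (no header).
#' @return Tibble with columns `chrom`, `start`, `end`, `event`, `clone`,
#'   `total_copies`.
#' @export
read_cnv_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer(),
                          event = character(), clone = character(), total_copies = integer()))
  }
  f <- strsplit(lines, "[ \t]+")
  bad_len <- which(lengths(f) < 6L)
  if (length(bad_len)) stop("CNV BED line ", bad_len[1], " has fewer than 6 fields")
  out <- tibble::tibble(
    chrom = vapply(f, `[[`, "", 1),
    start = as.integer(vapply(f, `[[`, "", 2)),
    end = as.integer(vapply(f, `[[`, "", 3)),
    event = vapply(f, `[[`, "", 4),
    clone = vapply(f, `[[`, "", 5),
    total_copies = as.integer(vapply(f, `[[`, "", 6))
  )
  if (anyNA(out$start) || anyNA(out$end)) stop("non-integer CNV coordinates")
  bad <- which(out$start >= out$end)
  if (length(bad)) stop("CNV segment with start >= end at line ", bad[1])
  known <- c("gain", "loss", "cn-LOH")
  bad_ev <- setdiff(unique(out$event), known)
  if (length(bad_ev)) {
    stop("unknown CNV event label(s): ", paste(bad_ev, collapse = ", "),
         " (expected gain, loss, cn-LOH)")
  }
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  by_clone_chrom <- split(out, paste(out$clone, out$chrom))
  for (g in by_clone_chrom) {
    if (nrow(g) > 1L && any(g$start[-1] < g$end[-nrow(g)])) {
      warning("overlapping CNV segments on the same clone (kept as given)")
      break
    }
  }
  cs_log("read_cnv_bed", path = path, n = nrow(out))
  out
}

#' Clone-tree JSON serialization
#'
#' `write_clone_tree()` and `read_clone_tree()` form a lossless round trip:
#' clone ids, parent map (root parent `null`), mutations, CNV segments and
#' allele states are preserved.
#'
#' @param tree A [clone_tree()].
#' @param path JSON file path.
#' @return `write_clone_tree()` returns `path` invisibly; `read_clone_tree()`
#'   a [clone_tree()].
#' @export
write_clone_tree <- function(tree, path) {
  obj <- list(
    clone_ids = tree$clone_ids,
    parent = as.list(ifelse(is.na(tree$parent), NA, tree$parent)),
    mutations = tree$mutations,
    cnv_segments = tree$cnv_segments,
    allele_state = tree$allele_state
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null", na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_clone_tree
#' @export
read_clone_tree <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  parent <- unlist(lapply(obj$parent, function(v) if (is.null(v)) NA_character_ else v))
  parent <- parent[obj$clone_ids]
  names(parent) <- obj$clone_ids
  clone_tree(
    parent = parent,
    mutations = tibble::as_tibble(obj$mutations),
    cnv_segments = if (length(obj$cnv_segments)) tibble::as_tibble(obj$cnv_segments) else NULL,
    allele_state = tibble::as_tibble(obj$allele_state)
  )
}

#' Clone-fraction TSV serialization
#'
#' Clones are rows, sections are columns; the first column (`clone`) holds
#' clone ids.
#'
#' @param fractions Clones x sections numeric matrix.
#' @param path TSV path.
#' @return The written path (invisibly) or the read matrix.
#' @export
write_fractions_tsv <- function(fractions, path) {
  write_expression_tsv(fractions, path, id_col = "clone")
}

#' @rdname write_fractions_tsv
#' @export
read_fractions_tsv <- function(path) {
  read_expression_tsv(path)
}
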