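#' Construct a single-cell count matrix
#'
#' A light container for a genes-by-cells matrix of non-negative integer
#' UMI counts, with unique gene and cell identifiers and a per-gene
#' mitochondrial flag. The flag drives the percent-mitochondrial QC metric.
#'
#' @param counts A genes x cells matrix (dense or [Matrix::sparseMatrix()])
#'   of non-negative integers. Row names are gene identifiers, column names
#'   cell identifiers; they may instead be supplied via `gene_ids` /
#'   `cell_ids`.
#' @param gene_ids,cell_ids Optional character vectors overriding dimnames.
#' @param mito_prefix Gene-identifier prefix marking mitochondrial genes
#'   (default `"MT-"`).
#' @param mito_flags Optional logical vector (length = number of genes)
#'   overriding the prefix rule.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, gene_ids = NULL, cell_ids = NULL,
                         mito_prefix = "MT-", mito_flags = NULL) {
  counts <- as_dgc(counts)
  if (!is.null(gene_ids)) rownames(counts) <- gene_ids
  if (!is.null(cell_ids)) colnames(counts) <- cell_ids
  gene_ids <- rownames(counts)
  cell_ids <- colnames(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    abort_input("count_matrix requires gene and cell identifiers")
  }
  if (anyDuplicated(gene_ids)) {
    abort_input("duplicate gene identifier: %s",
                gene_ids[duplicated(gene_ids)][1])
  }
  if (anyDuplicated(cell_ids)) {
    abort_input("duplicate cell identifier: %s",
                cell_ids[duplicated(cell_ids)][1])
  }
  v <- counts@x
  if (any(v < 0) || any(v != round(v))) {
    abort_input("counts must be non-negative integers")
  }
  if (is.null(mito_flags)) {
    mito_flags <- startsWith(gene_ids, mito_prefix)
  }
  stopifnot(length(mito_flags) == length(gene_ids))
  structure(
    list(counts = counts, mito_flags = mito_flags),
    class = "count_matrix"
  )
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' Gene and cell identifiers of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$counts)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$counts)

#' @export
print.count_matrix <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<count_matrix> %d genes x %d cells (%d mitochondrial genes)\n",
              d[1], d[2], sum(x$mito_flags)))
  invisible(x)
}

#' Subset the cells of a count matrix
#' @param x A `count_matrix`.
#' @param cells Character vector of cell identifiers or logical/integer index.
#' @return A `count_matrix` restricted to those cells; genes unchanged.
#' @export
subset_cells <- function(x, cells) {
  stopifnot(inherits(x, "count_matrix"))
  count_matrix(x$counts[, cells, drop = FALSE], mito_flags = x$mito_flags)
}
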