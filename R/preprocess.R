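#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the number of detected features (genes with
#' count > 0), the total count, and the percentage of mitochondrial reads,
#' and flags cells passing the standard droplet-QC rule: a cell fails when
#' features < `min_features` or counts < `min_counts` (the "features
#' and/or counts" rule) or when the mitochondrial percentage exceeds
#' `max_mito`. All inequalities are strict, so cells sitting exactly at a
#' threshold pass. An all-zero cell has `pct_mito = 0` by convention and
#' fails on the feature count. No cells are removed.
#'
#' @param counts A [count_matrix()].
#' @param min_features,min_counts,max_mito QC thresholds (defaults 500,
#'   500, and 20 percent).
#' @return A tibble with columns `cell_id`, `n_features`, `n_counts`,
#'   `pct_mito`, `pass`.
#' @export
compute_qc <- function(counts, min_features = 500, min_counts = 500,
                       max_mito = 20) {
  stopifnot(inherits(counts, "count_matrix"))
  if (any(dim(counts) == 0)) abort_input("empty count matrix")
  m <- counts$counts
  n_counts <- Matrix::colSums(m)
  n_features <- Matrix::colSums(m > 0)
  mito_counts <- Matrix::colSums(m[counts$mito_flags, , drop = FALSE])
  pct_mito <- ifelse(n_counts == 0, 0, 100 * mito_counts / n_counts)
  tibble(
    cell_id = cell_ids(counts),
    n_features = as.integer(n_features),
    n_counts = as.numeric(n_counts),
    pct_mito = as.numeric(pct_mito),
    pass = n_features >= min_features & n_counts >= min_counts &
      pct_mito <= max_mito
  )
}

#' Remove cells failing quality control
#'
#' Column-subsets a count matrix to the QC-passing cells; genes are never
#' removed and the input object is not modified.
#'
#' @param counts A [count_matrix()].
#' @param qc The QC tibble from [compute_qc()] computed on the same
#'   matrix.
#' @return A filtered [count_matrix()].
#' @export
filter_cells <- function(counts, qc) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!setequal(qc$cell_id, cell_ids(counts))) {
    abort_input("QC report does not match the count matrix cells")
  }
  keep <- qc$cell_id[qc$pass]
  if (length(keep) == 0) {
    abort_input("no cells pass quality control; nothing to keep")
  }
  subset_cells(counts, intersect(cell_ids(counts), keep))
}

#' Library-size log normalization
#'
#' Scales each cell to a common library size and log-transforms:
#' `value(g, c) = log(1 + scale * count(g, c) / total(c))` (natural log).
#' This is the standard log-normalization used before per-cell module
#' scoring; cells with zero total counts must be removed by QC first.
#'
#' @param counts A filtered [count_matrix()].
#' @param scale Target library size (default 10,000).
#' @return A `normalized_matrix`: a genes x cells dense numeric matrix of
#'   log-normalized values with attributes `scale` and `pseudocount`.
#' @export
log_normalize <- function(counts, scale = 10000) {
  stopifnot(inherits(counts, "count_matrix"), scale > 0)
  totals <- Matrix::colSums(counts$counts)
  if (any(totals == 0)) {
    abort_input("cell with zero total counts; run QC filtering first")
  }
  m <- as.matrix(counts$counts)
  out <- log1p(sweep(m, 2, totals / scale, "/"))
  structure(out, scale = scale, pseudocount = 1,
            mito_flags = counts$mito_flags,
            class = c("normalized_matrix", class(out)))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells (log1p, scale %g)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

#' Cell coordinates on the top principal components
#'
#' Projects cells onto the leading principal components of the
#' gene-centered log-normalized matrix. The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive, making
#' the output deterministic across linear-algebra backends.
#'
#' @param norm A `normalized_matrix` from [log_normalize()].
#' @param k Number of components (default 20).
#' @return A tibble: `cell_id`, `PC1` ... `PCk`.
#' @export
top_principal_components <- function(norm, k = 20) {
  stopifnot(inherits(norm, "normalized_matrix"))
  x <- t(unclass(norm))               # cells x genes
  if (k > min(dim(x))) {
    abort_input("k = %d exceeds the maximum rank %d", k, min(dim(x)))
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = k)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  scores <- sweep(pc$x, 2, flip, "*")
  out <- as_tibble(scores)
  names(out) <- paste0("PC", seq_len(ncol(out)))
  dplyr::bind_cols(tibble(cell_id = rownames(x)), out)
}
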