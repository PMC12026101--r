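#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv`, `barcodes.tsv` (optionally
#' `.gz`-compressed) under `dir`: a genes-as-rows sparse integer matrix
#' with 1-based indices, one feature id per line, one barcode per line.
#' Dimensions are checked for consistency, duplicate identifiers and
#' non-integer entries are rejected, and mitochondrial genes are flagged
#' by identifier prefix.
#'
#' @param dir Directory containing the triplet.
#' @param mito_prefix Prefix marking mitochondrial genes (default
#'   `"MT-"`).
#' @return A [count_matrix()].
#' @export
read_mtx_triplet <- function(dir, mito_prefix = "MT-") {
  find1 <- function(base) {
    for (f in file.path(dir, c(base, paste0(base, ".gz")))) {
      if (file.exists(f)) return(f)
    }
    abort_input("missing %s(.gz) in %s", base, dir)
  }
  mf <- find1("matrix.mtx")
  con <- if (endsWith(mf, ".gz")) gzfile(mf) else file(mf)
  m <- Matrix::readMM(con)
  features <- readr::read_tsv(find1("features.tsv"), col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  barcodes <- readr::read_tsv(find1("barcodes.tsv"), col_names = FALSE,
                              show_col_types = FALSE, progress = FALSE)
  if (nrow(features) != nrow(m)) {
    abort_input("features.tsv has %d rows but matrix has %d",
                nrow(features), nrow(m))
  }
  if (nrow(barcodes) != ncol(m)) {
    abort_input("barcodes.tsv has %d rows but matrix has %d columns",
                nrow(barcodes), ncol(m))
  }
  count_matrix(m, gene_ids = as.character(features[[1]]),
               cell_ids = as.character(barcodes[[1]]),
               mito_prefix = mito_prefix)
}

#' Write a count matrix as a 10x-style MTX triplet
#'
#' @param counts A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx_triplet <- function(counts, dir) {
  stopifnot(inherits(counts, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(counts$counts, file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(counts), file.path(dir, "features.tsv"))
  writeLines(cell_ids(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene signatures from a GMT file
#'
#' GMT: one tab-delimited line per set — name, description, then the
#' member genes. Malformed lines are rejected with their line number;
#' duplicate genes within a set are an error (signatures are sets).
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (signature name -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sigs <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort_input("malformed GMT line %d: fewer than 3 fields", i)
    }
    genes <- parts[-(1:2)]
    dup <- genes[duplicated(genes)]
    if (length(dup)) {
      abort_input("GMT line %d: set '%s' repeats gene '%s'",
                  i, parts[1], dup[1])
    }
    if (parts[1] %in% names(sigs)) {
      abort_input("GMT line %d: duplicate set name '%s'", i, parts[1])
    }
    sigs[[parts[1]]] <- genes
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path, descriptions = NULL) {
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  descriptions <- descriptions %||% rep("na", length(signatures))
  lines <- purrr::imap_chr(signatures, function(genes, name) {
    paste(c(name, descriptions[[match(name, names(signatures))]], genes),
          collapse = "\t")
  })
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a typed TSV table against a declared schema
#'
#' Reads a tab-separated table and validates that the declared columns
#' exist with the declared types; readers reject rather than coerce.
#'
#' @param path Path to the TSV.
#' @param schema Named character vector, column -> one of `"character"`,
#'   `"numeric"`.
#' @return A tibble.
#' @export
read_table_schema <- function(path, schema) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in names(schema)) {
    if (!col %in% names(tab)) {
      abort_input("%s: missing required column '%s'", path, col)
    }
    ok <- switch(schema[[col]],
                 character = is.character(tab[[col]]),
                 numeric = is.numeric(tab[[col]]),
                 abort_input("unknown schema type '%s'", schema[[col]]))
    if (!ok) {
      abort_input("%s: column '%s' is not of type %s", path, col,
                  schema[[col]])
    }
  }
  tab
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `log2FC`, `pvalue`, `padj` (strictly typed).
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_deg_table <- function(path) {
  tab <- read_table_schema(path, c(gene = "character", log2FC = "numeric",
                                   pvalue = "numeric", padj = "numeric"))
  if (anyDuplicated(tab$gene)) {
    abort_input("%s: duplicate gene id '%s'", path,
                tab$gene[duplicated(tab$gene)][1])
  }
  tab
}

#' Read a dense expression TSV (genes as rows, first column gene id)
#'
#' @param path Path to the TSV.
#' @return A tibble whose first column is `gene`.
#' @export
read_expression_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  names(tab)[1] <- "gene"
  if (!is.character(tab$gene)) abort_input("%s: gene column must be text", path)
  if (anyDuplicated(tab$gene)) {
    abort_input("%s: duplicate gene id '%s'", path,
                tab$gene[duplicated(tab$gene)][1])
  }
  if (!all(vapply(tab[-1], is.numeric, logical(1)))) {
    abort_input("%s: non-numeric sample column", path)
  }
  tab
}
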