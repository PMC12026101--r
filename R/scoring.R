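#' Partition genes into expression bins
#'
#' Orders genes by their mean log-normalized expression across cells
#' (ties broken by gene identifier, C-locale order) and cuts the ordering
#' into `nbins` near-equal bins. The bins supply expression-matched
#' control genes for [module_score()].
#'
#' @param norm A `normalized_matrix` from [log_normalize()], or any
#'   genes x cells numeric matrix with rownames.
#' @param nbins Number of bins (default 30).
#' @return A tibble: `gene`, `mean_expr`, `bin` (1-based, non-decreasing
#'   in mean expression).
#' @export
bin_genes_by_mean <- function(norm, nbins = 30) {
  stopifnot(nbins >= 1)
  genes <- rownames(norm)
  if (length(genes) < nbins) {
    abort_input("fewer genes (%d) than bins (%d)", length(genes), nbins)
  }
  means <- rowMeans(unclass(norm))
  ord <- order(means, genes, method = "radix")
  bin <- integer(length(genes))
  bin[ord] <- ceiling(seq_along(ord) * nbins / length(ord))
  tibble(gene = genes, mean_expr = unname(means), bin = bin)
}

#' Per-cell gene-module scores with binned control genes
#'
#' For each signature, the score of a cell is the mean log-normalized
#' expression of the signature genes minus the mean expression of a
#' control gene pool. The pool is assembled once per signature per run:
#' for every signature gene, `ctrl` genes are sampled without replacement
#' from that gene's expression bin (all of them if the bin is smaller),
#' and the union of the draws forms the pool. Genes absent from the
#' matrix are dropped with a warning provided at least one remains.
#'
#' A module score is therefore centred at zero for a gene set with no
#' coordinated expression: the controls are matched to the signature's
#' abundance profile, so depth and capture-efficiency effects cancel.
#'
#' @param norm A `normalized_matrix` (genes x cells).
#' @param signatures A named list of character vectors, or a single
#'   character vector (scored as signature `"signature"`).
#' @param nbins Number of expression bins (default 30).
#' @param ctrl Control genes sampled per signature gene (default 100).
#' @param seed Integer seed for the control draws.
#' @return A tibble with `cell_id` and one score column per signature;
#'   attributes `params` (nbins, ctrl, seed) and `control_genes` (the
#'   sampled pool per signature, for audit and oracle replay).
#' @export
module_score <- function(norm, signatures, nbins = 30, ctrl = 100,
                         seed = 1L) {
  if (is.character(signatures)) signatures <- list(signature = signatures)
  stopifnot(is.list(signatures), length(signatures) > 0,
            !is.null(names(signatures)))
  bins <- bin_genes_by_mean(norm, nbins)
  bin_of <- setNames(bins$bin, bins$gene)
  bin_members <- split(bins$gene, bins$bin)
  x <- unclass(norm)

  pools <- list()
  scores <- with_seed(seed, {
    purrr::imap(signatures, function(genes, name) {
      present <- genes[genes %in% rownames(x)]
      if (length(present) == 0) {
        abort_input("no gene of signature '%s' is present in the matrix",
                    name)
      }
      if (length(present) < length(genes)) {
        warning(sprintf(
          "signature '%s': dropped %d gene(s) absent from the matrix",
          name, length(genes) - length(present)
        ), call. = FALSE)
      }
      drawn <- unlist(lapply(present, function(g) {
        cand <- bin_members[[as.character(bin_of[[g]])]]
        cand[sample.int(length(cand), min(ctrl, length(cand)))]
      }))
      pool <- unique(drawn)
      pools[[name]] <<- pool
      unname(colMeans(x[present, , drop = FALSE]) -
               colMeans(x[pool, , drop = FALSE]))
    })
  })
  out <- dplyr::bind_cols(tibble(cell_id = colnames(x)),
                          as_tibble(scores))
  attr(out, "params") <- list(nbins = nbins, ctrl = ctrl, seed = seed)
  attr(out, "control_genes") <- pools
  out
}

#' Consolidate the six state scores into the four-state set
#'
#' Averages the paired mesenchymal and neural-progenitor scores
#' (`MES = (MES1 + MES2)/2`, `NPC = (NPC1 + NPC2)/2`) and passes the `AC`
#' and `OPC` columns through, yielding the four consolidated scores the
#' cell-state plot is defined on.
#'
#' @param scores A tibble with columns `MES1`, `MES2`, `AC`, `OPC`,
#'   `NPC1`, `NPC2` (plus any identifier columns, preserved).
#' @return A tibble with columns `MES`, `AC`, `OPC`, `NPC` replacing the
#'   six raw columns.
#' @export
average_paired_scores <- function(scores) {
  need <- c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")
  missing <- setdiff(need, names(scores))
  if (length(missing)) {
    abort_input("missing score column: %s", missing[1])
  }
  scores |>
    mutate(
      MES = (.data$MES1 + .data$MES2) / 2,
      NPC = (.data$NPC1 + .data$NPC2) / 2
    ) |>
    select(-dplyr::all_of(c("MES1", "MES2", "NPC1", "NPC2"))) |>
    dplyr::relocate(dplyr::any_of("cell_id"), "MES", "AC", "OPC", "NPC")
}

#' Single-sample gene-set enrichment score (ssGSEA)
#'
#' Ranks the genes of one sample by descending expression (ties broken by
#' gene identifier) and accumulates the difference between the weighted
#' in-set empirical CDF — weights are the rank values raised to `alpha`,
#' normalized over the set — and the uniform out-of-set empirical CDF.
#' The score is the sum of the differences over all rank positions. Being
#' rank-based, it is invariant under any strictly monotone transform of
#' the expression vector.
#'
#' @param expr Named numeric vector: one sample's expression over genes.
#' @param genes Character vector, the gene set.
#' @param alpha Rank-weighting exponent (default 0.75).
#' @return A single numeric enrichment score (raw, not rescaled).
#' @export
ssgsea_score <- function(expr, genes, alpha = 0.75) {
  stopifnot(is.numeric(expr), !is.null(names(expr)))
  if (any(!is.finite(expr))) abort_input("non-finite expression value")
  present <- intersect(genes, names(expr))
  if (length(present) == 0) {
    abort_input("gene set does not overlap the expression vector")
  }
  n <- length(expr)
  if (length(present) == n) {
    abort_input("degenerate gene set: covers every gene (empty complement)")
  }
  ord <- order(-expr, names(expr), method = "radix")
  in_set <- names(expr)[ord] %in% present
  rank_val <- n - seq_len(n) + 1           # top gene gets rank n
  w <- rank_val^alpha
  p_in <- cumsum(w * in_set) / sum(w[in_set])
  p_out <- cumsum(!in_set) / (n - length(present))
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample and signature of a bulk matrix
#'
#' @param expr A tibble/data.frame whose first column holds gene ids and
#'   remaining columns one sample each, or a genes x samples matrix.
#' @param signatures Named list of gene sets.
#' @param alpha Rank-weighting exponent (default 0.75).
#' @return A tibble: `sample_id` plus one score column per signature.
#' @export
ssgsea_scores <- function(expr, signatures, alpha = 0.75) {
  mat <- as_expression_matrix(expr)
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  res <- purrr::map(signatures, function(genes) {
    apply(mat, 2, ssgsea_score, genes = genes, alpha = alpha)
  })
  dplyr::bind_cols(tibble(sample_id = colnames(mat)), as_tibble(res))
}

# accept tibble-with-gene-column or matrix
as_expression_matrix <- function(expr) {
  if (is.matrix(expr)) {
    stopifnot(!is.null(rownames(expr)), !is.null(colnames(expr)))
    return(expr)
  }
  expr <- as.data.frame(expr)
  genes <- as.character(expr[[1]])
  if (anyDuplicated(genes)) {
    abort_input("duplicate gene identifier: %s",
                genes[duplicated(genes)][1])
  }
  mat <- as.matrix(expr[, -1, drop = FALSE])
  rownames(mat) <- genes
  storage.mode(mat) <- "double"
  mat
}

# GSEA running-sum enrichment score from hit positions in an ordered list.
# w: |metric| in list order; returns signed maximum deviation.
gsea_es <- function(w, hit) {
  n <- length(w)
  m <- sum(hit)
  nr <- sum(w[hit])
  inc <- if (nr > 0) w * hit / nr else hit / m
  run <- cumsum(inc - (!hit) / (n - m))
  run[which.max(abs(run))]
}

#' Preranked gene-set enrichment analysis
#'
#' Computes the classic weighted Kolmogorov–Smirnov-style enrichment
#' score on a ranked gene list: genes are ordered by descending metric
#' (ties broken by gene identifier), hits increment a running sum in
#' proportion to their absolute metric, misses decrement it uniformly,
#' and the score is the running sum's maximum deviation from zero. The
#' null is built by permuting gene labels — `n_perm` random sets of the
#' same size drawn from the list — giving a normalized enrichment score
#' `NES = ES / mean(|ES*|)` over the same-sign permutation scores, and a
#' permutation p-value `(1 + #{|ES*| >= |ES|}) / (n_perm + 1)`.
#'
#' @param ranked A tibble/data.frame with columns `gene` and `metric`
#'   (e.g. log2 fold change), or a named numeric vector.
#' @param genes Character vector, the gene set.
#' @param n_perm Number of gene-label permutations (default 1000).
#' @param seed Integer seed.
#' @param exhaustive If `TRUE`, enumerate every distinct same-size gene
#'   subset instead of sampling (only feasible for small lists); `n_perm`
#'   and `seed` are then ignored and the null is exact.
#' @return An object of class `gsea_result`: list with `ES`, `NES`,
#'   `p_value`, `n_genes`, `n_hits`, `n_perm`, `seed`, `warnings`.
#'   [tidy()] returns it as a one-row tibble.
#' @export
preranked_gsea <- function(ranked, genes, n_perm = 1000, seed = 1L,
                           exhaustive = FALSE) {
  if (is.numeric(ranked) && !is.null(names(ranked))) {
    ranked <- tibble(gene = names(ranked), metric = unname(ranked))
  }
  ranked <- as_tibble(ranked)
  stopifnot(all(c("gene", "metric") %in% names(ranked)))
  if (any(!is.finite(ranked$metric))) {
    abort_input("ranking metric must be finite")
  }
  if (anyDuplicated(ranked$gene)) {
    abort_input("duplicate gene in ranked list: %s",
                ranked$gene[duplicated(ranked$gene)][1])
  }
  ord <- order(-ranked$metric, ranked$gene, method = "radix")
  g <- ranked$gene[ord]
  w <- abs(ranked$metric[ord])
  hit <- g %in% genes
  n <- length(g)
  m <- sum(hit)
  if (m == 0) abort_input("gene set does not overlap the ranked list")
  if (m == n) abort_input("gene set covers the whole ranked list")
  es <- gsea_es(w, hit)
  if (exhaustive) {
    combos <- utils::combn(n, m)
    perm <- apply(combos, 2, function(pos) {
      h <- logical(n)
      h[pos] <- TRUE
      gsea_es(w, h)
    })
    n_perm <- ncol(combos)
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) {
        h <- logical(n)
        h[sample.int(n, m)] <- TRUE
        gsea_es(w, h)
      }, numeric(1))
    })
  }
  warnings <- character()
  if (n_perm < 10) {
    warnings <- "n_perm < 10: permutation statistics are unreliable"
  }
  same <- perm[sign(perm) == sign(es)]
  nes <- if (es == 0 || length(same) == 0) 0 else es / mean(abs(same))
  p <- (1 + sum(abs(perm) >= abs(es))) / (n_perm + 1)
  structure(
    list(ES = es, NES = nes, p_value = p, n_genes = n, n_hits = m,
         n_perm = n_perm, seed = seed, warnings = warnings),
    class = "gsea_result"
  )
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf(
    "<gsea_result> ES = %.4f, NES = %.4f, p = %.4g (%d/%d genes, %d perms)\n",
    x$ES, x$NES, x$p_value, x$n_hits, x$n_genes, x$n_perm))
  for (w in x$warnings) cat(" warning:", w, "\n")
  invisible(x)
}

#' @rdname preranked_gsea
#' @param x A `gsea_result`.
#' @param ... Unused.
#' @export
tidy.gsea_result <- function(x, ...) {
  tibble(ES = x$ES, NES = x$NES, p_value = x$p_value,
         n_genes = x$n_genes, n_hits = x$n_hits, n_perm = x$n_perm)
}

#' @rdname preranked_gsea
#' @export
glance.gsea_result <- function(x, ...) tidy(x)
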