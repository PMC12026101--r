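#' The six-gene immunosuppressive Treg-like (ITL) signature
#'
#' Returns the default TGFBR2-induced ITL gene set — *CD274* (PD-L1),
#' *NT5E* (CD73), *ENTPD1* (CD39), *LGALS1* (galectin-1), *PDCD1LG2*
#' (PD-L2), and *TGFB1* — the putative direct immunosuppressive effectors
#' shared between regulatory T cells and mesenchymal glioma stem cells.
#' Pass a different character vector anywhere a signature is accepted to
#' override it.
#'
#' @return Character vector of six gene symbols.
#' @export
itl_signature <- function() {
  c("CD274", "NT5E", "ENTPD1", "LGALS1", "PDCD1LG2", "TGFB1")
}

#' Significantly upregulated genes of a DE table
#'
#' Selects genes with `padj < padj_max` and `log2FC > lfc_min` (both
#' strict, so boundary rows are excluded), ordered by ascending adjusted
#' p then gene id for stability.
#'
#' @param table A DEG tibble with columns `gene`, `log2FC`, `pvalue`,
#'   `padj`.
#' @param padj_max Adjusted-p cutoff (default 0.05).
#' @param lfc_min log2 fold-change cutoff (default 0).
#' @return Character vector of gene ids.
#' @export
significant_up <- function(table, padj_max = 0.05, lfc_min = 0) {
  table <- as_tibble(table)
  need <- c("gene", "log2FC", "padj")
  missing <- setdiff(need, names(table))
  if (length(missing)) abort_input("missing DEG column: %s", missing[1])
  stopifnot(padj_max > 0, padj_max <= 1)
  hits <- table |>
    filter(.data$padj < padj_max, .data$log2FC > lfc_min) |>
    arrange(.data$padj, .data$gene)
  hits$gene
}

#' Intersect ordered gene lists stage by stage
#'
#' Computes the running intersection of two or more gene lists,
#' preserving the first list's order, and retains every stage list for
#' audit. This is the derivation step that nominates candidate genes
#' present in all contrasts (e.g. up in tumor vs normal, enriched in
#' mesenchymal tumors, and induced by reprogramming factors).
#'
#' @param lists Named (or unnamed) list of >= 2 character vectors.
#' @param thresholds Optional list of the thresholds that produced each
#'   stage, recorded in the result.
#' @return An `intersection_result`: list with `intersection` (character,
#'   in the first list's order), `stages`, `thresholds`. [tidy()] gives a
#'   per-stage summary tibble.
#' @export
intersect_stages <- function(lists, thresholds = NULL) {
  stopifnot(is.list(lists), length(lists) >= 2)
  lists <- purrr::map(lists, as.character)
  if (is.null(names(lists)) || any(names(lists) == "")) {
    names(lists) <- sprintf("stage%d", seq_along(lists))
  }
  inter <- Reduce(function(a, b) a[a %in% b], lists)
  structure(
    list(intersection = inter, stages = lists,
         thresholds = thresholds),
    class = "intersection_result"
  )
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf("<intersection_result> %d stage(s) -> %d gene(s)\n",
              length(x$stages), length(x$intersection)))
  if (length(x$intersection)) {
    cat(" ", paste(head(x$intersection, 10), collapse = ", "),
        if (length(x$intersection) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' @rdname intersect_stages
#' @param x An `intersection_result`.
#' @param ... Unused.
#' @export
tidy.intersection_result <- function(x, ...) {
  tibble(
    stage = names(x$stages),
    n_genes = unname(purrr::map_dbl(x$stages, length)),
    n_in_final = unname(purrr::map_dbl(x$stages,
                                       ~ sum(x$intersection %in% .x)))
  )
}

#' @rdname intersect_stages
#' @export
glance.intersection_result <- function(x, ...) {
  tibble(n_stages = length(x$stages),
         n_intersection = length(x$intersection))
}

#' Median high/low split of a cohort
#'
#' Labels samples strictly above the median of `values` as `"high"` and
#' samples at or below it as `"low"` (at-median ties go to `"low"`,
#' a fixed deterministic rule). Errors when every value is identical, as
#' no split exists.
#'
#' @param values Numeric vector, one value per sample.
#' @param sample_ids Optional sample identifiers.
#' @param gene_label Label of the split variable (e.g. `"CD44"`).
#' @return A tibble: `sample_id`, `value`, `group` (`"high"`/`"low"`),
#'   with attribute `median`.
#' @export
median_split <- function(values, sample_ids = NULL, gene_label = "gene") {
  stopifnot(is.numeric(values))
  if (length(values) < 2) abort_input("need at least 2 samples to split")
  if (any(!is.finite(values))) abort_input("non-finite value")
  if (diff(range(values)) == 0) {
    abort_input("all values identical: no median split exists for %s",
                gene_label)
  }
  med <- median(values)
  group <- ifelse(values > med, "high", "low")
  if (!any(group == "high")) {
    abort_input("median split for %s produced an empty high group",
                gene_label)
  }
  sample_ids <- sample_ids %||% sprintf("sample%d", seq_along(values))
  out <- tibble(sample_id = sample_ids, value = values, group = group)
  attr(out, "median") <- med
  attr(out, "gene_label") <- gene_label
  out
}

#' Detection status of genes in a single-cell matrix
#'
#' A gene is "detected" when it is nonzero in at least `min_frac` of
#' cells (inclusive); genes absent from the matrix are undetected. Used
#' to screen candidate effector genes — e.g. the canonical Treg master
#' regulators that are absent from glioma stem cells.
#'
#' @param norm A `normalized_matrix` or [count_matrix()].
#' @param genes Character vector of gene ids to screen.
#' @param min_frac Minimum detection fraction (default 0.01).
#' @return A tibble: `gene`, `frac_cells`, `detected`.
#' @export
detect_expressed <- function(norm, genes, min_frac = 0.01) {
  if (length(genes) == 0) abort_input("empty gene list")
  stopifnot(min_frac > 0, min_frac <= 1)
  x <- if (inherits(norm, "count_matrix")) norm$counts else unclass(norm)
  frac <- vapply(genes, function(g) {
    if (!g %in% rownames(x)) return(NA_real_)
    sum(x[g, ] > 0) / ncol(x)
  }, numeric(1), USE.NAMES = FALSE)
  tibble(
    gene = genes,
    frac_cells = ifelse(is.na(frac), 0, frac),
    detected = !is.na(frac) & frac >= min_frac
  )
}

#' Score the ITL signature in bulk samples or single cells
#'
#' `itl_score_bulk()` scores each bulk sample by ssGSEA
#' ([ssgsea_scores()]); `itl_score_cells()` scores each cell by the
#' binned-control module score ([module_score()]). Both record the
#' signature and parameters used.
#'
#' @param expr Bulk expression (tibble with gene column, or matrix).
#' @param norm A `normalized_matrix`.
#' @param signature Character vector (default [itl_signature()]).
#' @param alpha,nbins,ctrl,seed Passed to the underlying scorer.
#' @return A tibble: `sample_id`/`cell_id` and `ITL` score.
#' @export
itl_score_bulk <- function(expr, signature = itl_signature(),
                           alpha = 0.75) {
  out <- ssgsea_scores(expr, list(ITL = signature), alpha = alpha)
  attr(out, "signature") <- signature
  out
}

#' @rdname itl_score_bulk
#' @export
itl_score_cells <- function(norm, signature = itl_signature(),
                            nbins = 30, ctrl = 100, seed = 1L) {
  out <- module_score(norm, list(ITL = signature), nbins = nbins,
                      ctrl = ctrl, seed = seed)
  attr(out, "signature") <- signature
  out
}

#' Pairwise Pearson correlation panel with BH correction
#'
#' All-pairs Pearson correlations across the variable columns of a
#' samples x variables table, with two-sided p-values and
#' Benjamini–Hochberg adjustment applied over the upper triangle.
#' Zero-variance variables produce `NA` entries, flagged rather than
#' silently zeroed.
#'
#' @param score_table A tibble/data.frame of numeric columns (an optional
#'   `sample_id` column is ignored).
#' @return A `correlation_panel`: list of matrices `r`, `p`, `padj` and
#'   the sample size `n`. [tidy()] returns the upper triangle as a long
#'   tibble.
#' @export
correlation_panel <- function(score_table) {
  tab <- as_tibble(score_table)
  tab <- tab[, !names(tab) %in% c("sample_id", "cell_id"), drop = FALSE]
  stopifnot(all(vapply(tab, is.numeric, logical(1))))
  m <- as.matrix(tab)
  if (nrow(m) < 3) abort_input("need at least 3 observations")
  k <- ncol(m)
  r <- diag(1, k); p <- matrix(NA_real_, k, k)
  dimnames(r) <- dimnames(p) <- list(colnames(m), colnames(m))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (j <= i) next
      if (sd(m[, i]) == 0 || sd(m[, j]) == 0) {
        r[i, j] <- r[j, i] <- NA_real_
        next
      }
      ct <- cor.test(m[, i], m[, j], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  upper <- upper.tri(p)
  padj <- p
  padj[upper] <- p.adjust(p[upper], method = "BH")
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(r = r, p = p, padj = padj, n = nrow(m),
                 correction = "BH over the upper triangle"),
            class = "correlation_panel")
}

#' @export
print.correlation_panel <- function(x, ...) {
  cat(sprintf("<correlation_panel> %d variables, n = %d (BH-adjusted)\n",
              ncol(x$r), x$n))
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname correlation_panel
#' @param x A `correlation_panel`.
#' @param ... Unused.
#' @export
tidy.correlation_panel <- function(x, ...) {
  idx <- which(upper.tri(x$r), arr.ind = TRUE)
  tibble(
    var1 = rownames(x$r)[idx[, 1]],
    var2 = colnames(x$r)[idx[, 2]],
    r = x$r[idx],
    p_value = x$p[idx],
    padj = x$padj[idx],
    n = x$n,
    undefined = is.na(x$r[idx])
  )
}

#' Compare score distributions between groups
#'
#' Runs the named classical test — never auto-selected — on a per-
#' observation score split by group labels: two-sided Student's t
#' (`"t"`), one-way ANOVA with Tukey post hoc pairs (`"anova"`),
#' Mann–Whitney U (`"mann-whitney"`), or Kruskal–Wallis (`"kruskal"`).
#'
#' @param values Numeric vector of observations.
#' @param groups Vector of group labels, same length.
#' @param test One of `"t"`, `"anova"`, `"mann-whitney"`, `"kruskal"`.
#' @return A `group_comparison`: list with `test`, `statistic`,
#'   `p_value`, `n_per_group`, and for ANOVA a `tukey` tibble. [tidy()]
#'   returns a one-row summary.
#' @export
compare_groups <- function(values, groups,
                           test = c("t", "anova", "mann-whitney",
                                    "kruskal")) {
  test <- match.arg(test)
  stopifnot(length(values) == length(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort_input("need at least 2 groups")
  n_per <- table(groups)
  if (test %in% c("t", "anova") && any(n_per < 2)) {
    abort_input("group with fewer than 2 observations for a variance-based test")
  }
  two_group_only <- test %in% c("t", "mann-whitney")
  if (two_group_only && nlevels(groups) != 2) {
    abort_input("test '%s' requires exactly 2 groups", test)
  }
  tukey <- NULL
  res <- switch(
    test,
    "t" = {
      ht <- t.test(values ~ groups, var.equal = TRUE)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    "mann-whitney" = {
      ht <- suppressWarnings(
        wilcox.test(values ~ groups, exact = FALSE, correct = FALSE)
      )
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    "kruskal" = {
      ht <- kruskal.test(values, groups)
      list(statistic = unname(ht$statistic), p_value = ht$p.value)
    },
    "anova" = {
      fit <- aov(values ~ groups)
      sm <- summary(fit)[[1]]
      tk <- TukeyHSD(fit)$groups
      tukey <- tibble(
        pair = rownames(tk),
        diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
        p_adj = tk[, "p adj"]
      )
      list(statistic = sm[["F value"]][1],
           p_value = sm[["Pr(>F)"]][1])
    }
  )
  structure(
    list(test = test, statistic = res$statistic, p_value = res$p_value,
         n_per_group = as.list(n_per), tukey = tukey),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.4f, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  cat(" n per group:",
      paste(sprintf("%s=%d", names(x$n_per_group),
                    unlist(x$n_per_group)), collapse = ", "), "\n")
  if (!is.null(x$tukey)) {
    cat(" Tukey pairs:\n"); print(as.data.frame(x$tukey))
  }
  invisible(x)
}

#' @rdname compare_groups
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(test = x$test, statistic = x$statistic, p_value = x$p_value,
         n_groups = length(x$n_per_group))
}

#' @rdname compare_groups
#' @export
glance.group_comparison <- function(x, ...) tidy(x)
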