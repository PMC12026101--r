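test_that("significant_up applies strict thresholds with stable order", {
  tab <- tibble::tibble(
    gene = c("A", "B", "C", "D", "E"),
    log2FC = c(2, 1.5, 0, -2, 0.5),
    pvalue = c(1e-6, 1e-4, 1e-6, 1e-6, 0.05),
    padj = c(1e-5, 1e-3, 1e-5, 1e-5, 0.05)
  )
  # boundary rows (padj == cutoff, log2FC == cutoff) are excluded
  expect_equal(significant_up(tab, padj_max = 0.05, lfc_min = 0),
               c("A", "B"))
  expect_equal(significant_up(tab, padj_max = 1e-5, lfc_min = 0),
               character(0))
  # order: ascending padj, then gene id
  tied <- tibble::tibble(gene = c("Z", "Y"), log2FC = c(1, 1),
                         pvalue = c(0.001, 0.001), padj = c(0.01, 0.01))
  expect_equal(significant_up(tied), c("Y", "Z"))
  expect_equal(significant_up(tab[0, ]), character(0))
  expect_error(significant_up(dplyr::select(tab, -padj)),
               class = "itlsig_input_error")
})

test_that("intersect_stages preserves the first list's order", {
  res <- intersect_stages(list(up = c("d", "b", "a", "c"),
                               mes = c("a", "b", "x"),
                               os = c("b", "a", "y")))
  expect_equal(res$intersection, c("b", "a"))
  expect_equal(tidy(res)$n_genes, c(4, 3, 3))
  expect_equal(glance(res)$n_intersection, 2)
  # disjoint and nested cases
  expect_length(intersect_stages(list(c("a"), c("b")))$intersection, 0)
  expect_equal(intersect_stages(list(c("c", "b", "a"),
                                     c("a", "b")))$intersection,
               c("b", "a"))
  expect_error(intersect_stages(list(c("a"))))
})

test_that("median_split applies the documented tie rule", {
  s <- median_split(1:10)
  expect_equal(sum(s$group == "high"), 5)
  expect_equal(sum(s$group == "low"), 5)

  tied <- median_split(c(1, 2, 2, 3), gene_label = "CD44")
  expect_equal(tied$group, c("low", "low", "low", "high"))

  withr::with_seed(3, v <- rnorm(501))
  big <- median_split(v)
  expect_equal(nrow(big), 501)
  expect_lte(max(big$value[big$group == "low"]), median(v))
  expect_gte(min(big$value[big$group == "high"]), median(v))

  expect_error(median_split(rep(2, 6)), class = "itlsig_input_error")
  expect_error(median_split(3), class = "itlsig_input_error")
})

test_that("detect_expressed honours the inclusive detection fraction", {
  x <- matrix(0L, 600, 100)
  rownames(x) <- c(sprintf("G%03d", 1:599), "MT-01")
  colnames(x) <- sprintf("c%03d", 1:100)
  x[, ] <- 1L
  x["G001", ] <- 0L                      # all-zero gene
  x["G002", ] <- c(1L, rep(0L, 99))      # exactly 1% of cells
  norm <- log_normalize(count_matrix(x))
  det <- detect_expressed(norm, c("G001", "G002", "G003", "ABSENT"),
                          min_frac = 0.01)
  expect_equal(det$detected,
               c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(det$frac_cells[2], 0.01)
  expect_error(detect_expressed(norm, character(0)),
               class = "itlsig_input_error")
})

test_that("per-cell ITL score is higher in MES cells when planted", {
  sim <- simulate_sc_counts(
    sim_config(n_cells_per_state = 40, n_background_genes = 600,
               uplift = 4, itl_genes = itl_signature(), seed = 51)
  )
  norm <- log_normalize(sim$counts)
  itl <- itl_score_cells(norm, seed = 2)
  lab <- state_labels4(sim$truth)[itl$cell_id]
  expect_gt(mean(itl$ITL[lab == "MES"]), mean(itl$ITL[lab != "MES"]))
  expect_identical(itl_score_cells(norm, seed = 2)$ITL, itl$ITL)
})

test_that("correlation_panel matches cor.test and flags zero variance", {
  withr::with_seed(61, {
    n <- 400
    z <- rnorm(n)
    tab <- tibble::tibble(
      a = z,
      b = -0.8 * z + sqrt(1 - 0.64) * rnorm(n),
      c = rnorm(n),
      flat = rep(1, n)
    )
  })
  panel <- correlation_panel(tab)
  expect_equal(diag(panel$r), rep(1, 4), ignore_attr = TRUE)
  expect_equal(panel$r["a", "b"], -0.8, tolerance = 0.1 / 0.8)
  expect_true(is.na(panel$r["a", "flat"]))
  expect_equal(panel$r, t(panel$r))
  # p and BH agree with direct recomputation over the upper triangle
  ct <- cor.test(tab$a, tab$b)
  expect_equal(panel$p["a", "b"], ct$p.value, tolerance = 1e-12)
  up <- panel$p[upper.tri(panel$p)]
  expect_equal(panel$padj[upper.tri(panel$padj)],
               p.adjust(up, "BH"), tolerance = 1e-12)
  # permuting sample order leaves the panel unchanged
  withr::with_seed(62, perm <- sample(n))
  panel2 <- correlation_panel(tab[perm, ])
  expect_equal(panel2$r, panel$r, tolerance = 1e-12)
  td <- tidy(panel)
  expect_equal(nrow(td), choose(4, 2))
  expect_true(td$undefined[td$var2 == "flat" & td$var1 == "a"])
  expect_error(correlation_panel(tab[1:2, ]), class = "itlsig_input_error")
})

test_that("compare_groups runs the named classical tests", {
  withr::with_seed(71, {
    g1 <- rnorm(50)
    g2 <- rnorm(50) + 3          # 3 pooled SDs apart
  })
  vals <- c(g1, g2)
  grp <- rep(c("A", "B"), each = 50)

  shifted_t <- compare_groups(vals, grp, "t")
  expect_lt(shifted_t$p_value, 0.001)
  shifted_mw <- compare_groups(vals, grp, "mann-whitney")
  expect_lt(shifted_mw$p_value, 0.001)

  # identical distributions: Mann-Whitney p = 1 under tie handling
  same <- compare_groups(rep(c(1, 2, 3), 2), rep(c("A", "B"), 3),
                         "mann-whitney")
  expect_equal(same$p_value, 1)

  # Kruskal-Wallis with k = 2 agrees with the two-sided Mann-Whitney
  withr::with_seed(72, {
    v <- rnorm(60) + rep(c(0, 0.6), each = 30)
  })
  g <- rep(c("A", "B"), each = 30)
  kw <- compare_groups(v, g, "kruskal")
  mw <- compare_groups(v, g, "mann-whitney")
  expect_equal(kw$p_value, mw$p_value, tolerance = 1e-10)

  # ANOVA carries the Tukey pairwise table
  withr::with_seed(73, {
    v3 <- rnorm(90) + rep(c(0, 1, 2), each = 30)
  })
  g3 <- rep(c("A", "B", "C"), each = 30)
  av <- compare_groups(v3, g3, "anova")
  expect_lt(av$p_value, 1e-4)
  expect_equal(nrow(av$tukey), 3)
  expect_equal(tidy(av)$n_groups, 3)

  expect_error(compare_groups(v3, g3, "t"), "2 groups")
  expect_error(compare_groups(c(1, 2, 3), c("A", "A", "B"), "t"),
               class = "itlsig_input_error")
  expect_error(compare_groups(1:4, rep("A", 4), "kruskal"),
               class = "itlsig_input_error")
})

test_that("bulk ITL scoring separates planted subtypes", {
  planted <- tibble::tibble(gene = "TGFBR2", signature = "ITL", r = 0.8)
  cohort <- simulate_bulk_cohort(
    120, planted, signatures = list(ITL = itl_signature()), seed = 81
  )
  scores <- itl_score_bulk(cohort$expr)
  joined <- dplyr::left_join(scores, cohort$samples,
                             by = c(sample_id = "sample_id"))
  cmp <- compare_groups(joined$ITL, joined$subtype == "Mesenchymal",
                        "mann-whitney")
  expect_lt(cmp$p_value, 0.01)
  expect_gt(mean(joined$ITL[joined$subtype == "Mesenchymal"]),
            mean(joined$ITL[joined$subtype == "Proneural"]))
})
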