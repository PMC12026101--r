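test_that("bin_genes_by_mean partitions by mean with stable ties", {
  norm <- tiny_norm(n_genes = 300, n_cells = 8, seed = 1)
  bins <- bin_genes_by_mean(norm, nbins = 30)
  expect_equal(unname(table(bins$bin)), rep(10L, 30), ignore_attr = TRUE)
  # bin means are non-decreasing in bin index (sort-based oracle)
  bin_means <- tapply(bins$mean_expr, bins$bin, mean)
  expect_true(all(diff(bin_means) >= 0))
  # every gene in bin b has mean <= every gene in bin b+1
  ord <- bins[order(bins$mean_expr, bins$gene, method = "radix"), ]
  expect_true(all(diff(ord$bin) >= 0))

  # one gene per bin when nbins equals the gene count
  small <- tiny_norm(n_genes = 30, n_cells = 6, seed = 2)
  b30 <- bin_genes_by_mean(small, nbins = 30)
  expect_equal(sort(b30$bin), 1:30)
  expect_equal(b30$bin[order(b30$mean_expr, b30$gene, method = "radix")],
               1:30)

  # identical means: assignment follows identifier order
  flat <- matrix(1, 6, 4, dimnames = list(paste0("g", 6:1), paste0("c", 1:4)))
  bf <- bin_genes_by_mean(flat, nbins = 3)
  expect_equal(bf$bin[order(bf$gene, method = "radix")],
               c(1L, 1L, 2L, 2L, 3L, 3L))

  expect_error(bin_genes_by_mean(flat, nbins = 10),
               class = "itlsig_input_error")
})

test_that("module_score matches the recorded-draw oracle", {
  norm <- tiny_norm(n_genes = 50, n_cells = 20, seed = 3)
  sig <- list(SIG = rownames(norm)[c(4, 17, 23, 41)])
  ms <- module_score(norm, sig, nbins = 5, ctrl = 3, seed = 11)
  pool <- attr(ms, "control_genes")$SIG
  expect_equal(ms$SIG,
               oracle_module_score(unclass(norm), sig$SIG, pool),
               tolerance = 1e-12)
  # the pool really is drawn from the signature genes' bins
  bins <- bin_genes_by_mean(norm, nbins = 5)
  sig_bins <- bins$bin[match(sig$SIG, bins$gene)]
  expect_true(all(bins$bin[match(pool, bins$gene)] %in% sig_bins))
})

test_that("module_score is zero on a perfectly flat matrix", {
  flat <- matrix(3, 40, 6, dimnames = list(sprintf("g%02d", 1:40),
                                           sprintf("c%d", 1:6)))
  ms <- module_score(flat, list(S = c("g01", "g07")), nbins = 4,
                     ctrl = 5, seed = 1)
  expect_equal(ms$S, rep(0, 6))
})

test_that("module_score recovers a planted uplift as ctrl grows", {
  # signature genes shifted by +delta in every cell relative to bin-mates
  delta <- 0.8
  withr::with_seed(6, {
    base <- matrix(rnorm(400 * 10, mean = 5, sd = 0.01), 400, 10)
  })
  rownames(base) <- sprintf("g%03d", 1:400)
  colnames(base) <- sprintf("c%d", 1:10)
  sig <- c("g005", "g104", "g203")
  base[sig, ] <- base[sig, ] + delta
  ms <- module_score(base, list(S = sig), nbins = 2, ctrl = 150, seed = 4)
  expect_equal(mean(ms$S), delta, tolerance = 0.05)
})

test_that("module_score invariances hold", {
  norm <- tiny_norm(n_genes = 60, n_cells = 15, seed = 7)
  sig <- list(S = rownames(norm)[c(2, 9, 33)])
  ms <- module_score(norm, sig, nbins = 6, ctrl = 4, seed = 5)
  # cell permutation: same per-cell values
  withr::with_seed(8, cp <- sample(ncol(norm)))
  permed <- unclass(norm)[, cp]
  ms_p <- module_score(permed, sig, nbins = 6, ctrl = 4, seed = 5)
  expect_equal(setNames(ms_p$S, ms_p$cell_id)[ms$cell_id],
               setNames(ms$S, ms$cell_id), tolerance = 1e-12)
  # adding a constant to every gene in every cell cancels
  ms_c <- module_score(unclass(norm) + 2, sig, nbins = 6, ctrl = 4,
                       seed = 5)
  expect_equal(ms_c$S, ms$S, tolerance = 1e-12)
  # determinism per seed
  expect_identical(module_score(norm, sig, nbins = 6, ctrl = 4, seed = 5)$S,
                   ms$S)
})

test_that("module_score warns on absent genes and errors on no overlap", {
  norm <- tiny_norm(n_genes = 40, n_cells = 8)
  expect_warning(
    module_score(norm, list(S = c(rownames(norm)[1], "NOPE")),
                 nbins = 4, ctrl = 3, seed = 1),
    "dropped 1 gene"
  )
  expect_error(
    module_score(norm, list(GHOST = c("NO1", "NO2")), nbins = 4,
                 ctrl = 3, seed = 1),
    "GHOST"
  )
})

test_that("average_paired_scores averages the MES and NPC pairs", {
  tab <- tibble::tibble(
    cell_id = c("a", "b", "c"),
    MES1 = c(0.4, 0.1, -0.2), MES2 = c(0.4, 0.3, 0.6),
    AC = c(0, 0.2, 0.1), OPC = c(0.1, -0.1, 0),
    NPC1 = c(0.2, 0.5, 0), NPC2 = c(-0.2, 0.1, 0.4)
  )
  out <- average_paired_scores(tab)
  expect_equal(out$MES, (tab$MES1 + tab$MES2) / 2)
  expect_equal(out$NPC, (tab$NPC1 + tab$NPC2) / 2)
  expect_equal(out$AC, tab$AC)
  expect_equal(out$OPC, tab$OPC)
  expect_equal(out$MES[1], 0.4)   # identical pair passes through
  expect_equal(out$NPC[1], 0)     # symmetric pair cancels
  expect_error(average_paired_scores(dplyr::select(tab, -"MES2")), "MES2")
})

test_that("ssgsea_score matches the hand-unrolled ECDF oracle", {
  v <- tiny_expr_vector(n = 12, seed = 5)
  set <- names(v)[c(2, 7, 11)]
  expect_equal(ssgsea_score(v, set, alpha = 0.75),
               oracle_ssgsea(v, set, alpha = 0.75), tolerance = 1e-12)
  # a larger random case, several alphas
  w <- tiny_expr_vector(n = 40, seed = 9)
  setw <- names(w)[c(1, 5, 12, 30, 33)]
  for (a in c(0, 0.25, 0.75, 1)) {
    expect_equal(ssgsea_score(w, setw, alpha = a),
                 oracle_ssgsea(w, setw, alpha = a), tolerance = 1e-12)
  }
})

test_that("ssgsea_score is rank-invariant and rejects degenerate sets", {
  v <- tiny_expr_vector(n = 20, seed = 13)
  set <- names(v)[c(3, 8, 15)]
  s1 <- ssgsea_score(v, set)
  s2 <- ssgsea_score(exp(v / 2), set)        # strictly monotone transform
  s3 <- ssgsea_score(rank(v), set)
  expect_equal(s1, s2, tolerance = 1e-12)
  expect_equal(s1, s3, tolerance = 1e-12)
  expect_error(ssgsea_score(v, names(v)), "complement")
  expect_error(ssgsea_score(v, c("ZZ1", "ZZ2")), class = "itlsig_input_error")
})

test_that("ssgsea ranks ITL-loaded samples above ITL-poor samples", {
  genes <- c(itl_signature(), sprintf("BG%02d", 1:14))
  top <- setNames(c(20:15, 14:1), genes)      # ITL genes occupy top ranks
  bottom <- setNames(c(6:1, 20:7), genes)     # ITL genes at the bottom
  s_top <- itl_score_bulk(
    matrix(c(top, bottom), ncol = 2,
           dimnames = list(genes, c("hi", "lo")))
  )
  expect_gt(s_top$ITL[1], s_top$ITL[2])
})

test_that("preranked_gsea ES matches the running-sum oracle", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      n <- sample(15:50, 1)
      genes <- sprintf("g%02d", seq_len(n))
      metric <- round(rnorm(n, sd = 2), 3)
      set <- sample(genes, sample(3:6, 1))
      res <- preranked_gsea(tibble::tibble(gene = genes, metric = metric),
                            set, n_perm = 20, seed = 1)
      expect_equal(res$ES, oracle_gsea_es(metric, genes, set),
                   tolerance = 1e-12)
    }
  })
})

test_that("a first-ranked single-gene signature attains ES = 1", {
  ranked <- tibble::tibble(gene = letters[1:10], metric = seq(10, 1))
  res <- preranked_gsea(ranked, "a", n_perm = 50, seed = 1)
  expect_equal(res$ES, 1)
})

test_that("exhaustive NES and p match the enumeration oracle exactly", {
  ranked <- tibble::tibble(gene = sprintf("g%02d", 1:10),
                           metric = c(4.1, 3.2, 2.8, 1.9, 1.2, 0.7,
                                      -0.4, -1.1, -2.3, -3.0))
  set <- c("g01", "g03", "g07")
  res <- preranked_gsea(ranked, set, exhaustive = TRUE)
  orc <- oracle_gsea_exhaustive(ranked$metric, ranked$gene, set)
  expect_equal(res$ES, orc$ES, tolerance = 1e-12)
  expect_equal(res$NES, orc$NES, tolerance = 1e-12)
  expect_equal(res$p_value, orc$p_value, tolerance = 1e-12)
  expect_equal(res$n_perm, choose(10, 3))
  # Monte-Carlo converges to the exhaustive null (the +1 correction is
  # compared on the raw tail proportion, where it vanishes)
  mc <- preranked_gsea(ranked, set, n_perm = 20000, seed = 2)
  expect_equal(mc$NES, orc$NES, tolerance = 0.05)
  tail_prop <- mean(abs(orc$perm) >= abs(orc$ES))
  expect_equal(mc$p_value, tail_prop, tolerance = 0.1)
})

test_that("preranked_gsea input contracts", {
  ranked <- tibble::tibble(gene = letters[1:8], metric = 8:1)
  expect_error(preranked_gsea(ranked, c("zz")), class = "itlsig_input_error")
  expect_error(preranked_gsea(ranked, letters[1:8]),
               class = "itlsig_input_error")
  low <- preranked_gsea(ranked, c("a", "d"), n_perm = 5, seed = 1)
  expect_match(low$warnings, "unreliable")
  expect_equal(tidy(low)$ES, low$ES)
})

test_that("scores are deterministic given inputs, parameters and seed", {
  norm <- tiny_norm(n_genes = 60, n_cells = 10, seed = 23)
  sig <- list(S = rownames(norm)[c(5, 12)])
  expect_identical(module_score(norm, sig, nbins = 5, ctrl = 4, seed = 9),
                   module_score(norm, sig, nbins = 5, ctrl = 4, seed = 9))
  ranked <- tibble::tibble(gene = rownames(norm), metric = rev(seq_len(60)))
  r1 <- preranked_gsea(ranked, rownames(norm)[1:5], n_perm = 100, seed = 3)
  r2 <- preranked_gsea(ranked, rownames(norm)[1:5], n_perm = 100, seed = 3)
  expect_identical(tidy(r1), tidy(r2))
})
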