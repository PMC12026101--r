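# Independent brute-force oracles. Each re-derives the quantity it checks
# with plain loops and base R, never calling the implementation path.

# element-wise log-normalization recomputation
oracle_log_normalize <- function(counts_mat, scale = 10000) {
  out <- matrix(NA_real_, nrow(counts_mat), ncol(counts_mat),
                dimnames = dimnames(counts_mat))
  for (j in seq_len(ncol(counts_mat))) {
    tot <- sum(counts_mat[, j])
    for (i in seq_len(nrow(counts_mat))) {
      out[i, j] <- log(1 + scale * counts_mat[i, j] / tot)
    }
  }
  out
}

# module score recomputed per cell from the recorded control pool
oracle_module_score <- function(norm_mat, sig_genes, control_pool) {
  sig_genes <- intersect(sig_genes, rownames(norm_mat))
  vapply(seq_len(ncol(norm_mat)), function(j) {
    s <- 0
    for (g in sig_genes) s <- s + norm_mat[g, j]
    ctl <- 0
    for (g in control_pool) ctl <- ctl + norm_mat[g, j]
    s / length(sig_genes) - ctl / length(control_pool)
  }, numeric(1))
}

# ssGSEA by hand-unrolled ECDF accumulation
oracle_ssgsea <- function(expr, set_genes, alpha = 0.75) {
  df <- data.frame(gene = names(expr), value = unname(expr),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$value, df$gene, method = "radix"), ]
  n <- nrow(df)
  in_set <- df$gene %in% set_genes
  m <- sum(in_set)
  rank_val <- rev(seq_len(n))
  denom_in <- sum(rank_val[in_set]^alpha)
  total <- 0
  hits_w <- 0
  misses <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) hits_w <- hits_w + rank_val[i]^alpha else {
      misses <- misses + 1
    }
    total <- total + hits_w / denom_in - misses / (n - m)
  }
  total
}

# GSEA enrichment score by explicit running-sum walk
oracle_gsea_es <- function(metric, gene, set_genes) {
  df <- data.frame(gene = gene, metric = metric,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$metric, df$gene, method = "radix"), ]
  n <- nrow(df)
  hit <- df$gene %in% set_genes
  nr <- sum(abs(df$metric[hit]))
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(df$metric[i]) / nr else
      -1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# exhaustive-null NES and p by enumerating every same-size subset
oracle_gsea_exhaustive <- function(metric, gene, set_genes) {
  es <- oracle_gsea_es(metric, gene, set_genes)
  n <- length(gene)
  m <- sum(gene %in% set_genes)
  df <- data.frame(gene = gene, metric = metric,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$metric, df$gene, method = "radix"), ]
  combos <- combn(n, m)
  perm <- numeric(ncol(combos))
  for (k in seq_len(ncol(combos))) {
    perm[k] <- oracle_gsea_es(df$metric, df$gene,
                              df$gene[combos[, k]])
  }
  same <- perm[sign(perm) == sign(es)]
  list(
    ES = es,
    NES = if (es == 0 || !length(same)) 0 else es / mean(abs(same)),
    p_value = (1 + sum(abs(perm) >= abs(es))) / (length(perm) + 1),
    perm = perm
  )
}

# Fisher-z 95% confidence interval for a sample correlation
fisher_z_ci <- function(r_hat, n) {
  z <- atanh(r_hat)
  half <- qnorm(0.975) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

# rank-based AUC for a score separating positives from negatives
score_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
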