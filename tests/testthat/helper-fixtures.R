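# Small fixtures built in code at test time.

# deterministic dense count matrix with an MT- block
tiny_counts <- function(n_genes = 30, n_cells = 10, n_mito = 3,
                        seed = 42, lambda = 5) {
  withr::with_seed(seed, {
    x <- matrix(rpois(n_genes * n_cells, lambda), n_genes, n_cells)
    rownames(x) <- c(sprintf("G%03d", seq_len(n_genes - n_mito)),
                     sprintf("MT-%02d", seq_len(n_mito)))
    colnames(x) <- sprintf("c%02d", seq_len(n_cells))
    count_matrix(x)
  })
}

# normalized matrix straight from tiny_counts
tiny_norm <- function(...) log_normalize(tiny_counts(...))

# a named expression vector with unique values
tiny_expr_vector <- function(n = 12, seed = 5) {
  withr::with_seed(seed, {
    setNames(sample(seq_len(n) * 1.0), sprintf("g%02d", seq_len(n)))
  })
}

state_labels4 <- function(truth) {
  lab <- sub("[12]$", "", truth$cell_state_labels$state)
  setNames(lab, truth$cell_state_labels$cell_id)
}
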