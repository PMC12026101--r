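#' Simulation configuration for synthetic scRNA-seq counts
#'
#' Defines the ground-truth structure of a simulated droplet scRNA-seq
#' experiment: six planted transcriptional programs matching the GBM
#' cellular states (MES1, MES2, AC, OPC, NPC1, NPC2), a negative-binomial
#' count model, a mitochondrial gene block, and a fraction of cells forced
#' below quality-control thresholds.
#'
#' Marker genes of state *k* have negative-binomial mean
#' `uplift * nb_mean` in cells of state *k* and `nb_mean` everywhere else;
#' background genes have mean `nb_mean` in all cells. Mitochondrial reads
#' are added so that each cell's mitochondrial percentage is drawn
#' uniformly between `mito_fraction_low` and `mito_fraction_high`.
#'
#' @param n_cells_per_state Integer, cells simulated per state (same for
#'   all six states).
#' @param n_background_genes Integer, number of unstructured genes.
#' @param markers_per_state Integer, marker genes per state program.
#' @param uplift Multiplicative mean shift (> 1 for signal; exactly 1
#'   simulates a no-signal null) applied to a state's markers in its own
#'   cells.
#' @param nb_mean,nb_dispersion Baseline negative-binomial mean and
#'   dispersion (`size` in [stats::rnbinom()] terms).
#' @param mito_fraction_low,mito_fraction_high Per-cell mitochondrial read
#'   proportion is uniform on this interval.
#' @param frac_low_quality Fraction (relative to the normal cells) of
#'   additional cells binomially downsampled until they fail QC
#'   (< 500 detected features).
#' @param n_mito_genes Number of `MT-` prefixed genes carrying the
#'   mitochondrial reads.
#' @param itl_genes Optional character vector of extra gene names appended
#'   to both MES marker programs (used to plant an immunosuppressive
#'   Treg-like signature inside the mesenchymal state).
#' @param seed Integer seed; identical configurations and seeds yield
#'   byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cells_per_state = 200,
                       n_background_genes = 1000,
                       markers_per_state = 50,
                       uplift = 4,
                       nb_mean = 2,
                       nb_dispersion = 2,
                       mito_fraction_low = 0.01,
                       mito_fraction_high = 0.10,
                       frac_low_quality = 0,
                       n_mito_genes = 13,
                       itl_genes = character(),
                       seed = 1L) {
  cfg <- list(
    n_cells_per_state = as.integer(n_cells_per_state),
    n_background_genes = as.integer(n_background_genes),
    markers_per_state = as.integer(markers_per_state),
    uplift = uplift, nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    mito_fraction_low = mito_fraction_low,
    mito_fraction_high = mito_fraction_high,
    frac_low_quality = frac_low_quality,
    n_mito_genes = as.integer(n_mito_genes),
    itl_genes = as.character(itl_genes),
    seed = as.integer(seed)
  )
  if (cfg$n_cells_per_state < 1 || cfg$n_background_genes < 1 ||
      cfg$markers_per_state < 1 || cfg$n_mito_genes < 1) {
    abort_config("all dimension parameters must be >= 1")
  }
  if (cfg$uplift < 1) abort_config("uplift must be >= 1")
  if (cfg$nb_mean <= 0 || cfg$nb_dispersion <= 0) {
    abort_config("nb_mean and nb_dispersion must be positive")
  }
  if (cfg$mito_fraction_low < 0 || cfg$mito_fraction_high > 1 ||
      cfg$mito_fraction_low > cfg$mito_fraction_high) {
    abort_config("mito fractions must satisfy 0 <= low <= high <= 1")
  }
  if (cfg$frac_low_quality < 0 || cfg$frac_low_quality >= 1) {
    abort_config("frac_low_quality must be in [0, 1)")
  }
  structure(cfg, class = "sim_config")
}

sim_states <- c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")

#' Simulate a single-cell count matrix with planted state programs
#'
#' Draws a genes x cells matrix from the negative-binomial model described
#' in [sim_config()], together with a ground-truth record of every planted
#' feature: cell state labels, marker assignments, and which cells were
#' forced below QC thresholds by binomial downsampling.
#'
#' @param config A [sim_config()].
#' @return A list with elements `counts` (a [count_matrix()]) and `truth`,
#'   a list holding `cell_state_labels` (tibble: cell_id, state,
#'   low_quality), `marker_assignment` (named list state -> gene ids), and
#'   `signatures` (the marker lists as ready-to-score gene signatures).
#' @export
simulate_sc_counts <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    nps <- config$n_cells_per_state
    n_normal <- nps * length(sim_states)
    n_lq <- round(config$frac_low_quality * n_normal)

    bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
    markers <- lapply(sim_states, function(s) {
      sprintf("%s-M%03d", s, seq_len(config$markers_per_state))
    })
    names(markers) <- sim_states
    if (length(config$itl_genes)) {
      markers$MES1 <- c(markers$MES1, config$itl_genes)
      markers$MES2 <- c(markers$MES2, config$itl_genes)
    }
    mito_genes <- sprintf("MT-%02d", seq_len(config$n_mito_genes))
    nuclear <- c(bg_genes, unique(unlist(markers)))
    genes <- c(nuclear, mito_genes)

    states <- rep(sim_states, each = nps)
    if (n_lq > 0) {
      states <- c(states, sample(sim_states, n_lq, replace = TRUE))
    }
    n_cells <- length(states)
    cells <- sprintf("CELL%05d", seq_len(n_cells))
    low_quality <- c(rep(FALSE, n_normal), rep(TRUE, n_lq))

    # mean matrix is block-structured: build dense (desk-scale sizes)
    mu <- matrix(config$nb_mean, nrow = length(nuclear), ncol = n_cells,
                 dimnames = list(nuclear, cells))
    for (s in sim_states) {
      idx <- which(states == s)
      mu[markers[[s]], idx] <- config$uplift * config$nb_mean
    }
    x <- matrix(
      rnbinom(length(mu), size = config$nb_dispersion, mu = as.vector(mu)),
      nrow = nrow(mu), dimnames = dimnames(mu)
    )

    # mitochondrial block: per-cell proportion drawn uniformly, converted
    # to a mito read total and split multinomially across the MT- genes
    p_mito <- runif(n_cells, config$mito_fraction_low,
                    config$mito_fraction_high)
    nuc_tot <- colSums(x)
    mito_tot <- round(p_mito / (1 - p_mito) * nuc_tot)
    mt <- vapply(mito_tot, function(tot) {
      as.vector(rmultinom(1, tot, rep(1, config$n_mito_genes)))
    }, numeric(config$n_mito_genes))
    rownames(mt) <- mito_genes
    x <- rbind(x, mt)

    # forced low-quality cells: halve counts binomially until < 500 genes
    # are detected, giving QC filtering an unambiguous ground truth
    for (j in which(low_quality)) {
      while (sum(x[, j] > 0) >= 500) {
        x[, j] <- rbinom(nrow(x), size = x[, j], prob = 0.5)
      }
    }

    truth <- list(
      cell_state_labels = tibble(
        cell_id = cells,
        state = states,
        low_quality = low_quality
      ),
      marker_assignment = markers,
      signatures = markers
    )
    list(counts = count_matrix(x), truth = truth)
  })
}

#' Simulate a bulk expression cohort with planted gene-signature correlations
#'
#' Each signature is represented by a latent per-sample activity
#' \eqn{z \sim N(0,1)}; member genes are the latent plus small independent
#' noise, and each planted gene is generated as
#' \eqn{x = r z + \sqrt{1-r^2}\,\epsilon} so its population Pearson
#' correlation with the latent activity equals `r`. Samples are labelled
#' by molecular subtype from the tertiles of the first signature's
#' activity (top third "Mesenchymal", middle "Classical", bottom
#' "Proneural"), giving group comparisons a known ordering.
#'
#' @param n_samples Number of samples (columns).
#' @param planted A tibble/data.frame with columns `gene`, `signature`,
#'   `r` (|r| < 1): the planted gene-vs-signature correlations.
#' @param signatures Named list: signature name -> member gene ids.
#' @param n_noise_genes Unstructured genes appended to the matrix.
#' @param member_noise_sd Noise SD on signature member genes (small, so
#'   the mean of the members tracks the latent activity closely).
#' @param seed Integer seed.
#' @return List with `expr` (tibble, first column `gene`, one column per
#'   sample), `samples` (tibble: sample_id, subtype), and `truth`
#'   (`planted_correlations`, `signatures`, `latent` matrix).
#' @export
simulate_bulk_cohort <- function(n_samples,
                                 planted,
                                 signatures = list(
                                   ITL = sprintf("SIGGENE%02d", 1:10)
                                 ),
                                 n_noise_genes = 50,
                                 member_noise_sd = 0.1,
                                 seed = 1L) {
  planted <- as_tibble(planted)
  stopifnot(all(c("gene", "signature", "r") %in% names(planted)))
  if (any(abs(planted$r) >= 1)) {
    abort_config("planted correlations must satisfy |r| < 1")
  }
  if (!all(planted$signature %in% names(signatures))) {
    abort_config("planted signature not among the supplied signatures")
  }
  with_seed(seed, {
    samples <- sprintf("S%04d", seq_len(n_samples))
    latent <- vapply(names(signatures), function(s) rnorm(n_samples),
                     numeric(n_samples))
    rownames(latent) <- samples

    member_rows <- purrr::imap(signatures, function(genes, sig) {
      vals <- sapply(genes, function(g) {
        latent[, sig] + rnorm(n_samples, sd = member_noise_sd)
      })
      t(vals)
    })
    planted_rows <- t(mapply(function(g, sig, r) {
      r * latent[, sig] + sqrt(1 - r^2) * rnorm(n_samples)
    }, planted$gene, planted$signature, planted$r))
    if (nrow(planted)) rownames(planted_rows) <- planted$gene
    noise_rows <- matrix(rnorm(n_noise_genes * n_samples),
                         nrow = n_noise_genes,
                         dimnames = list(sprintf("NOISE%03d",
                                                 seq_len(n_noise_genes)),
                                         NULL))
    mat <- do.call(rbind, c(unname(member_rows),
                            if (nrow(planted)) list(planted_rows),
                            list(noise_rows)))
    colnames(mat) <- samples
    if (anyDuplicated(rownames(mat))) {
      abort_config("duplicate gene identifier in cohort: %s",
                   rownames(mat)[duplicated(rownames(mat))][1])
    }

    z1 <- latent[, 1]
    subtype <- cut(rank(z1, ties.method = "first"),
                   breaks = c(0, n_samples / 3, 2 * n_samples / 3,
                              n_samples),
                   labels = c("Proneural", "Classical", "Mesenchymal"))
    list(
      expr = tibble(gene = rownames(mat)) |>
        dplyr::bind_cols(as_tibble(mat)),
      samples = tibble(sample_id = samples,
                       subtype = as.character(subtype)),
      truth = list(planted_correlations = planted,
                   signatures = signatures,
                   latent = latent)
    )
  })
}

#' Simulate a triplet of differential-expression tables with a known
#' intersection
#'
#' Each table marks its planted gene set significantly upregulated
#' (adjusted p drawn below 0.05, log2 fold change in \[1, 4\]) and every
#' other universe gene non-significant (adjusted p >= 0.1). The triple
#' intersection of the planted sets is recorded as ground truth for the
#' signature-derivation pipeline.
#'
#' @param universe Character vector of gene ids.
#' @param planted_sets List of three character vectors, each a subset of
#'   `universe`.
#' @param contrasts Character vector of three contrast labels.
#' @param seed Integer seed.
#' @return List with `tables` (named list of DEG tibbles: gene, log2FC,
#'   pvalue, padj) and `truth` (`expected_intersection`, in `universe`
#'   order restricted to the first set's order downstream).
#' @export
simulate_deg_tables <- function(universe, planted_sets,
                                contrasts = c("GBM_vs_NT",
                                              "MES_vs_other",
                                              "OS_vs_ctrl"),
                                seed = 1L) {
  stopifnot(length(planted_sets) == 3, length(contrasts) == 3)
  for (s in planted_sets) {
    bad <- setdiff(s, universe)
    if (length(bad)) {
      abort_config("planted gene outside universe: %s", bad[1])
    }
  }
  with_seed(seed, {
    tables <- purrr::map2(planted_sets, contrasts, function(set, label) {
      up <- universe %in% set
      padj <- ifelse(up, runif(length(universe), 1e-10, 0.04),
                     runif(length(universe), 0.1, 1))
      tibble(
        gene = universe,
        log2FC = ifelse(up, runif(length(universe), 1, 4),
                        rnorm(length(universe), 0, 0.3)),
        pvalue = padj * runif(length(universe), 0.1, 1),
        padj = padj,
        contrast = label
      )
    })
    names(tables) <- contrasts
    list(
      tables = tables,
      truth = list(
        expected_intersection = Reduce(intersect, planted_sets),
        planted_sets = planted_sets
      )
    )
  })
}
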