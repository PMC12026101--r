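#' Configuration of an end-to-end analysis run
#'
#' Bundles every threshold, scoring parameter, input location and the
#' top-level seed of a pipeline run into one serializable object. The
#' configuration is written verbatim into the run manifest so a run can
#' be reproduced from its outputs alone. Stage seeds are expanded from
#' the single `seed` by a fixed labeling scheme, so each stage is also
#' independently reproducible.
#'
#' @param counts Input counts: a [count_matrix()], or a path to an MTX
#'   triplet directory.
#' @param signatures State signatures: a named list of gene sets
#'   (must include MES1, MES2, AC, OPC, NPC1, NPC2) or a GMT path.
#' @param itl_genes The ITL signature to score (default
#'   [itl_signature()]).
#' @param deg_tables Optional named list of DEG tibbles (or TSV paths)
#'   fed to the intersection stage.
#' @param min_features,min_counts,max_mito QC thresholds.
#' @param scale Log-normalization library size.
#' @param nbins,ctrl Module-score binning and control-pool parameters.
#' @param alpha ssGSEA weighting exponent.
#' @param n_perm GSEA permutations (reserved for GSEA stages).
#' @param padj_max,lfc_min DE significance thresholds.
#' @param min_frac Detection threshold for [detect_expressed()].
#' @param x_sign_convention Cell-state x-axis sign convention.
#' @param seed Top-level integer seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(counts, signatures, itl_genes = itl_signature(),
                       deg_tables = NULL,
                       min_features = 500, min_counts = 500,
                       max_mito = 20, scale = 10000,
                       nbins = 30, ctrl = 100, alpha = 0.75,
                       n_perm = 1000, padj_max = 0.05, lfc_min = 0,
                       min_frac = 0.01,
                       x_sign_convention = "neftel",
                       seed = 1L, out_dir = tempfile("itl_run_")) {
  structure(
    list(counts = counts, signatures = signatures, itl_genes = itl_genes,
         deg_tables = deg_tables, min_features = min_features,
         min_counts = min_counts, max_mito = max_mito, scale = scale,
         nbins = nbins, ctrl = ctrl, alpha = alpha, n_perm = n_perm,
         padj_max = padj_max, lfc_min = lfc_min, min_frac = min_frac,
         x_sign_convention = x_sign_convention,
         seed = as.integer(seed), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Scalar fields of [run_config()] may be set in a YAML file; `counts`,
#' `signatures` and `deg_tables` entries are interpreted as input paths.
#' Arguments passed directly to this function override the file
#' (call-site flags beat the file).
#'
#' @param path YAML file path.
#' @param ... Overrides for any [run_config()] argument.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  overrides <- list(...)
  y[names(overrides)] <- overrides
  do.call(run_config, y)
}

resolve_counts <- function(x) {
  if (inherits(x, "count_matrix")) x else read_mtx_triplet(x)
}

resolve_signatures <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) read_gmt(x)
  else x
}

#' Run the full analysis pipeline
#'
#' Executes, in order: quality control, cell filtering, log
#' normalization, six-state module scoring, pair averaging, cell-state
#' coordinates, per-cell ITL scoring and its correlation with the state
#' scores, and — when DEG tables are supplied — the significant-up /
#' intersection derivation. Every stage writes a plain-text output under
#' `config$out_dir`, and a JSON manifest records the configuration
#' snapshot, input hashes, and the MD5 of every output, so re-running an
#' identical configuration reproduces byte-identical payloads. A stage
#' failure aborts with the stage name attached.
#'
#' @param config A [run_config()].
#' @return A `run_manifest` list (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character()
  emit <- function(tab, name) {
    path <- file.path(config$out_dir, name)
    readr::write_tsv(tab, path, progress = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("stage '%s' failed: %s", name,
                           conditionMessage(e)),
                   class = "itlsig_stage_error", parent = e)
    })
  }

  counts <- stage("input", resolve_counts(config$counts))
  signatures <- stage("input", resolve_signatures(config$signatures))

  qc <- stage("qc", compute_qc(counts, config$min_features,
                               config$min_counts, config$max_mito))
  emit(qc, "qc.tsv")

  filtered <- stage("filter_cells", filter_cells(counts, qc))
  norm <- stage("normalize", log_normalize(filtered, config$scale))

  scores6 <- stage("module_score", module_score(
    norm, signatures[c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")],
    nbins = config$nbins, ctrl = config$ctrl,
    seed = stage_seed(config$seed, "module_score")
  ))
  emit(scores6, "module_scores.tsv")

  scores4 <- stage("average_pairs", average_paired_scores(scores6))
  states <- stage("cell_state", state_coordinates(
    scores4, x_sign_convention = config$x_sign_convention
  ))
  emit(states, "cell_states.tsv")

  itl <- stage("itl_score", itl_score_cells(
    norm, config$itl_genes, nbins = config$nbins, ctrl = config$ctrl,
    seed = stage_seed(config$seed, "itl_score")
  ))
  emit(itl, "itl_scores.tsv")

  state_cor <- stage("state_correlation", state_signature_correlation(
    scores4, itl$ITL, extra_name = "ITL"
  ))
  emit(state_cor, "itl_state_correlation.tsv")

  detect <- stage("detect_expressed", detect_expressed(
    norm, config$itl_genes, min_frac = config$min_frac
  ))
  emit(detect, "itl_detection.tsv")

  intersection <- NULL
  if (!is.null(config$deg_tables)) {
    degs <- stage("deg_input", purrr::map(config$deg_tables, function(t) {
      if (is.character(t)) read_deg_table(t) else as_tibble(t)
    }))
    ups <- stage("significant_up", purrr::map(
      degs, significant_up,
      padj_max = config$padj_max, lfc_min = config$lfc_min
    ))
    intersection <- stage("intersect_stages", intersect_stages(
      ups, thresholds = list(padj_max = config$padj_max,
                             lfc_min = config$lfc_min)
    ))
    path <- file.path(config$out_dir, "intersection.json")
    jsonlite::write_json(
      list(intersection = intersection$intersection,
           stages = intersection$stages,
           thresholds = intersection$thresholds),
      path, auto_unbox = TRUE, pretty = TRUE
    )
    outputs <- c(outputs, path)
  }

  cfg_snapshot <- config
  cfg_snapshot$counts <- if (is.character(config$counts)) {
    config$counts
  } else {
    "<in-memory count_matrix>"
  }
  cfg_snapshot$signatures <- if (is.character(config$signatures)) {
    config$signatures
  } else {
    "<in-memory signature list>"
  }
  cfg_snapshot$deg_tables <- if (is.null(config$deg_tables)) {
    NULL
  } else if (all(vapply(config$deg_tables, is.character, logical(1)))) {
    unlist(config$deg_tables)
  } else {
    "<in-memory DEG tables>"
  }

  manifest <- list(
    tool = "itlsig",
    version = as.character(packageVersion("itlsig")),
    config = unclass(cfg_snapshot),
    n_cells_in = ncol(counts$counts),
    n_cells_kept = ncol(filtered$counts),
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs))
  )
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  structure(c(manifest, list(path = manifest_path)),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> itlsig %s: %d cells in, %d kept, %d outputs\n",
              x$version, x$n_cells_in, x$n_cells_kept,
              length(x$outputs)))
  cat(" ", paste(names(x$outputs), collapse = ", "), "\n")
  invisible(x)
}
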