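#' Two-axis cell-state coordinates
#'
#' Maps every cell onto the two-dimensional GBM cellular-state plot from
#' its four consolidated module scores. The vertical coordinate is
#' `y = max(SCopc, SCnpc) - max(SCac, SCmes)`: positive y means the cell
#' is of OPC/NPC lineage, negative (or zero, by the documented tie rule)
#' AC/MES lineage. The horizontal coordinate is the within-lineage
#' contrast, `x = log2(|SCopc - SCnpc| + 1)` for OPC/NPC cells and
#' `x = log2(|SCac - SCmes| + 1)` for AC/MES cells. Under the default
#' `"neftel"` sign convention x is negative when the pair's first member
#' (OPC or AC) dominates and positive when the second (NPC or MES) does,
#' reproducing the four-quadrant state-plot layout; `"none"` leaves x as
#' the printed magnitude.
#'
#' @param scores A tibble with columns `cell_id` (optional), `MES`, `AC`,
#'   `OPC`, `NPC` — e.g. the output of [average_paired_scores()].
#' @param x_sign_convention `"neftel"` (default) or `"none"`.
#' @return A tibble of class `cell_state_points`: `cell_id`, the four
#'   scores, `x`, `y`, `lineage`, `state`.
#' @export
state_coordinates <- function(scores, x_sign_convention = c("neftel",
                                                            "none")) {
  x_sign_convention <- match.arg(x_sign_convention)
  scores <- as_tibble(scores)
  need <- c("MES", "AC", "OPC", "NPC")
  missing <- setdiff(need, names(scores))
  if (length(missing)) abort_input("missing score column: %s", missing[1])
  if (!"cell_id" %in% names(scores)) {
    scores$cell_id <- sprintf("cell%d", seq_len(nrow(scores)))
  }
  if (any(!is.finite(as.matrix(scores[need])))) {
    abort_input("non-finite module score")
  }
  y <- pmax(scores$OPC, scores$NPC) - pmax(scores$AC, scores$MES)
  opc_npc <- y > 0
  xmag <- ifelse(opc_npc,
                 log2(abs(scores$OPC - scores$NPC) + 1),
                 log2(abs(scores$AC - scores$MES) + 1))
  xsgn <- if (x_sign_convention == "neftel") {
    ifelse(opc_npc,
           sign(scores$NPC - scores$OPC),
           sign(scores$MES - scores$AC))
  } else {
    1
  }
  out <- tibble(
    cell_id = scores$cell_id,
    MES = scores$MES, AC = scores$AC, OPC = scores$OPC, NPC = scores$NPC,
    x = xsgn * xmag,
    y = y,
    lineage = ifelse(opc_npc, "OPC/NPC", "AC/MES"),
    state = assign_state(scores)
  )
  class(out) <- c("cell_state_points", class(out))
  out
}

#' Discrete cell-state assignment
#'
#' Labels each cell with the state whose consolidated module score is
#' largest; exact ties are broken by the fixed priority
#' MES > AC > OPC > NPC.
#'
#' @param scores A tibble with columns `MES`, `AC`, `OPC`, `NPC`.
#' @return Character vector of state labels, one per row.
#' @export
assign_state <- function(scores) {
  need <- c("MES", "AC", "OPC", "NPC")   # priority order for ties
  missing <- setdiff(need, names(scores))
  if (length(missing)) abort_input("missing score column: %s", missing[1])
  m <- as.matrix(as_tibble(scores)[need])
  if (any(!is.finite(m))) abort_input("non-finite module score")
  need[apply(m, 1, which.max)]
}

#' Correlate an external variable with the four state scores
#'
#' Pearson correlation (with two-sided p) between a per-cell variable —
#' a signature score or a single gene's expression — and each of the
#' four consolidated state scores. Zero-variance inputs yield `NA`
#' entries flagged in the output rather than a silent zero.
#'
#' @param scores A tibble with columns `MES`, `AC`, `OPC`, `NPC`.
#' @param extra Numeric vector, one value per row of `scores`.
#' @param extra_name Label for the variable (default `"extra"`).
#' @return A tibble: `state`, `variable`, `r`, `p_value`, `n`,
#'   `undefined` (TRUE where a variance was zero).
#' @export
state_signature_correlation <- function(scores, extra,
                                        extra_name = "extra") {
  need <- c("MES", "AC", "OPC", "NPC")
  stopifnot(all(need %in% names(scores)), length(extra) == nrow(scores))
  if (nrow(scores) < 3) abort_input("need at least 3 cells")
  purrr::map(need, function(s) {
    v <- scores[[s]]
    if (sd(v) == 0 || sd(extra) == 0) {
      tibble(state = s, variable = extra_name, r = NA_real_,
             p_value = NA_real_, n = length(v), undefined = TRUE)
    } else {
      ct <- cor.test(extra, v, method = "pearson")
      tibble(state = s, variable = extra_name, r = unname(ct$estimate),
             p_value = ct$p.value, n = length(v), undefined = FALSE)
    }
  }) |>
    dplyr::bind_rows()
}
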