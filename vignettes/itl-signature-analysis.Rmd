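---
title: "Mapping GBM cell states and the immunosuppressive Treg-like signature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping GBM cell states and the immunosuppressive Treg-like signature}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itlsig)
library(dplyr)
```

## The biological question

Glioblastoma (GBM) tumors contain malignant cells distributed across four
recurrent transcriptional states — mesenchymal-like (MES), astrocyte-like
(AC), oligodendrocyte-progenitor-like (OPC) and neural-progenitor-like
(NPC) — with the MES state linked to immune infiltration, therapy
resistance and poor prognosis. A subset of mesenchymal glioma stem cells
(GSCs) co-opts the effector repertoire of regulatory T cells: driven by
the TGFβ type II receptor (TGFBR2), these cells express a six-gene
immunosuppressive Treg-like (ITL) program — *CD274* (PD-L1), *NT5E*
(CD73), *ENTPD1* (CD39), *LGALS1* (galectin-1), *PDCD1LG2* (PD-L2) and
*TGFB1* — and suppress CD4+/CD8+ T cells without transdifferentiating
into Tregs (the canonical Treg regulators *FOXP3* and *CD25* are not
detected in these cells).

`itlsig` implements the computational battery behind that analysis as a
reusable, tested pipeline: single-cell QC and normalization, per-cell
module scoring, the two-axis cell-state mapping, single-sample and
preranked gene-set enrichment, the differential-expression intersection
that nominates signature genes, and correlation/group-comparison
statistics — all exercisable on a bundled synthetic-data generator with
known ground truth.

## Quality control and normalization

Cells are summarised by three metrics: detected features (genes with
count > 0), total counts, and the percentage of mitochondrial reads
(genes flagged by the configurable `MT-` identifier prefix). A cell
fails QC when features **< 500** or counts **< 500** or mitochondrial
percentage **> 20**. All three inequalities are strict, so a cell at
exactly 500 features or exactly 20% mitochondrial reads passes; the
"features and/or counts" rule is read as *fail if either* metric is
below 500. QC percentages use the raw totals of the unfiltered matrix,
the standard practice. An all-zero cell is assigned `pct_mito = 0` by
convention and fails on its feature count.

Filtered counts are library-size normalized and log-transformed:

$$v_{gc} = \log\!\left(1 + \mathrm{scale} \cdot
  \frac{x_{gc}}{\sum_g x_{gc}}\right), \qquad \mathrm{scale} = 10^4 .$$

We chose plain log normalization over a regularized negative-binomial
transform deliberately: every downstream statistic in this package is
either rank-based (ssGSEA, GSEA) or control-matched (module scores), so
it requires only a monotone, depth-corrected log-scale matrix — and the
closed-form transform is exactly reproducible by an element-wise oracle,
which a fitted regularization is not. Batch correction is out of scope;
the principal-component projection (`top_principal_components()`, k = 20
by default, component signs fixed by the largest-magnitude loading) is
provided to honor the standard processing contract but is not required
for scoring.

## Per-cell module scores

`module_score()` implements binned-control signature scoring. All genes
are ordered by mean expression and cut into `nbins = 30` near-equal bins
(ties broken by gene identifier in C-locale order, so the partition is
deterministic). For each signature gene, `ctrl = 100` control genes are
sampled without replacement from that gene's bin — the whole bin if it
is smaller — and the union of the draws forms one control pool per
signature per run. The cell's score is

$$SC = \overline{v}_{\text{signature}} - \overline{v}_{\text{control}},$$

the mean expression of the signature genes minus that of the pool.
Because controls are abundance-matched, the score is centred at zero
under exchangeable gene labels (verified by Monte-Carlo in the test
suite) and invariant to adding a constant to every gene. One control
draw is shared by all cells (not redrawn per cell), which both mirrors
the behavior users expect from the widely used single-cell toolkits and
makes the computation exactly replayable: the sampled pool is attached
to the result (`attr(x, "control_genes")`) so an independent
recomputation can verify every score to floating-point accuracy.

The six GBM state signatures (MES1, MES2, AC, OPC, NPC1, NPC2) are
scored per cell, then consolidated by pair averaging:
$SC_{mes} = (SC_{mes1} + SC_{mes2})/2$ and
$SC_{npc} = (SC_{npc1} + SC_{npc2})/2$.

## The two-axis cell-state map

For each cell, the vertical coordinate is

$$y = \max(SC_{opc}, SC_{npc}) - \max(SC_{ac}, SC_{mes}),$$

with $y > 0$ indicating OPC/NPC lineage and $y \le 0$ AC/MES lineage
(the measure-zero $y = 0$ tie is assigned to AC/MES, consistent with
"positive means OPC/NPC"). The horizontal coordinate is the
within-lineage contrast, $x = \log_2(|SC_{opc} - SC_{npc}| + 1)$ for
OPC/NPC cells and $x = \log_2(|SC_{ac} - SC_{mes}| + 1)$ for AC/MES
cells. Only the magnitude of x is defined by those formulas; the sign
convention is a genuinely open plotting choice, and we adopt the
four-quadrant layout — x < 0 when the pair's first member (OPC or AC)
dominates, x > 0 when the second (NPC or MES) does — exposed as
`x_sign_convention` (`"neftel"` or `"none"`). Discrete state labels are
the argmax of the four consolidated scores, with exact ties resolved by
the fixed priority MES > AC > OPC > NPC; assignment uses the
consolidated scores because the plot axes are defined on them. No
clipping or winsorization of extreme coordinates is applied.

## Enrichment statistics

**ssGSEA** (`ssgsea_score()`): genes of one sample are ranked by
descending expression (ties by identifier); with rank values $r_i$
(top gene = n) and weighting exponent $\alpha = 0.75$, the score is

$$\sum_{i=1}^{n} \left[
  \frac{\sum_{j \le i,\, j \in S} r_j^{\alpha}}
       {\sum_{j \in S} r_j^{\alpha}}
  - \frac{\#\{j \le i,\, j \notin S\}}{n - |S|} \right].$$

The raw score is reported without cohort-wise rescaling, matching the
originally published single-sample definition; α is exposed. A set
covering every gene leaves the out-of-set ECDF undefined and is rejected
as degenerate. Being rank-based, the score is invariant under strictly
monotone transforms of the expression vector.

**Preranked GSEA** (`preranked_gsea()`): the classic weighted running
sum on a list ranked by any user metric (default intent: log2 fold
change, since the analysis ranks a derived contrast rather than raw
replicates). Hits increment by $|m_i| / \sum_{hit} |m|$, misses
decrement by $1/(n - |S|)$, and ES is the signed maximum deviation. The
null permutes gene labels — same-size random sets — because the input is
a derived ranking with no sample-level replicates to permute.
$NES = ES / \overline{|ES^*|}$ over the same-sign permutation scores;
the p-value is the two-sided tail frequency
$(1 + \#\{|ES^*| \ge |ES|\})/(n_{perm} + 1)$, which has resolution
$1/(n_{perm}+1)$ and is uniform under the null (verified by a
Kolmogorov–Smirnov check in the tests). For lists small enough to
enumerate, `exhaustive = TRUE` replaces sampling with the complete
subset enumeration, making NES and p exact.

## Signature derivation and the statistical battery

The derivation pipeline intersects ordered gene lists from
differential-expression tables: `significant_up()` selects genes with
`padj < 0.05` and `log2FC > 0` (strict inequalities; thresholds exposed
and recorded in the result, since the original cutoffs are not printed),
and `intersect_stages()` takes the running intersection preserving the
first list's order, retaining each stage for audit. The battery around
it: `median_split()` dichotomizes cohorts at a gene's median (at-median
ties go to "low", a deterministic choice where no convention exists);
`detect_expressed()` calls a gene detected when nonzero in ≥ 1% of
cells (inclusive); `correlation_panel()` computes all-pairs Pearson r
with two-sided p and Benjamini–Hochberg adjustment over the upper
triangle (the correction is our addition, recorded in the output,
since correlation panels are typically reported with stars only);
zero-variance variables yield flagged `NA`s, never a silent 0.
`compare_groups()` runs exactly the named test — two-sided Student's t,
one-way ANOVA with Tukey post hoc pairs, Mann–Whitney U (normal
approximation with tie correction disabled, so identical samples give
p = 1), or Kruskal–Wallis — never auto-selected.

`itl_score_cells()` and `itl_score_bulk()` score the six-gene ITL set by
module score and ssGSEA respectively; both scorers are available for
pan-cancer panels, with the choice left as a configuration field.

## What the synthetic generator emulates — and what it does not

`simulate_sc_counts()` draws counts from a negative-binomial model
(mean/dispersion parameterization), the standard desk-scale surrogate
for droplet scRNA-seq. Its defaults define the study conditions used
throughout the tests: 200 cells per state, 1,000 background genes, 50
markers per state, uplift 4 (markers of a state have mean
`uplift × nb_mean` in their own cells), `nb_mean = 2`,
`nb_dispersion = 2`, and a 13-gene `MT-` block whose per-cell read
share is uniform on [1%, 10%] — comfortably inside the QC band, so
only deliberately planted cells fail QC. Those planted low-quality
cells are made by binomially halving a normal cell's counts until fewer
than 500 features remain, giving the QC stage unambiguous ground truth.
`itl_genes` plants a named set inside both MES programs so end-to-end
ITL recovery is testable. The generator does **not** simulate doublets,
ambient RNA, batch structure, UMI-level reads, or any realistic
library-size distribution (depth is controlled by `nb_mean` alone):
passing recovery tests therefore demonstrates the pipeline's
correctness on clean NB data, not robustness to those artifacts.

`simulate_bulk_cohort()` builds each signature from a latent N(0,1)
activity: member genes are the latent plus noise (SD 0.1), and a
planted gene with target correlation r is
$x = r z + \sqrt{1 - r^2}\,\epsilon$, so recovery can be judged against
Fisher-z intervals. `simulate_deg_tables()` plants significant-up sets
(padj in [1e-10, 0.04], log2FC in [1, 4]) against a non-significant
background (padj ≥ 0.1) and records the exact expected intersection.

## Numerical choices and problem sizes

All tie-breaking is by gene identifier in C-locale (radix) order —
determinism is preferred over fidelity to any particular toolkit's
internal ordering. Every stochastic operation takes an explicit seed and
runs on a private RNG stream; the pipeline expands one top-level seed
per stage by a fixed labeling scheme, so stages are independently
reproducible and two runs with the same configuration are byte-identical.
The test suite verifies the scoring implementations against brute-force
oracles on fixtures of up to 50 genes × 20 cells at 1e-10 relative
tolerance, calibrates nulls with 500 module-score draws and 200 GSEA
repetitions, and runs state/ITL recovery on five seeds of the default
1,200-cell configuration — sizes chosen so the whole suite completes in
well under a minute while keeping Monte-Carlo error far from the
acceptance margins.

## Known limitations

- No batch correction, doublet handling or highly-variable-gene
  selection; inputs are assumed to be single-batch matrices.
- DE tables are consumed, not fitted: the package does not re-implement
  a count-model DE engine.
- The ssGSEA cohort-normalization variant is not applied by default;
  users comparing across cohorts should standardize externally or use
  the module-score route.
- The curated candidate pool behind the six-gene signature is a
  narrative, not algorithmic, construct; `itl_signature()` is therefore
  a documented default, overridable everywhere it is consumed.
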