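---
title: "Methods: mapping niche ligands onto leukaemia receptor dependencies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mapping niche ligands onto leukaemia receptor dependencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichemapper)
```

## The problem

Aggressive myeloid leukaemias (blast-crisis CML, AML) grow inside a bone
marrow microenvironment whose stromal populations — mesenchymal stromal
cells, osteolineage cells, arteriolar and sinusoidal endothelium,
chondrocytes, fibroblasts — supply ligands to receptors on leukaemia
stem-enriched cells. Most genes differentially expressed in leukaemia are
irrelevant to therapy; the useful shortlist is the intersection of several
orthogonal lines of evidence. `nichemapper` encodes that intersection as a
reproducible, auditable cascade and adds the three downstream analyses that
typically follow it: temporal classification of ligand expression across
disease stages, survival-based receptor prioritization, and drug-synergy
quantification for the resulting therapeutic combinations.

## The receptor cascade

A gene survives the cascade when it is

1. **upregulated in disease**: BH-adjusted `p < 0.05` and `log2FC > 0` in a
   two-group comparison of disease vs healthy bulk RNA-seq, evaluated
   separately in two diseases and intersected into `both` /
   `bcCML_only` / `AML_only` categories;
2. **annotated as cell surface** in a user-supplied atlas, minus an explicit
   misannotation blacklist (genes carried by surface atlases but not truly
   on the surface; removals are tagged `misannotated`);
3. **a functional dependency**: depleted two-fold or more in an in vivo
   CRISPR dropout screen, aggregated as the per-gene median of guide
   log2 fold-changes with an inclusive cut at `-1` ("two-fold or more"
   includes exactly two-fold);
4. **matched to an enriched ligand**: the ligand–receptor table links it to
   at least one ligand carrying a passing enrichment call in at least one
   niche population. Receptors with no table entry are excluded as
   `no_known_ligand`; receptors whose ligands all fail are
   `no_enriched_ligand`.

Both significance boundaries are strict (`padj = 0.05` exactly is excluded),
matching the usual reading of "threshold of 0.05"; the screen cut is
inclusive. Guide aggregation uses the median for robustness to single
outlier guides; `mean` and `second_best` are available. The ledger
(`build_receptor_ledger()`) keeps every candidate with its flags and one
exclusion reason, and asserts the conservation identity
`candidates = survivors + sum(exclusions)` on every run.

### Differential expression model

The package uses a Welch t-test on `log2(cpm + 1)` with a pseudocount
fold-change `log2((cpm_d + 0.5)/(cpm_c + 0.5))`, not a negative-binomial
GLM. This is a deliberate design choice: the test is analytically
transparent, its null behaviour is verifiable against first principles
(the type-I error of the whole pipeline is checked at `alpha = 0.05` on
2,000 null genes), and planted-effect recovery — the property the cascade
actually depends on — is excellent at realistic effect sizes. For
publication-grade analysis of real counts a dispersion-shrinking NB model
is preferable; the module boundary (`de_test()` in, `DEResult` tibble out)
makes the swap trivial.

## Ligand enrichment

Marker testing follows the standard single-cell recipe: counts scaled to
10,000 per cell, `log1p`, one-vs-rest Wilcoxon rank-sum per population.
The rank-sum test uses mid-ranks, an exact two-sided p by enumeration of
all labelings when `n1 + n2 <= 10` (under which two identical samples give
`p = 1`), and otherwise a normal approximation with tie and continuity
corrections. A call passes at `padj < 0.05` (BH across all gene ×
population rows), `log2FC > 0` and detection fraction `pct_in >= 0.1` —
the detection gate mirrors common marker-test defaults and suppresses
ambient-level false calls. Effect sizes are capped at 5 only in the
exported `log2fc_capped` column, keeping circos sector widths readable
without touching the inference.

Interactome edges join cascade survivors to passing ligands through the
interaction table; each edge carries the set of passing populations and the
maximum capped fold-change, sorted deterministically so that identical
inputs give byte-identical edge lists.

## Temporal classification

Expression is summarised into a (gene × population × stage) tensor of mean
log-normalized expression and detection fractions over the four ordered
stages: naive, initiation (days 2–4), expansion (days 7–9), end (days
11–14). A (population, stage) is *expressed* when detection `>= theta_expr`
(default 0.1). The four classes, checked in the order lost > transient >
population_shift > steady with the first match winning:

* **lost** — expressed at naive in some population, expressed nowhere at
  the end stage. Lost requires the naive stage specifically: otherwise the
  transient template (off, on, on, off) would satisfy it and the two
  classes would be inseparable under the precedence order.
* **transient** — silent at naive, expressed at an interior stage, silent
  at the end.
* **population_shift** — some population expressed at every stage, and the
  top-expressing population differs between stages. A stage contributes to
  the shift test only when its top population dominates the runner-up by
  `theta_dom`-fold (default 2): without this guard every ubiquitously and
  evenly expressed gene gets called a shift because the noisy argmax
  jitters between comparable populations. Argmax ties break
  lexicographically by population label, which also makes the label
  invariant to population ordering.
* **steady** — one population expressed at all four stages with a
  trajectory coefficient of variation below `theta_cv` (default 0.5).

Anything else is `unclassified` (in practice: genes near the detection
boundary, or silent everywhere). The thresholds are free parameters of this
package — the four classes are defined in the literature by example, not by
rule — and all are arguments of `classify_trajectory()`.

Trajectory clustering z-scores each gene's stage profile within a
population, uses `1 - Pearson r` as distance and average-linkage
hierarchical clustering, and tags each cluster consensus as increasing /
decreasing / other. Z-scoring makes the clustering invariant to per-gene
affine rescaling (asserted by a property test); zero-variance genes go to a
dedicated flat cluster rather than contaminating the correlation matrix.
Cluster–pathway follow-up is available through `hypergeom_ora()`, an exact
upper-tail hypergeometric over-representation test.

Population-proportion drifts are tagged by the Spearman correlation between
stage index and proportion with `|rho| >= 0.8`; over four stages only a
perfectly monotone drift reaches that bound, which is the honest choice
with n = 4 points.

## Survival prioritization

Patients are split at the median expression of each receptor; values
strictly below the cutoff go low, values at or above go high, so 161
distinct values split 80/81. The log-rank statistic accumulates observed
minus expected events over distinct event times with the hypergeometric
variance (computed through the `survival` package and verified against an
independently coded accumulation on random datasets). The hazard ratio is
the closed-form O/E (Pike) estimator from the log-rank expected counts with
a log-scale normal CI — chosen over Cox partial likelihood because it is
closed-form, oracle-checkable, and adequate for two-group stratification;
Cox is deliberately out of scope.

`prioritize_receptors()` flags a receptor as poor-prognosis when the
BH-adjusted p across the tested panel is below `alpha` **and** `HR > 1`.
The direction gate means a protective association is never flagged. The
adjustment across the panel is a deliberate choice: screening ~22 receptors
against survival at raw `p < 0.05` would produce at least one false flag in
roughly half of all panels, which defeats the purpose of a shortlist;
`adjust = "none"` restores the raw behaviour and the raw p is always
reported.

## Drug synergy

The median-effect equation `fa/(1-fa) = (D/Dm)^m` is fitted by ordinary
least squares on `log10(fa/(1-fa))` vs `log10(D)` — the canonical
linearization, unweighted. Fractions affected of exactly 0 or 1 are
rejected rather than clipped: clipping silently manufactures leverage
points at arbitrary positions, and a rejected point is visible to the
analyst. The combination index `CI = d1/Dx1(fa) + d2/Dx2(fa)` is by
construction the sum of the normalized isobologram coordinates, and a sham
self-combination (one drug split against its own curve) gives `CI = 1`
identically — both are asserted as structural identities in the tests.

## The synthetic study generator

Each generator draws from a root seed plus a fixed per-dataset offset, so
every layer is independently and jointly reproducible; equal configurations
give byte-identical outputs, and the planted truth is emitted as a
machine-readable ledger. Default study conditions:

* **Bulk**: 2,000 genes, 10 samples per group per disease, negative
  binomial with `Var = mu + mu^2 * phi`, `phi = 0.1` (typical bulk RNA-seq
  biological dispersion), baseline means log-uniform on [5, 500], planted
  receptors at `log2FC = +2`. Two diseases share the control design. The
  moment structure is verified against an independent straight-loop
  gamma–Poisson sampler.
* **Screen**: 4 guides per gene, per-guide noise sd 0.3 in log2 space,
  planted dropouts at −1.5 (clearly past the −1 cut), plus dropout decoys
  that are not upregulated.
* **Niche**: four populations over four stages, 400 cells per stage,
  multinomial population assignment with MSC/osteolineage/arteriolar
  proportions rising and sinusoidal falling; Poisson counts with planted
  ligands at mean 5 in their expressing (population, stage) cells and an
  ambient background of 0.02 elsewhere. The background is kept well below
  the 0.1 detection threshold deliberately — with 0.05 the smallest
  populations would cross the threshold by chance often enough to make the
  planted classes non-separable by construction.
* **Survival**: 161 patients per receptor (the familiar TCGA-scale cohort),
  expression Normal(10, 1), exponential event times with rate
  `h0·exp(beta·(z − 10))`, `h0 = 0.08`, uniform censoring on (0, 30)
  (roughly 25% censoring), `beta = 1` for the two planted prognostic
  receptors. The exponential baseline is sufficient because the tested
  behaviour is log-rank/HR stratification, not hazard-shape estimation.
* **Synergy**: two drugs with `(m, Dm)` of (2, 1) and (1.5, 10), five-point
  dose grids at Dm × (0.25…4), and combination rows constructed so the
  planted combination index is 0.5 at every fraction affected.

What the generator does **not** emulate: sequencing-depth and batch
effects, UMI/ambient-RNA artifacts, doublets, dispersion trends across the
mean range, correlated genes, non-proportional hazards. Passing tests
therefore demonstrate that the pipeline's logic and statistics are correct
under clean planted conditions — not that any particular real dataset would
yield the same shortlist.

## Numerical and testing choices

* Exact rank-sum enumeration switches to the normal approximation above a
  pooled n of 10; both paths are compared against brute-force enumeration
  and `wilcox.test` in the suite.
* BH adjustment is checked against an independently coded step-down scan on
  random vectors; the hypergeometric tail against explicit combinatorial
  sums; Kaplan–Meier against a hand product-limit loop and the empirical
  survival function in the no-censoring limit.
* Log-rank degeneracies: zero variance with `O = E` returns `chi2 = 0`;
  zero variance with `O != E` is an error, not a silent NaN.
* Problem sizes in the replicated test suites (200 interactome-recovery
  replicates, 2,000 null log-rank replicates, 100 prognostic and noisy-fit
  replicates, 50 temporal replicates) were chosen to keep the whole suite
  around three minutes on one CPU while leaving Monte-Carlo error far
  smaller than the tested margins.
* All TSV/JSON emitters format doubles at 6 significant digits, making
  repeated runs at the same seed byte-identical — the determinism contract
  is asserted on files, not just in memory.

## The bundled worked-example fixture

`cascade_fixture()` ships a 38-gene candidate pool reproducing the
published audit counts (13 shared, 18 AML-only, 7 bcCML-only; 16
misannotated; 3 ligand-less; 4 without enriched ligands; 15 survivors).
The 16 blacklist names, the 7 excluded receptors and six well-known
receptors carry real gene symbols; the remaining names, the per-gene
category assignment and all ligand calls are synthetic placeholders, as the
underlying cohort data are not redistributable — the counts and the printed
gene lists are the fixture's factual content, and the files are suffixed
`_synthetic` accordingly.

## Known limitations

* The DE stand-in ignores count overdispersion structure; borderline genes
  near the significance boundary can differ from an NB-GLM analysis.
* Ligand "enrichment" is a marker test, not a ligand-activity model; a
  ligand expressed evenly across all populations is never called.
* The temporal classifier sees four stage means; it cannot distinguish a
  transient peak at day 2 from one at day 4 (both are "initiation"), and
  genes hovering at the detection threshold fall to `unclassified`.
* The O/E hazard ratio is biased towards the null relative to Cox when
  hazards are strongly non-proportional; with the exponential generator
  this is immaterial, with real registry data it may not be.
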