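# nichemapper

Leukaemia stem-enriched cells (LSCs) survive and expand inside the bone-marrow
stromal niche, and the ligands that niche supplies — from mesenchymal stromal
cells (MSCs), osteolineage cells and endothelial populations — engage surface
receptors on the leukaemia cells. `nichemapper` implements the computational
cascade that turns multi-omic evidence into a short, auditable list of
receptor–ligand axes worth testing at the bench, plus the downstream analyses
used to prioritize and validate them:

* **Receptor cascade** — two-group bulk differential expression (Welch t on
  `log2(cpm + 1)`, Benjamini–Hochberg FDR), filtered to genes upregulated in
  disease (`padj < 0.05`, `log2FC > 0`), annotated as cell surface, depleted
  two-fold or more in an in vivo CRISPR screen (per-gene guide median
  `log2FC <= -1`), cleaned with a 16-gene misannotation blacklist, and finally
  required to have a ligand that is significantly enriched in at least one
  niche population. Every candidate carries its filter flags and exclusion
  reason, so the audit trail (e.g. 38 candidates → 22 after blacklist → 15
  receptors with enriched niche ligands) is conserved by construction.
* **Ligand enrichment & interactome** — one-vs-rest Wilcoxon rank-sum marker
  tests per stromal population (exact by enumeration for small samples),
  enrichment calls gated on FDR, fold-change and detection fraction, and a
  deterministic receptor–ligand edge list with fold-changes capped at 5 for
  circos-style export.
* **Temporal classification** — stage-resolved expression over the four
  disease stages (naive, initiation, expansion, end), with each ligand
  assigned one of four trajectory classes: *steady*, *lost*, *transient*
  (up-then-down) or *population_shift* (expression persists but the
  expressing population changes), plus correlation-distance hierarchical
  clustering of trajectories and population-proportion drift tags.
* **Survival prioritization** — median-split stratification (strictly-below
  cutoff goes low, at-or-above goes high), Kaplan–Meier curves, the log-rank
  test, and the closed-form O/E (Pike) hazard ratio
  `HR = (O1/E1)/(O2/E2)` with `exp(log HR ± 1.96·sqrt(1/E1 + 1/E2))`
  confidence intervals.
* **Drug synergy** — Chou–Talalay median-effect analysis:
  `fa/(1-fa) = (D/Dm)^m` fitted by least squares on the linearized form,
  effective doses `Dx(fa) = Dm·(fa/(1-fa))^(1/m)`, and the combination index
  `CI = d1/Dx1(fa) + d2/Dx2(fa)` with normalized isobologram coordinates
  (CI < 1 synergy, 1 additivity, > 1 antagonism).
* **Synthetic multi-omic generator** — seeded, fully deterministic generators
  for every input layer (negative-binomial bulk counts, per-guide screen
  fold-changes, stage-labelled Poisson single-cell counts, interaction
  tables, exponential survival, dose–response curves) with a
  machine-readable ground-truth ledger, so the whole pipeline is testable
  end to end with planted signals.

Everything is tidyverse-native: functions take data frames (or count
matrices) and return tibbles, results chain with the pipe, fitted objects
have `tidy()`/`glance()` methods, and each result type has a ggplot2 helper
(`autoplot()`, `plot_combination_index()`, `plot_population_proportions()`,
...).

## Worked example

```r
library(nichemapper)

study  <- simulate_study(synth_config(seed = 1))  # planted ground truth
report <- run_all(study)
report
#> <pipeline_report>
#>   receptor candidates: 15 (both 11 / AML 2 / bcCML 2)
#>   misannotated removed: 3 -> post-blacklist 12
#>   ligand exclusions: 2 no known ligand, 2 no enriched ligand
#>   final receptors: 8; interactome edges: 8
#>   temporal classes: lost=2, population_shift=1, steady=43, transient=2, unclassified=12
#>   poor-prognosis receptors: REC02, REC01
```

The default study plants 8 true receptors (upregulated, surface-annotated,
screen dropouts, each with an enriched niche ligand), 2 receptors without any
known ligand, 2 whose ligands are never enriched, and 3 blacklisted
misannotations — and the report recovers exactly that structure: 15
candidates, 3 removed as misannotated, 2 + 2 excluded for ligand reasons, 8
survivors with all 8 planted receptor–ligand edges and no decoys. The two
receptors planted with an expression-dependent hazard (REC01, REC02) are the
only ones flagged as poor prognosis:

```r
head(report$prognosis, 4)
#>    gene cutoff n_low n_high   chi2        p     padj    hr hr_lo hr_hi poor_prognosis
#> 1 REC02  10.04    80     81 68.404 1.33e-16 1.60e-15 4.773 3.113  7.32           TRUE
#> 2 REC01  10.00    80     81 33.714 6.38e-09 3.83e-08 3.150 2.080  4.77           TRUE
#> 3 REC06   9.88    80     81  1.643 2.00e-01 8.00e-01 1.289 0.871  1.91          FALSE
#> 4 REC03  10.01    80     81  0.625 4.29e-01 9.40e-01 0.857 0.585  1.26          FALSE
```

Each row is one receptor's survival stratification on 161 patients: the
median split (80 low / 81 high), the log-rank chi-square and p, the BH
adjusted p across the tested panel, and the O/E hazard ratio of the
high-expression group with its 95% CI. `poor_prognosis` requires both
`padj < 0.05` and `HR > 1`.

The bundled worked-example fixture reproduces the published cascade counts
(38-candidate pool, 16-gene blacklist, 22 post-blacklist, 3 + 4 ligand
exclusions, 15 final receptors):

```r
cascade_fixture_counts()
#>   candidates blacklist_size post_blacklist no_known_ligand no_enriched_ligand survivors
#> 1         38             16             22               3                  4        15
```

Synergy analysis on the generated dose–response data recovers the planted
parameters exactly and quantifies the planted two-fold potency interaction:

```r
dose <- simulate_dose_response(synth_config(seed = 1))
f1 <- median_effect_fit(dose$single[dose$single$drug == "GES", ])
f1
#> <median_effect_fit> m = 2  Dm = 1  r = 1  (n = 5)
f2 <- median_effect_fit(dose$single[dose$single$drug == "venetoclax", ])
head(combination_index(f1, f2, dose$combo), 3)
#>      d1    d2  fa iso1 iso2  ci interpretation
#> 1 0.125 0.992 0.2 0.25 0.25 0.5        synergy
#> 2 0.164 1.421 0.3 0.25 0.25 0.5        synergy
#> 3 0.204 1.908 0.4 0.25 0.25 0.5        synergy
```

A combination index of 0.5 at every fraction affected means each drug
contributes half the dose additivity would require — the planted synergy.

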