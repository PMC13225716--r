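---
title: "Screening candidate regulators of Golgi organization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening candidate regulators of Golgi organization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiscreen)
```

## The problem and the model

Golgi organization varies across cancer cell lines even of the same tissue
origin: breast MDAMB231 and lung A549 cells keep a compact, organized Golgi
ribbon while breast MCF7 and lung CALU1 cells show a predominantly
disorganized Golgi. If a gene's expression level helps set that phenotype,
then comparing expression between a phenotype-discordant pair of cell lines
should enrich for its regulators. `golgiscreen` formalizes this intuition as
a four-stage prioritization pipeline over public-style inputs: a
Golgi-associated gene universe, a cell-line expression matrix (RPKM), a
protein-interaction edge list with per-channel confidences, and a curated
knockdown-evidence table.

The underlying model is deliberately simple and makes three assumptions
worth stating:

1. **Expression difference is a usable proxy for regulatory relevance.** No
   statistical test is performed on the RPKM values — with one profile per
   cell line there is no within-line replication — so the screen is a ranked
   fold-change filter, not an inference procedure.
2. **Concordance is evidence of causality.** If a gene is low in the
   disorganized line and its knockdown elsewhere in the literature
   disorganizes the Golgi, the expression difference plausibly explains the
   phenotype difference. This is scored, not assumed: discordant evidence
   still contributes (score 1), absence of evidence contributes nothing.
3. **Guilt by association.** A gene whose direct interactors regulate Golgi
   organization is more likely to do so itself; the count of such first-shell
   neighbors is the second score component, uncapped because restricting the
   interactor neighborhood would bias against hubs.

## Pipeline stages and their parameters

### Universe assembly

The universe is the union of an annotation-derived gene set (exact,
case-insensitive term matching on a flat gene-term table; no ontology
traversal, because a flat web-query export has already flattened the DAG)
and a curated regulator list. Symbols are compared after uppercase
normalization. Provenance (`annotation` / `curated` / `both`) is retained
per gene.

### Expression screen

For values $a$ (organized line) and $b$ (disorganized line), the symmetric
fold change is $\max(a,b)/\min(a,b)$. Symmetry is essential, not cosmetic: a
real regulator can be higher in the organized line of one cancer pair and
higher in the disorganized line of the other, so a one-directional screen
would silently discard valid candidates. Direction is kept as metadata
because the concordance score depends on it.

Tunable parameters, with defaults:

| parameter | default | units | rationale |
|---|---|---|---|
| `base_threshold` (breast) | 10 | fold-change ratio | a stringent cutoff sized so the passing set lands within the cap |
| `base_threshold` (lung) | 5 | fold-change ratio | the lung pair shows smaller expression contrasts |
| `cap` | 50 | genes | the adaptive top-N rule; see below |
| `pseudocount` | 0.01 | RPKM | used **only** when the smaller value is 0, so all nonzero ratios stay exact; 0.01 RPKM is below any meaningfully expressed gene |
| threshold comparison | `>=` | — | genes exactly at the threshold pass |

The **adaptive cap** handles the case where the base threshold is too
permissive: when more than `cap` genes pass, the effective threshold is
raised so that exactly the top `cap` genes by fold change remain, with ties
at the boundary broken by ascending symbol so the retained set is
deterministic. The table reports the realized `effective_threshold`.

### Literature concordance (score 1)

The phenotype a knockdown should reproduce, were the expression difference
causal, is the Golgi phenotype of the cell line where the gene is *lower*
expressed. The rubric is:

| knockdown phenotype | matches predicted? | score | rationale tag |
|---|---|---|---|
| reported, matches | yes | 2 | `concordant` |
| reported, differs, gene Golgi-involved | no | 1 | `involved_discordant` |
| reported, differs, not Golgi-involved | no | 1 | `discordant` |
| none reported | — | 0 | `no_data` |

The third row is a cell the rubric's published description does not name; we
score it 1 because knockdown data *do* exist (so not 0) and are not
concordant (so not 2) — the involvement flag then only differentiates the
rationale text. The full 3 × 2 × 2 input grid is pinned by an enumerated
truth-table test.

### Network neighbors (score 2)

Edges are filtered to one evidence channel (default `experimental`) at a
confidence cutoff (default 0.4). Scores supplied on the 0–1000 integer
convention are auto-detected (any value above 1) and divided by 1000.
Duplicate undirected pairs are merged by the per-channel maximum; self-loops
are dropped. Score 2 is the raw count of distinct neighbors inside the
universe — raw rather than binned, since the binning (if any) behind the
original rubric is not recoverable; a binning hook would be a thin wrapper
over this count.

### Selection and intersection

Combined score = score1 + score2; selection requires combined ≥ `cutoff`
(default 3). Missing score components default to 0 with a warning so a
partially curated evidence table still runs. Ranking order — combined
descending, then fold change descending, then symbol ascending — is our
choice (only "ranked" is specified by the screen this reimplements); it puts
the strongest total evidence first and is fully deterministic. Candidate
lists are intersected across cancer types on gene symbols.

## The synthetic-data generators

`synth_config()` + `simulate_bundle()` fabricate all five inputs with
planted ground truth, so every stage (and the whole pipeline) can be checked
for *exact* recovery:

* **Expression.** Each gene draws a log-normal baseline (meanlog 1,
  sdlog 0.8 — a plausible heavy-tailed RPKM spread with most genes between
  roughly 0.5 and 15 RPKM). Per cell line the baseline is jittered by a
  multiplicative factor bounded on the log scale so that no background
  between-line ratio can reach `background_max_fc` (default 3). Planted
  genes overwrite their pair's two columns with `baseline` and
  `baseline * fc_ratio`, realizing the requested ratio exactly.
* **Network.** Planted genes are wired to exactly `n_golgi_neighbors`
  non-planted universe members with experimental confidences uniform on
  [0.4, 1]; background edges draw confidences from Beta(2, 5) (most mass
  below 0.4) and never join a planted gene to a universe member, so each
  planted gene's Golgi-neighbor count is exactly its configured value.
* **Evidence.** Planted genes get the record that realizes their requested
  score under their planted direction (the inverse of the scoring rubric);
  all background universe genes get `none_reported`.
* Four cell lines are generated, named as the study layout's pairs
  (MDAMB231/MCF7, A549/CALU1), so configurations mirror a two-cancer-type
  comparison out of the box.

Two construction rules make ground truth derivable from the configuration
alone. First, `background_max_fc` must be strictly below the smallest base
threshold — otherwise background genes could pass the screen and the planted
selected set would no longer be exactly predictable; configurations
violating this are rejected at `synth_config()` time. Pure i.i.d. log-normal
noise per cell line would not give this guarantee (with sdlog 0.8, roughly
15% of background genes would exceed a 5-fold ratio by chance). Second, the
planted-to-universe edge exclusion above keeps the expected score-2 values
exact rather than lower bounds. When more planted genes pass a pair's
threshold than the cap admits, `ground_truth()` applies the same adaptive
top-`cap` rule (by nominal ratio, then symbol).

What the generators do **not** emulate — and hence what passing tests do not
show about real data: real RPKM distributions and their cross-line
correlation structure, scale-free interaction-network topology, annotation
incompleteness and symbol aliasing, or biased/contradictory literature
curation. The tests demonstrate that the pipeline's logic is exact, not that
the screen's biological yield on real inputs is well calibrated.

```{r}
bundle <- simulate_bundle(synth_config(seed = 1), tempfile("bundle"))
report <- run_golgi_screen(bundle$config, quiet = TRUE)
report
identical(sort(unlist(report$common_genes)), bundle$truth$common)
```

## Numerical choices

* **Zero RPKM.** How zeros were handled in the original screen is not
  recorded; we add the pseudocount (default 0.01 RPKM) only when the smaller
  value is zero, so `fold_change(5, 0)` = (5 + 0.01)/0.01 = 501 while all
  nonzero ratios remain exact.
* **Tolerances.** Fold-change equality (`direction = "equal"`) and threshold
  comparisons use a 1e-9 relative tolerance: planted ratios are realized as
  `(baseline * r) / baseline`, which need not round-trip exactly in binary
  floating point, and a gene planted exactly at the threshold must pass.
* **Tie-breaks.** Every ordering in the package ends with ascending symbol,
  making all outputs byte-reproducible; the determinism test compares raw
  output bytes across runs.
* **Degenerate inputs.** Both-zero expression with pseudocount 0 errors;
  empty universes, empty networks, genes absent from the network or the
  evidence table, and candidate-free screens all produce empty (not failing)
  results, with warnings where silence would mislead.

## Scope of the test suite

Unit and property tests run at small sizes chosen to keep the suite fast
while covering the combinatorics: random screens up to 50 genes and random
graphs up to 100 nodes are compared against brute-force re-enumeration (200
random configurations in the acceptance suite), the scoring rubric is pinned
by exhaustive enumeration, and planted-candidate recovery runs the default
500-gene two-pair bundle across 20 seeds. The screen counts of the original
analysis (universe of 390; 42 and 35 screened genes; 20 and 14-or-15
candidates; 8 shared) are **not** reproduction targets: they depend on
unpublished curated lists and on specific historical versions of the
annotation, expression, and interaction databases.

## Known limitations

* Fold change on unreplicated RPKM has no error model; a gene's passing the
  screen is not a statistical claim.
* The concordance score treats the literature as a single oracle record per
  gene; conflicting reports must be resolved upstream in the curated CSV.
* Score 2 weights all universe neighbors equally regardless of edge
  confidence above the cutoff; no diffusion or weighting is attempted.
* Term matching is flat; annotation completeness directly bounds the
  universe, and genes absent from the expression matrix are silently outside
  the screen.
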