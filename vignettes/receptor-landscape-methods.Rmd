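---
title: "Methods: thresholded receptor-landscape profiling across taxonomy and space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: thresholded receptor-landscape profiling across taxonomy and space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Neuromodulator receptor families — the 14 mouse serotonin (5-HT) receptor
genes (`Htr1a` … `Htr7`) are the default here — are expressed in complex,
overlapping patterns across essentially every cell type of the brain.
Modern whole-brain single-cell RNA-seq atlases assign every cell four
nested taxonomy labels (class > subclass > supertype > cluster), plus a
coarser "neighborhood" grouping and a neurotransmitter label; companion
MERFISH datasets measure a fixed gene panel per cell *in situ*, carry the
same cluster labels via cross-dataset label integration, and add a
parcellation annotation (division > structure) and an anteroposterior (AP)
section position.

`htrmap` implements the analysis layer that sits on top of such paired
datasets: detection thresholding, prevalence statistics at any taxonomy
level, co-localization and correlation matrices, supervised decoding of
group identity from boolean receptor profiles, primary-effector-family
assignment, and the cross-modal bridge that maps scRNA-seq-defined
"enriched clusters" into the spatial dataset. A synthetic-data generator
with planted ground truth replaces the multi-million-cell source datasets
so that every stage is testable at desk scale.

## Core statistics

**Detection and prevalence.** A gene is *detected* in a cell when its
log(CPM)-scale expression strictly exceeds the detection threshold
(default 3.5 for scRNA-seq — the stringent cutoff used to call
neurotransmitter release in the reference taxonomy — and 0.3 for the
spatial modality). The comparison is strict (`>`): a value exactly at the
threshold is not detected, matching the printed inequality of the
reference analysis; `thresholds(strict = FALSE)` switches to `>=`.
*Prevalence* of gene $g$ in group $G$ is

$$\mathrm{prev}_G(g) = 100 \cdot \frac{|\{i \in G : x_{ig} > \theta\}|}{|G|}.$$

The denominator is all cells of the group, never only family-positive
cells. Groups with zero members are omitted (the ratio is undefined), not
reported as 0. Prevalence is exactly the count-weighted mean of its
subgroup prevalences, which the tests assert as an identity.

**Co-localization.** Conditional detection percentages on the boolean
mask: entry $(y, x)$ is the percentage of cells detecting $y$ that also
detect $x$. The statistic is asymmetric; the identity
$\mathrm{coloc}[y,x] \cdot n_y = \mathrm{coloc}[x,y] \cdot n_x$ (both equal
$100 \cdot |\text{joint}|$) is tested exactly. Correlation matrices, by
contrast, use the *continuous* expression values — the two computations
answer different questions and are deliberately kept on different inputs.
Per-cell receptor counts are reported on two explicit bases (percent of
all cells, percent of family-positive cells), each summing to 100.

**Decoding.** Group identity (neurotransmitter, neighborhood, or class) is
decoded from the boolean detection profile with a random forest (200
trees, maximum depth 10, balanced class weights), evaluated by stratified
5-fold cross-validation with balanced accuracy (mean per-class recall),
whose uniform chance level is $100/K$ percent for $K$ classes. Out-of-fold
predictions feed a true-label-normalized confusion matrix (rows sum to 1)
and a per-class precision/recall/F1 report. Classes with fewer members
than the fold count are dropped with a warning, never silently merged.
Logistic regression and linear discriminant analysis run under the same
protocol as baselines.

**Attribution.** Feature attribution uses Monte-Carlo permutation Shapley
sampling over a probability forest fitted once to the full data (separate
from the CV loop used for accuracy). For each sampled row a random
feature ordering is walked from a random background row towards the row
of interest; the change in predicted class probability when a feature
switches in is its contribution for that permutation, and contributions
telescope exactly to $f(x) - f(\text{background})$. The summary is the
per-class mean absolute contribution per gene. A feature constant across
the data contributes exactly zero. The attribution sample is
class-weight balanced: a per-class quota of `attribution_sample / K`
rows, capped at class size (default cap 10,000 rows overall). Eight
permutations per row are the default; the estimator's variance shrinks as
$1/\sqrt{B}$ and the tests' qualitative assertions (zeros, row maxima)
hold already at small $B$.

**Effector families.** Receptors are aggregated by main intracellular
effector — Htr1/5 (Gi, cAMP decrease), Htr2 (Gq, Ca²⁺ increase),
Htr4/6/7 (Gs, cAMP increase), Htr3 (ionotropic) — by summing *raw*
expression values per cell (no detection thresholding: the question is
which pathway dominates, and the reference computation sums transcription
levels directly). The primary family is the argmax; all-zero cells are
"unassigned" rather than forced into a family; exact ties are broken by
the fixed family order above and counted in a message. Assignment is
invariant to positive rescaling of a cell's expression.

**Spatial mapping.** A cluster is *enriched* for a gene when at least 70%
of its cells detect the gene. The reference text states the rule once as
"at least 70%" and once as ">70%"; the package follows the inclusive
reading (`>=`) as the definition and exposes `enrichment_inclusive =
FALSE` for the strict one. Enriched clusters are projected into the
spatial dataset through the shared cluster vocabulary — which works even
for genes missing from the spatial panel, the point of the method. The
*enriched fraction* (percent of all gene-detecting cells that belong to
enriched clusters) is reported alongside, because when it is small the
cross-reference view covers only a minority of the gene's expression and
the *direct* mode (spatial detection at threshold 0.3) is the honest
alternative. The direct threshold is applied on the same scale the
spatial expression values are stored in, with the same strict-`>`
semantics as the scRNA-seq side. Regional prevalence normalizes counted
cells by *all* cells of a division or structure; the division value is
exactly the count-weighted mean of its structures' values (tested as an
identity). Cross-modal concordance is an ordinary least-squares
regression of spatial on scRNA-seq per-class prevalence; a slope below 1
quantifies the systematic sensitivity offset between modalities.

**AP profiles and peak sections.** Per-section prevalence along the AP
axis, sections ordered by mean AP coordinate; zero-cell sections are
omitted. Top-section selection takes local maxima (a section at least as
high as its neighbors, endpoints compared to their single neighbor),
ranks them by prevalence, and greedily enforces a minimum pairwise AP
spacing, defaulting to 10% of the profile's AP range — "adequately spaced
apart" is not quantified in the reference and the default is
configurable. If fewer spaced peaks than requested exist, the highest
remaining sections fill the list and the result is flagged.

## The synthetic-data generator

The generator defines the study conditions for all tests; it is not a
tuning knob. It plants a cluster × gene matrix of Bernoulli detection
probabilities and derives everything else from it:

* **Taxonomy.** Nested by integer division from a shape vector
  (classes, subclasses per class, supertypes per subclass, clusters per
  supertype); defaults to 10 classes / 40 clusters so full pipelines run
  in seconds. Cells draw clusters uniformly (or by supplied weights);
  upper levels are deterministic functions of the cluster, so every
  cluster has exactly one parent per level.
* **Detection.** Per cell and gene, Bernoulli with the planted
  probability. The default probability landscape draws per-gene base
  prevalence log-uniformly on (0.005, 0.35) — most family genes rare, a
  few widespread, mirroring the strongly skewed per-gene spread of real
  receptor families — and adds per-cluster N(0, 1.5) effects on the logit
  scale for strong cluster structure.
* **Amounts.** Detected values come from a normal truncated strictly
  above the detection threshold; undetected values are exactly 0. This
  guarantees the planted Bernoulli structure survives thresholding
  without distortion — empirical prevalence converges to the planted
  probability at the binomial rate, which the tests check at 4 SDs. The
  default detected-amount mean rises with the gene's overall detection
  probability, emulating the empirical coupling between how widespread a
  gene is and how strongly it runs within cells. The truncated-normal
  choice is a stand-in: the reference does not describe the real amount
  distributions, and nothing downstream depends on their shape beyond
  the threshold crossing.
* **Spatial side.** Spatial cells use the same cluster machinery (the
  shared vocabulary that makes cross-referencing meaningful), uniform
  section-plane coordinates, a uniform AP coordinate whose binning is the
  section label, and a deterministic grid parcellation (divisions are
  bands of x, structures split each band along y, so the
  structure → division map is single-valued by construction — a testable
  region assignment without any atlas registration). Only panel genes are
  emitted; `spatial_scale` multiplies all spatial detection
  probabilities, planting a known cross-modal regression slope.
* **Seeding.** One root integer seed; every component derives its own
  sub-seed from it. Same config, bit-identical output.

What the generator does *not* emulate: transcriptome-wide expression
(only the family under study), realistic amount distributions, spatial
autocorrelation of cell types within sections, atlas geometry, or
label-integration errors between modalities. Passing tests therefore
demonstrate correctness of the statistics and the recoverability of
planted structure — not robustness to registration artifacts or
integration noise in real atlas data.

## Parameters at a glance

| Parameter | Default | Units / scale | Where |
|---|---|---|---|
| `detection_scrna` | 3.5 | log(CPM) | `thresholds()` |
| `detection_spatial` | 0.3 | spatial expression scale | `thresholds()` |
| `enrichment_fraction` | 70 (inclusive) | percent of cluster | `thresholds()` |
| `n_trees` / `max_depth` | 200 / 10 | — | `decoder_spec()` |
| `n_splits` | 5 | stratified folds | `decoder_spec()` |
| `attribution_sample` | 10,000 | rows | `decoder_spec()` |
| `n_permutations` | 8 | per-row MC permutations | `decoder_spec()` |
| `top_k_groups` / `top_k_sections` | 10 / 4 | — | `pipeline_config()` |
| `min_spacing` | 10% of AP range | AP units | `select_top_sections()` |

## Numerical and interface choices

* Missing expression values are read as 0 (undetected) with a logged
  count; threshold semantics are unaffected and NAs never propagate.
* Undefined ratios are reported as missing, never as 0: zero-cell groups,
  co-localization rows with no conditioning cells, detected-only means
  over empty sets, correlations of constant genes.
* Ties: top-group ranking breaks ties lexicographically; primary-family
  ties use the fixed family order (and are counted); peak-section ties
  prefer the more anterior section. All deterministic.
* The ± on mean profile correlations is the standard error of the mean;
  both the per-group reduction (mean against all other groups) and the
  unordered-pair overall mean are exposed, since the convention is
  ambiguous.
* Neighborhood multi-membership: a separate, row-duplicated table is used
  *only* for neighborhood-grouped statistics; every other grouping runs
  on the unduplicated table. Cells absent from the membership table keep
  their single label.
* Tables travel as CSV (RFC 4180, UTF-8, header) or Parquet; matrices as
  wide tables keyed by `cell_label`. These two containers cover the
  atlas-style exports without binding the package to one serialization.
* The interactive dashboards of the original toolchain are replaced by a
  static, self-contained HTML report (`render_report()`) in which every
  figure is rendered from a serialized table in the results directory.
* `predict` methods that break exact probability ties with the RNG (the
  multinomial-logistic baseline does) are run under a derived seed, so
  decoding results are bit-reproducible for a given `decoder_spec()`.

## Problem sizes used by the test suite

Unit tests run on 10–1,000-cell fixtures where every statistic is checked
for exact equality against independent brute-force loop oracles. The
recovery and sanity suites use the sizes at which the planted effects are
unambiguous relative to binomial noise: enrichment recovery at 200 cells
per cluster over 100 seeded replicates (probabilities 0.9/0.8/0.5/0.1
against the 70% threshold put the nearest cluster 3.5 binomial SDs from
the boundary), decoding at 5,000 cells over 10 planted single-gene
classes, and cross-modal concordance at 50,000 cells per modality with a
planted slope of 0.5. The whole suite completes in well under a minute.

## Known limitations

* Headline percentages from the multi-million-cell source atlases are
  properties of those datasets; the desk-scale synthetic conditions
  validate the machinery, not those numbers. Users with the real exports
  can reproduce them by pointing `pipeline_config()` at the downloaded
  tables.
* Attribution is a Monte-Carlo estimate; per-entry values carry sampling
  error that shrinks with `n_permutations` and the attribution sample.
* No out-of-core support: tables are processed in memory. The full-atlas
  scale requires chunked adapters upstream of this package.
* CCF registration, UMAP computation and the original clustering are out
  of scope; their outputs (parcellation labels, embedding coordinates,
  cluster labels) are consumed as given.
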