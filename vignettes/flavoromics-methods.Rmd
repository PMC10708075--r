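---
title: "Methods: from GC-MS peak areas to signature flavor compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from GC-MS peak areas to signature flavor compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavoromics)
```

## The analysis problem

Headspace GC-MS of fruit produces, per replicate injection, a table of
identified volatile organic compounds (VOCs) with raw peak areas.  Two
questions drive the analysis this package implements for a two-group
(e.g. two-species) comparison:

1. **Which compounds actually smell?**  Peak area alone is a poor guide:
   perception depends on the odor threshold.  The odor activity value and
   its within-group relative form (ROAV) rank compounds by how far they
   exceed their thresholds.
2. **Which compounds distinguish the groups?**  A discriminant model
   (OPLS-DA) and a random forest each rank compounds; a fused score
   combines the two rankings into one screening criterion.

The package ships a published two-species rose-fruit study (*Rosa
roxburghii* Tratt., group label RR, and *Rosa sterilis*, RS; four
analytical replicates per group) as plain-text fixtures, and a synthetic
generator so that every stage can be exercised with known ground truth.

## Relative content

For sample $s$ and compound $c$,

$$C_{sc} = 100 \cdot \frac{a_{sc}}{\sum_{c'} a_{sc'}}\,,$$

the percentage of the sample's total peak area (area normalization).  Rows
therefore sum to 100 exactly; a sample with zero total area is a
malformed input and is rejected by name.  Group profiles report the
arithmetic mean and the sample standard deviation ($n-1$ denominator,
the convention for small numbers of analytical replicates) of the
per-replicate contents.  A compound "detected" in a group is one with a
positive group mean.

Area normalization makes the data *compositional*: contents compete for a
fixed total.  Consequences for the discriminant stage are discussed under
*Synthetic data* below.

## ROAV and key flavor compounds

With $C$ the group mean content (%) and $T$ the odor threshold in water
(mg/kg),

$$\mathrm{OAV} = C/T\,, \qquad
  \mathrm{ROAV}_i = 100\cdot\mathrm{OAV}_i/\mathrm{OAV}_{\max}\,,$$

computed independently within each group over the compounds that have a
threshold entry.  The most odor-active compound scores exactly 100;
compounds with ROAV $\ge 1$ are *key flavor compounds*, those with
$0 < \mathrm{ROAV} < 1$ *flavor modifiers*.  Compounds without a
threshold entry cannot be ranked; they are retained and flagged
`no_threshold` rather than silently dropped.  ROAV is a ratio statistic,
so rescaling all contents in a group by any positive factor leaves it
unchanged — this invariance is tested.

Two display conventions follow the field's tables: values below 0.1 print
as `<0.1`, and rounding to two decimals happens only at report time;
every computation uses full precision.

Because the packaged study tables store contents already rounded to two
decimals, recomputed ROAVs can differ from the printed ones by a few
hundredths (e.g. RS (E)-2-hexenal recomputes to 15.17 vs the printed
15.15); the package's checks therefore use a ±0.05 absolute band for
those comparisons.

## The flavor network

Key compounds are linked to their free-text odor descriptors (matched
exactly after trimming and case-folding; no synonym merging).  The graph
is bipartite; each edge carries the compound's ROAV, and a descriptor
node's weight is the sum of its incident ROAVs, so descriptors shared by
several key compounds emerge as flavor hubs.  The package emits the edge
list and a GraphML file; drawing is left to graph tools.

## OPLS-DA, VIP, and validation

The discriminant model is a from-scratch single-response orthogonal
projection to latent structures.  Columns are mean-centered and
unit-variance scaled by default (`pareto` and `none` are available);
zero-variance columns are dropped and recorded.  The class vector is
coded $\pm 1$ and centered.  For one response the NIPALS weight vector is
available in closed form ($w \propto X^\top y$), making the fit fully
deterministic.  Each of the `n_ortho` orthogonal components (default 1,
the usual choice for two classes) is built from the part of the loading
vector orthogonal to $w$ and removed from $X$ before the single
predictive component is fitted.  A degenerate orthogonal weight (norm
below $10^{-12}$) simply ends the extraction early.

Variable importance follows the VIP statistic

$$\mathrm{VIP}_j = \sqrt{\,p \cdot
  \frac{\sum_a \mathrm{SSY}_a\, (w_{aj}/\lVert w_a\rVert)^2}
       {\sum_a \mathrm{SSY}_a}}\,,$$

summing by default over the predictive *and* orthogonal components
weighted by the Y-variance each explains (a `predictive`-only switch is
provided; since orthogonal components explain essentially no Y-variance
the two agree to numerical precision).  The normalization guarantees
$\sum_j \mathrm{VIP}_j^2 = p$, which the test suite asserts on random
matrices.

Predictive ability is $Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ under
stratified venetian-blind cross-validation (default 7 folds, assigned in
sample order within each class — deterministic, no shuffling;
`n_folds >= n` gives leave-one-out).  The permutation test refits and
cross-validates the model on permuted labels and regresses the permuted
$R^2Y$ and $Q^2$ (plus the observed model at correlation 1) on the
absolute label correlation; intercepts near or below zero indicate the
observed model is not an overfitting artefact.

**A caution that shaped the pipeline design:** with four replicates per
group (eight samples), $Q^2$ is a noisy statistic.  Pure-noise data reach
$Q^2 > 0$ in roughly one run in six and $Q^2 > 0.5$ in about one in ten,
and conversely genuine signal occasionally cross-validates below 0.5.
The pipeline therefore gates its final signature list on *two* checks
before interpreting VIPs — $Q^2 > 0.5$ **and** a permutation p-value
below 0.05 (50 permutations by default) — mirroring how chemometric
practice validates a model before using it.  An invalid model yields an
empty signature list and a warning; the fusion table itself is still
reported.

## Random-forest Gini importance

The second ranking is the mean decrease in Gini impurity from a
classification forest (package `randomForest`; 500 trees,
$\lfloor\sqrt p\rfloor$ variables per split, no depth limit).  The
forest is seeded, so importances are exactly reproducible.  Raw
importances are reported alongside a sum-to-one normalized column; the
raw values enter the fusion stage, matching how such tables are printed.

## Fusion and the signature screen

VIP and Gini columns are each min–max normalized over the candidate
compounds,

$$X_{\mathrm{nom}} = \frac{X - X_{\min}}{X_{\max} - X_{\min}}\,, \qquad
  X_A = \tfrac12\,(X_{V\mathrm{nom}} + X_{G\mathrm{nom}})\,,$$

and a compound is a *signature differential flavor compound* when its
unnormalized VIP is $\ge 1$ (inclusive) and $X_A > 0.5$ (strict).  The
candidate set is the union of the per-group key-flavor sets — in the
packaged study, the twelve ROAV-qualified compounds.  Screening always
uses full precision; in the packaged study one compound (methyl
salicylate) has $X_A = 0.516\ldots > 0.5$ yet is excluded because its
VIP is below 1, a useful boundary case the tests pin down.  Ties at a
column's extremes all map to 0 or 1; a column with no spread has no
defined normalization and errors.

## Synthetic data

The generator draws replicate peak areas log-normally per compound and
group, moment-matched so the expected area equals the configured mean at
a configured coefficient of variation (default 0.4, of the same order as
the replicate scatter in the packaged study).  Group-absent compounds
get area zero; planted discriminant compounds are multiplied by a
fold-change in a designated group.  Output is bit-identical per seed.

Three presets define the test conditions:

* **paper** — the packaged study regenerated at replicate level: 61
  compounds, the published presence masks (48 RR / 26 RS / 13 common by
  construction), group means used as expected areas, per-compound CVs
  from the published SD/mean ratios, 4 replicates per group.
* **strong-signal** — 12 compounds, 4 planted at fold-change 8, two
  elevated in each group.  Three design points matter.  *(i)* The planted
  compounds are minor constituents (base area 0.5 vs 2 for the bulk):
  boosting a dominant compound would, after closure, depress every other
  content and smear the signal across all columns.  *(ii)* Planting is
  two-sided so the group totals stay balanced; one-sided planting
  measurably turns the entire bulk into spurious discriminants through
  the same closure effect.  *(iii)* The fold-change is large on purpose —
  in the packaged study the analogous compounds differ by
  presence/absence, an unbounded fold-change, and closure plus
  unit-variance scaling attenuate planted effects.
* **null** — identical to strong-signal but with no planted effects; both
  groups share one compositional distribution.

What the generator does *not* emulate: retention-time drift, co-elution,
detector saturation, missing identifications, and the exact per-replicate
closure artefacts of real data (it matches expected proportions, not the
distribution of ratios).  Passing tests on synthetic data therefore
establish correctness of the statistical machinery under known truth,
not instrument-level realism.

## Numerical and testing choices

* NIPALS/weight degeneracy tolerance $10^{-12}$; orthogonality of score
  vectors asserted at $10^{-8}$; VIP normalization at $10^{-9}$; the
  brute-force ROAV and VIP oracles agree with the implementation at
  $10^{-12}$ and $10^{-10}$.
* Ranks break ties by decreasing score then compound name (stable).
* Compound joins canonicalize names (trim, collapse whitespace,
  case-fold); CAS is carried as metadata.  Greek letters in the packaged
  fixtures are transliterated (`beta-ocimene`) so joins are robust across
  locales.
* The packaged study's value columns follow the printed table order
  (first RS, then RR), the orientation fixed by the published detection
  counts (48 RR / 26 RS).
* Convergence of generated means is asserted on mean *areas* (the
  generator's own parameters) at 1000 replicates within 5% — at that size
  the band sits at roughly four standard errors of the per-compound mean,
  so the check is stable; contents carry a small systematic ratio
  (closure) bias and are not the right scale for this assertion.
* Null calibration of $Q^2$ (permuted labels score $\le 0$ in at least
  90% of runs) is asserted over 100 seeded null experiments at 20
  replicates per group, the scale from which the rate is stable (~95%);
  at the study scale of 4 replicates chance separation makes that rate
  unattainable for any method, which is precisely why the pipeline gates
  on the permutation test as well.
* Monte-Carlo test sizes (20–100 seeds) keep the full suite under half a
  minute while leaving comfortable margins on every asserted rate.

## Known limitations

* The printed multivariate summaries of the packaged study (its
  $R^2X$/$Q^2$ and the VIP/Gini magnitudes) cannot be regenerated because
  the replicate-level data were never published; the package stores the
  printed importance columns and reproduces everything downstream of
  them exactly.  The software stack that produced them is also
  unspecified beyond its defaults, so the scaling used here
  (unit-variance) is the conventional, not the verified, choice.
* Odor thresholds are matrix-dependent; the packaged table transcribes
  the water thresholds used in the study and the package makes no
  attempt to estimate or harmonize thresholds.
* Descriptor matching is exact; "fruity" and "fruit" are different
  nodes.  A descriptor ontology is out of scope.
* Two-group designs only; multi-class OPLS-DA is not implemented.
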