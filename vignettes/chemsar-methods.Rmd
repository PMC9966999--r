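---
title: "Methods: chemical-space, scaffold and QSAR analysis of bioactivity datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-space, scaffold and QSAR analysis of bioactivity datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

chemsar analyzes a compound bioactivity dataset — an activity table of
SMILES structures with IC50 or pIC50 values, such as an inhibitor series
against a single enzyme target — through five connected stages: curation,
exploratory statistics, chemical-space projection, scaffold analysis with
activity-cliff detection, and multiclass QSAR classification. This
vignette records the models, conventions and numerical choices behind each
stage, and what the synthetic benchmark does and does not establish.

## Curation and potency classes

Potency is expressed as pIC50 = −log10(IC50 in mol/L). IC50 units must be
declared per file or per column; when IC50 values arrive without any unit,
nanomolar is assumed (the norm in public bioactivity databases) and
announced loudly with `message()`. Four potency classes are cut at pIC50 =
8, 7 and 6 — potent (≥ 8), active (8 > pIC50 ≥ 7), intermediate
(7 > pIC50 ≥ 6) and inactive (< 6) — with each boundary belonging to the
upper class, so pIC50 = 7.0 is *active*.

Structures are salt-stripped to the largest organic fragment and written
as Open Babel canonical SMILES; the operation is idempotent. Tautomers are
*not* merged: Open Babel has no tautomer canonicalizer, so two tautomeric
drawings of one compound survive as distinct structures. Rows with
unparseable SMILES, non-positive IC50, mutually inconsistent IC50/pIC50,
duplicated ids, or duplicated structures (first occurrence wins) are
rejected with logged reasons rather than silently dropped.

Class imbalance is repaired by random oversampling: minority-class records
are duplicated uniformly at random until every class matches the majority
count. Balancing happens **before** the train/test split, which means
duplicates of one original record can appear on both sides of the split.
This ordering is deliberate — it is the workflow whose training/test sizes
the pipeline reproduces — but it leaks information and flatters test
accuracy; users wanting a leak-free estimate should split first and
balance the training side only. The test set holds `ceiling(fraction × N)`
records, stratified by class by default (per-class counts rounded largest
remainder first so totals are exact).

## Descriptors and fingerprints

Six drug-likeness descriptors are computed through Open Babel: molecular
weight (g/mol), atom-contribution LogP, hydrogen-bond acceptor and donor
counts, rotatable bonds, and topological polar surface area (Å²).
Rotatable bonds are counted with the common SMARTS
`[!$(*#*)&!D1]-!@[!$(*#*)&!D1]` (single non-ring bonds between
non-terminal atoms, amide bonds included). Which LogP variant an external
tool used for any published table is generally unknowable, so exact
reproduction of third-party descriptor tables is not promised.

Fingerprints: MACCS keys are exposed with 167 positions so that position
*k* is MACCS key *k* (position 167 is never set); ECFP4 is the circular
fingerprint of radius 2, folded by OR from Open Babel's 4096 bits to a
configurable width, default 2048. PubChem (881 keys) and Klekota–Roth
(4860 keys) fingerprints are definitions, not algorithms: the package
ships a generic SMARTS-key engine (`smarts_key_fingerprint()`) that turns
any SMARTS list into a keyed fingerprint, plus `load_fingerprint_table()`
for tables precomputed elsewhere; asking for those schemes without a key
table is a capability error that names the remedy.

## Exploratory statistics

Per-group descriptor summaries report min/max/median/mean, bias-corrected
sample skewness and **excess** kurtosis (normal = 0). The excess
convention is the one consistent with typical published descriptor tables
(values like −0.65); a flag restores raw kurtosis (= excess + 3).
Degenerate samples (n < 3, or n < 4 for kurtosis, or zero variance)
report `NA`, never a fake 0. Normality is screened with Shapiro–Wilk for
3 ≤ n ≤ 5000.

Two-group comparison is a two-sided Mann–Whitney U test. When both groups
have ≤ 8 observations the p-value is exact: every assignment of the pooled
values into groups is enumerated, ties counted 1/2, and the two-sided
p-value is the fraction of assignments whose U deviates from the null mean
at least as much as observed. Larger samples use the normal approximation
with tie correction and continuity correction. The exact mode is verified
in the tests against an independent brute-force oracle.

## Chemical space and applicability domain

PCA is computed on z-score-standardized descriptors — correlation-matrix
PCA — because the six descriptors live on incommensurate scales (daltons,
Å², counts); covariance PCA would just rank descriptors by numeric
magnitude. Components are ordered by explained variance and each
component's sign is fixed so its largest-magnitude loading is positive;
published loading tables are therefore matched up to a per-component sign
flip. Constant columns are dropped with a warning.

The applicability domain is the bounding box of the training-set scores:
per-component closed intervals [min, max], optionally expanded by a
fractional margin of the range on each side. A query compound is in-domain
iff every used component lies inside its interval; boundary points count
as inside. By default the box uses the leading components reaching 90 %
cumulative variance (`components_for_coverage()`), since the number of
box components is a free choice.

## Scaffold analysis

The Murcko framework of a molecule is the union of its ring systems and
the linkers connecting them, obtained by iteratively pruning terminal
atoms (the 2-core of the heavy-atom graph). Atoms attached to the
framework by a bond of order ≥ 2 — carbonyl oxygens on rings or linkers —
are retained, following the dominant toolkit convention. Acyclic molecules
have no scaffold and map to the empty-string sentinel; they count toward N
in diversity reports but contribute no scaffold. The cyclic skeleton
genericizes the framework: every atom becomes carbon, every bond single,
so pyridine and benzene (or naphthalene and decalin) share one skeleton.

Scaffold diversity reports N (compounds), Ns (distinct scaffolds), Nss
(singleton scaffolds), Ncsk (distinct skeletons) and the ratios Ns/N,
Nss/N, Ncsk/N, Ncsk/Ns, rounded to three decimals for reporting with exact
values kept as an attribute.

The enrichment factor of a scaffold at an activity threshold (default
pIC50 ≥ 7) is its active fraction divided by the dataset's active
fraction: EF = 1 means average, 0 means no actives, 1/p means all active.
Published EF tables conventionally round the dataset proportion to two
decimals first (e.g. 351/683 → 0.51, so a fully active scaffold scores
1/0.51 = 1.961); the `ef` column follows that convention for table parity
and `ef_exact` keeps the exact fraction. Representative scaffolds are
those with frequency ≥ 10 **or** EF ≥ 1 (either suffices), ranked by EF
then frequency.

Scaffolds sharing a cyclic skeleton are grouped for modeling;
`manual_groups` can merge groups explicitly when chemical judgment says
two skeletons belong together. The R-group decomposition is deliberately
simplified: members whose Murcko scaffold equals the core are decomposed
into side chains anchored at framework atoms, with positions numbered by a
symmetry-aware (Morgan-refinement) rank so chemically equivalent positions
share a label; it is a transparent stand-in for interactive SAR tables,
not a full matched-pair engine.

## Activity landscape

All n(n−1)/2 compound pairs are scored with Tanimoto similarity (set
overlap for binary fingerprints, Σmin/Σmax for counts) and the absolute
pIC50 difference. The SAS map partitions pairs at a similarity threshold
(default 0.5) and an activity-difference threshold (default 2.0 pIC50
units) into smooth, activity-cliff, scaffold-hop and nondescript
quadrants; the thresholds are free parameters of the landscape, echoed
into the output's attributes. SALI = Δactivity / (1 − similarity)
quantifies each pair; identical fingerprints with differing activity give
`Inf` (serialized as `"inf"` in CSV contexts), with equal activity 0 by
convention. AC generators are compounds appearing in at least `min_count`
cliff pairs; the consensus across fingerprint schemes is the intersection
of the per-scheme generator sets. Pair generation is dense and in-memory,
comfortable to a few thousand compounds.

## Multiclass QSAR

Feature filtering drops fingerprint columns with variance < 0.1, then
scans remaining columns in index order and drops any column correlating
(|Pearson r| > 0.90) with an earlier retained column — the earlier column
wins, which makes the mask deterministic. The filter is fitted on the
training set only and applied unchanged to the test set; fitting it on all
data would leak test information into feature selection.

The algorithm registry has twelve entries: DT (unpruned CART), ET (extra
trees: no bootstrap, one random split per candidate feature, minimum node
size 1), RF, GB (gradient-boosted trees: depth 3, shrinkage 0.1, no
regularization), LGBM, XGB (xgboost defaults), MLP (single hidden layer of
8 units), LR (ridge logistic regression, λ = 1/n), KNN (k = 5), SVM (RBF,
probability outputs), NB (Bernoulli naive Bayes with Laplace smoothing),
and GP (Gaussian-process classifier, RBF kernel). LGBM has no backend in
this installation and raises a capability error; the other eleven run.
Every model is wrapped one-vs-rest: one binary classifier per class, the
predicted class being the one with the highest positive-class probability
(ties resolve toward the more potent class). All randomness is seeded
(default 42) and hyperparameters are the library defaults noted above.

Cross-validation is stratified 10-fold (reduced with a warning when the
smallest class is smaller than the fold count); out-of-fold predictions
are pooled into a single confusion matrix, which is how a single CV
accuracy per model is reported, with per-fold accuracies attached.

Metrics: accuracy = trace/total; micro-averaged recall is computed by its
support-weighted definition and equals accuracy for any multiclass
confusion matrix (the identity is asserted over random matrices in the
tests); the multiclass MCC is the Rk form
(c·s − Σpᵢtᵢ)/√((s²−Σpᵢ²)(s²−Σtᵢ²)), which reduces to the classical
binary MCC at k = 2 and returns 0 by convention when a marginal is
degenerate. A 4-class matrix can be collapsed to binary by block-summing
{potent, active} vs {intermediate, inactive}; alongside the binary
accuracy Q2 the marginal chance agreement Q2,rnd = Σ rowₖ·colₖ / total²
is reported (0.5 for perfectly balanced marginals) and ΔQ2 = Q2 − Q2,rnd.

## The synthetic benchmark

`make_benchmark_fixture()` generates ≈ 280 compounds from 18
hand-written scaffold templates (two steroid-like fused tetracyclics,
fused heteroaromatic bicyclics, biaryls, saturated rings) with one or two
attachment sites filled from a 12-substituent library. True pIC50 =
scaffold baseline + additive substituent effects — the simplest model
consistent with reading R-group tables as independent increments —
and observed pIC50 adds Gaussian noise with σ = 0.3, the scale of
within-assay variability. Baselines span 8.6 down to 5.0 so all four
classes appear, the potent class dominates the steroid-like subset, at
least three scaffolds are entirely active (EF = 1/p exactly), and one
scaffold has no actives (EF = 0). Most substituent effects are small
(±0.25); the designated modeling scaffold (a biphenyl) instead uses
effect levels near 0/−1/−2/−3 so its skeleton group spans all four
classes with ≈ 0.45 pIC50 margins to the class cuts — effects chosen to
dominate the noise.

Five activity-cliff pairs are planted as (base member, variant) differing
in a single terminal atom of one substituent, with a 3.5-unit true
potency gap; the minimal structural edit keeps ECFP4 Tanimoto above the
0.5 quadrant threshold on every cliff scaffold. Problem sizes throughout
(≈ 280 compounds, one modeling group of ≈ 80, 500-tree ensembles) were
chosen so the full validation runs in about a minute on one core while
every contract stays testable.

What passing the benchmark shows — and does not. The generator proves the
plumbing and the mathematics: EF arithmetic recovers planted enrichment
exactly on noise-free data, every planted cliff lands in the cliff
quadrant, skeleton grouping reconstructs the template assignment, and
extra trees separate the modeling group (test accuracy ≥ 0.8 at the
default seed). It does not emulate real medicinal chemistry: substituent
effects are truly additive (no interactions), noise is homoscedastic
Gaussian, scaffolds are clean single-series templates without measurement
artifacts, and the oversample-then-split workflow shares duplicates
across the split. Accuracy on the benchmark therefore validates the
pipeline, not any claim about prospective predictive power on real
compounds.

## Known limitations

* No tautomer merging; no stereochemistry handling in scaffold
  comparison beyond what canonical SMILES encodes.
* Charged ring systems lose formal charges during scaffold extraction
  (scaffolds are reported for the neutralized framework).
* The LGBM registry entry requires a LightGBM installation.
* Dense pairwise similarity is quadratic in compound count; practical to
  a few thousand compounds.
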