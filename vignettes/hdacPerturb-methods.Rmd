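---
title: "Models and methods behind hdacPerturb"
author: "hdacPerturb authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hdacPerturb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdacPerturb)
```

# Scope

hdacPerturb analyzes multiplexed-quantification (TMT) perturbation screens
of cell-line panels treated with HDAC inhibitors: fold-change
quantification, regulated-event counting, cross-condition consistency,
anchor co-regulation, KSEA kinase inference, transcript–protein
concordance, PISA thermal-engagement calls, and over-representation
statistics, plus a synthetic-data generator with planted ground truth.
Upstream raw-spectrum processing (search, reporter deconvolution,
peptide-to-protein rollup) and the upstream single-cell
differential-expression fit are out of scope; their outputs are this
package's inputs.

# Quantification model

The input is a `QuantMatrix`: non-negative reporter abundances, features ×
samples, with per-sample cell line, drug and replicate annotation. The
vehicle label is fixed to `"DMSO"`, and one *condition group* is a treated
(cell line, drug) pair with its replicates and the matched DMSO group of
the same cell line.

**Normalization.** `normalizeColumns()` rescales each sample column so
all column sums equal the mean original column sum. Equal per-channel
total signal is the assumption behind comparing reporter abundances
across channels; within-column feature proportions are untouched. If an
upstream pipeline has already normalized to a bridge channel, this step
is an inexpensive no-op-like correction and can be skipped by calling
`buildFoldChangeTable()` directly.

**Replicate filter.** For each feature and arm, the linear-scale CV
(sample SD / mean, n−1 denominator — the convention for duplicate
measurements) must be strictly below `cv_max = 0.3`. The filter is
applied to the treated and the vehicle arm independently, and either
failing voids the pair: a fold change against an unreliable denominator
is as untrustworthy as one from an unreliable numerator. Features with a
missing value in any replicate of an arm are unquantified for that group;
no imputation is attempted.

**Fold change.** log2FC = log2(mean treated / mean vehicle), the ratio of
replicate means rather than the mean of per-replicate ratios; the former
is robust to per-replicate scaling and makes the duplicate design
symmetric. `buildFoldChangeTable()` materializes all feature × group
entries with both CVs, replicate counts and a `quantified` flag, and is
tested against a naive per-feature reimplementation.

# Regulation and consistency

A feature is regulated in a group when |log2FC| strictly exceeds
`fc_threshold = 1` (two-fold). Strictness matters at the boundary: a
fold change of exactly 1.0 is not a call. `waterfallCounts()` gives the
per-group up/down totals used to rank condition groups by remodeling
strength.

`classifyConsistency()` counts regulated groups per feature over the
*HDACi* groups only — an outgroup compound (a non-HDACi kinase inhibitor
in the emulated design) must be excluded by the caller, because
universality is defined over HDACi-treated cells. With the default
`specific_cutoff = 14`: `universal` means regulated in all groups (and,
under the default stricter `require_full_coverage`, quantified in all),
`specific` means 1–13 regulated groups, `shared` covers the remainder,
`unresponsive` means none. The 14-group cutoff and the restriction of the
denominator to the 30 HDACi groups are both config-exposed because the
convention's denominator (30 HDACi vs all 35 groups) is a judgment call;
the default follows the definition of universality over HDACi-treated
cells.

`compositeViabilityCorrelation()` supports panel-selection arguments: the
Pearson correlation between a model subset's per-condition mean viability
and the global mean over all models.

# Anchor co-regulation

`anchorScreen()` correlates each feature's fold-change profile across
condition groups with an anchor's profile, using pairwise-complete
observations, and keeps partners passing a strict threshold. Defaults
follow the two screen conventions: signed r > 0.9 for protein partners,
|r| > 0.8 with ≥ 80% group coverage for phosphosites (`signed = FALSE`).
A minimum shared-group count is not part of either convention, so edges
supported by fewer than `min_points = 5` groups are flagged (`low_n`)
rather than dropped. `attributeFraction()` reports the percentage of all
distinct partners attached to one anchor, truncated to one decimal (68 of
81 partners displays as 83.9).

# KSEA and kinase candidates

For one condition group with site fold changes \(x\) and a kinase with
\(m\) quantified substrates,

\[ z = \frac{(\bar{x}_{substrates} - \bar{x}_{all})\,\sqrt{m}}{\mathrm{SD}(x_{all})} \]

with the background being *all* quantified sites of the group, sample SD,
two-sided normal p-values and BH adjustment across the kinases of the
group. The z-score variant, the background choice and the SD convention
are fixed and documented here because KSEA exists in several trimmed and
weighted flavors; the implementation is verified against a brute-force
oracle. Note z is invariant to a constant shift applied to all sites —
only deviations of the substrate set from the background matter.

`rankKinaseCandidates()` implements the two-criterion candidate rule for
a single phosphosite: a motif-predictor score strictly above 1 *and*
co-regulation of the kinase's protein profile with the site profile at
|r| strictly above 0.8, with kinases below a coverage floor (28 of 30
groups by default) excluded before testing. Motif scores are an external
predictor's output and are supplied as input; the synthetic generator
emits scores consistent with its planted kinase.

# Nine-group concordance

`classifyNineGroups()` thresholds the transcript normalized effect at
±0.05 and the protein log2FC at ±1 (both strict) and maps the pair onto a
row-major 3×3 grid: Group 1 = transcript-up/protein-down, Group 2 =
transcript-up/protein-null, Group 3 = transcript-up/protein-up, …,
Group 9 = transcript-down/protein-up. The grid is anchored by the
explicit definitions of Groups 1 and 3 and by the statement that Groups 3
and 7 are the concordant pair; this makes the transcript-specific groups
{2, 8} and the protein-specific groups {4, 6}. A published description
elsewhere lists "Groups 1, 4, 6, 9" as the single-layer responders, which
contradicts the anchored definition of Group 1 (both layers regulated,
discordantly); the grid here honors the anchored definitions, and the
mapping is the documented, overridable convention rather than a silent
guess. Transcript FDR is carried through but not re-tested by default
(the axis threshold alone decides states), with `require_fdr` to gate
low-confidence transcripts to the null state.

# PISA engagement model

The PISA readout pools the soluble fraction over a 10-point 48–58 °C
gradient; `pisaShift()` summarizes treated versus vehicle pooled
abundances as log2FC of replicate means with a two-sided Welch t-test on
log2 abundances. The significance rule for engagement calls — p < 0.05
per arm plus an absolute log2FC floor of 0.2, no multiple-testing
correction by default (a BH option exists) — is made explicit and
configurable because per-protein significance conventions vary.
`classifyEngagement()` combines matched live-cell and lysate arms:
`direct` requires concordant significant shifts in both arms, the
hallmark of physical engagement; `cell-context` (cell-arm only) flags
shifts requiring the cellular milieu; `lysate-only` the converse; the
rare both-significant discordant case is reported as `none` with
direction `mixed`. The two-state sigmoid simulator (`simulateMelting()`)
averages \(f(T) = 1/(1+e^{(T-T_m)/k})\) over the gradient; a positive
midpoint shift raises the pooled abundance, with sensitivity vanishing
for midpoints far outside the gradient window.

# Enrichment statistics

`hypergeomEnrich()` is one-sided over-representation: p = P(X ≥ k) for k
foreground hits of a term with K members in a background of N features
and a foreground of n. The background defaults, by the caller's
construction, to the features quantified in the relevant condition group
— a whole-genome universe would overstate enrichment of any
well-quantified category. BH adjustment across all tested terms;
enriched at adjusted p < 0.05. `bhAdjust()` delegates to
`stats::p.adjust(method = "BH")` after validation and is checked against
an independent step-up implementation in the tests.

# The synthetic-data generator

`simConfig()` holds the emulated design and its defaults: 5 cell lines ×
7 drugs (6 HDACi + 1 outgroup) + DMSO, 2 replicates, 2,000 proteins, 500
phosphosites, triplicate PISA over 48–58 °C. Replicate noise is
log-normal: per-replicate log2 abundance = baseline + condition effect +
N(0, σ) with σ = √(ln(1 + cv²))/ln 2, so the linear-scale CV matches
`replicate_cv = 0.05` — the few-percent regime typical of well-behaved
TMT replicates. Planted structure:

* **Universal effectors** (15 by default) shift every HDACi group by
  ±2 log2 units; vehicle columns never carry effects.
* **Divergent effectors** (100) shift all HDACi groups of a random 1–2
  of the 5 cell lines — the cell line is the heterogeneity axis of the
  emulated design, and one or two lines (≤ 12 of 30 groups) keeps a
  divergent effector inside the `specific` consistency class, so
  recovery can be scored against a single truth label.
* **Anchor module**: one anchor protein plus 20 partners share a
  per-group latent term λ_g ~ N(0, 1 log2); with 5% replicate CV the
  expected pairwise profile correlation is ≈ 0.97, comfortably above the
  0.9 screen threshold, while the latent swings of ±1 log2 resemble a
  strongly co-regulated module. Because module members' regulation
  follows the latent factor rather than an effector assignment, they are
  labelled `anchor` in the truth and excluded from the universal/
  divergent scoring universe in `truthRecoveryReport()`.
* **Planted kinase**: a per-group activity a_g ~ N(1.5, 0.5) log2 added
  to its 20 substrate sites, and (attenuated ×0.5) to the kinase's own
  protein row, giving both a dominant KSEA z and a site–kinase profile
  correlation near 0.95. Ten decoy kinases receive random unshifted
  substrate sets and sub-threshold motif scores; the planted kinase's
  motif score is 1.8.
* **Concordance panel**: 900 genes split evenly over the 9 groups, with
  protein/transcript values drawn inside the corresponding thresholded
  regions; the confusion matrix against truth is diagonal by
  construction. Because the panel is balanced, its overall
  proteome–transcriptome correlation is near zero — the panel validates
  the classifier, not the empirical correlation of real cohorts, where
  concordant genes dominate.
* **PISA truth**: 15 direct-stabilized, 10 direct-destabilized, 10
  cell-only and 10 lysate-only targets (midpoint shift ±2 °C on melting
  midpoints ~N(53, 1), slope 1 °C), the rest unengaged.

Identical config + seed gives bit-identical output; all randomness flows
from the single seed.

What the generator does **not** emulate: reporter-ion interference and
ratio compression beyond what column normalization induces, structured
(non-random) missingness, peptide-level variation, correlated biological
covariation among null features, and melting-curve shapes beyond the
two-state model. Passing recovery tests therefore demonstrate
correctness of the analysis chain under the stated noise model, not
field performance on raw instrument data.

# Numerical choices and degenerate inputs

* Strict inequalities at every published threshold (|log2FC| > 1,
  r > 0.9, score > 1, effect > 0.05, CV < 0.3); boundary values fall on
  the conservative side.
* Correlations use pairwise-complete observations; constant vectors are
  refused (`pearsonCorrelation()`) or skipped with a warning
  (`replicateCorrelation()`, KSEA with zero background SD).
* `pisaShift()` with zero variance in both arms returns p = 1 (equal
  means) or p = 0 (unequal), a stated convention for the noise-free
  limit.
* Precision of an empty prediction set is reported as 1.0 with a
  `precision_undefined` flag, keeping recovery reports total.
* Waterfall ties break lexicographically by group name, making outputs
  deterministic.
* Attribution percentages are truncated (not half-up rounded) to one
  decimal, matching the display convention of the screens this
  reproduces.

# Problem sizes used by the tests

The suite exercises most properties on compact designs (300 proteins, 60
PISA proteins) and the acceptance-style checks on the full emulated
design — 5 cell lines × 6 HDACi × 2 replicates with 2,000 proteins over
20 seeds, chosen as the smallest scale at which per-category recovery
rates are stable to within a few percent across seeds. Null calibrations
use 2,000 features × 30 groups (regulation, co-regulation) and 20 random
foregrounds × 50 terms (enrichment).

# Known limitations

* Peptide-to-protein rollup, isotope-impurity correction and
  bridge-channel normalization are upstream concerns; the package starts
  from feature-level abundances.
* The co-regulation screen applies no multiple-testing control, matching
  the screen convention it implements; at 30 points and r > 0.9 the
  per-feature false-positive rate is far below 0.1%, but users lowering
  the threshold should add their own control.
* KSEA inherits substrate-map quality; unmapped or promiscuous sites
  bias the background.
* Dose–response modeling, melting-curve (Tm) fitting per temperature
  channel and network retrieval from interaction databases are
  deliberately out of scope.
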