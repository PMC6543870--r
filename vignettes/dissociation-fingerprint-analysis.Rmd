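---
title: "Residence-time analysis of ligand dissociation trajectories"
author: "tauramd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residence-time analysis of ligand dissociation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tauramd)
```

## The model

`tauramd` treats ligand unbinding as a sequence of contact-loss events.
Random acceleration MD (RAMD) forces the ligand out of its binding site in
roughly a nanosecond by applying a randomly re-oriented constant force; a
simulation stops when the ligand center of mass has moved 30 Å from its
bound position. Two independent signals are extracted from a set of such
trajectories:

* **Egress-time statistics.** For each equilibration replica, the relative
  residence time is the time by which half of that replica's trajectories
  have dissociated; the compound-level estimate `tau_ramd()` is the mean of
  the replica values, with their sample SD as the uncertainty. Because these
  times are relative, they are placed on the experimental axis by an
  ordinary least-squares fit of log₁₀(τ_RAMD) against measured
  log₁₀(1/k_off) (`fit_scaling()`), with a declared outlier list excluded
  from the fit but not from prediction.
* **Interaction fingerprints.** Each frame is typed geometrically per
  protein residue into seven interaction bits, collapsed by logical OR into
  four categories — hydrogen bond (HB), aromatic (ARO), ionic (IP), apolar
  (APO) — so a feature is a (residue, category) pair such as `F138-APO`.
  The assumption is that the *pattern* of contacts sampled during the
  transition from bound to unbound, not the trajectory length, encodes what
  slows dissociation. Time order is deliberately discarded: each feature
  becomes its occurrence (fraction of transition frames), averaged over
  trajectories and compounds into a compounds × features matrix with labels
  log₁₀(1/k_off [s]).

Regression (ridge and RBF support-vector regression against a training-mean
null) then quantifies how much kinetic information the contact occurrences
carry, and Gaussian-mixture clustering groups compounds by dissociation
mechanism.

## Geometric typing and its parameters

The original fingerprints behind this protocol were produced with a
commercial cheminformatics toolkit whose numeric thresholds are not public.
`tauramd` re-implements the typing from widely used structural
interaction-fingerprint conventions; the defaults of `geometric_cutoffs()`
are therefore *conventions, not fitted values*, and all are configurable:

| criterion | default | unit |
|---|---|---|
| H-bond heavy-atom distance | ≤ 3.5 | Å |
| H-bond donor angle (when an explicit H is present) | ≥ 120 | ° |
| hydrophobic C···C | ≤ 4.5 | Å |
| aromatic face-to-face centroid / plane angle | ≤ 4.4 / ≤ 30 | Å / ° |
| aromatic edge-to-face centroid / plane angle | ≤ 5.5 / ≥ 60 | Å / ° |
| ionic (opposite formal charges) | ≤ 4.0 | Å |

Protein atoms are typed from built-in dictionaries over the 20 standard
amino acids (donors, acceptors, apolar side-chain carbons, charge centers
at pH 7, aromatic rings); ligand atoms from an explicit per-atom table, with
an element-based fallback (`default_ligand_types()`). Fingerprints are
computed against protein residues only — waters and ions are not typed, so
water-mediated bridges are invisible to the features. Topologies are PDB;
frames are DCD or multi-model PDB (no XTC reader is available to R here,
so that format is out of scope).

Because exact thresholds of the original toolkit are unrecoverable,
numeric reproduction of any third-party per-frame bit stream is *not*
promised; what the package guarantees (and tests) is exact agreement with
its own geometric definitions.

## Truncation, aggregation, filters

The bound-state reference is the feature set of frame 0. The transition part
of a trajectory starts at the first frame where the required number of
bound-state contacts is *simultaneously* absent — at least 2 (data set A),
⌈20 %⌉ (B), or ⌈60 %⌉ (C) of the bound set; fractions are rounded up because
contacts are whole. Later re-formation of a contact does not move the
truncation point, and the transition part ends at the dissociation frame
inclusive. A trajectory whose criterion is never met contributes nothing and
is reported with a warning. Note the ordering consequences: truncation
frames always satisfy t(B) ≤ t(C); t(A) ≤ t(B) additionally requires a bound
set of at least 10 contacts (so that ⌈0.2·n⌉ ≥ 2). Mode A counts losses on
the 4-category features, the granularity used everywhere else.

Two filters reduce noise, in this order:

* **Rare features** (`filter_rare()`): a feature is dropped only when its
  occurrence is below 5 % in *every* compound (max-over-compounds rule, the
  boundary value kept). The wording "rare in any compound" is ambiguous; the
  max rule is used because a contact relevant to even one compound should
  survive.
* **Correlated features** (`prune_correlated()`): a greedy scan in a
  canonical order (ascending residue number, then HB < ARO < IP < APO) drops
  any feature whose squared Pearson correlation with an already-kept feature
  exceeds 0.9. Which member of a pair survives is not defined by the
  protocol; the canonical order makes the choice deterministic.
  Zero-variance columns have no defined correlation and are kept.

Min-max normalization maps each feature to [0, 1]; constant columns map
to 0, which keeps them inert in every downstream model. By default the
normalization is fit on the full matrix before splitting, mirroring the
stated protocol; fitting it per training set (the leakage-free variant) is
available by normalizing inside your own loop, and for min-max scaling of
bounded occurrences the difference is marginal.

## Degenerate inputs and numerical choices

* `replica_t50()` treats censored (never-dissociated) trajectories as later
  than every observed time; they count in the denominator but can never be
  the median while they are < 50 % of the sample. At ≥ 50 % censoring the
  estimator refuses (the remedy is more trajectories, not extrapolation).
* All model work is in log₁₀; natural logs never reach an interface.
* Ridge regression is solved in closed form on centered data with an
  unpenalized intercept, so the grid value is the absolute penalty λ in
  (XᵀX + λI)β = Xᵀy.
* SVR with every training point inside the ε-tube has no support vectors;
  any constant inside the tube is optimal and the training mean is returned.
* `fit_gmm()` fits mixtures with one full covariance matrix per component
  and, by default, a light conjugate prior on means and covariances
  (mclust's `priorControl()`). Without it, maximum likelihood finds
  near-singular components whose likelihood spikes defeat AIC component
  selection even on cleanly separated Gaussian blobs; the prior plays the
  role of the covariance floor other GMM implementations apply by default.
  Repeats are made stochastic by seeding the initialization subset.
* AIC = −2·logL + 2·df compares a *single* covariance family across
  component counts; counts whose fit fails are dropped from the scan rather
  than silently refitted with a simpler family.
* Clusters are matched across the 50 repeats by rank after ordering each
  repeat's clusters by mean log residence time — not by composition — so the
  ensemble τ_c for rank j is the mean of the j-th-slowest cluster across
  repeats. Composition stability is reported as the mean pairwise adjusted
  Rand index, without a pass threshold (none is defined by the protocol).

## The evaluation protocol

Each of the (default 200) rounds draws a constrained 80/20 split: the test
set of a 94-compound study-sized set has 19 members, of which exactly 2 come
from the declared outlier pool (compounds whose residence time the
trajectory-length route misestimates) and at least ⌈20 %⌉ of the dominant
congeneric (indazole) pool — at least 9 when that pool has ≥ 45 members —
with the remainder drawn from unconstrained compounds. Pools overlapping is
resolved with outlier priority. Hyperparameters are re-selected each round
by exhaustive grid search under 10 random-permutation folds with 20 %
validation (LR strength 10⁻³…10³, 13 log-spaced; SVR cost 10⁻¹…10³,
ε ∈ {0.01, 0.05, 0.1, 0.2}, kernel width 10⁻³…10). Ten cross-validation runs
then train each model on a sub-training set and score MAE and Q²F3 on the
sub-training, validation and external test subsets; scaled τRAMD
predictions, when supplied, are scored on the identical subsets. Q²F3
divides the test-set mean squared error by the training-set label variance
(per-n forms), so the training-mean null scores 0 in expectation — up to a
finite-sample bias of order n/(n−3), visible at small n.

## What the synthetic generators emulate — and what they do not

`gen_toy_complex()` writes a miniature complex in which each requested
contact archetype satisfies the default cutoffs in frame 0, breaks at a
scripted frame, and the ligand crosses the 30 Å threshold at a scripted
egress frame. Its ligand typing table deliberately marks ring carbons as
non-apolar so that each archetype residue yields exactly one (residue,
category) feature — a property of this fixture, not a general typing rule.
`gen_if_series()` generates binary contact streams from explicit loss
schedules with optional transient re-formation. `gen_egress_times()` draws
replica-structured log-normal or exponential egress samples.
`gen_compound_set()` plants a linear law label = intercept + Σ wᵢ·occᵢ +
N(0, σ) over iid Beta(2, 2) occurrences, with default dimensions 94 × 47,
σ = 0.3 log₁₀(s), intercept −1 and unit-normal weights, chosen so labels
span roughly −4…2 log₁₀(s) — the spread of measured off-rates in kinase-type
inhibitor panels — and annotations sized like the study composition (45
congeneric, 8 + 6 outliers).

Passing tests on these generators shows the machinery is correct: exact
geometric typing, exact truncation arithmetic, metric closed forms,
recovery of planted regression weights and cluster structure. It does *not*
show that real dissociation trajectories carry this much signal: real
contact occurrences are strongly correlated, labels are not linear in them,
force-field and modeling errors are compound-specific rather than iid, and
trajectory counts per compound are small. The independence and Gaussianity
of the planted law are idealizations.

## Problem sizes used by the test suite

The suite runs the protocol at the study's native scale where that is cheap
(94 × 47 matrices, 200 rounds, 50 clustering repeats, 80-compound scaling
fits) and at reduced scale elsewhere (10–30 rounds for distributional
checks); the Monte-Carlo t50 check uses 4 × 2000 exponential draws. These
sizes are the package's choices for tight, deterministic tests with
comfortable margins over their tolerances.

## Known limitations

* No XTC input; no periodic-boundary handling beyond what upstream
  extraction provides (a minimum-image COM correction is assumed done).
* Waters and ions are not fingerprint partners; crystallographic-water
  bridges are invisible.
* Time-ordered (sequence-of-events) features are intentionally out of
  scope; occurrence averaging is the model.
* The geometric cutoffs are conventions; agreement with fingerprints from
  other toolkits will be qualitative, not bitwise.
* Absolute k_off is never computed; everything kinetic is relative until
  the scaling fit anchors it to measured data.
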