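---
title: "MNA descriptors and calibrated Bayesian activity prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MNA descriptors and calibrated Bayesian activity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnasar)
```

This vignette is the package's own account of its model, the choices made
where the design was genuinely open, and what the test suite's synthetic
results do and do not establish about real screening data.

## The molecular representation

Descriptor generation operates on a deliberately impoverished molecular
graph: atoms carry only an element symbol and a formal charge, every
hydrogen implied by standard valence and formal charge is present as an
explicit node, and edges carry no bond order, aromaticity or
stereochemistry. Two stereoisomers, or a Kekulé and an aromatic writing of
the same ring, therefore yield the same graph. Structure reading and
hydrogen completion are delegated to OpenBabel (via ChemmineOB/ChemmineR);
salts are stripped to the largest covalent fragment by default, since
activity tables typically register the salt while the measured entity is
the parent molecule. Isotopes are ignored: the descriptors are
constitutional.

The label of a charged atom appends the charge sign and, beyond ±1, its
magnitude (`O-`, `N+`, `Ca+2`). A carboxylate oxygen is thus a different
vocabulary item from a neutral one — the minimal, implementable reading of
"the representation reflects atomic charge"; finer charge typing (partial
charges, tautomer-aware protonation states) is out of scope.

## MNA descriptors

The level-0 descriptor of an atom is its label; the level-L descriptor is

```
label( sorted level-(L-1) descriptors of its neighbors )
```

with plain lexicographic sorting inside the parentheses, so the string is
canonical under any atom renumbering (duplicate sublabels simply stand
side by side). The descriptor set of a compound is the union over all
atoms of all levels `0..max_level`, with *set* semantics: presence counts,
multiplicity does not.

Two open choices are worth stating. **Depth**: nothing in the method fixes
the level; `max_level = 2` is the default here, the standard depth in the
MNA literature, and a configuration knob everywhere it matters. **Levels
included**: we accumulate all levels up to the maximum rather than keeping
only the top level — the vocabulary is richer and degrades gracefully for
tiny molecules (water at level 2 still contains `O`, `H`, `O(HH)`,
`H(O)`). Both choices are documented as this package's reading, not
claimed as the original PASS configuration.

## The Bayesian scorer

Training data are per-activity binary labels over a pool of `N` compounds.
All compounds in any labeled set form one pool; a compound not labeled
active for an activity counts among its inactives — inactivity is the
absence of evidence of activity, mirroring the asymmetric labeling rule of
screening corpora. With `n_d` compounds carrying descriptor `d`, and
activity `a` having `n_a` actives of which `n_da` carry `d`,

$$p_{da} = \frac{n_{da} + c\,p_a}{n_d + c}, \qquad p_a = \frac{n_a}{N},$$

and a query with descriptor set $D(x)$ scores

$$s(x,a) = \operatorname{mean}_{d \in D(x) \cap V}\ \arcsin(2 p_{da} - 1).$$

The regularization constant `c` (default 1, must be positive) pulls
rare-descriptor estimates toward the prior and keeps the arcsine off its
saturation points; the arcsine stabilizes the variance of the
per-descriptor proportion estimates so that common and rare descriptors
contribute on a comparable scale. Descriptors unseen in training are
ignored; a query sharing nothing with the vocabulary receives the prior
score $\arcsin(2p_a - 1)$ rather than an error, because a prediction tool
must answer for arbitrary novel structures. This estimator is a
faithful-behavior reconstruction of the naive-Bayes family used by
PASS-type engines, not a byte-level clone of any proprietary
implementation.

## Analytic leave-one-out and Pa/Pi calibration

For every training compound the model stores its leave-one-out score:
the score recomputed with the compound's own contributions removed from
all counts (`N−1`; `n_d` minus its descriptor membership; `n_a`, `n_da`
decremented iff it is active). A descriptor occurring in no *other*
compound drops out of the mean, exactly as it would be absent from the
vocabulary of a model retrained without the compound — which is why the
analytic LOO equals explicit retraining to floating-point noise (verified
to 1e−12 in the suite). Removing the only active of an activity leaves a
degenerate prior (`p_a = 0`); the score is still computed and the
condition is logged.

Prediction places a query's score in these empirical LOO distributions:
`Pa` is the fraction of training actives scoring strictly below it plus
half the ties; `Pi` the fraction of inactives above it, likewise with
half-credit (the mid-rank ROC convention). Calibrating against LOO rather
than plain training scores matters: plain scores of training actives are
optimistically shifted, and ranking against them would destroy the very
property that makes Pa interpretable. As it is, the LOO Pa values of the
training actives are uniform on [0, 1] by construction (the i-th smallest
of n scores has Pa = (i − 0.5)/n), so a `Pa > t` selection filter loses a
fraction ≈ t of true actives — about half at Pa > 0.5, about 70% at
Pa > 0.7. This is the package's central acceptance property and what
`scripts/acceptance.R` recomputes. Output lists are ordered by Pa − Pi
descending, putting the more probable activities on top.

## Validation

Accuracy per activity is IAP — the probability that a random active
outscores a random inactive, ties half-credit — computed by mid-ranks in
O(n log n); it is numerically the ROC AUC and invariant under monotone
rescaling of the scores. k-fold cross-validation uses seeded,
label-stratified folds dealt round-robin (so fold sizes balance and
`k = N` reduces exactly to leave-one-out, an algebraic cross-check in the
suite) and pools the out-of-fold scores into a single IAP rather than
averaging per-fold AUCs — stabler for activities with few actives. The
default is `k = 20` with the seed recorded in the report. Activities are
selected for predictive use only when LOO IAP is *strictly* above the
threshold (default 0.8); the report prints mean IAP over selected and
over all activities, since either convention is found in practice.

## Curation rules

* Potency endpoints (IC50, GI50, Ki, Kact) convert to nM by exact powers
  of ten; active iff strictly below 10,000 nM. Percent inhibition: active
  iff strictly above 50. The strictness follows the rule's wording
  ("less than", "exceeded").
* NCI60-style screens: rows with a non-empty failure reason are deleted
  first; surviving replicate −log10 GI50 values per compound × cell line
  collapse to their **median** ("medium" is read as median — the robust
  standard for replicate screening values; switchable to the mean), and
  the aggregate is active at ≥ 9 / 8 / 7 for the 1 / 10 / 100 nM
  thresholds. Values outside [0, 15] are implausible on a −log10 molar
  scale and are dropped with a warning.
* Conflicts resolve active-wins per compound × activity, a pure function
  of the record multiset (row order never matters).
* Activities enter training only with ≥ `min_actives` actives (default 3
  — below that a per-activity Bayesian model is noise) and ≥ 1 inactive.
* Cell-line and target names normalize by case-folding and
  punctuation-stripping against a user-supplied synonym table; the same
  exact-match mechanism serves as the target-key join for
  mechanism-of-action tables. No external registry is consulted.

## The synthetic generator

`make_descriptor_dataset()` emulates a curated binary training set at the
descriptor level: vocabulary items enter each compound's set by
independent coin flips, with `n_enriched` items upweighted in actives.
The defaults — 300 actives, 1200 inactives, 500 items, 10 enriched at
0.9 (active) vs 0.1 (inactive) over a 0.05 background — define a strongly
separable set sized like a mid-sized single-assay corpus while keeping
every suite run in seconds; the 1:4 class ratio reflects that screening
corpora hold far more inactives than actives. `make_smiles_dataset()` is
the smaller end-to-end layer: valid druglike SMILES assembled from a
fixed fragment library, with a sulfonamide substructure planted in
actives, exercising parsing → descriptors → curation → model as a whole.

What passing these tests shows: the estimator recovers planted
monotone descriptor–activity signal, its calibration behaves as designed,
and the cross-validation machinery is algebraically correct. What it does
not show: performance on real chemistry — correlated descriptors,
activity cliffs, assay noise, interlaboratory drift and chemical-series
bias are all absent from the generator, so IAP values on synthetic data
say nothing about the IAP to expect on a real corpus.

## Numerical choices and degenerate inputs

* Ties everywhere (Pa, Pi, IAP) take half-credit, the mid-rank
  convention.
* `regularization = 1` keeps every $p_{da}$ in the open interval (0, 1);
  the arcsine is then bounded away from ±π/2 for any finite counts.
* An empty query descriptor set is an error (no structure parsed); zero
  vocabulary overlap is not (prior fallback).
* Model files are JSON with full-precision doubles; on load the
  calibration arrays are recomputed from the exact integer counts, so a
  reloaded model predicts bit-for-bit identically regardless of decimal
  truncation in transit.
* The problem sizes used by the test suite (toy sets of 10–20 compounds
  for the retrain oracle, 500-compound null replicates, the 1500-compound
  planted fixture for calibration and k-fold agreement) were chosen so the
  whole suite runs in well under a minute while keeping every estimate's
  sampling error far below the asserted tolerances.

## Known limitations

* Formal charge is the only charge typing; tautomers and protonation
  states are taken as drawn.
* Descriptor sets are unweighted presence/absence; no counts, no
  fingerprint folding.
* Multi-activity dependence is not modeled: each activity is scored
  independently from shared counts.
* The applicability domain is only the prior fallback; a query far from
  the training chemistry still receives a (weakly informative) score.
* No molar-mass conversion: activity values given in mass concentration
  units are rejected rather than guessed.
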