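---
title: "Methods: from phenotypic screen to hit candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from phenotypic screen to hit candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`glioscreen` turns a multi-library, multi-concentration, multi-cell-line
phenotypic screen into binary training labels, a Monte-Carlo classifier
ensemble, a ranked virtual-screening hit list, and dose–response validation
fits. This vignette documents the models, the parameters that matter, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The screening model

The experimental unit is a well: a compound at one concentration on one
plate seeded with one glioblastoma stem-cell line, read out as a nuclei
count after imaging. Fields of view are assumed pre-summed into a single
count per well; image analysis is out of scope. Each plate carries DMSO
(vehicle) wells, and survival is defined plate-wise:

$$S = 100 \cdot \frac{n_\text{well}}{\overline{n}_\text{DMSO}}$$

computed within plate and cell line, so the mean normalised DMSO survival
is exactly 100% per plate and the measure is invariant to any global
rescaling of a plate's counts (plate effects cancel). Survival is *not*
capped at 100: proliferative responses are retained. Wells sharing (plate,
compound, concentration, cell line) are averaged before normalisation, and
per-plate survivals of the same compound are averaged afterwards —
replicate handling the data model needs but raw screens rarely specify.

Libraries overlap, so profiles are deduplicated, by default on the
salt-stripped canonical structure (compound-id keying is available for
structureless data). Merging takes the union of the cell line ×
concentration cells, with replicate-weighted means where cells collide.
Compounds whose SMILES cannot be parsed are quarantined and reported, never
silently dropped.

## The labelling rule

Labels are binary at the panel level and concentration-aware, since
different libraries were screened on different grids:

1. Per concentration, compute the cross-line mean survival. Concentrations
   with mean survival below `impact_threshold_percent` (default 70) are
   "impacting". The aggregation across lines is the arithmetic mean — a
   choice this package makes explicit because "effect closest to 50%" does
   not itself say how six lines are combined.
2. If no concentration impacts, the compound is negative (`no_impact`).
   If exactly one impacts, it is chosen. Otherwise the impacting
   concentration with mean survival closest to `midpoint_target_percent`
   (default 50) is chosen, ties going to the **lower** concentration
   (favouring potency and keeping the rule deterministic).
3. At the chosen concentration, count the cell lines at or below
   `survival_cutoff_percent` (default 35; the boundary is inclusive). The
   compound is positive iff that count is at least `min_lines` (default 2)
   and not all lines. A compound below the cutoff in every line is
   pan-toxic and labelled negative by default — general cytotoxins with a
   narrow therapeutic index are not interesting leads.

The 35% default is anchored on a paclitaxel positive control (≈36%
survival at 5 nM); it is a survival threshold, not a "35% decrease"
(survival ≤ 65%) — both readings circulate, and the cutoff is a config
knob so the other reading is one flag away. The impact threshold of 70%
must be laxer than the positive cutoff, or step 2 would be vacuous; 70% is
the package default and configurable.

## Featurisation and diversity diagnostics

SMILES are canonicalised with OpenBabel (via ChemmineOB) after salt
stripping: the input is split on `"."` and the largest organic fragment
(most heavy atoms among carbon-containing fragments, counted by SMILES
token) is retained; stereochemistry is preserved, and the operation is
idempotent. OpenBabel aborts batch conversions at the first invalid
string, so conversion runs in title-aligned chunks with a per-molecule
fallback; true parse failures surface as structured errors or quarantine
entries.

Descriptors are the toolkit's full numeric property set — OpenBabel's
calculated properties (MW, logP, molar refractivity, TPSA, H-bond
donor/acceptor counts) plus atom, bond and per-element counts. All
downstream code keys on descriptor *names*, never on their number, so the
set can grow with the toolkit. The matrix then passes through three
provenance-tracked steps: zero-variance columns are dropped; features are
selected once, globally, by strictly positive Gini-impurity importance
from a random forest (zero-importance features carry no signal, and
impurity importances cannot be negative — retaining "non-negative" scores
would retain everything); and z-scoring. In the training loop the scaler
is fit per Monte-Carlo training split and applied to its test split and to
screening compounds — the no-leakage default. The one known leakage caveat
is the global feature selection itself, performed before splitting; it is
kept because the pipeline's reference procedure orders the steps that way,
and it is documented here rather than hidden.

Chemical diversity is summarised with the continuous Tanimoto coefficient
on z-scored descriptors,

$$T(a,b) = \frac{\langle a,b\rangle}{\|a\|^2 + \|b\|^2 - \langle a,b\rangle},
\qquad d = 1 - T,$$

which can leave $[0,1]$ for vectors with negative components; values are
reported as computed, never clipped. Pair counts follow a declared
convention — ordered distinct pairs $n(n-1)$ by default (matching how a
103-compound positive set yields 10 506 pairs) or unordered $n(n-1)/2$;
mean and sd are identical under both.

## The Monte-Carlo ensemble

The naive baseline is the majority-class accuracy $\max(n_+, n_-)/n$ —
0.971 for a 103/3458 screen. Splits are stratified 70:30 with
largest-remainder apportionment of per-class quotas, which reproduces the
canonical 2493/1068 partition of 3561 compounds (72 positives in
training). Each member is an XGBoost classifier with `eta = 0.5`,
`max_depth = 2`, 100 rounds, `colsample_bytree = 0.5`, other settings at
library defaults; the confusion threshold is 0.5 (a choice this package
fixes explicitly). F1 is the standard harmonic mean of precision and
recall. PR-AUC uses the step-function (average-precision) estimator,
implemented directly since no installed package provides it.

The acceptance loop draws splits with the deterministic seed sequence
`base_seed, base_seed + 1, …` and accepts members whose test accuracy
strictly exceeds the baseline, until `n_models` (default 100) are accepted
or `max_attempts` (default `10 × n_models`) splits have been tried — the
cap prevents an unbounded loop on signal-free data, where the gate
correctly never fills (on planted-noise features, zero of twenty members
beat the baseline). Resampling ensures every positive is eventually used
for training. The whole run is reproducible bit-for-bit given (data,
config, base seed) up to the learner's documented determinism; ensembles
persist as a directory of serialised boosters plus a JSON manifest with
config, baseline, seeds, per-member metrics and scalers.

## Virtual screening

Screening libraries are canonicalised, deduplicated within and across
files, and cleared of compounds whose canonical structure appears in
training; every removal is logged with a reason. Each member scores each
compound after applying that member's own scaler, and the ensemble score
is the arithmetic mean of member probabilities. Hits are compounds with
mean score **≥** the threshold (default 0.22; the inclusive reading of a
"22% cutoff" is chosen and configurable). Each hit is annotated with its
minimum continuous-Tanimoto distance to the training positives and the
neighbour's id; hits closer than 0.3 are flagged as training analogues.
The original exclusion of such analogues was a manual judgement, so the
automation only flags — it never drops — preserving the human-in-the-loop
step.

## Dose–response fitting

Validation fits use the variable-slope four-parameter logistic
$y = b + (t - b) / (1 + (x/\mathrm{IC}_{50})^h)$, the standard model
behind IC50 tables produced by graphing software (the exact original model
is unstated, so this default is a documented inference). The fit is
least-squares via Levenberg–Marquardt, parameterised in $\log \mathrm{IC}_{50}$
with the starting point at the dose nearest the response midpoint; at
least four distinct positive doses are required, and zero-dose anchors are
excluded from the log-dose model. A fit whose plateaus collapse
(|top − bottom| below 2% of the response scale) is reported unconverged
rather than yielding a meaningless midpoint. The 95% CI is a
case-resampling bootstrap percentile interval (default 500 refits;
reported only when at least half converge); an interval crossing the
tested dose range is flagged "wide", and an IC50 beyond the highest tested
dose is reported censored as `> max dose`. IC50s are scale-equivariant in
dose and invariant to affine response transformations, which the tests
assert directly.

## What the synthetic generator emulates — and what it does not

`generate_screen()` reproduces the *structure* of the real screen: five
libraries of 786/187/1277/1276/330 compounds on their concentration grids
(3856 compounds, 295 planted cross-library duplicates, 3561 unique), six
cell lines, plates of 320 treatment wells with 16 DMSO and 8
positive-control wells, a mean DMSO count of 1500 nuclei. True actives
(default fraction 0.03, close to the real 2.9% positive rate) get Hill
dose–responses $1/(1+(d/\mathrm{IC}_{50})^h)$ in a uniformly drawn 2–5
sensitive lines, with IC50 log-uniform in 1/30–1/5 of the library's top
concentration and slopes in 1.5–3, so the top dose sits well past the
midpoint. Candidate actives are redrawn (rejection sampling, deterministic
under the seed) until the noiseless labelling rule accepts them *with at
least 0.5 survival points of slack to every decision boundary* — the
slack guarantees that rounding counts to integers cannot flip a noiseless
label, which is what makes exact label-recovery checks meaningful.
Inactive compounds sit at survival 1 everywhere.

Count noise is multiplicative mean-preserving lognormal (CV-parameterised,
default 0.1) on top of a lognormal between-plate baseline effect (CV 0.1),
because well counts are in the hundreds and plate effects dominate
counting error; Poisson noise is available as an option. Compound
structures are random heteroatom-chain SMILES, stored as the
lexicographic minimum of the chain and its reversal so that no two
generated strings denote the same linear molecule — valid for
canonicalisation and deduplication machinery, but *not* realistic
medicinal chemistry. Consequently, passing tests demonstrate the
pipeline's bookkeeping, statistics and recovery behaviour, not that real
GBM actives are learnable from descriptors: real descriptor–activity
structure, assay artefacts, spatial plate effects and library bias are all
outside the generator.

`generate_labelled_features()` supplies class-conditional Gaussians
(informative features shifted by `effect_size` sd between classes) as a
stand-in for descriptor space in learner tests, with optional planted
constant columns for the 200 → 189 filtering step;
`generate_screen_library()` plants internal duplicates, training overlaps
and positive-like compounds; `generate_dose_response()` draws
mean-preserving lognormal noise around an exact 4PL curve.

## Problem sizes and test design

The test suite checks exact arithmetic at the screen's true scale (3856
compounds, 103/3458 labels, 2493/1068 splits, 10 506 positive pairs) but
runs the stochastic recovery checks at deliberately moderate sizes chosen
as the smallest that make the properties sharp: 400-compound noiseless
screens for exact label recovery of 40 planted actives; 100-member
ensembles on 103/3458 Gaussian features at effect size 3 (mean test
ROC-AUC ≥ 0.9, and the gate filling within its attempt budget); 4000
compound libraries at 0.5% positive-like spike for ≥ 20-fold hit
enrichment; and 100 replicate dose–response simulations (CV 0.1, three
replicates) for ≥ 90% bootstrap-CI coverage at 300 refits. The
`scripts/acceptance.R` entry point recomputes all of these from scratch
under a caller-supplied seed.

## Known limitations

* Descriptors come from OpenBabel's property set (a few dozen), not a
  ~200-descriptor toolkit; the pipeline is descriptor-set agnostic by
  construction, but absolute model quality on real compounds will depend
  on the richer set.
* Global feature selection before splitting leaks label information into
  member test metrics (documented above).
* The bootstrap CI is percentile-based; with three replicates per dose its
  coverage is near, not exactly, nominal.
* No spatial plate-effect correction (B-score, median polish) is applied —
  the normalisation model is plate-mean only, by design.
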