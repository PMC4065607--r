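---
title: "Ranking engineered meganuclease variants: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking engineered meganuclease variants: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

I-CreI is a homodimeric LAGLIDADG endonuclease that cuts a 22 bp
pseudopalindromic DNA site. Redesigning it against a new genomic target is done
combinatorially: interface residues contacting the 5N3 region of the half-site
(positions 44, 68, 70, 75, 77 — the *p5N3 module*) and those contacting the
11N4 region (30, 32, 33, 38, 40 — *p11N4*) are mutated and screened
independently against all 64 possible 5N3 and 256 possible 11N4 region
targets, and full variants are then assembled by random pairing of modules and
screened in bulk against the target of interest. Only positive variants are
sequenced; every assembled-but-unsequenced combination is assumed negative.
The central 2N4 region makes no residue contact, its cleavage effect is
independent of the other regions, and the screening targets carry the
permissive GTAC center, so 2N4 contributes no model feature.

`mndesign` implements this pipeline end to end: the target coordinate system,
the combinatorial screen, feature encodings of (variant, target) pairs, a
LASSO + gradient-boosted-tree ensemble that ranks candidate variants per
target, per-target ranking metrics under target-level cross-validation, a
specificity module with an activity/specificity trade-off score, and a
calibrated generative simulator that stands in for the proprietary screening
data.

# Screening model and labeling

A candidate pool for a target is built by drawing `ceiling(k * n5 * n11)`
module pairs uniformly with replacement (`k` = oversampling, default 3) and
deduplicating. The expected fraction of distinct combinations is
`1 - (1 - 1/N)^(kN) -> 1 - exp(-k)`; at `N = 1600` and `k = 3` this is 95.0%,
which is why triple oversampling is the screening default. Positive-only
sequencing is modeled exactly: positives keep their measured activity score,
everything else becomes an assumed negative (activity 0, label 0,
`measured = FALSE`). Assumed negatives carry that provenance flag so analyses
can down-weight them; the default weight is 1, matching how the screen treats
them.

# Feature encodings

Three representations of a screening record:

* **categorical** — one factor column per protein key position (10) and per
  target position in 5N3/11N4 (7), plus two reals: the measured activity of
  the record's p5N3 module on the target's 5N3 region and of its p11N4 module
  on the 11N4 region (`MACT5`, `MACT11`).
* **Bin1** — one-hot expansion of every categorical column. Unseen levels at
  prediction time yield an all-zero block.
* **Bin2** — Bin1 plus element-wise products of pairs of order-1 binary
  sequence columns: protein x protein (M2M) and protein x target (M2T)
  products, each annotated with its parents and with the module side (p5N3,
  p11N4, or cross when the parents span both sides). Products of two
  indicators of the same position block are identically zero and never built;
  module-activity columns do not participate.

The support filter ("more than 200 non-zero components") is applied per
parent column by default: both parents must exceed the threshold. A
product-level variant is available (`filter = "product"`). The parent reading
bounds the pair enumeration and is implied by the product reading (a product's
support never exceeds its parents'); 200 is the screening-scale default and is
recomputed on the training rows of every cross-validation replicate. The key
position set is the ten enumerated interface positions; it is configuration,
not a hard-coded constant. Target-sequence features cover 5N3 and 11N4 only:
the 7N2 region's contacting residues are never varied by the combinatorial
process, so its nucleotides are constant within a library design and carry no
signal. Target x target products are off by default (`includeT2T`).

The named feature groups used in the ablation study are deterministic column
subsets: `Mact` (the two module-activity columns), `SM-5`/`SM-11` (Mact plus
one side's sequence features), `SM-5_11` (their union), `SM-M2M`/`SM-M2T`
(SM-5_11 plus one interaction class), `SM-Intra`/`SM-Cross` (SM-5_11 plus
within-side or cross-side products) and `SeqMact` (everything). A
`SeqMactFxStr` group additionally admits user-supplied external real-valued
columns (e.g. physics-based scores); no physics is computed here.

# Learners and the ensemble

Training is binary classification: the screen records activity scores only
for sequenced positives, so the continuous score cannot serve as a regression
response. The linear member is L1-penalized logistic regression (`glmnet`),
penalty chosen by inner cross-validation AUC over the lambda path (deviance
when folds are too small for stable AUC); defaults are a 12-value path with
`lambda.min.ratio = 0.05`, no standardization (the features are binary), and a
coordinate-descent tolerance of `1e-5` — at the package's data scales the
selected models and inner-CV AUC are indistinguishable from tighter
tolerances, at a tenth of the cost. The tree member is a gradient-boosted
decision-tree classifier with binomial loss (`xgboost`), trained on the
one-hot representation of the categorical dataset (trees over one-hot columns
span the same hypothesis space as trees over factors); depth and the number of
rounds come from inner CV with early stopping, single-threaded so predictions
are bit-identical under a fixed seed.

The ensemble score is the unweighted mean of the members' per-pool fractional
ranks, making it invariant under strictly monotone transforms of any member's
raw scores; a score-mean variant exists behind `combine = "score-mean"`. The
exact combination rule used in the original screening analysis is not fully
specified in the available material; the rank-mean is this package's
reconstruction, chosen because it needs no validation data and respects the
per-target ranking objective. Inner-CV hyperparameter selection sees training
folds only, and ensembles refuse members whose training-data fingerprints
differ.

Rankings are always descending-score with a lexicographic tie-break on the
variant identifier, so they are reproducible and independent of input order.

# Evaluation protocols

Cross-validation splits at the **target** level: a held-out target's entire
pool is unseen during training. Per-target metrics are the Mann-Whitney AUC
(ties count 1/2; single-class pools are excluded from AUC averaging but kept
for TopN), TopN (actives among the N highest-ranked, N = 10 by default) and
hitN (TopN >= 1); aggregates are means over test targets with standard errors
across replicates. A uniformly random scorer's expected hit rate has the
hypergeometric closed form `1 - C(K-m, N)/C(K, N)`, used as a calibration
oracle in the tests. Learning curves subsample training targets against the
same per-replicate test split (the full-size point reproduces the outer CV
exactly), and distance-constrained subsampling retains training targets at a
minimum Hamming distance from every test target, computed on the modeled
half-site regions 11N4+5N3 by default (`scope = "full"` switches to the whole
site); a size-matched uniform control isolates the effect of training-set
size from that of distance.

# Specificity and the trade-off score

A mutant's specificity on a target is its activity there divided by its total
activity over the 64-target 5N3 space; profiles are undefined (and flagged)
for all-zero rows. Candidates are ranked by `R_alpha = alpha * A +
(1 - alpha) * S` with `A` min-max rescaled across the candidate pool so the
two terms share a [0,1] scale (the original formulation does not state its
scaling; raw mixing is available via `rescale = FALSE`, and the package's
documented worked example of the formula uses the raw form). `alpha = 1`
reduces to pure activity ranking and `alpha = 0` to pure specificity ranking.
`countSpecificActives()` counts, among the top N, candidates that are truly
active and at least as specific as the wild-type reference — the wild type's
own specificity on its cognate 5N3 target within the same space.

# The generative simulator

The simulator is this package's construction; the screening study it emulates
has no published generative model. It is the minimal structure under which
every modeled feature class is identifiable:

```
score = clip01( b0 + w5 C5(m5, r5N3) + w11 C11(m11, r11N4)
                + nonspecific + M2M + M2T + noise ),   label = score >= tau
```

* **Module compatibilities** `C(m, s) = amp_m * decay^hamming(pref_m, s)`:
  each module has a preferred region target (libraries cover every region
  target), an amplitude in [0.5, 1] and a per-mismatch attenuation of 0.3.
  Measured library activities add Gaussian noise (sd 0.08) and are clipped.
  Library sizes default to 640 p5N3 and 512 p11N4 modules — roughly ten and
  two modules per region target, the scale at which module diversity makes
  pair effects attributable (see below).
* **Non-specific effects**: per residue-at-position, 60% zero otherwise
  N(0, 0.06^2), with planted deleterious 44F (-0.4) and 32K (-0.3).
* **M2M effects**: twelve planted residue pairs, within-side and cross-side,
  led by a strongly deleterious 44R+77R (-0.7). Planted pairs are pure
  epistasis: their component residues are individually neutral.
* **M2T effects**: twelve residue-nucleotide preferences at contacting
  position pairs (residue 70 with 5N3 bases 1-2, 44 with base 2, 68 with base
  3, 33 with 11N4 base 3, 30/38 with base 2, 40 with base 4), magnitudes
  0.2-0.45 with both signs.
* **Noise and thresholds**: latent sd 0.15; `tau = 0.25`; "strong" at 0.8.

The baseline `b0 = -1.05` is calibrated once so the default campaign (251
targets, 35 modules per side per pool, triple oversampling) reproduces the
screening scale's descriptive statistics: pools of about 1160 distinct
variants (35 x 35 = 1225 combinations at 95% coverage) and a mean of about 15
positives per target, with a heavy upper tail and a rejection-resampling
guarantee that every kept target has at least one positive — mirroring how
targets entered the real dataset. A zeroed-effects world
(`zeroSequenceEffects = TRUE`) removes all sequence-level terms and uses a
shallower baseline (-0.53, same calibration procedure) so module
compatibilities alone drive labels at the same positive rate; in that world
the module-activity features are sufficient and the sequence-based groups add
nothing.

Effect scales were set so that each feature class carries a distinguishable
share of the label variance — module compatibilities, main sequence effects,
M2M and M2T interactions all matter, with interactions mattering enough that
their ablation is visible above replicate noise. That is a design requirement
of the simulator (the ablation study must have signal to find), not a fit to
any empirical dataset.

The specificity-validation generator ties a mutant's amplitude to its breadth
through a steep logistic frontier: ultra-narrow binders are weak, activity
rises sharply past a breadth midpoint and saturates. This encodes the
activity/specificity tension: broadly active mutants are unspecific, highly
specific mutants are barely (or not at all) active, and the useful designs sit
just past the rise. The validation mode (default) floors amplitudes above the
activity threshold and rescues rows so every assayed mutant is active
somewhere, matching the validation set's composition, with a positive
fraction calibrated near 6.6% of mutant-target pairs. The candidate-space
mode (`ensureActive = FALSE`) drops the floor — an open candidate space
contains dead specialists. `simulatePredictedActivities()` emulates
sequence-model prediction error on such a space: breadth patterns are
predicted well but amplitudes poorly (sd 0.35), because amplitude reflects
hidden stability/expression determinants and the training labels are binary.
Under that error structure, ranking purely by predicted specificity surfaces
narrow binders regardless of whether they are alive — the failure mode the
trade-off score corrects, and the reason the alpha sweep peaks at
intermediate alpha.

## What the simulator does not emulate

Pool-size dispersion across targets (real pools ranged from under 500 to over
2000 variants; simulated pools are near-constant), sequencing and PCR
chemistry, assay noise structure beyond additive Gaussians, 2N4 effects, any
genomic target-space statistics, and auxiliary activity-boosting mutations
(such as I132V, carried as metadata only). Passing tests therefore show that
the pipeline recovers structure *of the kind the screen produces*, not that
it reproduces any particular laboratory figure.

# Identifiability of within-module pair effects

The deleterious 44R+77R pair involves two positions of the *same* module
half. In assembled pools, such a pair is carried by a handful of distinct
p5N3 modules, and each module's full five-residue signature is perfectly
collinear with the pair indicator on that module's records. At desk scales
(tens of targets) a sparse fit can therefore attribute the pair's effect to
collinear module-signature products: the fitted model predicts pair carriers
as inactive, but the named product coefficient may be zero. The effect is
real and recoverable from the generator by paired counterfactuals (carriers
score strictly below their pair-broken counterparts), and the acceptance
suite checks exactly that, alongside coefficient-sign recovery for the
planted effects whose components vary independently in assembly: the main
effects (44F, 32K), cross-module pairs, and residue-nucleotide preferences.
This mirrors a general property of combinatorial screens: cross-module and
protein-target interactions are identified by design, within-module epistasis
only at campaign scale (we verified that recovery of the named coefficient
improves with dataset size but remains partial even at 251 targets under the
default library diversity).

# Problem sizes in tests

The test suite builds an 8-target fixture for module-level tests, 40-target
datasets with 30 cross-validation replicates for the ablation-ordering check,
20 seeds of 40-target datasets for effect recovery, the full default
251-target campaign once for calibration checks, and a 10,000-candidate space
for the trade-off sweep. These sizes are the package's choices for a
reproducible desk-scale validation of a pipeline whose real inputs are
proprietary screening campaigns.

# Known limitations

* The ensemble combination rule is a reconstruction (rank-mean); alternatives
  are exposed but untested against the original.
* rankSVM and AUC-optimized boosting, reported as competitive-but-excluded in
  the original ensemble, are not implemented.
* Assumed negatives are treated as true negatives during training and
  evaluation, as the screen does; the simulator makes them exactly true,
  which real screens cannot guarantee.
* No physics-based (FoldX/Rosetta-style) scoring is computed; the
  `SeqMactFxStr` group only schemas external columns.
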