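# mndesign

Machine-learning design of I-CreI meganuclease variants for new DNA targets.

## The problem

I-CreI is a homodimeric LAGLIDADG homing endonuclease that cleaves a 22 bp
pseudopalindromic site, indexed −11…+11 around its center. Redesign against a
new target works combinatorially: module libraries of mutants at the
interface positions contacting the 5N3 region (Q44, R68, R70, D75, I77) and
the 11N4 region (N30, S32, Y33, Q38, S40) are screened once against all 64
5N3 and 256 11N4 region targets; full variants are then assembled by random
module pairing (typically 3× the theoretical diversity, covering
1 − e⁻³ ≈ 95% of combinations) and screened in bulk, with only positives
sequenced. Screening ~1,160 variants per target is expensive. `mndesign`
learns from such screens to *rank* candidate variants for an unseen target,
so that a handful of synthesized molecules replaces a high-throughput
campaign.

For a target *t* and candidate protein *p* the package trains an ensemble
scorer *A(t, p)* — an L1-penalized logistic model (glmnet) on one-hot +
pairwise-interaction encodings (Bin1/Bin2) combined with a gradient-boosted
tree classifier (xgboost) on the categorical encoding, averaged by per-pool
fractional rank. Feature groups (`Mact`, `SM-5_11`, `SM-M2M`, `SM-M2T`,
`SM-Intra`, `SM-Cross`, `SeqMact`) reproduce the ablation family used to
dissect which feature classes matter. Rankings are evaluated per target with
AUC, TopN and %TopN under target-level cross-validation. A specificity module
computes S(p, t) = A(p, t) / Σₜ′ A(p, t′) over the 64-target 5N3 space and
ranks designs by the trade-off score **Rα = α·A + (1 − α)·S**.

Because the original screening data are proprietary, the package ships a
calibrated generative simulator (module compatibilities + non-specific,
protein–protein and protein–target effects, squashed to [0, 1] and
thresholded) whose defaults reproduce the campaign's descriptive statistics:
251 targets, ~1,160-variant pools, ~15 positives per target, every target at
least one positive.

## Worked example

```r
library(mndesign)

model <- groundTruthModel(seed = 1)                 # simulator ground truth
ds <- generateScreeningDataset(model, nTargets = 20, seed = 1)
ds
#> ScreeningSet: 20 targets, 23164 records
#>   mean pool size 1158, mean positives/target 18.4

scorer <- trainScorer(ds, group = "SeqMact", learner = "ensemble", seed = 1)
cv <- outerCv(ds, replicates = 10, featureGroup = "SeqMact",
              learner = "lasso", seed = 1)
cv
#> CVSummary: 10 replicates, group SeqMact
#>   mean AUC 0.987 (SE 0.002) | mean Top10 6.05 | %Top10 95.0%
```

The mean AUC is the probability that a random active variant outranks a
random inactive one in a held-out target's pool; %Top10 is the fraction of
held-out targets with at least one true active among the ten top-ranked
candidates — i.e. the success rate of a ten-molecule synthesis budget.

A command-line interface wraps the same pipeline
(`inst/cli/mndesign simulate|train|evaluate|rank`); `rank --alpha 0.5 --top 10`
ranks candidates by the activity/specificity trade-off.

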