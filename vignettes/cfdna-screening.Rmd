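---
title: "Quantitative cfDNA screening with stabilised decision trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative cfDNA screening with stabilised decision trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfscreen)
```

## The problem

Plasma of cancer patients tends to carry more nuclear cell-free DNA
(cfDNA) and, perhaps counter-intuitively, less mitochondrial cfDNA than
plasma of healthy subjects. cfscreen operationalises a screening analysis
built on five quantitative and structural cfDNA markers:

* **Ref A 67 / 145 / 320** — nuclear cfDNA concentration (copies per mL
  of plasma) measured with amplicons of 67, 145 and 320 bp. The 67 bp
  amplicon approximates total cfDNA; the longer amplicons capture the
  upper tail of the fragment-size distribution.
* **Ref M 67** — mitochondrial cfDNA concentration (copies/mL, 67 bp
  amplicon).
* **MNR** — the mitochondrial-to-nuclear ratio, Ref M 67 / Ref A 67,
  lower in cancer.

No single marker separates cancer from healthy well enough for
screening, and the cohorts such markers are measured on are strongly
age-confounded (healthy donors are younger than cancer patients). The
package therefore combines (i) per-marker ROC screening under
age-matched resampling and (ii) an iterative decision-tree builder that
stabilises every node against resampling noise before descending.

## From Q-PCR output to copies per mL

Nuclear copy numbers divide the measured mass concentration (pg/uL) by
3.3 pg, the mass of one haploid human genome, and rescale by the elution
volume over the plasma volume (`nuclear_copies_per_ml()`).
Mitochondrial concentrations are quantified against a double-stranded
plasmid standard, so the mass-to-copies conversion runs through
Avogadro's number, the nucleotide molecular weight, the plasmid length
and a factor 2 for the double strand (`mito_copies_per_ml()`). For
murine samples, where no absolute standard is used, the relative
mitochondrial load is `2^-(Cq_mito - Cq_nuc)`
(`relative_mito_quant()`). Human analyses are carried in copies per mL
throughout; the mass-based murine convention is supported only through
these two entry points and is deliberately not reconciled with the
copy-number scale.

Two sample-level quality-control rules precede any analysis
(`apply_qc_filters()`): samples with Ref A 67 below 450 copies/mL carry
too little template to be quantified reliably, and samples whose cfDNA
integrity index DII = Ref A 320 / Ref A 67 exceeds 0.4 are suspected of
contamination with long genomic DNA from lysed white blood cells. Both
bounds are strict (a sample at exactly 450 copies/mL or DII = 0.4 is
retained — the literal reading of "below 450" and "> 0.4"), a sample
failing both rules is reported under the low-Ref A 67 reason only, and a
sample whose DII cannot be computed because Ref A 320 is missing passes
the DII rule and is flagged: QC never imputes.

## The synthetic cohort generator

No subject-level data accompany the study this package
operationalises, so `generate_cohort()` simulates cohorts reproducing
the features the method depends on; everything downstream is exercised
on them.

**Marker law.** Markers are multivariate log-normal: positive,
right-skewed, spanning orders of magnitude, which matches how plasma
cfDNA concentrations present. Groups share one covariance matrix and
differ by a location shift on the log10 scale. MNR is derived, never
sampled, so MNR = Ref M 67 / Ref A 67 holds exactly.

**Calibration.** Under this model a marker with log-scale group shift
$\delta$ and log-scale SD $\sigma$ has AUC
$\Phi(\delta / (\sigma\sqrt{2}))$. The shipped colorectal (CRC)
configuration inverts this identity at the published per-marker AUC
estimates (0.83, 0.83, 0.76 for the three nuclear markers, 0.59 for
Ref M 67), giving shifts (0.675, 0.742, 0.599, −0.193) at SDs
(0.50, 0.55, 0.60, 0.60). The correlation structure is a nested nuclear
block (Ref A 67–Ref A 145 0.90, Ref A 67–Ref A 320 0.70,
Ref A 145–Ref A 320 0.75 — the longer amplicons measure sub-fractions of
the 67 bp total) with Ref M 67 independent; the derived MNR then has an
implied AUC of 0.784 against its published estimate of 0.78 without any
further freedom. The breast configuration is solved the same way from
its published AUCs (0.77, 0.69, 0.60, 0.72; implied MNR 0.82). The
published AUCs do not uniquely determine a covariance; the correlations
above are the simplest structure consistent with the reported
relationships, and dispersion was fixed once, before calibration of the
shifts.

**Ages and demographics.** Integer ages are drawn from
piecewise-constant distributions over 5-year bands on 30–70 years
(25–65, all female, for the breast configuration), healthy subjects
peaking in their 40s and cancer subjects in their 60s — the age bias the
matching machinery exists to remove. Cancer subjects receive stage
labels; an optional `stage_shift_frac` lets early stages receive only a
fraction of the full marker shift so that stage-graded analyses have a
testable analogue (off by default, because the marginal calibration
above describes the all-stage cohort). An optional linear age–marker
trend hook exists and is off by default; its magnitude is not
established. Default per-marker missingness is 4% on Ref A 145,
Ref A 320 and Ref M 67 (never on Ref A 67, which QC requires), chosen so
that complete-case removal deletes roughly the 10% of subjects the
original cohort lost.

**What the generator does not emulate** — and hence what passing tests
do not establish about real plasma: pre-analytical variation (hemolysis,
freeze–thaw, delayed processing), batch effects between collection
sites, non-log-normal tails, group-specific covariance, and any
age–marker interaction beyond the optional linear hook. Results on
synthetic cohorts validate the machinery, not the clinical claim.

## Age-matched resampling

`assign_age_categories()` buckets subjects into the five CRC categories
`<45`, `45–50`, `51–55`, `56–60`, `>60` (with integer ages, age 45 falls
in `45–50`; the bounds admit either reading, so
`crc_age_scheme(age45_in_lower = TRUE)` is one flag away) or into
5-year bands within the 25–65 window for breast cohorts.
`age_matched_resample()` draws `min(n_cancer, n_healthy)` subjects per
group within each category — the rule that maximises usable subjects
while enforcing exact per-category parity — either without replacement
(a matched subcohort, used as the tree-building set) or with
replacement (one matched bootstrap replicate, the primitive all
resampling stages share). Whether the original 155+155 draw used
replacement within categories is not stated; both modes are
implemented and the replicate mode is used wherever a bootstrap is
called for. Subjects with missing or out-of-window ages are excluded
from matched analyses but retained in unadjusted ones.

## Per-marker ROC screening

`roc_curve()` places candidate thresholds at midpoints between
consecutive distinct pooled values (plus infinite sentinels), so the
reported cut-point is achievable by strict comparison on either side. A
subject is called cancer when its value is strictly above the threshold
for markers higher in cancer, strictly below for MNR and Ref M 67. The
AUC is the rank statistic with ties counted one half. The operating
threshold minimises the Euclidean distance to the ideal corner
(Se = 1, 1−Sp = 0), ties resolved toward the smaller threshold.

Confidence intervals use the **empirical (basic) bootstrap**
(`empirical_bootstrap_ci()`): compute the statistic on the data, form
the deviations of 2000 resampled statistics from it, and add the 2.5th
and 97.5th deviation percentiles back to the point estimate. The
percentile variant is deliberately not offered — the deviation-based
construction is the method this analysis specifies. Inside
`evaluate_marker()` the threshold is re-estimated within every
replicate, so the threshold CI reflects cut-point instability, not just
Se/Sp noise; with `age_matched = TRUE` every replicate re-draws a
matched bootstrap sample and the point estimate comes from one matched
subcohort. Resamples that lose a class are redrawn (at most 100
attempts), since small matched categories make single-class draws
possible.

## The tree engine

`grow_tree()` is a from-scratch recursive partitioner for a binary
outcome with continuous predictors. Splits minimise the within-node sum
of squares of the 0/1 outcome (`n·p·(1−p)` per node) — the
regression-tree criterion, which orders binary-outcome splits
identically to Gini. Defaults mirror the conventions of recursive
partitioning practice: `minsplit = 20`, `cp = 0.01` relative to the
root impurity, and a minimum-leaf rule expressed as 10% of the learning
set — the stopping rule that branch expansion halts when fewer than 10%
of the learning set would remain after a split. Ties between equal-gain
splits go to the lower variable index, then the lower threshold; leaf
labels are the majority class with ties labelled healthy (the
conservative call for a screening test); there are no surrogate splits
because analysis is complete-case upstream. `best_split()` is verified
against an exhaustive O(p·n²) enumeration oracle, and importance is the
total impurity decrease per variable, with no surrogate credit — a
documented divergence from implementations that award it.

`importance_over_resamples()` grows one tree per matched bootstrap
replicate (500 by default) and returns the full importance
distribution; age and sex enter as candidates by default precisely so
their near-zero importance after matching can be verified.

## The stabilised global tree

`build_global_tree()` is the package's centrepiece. At each node:

1. **Variable selection** (`select_node_variable()`): grow the best
   split on each of `n_trees` (default 500) matched bootstrap
   replicates of the subjects reaching the node, under the engine's
   admissibility rules evaluated against the full learning set.
   Replicates with no admissible split count as "no split". A
   chi-squared goodness-of-fit test against uniform selection
   frequencies must reject at `alpha`, **and** a continuity-corrected
   proportion test must separate the modal variable from the runner-up.
2. **Threshold estimation** (`estimate_node_threshold()`): the frozen
   variable's threshold is the median of the best single-split
   thresholds over `n_thresh` (default 2000) matched bootstrap
   replicates; its CI adds the 2.5th/97.5th percentiles of deviations
   from the replicate mean back to the median, and is widened if needed
   so the median always lies inside its own interval.
3. Subjects are routed (`value <= threshold` goes left) and the
   procedure recurses, stopping when no replicate can split the node,
   when the 10% minimum-leaf rule blocks all splits, or when the tests
   select no variable — plus depth and node-size guards.

Making the runner-up comparison binding (rather than advisory) is a
deliberate design choice. Bootstrap replicates of one cohort are
strongly correlated: on pure-noise cohorts, whichever variable is
spuriously best in that realisation wins a plurality of replicates, and
the goodness-of-fit test alone rejects far too readily — noise cohorts
grew spurious root splits in most null simulations. Requiring the modal
variable to also beat the runner-up restores the intended "no parameter
selected" behaviour under noise. The cost is conservatism when two
genuinely informative, strongly correlated markers compete (Ref A 67
and Ref A 145 often tie at sub-root nodes, where the builder then
refuses to freeze either and closes the node); pass
`require_top_two = FALSE` to make the runner-up test advisory and
recover deeper trees at the price of null robustness. The selection
log of every node (frequency table and both p-values) is kept on the
returned tree.

All randomness flows from one seed through stage-keyed sub-seeds, so an
entire tree is reproducible bit-for-bit from (cohort, configuration,
seed), and changing one stage's resample count does not perturb another
stage's draws.

## Evaluation

`split_train_test()` uses the matched subcohort as the training set and
all remaining subjects as the held-out set. `performance()` freezes the
tree and bootstraps the evaluation set only (2000 resamples), reporting
Se and Sp with basic-bootstrap CIs clipped to [0, 1] (the basic method
can overshoot; the clip is deliberate and visible). The "held-out
cross-validation" here is a frozen-tree test-set bootstrap — the tree
is never refitted. Subgroup rows (e.g. early stages pooled with all
healthy subjects) and cross-cohort application (a tree built on one
cohort applied to another) reuse the same report.

`compare_stability()` quantifies the motivating claim: over repeated
2/3–1/3 class-stratified partitions, the SD of held-out sensitivity of
the stabilised builder should not exceed that of a conventional
single-fit tree grown on the same 2/3. On age-biased synthetic cohorts
this holds in the package's acceptance checks.

## Numerical choices and problem sizes

Degenerate inputs are defined, not fatal: a single-class cohort grows a
single leaf; an all-tied Mann–Whitney comparison returns (z = 0,
p = 0.5); a constant variable at a node turns the node into a leaf; an
empty cohort passes QC with zeroed counts. Marker values stay in double
precision until rendering.

The test-suite simulations use cohorts of 200–500 subjects per group
with 40–500 resamples per stage, and the acceptance checks use the
resampling sizes stated with each property (e.g. 200 selection trees
and 500 threshold resamples per node for dominant-variable recovery);
these sizes give the Monte-Carlo properties comfortable margins while
keeping a full run in minutes. The redundancy check constructs its
decoy as a noisy monotone copy of the strongest marker with log10 noise
SD 0.45, chosen so the copy's discriminability ratio to its parent
(AUC 0.76 vs 0.83, correlation ≈ 0.75) reproduces the relationship
observed between the 320 bp and 67 bp nuclear markers — the situation
in which the original analysis found the redundant marker was never
selected at any node.

## Known limitations

The synthetic validation inherits every simplification listed under the
generator. The builder's conservatism under correlated competitors can
underfit relative to an analyst willing to break ties by fiat;
`require_top_two = FALSE` exists for that analyst. Cost-complexity
pruning, multiclass outcomes, categorical predictors and ensemble
prediction are out of scope: the method's output is one interpretable
tree.
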