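---
title: "Comparing dosing vehicles by dose-survival AUC: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing dosing vehicles by dose-survival AUC: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Historical anticancer screening programmes recorded, for hundreds of
thousands of compounds, how many of a small group of animals (typically
6-10) survived a given dose of the compound on a fixed assessment day. The
same compound was often tested in different *dosing vehicles* — saline,
carboxymethylcellulose (CMC), methylcellulose (MC), hydroxypropylcellulose
(HPC), distilled water & alcohol (DWA), Tween-80 and others — and the
vehicle can change the observed toxicity substantially. `vehitox`
implements an end-to-end procedure for deciding, from such dose-survival
records, which of two vehicles renders a compound less toxic, whether that
decision is statistically defensible, and how vehicles rank within a
family of structurally related compounds.

## Comparable experiments and aggregate curves

Two experiments are comparable only when every experimental factor other
than the vehicle matches exactly: compound, route, host species, number of
injections, injection interval, first injection day, number of repetitions,
assessment day and any restart days. `vehitox` stores these key fields as
character strings and compares them verbatim — no coercion is attempted, so
`"5"` and `"day5"` are simply different conditions.

Within one (condition, vehicle) group, replicate experiments (within and
across screening laboratories) are averaged: the aggregate curve carries
the mean survival fraction at each distinct dose. Replicates need not share
dose grids; the union of dose levels is used and each dose averages only
the experiments that tested it. Doses equal within a relative tolerance of
1e-9 are treated as one level, since float equality on dose values is
otherwise fragile. Survival is stored as a fraction in [0, 1]; percent
values (with or without a `%` sign) are converted on input, which avoids
0-100 vs 0-1 ambiguity downstream. Rows that violate the record invariants
(non-positive dose, survival outside [0, 1], survival inconsistent with a
whole number of surviving animals at percent-rounding precision) are
reported in a rejection table, never silently dropped.

## AUC comparison

Toxicity profiles are compared by the area under the piecewise-linear
dose-survival curve (AUC) over a common dose window, on the **linear** dose
axis (log axes in screening plots are purely cosmetic). A larger AUC means
higher survival, i.e. less toxicity. Three strategies align the two curves'
windows:

* **interpolation only** — the window is the intersection of the two dose
  ranges, with boundary survivals linearly interpolated;
* **extrapolate high** — a curve whose survival has already fallen to zero
  at its own top dose is additionally extended flat at zero up to the other
  curve's larger top dose;
* **extrapolate high-low** — additionally, a curve still at 100% survival
  at its lowest recorded dose is extended flat at 100% down to the other
  curve's smaller bottom dose.

Only flat (constant-survival) extension is ever applied, and eligibility of
the end-point survivals (0 or 1) is tested with tolerance 1e-9 because
aggregated means are floats. We follow the eligibility wording "at the
lowest recorded dose" rather than the lowest *common* dose. Extension never
alters survival inside a curve's original range.

The relative AUC difference is `100 * |A_a - A_b| / max(A_a, A_b)`. The
denominator choice was genuinely open (max, mean or a fixed reference all
arguable); `max` keeps the statistic symmetric under argument swap and
bounded in [0, 100]. A difference is called at thresholds of 30%, 40% or
60%; threshold 0 is a strict sign comparison, with relative differences
below 1e-9 treated as equality. Pairs with no window overlap, and
single-point curves (which have no area), are skipped with a logged reason
rather than forced into a verdict.

## Compound labels

Per-condition verdicts roll up to one compound label per vehicle pair:
`prefers_a`/`prefers_b` when every condition points the same way,
`no_preference` when all conditions show no difference, `equivocal` when a
preference coexists with no-difference conditions, and `contradictory` when
opposite preferences occur. Contradictory takes precedence over equivocal
when both patterns are present (the rules do not otherwise rank them).
Every condition key contributes one verdict; conditions are not pooled by
species or any coarser grouping. Only decided compounds enter modelling
(label 0 = less toxic in the first-named vehicle), and datasets below 50
compounds are flagged too small to model (`min_n` is configurable).

## Modelling protocol

Three classifier families are supported: CART decision trees (`rpart`),
random forests (`randomForest`, 100 trees), and PLS regression
(`mixOmics::pls`) used as a classifier by fitting the 0/1 label as a
quantity and cutting predictions at 0.5 (a prediction of exactly 0.5 is
assigned class 1; the rule "greater than or less than 0.5" leaves equality
open, and this choice makes the cut a total function).

Cross-validation is stratified 10-fold: each fold's class counts are within
one compound of the global ratio and fold sizes differ by at most one.
Descriptors are selected *inside each training fold* by absolute Pearson
(point-biserial) correlation with the label, constants excluded, ties
broken by ascending descriptor index. Decision trees and forests use a
budget of one tenth of the training-set size; PLS scans descriptor counts
5, 10, 20 and 50 and reports the best cross-validated balanced accuracy
(ties to the smaller count, for parsimony), with the number of PLS
components capped at one tenth of the number of data points. When the
selected descriptor block is rank-deficient (collinear binary keys are
common) and the NIPALS iteration diverges, the component count is reduced
until the fit succeeds; a fold whose learner fails outright aborts the
run. The
performance metric is balanced accuracy — the mean of sensitivity and
specificity — pooled over the out-of-fold predictions (the per-fold mean is
also reported; pooling is the primary figure because it uses every
compound exactly once).

Trees are grown with `rpart`'s default CART settings and no depth cap, with
the internal pruning cross-validation disabled (`xval = 0`): no pruning
protocol is part of the modelling procedure, and the internal CV would only
add cost without changing the fitted tree. All randomness — fold
assignment, forest seeds, label shuffles — flows from one master seed
through counter-based substreams, so every run is exactly reproducible.

## y-randomisation validation

Whether a model's performance could have arisen by chance is tested by
target shuffling: the labels are permuted (class counts conserved),
descriptors are **re-selected against the shuffled labels**, and the
identical CV protocol is re-run.

* **DT and PLS**: 300 null models by default; the real model is significant
  when its balanced accuracy sits in or above the null distribution's 99th
  percentile by the empirical CDF. The ECDF uses the weak inequality
  (`100 * mean(null <= real)`) so a tie with the 99th-percentile null
  counts. The null count is reducible for desk-scale runs and reports state
  the count used.
* **RF**: the real model is itself a distribution — 100 re-seeded forests —
  so 100 y-randomisations are each modelled 100 times. Each per-model seed
  drives both the fold assignment and the forest, so the 100-vector
  reflects both sources of variation. For every null distribution two
  statistics are computed against the real one: the histogram overlap
  (shared partition of [0, 1] into 20 equal bins — the bin count is a
  configurable reporting choice — summing the per-bin minimum of the two
  bin proportions) and the exceedance probability that a random real value
  beats a random null value. The exceedance probability is computed
  exhaustively over all pairs rather than by Monte-Carlo sampling — with
  100 x 100 values exhaustion is exact and cheap — with ties counting one
  half, which makes p(A,B) + p(B,A) = 1 exactly and the statistic unbiased
  under exchangeability; the standard error of the estimate is reported
  alongside. The collection is significant when the mean exceedance
  probability exceeds 80% — an arbitrary but fixed cut, kept configurable.
  The overlap is recorded but never used alone to declare significance.

## Cluster ordering

For families of structurally related compounds (matched by a SMARTS
pattern via ChemmineR/openbabel, e.g. `NP(=[O,S])(N)(N)` for
phosphoramides), preferences are tallied with extra rigour and no AUC
threshold: a compound counts as less toxic in a vehicle only when the
sign of the AUC difference agrees across **all three** strategies and all
of its conditions; anything mixed is excluded. A cluster shows a difference
for a vehicle pair iff the count preferring one vehicle exceeds the count
preferring the other *plus* the count showing no difference — a rule for
which the two directions are mutually exclusive.

Shown differences become strict edges (less-toxic to more-toxic vehicle)
and tallies without a shown difference become equivalence edges in a
partial-order graph. Consistency checking reports directed cycles among
strict edges and contradictions where two vehicles joined by an equivalence
path also stand in a strict relation. Equivalence is deliberately *not*
treated as transitive for ordering claims — it is an observed relation used
only for contradiction detection. A linear order (e.g. saline > CMC > MC >
DWA) is reported only when the strict relations totally order the vehicles
with no findings.

## The synthetic generator

Because the original screening dump is a large external download, the
package ships a generator that emulates its structure with known ground
truth. Survival follows a logistic in log-dose,
`s(d) = 1 / (1 + exp(slope * (ln d - ln LD50)))` — the simplest monotone
family reproducing the sigmoidal shape of real dose-survival plots — and
the observed group survival is `Binomial(n_animals, s) / n_animals`, so
the characteristic non-monotone noise of 6-10-animal groups (a single
animal dying out of order) arises naturally without an extra noise term.

The compound-and-vehicle LD50 is a per-compound baseline (log-uniform over
roughly 50-500 mg/kg/injection) plus structural-feature x vehicle shifts
and/or whole-vehicle offsets. By default two binary keys carry shifts of
+2 and -2 natural-log units in the second vehicle, a configured fraction of
compounds carries one of the keys, and the feature matrix doubles as the
descriptor matrix downstream — binary structural-key semantics without a
cheminformatics dependency. `null_mode` zeroes every shift for calibration
studies, and `degrade_to_equivocal()` adds a second, shift-free condition
(a different host species) to a chosen fraction of effect compounds so the
labelling stage has genuine equivocal cases to find. Dose grids are
geometric (default five doses spaced 1.5 natural-log units, jittered per
experiment by up to ±0.25), wide enough that both vehicles' transitions
fall inside the window. Each compound draws from its own seeded substream,
so compound C0007 is identical whether 10 or 1000 compounds are generated.

What the generator does **not** emulate: pharmacokinetics, tumour response,
correlated descriptor blocks, inter-lab systematic bias, or dose grids
chosen adaptively by the screener. Passing tests therefore demonstrate that
the machinery recovers known effects under idealised-but-noisy conditions,
not that any particular real vehicle pair is predictable.

## Problem sizes used in the shipped checks

The package's stochastic checks run at desk scale, chosen once: type-I
calibration uses 200 label-independent datasets of 60 compounds x 100
descriptors with 100-null decision-tree validations; signal recovery uses
120 compounds with ten planted keys at ±2 log-units, 100-null DT/PLS
validations and a 20 x 20 RF validation; ordering recovery uses 50
generator seeds of 30-compound clusters with vehicle offsets spaced 1.5
log-units (well above the binomial noise of 8-animal groups). Reports
always state the null counts used.

## Known limitations

* Curves are compared as raw piecewise-linear aggregates; no parametric
  dose-response model (probit/logit LD50 estimation) is fitted.
* The AUC-percentage denominator and the PLS tie-at-0.5 rule are
  documented package choices where the procedure itself is silent.
* Single-point curves cannot be compared and are skipped; a vehicle pair
  whose only evidence is single-dose experiments yields no verdict.
* `match_cluster()` needs ChemmineR/ChemmineOB; without them the ordering
  machinery still works on caller-supplied compound sets.
* Equivocal/contradictory compounds are excluded from modelling rather
  than modelled as a third class.
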