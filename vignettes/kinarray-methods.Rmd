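---
title: "Models and methods behind kinarray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

kinarray analyses phenotypic screens in which human protein kinases are
expressed from copper-inducible plasmids in arrayed *S. cerevisiae* strains.
Because most human kinases phosphorylate yeast proteins promiscuously,
an active kinase impairs colony growth under at least some stress
conditions, and the pattern of growth defects across conditions and strain
backgrounds becomes a readout of kinase activity. The same growth readout,
moved into a two-hybrid strain carrying a bait-prey pair plus a kinase
plasmid, reports phosphorylation-dependent changes in protein-protein
interactions. This vignette explains the models, the tunable parameters,
and the design decisions; the README shows the worked pipeline.

## The data model

The canonical unit is the *spot observation*: one colony of one construct
(a clone of a kinase or control protein, with or without a nuclear
localization sequence) in one strain under one condition, scored visually
on an ordinal 0-3 scale (none, weak, moderate, severe growth reduction).
All tables are tibbles and all stages are data-frame-in, tibble-out, so
the pipeline composes with the pipe.

Most proteins are covered by several clones, vectors and replicate spots.
`aggregate_to_kinase()` collapses them to one score per protein, strain and
condition. The default rule is the maximum over spots: any active construct
is taken as evidence of activity, which matches how kinase-level phenotypes
are called from redundant clone sets. A median rule is available for more
conservative collapsing (half-integer medians round down to stay on the
ordinal scale). Kinase-dead constructs always aggregate separately from
their wild-type kinase (suffix `-KD` when identifiers collide): merging
them would erase exactly the activity contrast the controls exist for.
Blank plate-grid cells are missing data, never score 0; counts downstream
are over non-missing entries only.

## Condition quality control

Some conditions suppress growth of most of the array regardless of which
kinase is expressed; they carry no kinase-specific signal. Plotting the
number of kinases with reduced growth per condition gives a bimodal
distribution: a low mode of specific conditions and a high mode of globally
toxic ones. `filter_conditions()` excludes condition-strain pairs whose
defect count strictly exceeds a cutoff (default 175 kinases, the reference
screen's published threshold); the cut is applied per condition-strain
pair, which is consistent with accounting in units of condition-strain
pairs. `detect_valley()` offers a data-driven alternative: the
minimum-density midpoint of the count histogram inside a search window.
When the minimum is a tied run of (often empty) bins, the centre of the
run is returned — the natural estimate for a wide gap — and among several
runs the lowest is chosen. A histogram with no interior minimum in the
window returns `NA` with a warning rather than inventing a threshold.

## Activity profiles and tiers

For each kinase and strain, activity is summarised as the number of
retained conditions with a defect (`condition_counts()`), then binned 0-4
(`bin_counts()`). Bin 0 is reserved for "no phenotype anywhere"; positive
counts are split at the quartiles of the strain's positive-count
distribution, ties going to the lower bin so equal counts always share a
bin. Quartile edges adapt to how many conditions each strain retained;
fixed edges are available to reproduce external tables.

`cluster_tiers()` clusters the kinases' per-strain bin vectors
(agglomerative, Euclidean distance) and cuts the tree into `k` groups.
Tier labels derive from descending cluster mean bins — never from cluster
indices — so labelling is deterministic: topmost, highly, moderately
(active), plus inactive at `k = 4`. Ward linkage is the default, as the
conventional general-purpose choice; `average` and `complete` are exposed
because the best linkage for a given bin table is an empirical matter.
In our planted-truth recovery experiments, average linkage is the more
reliable option: Ward's preference for equal-sized compact clusters tends
to split the sparse low-activity tier, while average linkage follows the
ordinal cluster means. Tier recovery in the acceptance analysis therefore
clusters with `k = 4` (the number of planted tiers) and average linkage.
Even so, hierarchical clustering of coarse 0-4 bins is intrinsically noisy
at the inactive/moderate boundary, and recovery quality varies a few
hundredths of adjusted Rand index from seed to seed.

## Group statistics

Group comparisons (kinases vs controls; tyrosine vs serine/threonine
ortholog classes) use the per-condition-strain *fraction* of group members
with a phenotype as the sampling unit, mirroring the box-plot convention of
array screens. The Mann-Whitney rank-sum test is implemented in the
package from first principles: `U` counts pairs with `x > y` plus half the
ties; the exact method enumerates the full permutation null (feasible for
`min(n) <= 8`, total `n <= 20`), and the large-sample path uses a normal
approximation with tie-corrected variance and a 0.5 continuity correction.
The implementation agrees with `stats::wilcox.test` to 1e-10 where both
apply, and with brute-force enumeration on thousands of random small
samples. No multiple-testing correction is applied by default, matching
raw reporting of screen p-values; Benjamini-Hochberg is available via
`adjust = "BH"`.

One statistical caveat belongs here because it is easy to trip over: the
fractions of two groups in the *same* condition-strain pair are not
independent — they share the condition's severity, and each group's
composition of latent activities is fixed within a screen. A rank-sum test
across condition-strain pairs therefore over-rejects when groups differ by
chance composition and under-rejects when severities vary strongly. The
package's type-I calibration check uses a null in which these couplings
are switched off (one activity tier for all kinases, equal class offsets,
no severity variation), where the per-pair fractions really are
exchangeable; under that null the empirical size at the 5% level is close
to nominal.

## The synthetic screen generator

`simulate_screen()` exists so every stage of the pipeline can be tested
against known truth without any external data. Scores are drawn from an
ordinal cumulative-logit model: for a spot of protein *k* in strain *s*
under condition *c*,

\[
\eta = a\,\mathrm{activity}_k + b\,\mathrm{severity}_c + \gamma_s +
d_{\mathrm{class}(k)},\qquad
P(\mathrm{score} \ge j) = \mathrm{logit}^{-1}(\eta - \theta_j),
\]

with strictly increasing thresholds \(\theta_1 < \theta_2 < \theta_3\).
The cumulative-logit form is the standard model for an ordered categorical
outcome; controls and kinase-dead constructs have activity 0.

The default configuration mirrors the reference screen's design: 266
kinases (41 tyrosine, 179 serine/threonine with a yeast ortholog, 46
without), 80 controls, a handful of kinase-dead variants, four strains
with distinct sensitivity offsets (the diploid background least sensitive,
the expression strain most), 73 conditions of which 17% are globally
toxic, two clones and two replicate spots per protein, and an 85%
evaluation rate per condition-strain — about 350,000 spots. Latent
activity tiers (inactive/moderate/high/topmost, activities 0-3) are drawn
with proportions 0.10/0.40/0.35/0.15. The coefficients were fixed once,
from expected-count algebra, to land the generator in the regime the
screen design implies: with `a = 2`, `theta = (7, 9, 11)`, condition
severities Normal(0, 0.4) for normal conditions versus Normal(4, 0.4) for
toxic ones, a normal condition shows a defect in roughly 65 of 266 kinases
(after max-aggregation over four spots), a toxic one in 230-266, the
defect-count histogram is bimodal with its valley in the 150-200 range,
and the count at which a normal condition would cross the 175 exclusion
threshold lies more than five severity standard deviations out. Tier
spacing of two logits keeps planted tiers recoverable from binned counts.

What the generator does *not* emulate: spatial plate artifacts (edge
effects, pinning failures) beyond missing cells, scorer drift between
batches, correlated condition families (all concentrations of one
treatment share biology), and clone-to-clone expression differences.
Passing recovery tests on synthetic screens therefore demonstrates that
the pipeline's logic is correct under the stated model, not that the
model captures every failure mode of real plates.

`simulate_y2h_plate()` emulates one bait-prey pair against a kinase
array: growth on control medium (SD3) is strong for every non-toxic
kinase, and the selective-medium (SD5) dilution score sits at a baseline
(3 of 4 steps when the pair interacts, 0 otherwise) shifted down two steps
for planted loss-of-interaction modulators or up for gain modulators.
Replicate noise is Gaussian on the latent dilution score (default SD 0.4
steps — scoring noise below half a step of a 1:10 series), then rounded
and clipped. Kinase-dead partners of phospho-dependent modulators lose the
shift; scaffold-type modulators keep it, which is what the
phospho-dependence flag detects.

`simulate_growth_curve()` samples a four-parameter logistic
\(\mathrm{OD}(t) = b + (K - b)/(1 + e^{-r(t - t_0)})\) on a 10-minute grid
over 24 h with Gaussian measurement noise, matching a plate-reader run.

## Phospho-Y2H calling

`dilution_score()` reduces a 1:10 dilution series to `1 +` the deepest
step with any growth (0 if none) — the ordinal strength measure used when
reading spotted plates. `call_modulators()` compares each kinase's SD5
score with the baseline estimated from unrelated-kinase controls (plate
median as fallback): a loss call needs a drop of at least `min_shift`
dilution steps (default 2 — one step is within scoring noise) in at least
`replicate_rule` of the replicates (default 2 of 3), and, critically, SD3
growth within `viability_max_drop` (default 1 step) of its baseline. The
SD3 gate exists because the most active kinases are growth-toxic on any
medium — precisely the confound that would otherwise flood a loss screen
with false calls; such kinases are reported with a toxicity flag instead.
Gain calls mirror the rule against a low baseline. Loss and gain are
mutually exclusive per kinase; calls are made within one copper induction
level only. These thresholds are reported in the call table's metadata
because the underlying plate reads do not define them uniquely.

## Growth kinetics

`fit_logistic()` fits the four-parameter logistic by Levenberg-Marquardt
least squares, initialised from the data (baseline = first OD, K = max OD,
t0 = half-range crossing, r = 0.5/h). Convergence is reported, never
assumed; flat or non-converged fits are flagged degenerate. The
four-parameter logistic is the minimal sigmoid for batch yeast growth; lag
extensions (Gompertz, Baranyi) are out of scope. `compare_wt_kd()`
contrasts wild-type against kinase-dead replicate curves; the default
metric is the trapezoidal area under the curve because it is defined even
for strongly inhibited, non-sigmoid curves, with fitted capacity `K` and
maximum OD as alternatives. The effect sign convention (kinase-dead minus
wild type) makes growth inhibition by the active kinase positive.

## Numerical choices and degenerate inputs

* Ordinal sampling uses one uniform draw per spot against the cumulative
  probabilities, which makes scores reproducible and monotone in the
  linear predictor.
* All generators run under `withr::with_seed`: byte-identical outputs for
  a given seed, with the caller's RNG state untouched.
* Quartile bin edges use the default continuous quantile definition;
  ties at an edge fall to the lower bin.
* Exact rank-sum enumeration compares with a tolerance of
  `sqrt(.Machine$double.eps)` so tied U values are counted as extreme.
* An empty control set, a unimodal count histogram, a flat growth curve,
  or an over-large `k` all produce warnings, flags, or typed errors —
  never silent results.

## Problem sizes in the test suite

The packaged checks run the full reference-scale screen (356 proteins x 4
strains x 73 conditions, ~350,000 spots) once for QC and tier recovery;
1000 scaled-down null screens (90 kinases, 20 conditions, 2 strains) for
the type-I calibration; 50 seeded two-hybrid plates of 100 kinases for
caller recovery; and 50 noisy growth curves for fit recovery. These sizes
keep the whole suite in the low minutes on one CPU while leaving Monte
Carlo error well below the decision margins of each check.

## Known limitations

* The 0-3 scores enter as data; no image quantification is provided.
* Identifier mapping is out of scope: protein identifiers are free-text
  symbols.
* The rank-sum comparison inherits the pseudo-replication caveat above;
  for confirmatory use, a mixed model over kinases would be the next step.
* Reproducing the published tier sizes from the published bin tables may
  require trying the exposed linkage options, since the original clustering
  settings are not fully specified.
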