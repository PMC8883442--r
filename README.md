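# kinarray

Analysis of human-kinase yeast-array phenotypic screens.

Expressing a human protein kinase in *Saccharomyces cerevisiae* lets its
activity be read out as a growth phenotype: an active kinase aberrantly
phosphorylates yeast proteins and impairs colony growth under at least some
stress conditions. Screens built on this principle array hundreds of
kinases (plus inactive controls and kinase-dead mutants) across several
strain backgrounds and dozens of conditions, score every colony on an
ordinal 0–3 scale (none / weak / moderate / severe growth reduction), and
then ask which kinases are active, how active, and — in the phospho-Y2H
variant — which kinases rewire a specific protein–protein interaction by
phosphorylation. kinarray is for the people analysing such screens: it
covers every step from raw spot tables to activity tiers, cross-strain
concordance, group statistics, interaction-modulation calls and liquid
growth-curve comparisons, with a synthetic-data generator so the whole
pipeline is testable end to end.

## The models at the core

**Ordinal score model.** Spot scores are treated as draws from a
cumulative-logit model. For protein *k*, strain *s*, condition *c*:

    eta = a * activity_k + b * severity_c + gamma_s + d_class(k)
    P(score >= j) = plogis(eta - theta_j),   j = 1, 2, 3

Controls and kinase-dead constructs have activity 0. The synthetic
generator samples from this model with planted tiers, toxic conditions and
strain offsets, which gives every downstream stage a known truth to be
tested against.

**Condition QC.** The number of kinases with reduced growth per condition
is bimodal: specific conditions versus globally toxic ones. Condition-strain
pairs with strictly more than 175 affected kinases (configurable; a valley
detector offers a data-driven alternative) are excluded.

**Activity tiers.** Per strain, each kinase's count of defect conditions is
binned 0–4 (bin 0 = no phenotype; quartile splits with ties to the lower
bin), and kinases are clustered on their bin vectors into topmost / highly /
moderately active tiers.

**Rank-sum statistics.** Group comparisons (kinases vs controls, tyrosine
vs S/T ortholog classes) use per-condition-strain phenotype fractions and a
Mann–Whitney U test implemented in the package: exact permutation
enumeration for small samples, tie- and continuity-corrected normal
approximation otherwise.

**Phospho-Y2H calls.** A kinase is a loss-of-interaction modulator if its
selective-media (SD5) dilution score drops ≥ 2 steps below the control-kinase
baseline in ≥ 2/3 of replicates while control-media (SD3) growth is intact —
the SD3 gate keeps growth-toxic kinases from being miscalled. Gain calls
mirror the rule; kinase-dead partners distinguish phospho-dependent
modulation from scaffold effects.

**Growth kinetics.** OD595 time series are fit with a four-parameter
logistic `baseline + (K - baseline) / (1 + exp(-r (t - t0)))`;
wild-type vs kinase-dead effects are summarised by AUC (default), fitted
capacity `K`, or maximum OD.

## Worked example

```r
library(kinarray)
library(dplyr)

# a synthetic screen at reference scale, with planted truth
sim <- simulate_screen(sim_config(seed = 42))
sim
#> Synthetic colony screen: 356000 spots; 356 proteins; 4 strains; 73 conditions (12 toxic)

mat <- aggregate_to_kinase(sim$observations, sim$constructs)  # clones -> kinases, rule = max
dc  <- defect_counts(mat, annotations = sim$annotations)      # kinases with defect per pair
fc  <- filter_conditions(dc, max_defect = 175)                # QC: flag toxic pairs

evaluable_accounting(sim$conditions, fc)
#> 208 condition-strain pairs retained; 31 condition(s) retained in all 4 strains
#> # A tibble: 4 × 2
#>   strain n_conditions
#>   <chr>         <int>
#> 1 BY4742           55
#> 2 L40c             51
#> 3 W303             48
#> 4 Y258             54
```

208 of the 73 × 4 evaluated condition-strain pairs survive QC — the 12
planted toxic conditions are removed in every strain where they were
evaluated. Activity tiering:

```r
bb <- condition_counts(mat, fc) |> bin_counts()
kinases <- sim$annotations$protein_id[!sim$annotations$is_control]
cluster_tiers(filter(bb, protein_id %in% kinases), k = 3)
#> Activity tiers (ward linkage, k = 3):
#> # A tibble: 3 × 3
#>   tier       n_kinases mean_bin
#>   <chr>          <int>    <dbl>
#> 1 topmost           46     4
#> 2 highly            89     3.05
#> 3 moderately       131     1.13

severe_strain_histogram(mat, fc)
#> # A tibble: 4 × 2
#>   n_strains n_kinases
#>       <int>     <int>
#> 1         4        26
#> 2         3        17
#> 3         2        23
#> 4         1        56
```

26 kinases cause a severe (score 3) defect in all four strains. Kinases
cause phenotypes far more often than controls:

```r
gf <- group_fractions(mat, sim$annotations, "kinase_vs_control",
                      severity = 1, retained = fc)
compare_groups(gf, list(c("kinase", "control")), method = "normal_approx")
#> # A tibble: 1 × 9
#>   group1 group2     n1    n2 median1 median2 statistic  p.value method
#>   <chr>  <chr>   <int> <int>   <dbl>   <dbl>     <dbl>    <dbl> <chr>
#> 1 kinase control   208   208   0.239       0     43264 5.29e-72 normal_approx
```

The median condition-strain pair shows defects in 24% of kinases but 0% of
controls. A phospho-Y2H screen with two planted loss modulators:

```r
pl <- simulate_y2h_plate(n_kinases = 100,
                         true_modulators = c(KIN017 = "loss", KIN052 = "loss"),
                         seed = 11)
calls <- call_modulators(pl)
phospho_dependence_table(calls)
#> # A tibble: 2 × 4
#>   kinase wt_mode kd_mode phospho_dependent
#>   <chr>  <chr>   <chr>   <lgl>
#> 1 KIN017 loss    none    TRUE
#> 2 KIN052 loss    none    TRUE
```

Both planted modulators are called (effect size 2 dilution steps, 3/3
replicates), their kinase-dead partners are silent, so the modulation is
phospho-dependent. Finally, a noisy 24 h growth curve is refit to within a
few percent of its planted parameters:

```r
glance(fit_logistic(simulate_growth_curve(K = 0.9, r = 0.45, t0 = 9,
                                          baseline = 0.12, noise_sd = 0.01,
                                          seed = 5)))
#> # A tibble: 1 × 8
#>       K     r    t0 baseline    rss converged degenerate     n
#>   <dbl> <dbl> <dbl>    <dbl>  <dbl> <lgl>     <lgl>      <int>
#> 1 0.901 0.444  9.00    0.119 0.0145 TRUE      FALSE        145
```

Each result type has `tidy()`/`glance()` methods and plot functions
(`plot_defect_counts()`, `autoplot()` on tier clusterings and logistic
fits, `plot_group_fractions()`, `plot_upset_counts()`).

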