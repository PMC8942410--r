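# dietshift

Analysis pipeline for a single-arm pre/post anti-inflammatory-diet
intervention in inflammatory bowel disease (IBD). Subjects with Crohn's
disease (CD) or ulcerative colitis (UC) are followed through a 6-week
baseline and an 8-week intervention with repeated stool metagenomes,
thrice-weekly 24-hour food queries scored into five diet categories
(prebiotics, probiotics, beneficial, adverse, alcohol), and a pre/post
14-analyte cytokine panel. The package asks, with tested reusable code: did
participants change their diet; which bacterial species track the study
period; which foods drive which species, in which diagnosis; and how do
intakes relate to circulating cytokines?

## The models at the core

**Mixed-effect random forest (MERF).** Repeated samples per patient break
exchangeability, so microbiome responses are modelled as

    Y_ij = f(X_ij) + b_j Z + eps_ij

with `f` a random forest, `b_j` a patient-level random intercept (variance
`D`) and `eps ~ N(0, sigma2_e)`, fitted by EM-style alternation: fit the
forest to `y - b`, then update `b`, `sigma2_e`, `D` with the closed-form
mixed-model steps using `V_j = Z D Z' + sigma2_e I`, until the marginal
likelihood stabilizes. Used twice: classifying intervention vs baseline from
species abundances, and regressing each species on category servings with
diagnosis, age, sex, BMI and food x diagnosis interactions.

**PIMP.** Feature significance via permutation: refit the whole model on
permuted responses (within-subject by default), p = (1 + #{null >=
observed})/(n_perm + 1), BH-adjusted.

**Repeated-measures correlation.** For screened food-species pairs, the
common within-subject association from an ANCOVA with a subject factor:
`r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_e))`, df = N - k - 1, run
separately per diagnosis.

Around these sit diet-category scoring with Table-style phase summaries and
Mann-Whitney comparisons under two-stage (Benjamini-Krieger-Yekutieli)
adaptive FDR, Shannon/Bray-Curtis/PERMANOVA community statistics (via
vegan), cytokine-food regressions with pre/post exact Wilcoxon tests, and
Monte-Carlo power for the paired signed-rank test. A synthetic cohort
generator with explicit ground truth makes the whole pipeline testable end
to end; see `vignettes/diet-microbiome-methods.Rmd` for the methods account.

## Worked example

```r
library(dietshift)

# five planted diet-responsive species (+prebiotics, -adverse effects)
truth  <- planted_truth(n_planted = 5)
cohort <- simulate_study(n_cd = 15, n_uc = 7, truth = truth, seed = 1)

diet_shift_summary(cohort$food_records)[1:4, c(1:4, 6:7)]
#>     category mean_baseline mean_intervention difference fold_change direction
#> 1 prebiotics          4.23              7.51      3.280        1.78  increase
#> 2 probiotics          1.07              1.60      0.526        1.49  increase
#> 3 beneficial          3.96              6.23      2.263        1.57  increase
#> 4    adverse         13.09              3.42     -9.673        3.83 reduction

cls <- classify_period(cohort$abundance, cohort$samples$phase,
                       cohort$samples$subject_id,
                       merf_control(num_trees = 300, max_iter = 10))
round(cls$auc, 3)
#> [1] 0.972
head(cls$ranking$feature, 5)   # the five planted species lead the ranking
#> [1] "s__Synthetic_species_05" "s__Synthetic_species_01" "s__Synthetic_species_04"
#> [4] "s__Synthetic_species_03" "s__Synthetic_species_02"

pow <- wilcoxon_power(n = 10, effect_mean = 0.005, effect_sd = 0.005,
                      alpha = 0.05, reps = 10000, seed = 1)
pow$power_hat      # paired signed-rank power for a 0.005 +/- 0.005 abundance shift
#> [1] 0.778
```

The fold changes mirror the configured intake shift (1.8x more prebiotics,
3.7-3.8x fewer adverse foods); the AUC says held-out (out-of-bag) samples
are almost perfectly assignable to study period from the microbiome; and a
10-subject pre/post design detects a 0.005 +/- 0.005 relative-abundance
shift with ~78% power (the exact test's achievable size at n = 10 is 0.0488,
slightly below the nominal 0.05).

The numbered scripts under `analysis/` run the complete study analysis on a
simulated cohort — `01_simulate_cohort.R` through `06_power.R` — writing
tables to `results/`. `run_pipeline()` orchestrates the same stages from a
single config (in memory or YAML) with a deterministic, timestamp-free
output bundle.

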