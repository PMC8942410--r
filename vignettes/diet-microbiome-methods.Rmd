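---
title: "Methods: modelling diet-microbiome-immune associations in a pre/post intervention cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling diet-microbiome-immune associations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`dietshift` implements the statistical machinery of a single-arm pre/post
dietary-intervention study in inflammatory bowel disease (IBD): subjects with
Crohn's disease (CD) or ulcerative colitis (UC) are followed through a 6-week
baseline and an 8-week anti-inflammatory-diet intervention, with repeated
stool metagenomes, thrice-weekly 24-hour food queries scored into five diet
categories (prebiotics, probiotics, beneficial, adverse, alcohol), and a
pre/post 14-analyte cytokine panel. This vignette explains each model, the
choices made where the design was genuinely open, and what the synthetic
cohort used in the tests does and does not establish.

## The mixed-effect random forest (MERF)

Repeated samples from the same patient are not exchangeable, and the
relationship between diet and species abundance has no reason to be linear.
The core model is therefore

$$Y_{ij} = f(X_{ij}) + b_j Z + \varepsilon_{ij},$$

where $Y_{ij}$ is the response for sample $i$ of patient $j$ (a species'
relative abundance, or the 0/1 study-period label), $f$ is a random-forest
regression learned from the fixed-effect features $X$, $b_j$ is a
patient-level random intercept with variance $D$, and
$\varepsilon \sim N(0, \sigma^2_e)$. Fitting alternates, EM-style:

1. given the current $b_j$, fit the forest to the working response
   $y_{ij} - b_j$;
2. given the forest's predictions, update $b_j$, $\sigma^2_e$ and $D$ with
   the standard linear-mixed-model closed forms using
   $V_j = Z D Z' + \sigma^2_e I$.

Numerical choices that matter:

* **Out-of-bag predictions drive the mixed-model updates.** In-sample forest
  predictions memorize the training response; using them collapses the
  residual variance and biases both $\sigma^2_e$ and $D$ toward zero. With
  out-of-bag predictions, simulations with 50 clusters of 20 observations,
  intercept SD 2 and noise SD 0.5 recover the per-cluster intercepts with
  correlation above 0.99, and a zero-variance truth yields
  $\hat D < 0.02\,\hat\sigma^2_e$.
* **Convergence is monitored on the marginal negative log-likelihood** of
  $y - f$ under $V_j$ (closed form for an intercept-only design). For a
  constant fixed-effect learner the alternation is exact EM and the trace is
  non-increasing to machine precision; with a forest the trace descends
  steeply and then fluctuates slightly as trees are refit on the moving
  working response. The fit stops when the relative change drops below
  `tol` (default `1e-4`) or at `max_iter`.
* **One forest seed across iterations.** Re-seeding every iteration adds
  tree-sampling noise to the trace; a fixed seed lets the forest settle as
  the working response settles.
* **Variance floors.** $D$ is floored at $10^{-10}$ (keeping $V_j$
  invertible when the between-cluster variance genuinely collapses) and
  $\sigma^2_e$ at $10^{-12}$.
* Binary classification is realized as MERF regression on the 0/1 label with
  a 0.5 threshold; the forest is a regressor throughout.
* Default forest settings: 300 trees, `mtry` $= \sqrt p$ for the
  classification use and $p/3$ for per-species regression, minimum node size
  5. Abundances enter as proportions without transformation.

For period classification, samples are scored by the **out-of-bag fixed
part only**. Adding the fitted subject intercept would hand each sample its
own subject's average label — under permuted labels that inflates apparent
discrimination (we measured AUC ≈ 0.6 instead of 0.5). Out-of-bag scores are
honest, at the price of the well-known slight pessimism of out-of-bag error
on null data.

## Permutation importance (PIMP)

Forest importances have no native null distribution, so significance comes
from refitting the entire model on permuted responses: with `n_perm`
permutations, $p = (1 + \#\{\text{null} \ge \text{observed}\})/(n_\text{perm}+1)$,
BH-adjusted across features. The permutation scheme defaults to
**within-subject** (responses shuffled only inside a patient's samples),
which preserves the repeated-measures structure the model assumes; a free
scheme is available. `n_perm` defaults to 99 — each additional permutation
refits a full MERF, which is the pipeline's cost center.

## Repeated-measures correlation

For food-species pairs passing the PIMP screen, the direction and strength
of the common within-subject association is the repeated-measures
correlation: an ANCOVA of $y$ on $x$ with subject as a factor and a common
slope, $r_{rm} = \mathrm{sign}(\beta)\sqrt{SS_x/(SS_x+SS_e)}$ with
$df = N - k - 1$ for $N$ paired observations from $k$ subjects, run
separately in CD and UC. Confidence intervals use a Fisher z-transform with
the rmcorr degrees of freedom (effective sample size $df+2$). Incomplete
pairs are dropped pairwise; subjects left with fewer than two pairs are
dropped with a logged count.

**Selection-aware FDR.** The screen and the correlation are computed on the
same data, so adjusting only the screened rows would inherit the screen's
selection bias (in a null simulation we observed one of two screened rows
"passing FDR"). The pipeline therefore computes rmcorr over the complete
species x category x diagnosis family — cheap, since each is a single linear
model — and takes BH q-values from that full family; the reported table is
the screened rows carrying their full-family q. Both raw p and q columns are
emitted.

## Diet scoring and phase comparison

Item-level food-query records are mapped to categories via a serving-
conversion table (a small illustrative map ships with the package; the full
240-item instrument is not published in machine-readable form) and summed
per record. Phase summaries report per-category means, the intervention
minus baseline difference with an SEM computed over per-subject phase-mean
pairs (record-level pooling cannot reproduce subject-paired SEMs), and fold
changes as larger/smaller with a direction label, reported to one decimal.
Phase comparisons use the Mann-Whitney test — exact when both phases have at
most 8 records and no ties, otherwise the tie-corrected normal
approximation — with the two-stage Benjamini-Krieger-Yekutieli adaptive
step-up across categories at $q = 0.05$. Models can use per-record daily
servings or weekly averages as the food covariate; weekly averages are the
pipeline default.

## Community statistics and cytokines

Shannon diversity (natural log), Bray-Curtis dissimilarity and PERMANOVA are
delegated to `vegan`; the wrapper enforces composition-scale inputs and
exposes within-subject permutation strata (recommended for repeated samples;
free permutation — the published analysis' choice — remains the default).
Cytokine levels are regressed on per-subject mean category servings by
ordinary least squares, pooling subject x period points by default (a
per-period mode exists); pre/post shifts use the exact Wilcoxon matched-pairs
signed-rank test with zero differences dropped, and $p \le 0.1$ labelled a
trend — a label, never a rejection.

## Power calculations

The power module simulates the study's primary-outcome calculation: `reps`
datasets of $n$ paired differences from
$N(\text{effect mean}, \text{effect SD})$, tested with the exact two-sided
signed-rank test. "0.005 ± 0.005" is interpreted as mean 0.005, SD 0.005 —
the idiom of the simulation tools this mirrors. At $n = 10$, $\alpha=0.05$,
10,000 replicates, the empirical power is ≈ 0.78-0.79; the exact test's
achievable size at $n=10$ is 0.0488, which is why the value sits just below
the nominal 0.80. The Spearman sample-size finder simulates bivariate
Gaussian data with the Pearson correlation $2\sin(\pi\rho_s/6)$ inducing the
requested Spearman $\rho_s$ and bisects on $n$ (power is monotone in $n$).

## The synthetic cohort generator

The generator exists so that every downstream stage can be validated against
known truth without any data download. It emulates: 22 subjects (15 CD, 7
UC) with group demographics (CD age 41.7 ± 13.3, BMI 29.3 ± 5.4, 73% female;
UC 37.8 ± 11.5, 25.4 ± 6.7, 29% female); weeks 1-6 baseline, 7-14
intervention; per-subject stool-sample counts from rounded N(6.5, 2.1) and
N(10.3, 5.1) clipped to at least one; food queries answered each day with
probability 3/7; daily category servings Gamma-distributed (shape 4) around
phase means prebiotics 4.08→7.51, probiotics 1.09→1.59, beneficial
3.88→6.13, adverse 12.64→3.42 servings/day, plus a small alcohol category
0.3→0.2 (no published value; chosen as a realistic minor intake).

Species abundances arise from a latent linear model — baseline level +
category effects x weekly servings + UC-interaction terms + per-subject
intercept (SD 1) + Gaussian noise (SD 0.5) — truncated at zero and
renormalized to a composition per sample. Truncate-and-renormalize is the
simplest mapping that preserves configured effect directions; it is not a
model of sequencing counts. Cytokines are linear in per-phase mean servings
with Gaussian noise (SD 5 pg/mL around a 30 pg/mL intercept).

**The planted-effect scenario** (`planted_truth()`) gives five
"diet-responsive" species a latent effect of +0.5 per prebiotic serving and
−0.15 per adverse serving. Both signs matter: the scenario mirrors the
SCFA-producer narrative (fed by fermentable fiber, suppressed by adverse
foods), and the adverse-food shift (12.64 → 3.42 servings/day) is by far the
intervention's most discriminative signal — weekly prebiotic intake alone
separates the phases at AUC ≈ 0.89, an information ceiling no effect size
can beat, while the combined response supports AUC ≈ 0.98. Effect magnitudes
are free parameters of the generator, not estimates from any dataset.

What passing tests on this cohort do **not** show: robustness to sequencing
noise, compositional count models, taxonomic misassignment, phylogenetic
structure, non-Gaussian latent dynamics, or diet measurement error. The
generator encodes exactly the structure the inference assumes — clustered,
food-driven, compositional — so recovery results validate the machinery, not
the biology.

## Problem sizes and determinism

The orchestrated pipeline defaults to desk-scale settings chosen for
routine reruns: association models with 50 trees and at most 3 EM
iterations (each species model is refit `n_perm + 1 = 100` times for the
permutation null, so this recipe is deliberately lean; the 99 permutation
refits average out per-fit importance noise), classification models with
300 trees and 10 iterations,
999 PERMANOVA permutations, and 10,000 replicates for the power calculation.
A full simulated-cohort run (22 subjects, 40 species) completes in a few
minutes on one core. Every stochastic stage draws its stream from the single
config seed, and a rerun of the same config produces byte-identical output
files; the run manifest (versions, seeds, parameters) deliberately omits
timestamps for that reason.

## Known limitations

* The random-effect design is an intercept per patient; no random slopes.
* Binary outcomes are handled as linear-probability MERF regressions, not a
  mixed-effects logistic forest.
* The exact Mann-Whitney threshold (both groups ≤ 8, no ties) and the
  Fisher-z CI for $r_{rm}$ are conventional choices, not derived ones.
* The shipped category map is illustrative; real analyses must supply the
  instrument's own item map.
* Under the all-zero truth the screened table is empty with high
  probability, not with certainty: the screen is itself a random variable.
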