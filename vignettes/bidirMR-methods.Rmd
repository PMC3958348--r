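---
title: "Bidirectional Mendelian randomization for adiposity and physical activity: models and methods"
author: "bidirMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bidirectional Mendelian randomization: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidirMR)
```

## The scientific question

Cross-sectional studies find that heavier children are less physically
active, but the association alone cannot tell whether adiposity suppresses
activity, inactivity drives weight gain, or shared confounders (family
environment, diet, puberty) produce both. bidirMR implements the causal
machinery used to separate these explanations in a birth cohort of
11-year-olds: genetic variants, assigned at conception and therefore
independent of later confounding, serve as instrumental variables in both
directions — a weighted allelic score of 32 established BMI loci instruments
adiposity, and split-sample genome-wide prediction scores instrument
activity.

## The instrumental-variable model

For outcome $y$, exposure $x$ and instrument $g$ (all per individual, with
covariates $W$, here age), the structural model is

$$ y = \beta x + W\gamma + \varepsilon, \qquad
   \mathrm{Cov}(g, \varepsilon) = 0 . $$

`tslsFit()` estimates $\beta$ by two-stage least squares: the first stage
regresses $x$ on $(g, W)$, the second regresses $y$ on the fitted $\hat x$
and $W$. Standard errors use the *structural* residuals
$y - x\hat\beta - W\hat\gamma$ (substituting the observed exposure back in),
the classical homoskedastic form, and normal-theory confidence intervals —
the large-sample convention for instrumental variables. Observational fits
(`olsFit()`) use t inference. A heteroskedasticity-robust option was
considered and deliberately left out of the default path because the
emulated analysis reports classical estimates; the residual bootstrap is
out of scope.

Instrument strength is summarised by the nested-model first-stage F and
partial $R^2$ (`firstStageDiagnostics()`): with RSS$_r$/RSS$_f$ the
first-stage residual sums of squares without/with the instrument,
$\mathrm{partial}\,R^2 = (\mathrm{RSS}_r - \mathrm{RSS}_f)/\mathrm{RSS}_r$
and $F$ is the corresponding nested ANOVA statistic. Fits with $F < 10$
carry a machine-readable `weak_instrument` flag (the conventional
rule-of-thumb threshold).

Endogeneity is tested with the Durbin (control-function) form of the
Durbin–Wu–Hausman test (`durbinWuHausman()`): the outcome regression is
augmented with the first-stage residual $\hat v$ and the squared t statistic
of $\hat v$'s coefficient is referred to $\chi^2_1$. The control-function
form is used as the implementation because the alternative
Hausman-contrast variance can fail to be positive definite in finite
samples; the two are asymptotically equivalent.

## Scores

`weightedAllelicScore()` computes $\sum_j w_j g_{ij}$ with external
meta-analysis weights $w_j$, and by default rescales by $J/\sum_j w_j$ so
the score lives on the 0–2J "average number of trait-increasing alleles"
scale (a 32-SNP score then has range 0–64, matching the reported mean of
about 29.6). Missing dosages are imputed as $2\,\mathrm{eaf}$ — the
frequency expectation, mirroring standard profile-scoring behaviour; the
source analysis does not document its missing-data rule, so this choice is
a package decision. Prediction scores (`buildPredictionScore()` /
`applyScore()`) keep every SNP at discovery $p \le 0.1$ (inclusive
boundary), weight by the signed discovery beta, and sum (not average)
across SNPs; allele orientation is reconciled per SNP by flipping dosage to
$2-g$ when the effect allele is the other strand's label.

The shipped `syntheticBmiPanel()` is a synthetic stand-in for the published
32-locus panel (whose per-SNP table is supplementary material not
redistributed here): weights mimic the published magnitude profile with a
single dominant FTO-like locus (0.39), and frequencies were calibrated once
so the allele-count score of a Hardy–Weinberg population has mean ≈ 29.6
and SD ≈ 4 on the 0–64 scale.

## GREML heritability

`computeGRM()` builds the standardized-dosage genetic relationship matrix
$A_{jk} = M^{-1}\sum_m (g_{jm}-2p_m)(g_{km}-2p_m) / (2p_m(1-p_m))$ with
sample frequencies and a minor-allele-frequency floor (default 0.01).
`remlFit()` maximises the restricted likelihood of
$y = X\beta + g + \varepsilon$, $\mathrm{Var}(y) = \sigma_g^2 A +
\sigma_e^2 I$, after one eigendecomposition of $A$; the total variance is
profiled out analytically and the likelihood is maximised over
$h^2 \in [0,1]$ by Brent/golden-section search (tolerance $10^{-8}$). The
scalar boundary-respecting parameterisation was chosen over unconstrained
$(\sigma_g^2, \sigma_e^2)$ Newton/EM iteration: at desk-scale n it is
robust, needs no step-halving safeguards, and guarantees $h^2 \in [0,1]$ by
construction. Standard errors come from the numerically differentiated
observed information in $(\sigma_g^2, \sigma_e^2)$ with a delta-method SE
for $h^2$; the test of $h^2 = 0$ uses the boundary mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$.

Cryptic-relatedness pruning (`pruneRelated()`) is greedy: while any pair
exceeds the cutoff, the individual in the most offending pairs is removed
(ties to the lowest id). The source analysis names only the 2.5% cutoff,
not the algorithm, so the greedy rule is a package decision. One numerical
caveat matters at desk scale: the off-diagonal sampling noise of an M-SNP
GRM has SD $1/\sqrt M$, so with M = 2,000 markers a 0.025 cutoff sits
*inside* the noise band and would prune essentially everyone.
`runReverseMR()` therefore floors the effective cutoff at $4/\sqrt M$; at
genome-wide marker counts ($M \approx 5\times10^5$, floor ≈ 0.006) the
requested 2.5% cutoff governs unchanged.

## Meta-analysis

`ivwFixed()` pools the two split-sample estimates with weights
$w_k = 1/\mathrm{SE}_k^2$ (pooled SE $(\sum w_k)^{-1/2}$, normal CI) and
`cochranQ()` tests their homogeneity against $\chi^2_{k-1}$. Fixed effects
only — with k = 2 halves of one cohort a random-effects variance is not
estimable in any useful sense.

## The synthetic cohort

Because the original individual-level data are access-restricted, the
package ships a generator (`simulateCohort()`) whose defaults are the
study's own operating point: n = 4,296 children; 32 instrument SNPs in
Hardy–Weinberg and linkage equilibrium; an allelic score explaining 2.8% of
exposure variance; BMI/FMI raw scales 18.9 (3.3) and 5.0 (2.7) kg/m² with
correlation 0.94; activity outcomes at 607.2 (178.4) counts/min and 427.3
(66.6) sedentary min/d with log-normal (right-skewed)
moderate-to-vigorous minutes; a planted forward effect of −0.18 SD/SD on
total and moderate-to-vigorous activity and +0.20 SD/SD on sedentary time;
activity heritability 0.21 (midpoint of the reported 17–25% range); and a
single latent standard-normal confounder loading 0.3 on both sides.
All structural variables are generated at unit variance with explicit
variance bookkeeping (components summing above 1 are an error), so the
omitted-variable bias of the observational estimator has the closed form
$c_x c_y$ — the oracle used in the tests.

Choices where the emulated study is silent, made once and not revisited:

* one latent confounder (the study lists many confounders but not their
  joint distribution); loadings 0.3/0.3 give an OLS bias of +0.09 SD/SD,
  large enough to separate OLS from IV at simulated scale;
* sex assignment Bernoulli(2252/4296) with the study's sex-specific
  means/SDs as affine output maps;
* confounder columns (maternal BMI, birth weight, maternal smoking at ~20%
  prevalence) load on the latent confounder and are independent of
  genotype by construction;
* the reverse mode plants the activity-to-adiposity effect through the
  standardized mean of the three activity traits;
* background SNP count defaults to 2,000 as a desk-scale stand-in for
  ~500,000 genotyped markers.

What the generator does **not** emulate — so passing tests say nothing
about these features of real data: linkage disequilibrium and population
stratification; genotyping/imputation error; inter-trait correlations
beyond those induced by the shared exposure, confounder and per-trait
polygenic components (real total and moderate-to-vigorous activity are far
more strongly correlated); non-wear and device artefacts in accelerometry;
and age structure (age is simulated but causally inert).

### Problem sizes and the weak-instrument regime

Prediction-score instrument strength is governed by the ratio of markers to
discovery-sample-size times heritability: the expected held-out variance
explained is roughly $h^2 / (1 + M/(n\,h^2))$. At the study's true scale
($M \approx 5\times10^5$, per-half n = 2,148) this puts the reverse
instrument deep in the weak regime (first-stage F ≤ 7). A desk-scale
cohort with M = 2,000 and n = 4,296 is *not* in that regime (F ≈ 40–80,
because the same heritability is concentrated in 250× fewer markers). The
test suite therefore exercises the weak-instrument reverse pipeline on
n = 1,000 cohorts (per-half n = 500, restoring the ratio; observed median
F ≈ 3), and exercises end-to-end causal-asymmetry recovery on n = 20,000
cohorts, where the forward IV test has ~99% power (at n = 4,296 the
study's own interval, −0.36 to 0.00, implies ~50% power, so a
detection-rate criterion cannot be met at that n). The GREML recovery
check runs at n = 2,000 with 500 markers; the dense-likelihood oracle at
n = 200. These sizes are the package's chosen operating points for its
checks, stated here so they are not mistaken for properties of the method.

## Accelerometry

`summarizeActigraphy()` applies the reported rules exactly as printed:
a valid day has ≥ 10 wear-hours, a valid record ≥ 3 valid days;
moderate-to-vigorous minutes are counts strictly above 3,600/min and
sedentary minutes strictly below 199/min, so boundary counts fall in the
unlabelled middle band. Non-wear detection is deliberately not implemented
— the source does not define its non-wear algorithm, and inventing one
would change the outcomes silently; wear time is the minutes present in
the trace. Zero-minute days are invalid days, not errors.

## Phenotype preparation

Adiposity and activity variables are standardised to sex-specific z-scores
(`zscoreBySex()`, denominator n−1) computed on the analysis sample's own
complete cases — the normalisation sample is not documented in the source,
so the package standardises per analysis. Skewed moderate-to-vigorous
minutes are natural-log transformed first; a +1 min/d offset is applied
only when zeros are present (off by default). Raw-unit effect sizes are
the z-coefficients multiplied by the raw outcome SD, computed from
*unrounded* coefficients — the printed raw values in the emulated tables
are inconsistent with their rounded z columns (e.g. −0.12 × 178.4 ≠
−22.3), so the package reports the product of the unrounded estimate.
Reported percentages round half-up to one decimal. Weight-status
classification takes a user-supplied age/sex cut-off table with inclusive
boundaries and linear interpolation in age; a synthetic example table
ships in `inst/extdata/` (the reference cut-off curves themselves are out
of scope).

## Numerical conventions

* Complete-case analysis per fit; n is reported per fit.
* Least squares via QR with an explicit rank check; rank deficiency is an
  error, not a silent drop.
* Logistic fits use IRLS (tolerance $10^{-8}$, ≤ 50 iterations); perfect
  separation is detected via diverging coefficients.
* GWAS scans use Frisch–Waugh–Lovell residualisation for speed when no
  dosage is missing, falling back to per-SNP complete-case solves
  otherwise; constant-dosage SNPs are skipped with a warning.
* All simulation entry points take an integer seed, restore the caller's
  RNG state, and are byte-reproducible given the seed.
* Sex-stratified analyses are separate fits per sex (no interaction
  model), reusing the full-sample z-scores.

## Worked example

```{r example, eval = FALSE}
sim <- simulateCohort(4296, syntheticBmiPanel(), TrueParams(),
                      n_background = 2000, seed = 1)
forward <- runForwardMR(sim$genotypes, sim$phenotypes)
forward[forward$exposure == "bmi", c("outcome", "ols_beta", "iv_beta",
                                     "first_stage_F", "dwh_p")]
reverse <- runReverseMR(sim$genotypes, sim$phenotypes, seed = 2)
reverse[, c("outcome", "pooled_beta", "pooled_ci_low", "pooled_ci_high",
            "weak_instrument")]
```

## Known limitations

* Just-identified designs only: no LIML/GMM, no over-identification test.
* Single-component GREML; no bivariate models or BLUP prediction.
* The generator's three activity traits share only structural correlation;
  measurement-level correlation between them is not modelled.
* The weak-instrument behaviour of split-sample IV (bias towards the null)
  is reproduced but not corrected; estimates from F < 10 instruments
  should be read as the flagged caution they carry.
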