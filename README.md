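# bidirMR

Bidirectional Mendelian randomization (MR) for childhood adiposity and
objectively measured physical activity.

Observational studies find that heavier children move less, but the
association cannot by itself distinguish "adiposity suppresses activity"
from "inactivity causes weight gain" or from shared confounding. bidirMR
implements the full instrumental-variable workflow used to separate these
explanations in a cohort of 11-year-olds, and a synthetic-cohort generator
with a known planted causal structure so the whole pipeline is testable
without access-restricted individual-level data.

## What it computes

For exposure *x* (BMI or fat-mass index, as sex-specific z-scores),
outcome *y* (total activity counts/min, log moderate-to-vigorous min/d,
sedentary min/d) and genetic instrument *g*:

* **Forward MR** — two-stage least squares of *y* on *x* instrumented by a
  weighted allelic score `sum_j w_j g_ij` of 32 BMI loci (rescaled to the
  0–64 "average risk alleles" scale), with first-stage F and partial R²
  weak-instrument diagnostics and the Durbin form of the
  Durbin–Wu–Hausman endogeneity test (squared t of the first-stage
  residual in the augmented outcome regression, referred to chi²(1)).
* **Reverse MR** — GREML heritability of each activity trait from a
  genetic relationship matrix
  `A_jk = (1/M) sum_m (g_jm − 2p_m)(g_km − 2p_m)/(2 p_m (1 − p_m))`,
  split-sample discovery GWAS, genome-wide prediction scores at p ≤ 0.1,
  cross-half 2SLS, and inverse-variance-weighted fixed-effects pooling
  with Cochran's Q.
* **Supporting stages** — accelerometer count summarisation (valid day =
  ≥10 wear-hours, valid record = ≥3 valid days; MVPA > 3,600 counts/min,
  sedentary < 199 counts/min, strict inequalities), sex-specific
  z-scoring, weight-status classification against a user-supplied age/sex
  cut-off table, instrument-sensitivity analysis (strongest single SNP vs
  the 31-SNP remainder score vs all 496 SNP pairs), and genotype–confounder
  validity checks.

Central data objects are S4: `GenotypeMatrix` (a `SummarizedExperiment`
with a SNPs × individuals `dosage` assay), `SnpPanel`, `ScoreDefinition`,
`IVFitResult`, `HeritabilityEstimate`, `MetaResult`, `GRM`.

## Worked example

```r
library(bidirMR)
sim <- simulateCohort(4296, syntheticBmiPanel(), TrueParams(),
                      n_background = 2000, seed = 1)
fw <- runForwardMR(sim$genotypes, sim$phenotypes)
fw[fw$exposure == "bmi", c("outcome", "n", "ols_beta", "iv_beta",
                           "iv_ci_low", "iv_ci_high", "iv_p",
                           "first_stage_F", "partial_r2", "dwh_p")]
#>   outcome    n ols_beta  iv_beta iv_ci_low iv_ci_high   iv_p first_stage_F partial_r2 dwh_p
#>  total_pa 4296  -0.1173 -0.13595   -0.3063     0.0344 0.1178           135     0.0304 0.828
#>      mvpa 4296  -0.0934  0.00852   -0.1631     0.1801 0.9225           135     0.0304 0.235
#> sedentary 4296   0.2799  0.18829    0.0229     0.3537 0.0257           135     0.0304 0.268
```

The cohort was simulated with a planted causal effect of adiposity on
activity of −0.18 SD/SD (+0.20 for sedentary time), a confounder loading
0.3 on both sides, and an allelic score explaining ~2.8% of BMI variance.
The report shows what the method is for: the first-stage F of 135 marks a
strong instrument; the IV point estimates track the planted effects within
their (wide) intervals; and the DWH p-values do not separate the IV and
observational estimates at this n — the observational slope for total
activity (−0.117) sits between the planted −0.18 and the
confounding-biased expectation −0.09.

The reverse direction, on the same cohort:

```r
rv <- runReverseMR(sim$genotypes, sim$phenotypes, outcomes = "total_pa",
                   seed = 2)
rv[, c("outcome", "h2_A", "h2_B", "F_A", "F_B", "pooled_beta",
       "pooled_ci_low", "pooled_ci_high", "pooled_p")]
#>  outcome h2_A h2_B  F_A  F_B pooled_beta pooled_ci_low pooled_ci_high pooled_p
#> total_pa 0.23 0.18 39.7 56.8     -0.0571        -0.259          0.145     0.58
```

GREML recovers the planted activity heritability (0.21) in each half, and
the pooled reverse estimate correctly covers zero: no causal effect of
activity on adiposity was planted, and none is found.

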