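---
title: "From a small trial to causal estimates: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From a small trial to causal estimates: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialmr)
```

# The problem

A short randomized trial can show that a treatment shifts a panel of
circulating biomarkers, but it is far too small to say anything about
disease endpoints. `trialmr` implements the inference chain that bridges
that gap:

1. **Signature.** From a two-arm trial with standardized biomarkers,
   fit an elastic-net penalized logistic regression of the treatment-arm
   label on the biomarkers. The nonzero coefficients define a
   *treatment-response signature*: for subject $i$ with standardized
   biomarker values $x_{ik}$, the score is
   $s_i = \sum_k w_k x_{ik}$.
2. **Instruments.** Score the signature in a large genotyped cohort,
   inverse-rank-normalize it, and run a per-variant association scan with
   the usual QC (INFO $\ge 0.7$, missingness $\le 10\%$, MAF $\ge 0.01$,
   exact HWE $p \ge 10^{-15}$). Genome-wide-significant variants
   ($p < 5\times10^{-8}$) are greedily LD-clumped ($r^2$ threshold 0.01
   exposure-side, 0.001 for disease instruments in the reverse direction)
   to yield approximately independent instruments.
3. **Causal estimation.** With exposure associations $\gamma_j$ and
   outcome associations $\Gamma_j$ per variant, the Wald ratio
   $\theta_j = \Gamma_j/\gamma_j$ is combined across instruments by
   inverse-variance weighting (IVW), the weighted median, the weighted
   mode, MR-Egger regression (whose intercept tests directional
   pleiotropy) and MR-PRESSO (which flags outlier instruments and
   re-estimates without them). One-sample MR regresses the binary outcome
   on a standardized weighted allele score. Both directions of causation
   are examined.
4. **Mediators.** Each signature biomarker is classified by
   direction-consistency rules: a *candidate mediator* must pair its
   signature correlation sign against its disease association in the
   beneficial direction, be FDR-significant observationally, and have an
   MR estimate of the same sign. The reverse pairing with observational
   significance is an *off-target* pattern.

Because individual-level trial and biobank data of this kind are not
redistributable, the package ships a synthetic-data module with known
ground truth; every stage is tested against planted effects.

# The synthetic generators and what they emulate

`simulate_trial()` draws a 1:1 randomized trial; defaults mirror the
motivating design: 84 men, 94 standardized biomarkers (92 proteins plus
testosterone and SHBG), three visits (baseline, week 8, week 12) and 4
dropouts whose post-baseline visits are removed, so analyses run on 80
completers. Biomarkers are Gaussian with an exchangeable between-biomarker
correlation (default 0.2) and a within-subject ICC across visits (default
0.5); the treated arm is shifted by `effect_vector` (SD units) at
post-baseline visits. The default effect vector is sparse - 10 of 94
biomarkers at 0.4-0.8 SD with mixed signs - chosen as a realistic sparse
response for a 12-week pharmacological intervention. Clinical outcomes
carry the trial-scale effects (-0.45, -0.59, -0.39 SD for total
cholesterol, fasting glucose, LDL-cholesterol).

`simulate_genotypes()` draws each individual as the sum of two
independent haplotypes; each haplotype thresholds a block-AR($\rho$)
latent Gaussian at the MAF quantile. Independence of the two haplotypes
makes Hardy-Weinberg equilibrium hold by construction, while the latent
correlation gives tunable within-block LD. This emulates the statistical
structure instrument selection assumes (LD blocks, HWE) and *not*
realistic human LD maps, imputation error or relatedness.

`simulate_cohort()` builds the exposure as
$\sqrt{h^2}\,\tilde g + c\,U + \varepsilon$ (genetic score scaled to
heritability $h^2$, a single shared standard-normal confounder $U$ with
loading $c$ on both exposure and outcome, Gaussian noise topping variance
up to 1) and draws the binary outcome from a logistic model with
`causal_logOR` per SD of exposure, optional direct (pleiotropic) variant
effects, and an intercept solved by bisection so the marginal prevalence
matches `baseline_prev` within $10^{-4}$. A single shared confounder is
the smallest structure that lets observational and MR estimates diverge.
`make_two_sample()` simulates two independent cohorts from the same
variant truth, mirroring non-overlapping exposure and outcome samples.

What passing tests on these data do **not** show: robustness to
population stratification, assay batch effects, non-Gaussian biomarker
distributions, or real LD complexity. The generators are calibrated to
the study conditions, not to any particular biobank.

# Signature fitting choices

* **Family.** Binomial elastic net: the arm label is binary and model
  quality is reported as an AUC, which implies a probabilistic
  classifier.
* **Mixing parameter.** $\alpha = 0.5$ is predetermined, not tuned.
* **Penalty selection.** $\lambda$ maximizes the leave-one-out
  cross-validated AUC over a 50-point log-spaced grid spanning four
  decades below the data-driven $\lambda_{\max}$; AUC ties break toward
  the larger penalty (the sparser model). Held-out AUC is computed by the
  rank-sum identity.
* **A caveat on LOO-CV AUC.** With a fixed label total, each held-out
  fit is slightly anti-correlated with the left-out label, so LOO-CV AUC
  is *pessimistic* under the null (measurably below 0.5) rather than
  centred on it. The suite therefore checks that the selected AUC shows
  no optimistic bias; with genuine signal the pessimism is negligible.
* **Standardization.** Columns are scaled to mean 0, SD 1 (denominator
  $n-1$) on the pooled trial sample; the parameters are stored so new
  samples can be scored on the training scale. Out-of-sample cohorts are
  standardized with their own cohort-wide parameters, since assay scales
  differ between platforms. Constant columns are excluded with a warning.
* **Input convention.** Whether the signature should be fit on follow-up
  levels or baseline-to-follow-up changes is genuinely open;
  `trial_biomarkers()` emits either (`visit = "wk12"` is the default,
  `visit = "change"` the alternative), so both conventions can be tested.
* **Permutations.** `permutation_test()` shuffles arm labels across the
  full sample and refits at the observed model's $\lambda$ (re-running
  the full cross-validation inside each of 500 permutations would be
  computationally disproportionate and is not what a fixed-penalty
  reference distribution requires). Empirical p-values are
  $\#\{|\beta^{perm}| \ge |\beta^{obs}|\}/B$, so a biomarker with
  observed coefficient 0 gets $p = 1$ by construction.
* **Unpenalized fits are refused** ($\lambda = 0$): with more biomarkers
  than subjects, complete separation is possible and the MLE diverges.
* **Trial effects on clinical outcomes** use an identity-link GEE with
  exchangeable working correlation and a sandwich SE (clusters =
  subjects; effect of interest = treatment x post-baseline). With a
  single visit per subject the model reduces to OLS and is fit that way.

# Genetics choices

* Genome-wide significance is $5\times10^{-8}$ and the clumping window 1
  Mb; both are conventions, exposed as arguments.
* The inverse-rank-normal transform uses the Blom offset (3/8) with
  tie-averaged ranks.
* Missing dosages are mean-imputed per variant so every variant is
  tested on the same $n$.
* The association scan adjusts for covariates directly (Frisch-Waugh
  projection for the linear family; per-variant IRLS for the logistic
  family, vectorized across variants when there are no covariates). A
  whole-genome ridge/LOCO step is out of scope; the simulated cohorts
  carry no polygenic background by default, so calibration properties
  hold without it.
* cis windows are inclusive at both flanks, coordinates 1-based.

# MR choices

* Wald-ratio SEs use the first-order delta approximation
  $|se_\Gamma/\gamma|$ by default (second-order available).
* IVW defaults to multiplicative random effects when more than three
  instruments are combined (heterogeneous instrument sets are the rule,
  not the exception); the SE is never deflated below the fixed-effect
  SE.
* Weighted-median and weighted-mode SEs come from a parametric bootstrap
  (1000 draws by default, seeded); the mode bandwidth is
  $\varphi \times 0.9\,\min(\mathrm{sd},\mathrm{mad})\,J^{-1/5}$ with
  $\varphi = 1$.
* MR-Egger reports t-based p-values on $J-2$ degrees of freedom with a
  multiplicative overdispersion factor bounded below by 1; confidence
  intervals throughout are Wald ($\pm 1.96\,se$) for cross-method
  comparability.
* MR-PRESSO uses the original defaults: 1000 simulations, global and
  outlier $\alpha = 0.05$, Bonferroni across variants. The corrected
  estimate is exactly IVW on the non-flagged subset. The distortion test
  is out of scope.
* Harmonization resolves strand by complement, negates the outcome beta
  when allele order is swapped, aligns palindromic variants by allele
  frequency, and drops them when both frequencies fall in (0.42, 0.58).
* One-sample scores default to exposure-GWAS beta weights; an unweighted
  allele-count score is available since the weighting is a genuine open
  choice. An all-zero weight vector is refused.
* Mediator rules require *sign* agreement in MR but not MR significance:
  with a handful of instruments per biomarker, MR confidence intervals
  that include the null are expected even for true mediators, and the
  screen's gate is the observational FDR.
* FDR families: one BH family per analysis type and outcome panel,
  applied separately to the observational and MR result sets.

# Numerical notes

* The logistic intercept matching a target prevalence is solved by
  bisection to $|\Delta \mathrm{prev}| < 10^{-4}$; unattainable targets
  raise an error rather than returning a boundary value.
* The exact HWE test enumerates heterozygote counts sharing the allele
  counts' parity in log space; tables with probability within a
  $10^{-12}$ relative tolerance of the observed one count as "as
  extreme".
* Clumping sorts by (p, position) so p-value ties are deterministic.
* All resampling (permutations, bootstraps, PRESSO simulations,
  generators) is seeded and reproducible; identical configs and seeds
  give identical output.

# Problem sizes used by the test suite

The suite exercises: oracle equivalence on dozens of random small
instances; parameter recovery over 200 replicate two-sample designs (50
instruments, two cohorts of 20,000, true log-OR -0.16 per SD);
robustness and outlier detection over 100 replicates each; calibration
of the Egger intercept test over 1000 replicates and of scan and
permutation p-values by KS uniformity; and 100 seeds of the full
pipeline (84-subject trial, 20 biomarkers, two cohorts of 10,000, 80
variants in 20 blocks, 4 planted mediators). These sizes were chosen so
Monte-Carlo error is small relative to the tolerances being checked.

# Known limitations

* MR-Egger additionally assumes the exposure betas are measured without
  error (the NOME assumption). At finite instrument strength its slope
  attenuates toward the null - the regression-dilution effect quantified
  by the $I^2_{GX}$ statistic - and the recovery simulations make this
  visible: IVW, weighted median and weighted mode are unbiased at the
  simulated instrument strength while the Egger slope is measurably
  attenuated. SIMEX-corrected Egger is not implemented.

* The generators emulate structure, not any real population; estimates
  on real data face stratification, selection and assay artifacts the
  synthetic tests cannot reveal.
* Correlated-instrument IVW, multivariable MR, Steiger filtering, GSMR
  and formal mediation proportions are out of scope; the mediator screen
  is a direction-consistency classification, not a mediation analysis.
* The logistic per-variant scan is exact ML per variant but does not
  model polygenic background; with strong polygenicity a mixed-model
  scan would be needed.
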