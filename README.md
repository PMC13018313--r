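# trialmr

Treatment-response biomarker signatures and Mendelian randomization, end
to end: from a small two-arm randomized trial to causal effect estimates
on binary disease outcomes, with a mediator screen over the signature's
biomarkers.

## Who this is for

Epidemiologists and biostatisticians who have (or want to prototype
against) three layers of data:

* a **randomized trial** measuring a biomarker panel (e.g. Olink
  proteomics plus hormones) in both arms,
* a **genotyped cohort** with the same biomarkers and disease outcomes,
* **GWAS summary statistics** for the outcomes from a non-overlapping
  sample.

The package builds a *treatment-response signature*
`s_i = Σ_k w_k x_ik` (weights from an elastic-net logistic regression of
the arm label on standardized biomarkers, α = 0.5, penalty chosen by
leave-one-out cross-validated AUC), selects genetic instruments for the
signature via a QC'd association scan with greedy LD clumping
(p < 5×10⁻⁸, r² ≤ 0.01), and estimates the signature's causal effect on
disease with the standard two-sample estimator suite —

* **IVW**: `θ̂ = Σ w_j θ_j / Σ w_j`, `w_j = γ_j²/se_Γj²` (equivalently
  zero-intercept WLS of Γ on γ), multiplicative random effects by
  default,
* **weighted median** (robust to <50% invalid weight),
* **weighted mode** (robust when a plurality of instruments is valid),
* **MR-Egger** (intercept = directional pleiotropy test),
* **MR-PRESSO** (simulation-based outlier flagging + corrected IVW),

plus one-sample genetic-score MR and bi-directional analyses. A
direction-consistency screen then classifies each signature biomarker as
candidate mediator, off-target signal, or not significant.

Because such data are not redistributable, a first-class synthetic-data
module (`simulate_trial()`, `simulate_genotypes()`, `simulate_cohort()`,
`make_two_sample()`, `run_pipeline()`) generates every layer with known
ground truth; the test suite validates each stage against planted
effects and independent oracles.

## Worked example

```r
library(trialmr)

# a 84-subject, 94-biomarker randomized trial with sparse planted effects
trial <- simulate_trial(sim_trial_config(seed = 7))
sig <- fit_signature(trial)          # elastic net + LOO-CV
length(sig$weights)                  # 33 selected biomarkers
round(sig$cv_auc, 2)                 # 0.81

# the published 20-term signature scores samples exactly as printed
pub <- published_signature()
z <- matrix(0, 1, 20, dimnames = list(NULL, pub$biomarkers))
z[1, "testosterone"] <- 1
score(pub, z)                        # 0.21

# two-sample MR on paired summary statistics with a known causal effect
ts <- make_two_sample(sim_cohort_config(
  n_individuals = 20000, n_variants = 50, h2 = 0.3,
  causal_logOR = -0.16, seed = 5))
res <- mr_two_sample(harmonize(ts$exposure, ts$outcome), seed = 1)
res
#> IVW (mult. random effects): beta -0.0954 (SE 0.0501, ...), OR 0.909
#> Weighted median: beta -0.0710 ... OR 0.931
#> Weighted mode:  beta -0.0835 ... OR 0.920
#> MR-Egger: beta 0.0711 ... intercept -0.0209 (p = 0.248)
```

The IVW log-odds estimate is the inverse-variance-weighted mean of the
per-variant Wald ratios; here it recovers the planted protective effect
(truth OR = exp(−0.16) ≈ 0.85) within sampling error, and the Egger
intercept shows no directional pleiotropy, as expected for this clean
simulation.

The full chain in one call:

```r
pp <- run_pipeline(seed = 1)
pp
#> Signature terms: 10 | LOO-CV AUC: 0.941
#> Instruments after clumping: 10
#> Observational OR per SD: 0.558 (p = 6.15e-63)
#> One-sample MR OR per SD: 0.826 (p = 1.22e-08)
#> Two-sample IVW OR: 0.513 (p = 1.14e-05)
#> Planted mediators recovered: 100%
```

All three stages agree on a protective signature, and the mediator
screen recovers the four biomarkers planted on the causal path.

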