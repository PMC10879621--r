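# mrmediation

Two-sample Mendelian randomization (MR) with a two-step mediation
decomposition, for summary-statistics-only causal inference.

## Who this is for

Epidemiologists and statistical geneticists asking two linked questions
from GWAS and eQTL summary data alone:

1. Does an exposure (say, the abundance of a gut-microbial taxon) causally
   affect an outcome (say, appendicular lean mass)?
2. How much of that effect is carried by a molecular mediator (say, the
   expression of one gene), instrumented by its own cis-eQTLs in the style
   of drug-target MR?

No individual-level genotypes are needed: inputs are per-SNP association
tables (identifier, alleles, frequency, beta, SE, p, n) and a labelled LD
(r²) matrix.

## The model

Genetic variants serve as instrumental variables. Per SNP the Wald ratio is
r_j = β_Yj / β_Xj; the primary estimator is inverse-variance weighted (IVW)
meta-analysis,

    β̂ = Σ w_j r_j / Σ w_j,   w_j = se(r_j)⁻²,

with a multiplicative random-effects standard error floored at the
fixed-effect one. MR-Egger (pleiotropy-robust slope + intercept test),
weighted median, simple/weighted mode, and SMR (top-eQTL chi-square test)
complete the suite. The total effect c of exposure on outcome decomposes
into the mediator path and the direct remainder:

    indirect = a × b,   c′ = c − a × b,   proportion mediated = a·b / c,

where a is the exposure→mediator effect and b the mediator→outcome effect,
each estimated by MR with its own instruments. The proportion's 95% CI uses
the product-of-coefficients delta method. Sensitivity diagnostics: Cochran's
Q, the Egger intercept, MR-PRESSO global/outlier tests, leave-one-out, and
funnel/scatter tables. A summary-level simulator with known structural
truth (`simulate_mediation_study()`) makes the whole pipeline testable by
parameter recovery.

## Worked example

Simulate a study whose truth is a = 0.4, b = 0.5, c′ = 0.3 (so the total
effect is 0.5 and the true proportion mediated 40%), then run the full
pipeline:

```r
library(mrmediation)

sim <- simulate_mediation_study(simulation_truth(seed = 42))
ins <- select_instruments(sim$exposure, sim$ld)
#> significance filter (p < 1e-05): 22 of 50 SNPs retained
#> LD clumping (r2 < 0.01, 30 kb): 22 SNPs retained
#> instrument-strength filter (F > 10): 22 SNPs retained

tab <- harmonize(ins, sim$outcome)
mr_ivw(tab)
#> MR estimate [ivw], 21 SNPs
#>   beta = 0.488887 (se 0.0412206), p = 1.904e-32
#>   OR = 1.631, 95% CI (1.504, 1.768)

cfg <- study_config_from_simulation(sim, n_boot = 200, n_sim = 500, seed = 7)
bundle <- run_study(cfg)
bundle$mediation
#> Two-step MR mediation decomposition
#>   a (exposure -> mediator): 0.39755 (se 0.0150737)
#>   b (mediator -> outcome):  0.476351 (se 0.0209826)
#>   c (total effect):         0.488887 (se 0.0412206)
#>   indirect (a x b):         0.189373 (se 0.0110064)
#>   direct (c' = c - a x b):  0.299514 (se 0.0426648)
#>   proportion mediated:      38.7% [95% CI 31.0%, 46.5%]
```

One SNP was dropped in harmonization as an ambiguous palindrome (21 of 22
retained). The IVW total effect 0.489 recovers the planted 0.5 within its
standard error, and the proportion-mediated interval covers the true 40%.
`render_report(bundle)` prints the per-arm estimates, heterogeneity and
pleiotropy diagnostics, and the decomposition; `run_study()` writes TSV
tables per arm when `output_dir` is set.

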