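---
title: "Methods: two-sample MR with a two-step mediation decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with a two-step mediation decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediation)
```

## The problem

Two-sample Mendelian randomization (MR) estimates the causal effect of an
exposure on an outcome from two independent sets of GWAS summary statistics,
using genetic variants as instrumental variables. This package implements
the full workflow for studies that additionally ask *how much* of an
exposure's effect travels through a molecular mediator — for instance, how
much of a gut-microbiome taxon's effect on appendicular lean mass is carried
by the expression of a single gene. The mediator's own instruments are
cis-eQTLs, in the style of drug-target MR.

Every estimator assumes the three instrumental-variable conditions:
relevance (enforced by the per-SNP F-statistic filter), independence from
confounders (a design assumption), and the exclusion restriction (probed by
the pleiotropy diagnostics, never proven).

## Instrument selection

`select_instruments()` applies, in order:

1. **Significance**: `pval < p_threshold`, default $10^{-5}$ — the customary
   relaxed threshold for exposures such as microbial taxa where genome-wide
   hits are scarce.
2. **LD clumping**: greedy index-SNP pruning at `clump_r2 = 0.01` within a
   `clump_window_kb = 30` kb window. Candidates are visited by ascending
   p-value (ties broken by position, then identifier, so results are
   reproducible); each index discards all not-yet-retained same-chromosome
   SNPs within the window whose $r^2$ with it reaches the threshold. The
   30 kb default is unusually narrow — 10 Mb is a common choice elsewhere —
   but both are plain configuration values.
3. **Instrument strength**: `f_stat > f_min = 10`. The F-statistic defaults
   to the summary-data approximation $(\beta/\mathrm{se})^2$, the square of
   the Wald z; a variance-explained variant
   $R^2(n-2)/(1-R^2)$ with $R^2 = 2p(1-p)\beta^2$ is available when allele
   frequencies and sample sizes are trustworthy. The strength filter runs
   after clumping; the order does not change the invariants but is fixed.

`select_cis_eqtls()` restricts to the gene's cis window (default 1 Mb on
either side), then applies the same significance filter and greedy pruning
at the looser `eqtl_r2 = 0.30` with no distance window — cis instruments
are deliberately allowed mild correlation to preserve strength.

Both inequalities (p and F) are strict. LD always comes from a supplied
labelled $r^2$ matrix; the package never computes LD from genotypes.

## Harmonization

`harmonize()` aligns outcome effects to the exposure's effect allele,
matching on identifier only. Non-palindromic allele pairs are resolved
exactly (same orientation, swapped orientation, strand complement, or both);
palindromic A/T and C/G pairs carry no strand information in their labels,
so alignment is inferred from allele frequency: both sides must fall outside
the ambiguity zone $[0.5 - a, 0.5 + a]$ (default half-width
`eaf_ambiguity = 0.08`, zone $[0.42, 0.58]$), and agreement in side of 0.5
keeps the SNP while disagreement flips the sign. A frequency inside the
zone, or missing, drops the SNP as ambiguous rather than guessing. The zone
half-width follows common practice; it is a parameter, not an inference
from any particular data set. Dropped rows remain in the table with their
`action_taken` label for audit; estimators use only retained rows.

Harmonization is involutive (re-harmonizing an aligned table changes
nothing) and coherent under a global allele flip of the outcome study; both
properties are tested on every simulated bundle.

## Estimators

Per SNP $j$ the Wald ratio is $r_j = \beta_{Yj} / \beta_{Xj}$ with
first-order standard error $\mathrm{se}_{Yj}/|\beta_{Xj}|$ (default; the
second-order form adds the exposure-side term and sits behind a flag). The
first-order choice makes IVW algebraically identical to weighted least
squares of $\beta_Y$ on $\beta_X$ through the origin with weights
$\mathrm{se}_Y^{-2}$ — an identity the test suite checks against an
independent `lm()` oracle at $10^{-10}$.

* **IVW**: $\hat\beta = \sum w_j r_j / \sum w_j$, $w_j =
  \mathrm{se}(r_j)^{-2}$. The default multiplicative random-effects model
  scales the fixed-effect standard error by $\max(1, \sqrt{Q/(J-1)})$,
  never deflating homogeneous tables.
* **MR-Egger**: weighted regression with intercept after orienting every
  SNP to $\beta_{Xj} \ge 0$ (required for identifiability). The intercept
  estimates average directional pleiotropy; standard errors are scaled by
  $\max(1, \sqrt{RSS_w/(J-2)})$ and p-values use $t_{J-2}$.
* **Weighted median**: linear interpolation of the sorted ratios at
  standardized cumulative weight $p_j = (S_j - w_j/2)/\sum w$ evaluated at
  0.5; consistent while valid instruments carry more than half the weight.
  With finite ratio noise $\sigma$ and valid-weight fraction $v$, the
  estimate targets the valid cluster's $0.5/v$ quantile — an offset of
  about $\Phi^{-1}(0.5/v)\,\sigma$ that vanishes as instruments strengthen;
  the robustness tests account for exactly this known offset rather than
  pretending the finite-sample estimator is exactly unbiased.
* **Modes**: normal-kernel density over the ratios (unit or
  inverse-variance weights), bandwidth $0.9\min(\mathrm{sd},
  \mathrm{mad})J^{-1/5}$ times a user factor, argmax on a 512-point grid
  spanning the ratio range plus three bandwidths. Mode estimators have no
  canonical construction; kernel, bandwidth rule and grid are design
  choices of this package and are stated here so results are interpretable.
* **SMR**: single top-eQTL instrument; $b_{xy} = \beta_{GWAS}/\beta_{eQTL}$,
  $T = z_G^2 z_E^2/(z_G^2 + z_E^2) \sim \chi^2_1$, standard error equal to
  the second-order ratio se (identically $|b_{xy}|/\sqrt{T}$ when $T>0$).
  The HEIDI heterogeneity companion test is out of scope.

Median and mode standard errors come from a seeded parametric bootstrap
(default 1,000 replicates) that redraws each SNP's exposure and outcome
effects from their sampling normals; the seed is a required argument, so no
result ever depends on hidden global RNG state. Reported odds ratios are
$\exp(\hat\beta)$ with interval $\exp(\hat\beta \pm 1.96\,\mathrm{se})$ — a
labelled convention; inputs are taken as given on the log or SD scale.

## Diagnostics

* **Cochran's Q** with $J-1$ df; $I^2 = \max(0, (Q - df)/Q)$ is reported as
  a convenience extra.
* **Egger intercept test** — delegated to the Egger fit.
* **MR-PRESSO**: observed weighted RSS about leave-one-out IVW predictions;
  the null distribution is parametric simulation, the global p-value uses
  add-one smoothing $(1 + k)/(n_{sim} + 1)$ so it is never exactly zero,
  and per-SNP outlier p-values are Bonferroni-multiplied. The distortion
  test is deliberately omitted: only detection is in scope.
* **Leave-one-out** IVW refits plus the all-SNP row, and plot-ready
  scatter/funnel tables with per-method fitted lines.

## Two-step mediation

With $a$ (exposure on mediator), $b$ (mediator on outcome, instrumented by
the mediator's own cis-eQTLs) and $c$ (total effect), the decomposition is

$$\text{indirect} = a b, \qquad c' = c - a b, \qquad
\text{proportion mediated} = \frac{ab}{c}.$$

Additivity `indirect + c_prime == c` holds bit-for-bit by construction.
Standard errors use the product-of-coefficients delta method with the two
MR steps treated as independent — appropriate when the exposure, mediator
and outcome statistics come from non-overlapping studies, which is exactly
what the simulator emulates with disjoint instrument sets. The
proportion's confidence interval is symmetric normal (delta method); a
seeded simulation interval is available behind `ci_method = "simulation"`.
All three effects must share one additive scale: the decomposition is
meaningless across mixed log-odds/SD inputs, and the package leaves scale
responsibility with the caller. The proportion is undefined at $c = 0$
(error); at $ab = 0$ the proportion is 0 with its uncertainty taken from
the indirect effect alone.

Which estimator supplies $b$ is ambiguous in practice (IVW over all cis
instruments, or single-instrument SMR); `run_study()` defaults to IVW and
exposes `b_method = "smr"`.

## The simulator and what passing tests mean

`simulate_mediation_study()` draws, for each exposure SNP: a minor-allele
frequency $p_j \sim U(0.05, 0.5)$, a true effect $\gamma_j \sim N(0,
\sigma^2)$ rescaled so the instruments jointly explain a target variance
fraction (default 0.10 across 30 SNPs), a pleiotropic outcome effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ (defaults 0 and 0.02:
balanced pleiotropy), and observed effects from
$N(\cdot, \mathrm{se}^2)$ with the standardized-trait standard error
$\mathrm{se} = (2p(1-p)n)^{-1/2}$. Mediator eQTL instruments are a disjoint
SNP set placed inside the declared gene window (default variance explained
0.05 across 10 SNPs — eQTLs are individually strong); outcome-specific
instruments (default 10, variance 0.05) exist so the reverse direction has
genuine instruments. Defaults for the structural truth are $a = 0.4$,
$b = 0.5$, $c' = 0.3$ (total 0.5, proportion 0.4) with $n = 50{,}000$ per
study. A fifth of outcome records get allele swaps/complements and a tenth
of SNPs are palindromic, so harmonization is exercised on every bundle;
allele frequencies differ across studies by $N(0, 0.005^2)$ noise.

What the simulator does **not** emulate: realistic LD (blocks are constant
$r^2$, zero across blocks), sample overlap between studies, non-normal
effect distributions, winner's-curse-free replication designs, or
population stratification. Recovery tests therefore certify the estimators
and the pipeline plumbing under the stated statistical model, not
robustness to everything real GWAS data can do.

Problem sizes used by the test suite and the acceptance script were chosen
to give tight Monte-Carlo bands while remaining quick on a laptop: 1,000
random tables for the oracle identities, 10,000 tables for Q calibration,
1,000 for IVW coverage, 500 simulated studies for mediation recovery, 500
for weighted-median contamination, 200 each for Egger-intercept recovery
and clean MR-PRESSO behaviour. Replicate seeds are drawn from one master
stream rather than consecutive integers, which measurably decorrelates
replicates.

Two calibration choices deserve explicit statement. First, IVW coverage is
assessed with the fixed-effect model because the homogeneous null simulation
*is* the fixed-effect generating model; the random-effects default, floored
at 1, is mildly conservative there by design. Second, the bidirectional
directionality check uses an asymmetric-power configuration (a weak
exposure study, a large outcome study, a small total effect, and strong
outcome-specific instruments) mirroring the study design this package
targets: with equal, well-powered studies and a large total effect,
exposure SNPs become genome-wide significant for the outcome and
contaminate reverse-direction selection — a known limitation of reverse MR
without directionality filtering, which is out of scope here.

## Numerical conventions and edge cases

* Wald ratios error on $\beta_X = 0$, naming the SNP.
* Equal clumping p-values break ties by position then identifier.
* The mode bandwidth falls back to a tiny positive value when all ratios
  coincide, so the degenerate case returns that common value.
* Interval multiplier is the conventional 1.96 throughout.
* LD matrices are repaired (symmetrized, diagonal reset) only within
  $10^{-8}$; larger deviations are errors, and entries are clamped to
  $[0,1]$ after repair.
* `run_study()` derives fixed sub-seed offsets per arm from the config
  seed; identical config and seed give byte-identical reports.

## Known limitations

Single mediator only (no multivariable MR); no proxy-SNP lookup for
unmatched instruments; no Steiger directionality filtering; no sample
overlap correction; the SMR arm reports no HEIDI test; LD comes solely from
a user-supplied matrix.
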