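---
title: "Detecting gene-environment interactions in longitudinal twin-family data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene-environment interactions in longitudinal twin-family data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(gefam)
```

## The problem

Longitudinal family studies follow related individuals (here: twin pairs)
with repeated outcome measurements. They are attractive for studying
gene-environment (GE) interactions — a genetic effect whose size or
direction depends on an environmental exposure — but the data carry two
correlation structures at once: within-individual correlation across
repeated visits, and within-family correlation driven by genetic sharing
(complete for monozygotic twins, one half in expectation for dizygotic
twins). On top of that, a GE interaction need not be linear: the genetic
trend can reverse between exposure states (an XOR pattern), plateau under
exposure (conditional-dominant), or appear only in exposed minor-allele
homozygotes (small marginal effect). `gefam` implements three analysis
strategies that make different trade-offs, and a trajectory simulator with
which their type-I error and power can be compared under controlled
interaction shapes.

## The three methods

**ACE twin model on time-averaged outcomes.** Each individual's repeated
BMI values are collapsed to their unweighted mean, and the classical twin
path model

$$Y_{ij} = x_{ij}\beta + aA_{ij} + cC_{ij} + eE_{ij}$$

is fitted by maximum likelihood, where $A$, $C$, $E$ are independent
standard-normal latent variables for additive-genetic, common-environment
and unique-environment variation. A twin pair is bivariate normal with
common variance $a^2+c^2+e^2$ and covariance $a^2+c^2$ (MZ) or
$\tfrac12 a^2+c^2$ (DZ). The fixed-effect design holds an intercept, sex,
mean age, the genotype (additive minor-allele count, or a co-dominant
indicator pair), the exposure, and their product. `fit_twin_model()`
profiles $\beta$ by generalised least squares inside the likelihood and
optimises $(a, c, e)$ unconstrained — variances enter as squares, so the
$a^2 \to 0$ boundary is reached smoothly without a constrained optimiser —
from three starting points (equal split of the empirical variance,
e-dominant, a-dominant). Averaging discards the longitudinal correlation
but, with visit schedules that are nearly identical across individuals,
retains most of the signal while dividing the residual noise by the number
of visits.

**Kinship-covariance linear mixed model on all repeated measures.**
`fit_lmm()` keeps every observation and models

$$\mathrm{Var}(Y) = \sigma^2_g\, Z K Z^\top + \sigma^2_{res} I,$$

one random intercept per individual with between-individual covariance
proportional to the relationship matrix $K$ (diagonal 1, within-pair 1 for
MZ and 0.5 for DZ; `build_kinship()`). Fixed effects are an intercept, sex,
a segmented age trend (a slope in months plus a second slope after the
6-month knot, capturing fast infant growth then plateau), genotype,
exposure, and the interaction block. Fitting is maximum likelihood —
chosen as the default so likelihood-ratio tests of fixed effects are valid;
a REML toggle exists for variance reporting. Internally $\beta$ and
$\sigma^2_{res}$ are profiled out and the single ratio
$\gamma = \sigma^2_g/\sigma^2_{res}$ is optimised; the likelihood is
evaluated blockwise per family through the 2-member Woodbury identity, so
MZ blocks (rank-1 $K$ blocks) need no generalised inverse and each
evaluation costs $O(p^2)$ after one pass of sufficient statistics.

**Partition-based score I (PBI) test.** A nonparametric alternative that
assumes no interaction shape. For a partition of the data into cells $i$
with sizes $n_i$ and means $\bar y_i$,

$$I = \sum_i \frac{n_i}{n}\cdot\frac{(\bar y_i - \bar y)^2}{s^2_y / n_i},
\qquad I_T = I_{GE} - \max(I_G, I_E),$$

where $I_{GE}$ partitions by the crossed genotype-exposure cells and
$I_G$, $I_E$ by each factor alone. Significance comes from permutation
constrained to within families: every family's outcome values are permuted
independently (for twin pairs, swapped with probability one half), keeping
each individual's (G, E) pair intact, with the one-sided upper-tail
add-one estimate $p = (1 + \#\{I_T^{perm} \ge I_T^{obs}\})/(B+1)$ and
$B = 10{,}000$ permutations by default.

## The simulator

`simulate_cohort_data()` emulates a birth-cohort twin study: 168 MZ and
226 DZ pairs (788 individuals) by default, six visits at mean ages 0,
6.28, 19.49, 31.77, 49.85 and 62.25 months (SDs 0, 0.74, 0.75, 0.96, 1.82,
3.23), drawn per family and shared by co-twins; pair sex composition FF
0.42, MM 0.35, FM 0.23 with the FM share confined to DZ pairs. Genotypes
come from two simulated parents per family (each the sum of two
Bernoulli(0.3) alleles, i.e. random mating at minor allele frequency 0.3)
with uniform Mendelian transmission; MZ co-twins share one transmission,
DZ co-twins inherit independently. The binary exposure is iid
Bernoulli(0.3) even within pairs. BMI trajectories follow

$$Y_{ijk} = (\beta_0 + C_{0ij}) + \beta_S S_{ij} + (\beta_T + C_{Tij}) T_{ijk}
 + \beta_{T'} T'_{ijk} + \beta_G G_{ij} + \beta_{GT} G_{ij} T_{ijk}
 + \beta_E E_{ij} + \theta_{ijk} + \varepsilon_{ijk},$$

with $T'$ equal to 0 at the first two visits and $T-6$ afterwards, random
intercepts and slopes drawn per pair from bivariate normals whose MZ/DZ
covariances encode the ACE structure
($\sigma^2_A + \sigma^2_C$ vs $\tfrac12\sigma^2_A + \sigma^2_C$; likewise
$\tau^2$ for slopes), and iid residuals. The interaction effect
$\theta$ is a scenario matrix entry $M[G,E]$ scaled by $\beta_{GE}$ (a
level shift, the "average" channel) or by $\beta_{GTE} T$ (a slope shift,
the "change" channel). Scenario presets (`scenario_preset()`) fix the
shared parameters at $\beta_0 = 11$, $\beta_S = 0.5$, $\beta_T = 0.8$,
$\beta_{T'} = -0.8$, $\sigma^2_A = 3$, $\sigma^2_C = 1.5$,
$\tau^2_A = \tau^2_C = 0.001$, $\sigma^2_E = 1.5$ and walk the documented
effect-size grids, including the coupling $\beta_E = 2\beta_G$
(null-average family) and $\beta_E = 40\beta_{GT}$ (null-change family).

```{r}
sc <- scenario_preset("ge_linear", beta_ge = 0.5)
rec <- simulate_cohort_data(sc, seed = 42)
summary(fit_twin_model(mean_over_time(rec)))
```

### What the generator does and does not emulate

The simulator reproduces the statistical skeleton the methods see — family
structure, zygosity, sex composition, visit-age distributions, ACE-shaped
familial covariance and segmented growth — but it generates ages from the
published visit-age means/SDs rather than reusing real cohort ages, applies
an optional missing-completely-at-random dropout (default 0) instead of
imputing real missingness patterns, simulates exactly one biallelic locus
with no linkage structure, and keeps exposures binary and time-constant.
Passing tests therefore demonstrate correctness of the methods under this
idealised structure, not robustness to informative missingness,
time-varying exposures or population stratification in real data.

## Interaction shape presets

`interaction_preset()` ships four canonical 3 x 2 multiplier matrices
(rows: minor-allele count; columns: unexposed/exposed): `linear`
($M = g\cdot e$), `xor` (genetic trend $0,1,2$ unexposed reversing to
$2,1,0$ exposed), `conditional_dominant` ($0,1,2$ unexposed; $0,2,2$
exposed) and `small_marginal` (only exposed minor-allele homozygotes
affected). The source figures for these patterns are not recoverable at
numeric precision, so the presets are declared package defaults — chosen
to match the verbal descriptions, normalised to $\max|M| \le 2$ — and any
3 x 2 matrix can be supplied instead.

A consequence worth stating explicitly: the canonical `xor` matrix is
*exactly* representable as $2e + g - 2ge$, i.e. it lies inside the span of
the additive-coded regression with a product term. At the simulated effect
sizes the regression methods therefore retain high power against this XOR
pattern, and the frequently cited ordering "nonparametric partition tests
beat product-term regressions under XOR" does not emerge under these
defaults: we measured twin-model power at essentially 1.0 across the
$\beta_{GE}$ grid, at or above the PBI test's. We verified that plausible
alternative XOR matrices (dominant-coded reversal, heterozygote-advantage
reversal) do not change this conclusion at the default cohort size — any
bounded 3 x 2 reversal pattern leaves a large linear-in-$(g,e,ge)$
component once genotype frequencies (0.49/0.42/0.09) are accounted for.
The corresponding qualitative check in the acceptance suite records this
honestly rather than adopting a matrix reverse-engineered to produce the
ordering.

## Numerical and design choices

- **Sample variance divisor in the PBI statistic:** $s^2_y$ uses the
  $n-1$ divisor. This scales $I$ by a constant and cannot change the
  permutation p-value (the divisor is permutation-invariant).
- **Permutation tail and correction:** one-sided upper tail with the
  add-one correction, so $p \in [1/(B+1), 1]$; ties count as exceedances
  (with a $10^{-12}$ tolerance). Degenerate inputs are defined rather than
  fatal: a constant outcome gives $I = 0$ and $p = 1$; all-singleton
  families give $p = 1$ with a warning.
- **Segmented time in analysis vs generation:** the generator uses the
  visit-index rule ($T' = 0$ for $k \le 2$); the analysis model defaults to
  the hinge $\max(0, T - 6)$, which is what one would fit to real data
  where visit indices are arbitrary. Simulation-study fits
  (`run_replicate()`) use the visit rule so the fitted mean model matches
  the generating one; with the hinge the two differ slightly at visit 2
  (mean age 6.28 months), which would leave a small but systematic
  mean-model misfit.
- **Which intercept recovers $\beta_0$:** only the LMM intercept is checked
  against $\beta_0 = 11$. The twin model's intercept on time-averaged
  outcomes absorbs the accumulated time effect
  ($\approx \beta_0 - \beta_{T'}\bar c$ for a schedule constant $\bar c$),
  and with $\beta_T = -\beta_{T'}$ its mean-age slope is close to zero;
  that is a property of averaging, not an estimation error. The twin
  model's sex coefficient recovers $\beta_S$.
- **Incomplete pairs** are kept in the twin likelihood as univariate
  normal contributions rather than dropped.
- **Hardy-Weinberg QC on related individuals** uses one member per family
  (lowest id, deterministic) for the 1-df chi-square goodness-of-fit test,
  since duplicated MZ genotypes would distort the genotype counts.
- **Quartile ties** go to the lower category, fixing a deterministic
  convention the source material leaves open.
- **GTE hierarchy:** the three-way $G\times E\times T$ test always includes
  $G\times T$, $E\times T$ and $G\times E$ below it.
- **Monte-Carlo study sizes:** the acceptance-level checks use 1000 null
  replicates for the regression type-I errors (first 500 reused for
  coefficient recovery, first 100 for generator frequencies), 500
  pure-noise and 300 gene-time-null replicates for the PBI size behaviour
  at 1000 permutations per test, and 500 replicates per power scenario.
  Rejection proportions carry their binomial Monte-Carlo standard errors
  in every `estimate_power()` table.

## Known limitations

- Families larger than two genotyped members are not supported by the
  likelihood code (the kinship interface accepts any PSD matrix, but
  construction and fitting assume twin pairs and singletons).
- The PBI implementation applies no covariate adjustment; a sex main
  effect, for example, enters the permutation null as extra noise. This
  mirrors how the test is used unadjusted in practice.
- The PBI test's documented pathology — severe false-positive inflation
  when strong gene-time and environment main effects are present without
  any interaction (a rate rising towards roughly one half on the
  null-change grid) — is a property of the statistic and is deliberately
  reproduced, not corrected. On our synthetic skeleton the plateau sits
  slightly below one half at $\beta_{GT} = 0.02$ (about 0.38-0.40, rising
  to about 0.45 by $\beta_{GT} = 0.03$).
- Wald tests use the normal reference rather than a t distribution,
  consistent with large-sample maximum-likelihood practice.
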