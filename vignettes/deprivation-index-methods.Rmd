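---
title: "Methods: a multidimensional S/SDOH deprivation index for cognitive-aging cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multidimensional S/SDOH deprivation index for cognitive-aging cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohci)
```

## The measurement problem

Disadvantage relevant to cognitive aging is multidimensional: material
hardship, education quality, healthcare barriers, social stressors,
psychological traits and health behaviors act jointly, and no single scale
captures their accumulation. `sdohci` measures it with the Alkire–Foster
(AF) dual-cutoff counting approach. Each of 37 indicators is first
dichotomized at its own deprivation threshold; a participant is then
identified as multidimensionally deprived when their weighted deprivation
count reaches a second cutoff `d`. The composite index is the adjusted
headcount ratio

$$M_0 = H \cdot A,$$

the product of the deprived fraction ($H$) and the average weighted share of
indicators on which the deprived are deprived ($A$). $M_0$ rises when more
people are deprived *or* when the deprived are deprived more intensely, and
it decomposes exactly both by population subgroup (population-share
weighting) and by indicator (censored headcounts). The counting approach
makes no distributional assumption about the underlying scales, which is why
it remains usable at cohort sizes of a few hundred.

## The indicator registry

The default registry nests 37 indicators in 10 factors across the three
dimensions of the NIA Health Disparities Research Framework:

```{r registry}
default_registry()
```

Deprivation rules come in four kinds:

* **`deficit_sd` / `adverse_sd`** — scale scores cut at `mean − t·SD`
  (deficits: low cohesion, low personality-trait scores, low religiosity,
  low life satisfaction) or `mean + t·SD` (adverse exposures: disorder,
  stressors, neuroticism, high-effort coping, vigilance, discrimination),
  with `t = 1` by default. Both boundaries are **inclusive** — a score
  exactly at the cut is deprived — matching the `≤ −1 SD` / `≥ +1 SD`
  convention. Reference statistics are the analytic sample's own mean and
  SD (`n − 1` denominator); external norms can be supplied per indicator.
* **Composites** — no college attendance; reading achievement `z ≤ −1`
  against external test norms; household living standards; the asset index;
  and nine barriers-to-care components (17 items; deprived at ≥ 1 endorsed
  item by default, overridable because published component thresholds vary
  across instruments).
* **`direct_binary`** — hardship and the seven health-behavior flags, whose
  instrument-specific cutoffs are applied upstream.

Three genuinely open readings were settled as follows, each with the
alternative available as a flag:

* **Living standards.** The rule is
  `(renter AND > 2 persons/room) OR no car OR no internet`: the crowding
  clause binds to home ownership (a homeowner in a crowded dwelling is not
  deprived on this indicator), while car and internet access are standalone
  shortfalls. Crowding is strictly `> 2`. An all-conjunctive variant exists
  (`living_standards_conjunctive`).
* **Education.** Years of education (no college attendance) and reading
  skills (`z ≤ −1`) are kept as two separate indicators, because gap
  reporting treats them separately; a single conjunctive indicator
  (`education_conjunctive`) is available and shrinks the registry to 36.
* **Coping vs discrimination.** The coping factor holds a single indicator
  (high-effort coping), which pins the nested-weight arithmetic (a
  one-indicator factor has indicator weight 1); vigilance sits with everyday
  discrimination in the discrimination factor.

Missing data are handled by complete-case analysis at the participant
level: any participant missing a registry source column is dropped, with
the count logged.

### The polychoric asset index

Ordinal asset items are summarized by the first principal component of
their polychoric correlation matrix. Estimation is two-step: thresholds
from the marginal category frequencies via the inverse normal, then each
pairwise latent correlation by maximizing the bivariate-normal cell
likelihood. Two-step is standard practice, much faster than full ML, and
accurate at these sample sizes. The bivariate normal rectangle probability
is computed by the exact one-dimensional reduction
$\int^{h}\phi(x)\,\Phi\!\big((k-\rho x)/\sqrt{1-\rho^2}\big)\,dx$ on 64
Gauss–Legendre nodes, with cell probabilities floored at $10^{-12}$ and the
correlation searched on $[-0.9999, 0.9999]$. A non-positive-definite matrix
(possible with inconsistent pairwise estimates) is repaired by eigenvalue
clipping at $10^{-8}$ and rescaling to unit diagonal, with a warning.
Participants are scored with normal-score category quantifications; the
component sign is fixed so ownership loads positively, and deprivation is
`score ≤ mean − 1 SD`. Because the cut is taken on a discrete score
distribution, the deprived fraction is only approximately the Gaussian
one-SD tail (0.159).

## Weighting, identification, aggregation

* **EIW** gives every indicator weight 1 (total weight 37); the cutoff is a
  count, default `d = 11` — "deprived on 11 indicators or more", an
  inclusive `≥`.
* **ENW** gives the 10 factors equal weight, split evenly within factor
  (religiosity's three indicators get 1/3 each; coping's single indicator
  gets 1); total weight is 10 and the cutoff is a share of total weight
  (e.g. 0.30), again inclusive.

Weighted-count comparisons use a $10^{-9}$ tolerance because nested weights
are rationals whose sums carry floating-point error. `af_measures()`
computes $M_0$ by both routes ($H\cdot A$ and censored score total over
$n\cdot W$) and asserts their equality; `subgroup_decompose()` asserts the
population-share identity on every call. When nobody is poor, $H = M_0 = 0$
and $A$ is reported as missing (not zero).

**Contributions** use censored headcounts (deprived *and* poor), the
convention under which contributions sum to exactly 1; an uncensored
variant is available but breaks the unit sum. Contributions are undefined
at $M_0 = 0$ and raise an error rather than returning silently.

**Cutoff calibration** (`calibrate_cutoff`) returns the cutoff whose
headcount is nearest a target prevalence, ties broken toward the smaller
cutoff. The default target, 19.2%, is the poverty rate of older Black
adults in the U.S., which under the default calibrated simulator puts the
cutoff at `d = 11`.

**Inference for subgroup gaps** uses a within-group nonparametric bootstrap
of the $M_0$ difference with a two-sided percentile p-value (twice the
smaller tail mass around zero, floored at $1/n_{boot}$), since no analytic
standard error is assumed; results are flagged when a group has no poor
members. Normal-approximation alternatives were considered and rejected as
adding assumptions without materially changing power at these sizes.

**Burden**, the regression exposure, is the uncensored weighted share
$c_i/W \in [0,1]$ for every participant. The censored convention (burden
zero below the poverty cutoff) is available via a flag; the uncensored
share is the default because the exposure should retain gradient
information below the cutoff in regression use.

## Cognitive outcomes

PCI is MoCA total ≤ 23 (inclusive). PCP comes from the PACC composite: each
component is z-scored on the analytic sample (`n − 1` SD), the timed Trails
A/B components are negated so higher is better everywhere, and the
composite is the unweighted mean of the four component z-scores (episodic
recall enters as one combined free-plus-cued component by default, and can
be split into two). PCP is `PACC ≤ mean − 1 SD`; the boundary is inclusive
for consistency with the registry's other one-SD rules, with a strict-mode
flag. Degenerate scales (zero SD) raise errors naming the component.

Association models are logistic (IRLS via `glm`), reported as odds ratios
with Wald intervals — symmetric on the log scale — and Tjur's $R^2$ (mean
fitted probability among cases minus non-cases). Perfect separation is
flagged, not fatal. Descriptive tables use Yates continuity-corrected
chi-square for 2×2 categorical rows — the variant pinned by reproducing
published descriptive p-values to three decimals — and Welch's t-test for
continuous rows (pooled-variance optional). Marital status collapses to
married/partnered vs single in the models, with the six-level coding
retained for descriptives; the age term is dichotomized at 65 with under-65
as the reference level (exposed as configuration, since published tables
are ambiguous about the reference).

## The synthetic cohort generator

Individual-level S/SDOH cohort data are typically restricted, so the
generator is a first-class, tested module, not a fixture. It emulates:

* **Marginal prevalences.** Indicator $j$ is deprived with probability
  $\mathrm{logistic}(\alpha_j + \lambda_j\theta)$, $\theta \sim N(0,1)$ a
  single latent deprivation propensity shared by all indicators.
  $\alpha_j$ is found by root-finding so the marginal matches its target
  (Gauss–Hermite quadrature, 40 nodes); an unreachable target raises an
  error naming the indicator.
* **Weak positive dependence.** A single factor with common loading
  $\lambda = 0.8$ yields pairwise indicator correlations of roughly
  0.05–0.15 — positive but weak, consistent with the reported absence of
  strong pairwise overlap among S/SDOH indicators. (One latent factor per
  dimension was considered and rejected as the default: the data motivating
  the design give no between-dimension correlation structure to fit, and
  one factor with small loadings already reproduces the observable target.)
* **Calibration.** Baseline prevalences (the 0.159 one-SD tail for
  scale-threshold indicators; 0.10 for barriers components; 0.10–0.35 for
  hardship, education and the behavior flags, values typical of
  community-dwelling older-adult cohorts) are shifted by a common
  logit-scale constant so the *theoretical* fraction deprived on ≥ 11
  indicators equals 19.2% (Poisson-binomial tail integrated over the latent
  factor). The asset indicator is excluded from the shift because its
  prevalence is pinned near the one-SD tail by its own rule.
* **Outcomes.** PCI and PCP are Bernoulli draws from logistic models on
  the burden share with age-65+ and female terms; the default log odds
  ratios are taken from the adjusted estimates the index was designed
  around (burden OR 11.48 for PCI and 13.84 for PCP; age ORs 1.90/6.49,
  female ORs 0.90/0.29), and each intercept is solved against the realized
  covariates so the marginal outcome prevalence hits its target (33.7% PCI,
  15.1% PCP). Demographics are drawn independently of $\theta$ by default —
  confounding is opt-in — because the motivating analyses adjust for, but
  do not quantify, demographic–deprivation dependence.
* **Raw columns.** Every source column is constructed so that re-applying
  the registry reproduces the drawn binary matrix cell for cell: scale
  scores are placed on the deprived side of the sample-SD cut with a
  guard gap and a monotone shift search (the sample cut moves more slowly
  than the deprived maximum, so the search provably terminates for
  prevalences below 50%); all-non-deprived scales use a floor-effect
  mixture whose minimum z-score is provably above −1; MoCA totals are
  sampled within the impaired/normal ranges; PACC components are affine in
  a placed latent vector. Two deliberate exceptions: the asset indicator is
  *defined* by running the polychoric rule on generated θ-driven ordinal
  items (its one-SD cut depends on the realized score distribution and
  cannot be imposed), and PACC labels are re-derived after integer rounding
  of the fluency count, so a borderline draw can flip.

What the generator does **not** emulate: the true joint distribution of any
real cohort (no instrument-level item structure, no spatial clustering, no
measured demographic–deprivation confounding, perfectly correlated PACC
components). Passing tests therefore demonstrate that the *pipeline*
computes its estimands correctly under a known data-generating process, not
that any particular cohort's numbers will be reproduced.

## Verification strategy and problem sizes

The test suite checks every aggregation against an independent brute-force
oracle (explicit per-participant loops) on 200 random small matrices with
random weights under both cutoff conventions, plus exact hand-computed toy
cases (a 4×3 matrix with H = 1/2, A = 5/6, M0 = 5/12 and contributions
0.4/0.4/0.2). Polychoric estimation is verified against 2-D cubature of the
bivariate normal density at n = 20,000 (recovery of ρ = 0.6 within ±0.05).
Calibration is verified on a 50,000-participant cohort (headcount within
±0.01 of 19.2% and recovered cutoff 11). Effect recovery uses 100 replicate
cohorts of n = 312: 95% Wald coverage of the true burden log-OR must reach
90/100, and the type-I error under a null effect stays within Monte-Carlo
error of 5%. These sizes keep each property estimable with comfortable
Monte-Carlo margins while the full suite runs in about a minute.

## Known limitations

* Contribution decompositions use the censored convention throughout;
  published radar charts built from uncensored headcounts would differ.
* The bootstrap gap test resamples participants within groups and is not a
  survey-design-aware variance estimator; no M1/M2 (gap/severity) members
  are implemented since all indicators are binary.
* The burden denominator ("total weighted indicators") admits a censored
  reading; both are implemented and the uncensored share is the default.
* ADI/SVI enter only as optional precomputed columns; deriving them from
  geographic identifiers is out of scope.
* SD-threshold indicators computed on the analytic sample make deprivation
  relative to the cohort itself; cross-cohort comparisons need external
  norms, which every rule accepts.
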