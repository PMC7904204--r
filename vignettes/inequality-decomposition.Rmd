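---
title: "Measuring and decomposing socioeconomic inequality in adolescent undernutrition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and decomposing socioeconomic inequality in adolescent undernutrition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqdecomp)
```

## The problem

Cross-sectional surveys of adolescents (ages 10–19) measure height and
weight, a household wealth score, and a handful of socio-demographic
covariates. Two standard undernutrition indicators are derived from
growth-reference z-scores: **thinness** (BMI-for-age z < −2 SD, acute
undernutrition) and **stunting** (height-for-age z ≤ −2 SD, chronic
undernutrition), plus their co-existence in the same individual. The
boundary operators differ deliberately — a z-score of exactly −2 counts
as stunted but not thin — and the package preserves that asymmetry in
`classify_nutrition()`.

Beyond prevalence, the policy question is distributional: *how strongly
is undernutrition concentrated among the poor, and which observable
factors account for that concentration?* The package answers with the
concentration index and its regression-based decomposition.

## The concentration index

Each individual receives a **fractional rank** in the wealth
distribution: order by the continuous wealth score and set
$R_i = (\sum_{j \prec i} w_j + w_i/2) / \sum_j w_j$, the cumulative
weight of strictly poorer individuals plus half one's own weight. With
equal weights and distinct scores $R_i = (i - 0.5)/n$. The
**concentration index** of an outcome $y$ with weighted mean $\mu$ is

$$C = \frac{2}{\mu}\,\mathrm{cov}_w(y, R),$$

lying in $[-1, 1]$, and in $[\mu - 1, 1 - \mu]$ for binary $y$. Negative
$C$ means the outcome is concentrated among the poor (the concentration
curve lies above the diagonal). The package reports the signed index
together with the neutral description "concentrated among the poor/rich"
rather than the ambiguous pro-rich/pro-poor labels, which the literature
uses inconsistently.

Numerical choices:

* **Population covariance** (divide by total weight, not total − 1).
  This is not cosmetic: only the population form makes the decomposition
  identity below exact.
* **Ties** share the midpoint rank of the tied group's pooled weight
  span — the health-economics convention. Tie handling matters when the
  wealth measure is coarse; with a continuous score ties are a
  measure-zero event, and the synthetic generator offers a
  `tie_fraction` knob precisely to exercise this path in tests.
* **Ranking uses the continuous wealth score**, never the quintile:
  quintiles discard within-group ordering and shrink $|C|$.
* Degenerate inputs fail loudly: $\mu = 0$ and constant ranks are
  errors, not silent zeros or NaNs.
* The index and the curve are mutually consistent:
  $C \approx 1 - 2 \times$ (trapezoid area under the curve), to $O(1/n)$.

## The decomposition

Fit the linear probability model (weighted OLS)

$$y_i = \alpha + \sum_k \beta_k x_{ki} + \varepsilon_i,$$

where the $x_k$ are dummy columns for the non-reference categories of
each covariate. Then

$$C = \sum_k \underbrace{\frac{\beta_k \bar{x}_k}{\mu}}_{\eta_k}
      C_k + \frac{GC_\varepsilon}{\mu},$$

with $C_k$ the concentration index of covariate $k$ (same estimator,
applied to the dummy) and $GC_\varepsilon = 2\,\mathrm{cov}_w(\varepsilon, R)$
the generalized concentration index of the residual. Because weighted
OLS residuals are exactly orthogonal to every design column, the
explained part $\sum_k \eta_k C_k$ ("calculated CI") plus the residual
term equals the actual index to machine precision; the test suite
enforces $10^{-10}$ on random datasets and the residual is additionally
computed both as $2\,\mathrm{cov}_w(\varepsilon,R)/\mu$ and as
actual − calculated, which must agree.

Design decisions that were genuinely open:

* **OLS, not logistic marginal effects, is the default engine.** The
  decomposition identity is linear; only OLS gives exact adding-up. An
  `engine = "logit"` alternative replaces $\beta_k$ with average partial
  effects from the logistic fit — the approximation error then lands in
  the residual — and results carry the engine tag.
* **Percentage contributions are relative to the calculated (explained)
  CI**, not the actual CI. This is the only convention under which
  per-factor totals sum to exactly 100 across a table, which published
  decomposition tables of this kind satisfy.
* **Empty categories** (a spec'd category with no observations) are
  reported with a zero contribution and an undefined $C_k$ rather than
  breaking the fit: an all-zero dummy has zero rank-covariance, so its
  contribution is identically zero whatever its coefficient would be; it
  is dropped from the design to preserve full rank.
* **Reference-category rows are emitted blank** rather than omitted,
  matching the layout convention of published tables.
* **Complete-case analysis per outcome**: records missing the outcome,
  the score or any model factor are dropped and the remaining n is
  reported. Differing analytic Ns across outcomes are therefore expected.
* Association tables (`odds_ratio_table()`) fit one multivariable
  logistic model with all covariates entered simultaneously and report
  Wald 95% intervals, the conventional "OR (95% CI)" presentation.

Formatted output (`decomp_table()`, `print()`) rounds **half away from
zero** — elasticities, covariate CIs and absolute contributions at 3
decimals, percentages at 1 — because that is how published survey tables
round; base R's round-half-to-even would disagree with them at exactly
representable ties. Rounded per-factor percentage totals consequently
sum to 100.0 only within rounding accumulation (±0.3 on realistic
tables), which the tests assert.

## LMS z-scores

The z-score of a measurement $x$ against a reference summarized by
$(L, M, S)$ — Box-Cox power, median, coefficient of variation — is
$z = ((x/M)^L - 1)/(LS)$ for $L \neq 0$ and $z = \ln(x/M)/S$ at $L = 0$;
the branches join continuously (tested at $|L| = 10^{-8}$ to within
$10^{-5}$) and invert exactly ($10^{-9}$ round-trip tolerance).
Reference tables are user-supplied CSVs keyed by (sex, age in months,
indicator); exact ages return stored rows, intermediate ages are
linearly interpolated in each parameter, and out-of-range ages raise an
error naming the bounds. Age given in years is mapped to **completed
months** (`age_to_months()`, floor of days/30.4375) — surveys rarely
state their mapping, so the package fixes one and documents it.
Implausible z-scores ($|z| > 5$) are **flagged, not dropped**, by
default; exclusion policy is left to the analyst because published
analytic sample sizes rarely specify theirs. No tail "restriction"
adjustment for extreme values is applied. A small synthetic fixture
(`make_lms_fixture()`, clearly not a WHO release) ships for tests and
examples so no download is ever required.

## What the synthetic generator emulates — and what it does not

`generate_population()` emulates the *statistical structure* of a large
two-state adolescent survey: ~20.6k records with roughly 29% boys;
a continuous standard-normal wealth score with empirical quintiles;
eight categorical covariates (age group, education, working status,
media exposure, caste, religion, residence, state) whose category
probabilities shift with wealth rank through per-category log-odds
coefficients; and latent BMI-for-age and height-for-age z-scores that
are linear in wealth rank and covariate dummies, share an individual
frailty term (producing realistic co-existence of thinness and
stunting), and carry Gaussian noise. Per-sex latent locations are
calibrated so the target prevalences are achieved — the defaults place
thinness at 25.8% (boys) / 13.1% (girls) and stunting at 25.6% / 39.3%,
the sex pattern consistent with the height-for-age z-score means the
generator also reproduces (about −1.3 for boys, −1.7 for girls).

`gradient_strength` scales the *entire* socioeconomic gradient — both
the direct wealth-rank effect on the latent z-scores and the
covariate–wealth dependence — so 0 yields outcome concentration indices
of 0 in expectation (a property the tests check at n = 20,000 within
±0.02). At the default of 1 the outcome indices come out at roughly
−0.13 to −0.30 across sexes and outcomes, with household wealth
accounting for 70–80% of the explained inequality — the qualitative
regime reported for adolescent undernutrition in poor settings. Weights
are equal by default (survey reports of this kind rarely state whether
weights entered estimation, so both paths are supported and tested to
coincide when weights are equal).

The generator does **not** emulate: multi-stage cluster sampling and its
design effects (records are i.i.d. given the latent model), household
asset scoring (the wealth score is taken as given), item nonresponse
patterns, or measurement error in height and weight. Passing tests
therefore demonstrate correctness of the estimators under a known
generative model — not robustness to the design features of any real
survey.

`generate_lpm_population()` is the second generator: outcomes drawn with
an exact (clipped) linear mean $E[y|x] = \alpha + \sum_k \beta_k x_k$,
with the realized per-covariate contributions attached as ground truth.
It exists because decomposition parameter-recovery tests need exact
linear structure, while z-score realism needs the latent-threshold
model; one generator cannot honestly provide both. Clipping above 10% of
records warns; an infeasible intercept errors.

## Problem sizes and runtime

The test suite runs at deliberately chosen sizes: identity and oracle
checks at n ≤ 1,000 (100 and 1,000 replicates respectively), analytic
limits at n = 20,000, decomposition parameter recovery at n = 50,000,
logistic coverage over 200 replicates of n = 400, and one full report
bundle at the study scale of n = 20,594. The complete suite runs in
well under a minute on one CPU; the acceptance script in a few seconds.

## Known limitations

* No standard errors or dominance tests for the concentration index, and
  no bootstrap uncertainty for contributions — the package reports point
  decompositions.
* No Erreygers or Wagstaff normalization of the index for bounded
  outcomes; the standard index is used throughout, and the generalized
  index appears only inside the residual term.
* The linear probability model can predict outside [0, 1]; that is
  inherent to the method and documented rather than patched.
* Logistic fits use Wald intervals and treat weights as frequency-style;
  no survey-design (clustered) variance correction is offered.
* The decomposition attributes, it does not identify causes: a
  covariate's contribution mixes its association with the outcome and
  its own concentration over wealth.
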