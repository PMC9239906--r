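---
title: "Methods: interventional disparity measures with jointly intervened mediators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interventional disparity measures with jointly intervened mediators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intdisp)
```

## The question the package answers

Childhood BMI is partly driven by polygenic liability, which cannot itself be
intervened on. Parental-feeding behaviours sit downstream of that liability
and *can* be targeted. `intdisp` quantifies how much of the disparity in BMI
across levels of genetic liability would remain if parental feeding were
shifted by a hypothetical intervention — the health-disparity framing of
mediation analysis, applied to a 5-level exposure (quintiles of a polygenic
score for BMI, PGS-BMI), three correlated mediators (emotional feeding,
restriction, pressure to eat, as factor scores), a continuous outcome (BMI at
age 12, kg/m²), and three confounders (child sex, maternal education,
maternal pre-pregnancy BMI).

## Estimands

Let $X \in \{1,\dots,5\}$ be the exposure category (1 = lowest liability),
$M$ the three-dimensional mediator vector, $Y$ the outcome and $C$ the
confounders. Write $M_C^j$ for a random draw from the joint distribution of
$M$ given $C$ with $X$ set to $j$, and $Y(m)$ for the potential outcome with
$M$ set to $m$.

Two families of contrasts are reported, for $j = 2,\dots,5$:

* **Adjusted total association.**
  $\mathrm{AdjTA}_j = \sum_c \left[ E\{Y \mid X=j, C=c\} - E\{Y \mid X=1, C=c\} \right] \Pr(C=c)$
* **Interventional disparity measure, direct effect.**
  $\mathrm{IDMDE}_j = \sum_c \left[ E\{Y(M_C^1) \mid X=j, C=c\} - E\{Y(M_C^1) \mid X=1, C=c\} \right] \Pr(C=c)$

and their **Difference** $\mathrm{AdjTA}_j - \mathrm{IDMDE}_j$, the portion
of the disparity removable by setting the mediators to their joint
distribution under the reference category ("shift to reference",
`shift_to_reference`). The second intervention family shifts the mediator
distribution down one liability category: contrasts $(j+1)$ versus $j$ with
mediators drawn at level $j$, for $j = 1,\dots,4$ (`shift_down_one`). (As
printed, the shifted-reference definition indexes $j = 2,\dots,5$ with
$X = j+1$, which would reference a sixth category; the package implements the
four adjacent contrasts that the reported tables actually label, 21 through
54.)

The mediators are always intervened on **jointly**: the three feeding
behaviours are correlated (pressure to eat negatively with the other two),
so a univariate intervention is neither realistic nor identified without a
causal ordering among the mediators, which we do not assume. Identification
relies on consistency, no interference, and no unmeasured confounding of the
mediator–outcome relations given $C$; these are assumptions about the data,
not testable by the package.

## Estimation

Three regression components are fitted by least squares:

1. **Mediator model** — three seemingly-unrelated regressions of the
   mediators on exposure-category indicators and confounder main effects,
   sharing one design; the joint law is retained as the coefficient matrix
   plus the residual covariance $\hat\Sigma_u$ (cross-product of residuals
   over $n - p$) and the residual rows themselves.
2. **Outcome model** — $Y$ on category indicators, mediator main effects,
   confounder main effects, and **all mediator-by-confounder products**. The
   interaction set follows the motivating cohort analysis, which included
   confounder-mediator interactions in the outcome estimation step; the
   mediator models carry main effects only.
3. **Total model** — $Y$ on category indicators and confounders, behind
   AdjTA.

`estimate_idm_de()` evaluates the plug-in Monte Carlo g-computation: for each
row $i$ and each of $K$ draws, a counterfactual mediator vector is drawn from
the fitted joint law at the contrast's reference level given $C_i$ (Gaussian
dialect by default — trivariate normal noise with covariance $\hat\Sigma_u$;
an `empirical` dialect resamples whole residual rows, preserving
cross-mediator dependence without normality), and the fitted outcome model is
evaluated at both exposure levels with the mediators set to that draw.
Averaging over the $n$ observed rows realizes $\sum_c \cdots \Pr(C=c)$ with
the empirical confounder distribution — with a continuous confounder
(maternal BMI) an explicit sum over $c$ is infeasible, and the empirical
average is its natural sample analogue. The "$K$-fold expanded dataset" is
processed as $K$ draws per row in blocks, never materialized in full.

Three numerical properties anchor the implementation and are asserted by the
test suite:

* **Common draws and collapse.** By default the same mediator draws serve
  both arms of a contrast. Because no model carries exposure-by-mediator or
  exposure-by-confounder terms, the arm difference is then *exactly* the
  difference of the outcome-model category coefficients, for any $K$ — Monte
  Carlo noise cancels identically. This is the primary internal correctness
  check of the g-computation loop (and the reason results are insensitive to
  $K$ under the default model forms; $K$ matters once the model forms are
  extended). A flag disables common draws for diagnostics.
* **Telescoping.** The four shift-down-one AdjTA contrasts sum exactly to
  the top shift-to-reference contrast, since all come from one fitted total
  model.
* **Scheme agreement.** The (2 vs 1) contrast is the same estimand in both
  schemes; draws are seeded per mediator reference level, so the two schemes
  produce bitwise-identical values for it.

Defaults mirror the motivating cohort analysis: $K = 1000$, $B = 1000$ bootstrap
replicates, 95% intervals.

## Bootstrap inference

`bootstrap_effects()` resamples rows with replacement, refits all three
models, and recomputes every contrast within each replicate (so the
Difference's interval reflects the joint sampling law of AdjTA and IDM-DE).
Intervals are **percentile bootstrap** — the interval type was not stated in
the motivating analysis, and the percentile interval is the simplest defensible default.
Quantiles use linear interpolation between order statistics at plotting
positions $k/(B+1)$ (`type = 6`), chosen so results are reproducible across
implementations and so the $B = 2$ degenerate case returns the replicate
range. Replicates whose resample empties an exposure category (or makes a
design rank deficient) are counted, reported, and redrawn, up to $2B$
attempts — keeping the effective $B$ nominal without biasing toward
degenerate samples. Exposure categories assigned on the full sample are kept
as-is within replicates; quintile boundaries are not re-estimated per
replicate.

## The synthetic cohort generator

The cohort behind the motivating analysis is restricted-access, so the package ships a
linear-Gaussian structural generator (`generator_config()`,
`generate_cohort()`) that emulates the analysis table: two Bernoulli
confounders and one Gaussian confounder, a Gaussian polygenic score
(optionally loaded on maternal BMI to mimic shared genetics; default 0, which
keeps the calibration closed forms exact), mediators linear in the exposure
and confounders with trivariate Gaussian residuals, and a linear outcome with
optional mediator-by-confounder interaction terms.

`calibrate_from_moments()` inverts this law in closed form so that the
implied moments hit specified targets; `default_config()` applies it to the
published analysis-sample descriptives: score mean/SD 0.27/0.28, mediator
SDs 0.44/0.50/0.62, outcome 19.0 (3.3) kg/m², maternal BMI 22.8 (3.6),
49% boys, 47% high maternal education, and correlations
$r(\text{score}, \text{BMI}) = 0.36$,
$r(\text{score}, \text{restriction}) = 0.12$,
$r(\text{pressure}, \text{emotional}) = -0.22$,
$r(\text{pressure}, \text{restriction}) = -0.23$. Quantities those
descriptives do not identify were fixed once as modest, plausible values and
are documented here as the package's own choices: the unpublished
correlations $r(\text{score}, \text{emotional}) = 0.04$,
$r(\text{score}, \text{pressure}) = -0.08$ (restriction responds most to
child liability; pressure to eat tends the other way),
$r(\text{emotional}, \text{restriction}) = 0.15$; confounder effects on
mediators of at most 0.06 SD; outcome effects of sex $-0.15$, maternal
education $-0.25$ and maternal BMI $0.28$ kg/m² per kg/m²; and
mediator-outcome coefficients $(0.45, 0.90, -0.55)$ for emotional feeding,
restriction and pressure to eat. The default cohort size is 4248, the
complete-case analysis sample of the motivating cohort study.

### Two pathway modes

* `pathway = "continuous"` (default): exposure effects act through the
  continuous score — realistic, used for moment calibration. Under this
  regime the residual *within-quintile* score variation confounds the
  mediator-outcome relation from the categorical models' viewpoint, so no
  finite-sample estimator can recover structural truth exactly; no oracle
  truth is claimed for it.
* `pathway = "categorical"`: exposure effects act only through the
  quintile-conditional mean of the score, $g_j = \mu + \sigma \lambda_j$
  with $\lambda_j$ the mean of a standard normal within its $j$-th quintile
  ($\lambda = \pm 1.400, \pm 0.532, 0$; variance $\approx 0.897$, which is
  also the attenuation factor the categorical calibration corrects by). The
  categorical regression models are then correctly specified and the
  no-unmeasured-confounding assumption holds exactly — the regime in which
  the estimator is validated against the oracles.

### Oracles

`closed_form_effects()` gives analytic truth under a known configuration:
$\mathrm{IDMDE}$ of contrast $(a, b)$ is $\beta_X (g_a - g_b)$ and
$\mathrm{AdjTA}$ is $(\beta_X + \beta_M^\top \alpha_X)(g_a - g_b)$, valid
for categorical-pathway configurations (and continuous ones with the score
independent of confounders) with zero interaction coefficients.
`brute_force_effects()` simulates the structural equations directly — draw
counterfactual mediators from the *true* law, evaluate the *true* outcome
equation at both arms, average — and is the fallback when interactions are
present; shared residual noise across arms gives it near-zero Monte Carlo
error in the linear case. The two oracles cross-validate each other in the
test suite over randomly drawn configurations.

### What the generator does not emulate

Marginals are Gaussian by construction. The source data are visibly not:
the reported restriction means by quintile run from $-0.13$ to $0.20$, which
is not attainable jointly with $r = 0.12$ and SD $= 0.50$ under any
linear-Gaussian law (the implied extremes are about $\pm 0.08$). We therefore
match the published moments and correlations, not the published stratum
means. Passing tests demonstrate that the estimator recovers truth when its
models are correctly specified and that the generator reproduces the target
moment structure — not that the models are correct for the real cohort, nor
anything about skewness, nonlinearity, or informative missingness (only a
complete-case path is supported).

## Data handling choices

* **Complete-case rule.** The source describes completeness for exposure,
  mediators and outcome; the fitted models also condition on the confounders,
  so rows with missing confounders are excluded too. `complete_cases()` takes
  a `min_rows` floor (the pipeline uses 50) rather than hard-coding one, so
  small hand-built tables remain usable in tests and examples.
* **Quintile assignment.** Category $j$ takes ascending-score ranks up to
  $\lceil nj/5 \rceil$; ties break by stable input order. Sizes differ by at
  most one (e.g. $n = 4248$ gives sizes 849/850), and the assignment is
  invariant to order-preserving transforms of the score.
* **Encodings.** Sex: 1 = boy; maternal education: 1 = A-levels or higher —
  fixed so coefficient signs are reproducible.

## Problem sizes used by the test suite

Estimator validation runs at $n = 20{,}000$, $K = 200$ against the closed
form (every contrast within ±0.03 kg/m²); parameter recovery at
$n = 50{,}000$ (within 3 SE); calibration checks at $n = 200{,}000$
(correlations within ±0.01); the calibration fixed point at $n = 10^6$
(coefficients within 2%, the smallest loading having ~0.8% relative sampling
error at that size); and bootstrap coverage over 200 simulated cohorts of
$n = 2000$ with $B = 200$, $K = 50$ (empirical 95% coverage required to fall
in [0.90, 0.99]). These sizes were chosen so each check is decisively powered
for the property it tests.

## Known limitations

* Mediator-specific path effects are out of scope by design — the mediators
  are intervened on jointly only.
* No exposure-by-mediator interactions are estimated (the model forms make
  the collapse property exact; richer outcome models would make $K$ matter).
* Percentile intervals only; no BCa or studentized variants.
* Multiply-imputed inputs are not supported; deduplication of multiple
  births is assumed done upstream.
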