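# intdisp

Interventional disparity measures with jointly intervened mediators.

## What it is for

Polygenic liability for childhood obesity cannot be intervened on, but
downstream behaviours can. For cohorts with a polygenic score for BMI
(categorized into quintiles, `X = 1..5`), three correlated parental-feeding
factor scores (emotional feeding, restriction, pressure to eat — the joint
mediator vector `M`), BMI in early adolescence as outcome `Y`, and
confounders `C` (child sex, maternal education, maternal pre-pregnancy BMI),
`intdisp` estimates, for each liability category `j` versus a reference:

- the **adjusted total association**

  `AdjTA_j = Σ_c [ E{Y | X=j, C=c} − E{Y | X=1, C=c} ] Pr(C=c)`

- the **interventional disparity measure direct effect** — the disparity that
  would *remain* had the joint mediator vector been drawn from its
  distribution under the reference category (`M_C^1`):

  `IDMDE_j = Σ_c [ E{Y(M_C^1) | X=j, C=c} − E{Y(M_C^1) | X=1, C=c} ] Pr(C=c)`

- and their **Difference** `AdjTA_j − IDMDE_j`, the portion of the disparity
  removable by the hypothetical parental-feeding intervention.

Two intervention schemes are reported: shifting the mediator distribution to
the lowest-liability category (contrasts `j` vs 1), and shifting it down one
category (contrasts `j+1` vs `j`, mediators drawn at level `j`).

Estimation is plug-in parametric g-computation: least-squares mediator,
outcome (with mediator×confounder interactions) and total-association models,
Monte Carlo expansion with `K` counterfactual mediator draws per row
(default 1000), standardization over the empirical confounder distribution,
and percentile-bootstrap confidence intervals (`B = 1000` by default).
Because the motivating cohort data are restricted-access, the package also
ships a moment-calibrated synthetic cohort generator and analytic /
brute-force oracles so the whole pipeline is testable end to end.

## Worked example

Generate a cohort of the analysis-sample size from the default calibrated
configuration, then run the full pipeline:

```r
library(intdisp)

cohort  <- generate_cohort(default_config(), n = 4248, seed = 2026)
cohort  <- complete_cases(cohort, min_rows = 50)
results <- bootstrap_effects(cohort,
                             estimation_settings(K = 200, seed = 1),
                             bootstrap_settings(B = 200, seed = 2))
print(as.data.frame(results), digits = 3)
```

```
               scheme label   quantity estimate   lower  upper
1  shift_to_reference     2     adj_ta   0.8933  0.5798 1.1717
2  shift_to_reference     3     adj_ta   1.7302  1.4485 1.9574
3  shift_to_reference     4     adj_ta   2.1805  1.8944 2.4392
4  shift_to_reference     5     adj_ta   3.1709  2.9054 3.4330
5      shift_down_one    21     adj_ta   0.8933  0.5798 1.1717
6      shift_down_one    32     adj_ta   0.8370  0.5532 1.1001
7      shift_down_one    43     adj_ta   0.4502  0.1692 0.7163
8      shift_down_one    54     adj_ta   0.9905  0.7111 1.2686
9  shift_to_reference     2     idm_de   0.7885  0.4894 1.0562
10 shift_to_reference     3     idm_de   1.5972  1.2904 1.8518
11 shift_to_reference     4     idm_de   1.9950  1.7280 2.2735
12 shift_to_reference     5     idm_de   2.9633  2.6962 3.2098
13     shift_down_one    21     idm_de   0.7885  0.4894 1.0562
14     shift_down_one    32     idm_de   0.8088  0.5101 1.0787
15     shift_down_one    43     idm_de   0.3978  0.1240 0.6861
16     shift_down_one    54     idm_de   0.9683  0.6728 1.2296
17 shift_to_reference     2 difference   0.1048  0.0465 0.1741
18 shift_to_reference     3 difference   0.1330  0.0625 0.2016
19 shift_to_reference     4 difference   0.1854  0.1202 0.2589
20 shift_to_reference     5 difference   0.2076  0.1316 0.2723
21     shift_down_one    21 difference   0.1048  0.0465 0.1741
22     shift_down_one    32 difference   0.0282 -0.0418 0.0932
23     shift_down_one    43 difference   0.0524 -0.0112 0.1158
24     shift_down_one    54 difference   0.0222 -0.0427 0.0884
```

Reading the output: row 4 says the top liability quintile is associated with
about 3.2 kg/m² higher BMI than the lowest quintile after confounder
adjustment; row 12 says about 3.0 kg/m² of that would remain had parental
feeding been shifted to its distribution under the lowest-liability category;
row 20 is the removable portion, about 0.21 kg/m² with 95% percentile
interval (0.13, 0.27). The size of the removable portion is set by the
default generator's calibrated coefficients — on real data these quantities
are whatever the fitted models produce.

Other entry points: `fit_models()`, `estimate_all()` (point estimates only),
`closed_form_effects()` / `brute_force_effects()` (truth under a known
generator configuration), and `run_simulate()` / `run_estimate()` driven by a
JSON/YAML run config (also available as a thin CLI in `inst/cli/intdisp.R`
with subcommands `simulate`, `fit`, `estimate`, `oracle`).

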