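---
title: "Probit structured additive regression for adverse birth outcomes: model, priors and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probit structured additive regression for adverse birth outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Household air pollution from cooking with unclean fuels (wood, charcoal,
coal, kerosene, dung, crop residue) is a leading environmental exposure in
low- and middle-income countries, and mothers and infants bear much of its
burden. The question this package addresses is whether unclean cooking-fuel
use is associated with adverse birth outcomes — stillbirth, low birth
weight (< 2500 g) and preterm birth (< 37 weeks) — in a DHS-style national
survey where births are nested within mothers and outcomes vary strongly
across states.

Two analysis layers are involved. First, descriptive contingency-table
statistics: prevalence ratios (PR) and odds ratios (OR) of each
characteristic across the clean/unclean fuel split, with chi-square or
Fisher tests. Second, a Bayesian probit structured additive regression
(STAR) that estimates the fuel effect while adjusting for nonlinear age,
repeated births per mother, and spatial heterogeneity.

## The model

For birth $i$, with $Y_i \in \{0,1\}$ an adverse outcome indicator,

$$\Pr(Y_i = 1 \mid \cdot) = \Phi(\eta_i),$$

$$\eta_i = \gamma_0 + \gamma_1\,\text{fuel}_i + \dots + \gamma_k\,\text{cov}_i
  + f_{\text{age}}(a_i) + b_{m(i)} + u_{s(i)} + v_{s(i)},$$

where $\Phi$ is the standard normal CDF (probit link), $m(i)$ indexes the
mother and $s(i)$ the state of residence, and

* the fixed effects $\gamma$ (intercept, cooking fuel, education and
  region dummies) carry essentially flat Gaussian priors, implemented with
  precision $10^{-8}$ for numerical stability;
* $f_{\text{age}}$ is a Bayesian P-spline: a cubic B-spline basis with 20
  equidistant interior knots over the observed age range and a
  second-order random-walk prior on the coefficients,
  $p(\beta \mid \tau^2) \propto \exp\{-\beta^\top K \beta / 2\tau^2\}$ with
  $K = D_2^\top D_2$;
* $b_m \sim N(0, \sigma_b^2)$ is an i.i.d. mother random intercept,
  absorbing the correlation between births of the same mother;
* $u$ is the structured spatial effect with an intrinsic CAR (Gaussian
  Markov random field) prior of precision $Q/\sigma_u^2$,
  $Q = \operatorname{diag}(\text{degree}) - A$ on the state contiguity
  graph; $v \sim N(0, \sigma_v^2)$ is the unstructured (exchangeable)
  state effect;
* every variance component has a weakly informative inverse-gamma
  hyperprior, $IG(a, b)$ with $a = b = 0.001$ by default.

### Sampling

Fitting uses Gibbs sampling with Albert–Chib data augmentation: a latent
$z_i \sim N(\eta_i, 1)$ truncated to be positive when $y_i = 1$ and
negative when $y_i = 0$ turns the probit likelihood Gaussian, so every
coefficient block has a multivariate-normal full conditional and every
variance an inverse-gamma one (shape $a + \text{rank}/2$, scale
$b + \text{quadratic form}/2$, where the rank is $m - r$ for the spline
penalty, $n_{\text{areas}} - 1$ for the ICAR block, and the block size for
the i.i.d. blocks). The default schedule is 25,000 iterations, 5,000
burn-in and thinning 10 (2,000 stored draws); thinning is a storage
choice, not an inferential one. Model selection uses the deviance
information criterion with $\bar D$ the posterior mean deviance,
$\hat D$ the deviance at posterior-mean parameters, $p_D = \bar D - \hat
D$ and $\text{DIC} = \bar D + p_D$.

### Identifiability

The random-walk and ICAR priors are improper: adding a constant to the
spline coefficients or to the structured field and subtracting it from the
intercept leaves the likelihood and prior unchanged. We resolve this by
re-centring both blocks to mean zero at every iteration and absorbing the
shift into the intercept (standard GMRF practice, and — unlike corner
constraints — it yields a testable invariant: stored spline-fit values and
structured-field draws sum to zero to $10^{-8}$ at every stored draw).
Because the B-spline basis rows sum to one, subtracting a constant from
all spline coefficients shifts the fitted curve by exactly that constant,
so the re-centring is exact, not approximate. The unstructured block keeps
its proper i.i.d. prior and needs no constraint. Both spatial terms enter
jointly with only this centring; when region fixed effects are also
present (Model 4), region and state-level effects compete for the same
broad-scale variation — the fixed contrasts remain interpretable but some
confounding between the region dummies and the smooth spatial surface is
unavoidable, as in any convolution-style spatial model with area-level
covariates.

### The model ladder

Four nested models are compared by DIC, per outcome: Model 1 = fuel +
both spatial components; Model 2 adds the mother random intercept; Model 3
adds the nonlinear age effect; Model 4 adds education and region fixed
effects. Household wealth is accepted by the design-assembly code but
excluded from the Model 4 template (a warning notes why): wealth quintile
essentially determines cooking-fuel type in these data, and a joint fit is
unstable. Ladder fits derive per-model seeds from one master seed so that
DIC comparisons are not confounded by shared RNG streams.

## Descriptive estimators

The descriptive layer works from 2×2 counts with layout `a` = present &
unclean, `b` = absent & unclean, `c` = present & clean, `d` = absent &
clean:

* PR = $[a/(a+b)] / [c/(c+d)]$ with the Katz log-scale interval
  $\exp\{\log \text{PR} \pm z \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}\}$;
* OR = $ad/bc$ with the Woolf interval
  $\exp\{\log \text{OR} \pm z \sqrt{1/a + 1/b + 1/c + 1/d}\}$.

These two interval methods were chosen because they reproduce the
published descriptive table's intervals to two decimals from its printed
counts. No continuity or Haldane correction is applied (the tables are
large; a zero cell is surfaced as an error rather than silently
corrected). Tests of association use Pearson's chi-square without Yates
correction, switching to Fisher's exact test when any expected cell is
below 5. The report generator applies the row-appropriate estimator:
binary outcome/exposure rows (smoking, birth status, birth weight,
duration) get PRs across fuel columns; mother-level categorical rows
(education, wealth, region) get ORs against a reference category. The
reference level for region is exposed as a parameter rather than
hard-coded, because published tables of this kind are not always
internally consistent about which region anchors the comparison.

## The synthetic cohort generator

The survey microdata are access-restricted, so the package ships a
generator that emulates their structure rather than their records. Its
defaults are the study conditions, fixed once:

| quantity | default | basis |
|---|---|---|
| mothers | 41,821 | survey size |
| births per mother | 1 + geometric, mean 3.05, truncated at 15 | matches 127,545 births / 41,821 mothers; the survey does not publish this distribution |
| unclean-fuel prevalence | 0.893 | survey marginal |
| stillbirth intercept | $\Phi^{-1}(0.143)$ | survey marginal |
| fuel effect (stillbirth) | +0.14 | multivariable posterior mean |
| education effects | −0.07, −0.23, −0.39 | multivariable posterior means |
| LBW / preterm intercepts | $\Phi^{-1}(0.073)$, $\Phi^{-1}(0.01)$ | survey marginals |
| age effect | scaled logistic, increasing on [15, 49], centred | monotone-increasing risk with age; amplitude 0.6 probit units |
| $\sigma_b, \sigma_u, \sigma_v$ | 0.5, 0.35, 0.15 | moderate clustering, spatially smooth field dominating the exchangeable one — typical of national mortality surfaces |
| fuel–wealth log-odds | −1.5 per quintile | strong collinearity: richest-vs-poorest unclean-use gap > 50 points, mirroring the near-deterministic fuel/wealth split in the survey |
| missingness | 93.9% (weight), 68.8% (duration), MCAR | survey response rates |
| mother's age | N(35.9, 7.9²) truncated to [15, 49] | survey mean ± SD |

The fuel model solves its intercept numerically so the marginal unclean
prevalence equals the target whatever the collinearity strength. All three
outcomes share the mother, spatial and age effects; each has its own
intercept and fuel coefficient. The generator records the full generating
truth (coefficients, per-area fields, per-mother intercepts, per-birth
linear predictor), which is what parameter-recovery and calibration tests
consume.

What the generator does *not* emulate: the two-stage stratified cluster
sampling design (the models here do not use survey weights), informative
missingness (masks are MCAR by construction), within-mother age variation
across births (a mother's recorded age is used for all her births),
geographic coordinates, and any real spatial covariate surface. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimator under its own assumptions — not robustness to survey-design
artefacts in real data.

The bundled `nigeria37` area fixture is a hand-encoded approximate
contiguity list for Nigeria's 36 states plus the Federal Capital
Territory, tagged by geopolitical region. It is synthetic in the sense of
being encoded from a printed map rather than derived from GIS boundary
files; model code is graph-agnostic and lattice generators are provided
for tests.

## Numerical choices

* Truncated-normal draws use inverse-CDF sampling with the uniform
  clamped to $[10^{-15}, 1 - 10^{-15}]$ and the latent variable clamped to
  $\eta \pm 8$; deviance computations clamp probabilities to
  $[10^{-12}, 1 - 10^{-12}]$.
* Fixed-block Cholesky factors are precomputed (the flat prior is
  constant); spline and ICAR blocks re-factorise each iteration because
  their prior precisions carry the current variance draw.
* A divergence guard flags any variance draw above $10^6$ and raises a
  single warning listing how many iterations were affected.
* Areas with no observations keep their prior-only conditional (the ICAR
  solve smooths them toward their neighbours); they are not an error.
* Equal-tailed credible intervals use type-7 quantiles; the smooth is
  summarised with both 80% and 95% bands on a user grid.
* Split-chain $\widehat R$ and an initial-positive-sequence effective
  sample size are reported per fixed effect and for the deviance; there
  is no automatic stopping rule.
* Complete-case analysis throughout, with a kept/dropped audit attached
  to every design.

## Validation design and problem sizes

The test suite validates the sampler by independent routes rather than by
reproducing the published multivariable table (which would require the
restricted microdata):

* **Oracle equivalence** — with random effects and smooth off and flat
  priors, posterior means from ~5,000 births match an independently
  implemented Newton–Raphson probit MLE within 3 posterior SDs, and the
  posterior SD matches the frequentist standard error.
* **Parameter recovery** — 20 replicate cohorts of ~5,000 births are
  generated with the fuel effect at its study value (+0.14) and fitted
  with the full Model-4 structure at 3,000 iterations / 500 burn-in; the
  95% CrI must cover the truth in at least 17 of 20 replicates.
* **Identifiability** — sum-to-zero invariants hold at every stored
  iteration to $10^{-8}$.
* **DIC behaviour** — the identity $\text{DIC} = \bar D + p_D$ holds
  exactly; $p_D$ for a flat-prior two-parameter probit fit is ~2; and on
  data generated with mother effects and a nonlinear age effect the
  median DIC over 5 replicates ranks Model 3 below Model 1.
* **Generator calibration** — with null effects and intercept
  $\Phi^{-1}(0.143)$ the simulated stillbirth rate sits within 3 binomial
  SDs of 14.3%, and analogously for the 89.3% fuel prevalence; the
  per-decile outcome rate matches $\Phi(\eta)$ within binomial error.
* **Katz coverage** — 95% intervals achieve 95% ± 2% empirical coverage
  over 2,000 simulated tables with known PR.

Reduced problem sizes (cohorts of ~5,000 births, 1,500–3,000 iterations)
are used in replicate experiments; they were chosen as the smallest scale
at which posterior intervals are informative for effects of magnitude
~0.15 probit units, and the analysis drivers under `analysis/` run at
6,000 mothers (~18,000 births) for the same reason. The descriptive layer
is exact at any scale.

## Known limitations

* Mother's age enters at the mother level; birth-order or time-varying
  age effects are not modelled.
* The logit link, survey-weighted estimators, multinomial/survival
  outcomes, and map rendering are out of scope; spatial-effect summaries
  are delivered as per-area tables.
* DIC is the only model-choice criterion implemented (no WAIC/LOO).
* With strong fuel–wealth collinearity a joint fuel + wealth fit is
  legitimately unstable; the software warns and the ladder omits wealth
  by design.
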