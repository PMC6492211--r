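---
title: "Variable selection with multiply imputed data: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variable selection with multiply imputed data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mivarsel)
```

`mivarsel` builds logistic prediction models from incomplete covariate data
handled by multiple imputation (MI), and evaluates how different
variable-selection strategies behave in that setting. This vignette documents
the statistical model, the algorithms, the tunable parameters, and — most
importantly for a package of this kind — the design decisions taken where
several defensible implementations exist.

## The model and the selection problem

Throughout, the outcome is binary and modeled by logistic regression,

$$\operatorname{logit} P(Y_i = 1 \mid x_i) = \beta_0 + x_i^\top \beta,$$

with $p$ covariates that may be continuous or binary. Covariates (never the
outcome) may be missing; missingness is assumed to be *missing at random*
(MAR): the probability that a value is missing depends only on observed
quantities. Chained-equations imputation then yields $m$ completed copies of
the data, and the task is to produce **one** coefficient vector — intercept
plus $p$ slopes, zero for unselected covariates — from the $m$ copies. The
package's `pooled_model` container enforces that predictions depend only on
this single coefficient vector: pooling always happens on the coefficient
scale, never by averaging $m$ separate prediction vectors.

## Lasso core

`fit_path()` minimizes the weighted negative average log-likelihood plus
$\lambda \lVert \beta \rVert_1$ with an unpenalized intercept, covariates
standardized internally to weighted mean zero and variance one (coefficients
are returned on the original scale), along a decreasing grid of 100
log-spaced penalties from $\lambda_{max}$ (the smallest penalty at which all
slopes are zero) down to $0.001\,\lambda_{max}$. The convex subproblems are
solved by `glmnet`'s coordinate descent at a tight tolerance (`thresh =
1e-10`); the test suite verifies the Karush–Kuhn–Tucker subgradient
conditions at every grid point and the agreement of the unpenalized end of
the path with a maximum-likelihood oracle.

`cv_curve()` performs a single 10-fold cross-validation of the binomial
deviance $-2\sum w_i [y_i \log \hat p_i + (1-y_i)\log(1-\hat p_i)]/\sum w_i$,
with predicted probabilities clipped at $10^{-15}$ so single-class folds stay
finite. Fold assignment is stratified by outcome and, when the data are
stacked completions, grouped by subject: a subject's $m$ rows are held out
together or not at all, so the penalty choice reflects imputation
variability. The reported standard error is the across-fold standard
deviation divided by $\sqrt{k}$.

`choose_penalty()` returns both rules: $\lambda_{opt}$ minimizes the mean
cross-validated deviance (ties broken toward the larger, more parsimonious
penalty), and $\lambda_{1se}$ is the largest penalty whose mean deviance
stays within one standard error — the standard error *at the minimizer*, the
convention of the software cited above — of the minimum. The 1-se model is
deliberately over-shrunk; that is the point of offering recalibration.

## Selection strategies

Two families are implemented (see the README table for the catalogue):

* **Bootstrap inclusion frequencies** (`bootstrap_inclusion()`,
  `select_by_frequency()`): from each completed dataset draw $B$ bootstrap
  resamples of subjects, run the base selector (backward elimination by AIC,
  or lasso with the penalty re-chosen by cross-validation *within each
  resample*), and keep covariates retained in at least 50% of the $mB$ fits
  (the comparison is inclusive, $\geq$). The final model refits the selected
  set unpenalized on each completion and averages the coefficients (Rubin
  point-estimate pooling). Backward elimination can fail on separated
  resamples; such fits are excluded from the frequency denominator and
  counted.
* **Lasso on the original MI data**: per-completion lasso with averaging
  (`select_sepav()`; the union variant `SepAv` or the majority variant
  `SepAvF`), or a single lasso on the stacked data (`select_stacked()`), with
  uniform $1/m$ row weights (`Stack`) or the missingness weights
  $w_i = (1/m)\,(\text{observed covariates of } i)/p$ (`StackW`), which
  down-weight subjects whose rows carry more imputed values.

Design decisions worth recording:

* **SepAv averaging includes zeros.** When a variable is selected in only
  some completions, the completions where its coefficient is zero still enter
  the average. This is the Rubin-consistent reading of "average the
  coefficient estimates over the $m$ models", and it produces SepAv's
  characteristic many-small-coefficients behavior. The alternative
  (averaging only over selecting completions) would inflate small effects.
* **Stack uses $1/m$ rather than unit row weights.** Point estimates at a
  fixed penalty are identical either way (the objective is weight-scale
  invariant); $1/m$ keeps the cross-validated deviance on the per-subject
  scale so penalties are comparable with the separate-data methods.
* **Bootstrap resamples are drawn independently per completion**, and $B$
  defaults to 100.
* **Backward elimination** is greedy: at each step the single removal that
  most decreases AIC is taken, stopping when no removal decreases it. The
  test suite checks every step against an exhaustive single-removal oracle.

## Recalibration

Only 1-se models are recalibrated (optimal-penalty shrinkage is already
tuned; asking for recalibration there is a usage error). *Score*
recalibration fits $\operatorname{logit} P(Y=1) = \gamma_0 + \gamma_1 Z$ on
the derivation data, where $Z$ is the model's linear predictor, and maps
slopes to $\gamma_1 \hat\beta_j$. The new intercept is
$\gamma_0 + \gamma_1 \hat\beta_0$, so the recalibrated linear predictor is
exactly $\gamma_0 + \gamma_1 Z$ — the natural completion of the slope rule,
which the source description leaves implicit. Score recalibration preserves
coefficient ratios and the ranking of predictions, hence the AUC, exactly.
*Refit* recalibration replaces the shrunken coefficients by the unpenalized
ML fit of the selected set. For separate-MI methods the recalibration model
is fit per completion and the $\gamma$'s (or coefficients) averaged; for
stacked methods it is fit once on the weighted stack. Recalibration uses the
derivation data itself — it corrects shrinkage, it is not external
validation.

## The synthetic-data generator

`build_mechanism()` encodes two generating mechanisms used by the test suite
and the reproduction script. Both draw latent covariates from a multivariate
normal distribution with mean zero and unit variances; mechanism one ($p=15$)
uses a sparse correlation structure
($\rho_{1,10}=\rho_{2,6}=\rho_{7,14}=\rho_{9,13}=0.5$, $\rho_{4,8}=-0.7$,
$\rho_{7,8}=0.3$, $\rho_{11,12}=0.7$; all other pairs uncorrelated),
mechanism two ($p=25$) an AR(1) structure with $\rho = 0.5$. Variables
2, 4, 5, 9, 10, 11, 12 are dichotomized **strictly at zero** (ties have
probability zero) and coded $\{0,1\}$. True coefficients sit on covariates
4–10 ($\beta_4=-0.5$, $\beta_5=\beta_6=\beta_7=0.5$, $\beta_8=\beta_9=1$,
$\beta_{10}=1.5$), the intercept is $-0.25$, and the outcome is drawn from
the logistic model applied to the *transformed* covariates. Under this
literal construction the mean linear predictor is $+1.0$ and the outcome
prevalence is about 66%; the acceptance checks compare the measured
prevalence against the 60% reference value and report whatever the generator
actually produces.

Missingness (`impose_mar()`) gives every subject one probability
$p_i = \operatorname{expit}(\alpha_0 + 0.5\sum_{k \notin J} X_{ki} + 0.5
Y_i)$ built from the always-observed covariates (binary ones in their
$\{0,1\}$ coding, matching the outcome model) and the outcome; for each
variable $j$ in the missingness set $J$, indicators $R_{ji}$ are drawn
**independently across $j$** given $p_i$ — one model per variable of
identical form, independence being the natural reading. $\alpha_0$ is
re-solved for every generated dataset from its own offsets by a bracketing
root finder (`solve_alpha0()`, achieved mean within $10^{-10}$), so the
expected per-variable missingness equals the target `miss` and the overall
missing-entry fraction equals $|J|\,\text{miss}/p$. Validation data are
always generated fully observed.

What the generator emulates: realistic mixtures of correlated continuous and
binary predictors, effect sizes from weak to strong, outcome-dependent MAR
missingness concentrated on a subset of variables. What it does not emulate:
nonlinear effects, interactions, measurement error, missingness in the
outcome, or not-at-random mechanisms — so passing tests demonstrate correct
behavior of the machinery under MAR with linear effects, not robustness
beyond it.

## Chained-equations imputation

`impute_chained()` initializes missing entries by random draws from the
observed values of their column, then performs 5 sweeps (default), visiting
incomplete variables in order of increasing missingness (stabilizes the
early sweeps), regressing each on all other covariates **plus the outcome**.
Continuous variables use predictive mean matching with 5 donors (default):
a Bayesian-perturbed linear fit ($\sigma^2$ from the scaled inverse
chi-square, $\beta^\ast \sim N(\hat\beta, \sigma^2 (X^\top X)^{-1})$),
predictions for observed cases from $\hat\beta$ and for missing cases from
$\beta^\ast$, and each missing entry copies the observed value of one of the
5 nearest-prediction donors — imputed values are always observed donor
values. Binary variables use logistic draws with coefficients perturbed by
the normal approximation to their posterior; separation falls back to a
ridge-stabilized fit (logged), a one-class observed target imputes the
constant class. Cycle and donor counts are conventional chained-equations
defaults and exposed as arguments. Observed cells are never modified — the
suite checks this bit-exactly — and each completion consumes its own child
seed, so runs are reproducible.

## Evaluation and internal validation

`evaluate_external()` scores a pooled model on freshly generated, fully
observed validation data (default $n = 5000$, one fresh set per replicate to
avoid coupling across replicates): AUC with the Mann–Whitney tie convention
(ties count 1/2), Brier score, and counts of selected true/noise covariates.
`events_per_variable()` uses the smaller outcome class over $p + 1$
estimated parameters (intercept included). `summarize_scenario()` reports
per-variant means, empirical SDs and normal-approximation CI half-widths
$1.96\,\mathrm{SD}/\sqrt{\text{reps}}$.

`optimism_correct()` implements the enhanced bootstrap for a *complete*
MI pipeline: resample subjects with replacement from the incomplete data,
re-impute, re-select, evaluate the bootstrap model on its own bootstrap
imputations (apparent) and on the original imputations (test), and subtract
the mean apparent-minus-test difference from the apparent performance.
Metrics are averaged over imputations first, then over bootstrap samples;
the original imputations are the fixed test bed for every bootstrap model.
Bootstrap-level pipeline failures are skipped and reported via the effective
$B$. Per-imputation (not stacked) evaluation of the bootstrap model was
chosen as the reading most consistent with averaging "across bootstrap
samples and imputed datasets".

## Numerical choices and degenerate inputs

* Solver tolerance `1e-10` (coordinate descent), IRLS tolerance `1e-10` on
  the maximum coefficient change; predicted probabilities clipped at
  `1e-15` inside deviances.
* Deviance ties on the penalty grid break toward the larger penalty.
* Separation: backward elimination and unpenalized refits raise a typed
  condition (`mivarsel_convergence_error`) that scenario drivers catch,
  count and exclude; imputation sub-models fall back to ridge-stabilized
  fits instead, since an imputation must always be produced.
* Empty selections yield intercept-only models (logged), degenerate
  (constant) scores make score recalibration a warning no-op.
* All stochastic stages consume `child_seed(master, stage, ...)`, making
  full scenario runs bit-reproducible and order-independent.

## Scale of the shipped checks

The test suite and `scripts/acceptance.R` run the scenario machinery at
reduced replication counts chosen so the whole suite completes in minutes:
the headline method comparison (mechanism one, $n=200$, 50% per-variable
missingness, $m=10$) uses 100 replicates with a validation size of 5000; the
selection-ordering checks (mechanism one, $n=600$, 10% missingness) use 100
replicates with $m=3$ and $B=10$ — $m=3$ is adequate at 4% overall
missingness by the one-imputation-per-percent rule of thumb, and $B=10$
(30 fits per frequency estimate) is the smallest bootstrap count that keeps
the 50% inclusion threshold meaningful. Monte-Carlo error at these scales is
visible in the second decimal of AUC/Brier means; conclusions that depend on
differences near 0.001 are at the edge of what 100 replicates can resolve.

## Known limitations

* Only binary outcomes and logistic models; no survival or linear analogues.
* No grouped-lasso-across-completions or elastic-net variants of MI
  selection; no Rubin-variance Wald backward elimination.
* Imputation models are main-effects linear/logistic only (no polytomous
  models, no passive imputation).
* The double bootstrap needed to internally validate the
  inclusion-frequency methods themselves is out of scope.
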