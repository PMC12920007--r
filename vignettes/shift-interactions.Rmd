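---
title: "Shift-based interaction analysis for exposure mixtures: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shift-based interaction analysis for exposure mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixshift)
```

# The model and the target parameter

`mixshift` analyzes observational triples $O = (W, A, Y)$: a vector of
confounders $W$ (which may include exposures not under direct study),
continuous exposures $A = (A_1, \dots, A_p)$, and a continuous or binary
outcome $Y$, assumed i.i.d. from an unknown distribution with exposure
density $g_0(a \mid w)$ and outcome regression
$\bar Q_0(a, w) = E[Y \mid A = a, W = w]$.

A *stochastic shift intervention* moves every subject's exposure by a fixed
amount: the post-intervention exposure is $A + \delta$, equivalently the
exposure density becomes $g_\delta(a \mid w) = g_0(a - \delta \mid w)$. The
shifted mean outcome is

$$E_\delta[Y] = \int \bar Q_0(a, w)\, g_0(a - \delta \mid w)\, p_0(w)\, da\, dw
= E[\bar Q_0(A + \delta, W)].$$

The **sign convention** deserves one sentence because it is easy to get
wrong: with $g_\delta(a \mid w) = g_0(a - \delta \mid w)$, the density ratio
entering the estimator is evaluated at the *observed* exposures,
$H_\delta(A, W) = g_0(A - \delta \mid W) / g_0(A \mid W)$, while the outcome
regression substitution is evaluated at the *post-intervention* exposures
$A + \delta$. This is the only pairing under which
$\int \bar Q(a, w) g_0(a - \delta \mid w)\, da = E[\bar Q(A + \delta, W)]$
by change of variables, and the package verifies it empirically against
Monte-Carlo truth in its test suite. A downward regulatory shift
("subtract one unit") is requested as $\delta = -1$.

For two exposures the **interaction parameter** is the departure of the
joint shift from additivity of the marginals:

$$\Psi_{int} = E_{\delta_i, \delta_j}[Y] - E_{\delta_i}[Y] -
E_{\delta_j}[Y] + E[Y],$$

positive for synergy, negative for antagonism. A three-way analogue is
available as the third-order finite difference over the eight shift
configurations (`gcomp_threeway()`); it is provided as a g-computation
contrast only, without targeted inference, because the number of shifted
means and the attendant positivity risk grow quickly with the interaction
order. The printed three-way display one sometimes sees with all
lower-order terms inside a single subtraction is sign-ambiguous; the
finite-difference form used here is the one annihilated by purely additive
and purely pairwise response surfaces, which is the property that makes
the parameter interpretable.

# Estimation

## Efficient influence function and TMLE

The EIF of the single-shift mean is

$$D_\delta(O) = H_\delta(A, W)\,\{Y - \bar Q(A, W)\} +
\bar Q(A + \delta, W) - E_\delta[Y].$$

`tmle_shift_mean()` updates an initial $\bar Q$ along a one-dimensional
submodel with covariate $H_\delta$ — by default a logistic fluctuation on
the outcome rescaled to $[0, 1]$ with $H$ entered as a covariate (offset
$\mathrm{logit}\,\bar Q$, no intercept), optionally a linear fluctuation
$\bar Q^* = \bar Q + \epsilon H$. The maximum-likelihood $\epsilon$ sets
the empirical mean of the first EIF component to zero exactly (the score
equation), so the estimate $\hat\psi = n^{-1}\sum_i \bar Q^*(A_i + \delta,
W_i)$ has $|\,\overline{D}\,| \le 10^{-6}$ on the rescaled outcome after a
single step. The standard error is $\sqrt{\widehat{\mathrm{Var}}(D)/n}$;
intervals are Wald at level $1 - \alpha$ (default 95%).

## Two routes to the interaction

* **Delta method** (`interaction_delta_method()`): the four component means
  (joint, two marginals, baseline) are targeted separately and combined
  linearly; the variance uses the combined influence function
  $D = D_\delta - D_{\delta_i} - D_{\delta_j} + D_0$ with
  $D_{0,i} = Y_i - \bar y$, which accounts for all component covariances.
* **Direct targeting** (`tmle_interaction_direct()`): one fluctuation with
  the combined covariate $H^* = H_\delta - H_{\delta_i} - H_{\delta_j} + 1$,
  after which the updated regression is evaluated at the four exposure
  configurations and averaged. The baseline contributes the constant $+1$
  in $H^*$ and the $(Y - \bar Q^*)$ term in the EIF; its plug-in uses
  $\bar Q^*$ at the observed exposures so that the empirical EIF mean
  equals the fluctuation score exactly (and is therefore zero).

The two routes agree within estimation error; the delta method is the
default because the marginal-shift estimates are themselves reportable.
With all shifts zero both return exactly zero.

## Nuisance estimation

Both nuisances are fit by **discrete cross-validated selection** over a
learner roster (`cv_select_learner()`): the member with the smallest V-fold
cross-validated squared-error loss (log loss for binary targets) is refit
on the full training data. The default roster is intercept-only, a
main-terms GLM, a random forest (`ranger`) and gradient boosting
(`xgboost`); a lightweight roster substitutes a second-order GLM
(`glm_twoway`: main terms everywhere, squares and pairwise products of the
*exposure* columns only, linear in confounders) for the tree ensembles.
Restricting the second-order expansion to exposures keeps the parameter
count manageable on small training folds while retaining exactly the terms
that g-computation pair ranking needs; a roster whose selected member
cannot express exposure products will correctly rank every pair at zero
and discover nothing, which on a small fold is a statement about the data,
not an error.

The density ratio $H_\delta$ is estimated two ways (`fit_ratio()`):

* **Classification-based** (default): each observation is duplicated, one
  copy labelled $\xi = 0$ with its observed exposures and one labelled
  $\xi = 1$ with exposures $A + \delta$; a probabilistic classifier for
  $P(\xi = 1 \mid A, W)$ is fit on the $2n$ rows, and with balanced classes
  the odds $p/(1-p)$ estimate the ratio directly. Joint shifts use a
  single classifier on the jointly shifted copies, respecting exposure
  dependence.
* **Direct conditional density**: a homoscedastic location model per
  targeted exposure — regress $A_k$ on $W$, place a Gaussian kernel
  density with Silverman bandwidth on the residuals, and evaluate
  $\hat g(a - \delta \mid w) / \hat g(a \mid w)$; per-exposure ratios
  multiply for joint shifts.

Classifier probabilities are bounded at $(10^{-6}, 1 - 10^{-6})$ before
forming odds; ratios are truncated to $[10^{-6}, \lambda]$ with ceiling
$\lambda = 50$ by default. No symmetric lower bound is imposed: ratios
below one reflect movement into denser regions of the exposure
distribution and pose no positivity risk.

## Positivity and adaptive shifts

If the requested $\delta$ pushes exposures outside their support, the
ratio blows up. `adapt_delta()` multiplies $|\delta|$ by 0.9 on a grid —
refitting the ratio model each step — until the maximum pre-truncation
ratio over the training fold falls below $\lambda$, failing with a
positivity error below 1% of the requested magnitude. The grid factor and
floor are pragmatic defaults for a procedure whose only requirements are
monotone descent and a finite stopping rule.

# Discovery–estimation with cross-validation

Because "the top synergistic pair" is defined by the data, using the same
rows to find it and to test it yields anti-conservative inference.
`run_discovery_estimation()` therefore splits the sample into $K$ folds
(validation sizes differing by at most one) and, per fold:

1. fits $\bar Q$ on the training rows;
2. ranks all $p(p-1)/2$ pairs by the g-computation contrast
   $\frac1n\sum \bar Q(A + \delta_{ij}) - \bar Q(A + \delta_i) -
   \bar Q(A + \delta_j) + \bar Q(A)$, ties broken lexicographically; a
   pair enters the synergy set only with a positive value (beyond a
   scale-aware numerical zero, $10^{-8}\,\mathrm{sd}(Y)$, so float residue
   from an additive fit never qualifies) and the antagonism set only with
   a negative one; optionally, single exposures are ranked the same way by
   their marginal shift contrast;
3. adapts $\delta$ on the training rows and fits the three ratio models;
4. estimates baseline, marginals, joint and interaction by TMLE on the
   validation rows with the training-fold nuisances (CV-TMLE).

**Pooling is by rank, not pair identity**: the rank-1 discovery may be a
different pair in different folds, so pooled rows are labelled by rank
with per-fold pair names recorded (`Var 1: A1/A2`-style labels), and the
consistency table (`rank_consistency()`) reports how often each pair was
discovered, flagging pairs present in more than half the folds as robust.
The pooled estimate is a *single* targeting step over the stacked
validation rows — each row carrying its own fold's nuisance predictions
and clever covariates, mapped to a common outcome scaling — followed by
the stacked plug-in mean, with the SE from the stacked EIF over all $n$.
A single global fluctuation (rather than reusing fold-specific
$\epsilon$s) was chosen because it reduces to standard CV-TMLE and solves
one score equation for the pooled parameter. The pooled row reports the
average adapted shift $\bar\delta = K^{-1}\sum_k \delta_k$.

Result tables serialize marginal and joint rows as *changes versus the
baseline mean outcome* (with the EIF of the difference for the SE), which
is how applied shift analyses are usually read; the interaction row is the
targeted contrast itself. Folds that discover no pair of the required sign
or fail positivity are reported in the result's `failures` list, never
silently dropped.

# The synthetic-data framework

`simulate_dataset()` draws from a six-exposure mechanism with four
exchangeably correlated Gaussian confounders ($\rho = 0.3$, from the
moderate 0.2–0.4 band) and outcome

$$Y = 1 + 0.3 W_1 + 0.2 W_2 + 0.3 A_1 + 0.2 A_2 - 0.3 A_3 +
\beta_s A_1 A_2 + \beta_a A_5 A_6 + 0.2 A_4^2 + \varepsilon,
\quad \varepsilon \sim N(0, 1),$$

with synergy strength $\beta_s \in \{0.25, 0.40, 0.60\}$ and antagonism
$\beta_a \in \{-0.20, -0.45, -0.70\}$ in the usual grids. Exposure
families emulate common environmental-exposure shapes and are confounded
by $W$: $A_1, A_2 \sim$ Gamma(2, $e^{0.2 W_1}$) and Gamma(2, $e^{0.2
W_2}$) (right-skewed), $A_3 \sim 4\,\mathrm{Beta}(2,2) + 0.1 W_3$
(bounded), $A_4, A_5 \sim N(2 + 0.2 W_3, 1)$ and $A_6 \sim N(2 + 0.2 W_4,
1)$ truncated to $[0, 6]$. The exact family parameters and the
$A$-given-$W$ links are this package's documented defaults (the general
shapes, not these constants, are what the families are meant to emulate);
all are overridable through `sim_scenario()`.

For shifts of $+0.5$ on $A_1$ and $A_2$ the truth is available in closed
form, $\Psi_{int} = \beta_s \delta_1 \delta_2$, because $Y$ is linear in
$A_1 A_2$ and every other term cancels in the double difference;
`true_interaction()` returns both this value and a large-sample
Monte-Carlo evaluation from the same mechanism (fresh outcome noise per
shifted regime), and the two are required to agree within Monte-Carlo
error. `run_replicates()` repeats the full two-stage pipeline over seeded
replicates and reports mean absolute bias, MSE (computed so that
$\mathrm{MSE} = \mathrm{bias}^2 + \mathrm{Var}$ holds exactly, i.e. with
the population-variance convention), 95% CI coverage, the discovery rate
of $(A_1, A_2)$, and scaled bias $|\mathrm{bias}|\sqrt n$. A replicate
counts as a discovery when $(A_1, A_2)$ is the rank-1 synergy pair in a
strict majority of folds.

**What the generator does not emulate**: measurement error, missing data
(rejected at validation by design — the estimator's semantics assume
complete cases), heavy-tailed or multimodal exposures, exposure-dependent
outcome noise, and non-smooth response surfaces. Passing tests on this
mechanism show the estimator's internal consistency and its behaviour
under realistic confounding and skew, not performance under those harder
features.

A second generator, `make_niehs_like_fixture()`, emulates the *layout* of
a well-known mixtures benchmark — seven lognormal-ish exposures in two
correlated clusters, a binary confounder, null-but-correlated members, and
supra-additive / antagonistic pairs involving a common partner — with
invented coefficients, for integration tests of the discovery engine. Its
constants are labelled synthetic throughout; they are not any external
dataset's key.

# Problem sizes and numerical choices

Desk-scale defaults used by the simulation harness and the acceptance
script: $K = 2$ folds (maximizing per-fold sample for both stages), the
lightweight roster for both nuisances, classifier-based ratios, the
delta-method route, 25–50 replicates per scenario at $n \in \{500, 1000,
2000\}$. One replicate at $n = 1000$ costs roughly half a second on one
CPU; the full acceptance run is a few minutes. With replicates in the tens,
binomial error on coverage and discovery rates is a few percentage points.

Numerical conventions collected in one place: outcomes are rescaled to
$[0, 1]$ for the logistic fluctuation using $(\min Y - m, \max Y + m)$
with $m = 0.1\,\mathrm{range}(Y)$ (exactly $(0, 1)$ for binary outcomes);
unit-scale regression predictions are bounded to $(10^{-4}, 1 - 10^{-4})$,
while natural-scale predictions used by g-computation are left unbounded
(so additive fits cancel exactly); fluctuations with $|\epsilon| > 10$ are
flagged as non-converged; a degenerate (all-zero) combined covariate skips
targeting with $\epsilon = 0$; the positivity ceiling is $\lambda = 50$
with ratio floor $10^{-6}$; fold assignment, learner selection and all
generators are driven by one master seed fanned out through a deterministic
counter scheme recorded in the run manifest.

# Known limitations

* The direct conditional-density method assumes a homoscedastic location
  model per exposure; strongly heteroscedastic or multimodal conditional
  laws need the classifier route (the default).
* Kernel-density ratio estimates at points far from the residual bulk
  carry visible Monte-Carlo noise even at $n = 5000$; the classifier route
  is smoother there.
* Only additive shifts are supported; multiplicative or covariate-dependent
  shift maps would require Jacobian corrections not implemented here.
* The three-way parameter has no targeted (TMLE) counterpart in this
  package.
* Pooling by rank answers "what is the effect of the rank-1 discovery",
  which is the honest data-adaptive target but mixes pair identities when
  folds disagree; the consistency table should always be read alongside
  the pooled row, and `pool_by = "pair"` realigns by the modal pair when
  identity matters more than rank.
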