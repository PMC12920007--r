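# mixshift

Semiparametric discovery and estimation of **interaction between continuous
exposures** in a mixture, defined through **stochastic shift interventions**
and estimated by **targeted maximum likelihood (TMLE)** with
efficient-influence-function inference.

## The problem

Environmental-health studies routinely measure many correlated chemical
exposures together with confounders and a health outcome. The policy
question is rarely "what if exposure were set to zero" but "what happens if
we *shift* exposures — and is reducing two exposures together worth more
(or less) than the sum of reducing each alone?" Product terms in a linear
model answer a different, model-dependent question; `mixshift` targets the
additive-scale causal contrast directly, without parametric assumptions on
the exposure–outcome surface.

## The parameter

For an observation \(O = (W, A, Y)\) — confounders, exposures, outcome —
and a shift \(\delta\), the shifted exposure density is
\(g_\delta(a \mid w) = g_0(a - \delta \mid w)\) (each subject's exposure
moves by \(\delta\)). Writing \(E_\delta[Y]\) for the mean outcome under a
shift, the two-way interaction parameter for exposures \(A_i, A_j\) is

\[
\Psi_{int} \;=\; E_{\delta_i,\delta_j}[Y]
\;-\; E_{\delta_i}[Y] \;-\; E_{\delta_j}[Y] \;+\; E[Y] ,
\]

the departure of the joint shift from additivity of the marginal shifts:
positive = synergy (super-additive), negative = antagonism. Estimation
uses the efficient influence function of the shifted mean,

\[
D_\delta(O) = H_\delta(A, W)\,\{Y - \bar Q(A, W)\}
+ \bar Q(A + \delta, W) - E_\delta[Y],
\qquad
H_\delta(A, W) = \frac{g_0(A - \delta \mid W)}{g_0(A \mid W)},
\]

with a one-dimensional fluctuation of the outcome regression \(\bar Q\)
along the clever covariate \(H_\delta\) (TMLE), so that the empirical EIF
mean is zero and Wald confidence intervals follow from its variance.
Both estimation routes are implemented: combining four separately targeted
means (delta method) and a single-pass TMLE with the combined covariate
\(H^* = H_{\delta} - H_{\delta_i} - H_{\delta_j} + 1\).

Because "the most synergistic pair" is a data-adaptive target, the package
separates **discovery** from **estimation** with K-fold cross-validation:
pairs are ranked by a fast g-computation contrast on each training fold,
the top-ranked pairs are estimated by TMLE on the held-out validation fold,
and fold estimates are pooled by rank through one targeting step over the
stacked validation predictions, paired with the average (positivity-adapted)
shift \(\bar\delta\).

## Worked example

A built-in synthetic benchmark with seven correlated exposures, a binary
confounder, and known structure (A1, A2, A7 positive effects;
A4, A5 negative; A3, A6 null; supra-additive A1×A7 and A2×A7; antagonistic
A5×A7):

```r
library(mixshift)
dat <- make_niehs_like_fixture(seed = 42, n = 1000)
cfg <- shift_config(K = 3, delta = 1, seed = 1,
                    q_roster = c("mean", "glm", "glm_twoway"),
                    g_roster = c("mean", "glm", "glm_twoway"))
res <- run_discovery_estimation(dat, cfg)
res
#> discovery_result: n = 1000, K = 3, approach = delta
#>   pooled rank-1 synergy interaction: interaction (delta) A1 & A7:
#>   psi = 0.1093 (SE 0.2652), 95% CI [-0.4104, 0.6291], p = 0.68

subset(res$table, fold == "Pooled" & block == "synergy")
#>    condition   psi    se  ci_lo ci_hi  p_value             delta
#>    Var 1: A1 0.859 0.208  0.452 1.265 3.50e-05          0.397065
#>    Var 2: A7 0.852 0.242  0.378 1.327 4.32e-04          0.397065
#>        Joint 1.820 0.262  1.307 2.334 3.57e-12          0.397065
#>  Interaction 0.109 0.265 -0.410 0.629 6.80e-01 0.397065,0.397065

res$consistency$synergy
#>   exposure_i exposure_j frequency mean_rank robust
#> 1         A1         A7         3         1   TRUE
```

Reading the output: the requested shift of 1 unit was adaptively shrunk to
0.397 so the density ratio stays below the positivity ceiling
(\(\lambda = 50\)); the pooled marginal rows say a 0.4-unit increase in A1
(A7) raises the mean outcome by 0.86 (0.85) over baseline, the joint shift
by 1.82, and the interaction row estimates the super-additive excess
(0.11, CI covering zero at this shift size). The consistency table shows
(A1, A7) was the rank-1 synergy pair in all three folds — a robust
discovery.

A shell entry point wraps the same functions:

```sh
inst/exec/mixshift analyze  --data exposures.csv --config config.yaml --out-dir out
inst/exec/mixshift simulate --config sim.yaml --out-dir out
```

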