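---
title: "Modelling barriers to healthcare with a selection multinomial probit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling barriers to healthcare with a selection multinomial probit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selmnp)
```

## The problem

Population surveys ask two questions about access to healthcare: *did you
experience a need for medical care in the past year?* and, for those who
report having gone without needed care, *what was the main reason?*  The
analysis problem has a selection structure: whether needs were met -- and
which barrier prevented it -- is only observed among people who experienced
needs at all.  Modelling the barrier outcome on the "needs" subsample alone
risks sample-selection bias whenever unobserved drivers of *having* needs
also drive *how they end*.

`selmnp` implements the joint model: a two-equation system estimated by
maximum simulated likelihood on longitudinal survey data, with survey weights
and individual-level clustering.

## The model

**Selection (needs) equation.**  For person-year \(i\),
\[
y_{1i} = \mathbf 1\{\, x_{1i}'\beta_1 + \varepsilon_{1i} > 0 \,\},\qquad
\varepsilon_{1i}\sim N(0,1).
\]

**Outcome (barrier) equation.**  Conditional on \(y_{1i}=1\), four latent
utilities
\[
y^*_{2ij} = x_{2i}'\beta_{2j} + \varepsilon_{2ij}, \qquad j = 1,\dots,4,
\]
with the observed category \(y_{2i} = \arg\max_j y^*_{2ij}\): met needs
(reference, \(\beta_{21}\equiv 0\)), financial difficulty, time constraint,
lack of caring and support.  The multinomial *probit* form avoids the
independence-of-irrelevant-alternatives restriction a logit would impose.

**Error structure.**  \((\varepsilon_{1i}, \varepsilon_{2i1},\dots,
\varepsilon_{2i4})\) is multivariate normal; utilities are differenced
against the reference, \(u_j = \varepsilon_{2ij} - \varepsilon_{2i1}\)
(j = 2, 3, 4), giving a 3-dimensional outcome-error vector with covariance
\(\Omega\) and cross-equation correlations
\(\rho_j = \mathrm{Corr}(\varepsilon_1, u_j)\).  Nonzero \(\rho\) is exactly
what makes joint estimation necessary.

Two normalisations make the system identified:

* **Scale.**  \(\Omega_{11} = 2\), the value implied by iid standard-normal
  alternative-level errors.  The default "iid mode" fixes all of
  \(\Omega = I_3 + \mathbf 1\mathbf 1'\) and estimates only
  \(\rho_2,\rho_3,\rho_4\); an "unrestricted" mode frees the remaining
  Cholesky entries of \(\Omega\).  Without alternative-specific regressors
  the MNP covariance is weakly identified, which is why iid mode is the
  default rather than an option of last resort.
* **Exclusion restrictions.**  The default specification excludes alcohol
  consumption from the selection equation and exercise and obesity from the
  outcome equation, and uses gender-specific age-squared terms in the
  selection equation but main age-squared plus gender interactions in the
  outcome equation.

## Simulation of the likelihood

Each observation's likelihood contribution is a rectangle probability of a
3- or 4-dimensional normal: \(\Phi(-x_1'\beta_1)\) for non-needs rows, and
\(P(\varepsilon_1 > -x_1'\beta_1,\; M_j u + c_j > 0)\) otherwise, where
\(M_j u + c_j > 0\) is the linear-inequality form of the argmax condition
(`alternative_region()`).  These probabilities have no closed form; the
package evaluates them with the Geweke--Hajivassiliou--Keane (GHK) recursive
importance sampler (`ghk_mvn_rectangle()`):

* **Halton draws** (prime bases 2, 3, 5, 7) with **antithetic pairing**;
  the default is 200 draws per observation.  Low-discrepancy draws cut the
  simulation variance well below pseudo-random sampling at the same cost.
* **Per-observation random shifts**: every observation works with its own
  modulo-1 shift of the Halton set, drawn deterministically from the seed.
  A single shared draw set would leave the simulation error correlated
  across observations, so it would not average out as the sample grows --
  empirically this visibly distorted the recovered correlations at panel
  scale.  The shifts are keyed on (cluster, row content) rather than row
  position, which makes the likelihood exactly invariant under splitting a
  row's weight across identical copies.
* **Common random numbers**: the same draw sets are reused for every
  parameter evaluation, making the simulated likelihood a smooth,
  deterministic function of the parameters -- a requirement for quasi-Newton
  optimisation and for bit-reproducibility given a seed.
* The selection error is ordered last in the GHK recursion, where no draw is
  needed, so a 4-dimensional joint probability costs three truncated-normal
  draws per point.

A deterministic tensor-quadrature integrator over the same
separation-of-variables transform (`mvn_rectangle_quadrature()`) serves as an
independent reference: at 500 draws the GHK estimates agree with it to a few
parts in \(10^{-5}\) on random 4-dimensional rectangles, comfortably inside
the 0.005 working tolerance the test suite enforces.

## Estimation

`fit_selmnp()` maximises the weighted log-likelihood
\(\sum_i w_i \log p_i\) in three stages:

1. **Pilots.**  A weighted probit (`glm`) for the selection equation; an
   independent multinomial probit for the outcome equation (MSL with
   \(\rho = 0\)), warm-started from a multinomial logit scaled by
   \(\sqrt{2/(\pi^2/3)}\), the ratio of differenced-error standard
   deviations.  At \(\rho = 0\) the joint likelihood factorises, so the
   pilots already sit at the factorised optimum.
2. **Correlation pre-stage.**  The three correlations are optimised alone --
   after the pilots, most of the remaining likelihood improvement lives
   there.
3. **Full BFGS** over all coefficients and correlations, with parameters
   standardised by the dispersion of their design columns (`parscale`);
   age-squared columns have dispersions three orders of magnitude larger
   than dummies, and without this scaling the quasi-Newton steps crawl.
   Iterations run in cycles of 20 with an absolute stopping rule
   (`abstol`, default 0.05 log-points per cycle): improvements below that
   sit in the GHK simulation noise and carry no information about the
   estimates, and chasing them wastes minutes of flat-tail iterations.
   Internally the optimiser works on the weight-sum-normalised objective,
   which is exactly invariant under reweighting transformations that
   duplicate rows.

Two estimation caveats that the package surfaces rather than hides.  First,
when almost everyone experiences needs, the selection correlations are
weakly identified: their profile likelihood can be flat over wide ranges,
and the unconstrained maximiser may settle anywhere along that ridge.  For
checks that rely on the factorisation of the likelihood at zero correlation,
`fit_selmnp(fix_rho = c(0, 0, 0))` holds the correlations fixed, which turns
the joint fit into the exact product of the two pilot models -- the shipped
factorisation test uses this constrained form precisely because the
unconstrained optimum on a flat ridge is not a well-defined comparison
point.  Second, a rare covariate whose carriers all land in one outcome
group (quasi-separation) produces a vanishing score column; the BHHH matrix
is then singular and the fit warns and falls back to a pseudo-inverse
instead of failing.

Gradients are finite differences taken in the *reduced index space*: the
log-probability of an observation depends on the parameters only through the
four scalars \(x_1'\beta_1, \eta_2, \eta_3, \eta_4\), so bumping those
four indices and chaining through the covariate rows reproduces the full
gradient at a handful of likelihood passes instead of two per coefficient
(forward differences inside the optimiser, central differences for the final
per-observation score matrix feeding the sandwich).

Correlations are parameterised as \(\rho_j = \tanh(\zeta_j)\) so the
optimiser is unconstrained; parameter vectors implying a joint error
covariance within 0.005 of singularity are rejected with a penalty, which
keeps the GHK recursion away from degenerate Cholesky factors.

**Inference.**  The data are pooled person-years; observations within a
person are dependent.  The variance is the cluster-robust sandwich
\(A^{-1} B A^{-1}\) (`sandwich_vcov()`), with \(B\) built from
within-individual sums of weighted scores and \(A\) the BHHH (outer-product)
approximation to the negative Hessian by default -- the standard choice for
simulated likelihoods, where a finite-difference Hessian would cost
\(O(p)\) extra gradient passes (available via `hessian = "numeric"`).
Weights are normalised to mean 1 (estimates are invariant; log-likelihood
magnitudes become comparable across datasets).  P-values are two-sided
normal, appropriate at panel-survey sample sizes.  BIC uses the number of
observations by default (`bic_n = "individuals"` switches to persons).

**Reporting scale.**  Age coefficients are estimated in raw (centred) years
and only *displayed* multiplied by 10 (linear, interactions) or 1000
(quadratics), so printed magnitudes are readable; internally nothing is
rescaled.

## Diagnostics

* `compute_vif()` -- variance inflation factors per design column; age
  centring (the default is the unweighted sample mean) exists precisely to
  keep the polynomial and interaction terms from inflating these.
* `hl_first_equation()` -- Hosmer--Lemeshow calibration test of the
  selection equation, applied to an *unweighted* probit refit: the grouped
  chi-square reference distribution is not valid under survey weighting, so
  the test is run on the unweighted fit as a specification check.
* `information_criteria()` -- AIC/BIC for comparing candidate term lists;
  the package deliberately offers no automatic variable selection.

## Average adjusted probabilities

`average_adjusted_probability()` answers the substantive question -- how do
needs and barriers move over the life cycle?  For each grid point (gender,
age in 20--90 by 5, matching the span of adult ages the survey covers), it
overwrites every observation's gender and age *and every term derived from
them* (centred age, quadratics, interactions -- the only internally coherent
choice), keeps all other covariates at observed values, and averages the
predicted probabilities with the survey weights.  Joint probabilities
\(P(y_1 = 1, y_2 = j)\) are the default (they add up to the unmet total by
construction); conditional-on-needs probabilities are behind
`type = "conditional"`.  Confidence intervals use the delta method with the
same reduced-index Jacobian; a parametric bootstrap would also work but is
an order of magnitude more expensive for no practical gain at these sample
sizes.

## The synthetic panel generator

Real national health-panel microdata are access-restricted, so the package
carries a generator (`simulate_panel()`) whose *defaults are the study
conditions*: five annual waves; permanent attrition of 2% per wave (wave-5
retention \(0.98^4 \approx 0.922\)); covariate marginals equal to the pooled
descriptive statistics of the emulated survey (e.g. 46.2% men, age
\(N(52.75, 17.67^2)\) truncated to 19--95, 3.3% public-assistance
beneficiaries); outcomes generated from the latent model above with the
published coefficient estimates (display scaling undone) as the truth; and
log-normal weights (sdlog 0.3, mean normalised to 1).  Where the emulated
survey reports no value, defaults were chosen once on plausibility grounds:
cross-equation correlations of 0.3 (unknowable from published estimates;
clearly labelled and configurable), a 5% per-wave marginal-preserving
redraw for time-varying covariates, and independent baseline covariates
(only marginals are published; a correlation hook is the natural extension).

What the generator does **not** emulate: cross-covariate dependence,
informative (outcome-correlated) attrition, the two-stage cluster sampling
behind the weights, and item nonresponse.  Passing tests therefore
demonstrate the *estimator's* correctness under the stated conditions, not
robustness of substantive conclusions to those real-data features.

A note on levels: with the published coefficients as truth, the simulated
needs share comes out near 0.99 rather than the survey's 0.967, because the
published estimates were produced under a different (unpublished) error
normalisation and with correlated covariates.  The generator's job is
parameter recovery -- the truth is known exactly and the estimator must find
it -- not reproduction of published prevalences, which would require the
restricted microdata.

## Numerical choices, sizes and limitations

* GHK: 200 draws per observation for estimation, 500 where a single
  probability is checked against a reference; antithetic Halton, first 10
  points skipped.
* Finite-difference step \(10^{-4}\) (central) in index space; BFGS
  relative tolerance \(10^{-8}\), iteration cap 200.
* Problem sizes in the shipped tests: parameter recovery uses 2,000
  individuals over 5 waves (the scale at which the full specification is
  comfortably identified); the factorisation check uses 1,000; unit tests
  use a 4-term specification at a few hundred individuals.  A full coverage
  study (hundreds of replications) is an overnight exercise left to the
  user; single-fit recovery plus the factorisation, symmetry and oracle
  checks are what ships.
* Ties in the argmax are measure-zero and broken towards the lower index;
  degenerate designs (constant columns, exact collinearity) and empty
  outcome groups raise errors rather than silently proceeding.
* Known limitations: no random effects (the model is pooled with clustered
  variance, which is what the weighted panel analysis calls for); no
  design-based variance beyond weights + clustering; no analytic GHK
  gradient (finite differences in index space are cheap enough at these
  scales); the unrestricted-\(\Omega\) mode is provided but weakly
  identified without alternative-specific regressors.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(n_individuals = 500, n_waves = 3, seed = 1)
panel <- simulate_panel(cfg)
coded <- derive_outcomes(panel)
design <- build_design(coded$data, default_model_spec(cfg$age_center))
fit <- fit_selmnp(design, n_draws = 200, seed = 2)
summary(fit)
aap <- average_adjusted_probability(fit, coded$data)
plot_aap(aap, "barriers")
```

The same flow is available as one call through `run_pipeline()` with a YAML
configuration, or from a shell via `inst/scripts/selmnp-cli.R`.
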