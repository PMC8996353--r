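---
title: "Models and methods for multi-scanner test-retest reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for multi-scanner test-retest reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retest)
```

# The measurement problem

A task measure — a voxel's contrast value, a region's extracted activity,
a behavioral psychometric parameter — is useful for individual-differences
research only insofar as it ranks the same people the same way when the
measurement is repeated. `retest` quantifies this with intraclass
correlation coefficients (ICCs): the share of total measurement variance
attributable to stable between-subject differences. The package targets
the design in which such reliability is typically estimated: up to three
sessions per participant, weeks apart, on two scanners of the same build
visited in alternating order (ABA or BAB, balanced across participants),
with measurements at many exchangeable spatial units (voxels or atlas
regions) and two in-scanner face-emotion tasks providing behavioral
metrics.

Two formulations are implemented throughout:

* **Absolute agreement, ICC(2,1)** — scanner is a random effect;
  systematic scanner differences count against reliability:
  $\mathrm{ICC}(2,1) = \sigma^2_p / (\sigma^2_p + \sigma^2_s + \sigma^2_e)$.
* **Consistency, ICC(3,1)** — scanner, visit and task order are fixed
  effects; only the stability of subject rankings matters:
  $\mathrm{ICC}(3,1) = \sigma^2_p / (\sigma^2_p + \sigma^2_e)$.

# Per-unit estimation: regularized mixed models

For each unit, `fit_icc()` fits the Gaussian linear mixed model

$$y_{ij} = \mathbf{x}_{ij}^\top\beta + u_{j} (+ s_{\mathrm{scanner}(ij)}) + \varepsilon_{ij}$$

with subjects $j$, sessions $i$, fixed effects $\beta$ for scanner (in the
consistency formulation), visit (as an unordered factor, so no linearity
in time is imposed) and task order, and a Gamma(shape = 2, rate = 0.5)
prior on each random-effect *standard deviation*. The prior's density
vanishes at zero and has its mode at SD = 2, so variance components are
regularized away from the boundary: the resulting ICC is always inside
$[0,1]$, degenerate zero-variance fits are avoided, and unbalanced or
missing-session data pose no problem — the three properties that motivate
the Bayesian treatment over the classical ANOVA estimator, which can go
negative on noise. The prior target (SD rather than variance) is a
modeling choice exposed through `icc_model_spec()`; `prior_shape = NA`
gives the flat-prior limit in which the estimator reduces to REML.

Two estimators are available:

* `estimator = "map"` (default): maximizes the marginal posterior with
  the fixed effects integrated out (a REML-type objective plus the
  log-prior), by Nelder-Mead on the log-SD scale from two starting points,
  with the marginal covariance handled by dense Cholesky factorization
  (at most a few hundred observations per unit). On balanced data in the
  flat-prior limit this reproduces the Shrout-Fleiss ANOVA ICC to about
  $10^{-3}$, which the test suite uses as an oracle-equivalence check.
* `estimator = "mcmc"`: a Gibbs sampler (below) yields the posterior
  mean, SE and 2.5/97.5% quantiles of the ICC. In a 200-replicate
  simulation at 40 subjects x 3 sessions with true consistency ICC 0.6,
  the posterior mean is essentially unbiased and the 95% quantile
  interval covers the truth 95% of the time.

Degenerate inputs (all values equal) return ICC 0 with a `"degenerate"`
status rather than failing; `icc_by_unit()` isolates per-unit failures in
a `status` column so one pathological voxel never aborts a whole-brain
run. A rank-deficient fixed design (e.g. every participant on the same
scanner order, so scanner is aliased with visit) raises an
identifiability error naming the aliased columns.

# The integrative Bayesian multilevel model

Fitting units independently ignores that they are draws from a common
population of regions. `fit_bml()` places all regions in one hierarchical
model,

$$y_{ijk} = a_0 + a_1\,\mathrm{scanner} + a_2\,\mathrm{order}
 + \xi_{0i} + \xi_{1i}\,\mathrm{scanner} + \xi_{2i}\,\mathrm{order}
 + \eta_j + \gamma_{ij}
 + \zeta_{0k} + \zeta_{1k}\,\mathrm{scanner} + \zeta_{2k}\,\mathrm{order}
 + \mu_{0ik} + \nu_{0jk} + \varepsilon_{ijk},$$

with sessions $i$, subjects $j$, regions $k$; every family is iid
Gaussian with its own scale, covariates are coded as centered $\pm 1/2$
contrasts so $a_0$ is the grand mean, and scales carry weakly-informative
half-Student-t(3, 0, 2.5 sd(y)) priors. Covariate slopes are modeled for
the session and region families and assumed independent of the
intercepts within each family (whether the original formulation
correlated them is unstated; independence is the parsimonious reading).
Session effects are random here — exchangeable draws — even though the
unit-wise models treat visit as fixed; the two conventions serve the two
different estimands and are kept deliberately.

The pooled model "globally calibrates" the per-region ICCs: extreme
independent estimates are shrunk toward the population center, so the
across-region dispersion of BML ICCs is at most that of the independent
per-unit fits (`compare_shrinkage()` quantifies this; with overall
modest reliability the pooled estimates sit systematically below the
unit-wise ones).

## Region-specific ICC from the posterior

The region ICC needs region-$k$-specific variance contributions from the
interaction families, but a homoscedastic family has a single scale that
cannot vary with $k$. The package therefore computes, per posterior draw,
the *empirical variance of the realized effects at region* $k$
($\mu_{0\cdot k}$ across sessions, $\nu_{0\cdot k}$ across subjects,
sample variance with denominator $n-1$), and combines them with the
global scale draws. Two readings are provided (`bml_icc(formula = ...)`):

* `subject_attributable` (default) counts subject-linked variance only:
  $$\mathrm{ICC}_k = \frac{\sigma^2_\eta + \sigma^2_{\nu_0 k}}
  {\sigma^2_\eta + \sigma^2_{\nu_0 k} + \sigma^2_{\xi_0} +
   \sigma^2_\gamma + \sigma^2_{\mu_0 k} + \sigma^2_\varepsilon}.$$
* `as_printed` follows the published expression literally: it adds the
  region-intercept variance $\sigma^2_{\zeta_0}$ (a between-region, not
  between-subject, term) to the numerator and denominator and counts
  $\sigma^2_{\nu_0 k}$ a second time in the denominator. Because a
  single scalar per region has no empirical variance, $\sigma^2_{\zeta_0}$
  is taken from the family scale draw. The expression is most plausibly a
  typographical slip, which is why it is not the default, but both
  readings are computed rather than guessing a single intent.

Draws are summarized by mean, SE and the 2.5/97.5% quantiles, then binned
with `bin_icc()`.

## Sampling and diagnostics

The posterior is sampled with a purpose-built Gibbs sampler
(`gibbs_lmm()`): Gaussian full conditionals for every effect family and
the fixed coefficients, univariate slice sampling for each scale (which
accommodates the Gamma and half-t priors uniformly). Crossed designs
make naive single-site Gibbs mix slowly along the non-identified
location directions (the intercept trades off against every family
mean), so the sampler interleaves *sweep* moves: exact Gibbs updates of
the shared location between a family and the population intercept, and
between each interaction family and its parent main-effect family. These
are reparameterized Gibbs steps, so the stationary distribution is
untouched; on the package's reference simulation they reduce the worst
split-$\hat R$ from about 2.2 to about 1.1. The sampler was validated
against an independent JAGS implementation of the same random-intercept
model (posterior means of all scales agree to well under 5%); that
cross-check is part of the test suite.

`bml_diagnostics()` reports split-$\hat R$, bulk ESS (sum of per-chain
effective sample sizes) and a tail ESS (effective size of the 5%/95%
exceedance indicators) for every population effect and scale; any scale
with $\hat R > 1.05$ attaches a convergence warning to the fit. Scales of
three-level families (the session family and its covariate slopes) are
intrinsically hard to identify — three Gaussian draws say little about
their SD — so their posteriors lean on the prior and their $\hat R$
converges slowest; the region-relevant scales ($\eta, \gamma, \mu_0,
\nu_0, \varepsilon$) are well behaved at the default settings.

# Behavioral psychometrics

The two in-scanner tasks yield per-session scalars whose reliability is
assessed with the same unit-wise machinery (each metric playing the role
of a unit, with participant random effect and scanner/visit/order fixed
effects):

* **Face-emotion labeling**: a four-parameter logistic
  $P(\mathrm{angry} \mid m) = l + (u-l)/(1+\exp(s(m - x_0)))$ is fitted
  to the 15-step angry-to-happy morph continuum. The free asymptotes
  absorb lapse behavior ("adjusted for the maximum probability of either
  judgment"); the inflection $x_0$ is the bias index — 8 is unbiased,
  lower values indicate a hostile interpretation bias. The default
  objective is bounded least squares on the per-morph response
  proportions (nine multi-starts over slope x inflection,
  Levenberg-Marquardt within box bounds $l,u \in [0,1]$,
  $s \in (0, 20]$, $x_0 \in [1, 15]$); a trial-level binomial likelihood
  is exposed as an option since the original objective is unstated — on
  clean data the two land within a tenth of a morph step. The morph axis
  is the integer index 1-15 (consistent with "an inflection point of 8"),
  not a rescaled intensity. Mean RT per morph is regressed jointly on
  centered linear $(m-8)$ and quadratic $(m-8)^2$ regressors — raw, not
  orthogonal, polynomials, stated explicitly because the coefficients
  differ under orthogonal coding. A negative quadratic means slower
  responses to ambiguous mid-continuum faces.
* **Visual search**: from correct trials only, the faces-vs-scramble mean
  RT difference and, per cue condition, the OLS slope of mean RT on
  $\ln(\text{set size})$ over set sizes {1, 5, 30}, plus their average.

Quality control excludes a session when accuracy is below 70% or more
than 15% of trials received no response — strict inequalities, so a
session at exactly the printed thresholds is retained. Accuracy is the
proportion correct among *responded* trials and the nonresponse rate is
over all non-fixation trials (the denominators are not printed in the
source description; this reading keeps the two rules independent). For
the labeling task, accuracy is evaluated only at the overt endpoints
(morphs 1 and 15), the only trials with a defined correct answer.

# What the generator simulates — and what it does not

`simulate_design()` and `simulate_unit_data()` reproduce the crossed
structure the estimators assume: balanced pseudo-randomized ABA/BAB
scanner orders, task order counterbalanced across participants and
constant within participant, optional session dropout that never leaves
a subject with fewer than two sessions, and Gaussian draws for every
variance component of the multilevel decomposition (participant,
session, unit, their pairwise interactions, residual, optionally a
random scanner intercept — the latter mirroring the ICC(2,1)
formulation, while the fixed scanner offset mirrors ICC(3,1)). The
defaults (`generator_params()`) place per-unit consistency ICCs in the
fair-to-good range with between-unit spread via the participant-by-unit
component, spanning the conventional bins (0.4/0.6/0.75); the study the
design emulates does not report its empirical component magnitudes, so
these are chosen as field-plausible rather than matched. Session spacing
(2-6 weeks) is design metadata only: the models contain no time-decay
term, so none is simulated. Trial-level generators reproduce the printed
session designs exactly: 27 instances of each of the 9 emotion x set-size
cells (243 search trials), 30 presentations of each of 15 morphs plus 90
fixation trials (540 labeling trials).

Passing recovery tests on these simulations shows the estimators invert
the generative model they assume; it does not certify behavior under
features real fMRI data adds — spatial correlation between units,
heavy-tailed or artifact-contaminated measurements, session-varying
scanner hardware states, or practice effects beyond a visit shift.

# Numerical choices and conventions

* Reliability bins: poor $[0, 0.4)$, fair $[0.4, 0.6)$, good
  $[0.6, 0.75]$, excellent $(0.75, 1]$. Boundary membership is unstated
  in the source convention except that excellent is strictly above 0.75;
  lower-closed intervals are used and recorded here.
* Conjunction maps use a strict `icc > threshold` rule (default 0.4), so
  a unit at exactly the threshold is not "reliable".
* tSNR = mean(signal) / sd(residuals) with the sample ($n-1$) SD; the
  denominator convention is unstated in the source and recorded here.
* The task-order factor is an opaque two-level label (`first`/`second`);
  how the original coded order when both tasks are analyzed is unstated.
* MAP optimizer: Nelder-Mead, relative tolerance $10^{-10}$, two starts
  (sd(y)/2 and an asymmetric start); non-convergence is reported in the
  fit status, and the best objective value is kept.
* Gibbs sampler: slice sampling with stepping-out (width 1 on the log-SD
  scale, 30 steps max); scales are floored at $10^{-10}$ so degenerate
  (constant) data concentrates cleanly at zero rather than overflowing;
  per-unit seeds in `icc_by_unit()` are derived deterministically from
  the master seed, so results are reproducible and independent of unit
  order or parallel scheduling.
* Reference problem sizes used by the test suite, chosen to exercise the
  estimators at study-like scale while keeping the default check run
  fast: oracle equivalence at 60 subjects x 3 sessions; posterior
  calibration over 200 replicates of 40 subjects x 3 sessions; BML
  recovery at 20 subjects x 3 sessions x 30 regions with 2 chains x 750
  kept draws.

# Limitations

* Regions are exchangeable labels: no spatial adjacency, smoothing or
  cluster inference (by design — the pooled model replaces multiplicity
  correction).
* The BML omits covariate slopes on the two interaction families
  (session x region, subject x region); the region ICC uses only the
  intercept families either way.
* All random effects are Gaussian; no heavy-tailed option.
* MCMC memory grows with draws x (subjects x regions) because realized
  subject-by-region effects must be retained for region-specific ICCs;
  at 40 subjects x 214 regions keep the draw count moderate or thin
  chains.
* The MAP estimator reports a point ICC only; interval-bearing output
  requires `estimator = "mcmc"`.
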