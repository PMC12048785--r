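---
title: "MaxDiff estimation and segmentation: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MaxDiff estimation and segmentation: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxdiffseg)
```

# The measurement problem

Best-worst scaling (MaxDiff) measures the relative importance of K items
by showing respondents repeated small subsets (here a = 4 of K = 16
gamification elements such as goals, progress, badges, narrative) and
asking for the most and least preferred item in each subset. Because every
answer is a forced trade-off, the data are free of the scale-use biases
that plague ratings, and they identify a ratio-interpretable importance
scale.

This package implements the full analysis chain around that instrument:
design generation, choice-data validation, pooled and heterogeneous
utility estimation, latent-class segmentation with the model-selection
metric suite, segment profiling, and segment-membership prediction — plus
a synthetic respondent generator so that the whole chain can be validated
by parameter recovery when raw study data are not available.

# The choice model

Every task contributes two *exploded* observations. With item utilities
$u \in \mathbb{R}^K$ and shown set $S$:

$$P(\text{best} = c \mid S) = \frac{e^{u_c}}{\sum_{j \in S} e^{u_j}},
\qquad
P(\text{worst} = c \mid S) = \frac{e^{-u_c}}{\sum_{j \in S} e^{-u_j}}.$$

The worst pick is a multinomial choice over **all** a shown items under
negated utilities (not the a − 1 items left after the best pick). This
convention is what makes the chance baseline per task equal
$2\ln(1/a)$, and it is the convention under which the package's
model-fit metrics reproduce published metric tables exactly (see below).

Utilities are identified by the sum-to-zero (effects-coding) constraint,
giving K − 1 free parameters per utility vector. The pooled
log-likelihood is concave; `fit_aggregate()` maximizes it by damped
Newton iteration in the identified basis, stopping at gradient norm
below 1e-8 or relative log-likelihood change below 1e-10. Standard errors
come from the observed information. Complete separation (an item chosen
always or never whenever shown) is detected up front and met with a small
ridge (default 1e-6) and a warning.

## Rescaled scores

Logit utilities are hard to communicate; score tables report a positive
transform normalized to sum to 100. The default "probability" method uses

$$q_i = \frac{e^{u_i}}{e^{u_i} + a - 1}, \qquad
\text{score}_i = 100 \cdot \frac{q_i}{\sum_j q_j},$$

the probability that item i beats a − 1 "average" items in a task. A
plain softmax method is also available. Both transforms are strictly
increasing in $u_i$, so rankings never depend on the method, and both are
exactly invertible (`invert_rescaled()`; the probability method pins the
free scale of q by root-finding on the sum-to-zero constraint). The
inversion is what lets published score tables act as simulation inputs.

# Latent-class segmentation

`fit_latent_class()` fits a finite mixture of exploded-logit models over
respondents: class shares $\pi_c$ on the simplex and one utility vector
per class. Estimation is EM:

* E-step: posterior membership from per-respondent class log-likelihoods;
* M-step: one weighted Newton refit per class (warm-started, so the
  refit is cheap) and $\pi_c$ set to mean posterior.

The M-step refits to convergence, so the EM log-likelihood is
non-decreasing, which the tests assert. Initialization is by random
posterior draws from a symmetric Dirichlet(1); by default 20 restarts are
run briefly (40 iterations) and the best is polished to tolerance 1e-8
with a 500-iteration cap. Classes are reported in order of decreasing
share; the share ordering, not any semantic label, is the algorithm's
output — segment names ("goal-preferred", "reward-motivated") are an
analyst's reading of the utility profiles. A class whose share collapses
below 1e-6 is kept, flagged with a warning, rather than silently dropped.

## Model-selection metrics

For C classes the parameter count is $k = C(K-1) + (C-1)$ and the
effective sample size is the number of exploded choices
$N = R \cdot T \cdot 2$. With $LL_0 = -N\ln a$ the chance-model
baseline, `fit_metrics()` reports

* percentage certainty $100\,(1 - LL/LL_0)$ (a pseudo-R²),
* AIC $-2LL + 2k$, BIC $-2LL + k\ln N$, CAIC $-2LL + k(\ln N + 1)$,
* sample-size adjusted BIC $-2LL + k\ln\!\big((N+2)/24\big)$,
* likelihood-ratio chi-square $2(LL - LL_0)$ and its ratio to k.

These exact definitions — in particular N counting exploded choices and
the $(N+2)/24$ adjustment — were fixed so that the suite reproduces
published metric tables for this study design (378 respondents, 12 tasks,
4 shown of 16 items, C = 2..5) to print precision from the printed
log-likelihoods alone; the acceptance tests pin all 64 values. The
package reports the metrics and the modal segment sizes for a scan over
C (`model_scan()`) but deliberately does not auto-select C: in practice
that choice weighs metric minima, the size of successive drops, and the
balance of segment sizes.

# Hierarchical Bayes estimation

`fit_hb()` estimates respondent-level utilities under a two-level model:
$\theta_r \sim N(\alpha, \Sigma)$ in the K − 1 identified basis, with the
exploded-logit likelihood below. The Gibbs sampler uses:

* random-walk Metropolis for each $\theta_r$ (all respondents proposed
  and evaluated in one vectorized pass), step sizes auto-tuned during
  burn-in toward acceptance 0.23–0.44;
* the conjugate normal update for $\alpha$ (flat prior);
* the conjugate inverse-Wishart update for $\Sigma$ (weak prior:
  df = K + 1, identity scale);
* two extra moves that repair the notoriously slow mixing of location
  and scale in such hierarchies: a joint translation of $\alpha$ and all
  $\theta_r$ judged by the pooled likelihood, and a joint rescaling of
  all deviations together with $\Sigma$ (the population-prior quadratic
  forms cancel, leaving the pooled likelihood change, the
  inverse-Wishart density ratio and the Jacobian).

Chains start at the pooled maximum-likelihood utilities. Point estimates
are posterior means of post-burn-in draws; each respondent's estimate
sums to zero by construction. Convergence is monitored by split-chain
scale reduction on $\alpha$ with a warning above 1.1.

Two behaviours of this model are worth knowing. First, with only
12 tasks (24 exploded choices) per respondent, individual utilities are
weakly identified, and the posterior for $\Sigma$ does not collapse to
zero even when the data are generated with no heterogeneity: the sampler
was validated to recover near-zero $\Sigma$ once respondents answer
enough tasks (e.g. 48), and to recover $\Sigma \approx \sigma^2 I$ when
data are generated with $\sigma = 0.5$. Second, averaging
individual-level utilities spreads extreme items slightly more than the
pooled fit does (a Jensen effect); the same pattern is visible in
published tables whose pooled-logit and HB columns differ most at the
extremes. Tests therefore check the pooled-vs-HB equivalence at a
data-rich design and treat the study-scale comparison as a closeness
check (within 1.5 score points, near-identical rankings).

# Design generation

`generate_design()` builds questionnaire versions in the spirit of a
balanced incomplete block design. Within a version, each item's
appearance count is fixed to $\lfloor Ta/K \rfloor$ or
$\lceil Ta/K \rceil$ (exactly $Ta/K$ when K divides Ta, as in the
16/4/12 reference layout, where every item appears exactly 3 times per
version). Tasks are filled greedily: a forcing rule places any item whose
remaining quota equals the number of remaining tasks (which provably
keeps the quotas satisfiable), and remaining slots go to the items with
the fewest co-occurrences with the task so far — version-level counts
weighted above design-level counts — with seeded random tie-breaks.
Display positions are randomized. The audit (`design_diagnostics()`)
reports one-way, pairwise and positional counts and checks two merit
flags: exact one-way balance and a pairwise max/min ratio below a
threshold (default 2). Positional balance is audited but not enforced.
The mean pairwise co-occurrence always equals
$V \cdot T \binom{a}{2} / \binom{K}{2}$, which the tests verify by brute
force. The sample-size rule of thumb — enough respondents that every item
is seen several hundred times — is exposed as a diagnostic
(`item_appearances()`), not a hard constraint: 200 respondents on the
reference design see every item exactly 600 times.

# The synthetic population generator

`simulate_population()` draws the data-generating process the analysis
chain assumes: class membership from fixed shares, individual utilities
$\beta_r = u_{class} + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 I)$
re-centered to sum to zero, versions assigned round-robin, and
class-conditional covariates (normal per class for 7-point scale scores,
categorical with per-class probabilities). The defaults mirror the
reference study conditions: 378 respondents, 16 items, 4 per task,
12 tasks, within-class heterogeneity $\sigma = 0.5$ chosen so that
pooled-logit and HB score columns sit close together, as they do in
published comparisons.

One subtlety is deliberate. Sampling the best pick from
$\text{softmax}(\beta)$ and the worst from $\text{softmax}(-\beta)$
independently can produce best = worst, which is not a valid response;
but redrawing the worst pick on collision distorts the worst margin and
measurably biases the estimator (at the study scale the bias reaches
about 2 standard errors on extreme items, enough to break recovery
checks). The generator instead draws the (best, worst) pair from the
maximum-entropy zero-diagonal coupling of the two softmax margins,
computed by Sinkhorn scaling. Such a coupling always exists here because
$p^{best}_i + p^{worst}_i \le 1$ reduces to
$(\sum_{j \ne i} e^{u_j})(\sum_{j \ne i} e^{-u_j}) \ge (a-1)^2$, which
holds by Cauchy–Schwarz for $a \ge 2$. Records are always valid
(best ≠ worst) and the exploded-logit estimator stays exactly unbiased,
because its score depends on the two margins only.

Two scenarios ship with the package (`builtin_scenarios()`): a
three-segment gamification-preference population (shares
42.6/29.9/27.5%) and a four-segment motivation population (shares
20.9/33.9/16.9/28.3%), each with segment-level sum-to-100 score columns
inverted to utilities and covariate generators for the Hexad user-type
and gamification-drive scales. Covariate means and SDs per segment follow
the published segment comparisons; the age-group and exercise-interest
category splits are chosen to reproduce the reported qualitative
contrasts (e.g. the reward segments skewing older) since exact
cross-tabulations are not published. Scale scores are drawn as plain
normals — they are not truncated to the 1–7 range and item-level response
styles (straight-lining, inattention) are not modeled, so passing
recovery tests says nothing about such artifacts in real data.

# Segment profiling and membership prediction

Profiling compares covariates across modal segments:
`crosstab_test()` (Pearson chi-square, no continuity correction, with the
standard warning when over 20% of expected counts fall below 5) and
`manova_profile()` (one-way MANOVA; Wilks' lambda with Rao's F, per
covariate univariate F tests, and pairwise mean comparisons against a
reference segment from the pooled within-group variance). Wilks is the
default statistic because the workflow targets one-way designs; the
pairwise adjustment is Bonferroni by default and configurable to none,
since the adjustment behind published pairwise p-values in this domain is
typically unstated. With a single covariate the lambda reduces to
SSW/SST and the F equals the one-way ANOVA F, which the tests assert.

`fit_membership_model()` fits the multinomial logistic regression that
turns a fitted segmentation into a deployable classifier: a user-chosen
reference segment, user-specified predictors (no automated variable
search — published final models are the product of such a search, and
this package fits the supplied set), Wald tests from the observed
information, and odds ratios Exp(B) per coefficient. Numeric predictors
enter raw, so Exp(B) is the odds multiplier per scale point. Separation
is met by refitting with a small weight-decay ridge after a warning;
rank-deficient designs are rejected naming the collinear columns.
`predict_membership()` is the softmax over stored linear predictors with
the reference class pinned at zero, and works after a JSON round trip of
the fitted model.

# Numerical choices and degenerate inputs

* Newton steps are damped (step halving) and fall back to a tiny
  Levenberg ridge only on numerically singular information.
* EM tolerance is relative (1e-8 on the log-likelihood); restarts use a
  looser short-run tolerance before the winner is polished.
* Ties in modal assignment go to the lower class index; ranking ties
  share the smaller rank and skip the next (competition ranking).
* `invert_rescaled()` rejects zero scores (the transform is not
  invertible at 0) and non-sum-100 inputs.
* Empty response sets, items never shown, more classes than respondents,
  and empty contingency margins are all rejected with explicit messages.
* All randomness is seeded; a single pipeline seed is expanded into
  per-stage substreams (`run_maxdiff()`), so any stage re-runs stably in
  isolation.

# Problem sizes used in the test suite

Unit tests run on small designs (6 items, 3 per task) with 30–200
respondents; recovery checks run at the reference scale (378
respondents, 16 items, 300 design versions, $\sigma = 0.5$) with 10 EM
restarts; HB checks use shortened chains (hundreds of sweeps) except the
pooled-equivalence check, which uses 1000 + 1000 sweeps at a 150 × 48
design. These sizes keep the full suite under a couple of minutes while
leaving every scientific claim exercised by at least one test at the
scale where it is meaningful.

# Known limitations

* The rescaling transform behind published score tables is generally not
  stated in print; only the sum-to-100 property is checkable. The
  probability transform is the package default and the softmax is one
  flag away.
* HB priors and tuning schedules in commercial tools are proprietary;
  population-level agreement properties are the verifiable targets, not
  individual published HB columns.
* Latent-class EM finds local optima; restarts mitigate but do not
  guarantee the global one. The reported model is the best of the
  restarts.
* No covariate-conditioned class membership inside the mixture, no
  anchored MaxDiff, no adaptive designs, no D-optimal search, and no
  respondent-inattention simulation.
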