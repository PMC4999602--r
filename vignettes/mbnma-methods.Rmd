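---
title: "Dose-response network meta-analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response network meta-analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
the synthesis models, the priors and estimation protocol, what the
simulator does and does not emulate, and the places where the design was
genuinely open and a choice had to be made.

## The synthesis models

All models share a binomial likelihood with a logit link.  Arm $k$ of
study $i$ observes $r_{ik}$ responders among $n_{ik}$ patients, and

$$\mathrm{logit}(p_{ik}) = \begin{cases}\mu_i & k = 1\\
\mu_i + \delta_{ik} & k \ge 2.\end{cases}$$

The study baselines $\mu_i$ are *always* independent
$\mathrm{N}(0, 1000)$ nuisance parameters, never random effects: a
random-effects baseline couples arms across studies and can bias the
relative effects, defeating the point of concurrent control.  When the
placebo response is itself of interest (for prediction), a *separate*
random-effects model is fitted to the placebo arms alone
(`placebo_model()`); the two models share no parameters, so the
anchoring cannot feed back into the relative effects.

The families differ only in the mean model for $\delta_{ik}$:

* **Lumped / split NMA** — one basic parameter $d_t$ per non-reference
  node (agent, or agent-dose pair), mean
  $d_{t_{ik}} - d_{t_{i1}}$.  Every other contrast is a difference of
  basic parameters, which is what makes the estimates consistent.
* **Dose-response MBNMA** — the mean is
  $f(x_{ik}, t_{ik}) - f(x_{i1}, t_{i1})$ for a parametric $f$ on the
  log-odds scale, evaluated at the arm's standardized dose.  Placebo is
  a distinguished agent with $f \equiv 0$, the fixed zero of the scale.
* **Unrelated mean effects (UME)** — one free mean per treatment pair
  that is directly compared in at least one study (identified by the
  pairs actually observed; never-compared pairs get no parameter).
  No consistency, no dose-response; its only use is model criticism.

Under random effects, $\delta_{ik} \sim \mathrm{N}(\cdot, \sigma^2)$
with a single $\sigma$ common to all contrasts.  Heterogeneity variants
on the dose-response parameters themselves (rather than on the adjusted
outcome) are deliberately not offered: they are poorly identified and
interact badly with multi-arm trials.

### Multi-arm trials

The $a - 1$ relative effects of an $a$-arm trial are correlated
(covariance $\sigma^2/2$ under a common $\sigma$).  The samplers realize
this multivariate normal via sequential univariate conditionals: counting
arms $j = 2..a$, the $j$-th effect has conditional mean
$m_j + \tfrac{1}{j-1}\sum_{h<j}(\delta_h - m_h)$ and conditional
variance $\sigma^2 j / (2(j-1))$.  `dmultiarm_delta()` exposes the joint
density of this scheme; the test suite verifies it against a brute-force
multivariate-normal density to $10^{-8}$, and the same scheme is used
forward in the simulator, backward in the JAGS model code, and in
posterior-predictive simulation.

### Dose-response functions and class effects

The Emax model $f(x,t) = E_{\max,t}\, x / (ED_{50,t} + x)$ is the
physiologically motivated default: monotone, saturating at
$E_{\max,t}$, half-maximal at $ED_{50,t}$.  $ED_{50}$ is a dose, hence
positive, and is parameterized as $\log ED_{50}$ both in the sampler and
in the class-effect hierarchy; summaries back-transform draw-wise.
$E_{\max}$ is sign-unconstrained so harmful agents are representable.
The linear model (optionally with a per-agent intercept $b_t$) is also
shipped; the intercept belongs to active agents only, so the
with-intercept model is discontinuous as the dose of an active agent
approaches zero — interpretable as absorbing nonlinearity near zero
dose.  Whether $b_t$ should be shared across agents is not settled;
the package keeps it per-agent, the more flexible reading.

Class effects replace independent per-agent parameters with draws around
a common mean, e.g. $\log ED_{50,t} \sim \mathrm{N}(\mu_{ED50},
\sigma^2_{ED50})$, borrowing strength when each agent alone cannot
identify its curve.  Class means get the same vague
$\mathrm{N}(0,1000)$ prior as other effects (the natural extension;
nothing stronger is defensible without context), class SDs get
uniform(0, 4) — except the $E_{\max}$ class SD, which gets uniform(0, 20)
because log-odds maximum effects routinely exceed the range a (0, 4)
prior would softly cap when the parameter is weakly identified.

A user-supplied $f$ registers by name (`dose_response()` +
`register_dose_response()`) with an R evaluator (used for prediction and
simulation) and a JAGS expression (used in the model code); nothing else
in the pipeline changes.

## Estimation protocol

Gibbs sampling via JAGS.  Defaults follow the reference protocol: three
chains, 40,000 burn-in, 40,000 sampling iterations thinned by 10.  The
JAGS `glm` module is loaded when available — block updates of the
logistic likelihood roughly halve the split-$\widehat R$ of the Emax
model relative to one-at-a-time slice sampling — and up to 5,000 of the
burn-in iterations are used for sampler adaptation.  Chains start from
overdispersed draws in a moderate range around the prior centres
(e.g. N(0, 0.7) for dose-response parameters, so that $\exp(\log ED_{50})$
does not initialize astronomically), with all RNG seeds derived from one
master seed; identical seed and configuration reproduce the draws
exactly.

Convergence is monitored with the split-chain Gelman-Rubin statistic
(each chain halved, so trending chains are caught), floored at 1; the
automated warning threshold is 1.05, a conventional choice.  Chains that
are identical to one another return exactly 1 (there is no between-chain
evidence of non-convergence to report), and constant chains at different
values return `Inf`.

Summaries are medians and equal-tailed 95% credible intervals of the
pooled post-thinning draws, with transforms applied draw-wise.  A
reduced preset (3 chains, 2,000 + 2,000, thin 1) is provided for test
suites and simulation studies; the package's own long-running
experiments use 10,000 + 10,000 thinned by 2, the shortest configuration
whose split-$\widehat R$ on the Emax model is respectable.

## Model criticism

Residual deviance compares each arm's fitted probability with its
saturated value:
$2[r\log\frac{r}{n\hat p} + (n-r)\log\frac{n-r}{n-n\hat p}]$ with
$0\log 0 = 0$; a well-fitting model contributes about 1 per data point.
The DIC uses the *plug-in* effective parameter count
$p_D = \bar D - D(\bar p)$, with the plug-in point the posterior mean of
the fitted probabilities on the probability scale — sampler-reported
$p_D$ values are unreliable for these nonlinear models, and the
probability-scale mean pairs directly with the binomial deviance (the
linear-predictor-scale alternative differs only through Jensen gaps and
is not exposed).  A single-draw "posterior" yields $p_D = 0$ exactly;
negative $p_D$ triggers a warning rather than silent acceptance.  DIC
differences below 3 are flagged as not meaningful.

The inconsistency screen compares a consistency model against the UME
fit on the same split-coded data: paired per-point deviance
contributions (points fitting much worse under consistency localize the
problem) and the two $\sigma$ posteriors.  Genuine inconsistency
inflates the consistency model's $\sigma$ but not the UME's.  The bare
comparison of posterior medians is reported but is nearly a coin flip
under consistent data (both models estimate the same $\sigma$ from the
same data), so the calibrated flag requires
$\Pr(\sigma_{UME} < \sigma_{cons}) \ge 0.8$, computed by pairing the two
independent posteriors' draws.  The 0.8 threshold is a design choice:
high enough that the null rarely reaches it (the two estimates are
strongly positively correlated, so their standardized difference
concentrates near zero), low enough that a one-log-odds bias on a
well-populated edge usually separates the posteriors decisively.  In the
package's simulation experiments the flag never fires on consistent
networks (0 of 10) and fires on 7 of 10 networks with a one-log-odds
bias injected on the best-populated edge; the misses are realizations
where the three-arm trials spanning the same edge — which stay
consistent — leave the edge's direct evidence internally heterogeneous,
inflating both models' $\sigma$ and absorbing part of the signal.

The posterior-predictive check (`vpc()`) re-simulates every arm from the
fitted model — new study effects drawn through the multi-arm scheme,
then binomial noise — and tabulates observed proportions against 95%
predictive intervals, plot-ready against standardized dose.

## The simulator

`network_truth()` + `simulate_network()` generate networks the way the
fitted random-effects model assumes data arise: per study a baseline
from $\mathrm{N}(m, s^2)$, correlated study effects through the
sequential multi-arm scheme, binomial outcomes.  Default conditions:
40 studies, 4 active agents + placebo, Emax truth with maximum effects
(1.0, 1.5, 2.0, 2.5) log-odds and ED50 equal to the common dose,
$\sigma = 0.25$, baselines $\mathrm{N}(-1.5, 0.3^2)$, 200 subjects per
arm.  The layout is deterministic: 70% two-arm placebo-controlled trials
cycling over agent-dose combinations (doses 0.25–4 times the common
dose, agent varying fastest so small layouts stay balanced), 15%
three-arm trials (placebo + two agents), 15% head-to-head trials at the
common dose, with the first two agents compared most often — the
market-leader pattern seen in real analgesic networks, which also gives
the inconsistency experiments a well-populated active-active edge.
Each study draws from a sub-seed of the master seed, so
`inject_inconsistency()` can regenerate just the direct studies of one
edge (with a log-odds offset added to their effect means) while leaving
every other study byte-identical.

What the simulator does *not* emulate: unequal arm sizes, baseline
covariates or effect modifiers (the usual drivers of real-world
inconsistency), dropout, dose titration, continuous endpoints, and
reporting artifacts.  Tests passing on these networks therefore
demonstrate internal statistical correctness — the estimators recover
the generative process they assume — not robustness to the ways real
trial data violate that process.

## Numerical choices and degenerate inputs

* Fitted probabilities from the sampler are strictly inside (0, 1);
  deviance computation refuses exact 0/1 fitted values rather than
  clipping by statistically meaningful amounts.
* Reference-arm tie-break: arm 1 of a study is its placebo arm when
  present, otherwise the arm whose treatment comes first in the network
  ordering.  This is a convention (nothing in the model identifies it),
  but it must be deterministic since $\mu_i$ and every $\delta_{ik}$ are
  defined against it; it also guarantees ordered UME pairs.
* Dose standardization happens once, at load time; models never see raw
  doses.  Scaling an agent's raw doses and its common dose together
  leaves everything invariant.
* A split network can disconnect even when the agent-level network is
  connected; joint NMA fitting refuses disconnected coded networks
  (listing the components), while the dose-response families only
  require agent-level connectivity, since the dose-response function
  bridges doses of an agent.
* Prediction combines the relative-effect and placebo posteriors by
  resampling the shorter draw set with a fixed seed; "new trial" mode
  adds a drawn study effect, so its intervals are at least as wide as
  "typical trial" intervals everywhere.
* A single placebo arm cannot identify the placebo between-trial SD and
  is rejected, as are class effects with fewer than two active agents.

## Known limitations

The Emax model with vague priors is weakly identified when the trialed
dose range does not bracket the ED50 generously: the likelihood has a
ridge along "larger $E_{\max}$, larger $ED_{50}$, slope fixed", and the
$\mathrm{N}(0, 1000)$ prior on $\log ED_{50}$ places substantial mass
far up that ridge.  The package's recovery experiments (20 simulated
networks under the default conditions) put the frequentist coverage of
the equal-tailed 95% $E_{\max}$ intervals at 86–89% rather than the
nominal 95%: the missing intervals are those whose lower bound has
drifted above the generating value while the upper bound runs to the
prior's edge.  Exchangeable-ED50 fits shrink the agents toward a common
ED50 but the class mean rides the same ridge, so coverage is similar.
This mirrors the identification trouble reported for this model family
in practice; informative ED50 priors or richer dose ranges are the
remedies, and the un-pooled parameters should be read with their full
intervals, not their medians.  Node-splitting for localizing
inconsistency, meta-regression on trial covariates, continuous-outcome
likelihoods and time-course models are out of scope; the likelihood
layer is link-generic, so a normal-likelihood extension would slot into
the same machinery.
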