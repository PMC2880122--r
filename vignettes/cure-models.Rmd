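---
title: "Mixture cure regression and cure survival CART: models, algorithms, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixture cure regression and cure survival CART}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curecart)
```

## Why a cure model

In a randomized withdrawal trial, responders to open-label treatment are
randomized to continue drug or switch to placebo, and the endpoint is
relapse. Most subjects never relapse within follow-up — reported
relapse-free fractions in such trials run from roughly 60% to over 90% —
so the usual survival-analysis premise that every subject would eventually
fail under complete follow-up is untenable. A mixture cure model makes the
long-term survivors explicit: subject $i$ is *cured* with probability
$c_i$ and, if uncured, relapses according to an ordinary survival law.
Treatment effects then separate into an effect on *whether* a subject
relapses (cured incidence) and on *when* an uncured subject relapses
(latency), which are scientifically different questions.

## The semiparametric model and its EM

The cured incidence is logistic, $c_i = \mathrm{expit}(\alpha^\top X_i)$
with intercept in $X_i$; a **positive coefficient raises the cure
probability**. This orientation matters: with it, driving the intercept to
$-\infty$ (no cure) recovers standard Cox regression as a limiting case,
which the package exposes via `fix_alpha_intercept` and verifies in its
tests. Uncured latency is Cox proportional hazards,
$S_u(t\mid Z_i) = \exp\{-e^{\beta^\top Z_i}\Lambda_0(t)\}$, with
$\Lambda_0$ an unspecified step function.

Cure status is latent for censored subjects, so the observed-data
log-likelihood mixes the two classes in each censored contribution,
$\log\{c_i + (1-c_i)S_u(T_i)\}$. The EM alternates:

* **E-step** — posterior uncure weights
  $w_i = \Delta_i + (1-\Delta_i)\,(1-c_i)S_u(T_i)/\{c_i+(1-c_i)S_u(T_i)\}$,
  with the $0/0$ case ($c_i = 1$, $S_u = 0$) resolved to $w_i = 0$ by
  continuity.
* **M-step, incidence** — Newton–Raphson for the fractional-response
  logistic likelihood $\sum_i (1-w_i)\log c_i + w_i \log(1-c_i)$.
* **M-step, latency** — Newton–Raphson for the weighted Cox partial
  likelihood in which weights discount censored subjects' contributions to
  risk-set denominators (events always carry weight 1).
* **M-step, baseline** — weighted Breslow estimator, jump
  $d(t)/\sum_{T_j\ge t} w_j e^{\beta^\top Z_j}$ at each distinct event
  time. Ties are handled Breslow-style throughout, and an event is taken
  to precede a censoring at the same time.

**Monotonicity is enforced, not assumed.** Both Newton–Raphson M-steps
warm-start from the current coefficients, project candidate steps onto the
$|\cdot|\le 20$ box, and step-halve until the step does not decrease its
objective; a step that cannot improve inside the box is rejected. This
makes every M-step a generalized-EM step, so the observed-data
log-likelihood trace is nondecreasing by construction — a property the
test suite checks to slack $10^{-8}$ over simulated trials. The $|20|$ cap
(a linear predictor of $\pm 20$ is a probability within $2\cdot 10^{-9}$
of 0 or 1) replaces divergence under separation with a flagged boundary
solution, mirroring the standard-Cox-as-limit behavior.

**Zero-tail constraint.** By default $S_u(t) = 0$ beyond the largest event
time (the usual identifiability device for cure models: a censored subject
outliving every event is treated as cured). It is configurable
(`zero_tail = FALSE` gives the finite extension), and the reduction-to-Cox
check runs with it off, because under the constraint subjects censored
after the last event are excluded from risk sets no matter how small the
cure fraction is — the exact Cox limit holds only for the finite
extension.

**Starts.** The EM is known to be sensitive to starting values in this
model class. Start 0 pairs a plain logistic fit of $1-\Delta$ on $X$ with
a standard Cox fit on $Z$; one deterministic near-zero-cure start
($\alpha_0 = -6$) covers the boundary ridge where the model collapses to
standard Cox; remaining starts (default total: 20) perturb start 0
uniformly within $\pm 2$ naive standard errors. Each start's baseline is
initialized at the *fixed point* of the weight/Breslow recursion for that
start's coefficients — itself an EM over the baseline alone — so every
start begins at the profile likelihood of its coefficients rather than at
an arbitrary baseline. This mattered in practice: with a naive $w\equiv 1$
baseline, the EM's first E-step could jump into a different basin and miss
boundary modes that a dense grid search over the profile likelihood finds.
The converged solution with the highest likelihood is kept. Convergence
requires both $|\Delta l_f|/(|l_f|+1) < 10^{-7}$ and a maximum coefficient
change below $10^{-6}$, capped at 1000 iterations.

**Standard errors.** The observed information of the profile likelihood
(baseline re-profiled at every perturbed coefficient value, numerical
Hessian) or a nonparametric bootstrap (default 200 replicates, refitting
from the point estimate). The two agree to within ~25% on simulated data;
neither is claimed to reproduce any published table, since the estimator
behind published values is not stated there.

**AIC and subset search.** $\mathrm{AIC} = -2 l_f + 2k$ with $k$ counting
regression coefficients only, the baseline excluded. This convention was
fixed by verifying it reproduces published (log-likelihood, AIC) pairs for
logistic, Cox and cure fits exactly; a fifth published pair differs by
0.001, consistent with rounding of the printed log-likelihood. The
best-subset search enumerates assignments of candidates to the two
components; under the incidence-first guidelines the treatment indicator
is always in the incidence model, the latency set is capped (default 2),
and no covariate serves in both components. With guidelines off, each
covariate independently enters neither, either, or both.

**Population curves.** `predict_population_survival` averages
$c(x) + (1-c(x))S_u(t\mid z)$ over the empirical joint distribution of the
adjustment covariates, with displayed covariates fixed; under the
zero-tail constraint the curve levels off at the profile's average cure
probability.

## Parametric node models

Inside trees, semiparametric fits would be fitted thousands of times, so
nodes carry parametric mixture cure models: cure fraction $c_h$ and
Weibull latency $S(t) = \exp(-\mu_h t^{\rho_h})$, the exponential being
$\rho_h = 1$. (The Weibull parameterization was fixed as stated here;
optimization runs on $\mathrm{logit}(c)$, $\log\mu$, $\log\rho$ to keep it
unconstrained.) The EM updates $c_h$ in closed form (mean posterior cured
probability), profiles $\mu_h = D/\sum_i w_i T_i^{\rho_h}$ in closed form,
and maximizes the one-dimensional $\rho_h$ profile numerically; for the
Weibull a starting $\rho$ is chosen by running the EM from each point of
the log-spaced grid $\{0.25, 0.5, 1, 2, 4\}$ and keeping the best. Because
the EM crawls when $c_h$ approaches 0 or 1 (a regime tree children hit
routinely), a Nelder–Mead polish on the transformed parameters finishes
any fit that has not converged within its iteration budget; without this,
true-boundary splits were occasionally declared inadmissible for
non-convergence and cutpoints shifted by one covariate level. Survival and
density terms are floored at $10^{-300}$ before logs.

## The tree

* **Impurity.** Node deviance $R(h) = -2\,\mathrm{loglik}(h)/n$ uses the
  **root** sample size as divisor for every node. The alternative
  (node-local $n$) was considered and rejected: with a global divisor $R$
  is additive over any partition, split improvements
  $R(h) - R(l(h)) - R(r(h))$ are comparable anywhere in the tree, and the
  cost-complexity machinery applies unchanged.
* **Splitting.** Candidate cuts are midpoints of adjacent distinct
  observed values (a binary covariate yields its single 0/1 cut).
  Improvements are used raw — they are likelihood-ratio statistics, but no
  $\chi^2$ threshold is imposed; size constraints do the regularizing, and
  pruning plus cross-validation do the model selection. Ties break
  deterministically: first covariate in declared order, then smaller
  cutpoint. Growth is best-first (the largest admissible improvement
  anywhere in the tree is applied next), stopping at
  `max_terminal_nodes` (default 10), when no admissible split remains, or
  when no split improves. Children must have at least `min_node_size = 20`
  subjects and `min_events = 5` events — a 2–3-parameter cure model per
  node needs that much information — and a child fit that fails to
  converge makes its split inadmissible.
* **Pruning.** Weakest-link: repeatedly collapse the branch minimizing
  $g(h) = \{R(h) - \sum_{\text{leaves}} R\}/(\#\text{leaves} - 1)$, ties
  collapsed together. The resulting subtree sequence is nested, its
  thresholds strictly increase from 0, and the package's tests verify each
  member minimizes $\sum_{\text{leaves}} R + \gamma\,\#\text{leaves}$
  against exhaustive enumeration of all pruned subtrees.
* **Cross-validation.** Evaluation penalties are the geometric means
  $\sqrt{\gamma_k \gamma_{k+1}}$ of successive pruning thresholds — the
  standard choice of a representative penalty inside each interval — plus
  the last threshold itself so the root-only tree is also scored. Folds
  are stratified by event status; per fold, a tree is grown and pruned on
  the training data, test subjects are routed through the *training* tree,
  and their log-likelihood is evaluated at the *training* node estimates.
  A replication's deviance is $-2\times$ (summed held-out log-likelihood)
  $/\,n$; the reported SE is the standard deviation of replication means.
  Published analyses of this kind replicate 10-fold cross-validation 500
  times; the package default is 10 replications, with 500 available as an
  option. Selection offers the minimum rule and the 1-SE rule (smallest
  subtree within one SE of the minimum).

## The follow-up test

$q_n$ is the fraction of subjects with an uncensored time in
$(2t^* - t_{\max},\, t^*]$, $t^*$ the largest uncensored and $t_{\max}$
the largest observed time; the half-open interval convention makes
$q_n = 0$ whenever the last observation is an event. A long event-free
plateau widens the interval and raises $q_n$. Critical values are
simulated: B (default 1000) datasets of the observed size are drawn from
the supplied fitted parametric cure model with censoring resampled from
the reverse Kaplan–Meier estimate, and the level-$\ell$ critical point is
the $\ell$-quantile of the simulated statistics; follow-up is judged
sufficient when the observed $q_n$ reaches it. Note the logic: the
parametric latency has unbounded support, so the simulated reference
describes data that *never* level off harder than the fitted tail; an
observed $q_n$ in its upper tail is evidence that events genuinely stopped
short of the end of follow-up. Consequently the verdict is conservative
when the fitted family itself has a short tail, and the directional tests
use data whose event support ends well inside the follow-up window.

## The synthetic-data generator

`simulate_cure_dataset` draws covariates (Bernoulli, discrete-uniform,
normal), latent cure status from the logistic incidence, latent event
times from exponential, Weibull, or user-inverted proportional-hazards
latency, and censors at an administrative horizon with optional
exponential dropout; cured subjects appear censored at the censoring time.
`simulate_partitioned_dataset` is its region-wise counterpart for tree
validation. One integer seed drives a single generator stream, so fixtures
are bit-reproducible.

The `simulate_sertraline_like` preset emulates the structure of a 16-week
randomized withdrawal trial: $n = 235$, treatment Bernoulli(0.5), an
integer symptom score 0–20, gender Bernoulli(0.5), complication
Bernoulli(0.3), administrative censoring at 16 weeks, no dropout.
Incidence coefficients $(1.6, 1.2, -0.12)$ on (intercept, treatment,
score) and exponential latency $\mu = 0.04$ with coefficients
$(1.0, -0.9)$ on (gender, complication) were chosen once so that simulated
arm-level relapse rates land near the 8.5% / 19.5% reported for such
trials, with effect directions matching the published analyses.

What the generator does **not** emulate: correlated covariates,
informative or covariate-dependent censoring, measurement error in scores,
competing risks, or latency laws outside the proportional-hazards family.
Tests passing on these data therefore certify the algorithms — ascent,
oracle equivalence, recovery under the assumed model — not robustness to
real-data violations of the model.

## Problem sizes and numerical choices in the test suite

The suite exercises: EM ascent on 50 trials of $n = 235$; reduction to an
independently optimized Cox partial likelihood on 20 fixtures
(tolerance $10^{-3}$); grid-search oracles on $n \le 12$ toys
(gap $\le 10^{-4}$); recovery over 200 simulations at $n = 500$ under a
design with clearly sufficient follow-up (bounded latency covariate,
horizon far beyond the latency scale — under-follow-up designs confound
cure with slow latency and bias any cure model); planted-split recovery
over 100 seeds at $n = 1600$; root-only selection on homogeneous data over
50 seeds with 2 cross-validation replications; pruning oracles by
exhaustive enumeration; Weibull/exponential consistency to $10^{-6}$; and
$q_n$ directional verdicts over 50 seeds with $B = 200$. These sizes are
the package's chosen balance of statistical resolution against routine run
time.

## Known limitations

* No left truncation, interval censoring, time-varying covariates or
  effects, competing risks, or promotion-time cure models.
* Incidence/latency covariate sets must be chosen with care: with short
  follow-up the cure fraction and slow latency are weakly identified, and
  the zero-tail constraint resolves the ambiguity by fiat. Run the $q_n$
  test first.
* Tree node models carry no covariates; structure is expressed entirely
  through splits (a semiparametric-latency tree is out of scope).
* Standard errors ignore the uncertainty of model selection (subset search
  or tree selection).
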