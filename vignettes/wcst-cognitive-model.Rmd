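---
title: "A Bayesian cognitive-agent model of the Wisconsin Card Sorting Test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian cognitive-agent model of the Wisconsin Card Sorting Test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(wcstbayes)
library(dplyr)
```

## The task and the modelling problem

In the Wisconsin Card Sorting Test (WCST) a participant matches a stream of
target cards to one of four stimulus cards. Each card varies on three
feature dimensions — color, shape and number of objects — and exactly one
dimension, the hidden *sorting rule*, determines which match is correct.
The only information about the rule is the examiner's binary feedback, and
after ten consecutive correct responses the rule changes without warning.
Clinically the test is scored with summary counts: perseverative errors
(continuing to sort by a previously valid rule), other "casual" errors,
trials to complete the first category, and failures to maintain set.

`wcstbayes` models the participant as a Bayesian agent that maintains a
probability distribution over the three candidate rules and updates it by
Bayes' rule from the response–feedback pairs it observes. The package
provides (i) a generative simulator of full sessions, (ii) trial-by-trial
information-theoretic read-outs of the agent's belief dynamics, (iii) the
Heaton-style clinical scorer, and (iv) exact-likelihood Bayesian estimation
of the agent's two cognitive parameters from observed sessions, with the
standard simulation-based validation battery.

## The generative model

At trial $t$ the agent holds a predictive distribution $p(s_t \mid
x_{0:t-1})$ over rules $s_t \in \{\text{color}, \text{shape},
\text{number}\}$, samples an attended feature from it, and chooses the
stimulus card matching the target on that feature. After feedback $f_t$ the
agent computes the likelihood of the observation under each candidate rule.
With $m_i \in \{0,1\}$ the indicator that the chosen card matches the
target on dimension $i$,

$$
p(x_t \mid s_t = i) \;=\;
\frac{f_t\, m_i + (1-f_t)(1-m_i)}
     {f_t \sum_j m_j + (1-f_t)\sum_j (1-m_j)},
$$

and the posterior follows by Bayes' rule. Ambiguity is central: a chosen
card may match the target on several dimensions, in which case positive
feedback cannot single out the rule.

Belief propagation to the next trial goes through a row-stochastic
*stability matrix* $\Gamma(t)$ whose diagonal holds the per-rule
*activation levels* $\omega_t \in [0,1]^3$ — the agent's accumulated
evidence that each rule is currently in force — and whose off-diagonal
entries split the complement evenly:

$$
p(s_{t+1} = k \mid x_{0:t}) = \sum_i \Gamma_{ik}(t)\, p(s_t = i \mid x_{0:t}),
\qquad
\Gamma_{ii} = \omega^{(i)}_t,\;
\Gamma_{ij} = \tfrac12\bigl(1 - \omega^{(i)}_t\bigr).
$$

A highly activated rule is stable and keeps its posterior mass; a weakly
activated one leaks mass to its competitors. This leak is what produces
perseveration: when all activations are low after a rule change, mass
flows back towards the rule the posterior has just excluded.

### The activation update and its two parameters

Activations are driven by the match vector and the feedback through two
parameters on the unit interval:

* **Flexibility** $\lambda$ — how much activation a feature *disconfirmed*
  by the current feedback retains;
* **Information loss** $\delta$ — the exponent of the multiplicative
  rescaling $\omega^\delta$, which slows the climb of a confirmed feature's
  activation towards 1.

The default update (`semantics = "evidence"`) applies the two ingredients
of the activation equation to the features the feedback actually bears
evidence on:

| feedback | feature matched? | evidential status | update |
|---|---|---|---|
| 1 | yes | confirmed | $\omega \leftarrow \omega^{\delta}$ |
| 1 | no  | disconfirmed (rule must be among matches) | $\omega \leftarrow \lambda\,\omega^{\delta}$ |
| 0 | yes | disconfirmed | $\omega \leftarrow \lambda\,\omega^{\delta}$ |
| 0 | no  | no evidence | unchanged |

Under repeated disconfirmation an activation settles at the fixed point
$\lambda^{1/(1-\delta)}$ of $x \mapsto \lambda x^{\delta}$: a flexible
agent ($\lambda$ high) keeps competing rules available at high activation,
so after a rule change its beliefs shift cleanly to the remaining
candidates; an inflexible agent lets competitors decay to near zero, and
the resulting instability drains posterior mass back towards the old rule
for several trials — graded perseveration. A confirmed activation climbs
as $\omega_k = 0.5^{\delta^k}$, so $\delta$ sets how many confirmations
are needed before the internal model commits, which lengthens the first
category and, at high $\delta$, sustains a residual lapse rate.

A literal transcription of the compact activation equation
($\omega_t = f\,\omega^{\delta} m + \lambda[(1-f)\,\omega^{\delta}(1-m)]\,\omega$)
is available as `semantics = "compact"`, with both conventions for gating
the matching signal by feedback (`matching_signal = "feedback"` or
`"always"`). We do not use it as the default because, taken literally, a
single positive feedback zeroes every unmatched activation permanently
(the $0^\delta$ absorbing state), after which the transition matrix
actively *anti-predicts* newly confirmed rules; the simulated clinical
scores are then far from the reference factorial pattern and perseverative
errors *increase* with flexibility, contradicting the construct the
parameter is meant to encode. The evidence-gated reading keeps every term
of the equation and restores the intended monotonicities; the choice is a
genuine interpretive decision and both variants are exposed.

Two numerical guards apply under either semantics: activations are clamped
below at `activation_floor` ($10^{-6}$, configurable) because exactly zero
activations are absorbing, and above at $1 - 10^{-15}$ so the predictive
distribution never loses support entirely — the exact likelihood of any
action sequence therefore stays finite.

### Simulating

```{r simulate}
params <- agent_params(lambda = 0.3, delta = 0.4)
session <- run_agent(params, task_config(), seed = 101)
session
score_session(session)
```

## Information-theoretic trajectories

Three per-trial quantities, all in nats, summarise the agent's epistemic
dynamics: *Bayesian surprise* (the Kullback–Leibler divergence between the
updated and the held predictive distribution — how much the observation
moved the beliefs), *Shannon surprise* ($-\log$ of the predictive
probability of the observation — how unexpected it was), and *predictive
entropy* (the agent's uncertainty about the current rule, at most
$\ln 3 \approx 1.10$). They are deterministic functions of the observed
actions and feedback once the parameters are fixed, so they can be
reconstructed for any session, including an observed one at its posterior
mean:

```{r trajectories, fig.height = 5}
autoplot(reconstruct_trajectories(session))
```

Entropy collapses within a category as the agent commits and rebounds at
every rule change; with high information loss the collapse is incomplete
and errors arrive out of low-entropy states with large Shannon surprise.

## Clinical scoring

`score_session()` reports total, perseverative and other errors, trials to
first category (with a censoring flag when no category is completed),
failures to maintain set (an error directly after five or more consecutive
correct responses under the still-active rule), and completed categories.

The perseveration criterion is configurable. The default (`"principle"`)
counts every error whose chosen card is consistent with the perseverated-to
principle — the rule in force before the most recent change — mirroring the
definitional reading "an error that applies a previously valid rule".
`"unambiguous"` additionally requires the chosen card to match the target
on exactly one dimension, and `"sandwich"` extends it to ambiguous errors
flanked by unambiguous perseverative errors. Published Heaton-style scoring
sits between these operationalizations; the differences are small relative
to the across-agent spread at any fixed parameter value.

The factorial simulation reproduces the characteristic pattern of the
clinical scores (shown here at reduced cohort size; the package tests use
150–400 agents per cell):

```{r factorial}
scores <- run_factorial(n_agents = 20, seed = 1)
summarize_factorial(scores) |>
  filter(measure == "PE") |>
  tidyr::pivot_wider(names_from = lambda, values_from = c(mean, sd))
```

Perseverative errors fall with flexibility at every level of information
loss; failures to maintain set and trials to first category rise with
information loss at every flexibility.

## Estimating the cognitive parameters

Conditioned on the observed actions and feedback, the belief recursion is
deterministic, so the likelihood of a session is an exact product of
per-trial action probabilities
$q(a_t) = (1-\xi)\sum_i p(s_t = i \mid x_{0:t-1})\,
\mathbb{1}[\text{card}_i = a_t] + \xi/4$,
with $\xi$ a small lapse weight (default 0 for simulated data, 0.01 when
fitting observed data so that responses matching no feature keep positive
likelihood). `grid_posterior()` evaluates this likelihood on a grid over
$(\lambda, \delta) \in [0,1]^2$ (default $101 \times 101$; doubling the
resolution moves posterior means by well under 0.005) under the uniform
prior, normalises with log-sum-exp, and summarises the marginals.

```{r fit}
fit <- grid_posterior(session, param_grid(51, 51))
tidy(fit)
```

For observed data without rule annotations, `fit_observed()` first
reconstructs the rule sequence from the feedback stream under the known
protocol (rule order and run-length criterion), verifies consistency, then
fits and returns trajectories at the posterior mean.

### Validation: recovery, coverage, simulation-based calibration

`recovery_study()` draws parameters from the prior, simulates a session
each, fits the grid posterior, and reports per-parameter RMSE and $R^2$ of
the posterior means, the calibration error (mean absolute gap between
nominal and empirical coverage of central credible intervals over a
19-point grid of levels), and simulation-based calibration ranks (the rank
of the truth among posterior draws, jittered uniformly within grid cells;
a biased posterior shows a non-uniform rank histogram).

```{r recovery}
rec <- recovery_study(n_sets = 30, grid = param_grid(41, 41), seed = 5)
tidy(rec)
```

At the package's validation scale (300 sets, $101\times101$ grid, run in
the test suite and the acceptance script) the grid posterior is well
calibrated — calibration errors around 0.01, coverage within Monte Carlo
error of nominal, uniform SBC ranks. Point recovery is asymmetric:
information loss is recovered sharply (RMSE $\approx 0.09$, $R^2 \approx
0.91$) because it shapes convergence within every category, while
flexibility — whose behavioural signature is concentrated in the few
trials after each rule change — recovers more loosely (RMSE $\approx
0.15$, $R^2 \approx 0.75$). Recovery of $\delta$ degrades in the (0, 0.1)
range where different values produce nearly indistinguishable behaviour.

## What the synthetic data do and do not emulate

The simulator emulates the automated 128-trial Heaton protocol: rule
change after 10 consecutive correct responses, cyclic
color–shape–number rule order, targets drawn uniformly from the 60 cards
not identical to a stimulus card (a target identical to a stimulus card
would match it on all three dimensions and carry no information; the
64-card and fixed-list policies are available for sensitivity checks).
Simulated agents differ from human participants in known ways: no
fatigue or learning-to-learn across categories, no initial sorting
preference, a single lapse process rather than structured attention
failures, and a memoryless response rule. Passing the package's checks
therefore validates the computational machinery and the internal
consistency of estimation — not the claim that human data are generated by
this process.

## Numerical choices and limitations

* Logarithms are natural throughout; entropies plateau near
  $\ln 3 \approx 1.10$.
* Bayesian surprise is computed between the successive predictive
  distributions (the updated internal model against the one it replaces).
* Activation floor $10^{-6}$ and ceiling $1-10^{-15}$; results are
  insensitive to the floor over several orders of magnitude.
* Grid quantiles treat each node as a cell with uniform mass (piecewise
  linear CDF); a step-function CDF would systematically shorten credible
  intervals for sharp posteriors.
* Cohort runs derive per-agent seeds from one master seed, so every
  experiment replays bit-identically.
* Known limitations: the two parameters are partially entangled at high
  information loss (first-category length responds to both); flexibility
  is weakly identified from a single 128-trial session (posterior SD
  around 0.15), so individual-level conclusions about $\lambda$ warrant
  full posteriors, not point estimates; and the model covers only the
  three-dimensional, deterministic-feedback WCST variant.
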