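# wcstbayes

Bayesian cognitive-agent modelling of the Wisconsin Card Sorting Test
(WCST), for computational psychiatrists, neuropsychologists and cognitive
modellers who want more from WCST protocols than summary error counts.

The WCST asks a participant to match target cards to four stimulus cards
that vary in color, shape and number, inferring a hidden sorting rule from
binary feedback; the rule changes without warning after ten consecutive
correct responses. `wcstbayes` models the participant as a Bayesian agent
holding beliefs $p(s_t \mid x_{0:t-1})$ over the three candidate rules,
updated by Bayes' rule from each response–feedback pair and propagated
between trials through a stability matrix $\Gamma(t)$ whose diagonal holds
per-rule activation levels $\omega_t$. Two interpretable parameters on
$[0,1]$ govern the dynamics:

* **flexibility** $\lambda$ — activation retained by features the feedback
  disconfirms; low values produce perseveration,
* **information loss** $\delta$ — the exponent of the activation rescaling
  $\omega^{\delta}$; high values slow convergence of the internal model.

The package provides:

* `run_agent()` — generative simulation of full sessions with belief
  snapshots;
* `reconstruct_trajectories()` — trial-by-trial Bayesian surprise
  (KL divergence between successive predictive beliefs), Shannon surprise
  ($-\log$ predictive probability of the observation) and predictive
  entropy, in nats;
* `score_session()` / `classify_errors()` — Heaton-style clinical scores:
  perseverative and other errors, trials to first category, failures to
  maintain set;
* `grid_posterior()` / `fit_observed()` — exact trial-wise likelihood and
  gridded posterior over $(\lambda, \delta)$ under a uniform prior, with
  `tidy()`/`glance()` methods and `autoplot()` figures;
* `recovery_study()` — simulation-based validation (RMSE, $R^2$, coverage
  calibration, SBC rank histograms);
* `run_factorial()`, `run_info_dynamics()`, `synthetic_cohort()` — the
  factorial simulation designs and a group-structured fixture generator;
* a thin command-line wrapper in `inst/scripts/wcst`
  (`simulate`, `score`, `fit`, `table2`, `dynamics`, `recover`).

## Worked example

Simulate an inflexible agent on the 128-trial protocol, score it
clinically, and recover its parameters from the behaviour alone:

```r
library(wcstbayes)

session <- run_agent(agent_params(lambda = 0.3, delta = 0.4),
                     task_config(), seed = 101)
score_session(session)
#> # A tibble: 1 × 7
#>   total_errors perseverative_errors other_errors trials_to_first_category ...
#> 1           34                   21           13                       15

tidy(grid_posterior(session, param_grid()))
#> # A tibble: 2 × 5
#>   parameter  mean median conf.low conf.high
#> 1 lambda    0.325  0.314   0.0881     0.619
#> 2 delta     0.420  0.418   0.270      0.578

head(reconstruct_trajectories(session), 3)
#> # A tibble: 3 × 4
#>   trial bayesian_surprise shannon_surprise entropy
#> 1     1         0.377                1.10    1.10
#> 2     2         0.0110               0.822   0.721
#> 3     3         0.0000607            0.772   0.628
```

The low flexibility shows up directly: 21 of 34 errors are perseverative,
and the posterior mean $\hat\lambda = 0.33$ recovers the generating value
0.3 with $\hat\delta = 0.42$ near the true 0.4. The trajectory starts at
maximal entropy $\ln 3 \approx 1.10$ and collapses as the agent locks onto
the rule; `autoplot()` on any of these objects draws the corresponding
figure.

See the vignette (`vignettes/wcst-cognitive-model.Rmd`) for the model
equations, the activation-update semantics and their rationale, parameter
identifiability, and validation methodology.

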