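---
title: "The hybrid learning model and its synthetic validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid learning model and its synthetic validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twostagerl)
library(dplyr)
```

## The task

`twostagerl` models a two-stage Markov decision task with uncued reward
reversals. On each trial the subject makes a first-stage choice between two
actions (`a1`, `a2`); each action leads to its strongly associated
second-stage state with probability 0.7 (a *common* transition) and to the
other state otherwise (*rare*). A second binary choice in that state then
pays 100 points or nothing, with probabilities set by a block schedule.

A session is six blocks of 40 trials (240 trials; the practice variant is
six blocks of 5). In block 1 both states offer a 0.6 vs 0.2 option, so
neither first-stage action dominates. From block 2 on, one state is
*favored* — its better option pays at 0.8 — while both options of the other
state pay at 0.2; the favored state alternates at every block boundary, and
nothing signals the change. The first-stage action more strongly linked to
the favored state is the *advantageous* action of that block.

```{r}
cfg <- default_task_config()
cfg
favored_states(cfg)
```

Which physical stimulus carries the high-probability option within a state
is arbitrary and not modeled (only contingencies matter, not screen
position or color assignments), so option identity is simply stable within
a state.

## The hybrid value-update model

First-stage behavior is described by two action values $V(a_1), V(a_2)$.
After each trial both values decay and the chosen (and sometimes unchosen)
action receives an increment that depends on the outcome valence and the
transition type:

$$V_{t+1}(x) = \gamma V_t(x) + \Delta, \qquad
  \Delta \in \{\Delta_+^{mf}, \Delta_+^{mb}, \Delta_-^{mf}, \Delta_-^{mb}\}$$

| previous trial | chosen action | unchosen action |
|---|---|---|
| common, rewarded | $+\,\Delta_+^{mf} + \Delta_+^{mb}$ | — |
| rare, rewarded | $+\,\Delta_+^{mf}$ | $+\,\Delta_+^{mb}$ |
| common, unrewarded | $+\,\Delta_-^{mf} + \Delta_-^{mb}$ | — |
| rare, unrewarded | $+\,\Delta_-^{mf}$ | $+\,\Delta_-^{mb}$ |

The model-free increments always credit the chosen action; the model-based
increments credit the action whose common transition leads to the state
where the outcome occurred — after a rare transition that is the *unchosen*
action. A negative $\Delta_-$ expresses lose-shift; a positive one,
staying despite no reward.

Choice probability is the logistic of the value difference,

$$P_t(a_1) = \frac{1}{1 + e^{-(V_t(a_1) - V_t(a_2))}},$$

with no inverse temperature: choice stochasticity is absorbed by the
magnitude of the increments.

The decay form is mathematically equivalent to a Rescorla–Wagner form with
learning rate $\alpha = 1 - \gamma$ and reinforcement strengths
$\kappa = \Delta / \alpha$ (`kappa_params()`, `to_delta()`). The package
fits the decay form because $\kappa$ becomes unidentifiable as $\alpha \to
0$ — $\kappa$ can blow up to compensate a vanishing learning rate. The
equivalence of the two recursions is property-tested to $10^{-12}$.

Conventions the model itself leaves open, fixed as package-wide choices:

* **Initial values** are $V_0 = (0, 0)$, making the first choice uniform.
* **Decay applies to both actions every trial**, chosen and unchosen alike;
  the chosen action's update is thus literally $\gamma V + \Delta$.
* **Outcome is binarized** — only valence enters the equations, never the
  0/100 magnitude.
* **Only first-stage choices enter the likelihood.** Second-stage choices
  are recorded but contribute nothing to the fit.
* **Values are never reset at block boundaries**: reversals are uncued, so
  a learner cannot know a block changed.

## Fitting

`fit_subject()` maximizes the session log-likelihood with Nelder–Mead from
random initial points (default 500 restarts; tests and the bundled
reproduction use smaller budgets with the seed recorded in the output).
Numerical choices:

* $\gamma$ is optimized through a logistic transform of an unconstrained
  surrogate, which keeps the simplex unconstrained while confining the
  reported value to $[0, 1]$ without boundary clipping. The four $\Delta$s
  float freely.
* Initial points draw $\gamma$ uniformly on $(0.05, 0.95)$ and each
  $\Delta$ uniformly on $(-2, 2)$, a box that brackets the condition
  presets and their quartile ranges.
* Convergence tolerance is $10^{-6}$ on the function value with at most
  2000 iterations per restart; non-converged restarts still contribute
  their best point and are counted in `n_converged`.
* Each restart consumes a fixed number of random draws, so for a fixed
  seed a larger restart budget extends the same stream — the best
  log-likelihood is non-decreasing in the budget, and refits are
  bit-reproducible.
* Sessions with a single unique first-stage choice are flagged
  `degenerate` (their MLE diverges along the increment directions) rather
  than silently fitted; per-subject seeds in `fit_cohort()` derive from the
  subject identifier, not from row order, so shuffling a dataset changes
  nothing.

The optimizer is validated two ways: the fitted likelihood must dominate
the generating parameters in-sample, and it must reach at least the best
point of a coarse grid oracle over $\gamma \in [0,1]$ (step 0.1) and each
$\Delta \in [-3, 3]$. Any finite grid maximum is a lower bound on the true
maximum, so the check is valid at any resolution; the suite uses steps of
0.25–0.5 on the $\Delta$s, which keeps the oracle to a few million
likelihood evaluations.

## Synthetic cohorts

No raw trial data accompanies the study this design comes from, so the
package validates everything on synthetic cohorts whose generator is
first-class, tested code. A cohort (`cohort_spec()`) is 26 subjects per
condition by default, each playing one 240-trial session with hybrid-model
parameters drawn around its condition's preset:

```{r}
tidy_preset <- function(cond) {
  tibble::as_tibble(unclass(condition_preset(cond))) |>
    mutate(condition = cond, .before = 1)
}
bind_rows(tidy_preset("control"), tidy_preset("stress"))
```

These presets are the reported median best-fitting estimates per condition;
the qualitative story they encode is that the stress preset has a higher
decay factor (slower learning) and a near-zero model-free loss increment
where the control preset's is clearly positive. Between-subject
heterogeneity is symmetric normal jitter with per-parameter standard
deviations derived from the reported interquartile ranges
(`condition_jitter_sd()`, IQR/1.349, the normal-equivalent sd); jittered
$\gamma$ is clamped to $[0, 1]$. With this jitter a few synthetic subjects
per cohort land in near-perseverating regimes and are removed by the same
exclusion rule applied to real subjects — mirroring the fact that the
original sample also lost subjects to that rule.

Because the first-stage likelihood ignores stage 2, the generator must
invent a stage-2 policy. Agents keep a per-state action value updated by a
Rescorla–Wagner rule on the binarized outcome and choose by softmax. The
defaults (learning rate 0.5, inverse temperature 5) give fast, reliable but
non-deterministic tracking of the scheduled probabilities — enough to
produce realistic outcome streams, which is all stage 2 needs to do here.
Neither parameter is fitted.

`simulate_cohort()` attaches the drawn ground truth (including per-session
seeds) to its output, and the whole pipeline — simulate, exclude, fit,
analyze (`run_reproduction()`) — is bit-reproducible from one master seed
via fixed per-stage derivations recorded in the manifest.

## The analysis battery

* `exclude_perseverators()` removes subjects whose modal first-stage action
  exceeds 95% of trials — read strictly: exactly 95% is retained.
* `stay_probabilities()` classifies each trial after the first by the
  *previous* trial's outcome and transition and records whether the
  first-stage choice repeated. Block boundaries are not breaks: no cue
  marked them, so trial 41 is classified by trial 40.
* `stay_anova()` runs the 2 (outcome) × 2 (transition) × 2 (condition)
  mixed ANOVA on the per-subject cell means, using the conventional
  sum-of-squares partitioning for one between- and two within-subject
  factors; with two-level factors no sphericity correction exists to apply.
  Subjects with an empty cell (possible only in very short sessions) are
  dropped with a warning.
* `performance_summary()` reports total points, the modal-action
  proportion, and the probability of the advantageous first-stage action
  over blocks 2–6 only — block 1 has no advantageous action, so including
  it would only dilute the measure toward 0.5.
* `compare_conditions()` uses pooled-variance two-tailed t tests (the
  $n_1 + n_2 - 2$ df convention), `delta_regression()` ordinary least
  squares of $\Delta_-^{mf}$ on $\gamma$ and a treatment indicator
  (standardized coefficients from the same model on z-scored variables),
  and `delta_ancova()` an F test of condition adjusted for the
  advantageous-choice covariate (type II; identical to type III here since
  no interaction is modeled).

## What passing tests do and do not show

The synthetic generator reproduces the statistical structure the analyses
assume — transition and reward calibration, reversal dynamics, hybrid
choice behavior with condition-separated parameters — and on it the
pipeline recovers the generating parameters (rank correlations above 0.6
for the effect-carrying parameters at study size) and detects the
between-condition difference in $\Delta_-^{mf}$ in the expected direction.
That validates the machinery, not the original findings: real subjects
bring reaction times, latent-state inference, session-level
non-stationarity and stage-2 strategies the generator does not emulate, and
the published test statistics depend on the authors' raw data, which is not
deposited. Exact published values are therefore not reproduction targets
anywhere in the package.

One subtlety discovered while validating the generator: for a *pure*
model-free agent the textbook expectation is a reward main effect with
exactly zero reward-by-transition interaction in the stay table. In this
reversal variant the interaction is not exactly zero — conditioning on the
previous outcome induces a small selection dependence between transition
type and the value state (agents currently locked onto the advantageous
action are both more likely to be rewarded via a common transition and more
likely to stay). The effect is an order of magnitude smaller than a
model-based agent's interaction (about 0.04 vs about 0.97 on the contrast
scale in the suite's cohorts), so the suite tests the model-free signature
as an equivalence bound (|contrast| < 0.1, and at least tenfold smaller
than the model-based contrast) rather than as a point null.

## Problem sizes

The bundled validation uses cohorts of 26 subjects per condition fitted
with 30 restarts (parameter recovery), 60-session cohorts for the
stay-signature checks, 100 subjects per condition for the ANOVA regime
checks, $10^5$ draws for calibration rates, and 200 label permutations for
the ANOVA null calibration; these sizes give stable results at interactive
run times. The fitting default remains 500 restarts per subject.

## Limitations

* No reaction-time model: timing is out of scope throughout.
* "Stress" is only a parameter preset and a group label; nothing
  physiological is modeled.
* No hierarchical estimation or model comparison — one model, fitted per
  subject, as in the design being emulated.
* The stage-2 policy is a generator convention; fitted parameters are
  insensitive to it by construction, but cohort-level performance measures
  (total points) do depend on it.
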