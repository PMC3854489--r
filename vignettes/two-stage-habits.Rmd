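---
title: "Flat and hierarchical accounts of habit on the two-stage task: models, fitting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flat and hierarchical accounts of habit on the two-stage task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the task's generative model, the two agent families, the estimation and
model-selection machinery, what the synthetic cohorts do and do not
emulate, and the numerical and design choices made where the problem left
them open.

## The task

Each trial has two stages. A first-stage key press (1 or 2) leads to one of
two slot machines: key 1 commonly reaches machine A, key 2 machine B, each
with probability `p_common = 0.7`, fixed throughout. At the machine a
second key press pays a unit reward with probability 0.7 or 0.2, depending
on a latent four-entry schedule (one entry per machine × key). On every
trial after the first, with probability `p_reset = 1/7`, **all four**
entries are independently resampled uniformly from {0.2, 0.7}. A session
is 270 trials with a break recorded after trial 120 (metadata only; the
schedule is treated as contiguous across the break).

Two analytic properties anchor the simulator. Call a first-stage action
*best* when the maximum reward probability on its common machine strictly
exceeds the maximum on the other machine (ties count as not-best).
Enumerating the 2⁴ equally likely post-reset schedules, a best action stays
strictly best in 3 of 16 outcomes (`prob_remain_best()`), the product of
P(own machine has a 0.7 key) = 3/4 and P(other machine is all-0.2 while
winning the tie-break) = 1/4. The run length over which an action remains
best is then geometric with per-trial stopping rate
`p_reset × (1 − 3/16)`, mean 112/13 ≈ 8.6 trials
(`expected_best_duration()`; both are cross-checked against Monte-Carlo
oracles in the tests). The short run length is what forces continual
re-learning and keeps the habitual/goal-directed trade-off in play.

**Reset semantics.** The task description is ambiguous between a per-key
1/7 reset and a single global 1/7 event that resamples all four keys. The
3/16 derivation above is only coherent under a global event conditioned on
"a reset happened", so the global reading is implemented. This is a design
decision recorded here; `step_schedule()` is the single point of change.

## The flat hybrid family

State space: the first-stage state `s0` and the two machines. Model-free
values `Q_mf` start at 0 and update, per trial, in a fixed order:

1. the second-stage reward model row moves toward the outcome,
   `T2 ← (1 − α_T)·T2 + α_T·r` (row-stochasticity is preserved because the
   no-reward probability is the implicit complement);
2. the stage-1 value bootstraps from the **pre-update** stage-2 value with
   rate α₁;
3. the stage-2 value moves toward the reward with rate α₂ (prediction
   error δ₂ computed before the write);
4. the eligibility increment adds `α₁·λ·δ₂` to the stage-1 value.

Model-based values are the learned reward probabilities at stage 2 and
their backup through the fixed transition matrix at stage 1. Choice is a
softmax over `Q_net = w·Q_mb + (1 − w)·Q_mf` at both stages, with inverse
temperatures β₁, β₂ and a perseveration bonus added at stage 1 only, to
the logit of repeating the previous first-stage key — the task's
perseveration phenomenon is defined over first-stage actions, and the
previous second-stage context rarely recurs identically.

The default family ties `α_T = α₂`, giving the full model five learning
parameters plus β₁, β₂ (seven free in total); `flat_params()` exposes the
untied `alpha_T` for users who want it. The eight family members are the
full model crossed with the three toggles {λ = 0, w = 0, ρ = 0}; the w = 0
member is the pure model-free (purely habitual) account and the all-fixed
member has four free parameters. The exact identity of the three toggled
parameters is a reconstruction — the choice gives the family a pure-MF
member and a no-perseveration member, the two scientifically load-bearing
lesions — and each toggle is recorded in the `model_spec`, so alternative
families are one constructor call away.

## The hierarchical sequence family

At stage 1 the agent chooses among **six options**: singles 1 and 2, and
the open-loop sequences 11, 12, 21, 22. Sequence values are learned reward
probabilities mapped directly from `s0` to the terminal outcome (the
machine identity is skipped — only the outcome matters for value); single
values back up the per-machine key values through the fixed transitions.
Option choice adds `κ` to singles (the single-action preference) and the
perseveration bonus to every option whose *first key* repeats the
previously observed first-stage key. Perseveration cannot condition on the
previously executed option because that option is latent to the analyst;
using the observed key applies the same rule to singles and sequences.

Because sequences execute open-loop, observing the first key leaves three
candidate options. Renormalizing their stage-1 probabilities gives the
sequence posterior, and the stage-2 likelihood is the mixture of open-loop
execution (probability mass exactly on the sequence's second key) and
goal-directed softmax choice. In the `κ → ∞` limit the mixture reduces
exactly to the lesioned softmax — this identity is a regression test. The
lesioned family replaces the mixture by the plain softmax while leaving
stage-1 simulation untouched; it exists to test whether the sequence term
in the *likelihood* earns its keep.

The reaction-time predictor for an observed second press is
`1 − P_seq(a₁→a₂ | a₁)`: a press that completes a probably-ongoing
sequence is predicted fast. The functional form is a choice — any strictly
decreasing transform of the sequence posterior is observationally
equivalent because all RT comparisons in the analyses are ordinal
(arbitrary units). The bounded probability-scale form was chosen for
interpretability and is localized in `rt_prediction()`.

Learning updates both the executed sequence's row (rate `α_s`) and the
visited machine/key row (rate `α_a`). The family's toggles are {κ = 0,
ρ = 0, α_s tied to α_a}; tying α_s leaves three distinct optimized
parameters in the all-fixed member.

## Behavioral statistics

All stay analyses operate on lagged trial pairs within subject; the first
trial only serves as a predecessor, and the mid-session break is treated
as contiguous. The four modes select: all pairs (first-stage stay by
previous reward × previous transition); different-machine pairs
(second-stage stay by previous reward × repeated first key — the analysis
that separates the accounts); and same-vs-different-machine pairs split by
whether the first key repeated.

The group inference is a **summary-statistics approximation** to
mixed-effects logistic regression: per subject, a ridge-penalized ML
logistic fit (penalty 0.05 on all coefficients — just enough to keep
estimates finite under complete separation, negligible otherwise) on
±1-coded factors plus interaction, then two-sided one-sample t-tests on
the per-subject coefficients. Directions and significance of effects are
the scientific surface; absolute coefficient magnitudes are not
comparable to a GLMM's and are not asserted anywhere. Subjects with fewer
than 10 eligible pairs are excluded with a warning.

The recursive partitioning of second-stage stays is implemented from its
definition: at each node, a permutation p-value per covariate — absolute
difference in stay proportions for the binary covariates (previous
reward, repeated first key), a maximally selected two-sample statistic
over admissible thresholds for RT — Bonferroni-corrected across the three
covariates; the node splits on the winner while the adjusted p is below
α = 0.05 and the node holds at least `min_node` (default 40) pairs, with
at least `min_node/4` (≥ 5) pairs per side of an RT cut. P-values use the
add-one estimator `(1 + #{perm ≥ obs})/(B + 1)`, so the smallest
attainable value is 1/(B+1); the default B = 9999 matches conventional
practice, and tests scale B down. Any data-driven RT threshold is a
property of the data at hand, not a constant of the method, and is never
asserted against a fixed value.

## Fitting and model selection

Priors: Beta(1.1, 1.1) for unit-interval parameters, Gamma(shape 1.2,
scale 5) for inverse temperatures (mean 6 — weakly informative on the
scale softmax logits need), Normal(0, 1) for perseveration and κ (κ is a
real-valued preference of the same kind as perseveration, so it shares
that prior).

MAP estimation runs in the unconstrained space (log-odds for unit
parameters, log for positive ones) with the change-of-variables Jacobian
folded into the objective, BFGS from 10 prior-drawn restarts by default,
Nelder-Mead as a per-restart fallback. The Laplace evidence is computed
**in the same transformed space** — the approximation is
parameterization-dependent and the transformed posterior is closer to
Gaussian; the Jacobian term makes the result a proper evidence for the
native-space model. The Hessian is central finite differences with step
`1e-4·(1 + |θ|)` per coordinate; non-positive-definite Hessians are
repaired by clipping eigenvalues at 1e-8 with a warning and flagged if
degenerate. The 1-parameter fits are validated against a dense grid
argmax of the same objective, and the evidence against a closed-form
Bernoulli–Beta marginal and a two-parameter grid quadrature (agreement
within 0.1 and 0.5 nats respectively in the tests).

Model-level inference is the standard variational random-effects scheme
(iterate assignment responsibilities and Dirichlet concentrations),
exceedance probabilities by 10⁵ Dirichlet draws. Family-level inference
puts equal prior mass on each family divided equally within it
(`α0 = 1/|family|`) and estimates family exceedance by **Gibbs sampling**
of the assignments-and-frequencies model rather than by sampling the
variational posterior: the mean-field update has a rich-get-richer fixed
point that concentrates on the largest-α0 models when evidences are
nearly flat, exactly the regime where a family comparison must fall back
to its prior (0.5/0.5). The Gibbs chain targets the exact posterior,
agrees with the variational answer when evidence is decisive, and is
cheap at these dimensions (default 20,000 sweeps after 2,000 burn-in).

## Synthetic cohorts

`generate_cohort()` emulates the study design this package targets: 15
subjects × 270 trials, with the task constants above. Parameters are
either a fixed representative vector — moderate mid-range values
(hierarchical: β₁ = 4, β₂ = 2, α_a = α_s = 0.4, κ = 0.3, ρ = 0.3; flat:
β₁ = β₂ = 2.5, α₁ = α₂ = 0.5, λ = 0.6, w = 0.5, ρ = 0.2), chosen once as
plausible human-scale values producing decisive but stochastic choice —
or per-subject prior draws for recovery studies. Reaction times are
`0.5 s + 0.3 s × rt_prediction + N(0, 0.1 s)`, truncated at 0.05 s, for
hierarchical cohorts; flat cohorts get the same base and noise without
sequence structure. The 0.3 s effect against 0.1 s noise makes the
condition contrasts detectable at cohort scale without being trivial.
Each subject runs on a sub-seed derived from the master seed, so cohorts
are reproducible and independent of execution order.

What the generator does **not** emulate: first-stage RTs, fatigue and
break effects, attention lapses, response biases beyond perseveration,
and any mismatch between the agent family and human behavior. Passing
tests on synthetic cohorts therefore demonstrate that the analyses detect
the signatures *when the generating process matches the model class*,
and that the fitting machinery is consistent — not that human data would
show these effects.

## Problem sizes used by the test suite

Chosen as the package's own trade-off between statistical resolution and
runtime: signature checks use 2–4 agents × 4,000–6,000 trials;
cohort-level analyses 15 × 270 (the study design) or 15 × 1,000 for the
partition tree, whose deeper splits need more pairs per node; the
discriminating interaction claim 15 × 3,000 per family; parameter
recovery 20 subjects × 3,000 trials (Spearman ρ ≥ 0.7 asserted for β₁,
α₁, α₂ of the flat hybrid); family recovery 15 × 270 across three seeds
with each family's full model fitted (one model per family suffices for
family-level inference and keeps the harness proportionate).

## Known limitations

- The group regression approximates a GLMM; with very unbalanced designs
  or few subjects its SEs are optimistic relative to a full mixed model.
- The Laplace evidence is a local approximation; multimodal posteriors
  (possible for weakly identified λ/w combinations on short sessions) are
  handled only through restarts.
- Sequences are limited to length 2, matching the task's depth; option
  discovery and model-free evaluation of sequences are out of scope.
- The variational model-level BMS inherits the mean-field assumptions;
  family-level conclusions use the Gibbs estimate for robustness.
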