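---
title: "Modelling risk-sensitive reinforcement learning in reversal tasks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling risk-sensitive reinforcement learning in reversal tasks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

grackleRL analyses two-option colour-reward reversal experiments of the kind
run on wild-caught great-tailed grackles: each bird first learns which of two
colour-distinct tubes holds food (*initial learning*), and once it passes a
learning criterion the colour-reward pairing is swapped (*reversal
learning*). The package covers the full analytical chain for such data —
criterion logic and data audits, behavioural count models, a mechanistic
learning model, posterior forward simulation, and an evolutionary analysis of
the learning parameters themselves. This vignette explains the models, their
assumptions, and the numerical and design choices a user should know about.

## The task and its criteria

A bird finishes a phase under the **applied criterion** when at least 17 of
its most recent `min(t, 20)` completed trials are correct; trial 17 is
therefore the earliest possible finish. Incomplete trials — presentations on
which no choice was made — are excluded from criterion evaluation, switch
counting and model fitting throughout: a non-choice cannot speak to learning
(satiation or disturbance are equally good explanations), and excluding them
keeps the behavioural and mechanistic analyses on the same trial set.
`trials_to_finish` consequently counts completed trials.

Two legacy criteria are replicated for data-audit purposes only.
The **fixed-window** rule assesses 17/20 with set minima of 8 and 9 correct
across the last two 10-trial sets, but only at trials 20, 30, 40, …, so a
recorded pass can overshoot the true passing trial. Whether the (8, 9)
minima attach to the sets in order is undocumented; both readings are
implemented (`minima_ordered`), defaulting to the literal ordered reading.
A 7/10 + 10/10 split fails under either reading.
The **sliding-window** rule applies the same requirements at every trial
from 20 on. Because the window slides, a bird with three wrong then
seventeen correct choices fails at trial 20 (7/10 + 10/10) yet reaches
criterion at the *start* of trial 21 — whatever it chooses next, the window
will hold 8/10 and at least 9/10 correct. `criterion_sliding_window()`
reproduces this early-pass anomaly and flags it with a `pre_choice`
attribute.

Birds can stay in test past the applied criterion; `audit_extra_trials()`
reports these extra trials and `exclude_extra_trials()` removes them, which
is the default preprocessing for all model fits.

## The reinforcement learning model

Each bird `j` carries an attraction `A[i]` per option `i`, updated after
every completed trial:

    A[i, t+1] = (1 - phi) * A[i, t] + phi * pi[t]        (chosen option)
    A[i, t+1] = A[i, t]                                  (unchosen option)

where `pi` is the experienced payoff (1 for food, 0 otherwise, by default)
and `phi` in [0, 1] is the *information-updating rate*. Choice follows a
softmax with *risk-sensitivity rate* `lambda >= 0`:

    P(i) = exp(lambda * A[i]) / sum_m exp(lambda * A[m])

`lambda = 0` gives random choice; large `lambda` makes the bird
deterministically prefer its higher-valued option. Both parameters are
estimated per sex-by-phase cell (and optionally per population), with a
correlated 4-dimensional bird-level offset vector (phi and lambda per phase)
giving partial pooling across birds. Attractions start at 0 for both
options and persist across the phase boundary, so reversal-phase estimation
begins from the attraction state accumulated over all previous choices;
only `(phi, lambda)` switch at the boundary. The equation above updates only
the chosen option — there is no forgetting term for the unchosen one — and
this is fixed, not configurable, because the generative simulations and the
likelihood must agree.

### Priors and sampling

Fitting uses MCMC through JAGS. Priors are weakly informative: Normal(0, 1)
on logit-scale phi means; Normal(0, 1.5) on log-scale lambda means, the
wider scale chosen because lambda is admissible up to 15 (log 15 ≈ 2.7) and
the likelihood identifies it only weakly near the top of that range, where a
unit-scale prior shrinks estimates appreciably; and a Wishart(I, 6) prior on
the precision matrix of the bird offsets, the standard conjugate choice for
a freely estimated 4x4 covariance in this sampler (a half-Normal/LKJ
decomposition would be the natural alternative in a Hamiltonian sampler, but
no LKJ prior is available here and the Wishart behaves comparably at this
dimension). Softmax probabilities are computed as a logistic of
`lambda * (A1 - A2)` and clamped away from 0/1 by 1e-7, so the sampler is
stable for any `lambda` up to the cap and attraction gaps up to the payoff
magnitude.

Defaults (4 chains, 1000 adaptation, 500 burn-in, 2000 retained draws per
chain) are sized to clear 1000 effective samples for all group means on
cohorts of the study's size; `fit_rl()` warns whenever the contract is
missed rather than returning silently. Per-chain RNG seeds are derived from
the config seed, so a refit reproduces draws exactly.

### What the fit can and cannot identify

Two practical identification limits matter. First, criterion-stopped
*initial* phases are short (~30 trials) and start from equal attractions, so
`phi` and `lambda` trade off along a ridge there; estimates from
criterion-stopped data lean on the reversal phase and on pooling. Second,
above roughly `lambda ~ 5` with unit payoffs, choice behaviour saturates and
the likelihood flattens, so high risk-sensitivity values are recovered with
downward-shrinking uncertainty rather than precisely. Parameter-recovery
studies in this package therefore use fixed-length phases (70 trials per
phase by default), which make both phases informative; with
criterion-stopped cohorts the same fits remain valid but wider and mildly
shrunk.

## Behavioural count models

Trials-to-finish and switches-at-finish are modelled as multilevel Poisson
regressions with a log-link mean per sex-by-phase cell (index coding — an
independent mean per cell rather than reference-dummy contrasts, matching
the contrast-first reporting style) and a varying intercept per bird.
Priors: Normal(0, 1) on log-scale cell means, half-Normal(0, 1) on the
bird-intercept scale. Birds that never finished a phase (e.g. dropped early
from reversal) contribute no row for that phase. Contrasts are reported as
draw-wise male-minus-female differences of the natural-scale expected count
with means and 89% highest posterior density intervals; 89% is the
conventional reporting mass in this literature, and the HPD interval is
computed as the shortest sample interval containing the target mass.

## Forward simulation

`forward_simulate()` generates synthetic 'birds' from the fitted posterior:
in `full` mode each simulant takes one posterior draw of the group means
plus an offset drawn from that draw's fitted covariance — preserving the
correlation structure among sex- and phase-specific parameters — while
`averaged` mode uses posterior-mean parameters for representative
individuals. Simulants run the exact generative loop of the model under
the applied criterion. Because pathological parameter draws (e.g.
`lambda ~ 0`) can fail the criterion indefinitely, simulation caps each
phase at 300 trials by default; capped trajectories are excluded from means
and counted separately. Real birds always finished or were withdrawn, so
the cap only binds in the extreme tails of the posterior. Tube position
(left/right) is not modelled: the learning rules operate on colour
attractions only.

## Synthetic cohorts and the sex-effect presets

`generate_cohort()` emulates the study's structure: 49 birds across three
populations (core 17M/5F, middle 4M/4F, edge 11M/8F), two phases with the
rewarded option counterbalanced across birds, occasional incomplete trials
(rate 0.05 by default), up to two post-criterion extra trials per phase,
and three males (two core, one middle) dropped early from reversal after 30
completed trials — each a configurable knob. Bird-level heterogeneity is
multivariate normal on the logit/log scale (sd 0.3, exchangeable
correlation 0.2 by default). The ground-truth table is returned alongside
the observable data but is never read by any analysis function, which keeps
recovery tests honest.

The `paper_like` preset encodes the estimated qualitative sex pattern —
males with lower `phi` and higher `lambda` in both phases, females' `phi`
dropping to the male level in reversal. Its cell means
(M: phi 0.030/0.025, lambda 4.3/5.3; F: phi 0.050/0.025, lambda 2.8/3.3)
were calibrated once, by forward simulation, to land near the study-scale
behavioural magnitudes (roughly 33 initial trials for both sexes; reversal
trials ≈ 76 male vs 95 female; reversal switches ≈ 26 vs 36) and then
frozen. The `null` preset gives both sexes the mid-point parameters.

What the generator does *not* emulate: position biases and their
pseudorandomisation, motivational drift, inter-trial dependence beyond the
learning rule, or observer error. Passing tests on synthetic cohorts
therefore demonstrate internal consistency of the pipeline — that the
models recover what the generative process put in — not correctness of the
learning model as a description of real birds.

## The evolutionary model

To ask which learning parameters an environment favours, a population of
N = 300 agents evolves over 7000-generation runs. Each agent is born naive
and makes t = 1000 binary foraging choices governed by the same
attraction/softmax rules; the environment flips which option is optimal
with probability `u` before every choice (*stability*) and, with
probability `s`, lets optimal behaviour go unrewarded on a given choice
(*stochasticity*). Fitness is the reward count over the final 800 choices —
the first 200 are ignored so selection responds to steady-state behaviour.
Reproduction is asexual and fitness-proportionate (roulette wheel), with
offspring inheriting `(phi, lambda)` plus zero-centred normal mutation
(sd 0.05) on the logit/log scale; `lambda` is clipped to (0, 15] since
larger values produce identical choices. Reported optima average the
population-mean genotype over the last 5000 generations of 10 runs.

Choices the source description leaves open, resolved here: generation-0
genotypes are uniform on their supports; each lifetime simulates its own
environment stream (the optimal-option state does not persist across
agents); when a failure event occurs the optimal option simply pays
nothing — the alternative reading, in which the reward moves to the other
option that choice, is available via `reward_swap = TRUE`; and when an
entire generation collects zero fitness (possible at `s = 1`) parents are
drawn uniformly, as the wheel is undefined at total fitness zero. Agents
learn from realised rewards, not from latent optimality.

The package's tests exercise this model at a reduced scale — N = 100,
1500 generations, 3–6 runs, corner environments — which reproduces the
directional structure of the full-scale analysis (lower `phi`, higher
`lambda` under stable-but-stochastic conditions; a shallow `lambda` peak at
intermediate `u` within a stochasticity row) in a few minutes of CPU time.
Full-scale runs use `evo_config()` defaults unchanged.

## Problem sizes used in the shipped checks

The test suite and acceptance script size their computations for a single
CPU: recovery studies use 15 birds per sex with 70-trial fixed phases and
2-chain fits of 800 retained draws; behavioural and RL fits of the default
49-bird cohort use 2 chains; forward simulation uses 1000 simulants per
sex; and evolution runs use the reduced scale above. All of these are
choices of the shipped checks, not of the methods — every size is a
function argument.

## Known limitations

* The attraction model has no forgetting of the unchosen option and no
  lapse parameter; misfit from such mechanisms would surface in forward
  simulation, not in the raw estimates.
* High `lambda` values are bounded-identified (see above); contrasts of
  `lambda` between groups are more robust than its absolute level.
* The Poisson models ignore overdispersion beyond the bird intercepts by
  design; a negative-binomial extension is out of scope.
* The evolutionary model is deliberately minimal: no spatial structure,
  sexual reproduction, or life-history realism.
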