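---
title: "Belief propagation for active inference: models, schemes and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Belief propagation for active inference: models, schemes and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefprop)
```

## What this package computes

`beliefprop` simulates perception and action as *active inference*: an agent
embodies a generative model of how its sensations arise and continually
updates its beliefs — and selects its actions — so as to minimize variational
free energy, an upper bound on surprise (negative log evidence). Three
inference regimes are implemented and coupled:

1. **Discrete (categorical) models.** Hidden states evolve as a Markov
   decision process: a likelihood array $\mathbf{A}$ maps hidden states to
   outcomes, policy-dependent transition arrays $\mathbf{B}$ move states
   between epochs, $\mathbf{D}$ is the prior over initial states, and log
   preferences $\mathbf{C}$ encode which outcomes the agent wants. Beliefs
   about states at *every* epoch (past and future) are updated by message
   passing; policies are scored by their expected free energy
   $G(\pi)$ and actions realize the most probable policy.
2. **Continuous models.** Hidden states are represented in generalized
   coordinates of motion $\tilde{x} = (x, x', x'', \dots)$; a flow $f$ and a
   static observation map $g$, with precisions $\Pi_x$ and $\Pi_o$, define a
   generalized (variational) filter — predictive coding — whose first-order
   special case is the conjugate/(extended) Kalman posterior. Action descends
   the precision-weighted outcome prediction error directly.
3. **The link node.** Each discrete outcome is treated as a *model* of
   continuous dynamics: a Gaussian prior $(\eta_m, \Pi_m)$ over the hidden
   causes $v$ of the continuous level. Descending messages moment-match the
   categorical mixture of these priors into the single Gaussian the filter
   consumes; ascending messages score every model against the filter's
   posterior by *post hoc (reduced) Bayesian model comparison*, accumulated
   over the window: $E_m = -\ln o_m - \int L_m(t)\,dt$, with the ascending
   categorical posterior $\sigma(-E)$.

The showcase is a pictographic reading simulation: a two-level discrete
hierarchy (sentences over words; words over quadrant layouts and flips)
drives saccadic sampling of a synthetic 32×32-pixel glyph world through the
link node, and the belief trajectories are rendered as simulated
electrophysiology.

## Message passing: two conventions, on purpose

The marginal posterior over hidden states at epoch $\tau$ under policy $\pi$
collects a *forward* message from the past, a *backward* message from the
future, and a *likelihood* message from the outcome:

$$ s_{\pi,\tau} = \sigma\!\big(\ln \mathbf{B}_{\pi,\tau-1} s_{\pi,\tau-1}
  + \ln \mathbf{B}_{\pi,\tau}\!\cdot\! s_{\pi,\tau+1}
  + \ln \mathbf{A}\!\cdot\! o_\tau\big), $$

where boldface denotes column-normalized conditional probabilities and the
dot denotes the separately row-normalized transpose. `state_update_fixed_point()`
iterates this to convergence (tolerance $10^{-6}$, at most 64 sweeps). A
dynamical version, `state_update_gradient()`, introduces a state prediction
error $\varepsilon = (\text{messages}) - \ln s$ that drives a depolarization
$\nu$ with $s = \sigma(\nu)$ — the process theory in which $\varepsilon$ maps
to error-unit activity and $\nu$ to membrane potential (16 iterations per
epoch, step 0.25, by default).

A subtle point governs the temporal messages of the gradient scheme, and we
surface it as an explicit option rather than hiding it:

* With **sum-product** messages ($\ln \mathbf{B}s$, the log of the expected
  transition — the default, and the convention of the fixed point above) the
  update field is *not* the gradient of any scalar function: the cross
  second-derivatives of the forward and backward messages are asymmetric, so
  no free-energy Lyapunov function exists and the recorded marginal free
  energy $\sum_\tau s_\tau\cdot(\ln s_\tau - m_\tau)$ can rise transiently
  (up to a few times $10^{-2}$ nats on small random models). In exchange, the
  scheme's fixed points are the sum-product ones: exact on chains in the
  regimes below, and — critically — *tie-preserving*: two hypotheses with
  identical evidence keep identical beliefs indefinitely.
* With **variational** messages ($(\ln\mathbf{B})s$, the expected log
  transition) the error is exactly the negative gradient of the mean-field
  variational free energy, which therefore never increases along iterations
  (we observe strict decrease at step 0.25). The price is the well-known
  mean-field excess confidence: with near-deterministic transitions the
  floored log entries (−16 nats) act like a strong ferromagnetic coupling
  between epochs, and *exact ties break spontaneously* — seeded by
  floating-point noise — then lock in. The reading model deliberately holds
  two sentences tied over three words, so its simulations use the
  sum-product convention; the variational convention is the right tool when
  a certified descent property matters.

The two conventions coincide exactly where our exactness tests operate:
uniform transitions (both messages are constant) and hard observations under
deterministic models.

### Exactness regimes and known bias

With uniform transitions and any single observed epoch, the engine equals
exact enumeration (the `enumerate_posterior()` oracle) to machine precision;
deterministic (permutation) models recover the generating sequence one-hot.
For generic transitions the scheme is loopy and approximate, as in the
literature it implements: in particular, with *no* observations the backward
messages — built from posterior expectations rather than evidence-carrying
beta messages — bias the smoothed marginals slightly away from pure prior
propagation (about $2\times10^{-2}$ on random 3-state models). This is a
property of the scheme, not a bug, and tests pin it down.

### Numerical conventions

* **Log floor.** $\ln x$ is computed as $\ln(\max(x, e^{-16}))$ everywhere.
  The max form (rather than adding $e^{-16}$) leaves every probability above
  $1.1\times10^{-7}$ *exactly* unperturbed, which is what lets the engine
  match the exact oracle to $10^{-8}$ and better.
* **Policy pruning by action.** Once an action is emitted, policies whose
  prescription at that epoch differs are precluded (their posterior mass is
  zeroed and renormalized): the agent knows what it did. Without this, the
  Bayesian model average mixes counterfactual interpretations of the
  evidence and dilutes inference.
* **Ties** in action selection resolve to the lowest action index, for
  determinism.
* **Expected free energy** is risk plus ambiguity,
  $G(\pi) = \sum_{\tau>t}\big[o_{\pi\tau}\cdot(\ln o_{\pi\tau} - C_\tau)
  + s_{\pi\tau}\cdot H\big]$, with $H$ the conditional outcome entropy per
  state. $H$'s formula is not unique in the source literature's notation; the
  conditional-entropy definition is adopted (it makes $G$ with flat
  preferences equal the negative mutual information between states and
  outcomes, which is what drives epistemic saccades). With flat $C$ and a
  deterministic likelihood, minimizing $G$ maximizes expected information
  gain.

## Continuous filtering

`filter_step()` integrates $\dot{\tilde\mu} = \Delta\tilde\mu -
\partial_{\tilde\mu} F$ by explicit Euler, with the gradient assembled
analytically from precision-weighted prediction errors
($\varepsilon_x^{[i]} = \mu^{[i+1]} - f^{[i]}$,
$\varepsilon_o^{[i]} = o^{[i]} - g^{[i]}$; generalized maps for $i\ge1$ by
first-order Jacobian propagation). Stability of explicit Euler requires
`dt × curvature < 2`; for stiff configurations (precise priors, fast flows)
`substeps` subdivides each step without changing the sampling grid — the
reading model uses 8 micro-steps per 1/24-saccade step. Unobserved higher
orders of motion should carry (near-)zero outcome precision.

`curvature_spectrum()` returns the eigenvalues of the finite-difference
free-energy Hessian in the generalized expectations. At a Laplace minimum
these equal the posterior precision's eigenvalues; they bound the local decay
rates of the dynamics, so small curvature means critical slowing — free
energy minimization implicitly minimizes these exponents.

## The link node

`descending_prior()` moment-matches the categorical mixture
$\sum_m o_m\,\mathcal{N}(\eta_m, \Pi_m^{-1})$ to one Gaussian: the continuous
level needs a single prior, and under the Laplace assumption a Gaussian form
is the consistent choice. `reduced_log_evidence()` scores an alternative
prior against the posterior obtained under the full prior without refitting
(the Gaussian identity in the four precisions involved; its agreement with
brute-force quadrature is tested to $10^{-6}$ and observed at $10^{-13}$).
Evidence snapshots are taken at *every* integration step with the
instantaneous posterior (mean $\mu_v$; precision
$\Pi_\eta + \partial_v g^\top \Pi_o \partial_v g$) and Riemann-summed; with a
zero-length window the ascending posterior is exactly the descending prior.

## The reading world

The synthetic environment is six sentences of four words over
{flee, feed, wait}. Each word arranges two pictograms in a 2×2 quadrant
array (the rest blank): *flee* puts a bird next to a cat, *feed* a bird next
to seeds, *wait* seeds above (or below) a bird; a vertical flip (a font
change, uppercase/lowercase) and a horizontal flip (letter order) leave the
word's identity invariant. Seeing an *empty* quadrant is a first-class
outcome — emptiness is evidence. The glyphs are procedurally drawn 32×32
images (annulus-with-beak bird, eared-triangle cat, dot-scatter seeds) whose
pairwise normalized cross-correlations are below 0.5; the continuous level
observes their 4×4 block-mean features, contrast-attenuated by
$\exp(-\|x - v_L\|^2 / 2\sigma^2)$ with $\sigma = 0.35$ quadrant widths, so
that precise visual information is only available at fixation (no optic flow
during saccades).

Choices the sources leave open, fixed here once:

* **Sentence table.** Sentences 1 and 4 share words 1–3 and differ only at
  word 4, so a reader is left holding exactly two hypotheses until the last
  word — the narrative the simulation is meant to exhibit. The table is
  configurable.
* **Policy sets.** Level 2 has the single "advance to the next word" policy;
  level 1 entertains four single-saccade policies (one per quadrant target)
  over a two-fixation trial, with flat preferences: saccade targets are
  chosen purely epistemically, and the second fixation goes wherever the
  predicted outcome entropy is highest. Word trials therefore comprise one
  or two informative fixations.
* **Precisions.** The generative model assumes random fluctuations of
  variance 1/8 on visual channels and state noise ($\Pi = 8$), matching the
  process's visual noise; proprioception is precise ($\Pi = 32$ model-side,
  small process noise), which is what makes the *where* posterior definitive
  from saccade onset while *what* resolves only as contrast rises. Location
  priors use precision 16 and identity priors 32; the attractor time
  constant is 0.25 of a saccade, action gain 16. These values were chosen
  once for a functioning oculomotor loop under explicit Euler stability
  limits and are all exposed in `reading_config()`.
* **Timing.** One saccade = 24 integration steps ≈ 256 ms (the step count is
  stated ambiguously as 24 or 25 in the source literature; 24 is adopted),
  so one step ≈ 10.67 ms, which is also the raster bin: 16 gradient
  iterations per discrete epoch ≈ 170 ms, and the full four-word run spans
  ≈ 4.4 s.
* **Ephys.** Rasters are the per-iteration Bayesian model averages of the
  sentence (6 units) and word (3 units) factors, held during continuous
  windows (sustained, delay-period-like activity at the higher level).
  "LFPs" are the rasters band-passed 4–32 Hz with a 4th-order zero-phase
  Butterworth (odd-reflection padded, since plain forward–backward filtering
  has no edge handling); in-band power fractions are estimated with a
  Hann-tapered periodogram.

What the synthetic world does *not* emulate: pixel-level recognition (glyph
identity enters only through the link node's feature models), retinotopic vs
head-centered transforms, fixational eye movements, learning of any model
parameter, and neuromodulatory precision control. Passing tests show the
inference machinery is correct and the closed loop behaves as designed; they
do not certify performance on real eye-tracking or electrophysiological
data.

## A worked run

```{r reading, eval = FALSE}
run <- run_reading(seed = 1)
glance(run)
sentence_posterior(run)[, c("word", "entropy", "map", "p_true")]
autoplot(run)          # gaze path over the quadrant array
autoplot(run$ephys)    # rasters and band-passed traces
```

With the default seed the agent fixates quadrant 1 of word 1 (sees a bird),
saccades to the most informative quadrant, and after two fixations ascends a
near-certain word posterior; sentence uncertainty stays at $\ln 2$ (two
tied sentence hypotheses) until word 4 resolves it to the generating
sentence with posterior ≈ 1.0. Every saccade lands within 0.07 quadrant
widths of its commanded target. Problem sizes used throughout the test suite
are deliberately small (state spaces ≤ 48, horizons ≤ 6, 24-step windows):
they are the sizes at which the exact oracles can certify every computation.

## Limitations

* The deep scheduler is implemented and tested for two discrete levels (what
  the reading model needs); deeper stacks would nest the same pattern but
  are not exercised.
* Policy posteriors use expected free energy only (no habit priors, no
  additional evidence term, no precision/dopamine dynamics); a `gamma`
  precision is exposed.
* The continuous level supports one hierarchical layer; stacked
  predictive-coding hierarchies are out of scope.
* Serialization is JSON/YAML/CSV; there is no binary container format.
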