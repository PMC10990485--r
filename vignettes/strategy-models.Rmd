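---
title: "Ideal-observer strategy models of rotational generalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ideal-observer strategy models of rotational generalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rotgen)
```

## The task and its geometry

Stimuli live on a 4×4 feature grid with 0-based coordinates $(i, j)$, $i$
horizontal and $j$ vertical; north is $+j$, east is $+i$, and rotations are
counterclockwise. A *quadruplet* is a four-stimulus sequence obtained by
walking a category's three transition vectors — category 0: $\{E, N, W\}$,
category 1: $\{NE, W, SE\}$, category 2: $\{N, SE, N\}$ — from a start
cell. Each walk visits the four cells of one unit square exactly once, so a
quadruplet is fully described by its category, its rotation and the
*anchor*, the lower-left corner of that square. We place anchors on the
nine positions $[0,2]^2$: these are the lower-left corners of all unit
squares that fit a 3×3 translation range inside the grid, which gives nine
equiprobable translations and guarantees that every rotation of every
template stays on the grid. (The design description speaks of nine start
"positions excluding the outer ring"; a literal inner-cell reading of a
4×4 grid yields four cells, so the anchor reading is a reconstruction —
it is the unique one that produces nine equiprobable in-grid placements.)
Given an anchor and a rotated template, the start stimulus inside the
square is uniquely determined, a property `realise_quadruplet()` asserts
rather than assumes.

Because each dimension of a unit-square walk takes exactly two adjacent
levels twice each, projecting a quadruplet onto one dimension gives a
four-letter pattern over $\{A, B\}$ with $A$ the lower level. Only six
signed patterns (three unsigned ones) are realisable per dimension — the
test suite asserts this by enumerating all category × rotation × anchor
trials.

## The strategy models

All models are *static* ideal observers: they map a representation of the
current quadruplet to a category distribution fixed by the training
distribution, with no trial-order effects and no learning. `R` is uniform.
`R′` emits the true category on training trials and is uniform at transfer;
it represents a participant who solved training but generalises nothing.
Its temperature still counts as a free parameter ($k = 1$) even though its
transfer predictions are β-invariant — we follow the convention that every
non-uniform model carries the softmax parameter.

One-dimensional models are defined by their *ideal mapping*
(`derive_ideal_mapping()`): enumerate the training distribution (categories
× trained rotations × nine anchors, weighted equally, matching the balanced
training blocks), project every trial onto the tracked dimension, and
assign each pattern the uniform distribution over the categories that
produce it. Under canonical-only training each pattern is diagnostic; when
90°-rotated exemplars join the training set the unsigned patterns (and the
signed $j$ patterns) become two-to-one ambiguous, which is exactly why
those ideal observers sit at 50% expected training accuracy while the
signed-$i$ tracker and the 2D model stay at ceiling. Patterns that never
occur in training (e.g. signed tokens first seen on rotated transfer
trials under canonical-only training) map to the uniform distribution: an
observer with no training evidence about a pattern has no basis to prefer
a category. Predicted probabilities are graded (probability matching at
the prediction level) so the softmax sees a smooth vector, while expected
accuracies use argmax responding with uniform tie-breaking; both
conventions give the same 50%/100% table.

The 2D model matches the trial's full vector sequence against the twelve
rotated templates (which are pairwise distinct — asserted by enumeration)
and returns the matching category: it is translation- and
rotation-invariant by construction. In far transfer it reads ★$i$ as $i$
and ★$j$ as $j$; no cross-mapped 2D variant is defined. The four
cross-mapped 1D models (`1Dij_u` etc., fitted only on far-transfer data)
keep their trained mapping but read the other far dimension as their
trained dimension, capturing participants who re-attach their 1D strategy
to the wrong (or the other) axis of the new manifold.

## Likelihood, fitting, selection

Choices enter through a softmax of the prediction vector with temperature
β. We read the exponent as $p/\beta$ (temperature *division*): under this
reading β = 0.5 is a high-noise regime (a one-hot prediction then gives
only ≈ 79% choice probability), which matches how the recovery
temperatures are described; under the multiplication reading β = 0.5 would
be the *least* noisy setting considered. The likelihood is maximised over
200 linearly spaced β in $[0.01, 0.5]$, endpoints included, ties resolved
to the smallest β, so fits are exactly reproducible. `fit_model()`
aggregates identical (prediction, choice) pairs before scanning the grid;
this is an exact rewrite of the sum, not an approximation. Models are
compared per participant by $\mathrm{BIC} = k \ln T - 2 \ln \hat L$, with
training trials included alongside the requested transfer trials because
some models only separate during training. Feedback-less trials are scored
like any other — static observers have nothing to learn from feedback. The
even/odd cross-validation split uses 0-based positions within the fitted
subset (the convention is arbitrary but must be fixed for determinism).

## Group-level inference

Per-participant log evidences are $-\mathrm{BIC}/2$. The population is
modelled random-effects style: each participant's strategy is drawn from
unknown model frequencies $r \sim \mathrm{Dir}(\alpha_0)$ with
$\alpha_0 = 1$ (uniform). `rfx_bms()` runs the standard variational
scheme — responsibilities $\propto$ evidence × $\exp(\psi(\alpha_k) -
\psi(\sum \alpha))$, concentrations $\alpha = \alpha_0 + \sum_n z_{nk}$ —
to convergence (relative free-energy change below $10^{-8}$, cap 10 000
iterations; the free energy is asserted non-decreasing). The free energy
approximates the log group evidence, and the between-group Bayes factor
compares the pooled cohort (H0: one shared frequency vector) against the
product of the two separate cohorts (H1), under a uniform prior over
hypotheses. The underlying group-comparison method is cited without
equations in the source literature, so this implementation follows the
standard published form of the variational Dirichlet scheme; it is
validated in the tests against brute-force Monte-Carlo integration of the
Dirichlet mixture (within one log unit on small cohorts, the free energy
sitting just below the estimate as a lower bound should). Family-level
inference averages member evidences (uniform within-family prior) in the
log domain. Exceedance probabilities are available as a diagnostic
(`exceedance_prob()`) but the headline BF never uses them. Evidence labels
follow the strict threshold inequalities (BF > 3/10/100 for a difference,
BF < 0.3/0.1/0.01 against one), so a BF of exactly 0.1 is labelled
substantial, not strong.

## The synthetic-data generator

`simulate_participant()` emulates the *choice process only*: a strategy
agent walks the exact trial schedule of an experiment and samples each
choice from the softmax of its generating model's predictions at its
temperature. Schedules reproduce the published design row for row: the
single-session experiment has 120 canonical training trials followed by a
mixed phase of 105 training and 105 transfer trials; the two-day
experiments have 396 trials on day 1 and 600 on day 2, interleaving
pre-training (or, in experiment 4, a colour-count filler task), 48-trial
mapping blocks, and categorisation phases. Every 30-trial categorisation
block shows each category ten times; mixed blocks hold 15 feedback and 15
no-feedback trials with transfer transformations balanced within category
across the phase (15 exemplars per transformation, 5 per category — the
published design does not state the transformation mix, and equal
allocation is the neutral choice); two-rotation training phases balance
the rotations 5/5 within each category's block exemplars. The 30-trial
mixed-modality block of the two-day designs is treated as ordinary
training — the package works on abstract grid coordinates, where modality
is metadata — making 210 training trials available to the fits there.
Restricted mapping blocks are four 12-trial runs with the untrained
dimension fixed at one level per run, so each of the 16 cells still
appears exactly three times per 48-trial block while only the requested
dimension varies within a run.

What the generator does *not* emulate: perceptual confusability of
physical stimuli, learning dynamics within training, lapses, response
times, day-2 drop-out, or any coupling between feedback and behaviour.
Passing recovery tests therefore show that the *design and fitting
machinery* can identify strategies and temperatures from softmax-noisy
static agents — not that human data are free of learning or lapse
processes.

## Recovery and numerical choices

Model recovery (`run_model_recovery()`) simulates agents from every roster
model at temperatures 0.05, 0.2, 0.35 and 0.5 on the same schedules as the
experiments, refits the full roster, and tabulates confusion; the test
suite runs a scaled-down version (10 agents per model at β ∈ {0.05, 0.5},
single-session schedule — about 140 fitted datasets in a few seconds) and
asserts the diagonal is every row's maximum. The cohort sizes used in the
group-inference tests (6–60 agents) and the 25-block mapping simulations
were likewise chosen as the smallest sizes at which the tested properties
are deterministic consequences of the design rather than sampling
accidents.

Parameter recovery needs care at low temperature: a near-deterministic
agent makes essentially no errors over a session
($q(\beta) = 2/(e^{1/\beta} + 2) \approx 4\times10^{-9}$ at β = 0.05), so
the likelihood is monotone in β and the estimate sits at the grid floor
0.01 — the data simply carry no information about β below the error
floor. The recovery test therefore bounds the median absolute error by one
grid step plus twice the delta-method sd of the error-rate estimator,
$\sqrt{q(1-q)/T}\,/\,|q'(\beta)|$: vacuously wide at β = 0.05, about
0.02–0.04 at the higher temperatures, where recovery is genuinely
informative.

Other numerical conventions: all evidence arithmetic is in the log domain
with log-sum-exp; softmax uses max-subtraction; BIC ties in selection
resolve in roster order (R first), making selection deterministic;
`derive_seed()` gives every simulated agent an independent 31-bit stream
from one master seed, so every pipeline output is a pure function of
(configuration, seed).

## Known limitations

The models are static; participants who switch strategy mid-session will
be attributed a compromise fit. The BIC evidence approximation ignores the
shape of the likelihood around $\hat\beta$. The variational free energy is
a lower bound, and the between-group BF inherits its approximation error —
acceptable at the effect sizes of interest (the decisive BFs in simulated
opposed cohorts exceed the bound's slack by orders of magnitude), but
boundary-scale BFs near 1 should not be over-read. Published per-cohort
frequency fractions and BF tables depend on the original participant data
and are not reproduced here; the package reproduces the design's analytic
benchmarks and its identifiability properties instead.
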