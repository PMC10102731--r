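---
title: "Common concepts and symmetry spectra: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common concepts and symmetry spectra: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptsym)
```

## The model

`conceptsym` studies how memory-limited embodied agents represent a simple
world, how a group of such agents can be merged into one *common concept*,
and how much geometric and embodiment symmetry those representations carry.
Everything is information-theoretic and exact: all random variables are
finite and discrete, all distributions are stored as complete tables, and
every entropy, mutual information, multi-information and information
distance is evaluated from those tables in closed form (logarithms base 2,
units of bits, with the standard convention $0 \log 0 = 0$). No quantity in
the package is estimated from samples.

### The perception–action loop

An agent lives on the integer grid $\mathcal{R} = \mathbb{Z}^2$. At each
time step it senses the world through a four-valued pheromone sensor
$S_t \in \{\downarrow,\leftarrow,\uparrow,\rightarrow\}$, updates a small
discrete memory $M_t \in \{0,\dots,|M|-1\}$, and acts with a four-valued
actuator $A_t$ that moves it to an adjacent cell. The loop is unrolled in
time as a causal Bayesian network, and the joint distribution of all
variables factorizes over it. The controller
$C : M_t \times S_t \to M_{t+1} \times A_t$ is *deterministic*: information
maximization drives probabilistic controllers toward deterministic ones
anyway, and restricting to them shrinks the search space to
$(4|M|)^{4|M|}$ total tables.

The agent's task is to capture as much Shannon information as possible
about its *initial* position: maximize $I(R_0; M_T)$ with the memory read
out at horizon $T = 15$, the initial memory fixed to $0$, and $R_0$ uniform
on the start square $\{-d,\dots,d\}^2$. The utility is bounded by
$\min(\log_2 |R_0|,\ \log_2 |M|)$; for the single-source setup with $d = 5$
and $|M| = 8$ both package runs and the reference scenario reach about
$2.9$ of the $3$-bit capacity.

### The world: pheromone gradients

Two setups are built in. `s+` has a single pheromone source at the origin
and start radius $d = 5$; `sq` has four sources at $\{-5,5\}^2$ and
$d = 10$. The sensor points to the neighbouring cell with the highest
pheromone concentration. The concentration field itself is never needed —
only its *ordering* matters — so the package models "highest concentration
neighbour" as "neighbour minimizing Euclidean distance to the nearest
source". Distances are compared as squared integers, so ties are detected
exactly, and a tie is folded into the sensor table as a uniform
distribution over the tied directions (no sampling; the exact conditional
is propagated). Euclidean rather than Manhattan distance is a deliberate
modelling choice — an isotropic plume — and it changes which off-axis cells
tie; a custom `world_setup()` with explicit sources can be used to explore
alternatives.

The infinite grid is represented by the finite box
$\max(|x|,|y|) \le d + T$, which is closed under $T$-step dynamics from
every start cell, so the truncation is exact, not an approximation. The
forward propagation itself is a sparse sum–product over states
$(r_t, m_t)$ implemented in C++; a deterministic controller only branches
at sensor ties, so the active support stays small and one full evaluation
of $p(m_T \mid r_0)$ over all 121 start cells costs well under a
millisecond.

## Optimization

All optimizations in the package — controllers and both common-concept
mappings — run through one simulated-annealing routine over total mappings
between finite sets. The proposal re-assigns the image of one uniformly
chosen domain element; strictly improving moves are always accepted,
worsening ones with the Metropolis probability
$\exp(\Delta/\text{temperature})$. Cooling is geometric. The defaults are
chosen to be self-scaling and reproducible:

* `steps = 20000` proposals per restart, `restarts = 3`, best-ever mapping
  across restarts returned. These sizes reliably reach the known optima on
  every space where exhaustive search is feasible, and reach reference
  utilities (≈ 2.9 bit for `s+`, $|M| = 8$) on the controller space. The
  one exception is the objective-merge functional, whose landscape holds
  deep optima behind long barriers; its recommended budget is
  `steps = 1e5`, `restarts = 5` (the scale used throughout the shipped
  tests), which is cheap because one merge evaluation is a single grouped
  row-sum.
* after cooling, each restart's best mapping is refined by deterministic
  zero-temperature sweeps (every domain element set to its best image
  until a sweep yields no improvement). This polish removes the shallow
  single-coordinate misses a finite schedule leaves behind; it never
  hurts, and it is skipped for zero-step schedules so a degenerate
  schedule still returns its random initial mapping unchanged.
* the initial temperature defaults to the standard deviation of the
  utility over 100 random mappings, so the acceptance profile adapts to
  the scale of each objective;
* the cooling factor defaults to $(10^{-4})^{1/\text{steps}}$, i.e. the
  final temperature is $10^{-4}$ of the initial one;
* every run draws all randomness from the schedule's single seed:
  identical seeds give identical mappings, traces and artifacts.

Because annealing has no uniqueness guarantee, optimized agents are
treated as *ensembles*: quantities reported about them (utilities,
superstition, distances, symmetry counts) are medians or means over
independently seeded runs, never properties of one trajectory.

## Concepts and common concepts

A *concept* $(R, Y)$ is a spatial prior plus a conditional table
$p(y \mid r)$; the canonical example is $(R_0, M_T)$, extracted from an
agent by propagating a point prior from each start cell. Concepts carry an
optional *evaluator* so the conditional can be extended on demand to cells
outside the start region (needed under translated symmetry operations —
the prior stays on the start region, only conditional rows are added).

Two merges of $n$ input concepts $(R, Y^{(1)}),\dots,(R, Y^{(n)})$ sharing
one prior are implemented, both as annealed deterministic mappings:

* the **objective** common concept maps $R \to Y^*$, maximizing
  $\sum_i [\, I(Y^*; Y^{(i)}) - \alpha\, I(R; Y^*) \,]$ with
  $\alpha = 0.2$ by default. The regularizer is applied *inside* the sum,
  i.e. with effective weight $n\alpha$ — this follows the functional as
  printed in the source material; since the placement could be read either
  way, `alpha_inside = FALSE` exposes the once-only variant for
  sensitivity checks, and the inside form remains the default. Because
  $Y^*$ is a function of $R$, $I(R;Y^*) = H(Y^*)$ and the merge has zero
  superstition by construction.
* the **subjective** common concept maps the symbol tuple
  $Y^{(1)} \times \dots \times Y^{(n)} \to Y^*$, minimizing the
  conditional multi-information $I(Y^{(1)};\dots;Y^{(n)} \mid Y^*)$. It
  sees the world only through the agents' symbols. Tuples with joint
  probability below $10^{-12}$ cannot affect the objective; they are
  assigned a reserved symbol and excluded from proposals, which shrinks
  the search domain from $\prod_i |Y^{(i)}|$ to the populated tuples
  (typically a few dozen for near-deterministic inputs).

Diagnostics: `superstition()` is $H(Y \mid R)$ — representational
information not grounded in the world; `concept_distance()` is the
information distance $H(A|B) + H(B|A)$ through the shared spatial joint,
zero exactly under symbol permutation; `populated_symbols()` counts
symbols with marginal mass above $10^{-9}$.

## Symmetry spectra

An **extrinsic** operation acts on the world as translation ∘ rotation ∘
reflection (reflection along the $y$-axis; anticlockwise rotations in 90°
steps). Its quality for a concept is the equivariance score
$I(Y; Y^\xi)$, where $Y^\xi$ re-reads the *original* conditional at the
transformed position. The spectrum enumerates all $8(2t+1)^2$ operations
with $\max(|x_0|,|y_0|) \le t$ ($t = 5$ for `s+`, $10$ for `sq`) and
normalizes by the maximal utility. Two details are worth noting:

* translated operations push support cells outside the start region; the
  conditional is extended there by direct evaluation (sensor formula or
  propagation), so no operation in the family needs to be dropped;
* the histogram axis could equally be $I(R; Y^\xi)$; both normalization
  modes are implemented (`mode = "state"`), the equivariance form is the
  default, and the choice is recorded in the spectrum metadata.

An **intrinsic** operation is a pair of relabelings of the four sensor and
four action symbols — a re-wiring of the agent's embodiment, not of the
world. The 576 pairs form a group. Each is scored by propagating the
re-wired (never re-optimized) controller and measuring
$I(M^*; M_T^\pi)$ against a deterministic common concept. Because the full
group is always swept, the direction convention of the permutation pair
only relabels the spectrum's entries. "Good" symmetries are the entries
reaching at least 85% (with 82.5% and 87.5% as sensitivity brackets) of
the spectrum maximum; "best" means within relative tolerance $10^{-9}$ of
the maximum, which also absorbs floating-point dust when several
operations are exactly tied.

## Numerical choices and degenerate inputs

* Probability tables validate to sum 1 within $10^{-9}$; probabilities
  below $10^{-12}$ are treated as structural zeros when supports matter.
* Ties in the sensor argmax are exact integer comparisons, never float.
* `|M| = 1` agents, `d = 0` worlds and horizon-0 runs are all valid and
  yield exactly zero utility; an all-zero spectrum refuses to normalize
  rather than dividing by zero.
* A mapping space with a single codomain value has exactly one element;
  proposals degenerate to the identity and annealing returns it.

## Problem sizes used by the test suite

The shipped tests and the acceptance script run the full single-source
scenario (121 start cells, horizon 15) but keep annealing budgets at the
point of diminishing returns observed during development: 12k–20k steps
and 2–3 restarts for agents, 30k steps for common-concept merges, five
seeded replicates for ensemble medians, and a memory-size sweep at
$|M| \in \{2, 8\}$ with two agents per size. These are the package's own
default working sizes; all of them are plain function arguments and can be
scaled up freely.

## What the tests do and do not show

The world is fully synthetic and tiny by design: a smooth gradient field,
noiseless sensing up to exact ties, deterministic dynamics. Passing tests
demonstrate the correctness of the information measures, the exactness of
the propagation, and the reproducibility of the optimization pipeline —
they do not say anything about noisy sensors, stochastic worlds,
continuous space, or agents whose optimization interacts (the merge
deliberately models only the informational *outcome* of agreement, not
its mechanism). Known limitations: annealing optima are ensembles, so any
single run may sit in a local optimum; the objective common concept only
needs pairwise input statistics while the subjective one needs the full
tuple distribution, which grows exponentially in the number of agents
(the zero-tuple pruning keeps the studied scenarios small); and extrinsic
spectra of concepts without an evaluator are limited to operations whose
transformed cells are stored.
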