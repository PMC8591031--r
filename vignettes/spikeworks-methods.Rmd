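---
title: "Modelling with spikeworks: behaviours, pipelines, and guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling with spikeworks: behaviours, pipelines, and guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeworks)
```

## The modelling idea

Most spiking-network simulators trade flexibility for convenience: the
neuron models, plasticity rules and integration schemes they ship are easy
to use and hard to escape. spikeworks takes the opposite bet. A `Network`
holds `NeuronGroup`s and `SynapseGroup`s that are deliberately empty —
a neuron group is a registry of per-neuron state vectors, a synapse group a
registry of weight matrices with `dst$size` rows and `src$size` columns —
and *all* dynamics live in exchangeable behaviour modules. A behaviour has
two hooks: `set_variables()`, called once when the network is initialized,
and `new_iteration()`, called once per time step. Each behaviour is attached
under a positive numeric key; at initialization the keys of every behaviour
across the whole network are sorted into one global execution pipeline, and
a simulation step simply runs that pipeline in order and increments the
iteration counter.

Two consequences of this design carry most of the package's guarantees:

* **Ordering is total and observable.** For keys `k1 < k2`, every per-step
  effect of the first behaviour is visible to the second within the same
  step. Recurrent input, plasticity, homeostasis and recording are ordered
  by giving them higher keys than the neuron model. Keys are numbers, not
  integers, so a module can always be inserted between two existing ones
  (`2.5` between `2` and `3`).
* **Randomness is per-object.** The network owns one root seed; every
  group and behaviour derives an independent stream from the hash of that
  seed and its stable path (group name + key). Adding a recorder — or any
  passive module — therefore never perturbs the dynamical trajectory, which
  the test suite checks bitwise.

Equal keys are a modelling smell; the package resolves them
deterministically by registration order and warns, with an opt-in
`shuffle_ties` flag that shuffles ties from the network seed. We prefer a
reproducible default over a literally random order: a simulation that
cannot be replayed exactly cannot be debugged.

## The reference model

The bundled `example_network("lif")` is the package's reference model and
the network most tests are built from: 100 leaky integrate-and-fire neurons
on a 10 × 10 grid, coupled by one recurrent excitatory synapse group. The
membrane update per step is

$$v \leftarrow \lambda v + \xi + s \cdot (W \mathbf{1}_{spike}), \qquad
\xi \sim U(0, a),$$

with spike when $v > \theta$ followed by reset to 0 (resting and reset
voltages are both zero). Voltages are in arbitrary units; one iteration is
one time unit. Defaults: leak $\lambda = 0.9$, noise bound $a = 0.1$,
threshold $\theta = 0.5$, input strength $s = 0.1$, connection density 0.1
with weights drawn from $U(0,1)$. With a leak of 0.9 and mean noise 0.05
the noise-only equilibrium voltage sits exactly at the threshold, so the
population fires sparsely but never dies out and never saturates; the
defaults were chosen once to produce that regime (mean rate ≈ 0.2
spikes/neuron/step) and the storage tests only assert the wide bracket
(0.01, 0.6).

Internally the leak update is computed in explicit Euler form,
`v + ((leak - 1) * v + noise)`, which is algebraically `leak * v + noise`.
The point of this arithmetic choice is exact interchangeability: the same
model written as an equation string integrates as `v + dt * RHS`, and with
`dt = 1` the two code paths produce bitwise-identical floating point
trajectories. The closed-form decay $v(t) = \lambda^t v(0)$ still holds to
better than $10^{-12}$ absolute error over 1000 steps (the accumulated
rounding is of order $t \cdot \epsilon \cdot v$).

Any scalar parameter can be *diversified*: passing
`leak_factor = "normal(0.9,0.1)"` turns the parameter into one independent
draw per neuron from the behaviour's own stream. The grammar is
`NUMBER | NAME "(" args ")" [";plot"]` with `NAME` one of `uniform`,
`normal`, `lognormal`, `poisson`; a bare `"uniform"` means `uniform(0,1)`,
and custom sampler functions are accepted. The `";plot"` suffix is parsed
and recorded but the core never opens a device; `save_histogram()` in the
storage layer realizes it on demand.

## Recording and tags

Recorders are ordinary behaviours (give them a key above the dynamics so
they see end-of-step state). They evaluate compiled expression strings —
`"n.voltage"`, `"np.mean(n.voltage)"` — every `interval` iterations,
recording at iterations where `iteration %% interval == 0`, counting from
1. The expression language is deliberately tiny: `n.<var>` state access,
`np.<fn>` from a fixed whitelist (`mean`, `sum`, `std`, …, with `np.std`
the population standard deviation), arithmetic and comparisons. Nothing
else resolves; the evaluation environment is built from scratch per
expression, so a recording string can never reach the calling session. The
`np.` surface is kept numpy-flavoured so model strings read like the
computational-neuroscience literature they come from. Recorded values are
snapshots — R's value semantics give this for free, and the suite verifies
that recorded history never aliases live state.

Every recorded expression string doubles as a tag: `net["np.mean(n.voltage)"]`
returns the trace(s) recorded under that expression, through the same
depth-first tag search used for groups and behaviours. Queries are cached
per (root, tag) and invalidated by a structure version counter bumped on
every add/remove; a property test replays 200 random edit/query sequences
and compares every cached answer against a fresh recursive search. Unknown
tags return an empty list rather than an error — exploratory queries should
be safe. `merge_recorders()` replaces redundant recorders on one group by a
single one covering the union of expressions at the gcd of the intervals,
carrying history over so tag queries are uninterrupted.

## Plasticity and homeostasis

The plasticity modules follow the self-organizing recurrent network (SORN)
family of binary-neuron rules:

* **STDP**: $\Delta W_{ij} = \eta\,[s^{dst}_i(t)s^{src}_j(t{-}1) -
  s^{dst}_i(t{-}1)s^{src}_j(t)]$, clipped to `[w_min, w_max]`, with
  structurally absent synapses pinned to zero. The rule is exactly
  antisymmetric under swapping the pre- and postsynaptic trains, and the
  previous-step spike buffers are private to the behaviour, so neuron
  models stay ignorant of plasticity.
* **Synaptic normalization** rescales each neuron's incoming weights so
  their sum over *all* afferent synapse groups equals `norm_target`
  (default 1). Operating at the neuron group rather than per synapse group
  is what keeps the rule well-defined with multiple inputs — and invariant
  under partitioning.
* **Intrinsic plasticity** nudges each threshold by
  $\eta_{ip}(s_i - r_{target})$ per step. With the default LIF noise this
  settles the population rate onto the target; the suite checks ±20 % over
  the final 5000 of 20 000 steps at $\eta_{ip} = 0.01$,
  $r_{target} = 0.05$.
* **Diffusing-messenger homeostasis** is a minimal rendition of
  nitric-oxide-like regulation, not a re-implementation of any published
  model: per-neuron concentration
  $n \leftarrow (1-\lambda)n + \alpha s + D\nabla^2 n$ with a zero-flux
  discrete Laplacian on the group's grid layout, and threshold modulation
  $\eta_{nox}(n - n_{target})$. The reflecting Laplacian is a sum of
  antisymmetric neighbour differences, so with $\lambda = 0$ total
  messenger mass is conserved (checked to $10^{-12}$); stability requires
  $D < 1/(2 \cdot \#axes)$.

The Izhikevich model is included as the second neuron type: Euler at
dt = 1 ms, `v += 0.04 v² + 5v + 140 − u + I`, then `u += a(bv − u)` using
the freshly updated `v` (the convention of the model's published MATLAB
code), spike test `v ≥ 30` before the reset `v ← c, u ← u + d`.

## The equation engine

`parse_equation_set()` accepts one definition per line —
`d<name>/dt = <expr> : <unit>` for integrated states, `<name> = <expr> :
<unit>` for derived quantities — with unit tokens `second`, `volt`, `amp`
(power-of-ten prefixes, `1` for dimensionless) and parameters like
`"10*mV"`. All magnitudes are normalized to SI at parse time. Parsing does
a full dimensional check (every ODE right-hand side must be declared-unit
per second), reports all unresolved symbols at once, and an equation set
that parses can never raise a dimension error at runtime. Integration is
forward Euler only, `x ← x + dt·RHS(x, t)` with all right-hand sides
evaluated on pre-step values (simultaneous-update semantics, verified
against a hand-stepped coupled system); the first-order error is verified
to halve when `dt` halves. Noise enters through the reserved symbol
`xi_uniform(a, b)`, one draw per neuron per step from the behaviour's
stream — that is what lets the equation-defined LIF reproduce the
hand-coded one bitwise. The grammar is versioned with the package; exact
and adaptive integrators are out of scope by design.

## Partitioning

Locally connected networks waste almost all of a dense $D \times S$ weight
matrix. `partition_synapse_group()` cuts the destination grid into
axis-aligned blocks, pairs each with the minimal source block dilated by
the connection reach (the maximum Chebyshev distance over nonzero weights,
`infer_max_distance()` — Chebyshev because dilation is then itself an
axis-aligned box), and replaces the group by one dense sub-group per block
over `SubNeuronGroup` views. Weights are sliced, never recomputed, so
scattering the parts reproduces the original bitwise. Because destination
blocks tile the group exactly, each neuron's afferent sum lives in exactly
one part; the input behaviour accumulates spiking columns left-to-right in
long-double precision, and dropping all-zero columns cannot change any
partial sum — which is why partitioned and unpartitioned simulations agree
bitwise, not just approximately. Behaviours on the original synapse group
are cloned onto every part; normalization stays joint across parts because
it lives on the neuron group. Partition before `initialize_network()`,
with the weight matrix already created.

## Evolutionary parameter search

A simulation script asks for parameters with `get_gene(key, default)` and
reports fitness with `set_score(score)`; standalone it just receives the
defaults, under `evolve()` it receives the active individual's genome —
the same file runs unchanged in both modes. Selection is truncation: the
top `ceiling(survivor_fraction * N)` by score survive each generation
(higher is better; deterministic tie-break by lineage id), re-entering with
their cached score (elitism, so the per-generation best is non-decreasing).
Refill clones uniformly chosen survivors and perturbs each gene
multiplicatively by `exp(N(0, sigma))` — scale-free, which suits rates and
sizes; genes listed as `additive` get a Gaussian step instead, and bounds
clip. Failed evaluations (error, NaN, missing `set_score()`) score `-Inf`
and can never be selected; a fully failed generation aborts with the
history attached. Evaluation is sequential with per-individual derived
seeds; the `workers` setting is advisory — because selection is rank-based
with deterministic tie-breaks, the result is independent of evaluation
order by construction. Distribution across machines is out of scope.

## Storage and the CLI

`create_run()` allocates `Data/<experiment>/run_<k>` folders with
`dir.create()`-atomic index allocation; arrays go into one HDF5 container
per run (bitwise round-trip, including zero-length vectors via a tagged
placeholder), parameters and results into JSON written at full precision,
and `compare_runs()` assembles a sortable one-row-per-run table with
missing values as `NA`. `export_module_graph()` writes the pipeline as DOT:
nodes carry an `order` attribute equal to execution order, and an edge
A → B is drawn when A *declares* a write to a variable B declares it reads
— undeclared access yields a node without edges rather than wrong edges.
The `exec/spikeworks` script wraps `run_example()`, `evolve()` and the
graph export for shell use; images and video export are reduced to arrays
plus the histogram hook.

## Problem sizes and limitations

The test suite and the acceptance script run the study conditions at the
sizes stated throughout: 100-neuron grids for equivalence checks (500
steps), 1000 steps for decay/engine identities, 200 neurons × 20 000 steps
for intrinsic-plasticity convergence, population 20 × 30 generations for
the optimizer, 200 random cases for the tag-cache property.

What passing these tests shows is internal consistency of the machinery —
ordering, determinism, conservation laws, cross-implementation identities —
on synthetic networks whose statistics (independent uniform noise, uniform
random weights, regular grids) are far simpler than biological data. They
say nothing about the biological adequacy of any bundled model. Known
limitations, all deliberate: dense matrices only (partitioning, not sparse
storage, is the answer to locality), forward Euler only, no synaptic
delays or conductances, no recombination in the optimizer, and a
single-process scheduler.
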