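# spikeworks

A modular, behaviour-driven simulator for brain-inspired spiking neural
networks in R.

Most simulation environments make the common cases convenient and the
uncommon ones painful: exploring a novel plasticity rule or an unusual
update order means either fighting the framework or writing a simulator
from scratch. spikeworks keeps the framework minimal instead. A `Network`
contains `NeuronGroup`s and `SynapseGroup`s that are *empty shells* — a
neuron group is a registry of per-neuron state vectors, a synapse group a
registry of weight matrices with `dst × src` shape — and every piece of
dynamics is a user-exchangeable **behaviour module** with two hooks
(`set_variables()` at initialization, `new_iteration()` each step),
scheduled by a positive numeric key into one globally sorted execution
pipeline.

On top of that scaffold the package provides:

* a **behaviour library**: leaky integrate-and-fire and Izhikevich neuron
  models, recurrent synaptic input, refractory periods, SORN-style
  spike-timing-dependent plasticity
  (`ΔW_ij = η[s_i(t)s_j(t−1) − s_i(t−1)s_j(t)]`), joint afferent weight
  normalization, intrinsic plasticity
  (`θ ← θ + η_ip(s − r_target)`), and diffusing-messenger homeostasis on a
  spatial grid;
* **diversification strings** — any scalar parameter written as e.g.
  `"normal(0.9,0.1)"` becomes an independent per-neuron draw;
* **recorders** driven by compiled expression strings
  (`"np.mean(n.voltage)"`) that double as tags, and a cached **tag system**
  (`net["my_tag"]`) for retrieving any object in the network tree;
* an **equation engine**: `dv/dt = -v/tau : volt` strings with physical
  units, dimensional checking and forward-Euler integration, wrappable
  into a behaviour with threshold/reset semantics;
* **partitioning** of large, sparse, locally connected synapse groups into
  dense per-block groups over masked subgroup views — bitwise equivalent
  to the unpartitioned simulation;
* an **evolutionary optimizer** built on the `get_gene(key, default)` /
  `set_score(score)` contract, with truncation selection, elitism and
  log-normal mutation;
* a **storage manager** (`Data/<experiment>/run_<k>/` folders, HDF5 arrays,
  JSON parameters, run comparison tables), DOT export of the module
  pipeline, and a thin CLI (`exec/spikeworks`).

Everything is deterministic from one root seed: each group and behaviour
derives an independent RNG stream from the hash of the seed and its stable
path, so adding a recorder never changes the trajectory.

## Worked example

A 10 × 10 grid of LIF neurons with one recurrent excitatory synapse group.
The neuron model runs at key 1, synaptic input at key 2, recording at
key 9; each step does `v ← 0.9·v + U(0, 0.1) + 0.1·(W s)`, spikes where
`v > 0.5`, and resets spiking neurons to 0.

```r
library(spikeworks)

net <- Network$new(seed = 42)
ng <- net$add_neuron_group(100, name = "exc", behaviours = list(
  `1` = lif_behaviour(threshold = 0.5, leak_factor = 0.9,
                      noise_amplitude = 0.1),
  `2` = synaptic_input_behaviour(strength = 0.1),
  `9` = recorder(c("n.voltage", "np.mean(n.voltage)", "n.spike"))))
attach_spatial_layout(ng, 10, 10, 1)
sg <- net$add_synapse_group(ng, ng, name = "exc_exc", tags = "glutamate")
sg$new_mat("W", spec = "uniform", density = 0.1)

net$initialize_network()
net$simulate_iterations(1000)

spikes <- as.matrix(net["n.spike"][[1]])      # recorded trace, by tag
sprintf("mean firing rate: %.4f", mean(spikes))
#> [1] "mean firing rate: 0.2169"
mv <- as.numeric(net["np.mean(n.voltage)"][[1]])
sprintf("mean voltage over the last 100 steps: %.4f", mean(tail(mv, 100)))
#> [1] "mean voltage over the last 100 steps: 0.3380"
sum(spikes[1000, ])    # neurons active in the final step
#> [1] 25
```

About a fifth of the population fires in any step — sparse, sustained
recurrent activity: the noise alone holds the average voltage near the
0.5 threshold, recurrent input pushes individual neurons over it, and the
reset keeps the rate from running away. The recording strings are also
tags: `net["np.mean(n.voltage)"]` returns the recorded mean-voltage trace,
the same way `net["glutamate"]` returns the tagged synapse group. To make
the leak heterogeneous across neurons, change one argument:
`lif_behaviour(leak_factor = "normal(0.9,0.1)")`.

The same model can be written as equations and integrates bitwise
identically:

```r
equation_behaviour(
  "dv/dt = ((leak - 1) * v + xi_uniform(0, 0.1)) / tau : 1",
  parameters = list(leak = 0.9, tau = "1*second"),
  threshold = "v > 0.5", reset = "v = 0", dt = 1)
```

Bundled variants are available as one-liners:
`run_example("lif")`, `run_example("sorn")` (adds STDP + normalization +
intrinsic plasticity), `run_example("izhikevich")`, or from the shell:

```sh
exec/spikeworks run-example lif --steps 1000 --seed 42 --size 10,10,1
```

See `vignette("spikeworks-methods")` for the model definitions, parameter
meanings, numerical choices and design rationale.

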