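# Bundled example networks. The "lif" example is the package's worked
# reference model: a 10 x 10 grid of leaky integrate-and-fire neurons with
# one recurrent excitatory synapse group, uniform membrane noise, and
# recorders for the voltage vector and its mean.

#' Build a bundled example network
#'
#' @description
#' Three ready-made models:
#'
#' * `"lif"` — 100 LIF neurons on a `width x height x depth` grid with one
#'   recurrent excitatory synapse group (`density` connectivity, uniform
#'   weights), leak 0.9, uniform noise U(0, 0.1), threshold 0.5, input
#'   strength 0.1. Pipeline: neuron model (key 1), synaptic input (key 2),
#'   recorders (key 9) for `"n.voltage"`, `"np.mean(n.voltage)"` and
#'   `"n.spike"`. The defaults give sparse, sustained recurrent spiking.
#' * `"izhikevich"` — 100 regular-spiking Izhikevich neurons driven by a
#'   constant 10 mV/ms input current, with spike recorder.
#' * `"sorn"` — the LIF example plus SORN-style plasticity: STDP on the
#'   recurrent weights (key 3), joint afferent weight normalization (key 4)
#'   and intrinsic plasticity (key 5).
#'
#' @param name `"lif"`, `"izhikevich"`, or `"sorn"`.
#' @param seed network seed.
#' @param size grid dimensions `c(width, height, depth)` (default 10,10,1).
#' @param record extra recording expressions (character vector).
#' @param density recurrent connection density (default 0.1).
#' @param leak_factor LIF leak (scalar or diversification string).
#' @return an uninitialized [Network] with tags `"example"` and `name`.
#' @export
example_network <- function(name = c("lif", "izhikevich", "sorn"),
                            seed = 42, size = c(10, 10, 1),
                            record = character(0), density = 0.1,
                            leak_factor = 0.9) {
  name <- match.arg(name)
  size <- rep(as.integer(size), length.out = 3)
  n <- prod(size)
  net <- Network$new(seed = seed, tags = c("example", name))

  if (name == "izhikevich") {
    ng <- net$add_neuron_group(
      n, name = "exc",
      behaviours = list(
        `1` = izhikevich_behaviour(I = 10),
        `9` = recorder(unique(c("n.v", "np.mean(n.v)", "n.spike", record)))))
    attach_spatial_layout(ng, size[1], size[2], size[3])
    return(net)
  }

  behs <- list(
    `1` = lif_behaviour(threshold = 0.5, leak_factor = leak_factor,
                        noise_amplitude = 0.1),
    `2` = synaptic_input_behaviour(strength = 0.1),
    `9` = recorder(unique(c("n.voltage", "np.mean(n.voltage)", "n.spike",
                            record))))
  if (name == "sorn") {
    behs$`4` <- normalization_behaviour(norm_target = 1)
    behs$`5` <- ip_behaviour(eta_ip = 0.001, target_rate = 0.1)
  }
  ng <- net$add_neuron_group(n, name = "exc", tags = "excitatory",
                             behaviours = behs)
  attach_spatial_layout(ng, size[1], size[2], size[3])
  sg <- net$add_synapse_group(ng, ng, name = "exc_exc", tags = "glutamate")
  sg$new_mat("W", spec = "uniform", density = density)
  if (name == "sorn") {
    sg$add_behaviour(3, stdp_behaviour(eta_stdp = 0.001, w_min = 0, w_max = 1))
  }
  net
}

#' Run a bundled example and store its results
#'
#' Builds [example_network()], simulates it, and (optionally) saves the
#' recorded traces, the run parameters and summary results through the
#' storage manager. This is the engine behind the `run-example` CLI command.
#'
#' @param name example name (see [example_network()]).
#' @param steps iterations to simulate (default 1000).
#' @param seed network seed (default 42).
#' @param size grid dimensions `c(width, height, depth)`.
#' @param record extra recording expressions.
#' @param experiment storage experiment name; `NULL` (default) skips saving.
#' @param root storage data root (default "Data").
#' @return list with `network`, `mean_rate` (mean spike probability per
#'   neuron per step), `mean_voltage_trace`, and `run` (the storage folder or
#'   NULL).
#' @export
run_example <- function(name = "lif", steps = 1000, seed = 42,
                        size = c(10, 10, 1), record = character(0),
                        experiment = NULL, root = "Data") {
  net <- example_network(name, seed = seed, size = size, record = record)
  net$initialize_network()
  net$simulate_iterations(steps)

  spike_trace <- find_by_tag(net, "n.spike")[[1]]
  spikes <- as.matrix(spike_trace)
  mean_rate <- mean(spikes)
  vexpr <- if (name == "izhikevich") "np.mean(n.v)" else "np.mean(n.voltage)"
  mean_v <- as.numeric(find_by_tag(net, vexpr)[[1]])

  run <- NULL
  if (!is.null(experiment)) {
    run <- create_run(experiment, root = root)
    save_parameters(run, list(example = name, steps = steps, seed = seed,
                              width = size[1], height = size[2],
                              depth = size[3]))
    save_array(run, "spikes", spikes)
    save_array(run, "mean_voltage", mean_v)
    vtag <- if (name == "izhikevich") "n.v" else "n.voltage"
    save_array(run, "voltage", find_by_tag(net, vtag)[[1]])
    save_results(run, list(mean_rate = mean_rate))
    export_module_graph(net, file.path(run$path, "modules.dot"))
  }
  list(network = net, mean_rate = mean_rate, mean_voltage_trace = mean_v,
       run = run)
}
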