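# Shared builders for the test suite. Everything is generated in code from
# fixed seeds; no fixture files.

# A behaviour that appends a label to a shared log each step.
log_probe <- function(log, label) {
  behaviour(step = function(self, parent) {
    log$calls <- c(log$calls, label)
  })
}

# Chebyshev neighbour connectivity on a w x h grid: weight `w0` between any
# two distinct neurons at grid distance <= reach.
grid_neighbour_matrix <- function(x, y, reach = 1, w0 = 0.1) {
  n <- length(x)
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  cheb <- pmax(dx, dy)
  W <- matrix(0, n, n)
  W[cheb <= reach & cheb > 0] <- w0
  W
}

# The reference recurrent LIF grid used by several tests: 10 x 10 neurons,
# neighbour connectivity, neuron model key 1, input key 2, recorder key 9.
build_lif_grid <- function(seed = 11, steps_key_recorder = TRUE,
                           noise_amplitude = 0.1, threshold = 0.5) {
  net <- Network$new(seed = seed)
  behs <- list(
    `1` = lif_behaviour(threshold = threshold, leak_factor = 0.9,
                        noise_amplitude = noise_amplitude),
    `2` = synaptic_input_behaviour(strength = 0.1))
  if (steps_key_recorder) behs$`9` <- recorder("n.voltage")
  ng <- net$add_neuron_group(100, name = "exc", behaviours = behs)
  attach_spatial_layout(ng, 10, 10, 1)
  sg <- net$add_synapse_group(ng, ng, name = "rec")
  sg$adopt_mat("W", grid_neighbour_matrix(ng$get("x"), ng$get("y")))
  list(net = net, ng = ng, sg = sg)
}

# Scripted spiking: the group's spike vector follows the rows of `pattern`
# (logical matrix, one row per iteration), then stays silent.
scripted_spikes <- function(pattern) {
  behaviour(
    setup = function(self, parent) {
      parent$set("spike", rep(FALSE, parent$size))
      self$state <- pattern
    },
    step = function(self, parent) {
      it <- self$network$iteration
      s <- if (it <= nrow(self$state)) self$state[it, ] else rep(FALSE, parent$size)
      parent$set("spike", as.logical(s))
    })
}

# Run a src->dst pair with scripted spike trains under STDP and return the
# resulting weight change matrix (dst x src).
make_stdp_pair <- function(src_pattern, dst_pattern, eta = 0.01,
                           w0 = 0.5, w_min = 0, w_max = 1) {
  net <- Network$new(seed = 1)
  src <- net$add_neuron_group(ncol(src_pattern), name = "src", behaviours = list(
    `1` = scripted_spikes(src_pattern)))
  dst <- net$add_neuron_group(ncol(dst_pattern), name = "dst", behaviours = list(
    `2` = scripted_spikes(dst_pattern)))
  sg <- net$add_synapse_group(src, dst, name = "s")
  sg$adopt_mat("W", matrix(w0, ncol(dst_pattern), ncol(src_pattern)))
  sg$add_behaviour(5, stdp_behaviour(eta_stdp = eta, w_min = w_min, w_max = w_max))
  net$initialize_network()
  net$simulate_iterations(nrow(src_pattern))
  sg$get_mat("W") - w0
}
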