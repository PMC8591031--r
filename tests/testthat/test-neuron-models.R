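test_that("noise-free LIF follows the closed-form geometric decay", {
  net <- Network$new(seed = 7)
  ng <- net$add_neuron_group(10, name = "exc", behaviours = list(
    `1` = lif_behaviour(threshold = 10, leak_factor = 0.9,
                        noise_amplitude = 0, v_init = 0.4)))
  net$initialize_network()
  err <- 0
  for (t in 1:1000) {
    net$simulate_iterations(1)
    err <- max(err, max(abs(ng$get("voltage") - 0.4 * 0.9^t)))
  }
  expect_lt(err, 1e-12)
  expect_false(any(ng$get("spike")))
})

test_that("a suprathreshold voltage spikes once and resets to zero", {
  net <- Network$new(seed = 7)
  ng <- net$add_neuron_group(1, name = "exc", behaviours = list(
    `1` = lif_behaviour(threshold = 0.5, leak_factor = 0.9,
                        noise_amplitude = 0, v_init = 0.6)))
  net$initialize_network()
  net$simulate_iterations(1)           # 0.54 > 0.5 -> spike, reset
  expect_true(ng$get("spike"))
  expect_equal(ng$get("voltage"), 0)
  net$simulate_iterations(1)
  expect_false(ng$get("spike"))
})

test_that("diversified leak factors give per-neuron decay rates", {
  net <- Network$new(seed = 7)
  ng <- net$add_neuron_group(2, name = "exc", behaviours = list(
    `1` = lif_behaviour(threshold = 10, leak_factor = c(0.8, 0.95),
                        noise_amplitude = 0, v_init = 1)))
  net$initialize_network()
  net$simulate_iterations(20)
  expect_equal(ng$get("voltage"), c(0.8^20, 0.95^20), tolerance = 1e-12)

  # a distribution string yields heterogeneous values
  net2 <- Network$new(seed = 7)
  ng2 <- net2$add_neuron_group(1000, name = "exc", behaviours = list(
    `1` = lif_behaviour(leak_factor = "normal(0.9,0.01)", noise_amplitude = 0)))
  suppressWarnings(net2$initialize_network())
  leaks <- ng2$behaviours[[1]]$leak
  expect_length(unique(leaks), 1000)
  expect_lt(abs(mean(leaks) - 0.9), 0.01)
})

test_that("synaptic input adds strength * W %*% spikes to the destination", {
  net <- Network$new(seed = 1)
  src <- net$add_neuron_group(3, name = "src", behaviours = list(
    `1` = scripted_spikes(rbind(c(TRUE, FALSE, TRUE)))))
  dst <- net$add_neuron_group(1, name = "dst", behaviours = list(
    `2` = behaviour(setup = function(self, parent) parent$set("voltage", 0)),
    `3` = synaptic_input_behaviour(strength = 0.1)))
  sg <- net$add_synapse_group(src, dst, name = "s")
  sg$adopt_mat("W", matrix(1, 1, 3))
  net$initialize_network()
  net$simulate_iterations(1)
  expect_equal(dst$get("voltage"), 0.2)   # 0.1 * (1 + 1)
  net$simulate_iterations(1)              # no spikes -> unchanged
  expect_equal(dst$get("voltage"), 0.2)
})

test_that("contributions from several afferent groups sum", {
  net <- Network$new(seed = 1)
  a <- net$add_neuron_group(2, name = "a", behaviours = list(
    `1` = scripted_spikes(rbind(c(TRUE, TRUE)))))
  b <- net$add_neuron_group(2, name = "b", behaviours = list(
    `1.5` = scripted_spikes(rbind(c(TRUE, FALSE)))))   # non-integer keys sort too
  d <- net$add_neuron_group(1, name = "d", behaviours = list(
    `2` = behaviour(setup = function(self, parent) parent$set("voltage", 0)),
    `3` = synaptic_input_behaviour(strength = 1)))
  net$add_synapse_group(a, d, name = "ad")$adopt_mat("W", matrix(c(0.3, 0.4), 1, 2))
  net$add_synapse_group(b, d, name = "bd")$adopt_mat("W", matrix(c(0.5, 9), 1, 2))
  net$initialize_network()
  net$simulate_iterations(1)
  expect_equal(d$get("voltage"), 0.3 + 0.4 + 0.5)
  # missing matrix is reported with the synapse group's name
  net2 <- Network$new(seed = 1)
  s2 <- net2$add_neuron_group(1, name = "s2", behaviours = list(
    `1` = scripted_spikes(matrix(TRUE, 1, 1))))
  d2 <- net2$add_neuron_group(1, name = "d2", behaviours = list(
    `2` = behaviour(setup = function(self, parent) parent$set("voltage", 0)),
    `3` = synaptic_input_behaviour()))
  net2$add_synapse_group(s2, d2, name = "naked")
  expect_error(net2$initialize_network(), "naked")
})

test_that("refractory period forces the documented spike pattern", {
  drive <- function(refractory_steps, n_steps) {
    net <- Network$new(seed = 1)
    ng <- net$add_neuron_group(1, name = "n", behaviours = list(
      `1` = behaviour(
        setup = function(self, parent) {
          parent$set("voltage", 0); parent$set("spike", FALSE)
        },
        step = function(self, parent) {
          parent$set("voltage", 1); parent$set("spike", TRUE)
        }),
      `2` = refractory_behaviour(refractory_steps),
      `9` = recorder("n.spike")))
    net$initialize_network()
    net$simulate_iterations(n_steps)
    as.numeric(find_by_tag(net, "n.spike")[[1]])
  }
  expect_equal(drive(2, 9), rep(c(1, 0, 0), 3))
  expect_equal(drive(3, 8), c(1, 0, 0, 0, 1, 0, 0, 0))
  expect_error(refractory_behaviour(-1), ">= 0")
})

test_that("refractory_steps = 0 leaves the dynamics bitwise unchanged", {
  run <- function(with_refractory) {
    net <- Network$new(seed = 31)
    behs <- list(`1` = lif_behaviour())
    if (with_refractory) behs$`2` <- refractory_behaviour(0)
    ng <- net$add_neuron_group(50, name = "exc", behaviours = behs)
    net$initialize_network()
    net$simulate_iterations(200)
    ng$get("voltage")
  }
  expect_identical(run(TRUE), run(FALSE))
})

test_that("Izhikevich dynamics: rest, regular spiking, reset semantics", {
  # I = 0 from the resting parameter set: bounded, no spikes
  net <- Network$new(seed = 1)
  ng <- net$add_neuron_group(1, name = "iz", behaviours = list(
    `1` = izhikevich_behaviour(I = 0), `9` = recorder("n.v")))
  net$initialize_network()
  net$simulate_iterations(1000)
  v <- vapply(find_by_tag(net, "n.v")[[1]]$values, identity, numeric(1))
  expect_false(any(v >= 30))
  expect_true(all(abs(v) < 100))

  # regular-spiking set with I = 10 fires within 1000 steps
  net2 <- Network$new(seed = 1)
  ng2 <- net2$add_neuron_group(1, name = "iz", behaviours = list(
    `1` = izhikevich_behaviour(a = 0.02, b = 0.2, c = -65, d = 8, I = 10),
    `9` = recorder("n.spike")))
  net2$initialize_network()
  net2$simulate_iterations(1000)
  expect_gt(sum(as.numeric(find_by_tag(net2, "n.spike")[[1]])), 0)

  # an immediate forced spike (huge I, a = 0 so u has no intrinsic drift):
  # with d = 0 the reset leaves u untouched, with d = 8 it jumps by 8
  spike_u <- function(d) {
    net3 <- Network$new(seed = 1)
    ng3 <- net3$add_neuron_group(1, name = "iz", behaviours = list(
      `1` = izhikevich_behaviour(a = 0, d = d, I = 200)))
    net3$initialize_network()
    net3$simulate_iterations(1)
    expect_true(ng3$get("spike"))
    ng3$get("u")
  }
  u0 <- 0.2 * -65   # b * v0
  expect_equal(spike_u(0), u0)
  expect_equal(spike_u(8), u0 + 8)
})
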