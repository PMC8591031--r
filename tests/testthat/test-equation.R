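test_that("units parse with prefixes and dimensional algebra holds", {
  expect_equal(parse_quantity("10*mV")$magnitude, 0.01)
  expect_equal(parse_quantity("10*ms")$magnitude, 0.01)
  expect_equal(parse_quantity("2*nA")$magnitude, 2e-9)
  expect_equal(parse_quantity(3)$dim, c(0, 0, 0, 0))
  expect_error(parse_unit("furlong"), "unknown unit")
  # volt/second consistency of a leaky ODE
  eqs <- parse_equation_set("dv/dt = -v/tau : volt",
                            parameters = list(tau = "10*ms"))
  expect_length(eqs$odes, 1)
  # ampere cannot join a volt/second right-hand side
  expect_error(
    parse_equation_set("dv/dt = -v/tau + I : volt",
                       parameters = list(tau = "10*ms", I = "1*mA")),
    "dimension mismatch")
  # unresolved symbols are reported together
  expect_error(
    parse_equation_set("dv/dt = -v/tau + foo + bar : volt",
                       parameters = list(tau = "10*ms")),
    "foo.*bar|bar.*foo")
  # syntax errors carry the line number
  expect_error(parse_equation_set("dv/dt == -v : volt"), "line 1")
})

test_that("an empty equation set steps as a no-op", {
  eqs <- parse_equation_set("")
  expect_length(eqs$odes, 0)
  st <- euler_step(eqs, list(), Clock$new(1))
  expect_identical(st, list())
})

test_that("Euler integration is exact for the geometric decay step", {
  eqs <- parse_equation_set("dv/dt = -v/tau : volt",
                            parameters = list(tau = "10*ms"))
  clock <- Clock$new("1*ms")
  v <- 1
  for (i in 1:100) {
    v <- euler_step(eqs, list(v = v), clock, n = 1)$v
    clock$advance()
  }
  expect_equal(v, 0.9^100, tolerance = 1e-13)
  expect_equal(clock$t, 0.1, tolerance = 1e-12)
})

test_that("halving dt halves the Euler error against the exponential", {
  err_at <- function(dt_ms) {
    eqs <- parse_equation_set("dv/dt = -v/tau : volt",
                              parameters = list(tau = "10*ms"))
    clock <- Clock$new(sprintf("%g*ms", dt_ms))
    v <- 1
    maxerr <- 0
    for (i in seq_len(round(10 / dt_ms))) {   # 10 ms horizon
      v <- euler_step(eqs, list(v = v), clock, n = 1)$v
      clock$advance()
      maxerr <- max(maxerr, abs(v - exp(-clock$t / 0.01)))
    }
    maxerr
  }
  ratio <- err_at(0.1) / err_at(0.05)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("coupled ODEs update simultaneously from pre-step values", {
  eqs <- parse_equation_set(
    "dx/dt = y / tau : 1\ndy/dt = -x / tau : 1",
    parameters = list(tau = "1*second"))
  clock <- Clock$new(0.1)
  st <- list(x = 1, y = 0)
  # hand-stepped oracle of the same 2x2 linear system
  ox <- 1; oy <- 0
  for (i in 1:50) {
    st <- euler_step(eqs, st, clock, n = 1)
    clock$advance()
    tmp <- ox + 0.1 * oy
    oy <- oy + 0.1 * (-ox)
    ox <- tmp
  }
  expect_equal(st$x, ox, tolerance = 1e-14)
  expect_equal(st$y, oy, tolerance = 1e-14)
})

test_that("non-finite integration aborts with the state name", {
  eqs <- parse_equation_set("dv/dt = v * v / tau : 1",
                            parameters = list(tau = "1*second"))
  clock <- Clock$new(1)
  v <- 1e200
  expect_error(euler_step(eqs, list(v = v), clock, n = 1), "'v'")
})

test_that("equation-defined LIF matches the hand-coded behaviour bitwise", {
  run_hand <- function() {
    net <- Network$new(seed = 5)
    net$add_neuron_group(50, name = "exc", behaviours = list(
      `1` = lif_behaviour(threshold = 0.5, leak_factor = 0.9,
                          noise_amplitude = 0.1),
      `9` = recorder("n.voltage")))
    net$initialize_network()
    net$simulate_iterations(1000)
    as.matrix(find_by_tag(net, "n.voltage")[[1]])
  }
  run_eq <- function() {
    net <- Network$new(seed = 5)
    net$add_neuron_group(50, name = "exc", behaviours = list(
      `1` = equation_behaviour(
        "dv/dt = ((leak - 1) * v + xi_uniform(0, 0.1)) / tau : 1",
        parameters = list(leak = 0.9, tau = "1*second"),
        threshold = "v > 0.5", reset = "v = 0", dt = 1),
      `9` = recorder("n.v")))
    net$initialize_network()
    net$simulate_iterations(1000)
    as.matrix(find_by_tag(net, "n.v")[[1]])
  }
  expect_identical(run_hand(), run_eq())
})

test_that("threshold/reset wiring matches LIF semantics; pure ODEs skip spikes", {
  net <- Network$new(seed = 2)
  ng <- net$add_neuron_group(1, name = "g", behaviours = list(
    `1` = equation_behaviour(
      "dv/dt = drive / tau : 1",
      parameters = list(drive = 0.3, tau = "1*second"),
      init = list(v = 0),
      threshold = "v > 0.5", reset = "v = 0", dt = 1)))
  net$initialize_network()
  net$simulate_iterations(2)   # 0.3, 0.6 -> spike, reset
  expect_true(ng$get("spike"))
  expect_equal(ng$get("v"), 0)

  net2 <- Network$new(seed = 2)
  ng2 <- net2$add_neuron_group(1, name = "g", behaviours = list(
    `1` = equation_behaviour("dv/dt = drive / tau : 1",
                             parameters = list(drive = 0.3, tau = "1*second"),
                             dt = 1)))
  net2$initialize_network()
  net2$simulate_iterations(3)
  expect_false(ng2$has("spike"))
  expect_equal(ng2$get("v"), 0.9, tolerance = 1e-14)

  expect_error(
    equation_behaviour("dv/dt = -v/tau : 1",
                       parameters = list(tau = "1*second"),
                       threshold = "v > 1", reset = "w = 0"),
    "not an integrated state")
})
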