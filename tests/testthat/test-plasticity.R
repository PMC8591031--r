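test_that("STDP potentiates pre-before-post and depresses post-before-pre", {
  pre_then_post <- make_stdp_pair(
    src_pattern = rbind(TRUE, FALSE),
    dst_pattern = rbind(FALSE, TRUE))
  expect_equal(pre_then_post[1, 1], 0.01)

  post_then_pre <- make_stdp_pair(
    src_pattern = rbind(FALSE, TRUE),
    dst_pattern = rbind(TRUE, FALSE))
  expect_equal(post_then_pre[1, 1], -0.01)

  silent <- make_stdp_pair(
    src_pattern = rbind(FALSE, FALSE),
    dst_pattern = rbind(FALSE, FALSE))
  expect_equal(silent[1, 1], 0)
})

test_that("swapping pre/post spike trains negates the weight change exactly", {
  set.seed(42)
  for (case in 1:5) {
    A <- matrix(runif(20) < 0.4, 10, 2)
    B <- matrix(runif(30) < 0.4, 10, 3)
    # W starts mid-range so clipping never engages; dst x src orientation
    dW_fwd <- make_stdp_pair(A, B, eta = 0.001, w0 = 0.5)
    dW_rev <- make_stdp_pair(B, A, eta = 0.001, w0 = 0.5)
    expect_equal(dW_fwd, -t(dW_rev), tolerance = 1e-15)
  }
})

test_that("STDP respects clip bounds and the structural mask", {
  dW <- make_stdp_pair(rbind(TRUE, FALSE), rbind(FALSE, TRUE),
                       eta = 0.5, w0 = 0.9, w_max = 1)
  expect_equal(dW[1, 1], 0.1)   # clipped at w_max = 1

  net <- Network$new(seed = 2)
  src <- net$add_neuron_group(50, name = "src", behaviours = list(
    `1` = lif_behaviour()))
  sg <- net$add_synapse_group(src, src, name = "rec")
  sg$new_mat("W", "uniform", density = 0.2)
  sg$add_behaviour(5, stdp_behaviour(eta_stdp = 0.05))
  absent <- !sg$enabled
  net$initialize_network()
  net$simulate_iterations(300)
  expect_true(all(sg$get_mat("W")[absent] == 0))
})

test_that("normalization rescales rows to the target, jointly across groups", {
  net <- Network$new(seed = 1)
  a <- net$add_neuron_group(3, name = "a")
  b <- net$add_neuron_group(2, name = "b")
  d <- net$add_neuron_group(3, name = "d")
  s1 <- net$add_synapse_group(a, d, name = "s1")
  s2 <- net$add_synapse_group(b, d, name = "s2")
  # neuron 1: already normalized within s1; neuron 2: sums 0.3 + 0.7 across
  # the two groups; neuron 3: all-zero row stays untouched
  s1$adopt_mat("W", rbind(c(0.2, 0.6, 0.2), c(0.1, 0.1, 0.1), c(0, 0, 0)))
  s2$adopt_mat("W", rbind(c(0, 0), c(0.4, 0.3), c(0, 0)))
  net$initialize_network()
  normalize_afferent(d, norm_target = 1)
  W1 <- s1$get_mat("W"); W2 <- s2$get_mat("W")
  expect_equal(W1[1, ], c(0.2, 0.6, 0.2))
  joint <- rowSums(W1) + rowSums(W2)
  expect_equal(joint[1:2], c(1, 1), tolerance = 1e-12)
  expect_equal(joint[3], 0)
  # both groups share one scale factor (cross-group, not per-group)
  expect_equal(rowSums(W1)[2] / 0.3, rowSums(W2)[2] / 0.7, tolerance = 1e-12)

  # a [1,1] row halves to [0.5, 0.5]
  net2 <- Network$new(seed = 1)
  p <- net2$add_neuron_group(2, name = "p")
  q <- net2$add_neuron_group(1, name = "q")
  sq <- net2$add_synapse_group(p, q, name = "sq")
  sq$adopt_mat("W", matrix(c(1, 1), 1, 2))
  net2$initialize_network()
  normalize_afferent(q, 1)
  expect_equal(sq$get_mat("W")[1, ], c(0.5, 0.5))

  # negative weights: normalized by the sum of values, with a warning
  sq$set_mat("W", matrix(c(-0.5, 1.5), 1, 2))
  expect_warning(normalize_afferent(q, 1), "negative")
  expect_equal(sum(sq$get_mat("W")), 1, tolerance = 1e-12)
})

test_that("intrinsic plasticity moves thresholds against the rate error", {
  step_ip <- function(spike_value, n = 10) {
    net <- Network$new(seed = 1)
    ng <- net$add_neuron_group(1, name = "g", behaviours = list(
      `1` = behaviour(
        setup = function(self, parent) {
          parent$set("spike", spike_value)
          parent$set("threshold", 0.5)
        }),
      `2` = ip_behaviour(eta_ip = 0.01, target_rate = 0.1)))
    net$initialize_network()
    net$simulate_iterations(n)
    ng$get("threshold")
  }
  expect_equal(step_ip(TRUE), 0.5 + 10 * 0.01 * 0.9, tolerance = 1e-12)
  expect_equal(step_ip(FALSE), 0.5 - 10 * 0.01 * 0.1, tolerance = 1e-12)

  frozen <- function() {
    net <- Network$new(seed = 1)
    ng <- net$add_neuron_group(20, name = "g", behaviours = list(
      `1` = lif_behaviour(),
      `2` = ip_behaviour(eta_ip = 0, target_rate = 0.1)))
    net$initialize_network()
    net$simulate_iterations(50)
    ng$get("threshold")
  }
  expect_equal(frozen(), rep(0.5, 20))
})

test_that("diffusing homeostasis conserves mass and respects symmetry", {
  # silent network, no diffusion/decay: thresholds drift down at the
  # documented rate, messenger stays zero
  net <- Network$new(seed = 1)
  ng <- net$add_neuron_group(100, name = "g", behaviours = list(
    `1` = behaviour(setup = function(self, parent) {
      parent$set("spike", rep(FALSE, parent$size))
      parent$set("threshold", rep(1, parent$size))
    }),
    `2` = nox_behaviour(production = 1, diffusion = 0, decay = 0,
                        eta_nox = 0.01, nox_target = 0.2)))
  attach_spatial_layout(ng, 10, 10, 1)
  net$initialize_network()
  net$simulate_iterations(50)
  expect_equal(ng$get("nox"), rep(0, 100))
  expect_equal(ng$get("threshold"), rep(1 - 50 * 0.01 * 0.2, 100),
               tolerance = 1e-12)

  # a single centre spike diffuses; total mass conserved without decay
  net2 <- Network$new(seed = 1)
  centre <- rep(FALSE, 100); centre[45] <- TRUE
  ng2 <- net2$add_neuron_group(100, name = "g", behaviours = list(
    `1` = scripted_spikes(matrix(centre, 1, 100)),
    `2` = nox_behaviour(production = 1, diffusion = 0.2, decay = 0,
                        eta_nox = 0)))
  attach_spatial_layout(ng2, 10, 10, 1)
  net2$initialize_network()
  net2$simulate_iterations(1)
  expect_equal(sum(ng2$get("nox")), 1)
  net2$simulate_iterations(200)
  expect_lt(abs(sum(ng2$get("nox")) - 1), 1e-12)
  expect_gt(min(ng2$get("nox")), 0)   # it actually spread

  # uniform spiking keeps the field spatially uniform
  net3 <- Network$new(seed = 1)
  ng3 <- net3$add_neuron_group(100, name = "g", behaviours = list(
    `1` = behaviour(setup = function(self, parent)
      parent$set("spike", rep(TRUE, parent$size))),
    `2` = nox_behaviour(production = 0.5, diffusion = 0.2, decay = 0.05,
                        eta_nox = 0)))
  attach_spatial_layout(ng3, 10, 10, 1)
  net3$initialize_network()
  net3$simulate_iterations(30)
  expect_lt(diff(range(ng3$get("nox"))), 1e-12)

  # missing layout is rejected
  net4 <- Network$new(seed = 1)
  net4$add_neuron_group(4, name = "flat", behaviours = list(
    `1` = nox_behaviour()))
  expect_error(net4$initialize_network(), "spatial layout")
})
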