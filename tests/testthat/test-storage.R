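test_that("run folders allocate strictly increasing, collision-free indices", {
  td <- tempfile("data"); dir.create(td)
  r0 <- create_run("exp", root = td)
  r1 <- create_run("exp", root = td)
  r2 <- create_run("exp", root = td)
  expect_equal(c(r0$index, r1$index, r2$index), 0:2)
  expect_true(all(dir.exists(c(r0$path, r1$path, r2$path))))
  # racing allocations from two processes still get distinct indices
  take <- function(root) {
    spikeworks::create_run("race", root = root)$index
  }
  idx <- unlist(parallel::mclapply(1:4, function(i) take(td), mc.cores = 2))
  expect_equal(anyDuplicated(idx), 0)
})

test_that("arrays round-trip bitwise through the HDF5 container", {
  td <- tempfile("data"); dir.create(td)
  run <- create_run("exp", root = td)
  set.seed(1)
  m <- matrix(rnorm(100 * 100), 100, 100)
  save_array(run, "m", m)
  expect_identical(load_array(run, "m"), m)
  v <- rnorm(37)
  save_array(run, "v", v)
  expect_identical(load_array(run, "v"), v)
  save_array(run, "none", numeric(0))
  expect_identical(load_array(run, "none"), numeric(0))
  expect_error(load_array(run, "ghost"), "available: .*m")
  expect_error(save_array(run, "../evil", 1), "filesystem-safe")
})

test_that("recorder traces survive the save/load round trip", {
  net <- Network$new(seed = 21)
  ng <- net$add_neuron_group(10, name = "exc", behaviours = list(
    `1` = lif_behaviour(),
    `9` = recorder(c("n.voltage", "np.mean(n.voltage)"))))
  net$initialize_network()
  net$simulate_iterations(50)
  td <- tempfile("data"); dir.create(td)
  run <- create_run("exp", root = td)
  vt <- find_by_tag(net, "n.voltage")[[1]]
  mt <- find_by_tag(net, "np.mean(n.voltage)")[[1]]
  save_array(run, "voltage", vt)
  save_array(run, "mean_voltage", mt)
  expect_identical(load_array(run, "voltage"), as.matrix(vt))
  expect_identical(load_array(run, "mean_voltage"), as.numeric(mt))
})

test_that("parameters round-trip and runs compare into a sorted table", {
  td <- tempfile("data"); dir.create(td)
  leaks <- c(0.9, 0.8, 0.95)
  for (i in seq_along(leaks)) {
    run <- create_run("sweep", root = td)
    save_parameters(run, list(leak = leaks[i], label = sprintf("run%d", i)))
    if (i != 2) save_results(run, list(mean_rate = leaks[i] / 10))
  }
  tab <- compare_runs("sweep", c("leak", "mean_rate"), root = td)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$leak, sort(leaks))              # sorted by first column
  expect_true(is.na(tab$mean_rate[tab$leak == 0.8]))  # missing, not error
  only_runs <- compare_runs("sweep", character(0), root = td)
  expect_equal(only_runs$run, 0:2)
  # parameters are lossless
  r0 <- open_run("sweep", 0, root = td)
  expect_identical(load_parameters(r0)$leak, 0.9)
  expect_identical(load_parameters(r0)$label, "run1")
})

test_that("the module graph lists nodes in execution order with data edges", {
  x <- build_lif_grid(seed = 2)
  x$net$initialize_network()
  dot <- export_module_graph(x$net)
  lines <- strsplit(dot, "\n")[[1]]
  nodes <- grep("order=", lines, value = TRUE)
  expect_length(nodes, 3)   # LIF, input, recorder
  expect_true(grepl("LIF", nodes[1]) && grepl("order=1", nodes[1]))
  expect_true(grepl("SynapticInput", nodes[2]))
  expect_true(grepl("Recorder", nodes[3]))
  # LIF writes spike, input reads it; both write/read voltage
  expect_true(any(grepl('b1 -> b2 \\[label="spike"\\]', lines)))
  expect_true(any(grepl('b1 -> b3 \\[label="voltage"\\]', lines)))

  # single undeclared behaviour: one node, no edges
  net <- Network$new(seed = 1)
  net$add_neuron_group(2, name = "g", behaviours = list(`1` = behaviour()))
  net$initialize_network()
  dot2 <- export_module_graph(net)
  expect_equal(length(grep("->", strsplit(dot2, "\n")[[1]])), 0)

  # explicit read/write declarations produce one directed edge
  net2 <- Network$new(seed = 1)
  net2$add_neuron_group(2, name = "g", behaviours = list(
    `1` = behaviour(writes = "voltage",
                    setup = function(self, parent) parent$set("voltage", 0)),
    `2` = behaviour(reads = "voltage")))
  net2$initialize_network()
  lines3 <- strsplit(export_module_graph(net2), "\n")[[1]]
  expect_true(any(grepl('b1 -> b2 \\[label="voltage"\\]', lines3)))

  expect_error(export_module_graph(Network$new(seed = 1)), "initialize")
})

test_that("bundled examples run deterministically end to end", {
  td <- tempfile("data"); dir.create(td)
  res1 <- run_example("lif", steps = 200, seed = 42, experiment = "demo",
                      root = td)
  res2 <- run_example("lif", steps = 200, seed = 42, experiment = "demo",
                      root = td)
  expect_equal(res1$run$index, 0)
  expect_equal(res2$run$index, 1)
  expect_identical(load_array(res1$run, "spikes"),
                   load_array(res2$run, "spikes"))
  expect_identical(res1$mean_rate, res2$mean_rate)
  expect_gt(res1$mean_rate, 0.01)   # sustained activity
  expect_lt(res1$mean_rate, 0.6)    # but not saturated
  expect_true(file.exists(file.path(res1$run$path, "modules.dot")))

  res3 <- run_example("sorn", steps = 150, seed = 7)
  expect_gt(res3$mean_rate, 0)
  res4 <- run_example("izhikevich", steps = 150, seed = 7)
  expect_gt(res4$mean_rate, 0)
})
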