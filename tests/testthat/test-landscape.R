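test_that("noise-free Langevin paths match deterministic integration", {
  circ <- activated_node(1, 1)
  traj <- simulate_langevin(circ, x0 = 0, t_max = 20, dt = 0.01, sigma = 0,
                            seed = 1)
  expect_equal(unname(traj[nrow(traj), "X"]), 0.5, tolerance = 1e-2)
  ss <- steady_state(circ, x0 = 0)
  expect_equal(unname(traj[nrow(traj), "X"]), unname(ss$x), tolerance = 1e-2)
})

test_that("Langevin paths are reproducible and bounded", {
  circ <- make_fixture("toy_bistable", seed = 3)$circuit
  a <- simulate_langevin(circ, t_max = 10, sigma = 0.01, seed = 99)
  b <- simulate_langevin(circ, t_max = 10, sigma = 0.01, seed = 99)
  expect_identical(a, b)
  expect_true(all(a[, -1] >= 0))
  expect_true(all(t(a[, -1]) <= circ$nodes$total + 1e-12))
  expect_error(simulate_langevin(circ, t_max = 10, dt = 50, sigma = 0),
               "dt")
})

test_that("stationary variance of a linear node matches the OU closed form", {
  fx <- make_fixture("ou_node", seed = 1)
  # analytic: var = sigma / rate around mean basal/rate
  traj <- simulate_langevin(fx$circuit, x0 = fx$ground_truth$mean,
                            t_max = 4000, dt = 0.02, sigma = fx$sigma,
                            stride = 5L, seed = 21)
  x <- traj[traj[, "time"] > 50, "X"]
  expect_equal(mean(x), fx$ground_truth$mean, tolerance = 0.05)
  expect_equal(var(x), fx$ground_truth$stationary_var, tolerance = 0.15)
})

test_that("landscape density is normalized with finite potential", {
  circ <- make_fixture("toy_bistable", seed = 3)$circuit
  land <- estimate_landscape(circ, axes = list("X", "Y"), n_init = 60,
                             t_max = 30, sigma = 0.01, bins = 60, seed = 5)
  expect_equal(sum(land$density), 1, tolerance = 1e-9)
  expect_true(all(is.finite(land$U)))
  expect_identical(which.min(land$U), which.max(land$density))
})

test_that("basin counting recovers planted two-well structure", {
  fx <- make_fixture("two_gaussian_density", seed = 1,
                     options = list(weights = c(0.3, 0.7)))
  bas <- count_basins(fx$landscape, depth_threshold = 1)
  expect_identical(bas$n_basins, 2L)
  expect_equal(sum(bas$mass), 1, tolerance = 1e-9)
  expect_equal(sort(bas$mass), c(0.3, 0.7), tolerance = 0.02)
  # merging limit: threshold above every barrier yields a single basin
  all_one <- count_basins(fx$landscape, depth_threshold = 1e6)
  expect_identical(all_one$n_basins, 1L)
})

test_that("a monostable system yields a single basin", {
  # two-node cascade: X driven by the stimulus, Y driven by X; one attractor
  nodes <- data.frame(name = c("X", "Y"), total = 1, d = 1, basal = 0)
  edges <- data.frame(source = c(".stim", "X"), target = c("X", "Y"),
                      sign = 1, k = c(1, 2), j = c(1e-6, 0.3), n = c(1, 2))
  circ <- circuit(nodes, edges, input = "X", output = "Y", s = 1)
  land <- estimate_landscape(circ, axes = list("X", "Y"), n_init = 80,
                             t_max = 25, sigma = 0.01, bins = 30, seed = 2)
  bas <- count_basins(land, depth_threshold = 2)
  expect_identical(bas$n_basins, 1L)
})

test_that("doubling the trajectory budget leaves the basin count unchanged", {
  circ <- make_fixture("toy_bistable", seed = 3)$circuit
  n1 <- count_basins(estimate_landscape(circ, axes = list("X", "Y"),
                                        n_init = 60, t_max = 30,
                                        sigma = 0.012, bins = 50, seed = 8),
                     depth_threshold = 2)$n_basins
  n2 <- count_basins(estimate_landscape(circ, axes = list("X", "Y"),
                                        n_init = 120, t_max = 30,
                                        sigma = 0.012, bins = 50, seed = 8),
                     depth_threshold = 2)$n_basins
  expect_identical(n1, n2)
})
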