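test_that("state labeling with hysteresis counts dwell segments", {
  # direct-count example at unit sampling
  x <- c(0.1, 0.1, 0.9, 0.9, 0.9, 0.1)
  rec <- label_states(x, low = 0.3, high = 0.7)
  expect_identical(rec$segments$state, c("apoptosis", "necroptosis",
                                         "apoptosis"))
  expect_identical(rec$segments$duration, c(2, 3, 1))
  expect_equal(unname(rec$p[c("apoptosis", "necroptosis")]), c(0.5, 0.5))
  # constant high path: single segment, fully ordered
  rec2 <- label_states(rep(0.95, 10), 0.3, 0.7)
  expect_identical(nrow(rec2$segments), 1L)
  expect_equal(unname(rec2$p["necroptosis"]), 1)
  # in-band values retain the previous label
  rec3 <- label_states(c(0.9, 0.5, 0.5, 0.1, 0.5), 0.3, 0.7)
  expect_identical(rec3$labels,
                   c("necroptosis", "necroptosis", "necroptosis",
                     "apoptosis", "apoptosis"))
  expect_error(label_states(x, 0.7, 0.3), "low < high")
})

test_that("fully in-band paths are transient and entropy on them errors", {
  rec <- label_states(rep(0.5, 8), 0.3, 0.7)
  expect_true(all(rec$labels == "transient"))
  expect_identical(nrow(rec$segments), 0L)
  expect_error(shannon_entropy(rec), "no labeled states")
})

test_that("Shannon entropy obeys closed forms, bounds, and permutation invariance", {
  expect_equal(shannon_entropy(c(1, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.5)), 1)
  expect_equal(shannon_entropy(c(0.9, 0.1)), 0.4690, tolerance = 1e-4)
  expect_error(shannon_entropy(c(0.5, 0.6)), "summing to 1")
  set.seed(4)
  for (i in 1:20) {
    p <- runif(2 + i %% 3)
    p <- p / sum(p)
    s <- shannon_entropy(p)
    expect_gte(s, 0)
    expect_lte(s, log2(length(p)) + 1e-12)
    expect_equal(s, shannon_entropy(rev(p)))
    expect_equal(s, shannon_entropy(sample(p)))
  }
})

test_that("attractor-based thresholds bracket the bistable gap", {
  circ <- make_fixture("toy_bistable", seed = 3)$circuit
  thr <- attractor_thresholds(circ, "Y", n_starts = 20, seed = 2)
  att <- sort(find_attractors(circ, n_starts = 20, seed = 2)[, "Y"])
  expect_lt(thr[1], thr[2])
  expect_gt(thr[1], att[1])
  expect_lt(thr[2], att[length(att)])
  expect_null(attractor_thresholds(decay_node(), "X", n_starts = 20,
                                   seed = 2))
})

test_that("entropy of a switching bistable node is high, of a biased one low", {
  circ <- make_fixture("toy_bistable", seed = 3)$circuit
  thr <- attractor_thresholds(circ, "Y", n_starts = 20, seed = 2)
  traj <- simulate_langevin(circ, x0 = c(0, 0), t_max = 800, dt = 0.01,
                            sigma = 0.1, stride = 10L, seed = 31)
  rec <- label_states(traj[, "Y"], thr[1], thr[2], dt = 0.1)
  s_noisy <- shannon_entropy(rec)
  expect_gt(s_noisy, 0.25)
  # with weak noise the path stays in its initial basin: ordered fate
  traj2 <- simulate_langevin(circ, x0 = c(0, 0), t_max = 800, dt = 0.01,
                             sigma = 0.002, stride = 10L, seed = 32)
  rec2 <- label_states(traj2[, "Y"], thr[1], thr[2], dt = 0.1)
  expect_lt(shannon_entropy(rec2), s_noisy)
})

test_that("entropy phase map reports zero entropy outside coexistence", {
  m <- necroptosis_model()
  co <- classify_coexistent(m$circuit, "RIP1", seq(0.04, 0.16, by = 0.01),
                            n_starts = 60, seed = 2)
  mid <- co$interval[ceiling(length(co$interval) / 2)]
  map <- entropy_phase_map(m, rip1_grid = c(0, mid), term = "k5",
                           term_grid = 0.3, sigma = 0.005, dt = 0.01,
                           horizon = 150, burn_in = 15, n_starts = 60,
                           seed = 3)
  expect_identical(dim(map$S), c(1L, 2L))
  # RIP1 = 0: monostable apoptosis, ordered fate
  expect_false(map$coexistent[1, 1])
  expect_identical(map$S[1, 1], 0)
  # entropies live in [0, 1] bits for the two death modes
  expect_true(all(map$S >= 0 & map$S <= 1))
  # second column: inside the reference model's coexistence window
  expect_true(map$coexistent[1, 2])
})
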