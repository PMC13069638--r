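fake_curve <- function(y, total = 1, grid = seq(0, 1, length.out = length(y))) {
  cur <- data.frame(dose_fraction = grid, readout = y, converged = TRUE)
  class(cur) <- c("dose_response", "data.frame")
  attr(cur, "readout_total") <- total
  cur
}

test_that("H follows its defining formula", {
  expect_equal(compute_H(fake_curve(c(0.2, 0.8, 0.3)), total = 1), 0.5)
  expect_equal(compute_H(fake_curve(rep(0.4, 5)), total = 1), 0)
  expect_error(compute_H(fake_curve(c(0.1, 0.2)), total = 0), "total")
  # invariant under joint rescaling of readout and total
  y <- c(0.1, 0.6, 0.25)
  expect_equal(compute_H(fake_curve(y), 1), compute_H(fake_curve(3 * y), 3))
})

test_that("biphasic classification uses an inclusive 1% threshold", {
  # boundary: exactly 1% relative drop counts
  b <- classify_biphasic(fake_curve(c(0.1, 0.5, 0.495)))
  expect_equal(b$value, 0.01, tolerance = 1e-12)
  expect_true(b$flag)
  expect_false(classify_biphasic(fake_curve(c(0.1, 0.2, 0.6)))$flag)
  z <- classify_biphasic(fake_curve(c(0, 0, 0)))
  expect_false(z$flag)
  expect_identical(z$value, 0)
  # BD value invariant under joint rescaling
  y <- c(0.05, 0.7, 0.5)
  expect_equal(classify_biphasic(fake_curve(y))$value,
               classify_biphasic(fake_curve(5 * y, total = 5))$value)
})

test_that("emergence slope is the max windowed rise of the normalized readout", {
  g <- seq(0, 1, length.out = 21)
  ramp <- classify_emergent(fake_curve(g, grid = g))
  expect_equal(ramp$max_slope, 1, tolerance = 1e-9)
  expect_false(ramp$flag)
  step <- ifelse(g < 0.45, 0, 0.6)
  st <- classify_emergent(fake_curve(step, grid = g))
  expect_equal(st$max_slope, 6, tolerance = 1e-9)
  expect_true(st$flag)
  # flag is monotone in the threshold
  expect_false(classify_emergent(fake_curve(step, grid = g),
                                 threshold = 6.5)$flag)
  expect_error(classify_emergent(fake_curve(step, grid = g), window = 0.001),
               "window")
  expect_error(classify_emergent(fake_curve(step, grid = g), window = 0.077),
               "divide")
})

test_that("regulation typing distinguishes monotone and bell shapes", {
  expect_identical(classify_regulation(c(0.1, 0.2, 0.3, 0.4)), "positive")
  expect_identical(classify_regulation(c(0.4, 0.3, 0.2, 0.1)), "negative")
  expect_identical(classify_regulation(c(0.4, 0.2, 0.25, 0.5)), "bell")
  # jitter below tolerance does not flip a monotone call
  expect_identical(classify_regulation(c(0.1, 0.2, 0.199, 0.3), tol = 0.005),
                   "positive")
  expect_error(classify_regulation(c(0.1, 0.2)), "4")
})

test_that("coexistence classifier separates mono- and bistable systems", {
  mono <- decay_node()
  cd <- classify_coexistent(mono, "X", c(0.2, 0.6, 1), n_starts = 10,
                            seed = 1)
  expect_false(cd$flag)
  expect_length(cd$interval, 0)
  bist <- make_fixture("toy_bistable", seed = 3)$circuit
  # dose the (capacity of the) output node over levels keeping bistability
  cd2 <- classify_coexistent(bist, "X", c(0.9, 1), n_starts = 12, seed = 1)
  expect_true(cd2$flag)
  # agreement across multistart budgets (seeded)
  cd3 <- classify_coexistent(bist, "X", c(0.9, 1), n_starts = 40, seed = 9)
  expect_identical(cd2$flag, cd3$flag)
})

test_that("4PL fitting recovers planted parameters and flags degeneracy", {
  x <- seq(0.12, 1, length.out = 30)
  truth <- list(A = 0.15, B = 0.72, xmid = 0.4, scal = 0.09)
  y <- fpl_fun_test(x, truth)
  fit <- fit_fpl_piecewise(c(0.02, 0.05, 0.08, x),
                           c(0.4, 0.3, 0.2, y), breakpoint = 0.1)
  expect_false(fit$upper$degenerate)
  expect_equal(fit$upper_asymptote, truth$B, tolerance = 1e-6)
  expect_equal(fit$max_slope_location, truth$xmid, tolerance = 1e-6)
  flat <- fit_fpl_piecewise(seq(0.01, 1, length.out = 20),
                            rep(0.3, 20), breakpoint = 0.1)
  expect_true(flat$upper$degenerate)
  expect_equal(flat$upper$A, flat$upper$B)
  expect_error(fit_fpl_piecewise(x, y, breakpoint = 2), "breakpoint")
})
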