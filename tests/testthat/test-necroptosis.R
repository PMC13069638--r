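# Deterministic behavior of the shipped reference death circuit.
grid41 <- seq(0, 1, by = 0.025)

test_that("the reference RIP1 dose response is biphasic with low-RIP1 emergence", {
  m <- necroptosis_model()
  cur <- rip3_dose_curve(m, grid41)
  expect_true(all(cur$converged))
  expect_true(classify_biphasic(cur)$flag)
  ed <- classify_emergent(cur)
  expect_true(ed$flag)
  # steepest 10%-window rise sits at low RIP1 (below 25%)
  y <- cur$readout
  sl <- diff(y, lag = 4)
  expect_lt(grid41[which.max(sl)], 0.25)
  # interior peak, then decline toward wild type
  expect_gt(compute_H(cur), 0)
  expect_lt(which.max(y), length(y))
})

test_that("protein knockouts reshape the curve as expected", {
  m <- necroptosis_model()
  # no RIP3: identically zero readout
  r3 <- rip3_dose_curve(knockout_proteins(m, "RIP3"), grid41)
  expect_equal(max(abs(r3$readout)), 0, tolerance = 1e-8)
  # no C8: emergence preserved but no decline (plateau)
  c8 <- rip3_dose_curve(knockout_proteins(m, "C8"), grid41)
  expect_true(classify_emergent(c8)$flag)
  expect_false(classify_biphasic(c8)$flag)
  tailpart <- c8$readout[grid41 >= 0.5]
  expect_lt(diff(range(tailpart)) / max(c8$readout), 0.05)
  # no TRADD: biphasic shape preserved
  td <- rip3_dose_curve(knockout_proteins(m, "TRADD"), grid41)
  expect_true(classify_biphasic(td)$flag)
  expect_true(classify_emergent(td)$flag)
})

test_that("attractor count follows the 1 -> 2 -> 1 pattern along RIP1", {
  m <- necroptosis_model()
  att_at <- function(lv, seed = 1)
    find_attractors(set_total(m$circuit, "RIP1", lv), n_starts = 30,
                    seed = seed)
  lo <- att_at(0)
  expect_identical(nrow(lo), 1L)
  expect_lt(lo[1, "RIP3"], 0.1)          # apoptotic: no pRIP3
  co <- classify_coexistent(m$circuit, "RIP1", seq(0.04, 0.16, by = 0.01),
                            n_starts = 60, seed = 2)
  expect_true(co$flag)                   # a coexistence window exists
  hi <- att_at(1)
  expect_identical(nrow(hi), 1L)
  # necroptotic: pRIP3 well above the apoptotic state's (near zero)
  expect_gt(hi[1, "RIP3"], 0.15)
  # the two coexisting states separate along pRIP3
  dose <- co$interval[ceiling(length(co$interval) / 2)]
  mid <- find_attractors(set_total(m$circuit, "RIP1", dose),
                         n_starts = 60, seed = 3)
  expect_gte(nrow(mid), 2L)
  r3 <- sort(mid[, "RIP3"])
  expect_gt(r3[length(r3)] - r3[1], 0.2)
})

test_that("only the k3 feedback removal collapses the coexistence window", {
  m <- necroptosis_model()
  co <- classify_coexistent(m$circuit, "RIP1", seq(0.04, 0.16, by = 0.01),
                            n_starts = 60, seed = 2)
  dose <- co$interval[ceiling(length(co$interval) / 2)]
  n_att <- function(model)
    nrow(find_attractors(set_total(model$circuit, "RIP1", dose),
                         n_starts = 60, seed = 5))
  expect_identical(n_att(knockout_terms(m, "k3")), 1L)
  for (tm in c("k1", "k2", "k4", "k6", "k8"))
    expect_gte(n_att(knockout_terms(m, tm)), 2L)
})

test_that("knockout scan loses biphasic dynamics exactly on the IFFL terms", {
  m <- necroptosis_model()
  scan <- term_knockout_scan(m, grid41)
  expect_identical(scan$term, paste0("k", 1:9))
  core <- scan$term %in% c("k5", "k7", "k9")
  expect_true(all(!scan$BD[core]))
  expect_true(all(scan$BD[!core]))
})

test_that("expression scan is scale-free in the peak with a declining endpoint", {
  m <- necroptosis_model()
  levels <- c(0.02, 0.05, 0.1, 0.2, 0.4, 0.6, 0.8, 1)
  scan <- expression_scan(m, "RIP3", levels, grid41)
  # relative peak approximately constant (scale-free emergence)
  expect_lt(sd(scan$peak_rel) / mean(scan$peak_rel), 0.25)
  # absolute peak increases with RIP3 expression
  expect_true(all(diff(scan$peak_abs) > -1e-6))
  # relative terminal pRIP3 declines as RIP3 expression rises
  expect_true(all(diff(scan$end_rel) < 1e-6))
  # the rising H branch above ~20% RIP3 (the 4PL-fit regime) is monotone
  up <- scan$level >= 0.2
  expect_true(all(diff(scan$H[up]) > -1e-6))
  # H is coherent with its parts at every level
  expect_equal(scan$H, (scan$peak_abs - scan$end_abs) / scan$level,
               tolerance = 1e-10)
})

test_that("the k5-k7 plane has an interior H maximum and consistent indexing", {
  m <- necroptosis_model()
  k5g <- 10^seq(-1, 1, length.out = 7)
  k7g <- 10^seq(-1, 1, length.out = 7)
  pl <- k5_k7_phase_plane(m, k5g, k7g, grid41)
  expect_identical(dim(pl$H), c(7L, 7L))
  expect_equal(pl$max, max(pl$H), tolerance = 1e-12)
  # reversing a grid reverses the corresponding matrix dimension
  pl_r <- k5_k7_phase_plane(m, rev(k5g), k7g, grid41)
  expect_equal(pl_r$H, pl$H[7:1, ], tolerance = 1e-10)
  expect_equal(pl_r$max, pl$max, tolerance = 1e-10)
  # weak k5 decouples C8 drive: H collapses toward the C8-free plateau
  expect_lt(min(pl$H[1, ]), pl$max)
})

test_that("occupancy mass shifts toward the necroptotic basin across the window", {
  m <- necroptosis_model()
  co <- classify_coexistent(m$circuit, "RIP1", seq(0.04, 0.16, by = 0.01),
                            n_starts = 60, seed = 2)
  lo <- min(co$interval); hi <- max(co$interval)
  mean_prip3 <- function(rip1) {
    circ <- set_total(m$circuit, "RIP1", rip1)
    land <- estimate_landscape(circ, axes = list("RIP3", c("C8a", "C8b")),
                               n_init = 150, t_max = 40, sigma = 0.005,
                               bins = 60, seed = 9)
    sum(land$density * land$x)  # occupancy-weighted mean pRIP3
  }
  expect_gt(mean_prip3(hi), mean_prip3(lo))
})
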