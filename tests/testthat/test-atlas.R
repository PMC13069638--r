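test_that("topology encoding round-trips and enumerations have exact counts", {
  two <- enumerate_two_node()
  expect_length(two, 27)
  expect_false(anyDuplicated(two) > 0)
  # all-zero topology included exactly once
  zero <- vapply(two, function(cd) all(decode_topology(cd, 2) == 0),
                 logical(1))
  expect_identical(sum(zero), 1L)
  all3 <- enumerate_three_node("none")
  expect_length(all3, 6561)
  path3 <- enumerate_three_node("path_A_to_C")
  expect_length(path3, 5346)
  # round trip on random codes in both spaces
  set.seed(1)
  for (cd in sample(all3, 50))
    expect_identical(encode_topology(decode_topology(cd, 3)), cd)
  for (cd in sample(two, 10))
    expect_identical(encode_topology(decode_topology(cd, 2)), as.integer(cd))
})

test_that("path filter matches an independent reachability oracle", {
  # oracle: boolean matrix powers on 30 random codes
  set.seed(2)
  codes <- sample(0:6560, 30)
  keep_pkg <- codes %in% enumerate_three_node("path_A_to_C")
  oracle <- vapply(codes, function(cd) {
    w <- decode_topology(cd, 3)
    A <- matrix(0, 3, 3)
    idx <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2),
                 c(2, 2), c(3, 3))
    for (e in 1:8) A[idx[e, 1], idx[e, 2]] <- w[e] != 0
    M <- A
    for (p in 2:3) M <- M + (M %*% A)
    M[1, 3] > 0
  }, logical(1))
  expect_identical(keep_pkg, oracle)
})

test_that("IFFL detection equals the brute-force path oracle on all codes", {
  idx <- rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3), c(3, 1), c(3, 2),
               c(2, 2), c(3, 3))
  oracle_one <- function(cd) {
    w <- decode_topology(cd, 3)
    A <- matrix(0, 3, 3)
    for (e in 1:8) A[idx[e, 1], idx[e, 2]] <- w[e]
    for (x in 1:3) for (y in 1:3) for (z in 1:3)
      if (x != y && y != z && x != z &&
          A[x, z] != 0 && A[x, y] * A[y, z] != 0 &&
          A[x, z] != A[x, y] * A[y, z]) return(TRUE)
    FALSE
  }
  codes <- 0:6560
  pkg <- vapply(codes, function(cd) detect_iffl(cd)$flag, logical(1))
  orc <- vapply(codes, oracle_one, logical(1))
  expect_identical(pkg, orc)
  # canonical instances
  expect_true(detect_iffl(encode_topology(c(1, -1, 0, 1, 0, 0, 0, 0)))$flag)
  expect_false(detect_iffl(encode_topology(c(1, 1, 0, 1, 0, 0, 0, 0)))$flag)
  # death-circuit core: direct + against indirect - (witnessed)
  hit <- detect_iffl(encode_topology(c(1, 1, 0, -1, 0, 0, 0, 0)))
  expect_true(hit$flag)
  expect_gt(nrow(hit$witnesses), 0)
})

test_that("a planted IFFL topology achieves BE under random sampling", {
  fx <- make_fixture("planted_IFFL", seed = 11)
  codes <- structure(fx$code, n_nodes = 3L)
  rg <- sampling_ranges(seed = 2)
  res <- exhaustive_screen(codes, rg, n_per_topology = 400, seed = 2)
  expect_true(res$achieved)
  expect_true(res$iffl)
  expect_gt(res$n_pass, 0)
})

test_that("exhaustive screen checkpoints and resumes cleanly", {
  rg <- sampling_ranges(seed = 3)
  codes <- structure(c(100L, 200L, 300L), n_nodes = 3L)
  cp <- tempfile(fileext = ".csv")
  full <- exhaustive_screen(codes, rg, n_per_topology = 50, seed = 4,
                            checkpoint = cp)
  # simulate interruption: drop the last topology and resume
  part <- read.csv(cp)
  write.csv(part[part$code != 300L, ], cp, row.names = FALSE)
  resumed <- exhaustive_screen(codes, rg, n_per_topology = 50, seed = 4,
                               checkpoint = cp)
  expect_equal(resumed, full, tolerance = 1e-12, ignore_attr = TRUE)
  writeLines("garbage,header", cp)
  expect_error(exhaustive_screen(codes, rg, n_per_topology = 50, seed = 4,
                                 checkpoint = cp), "refusing")
})

test_that("minimal circuits recover planted families and contain IFFLs", {
  # three planted families around distinct minimal codes, achieving flags set
  base <- list(c(1, -1, 0, 1, 0, 0, 0, 0),    # IFFL via B (direct -)
               c(-1, 1, 0, 1, 0, 0, 0, 0),    # IFFL, signs flipped
               c(1, 1, 0, -1, 0, 0, 0, 0))    # IFFL, inhibition on B->C
  fam <- do.call(rbind, lapply(seq_along(base), function(i) {
    w0 <- base[[i]]
    kids <- lapply(1:4, function(e) {
      w <- w0
      slot <- which(w == 0)[e]
      w[slot] <- 1
      w
    })
    data.frame(code = vapply(c(list(w0), kids), encode_topology, numeric(1)),
               fam = i)
  }))
  atlas <- data.frame(code = fam$code,
                      E = vapply(fam$code, function(cd)
                        sum(decode_topology(cd, 3) != 0), numeric(1)),
                      n_pass = 5, P_BE = 0.01, se = 0.001, achieved = TRUE,
                      iffl = TRUE)
  mins <- minimal_circuits(atlas, k_clusters = 3)
  expect_identical(nrow(mins), 3L)
  expect_setequal(mins$code, vapply(base, encode_topology, numeric(1)))
  expect_true(all(vapply(mins$code, function(cd) detect_iffl(cd)$flag,
                         logical(1))))
})

test_that("atlas links connect only one-edge additions with -ln(p) potential", {
  w1 <- c(1, -1, 0, 1, 0, 0, 0, 0)
  w2 <- w1; w2[5] <- 1          # one added edge
  w3 <- w2; w3[6] <- -1         # two added edges from w1
  atlas <- data.frame(code = vapply(list(w1, w2, w3), encode_topology,
                                    numeric(1)),
                      E = c(3, 4, 5), n_pass = 1,
                      P_BE = c(exp(-2), 0.5, 0.25), se = 0,
                      achieved = TRUE, iffl = TRUE)
  g <- build_atlas(atlas)
  expect_equal(igraph::gsize(g), 2)  # w1->w2 and w2->w3 only
  el <- igraph::as_edgelist(g)
  expect_setequal(paste(el[, 1], el[, 2]),
                  paste(atlas$code[c(1, 2)], atlas$code[c(2, 3)]))
  expect_equal(igraph::V(g)$potential[1], 2)
})

test_that("edge addition re-screens one-edge variants of a base circuit", {
  fx <- make_fixture("planted_IFFL", seed = 11)
  rg <- sampling_ranges(seed = 5)
  # restrict to two candidate additions: C self-activation and C -> A promotion
  w0 <- decode_topology(fx$code, 3)
  adds <- data.frame(edge = c(8L, 5L), sign = c(1L, 1L))
  out <- edge_addition_analysis(fx$code, rg, n_per_topology = 300,
                                additions = adds, seed = 6)
  expect_identical(nrow(out), 2L)
  expect_identical(out$edge, c("C->C", "C->A"))
  expect_true(all(out$P_BE >= 0 & out$P_BE <= 1))
  base <- attr(out, "base")
  expect_equal(out$delta_P_BE, out$P_BE - base[["P_BE"]])
  # each variant code differs from the base by exactly one added edge
  for (cd in out$code) {
    dif <- decode_topology(cd, 3) - w0
    expect_identical(sum(dif != 0), 1L)
  }
})
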