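#' Integrate a circuit to steady state
#'
#' Runs the deterministic dynamics from `x0` until the residual
#' `max_i |F_i(x)|` drops below `tol` or `t_max` is exceeded. The default
#' engine is a compiled adaptive Cash--Karp Runge--Kutta 4(5) integrator
#' (absolute tolerance 1e-9, relative 1e-6); `method = "lsoda"` routes the
#' same vector field through [deSolve::lsoda()] and serves as an independent
#' cross-check. Trajectories remain in the box `[0, T]` because the vector
#' field is inward on its boundary; no clipping is applied.
#'
#' @param circ a `circuit`.
#' @param x0 initial state (default all-inactive zeros).
#' @param t_max time horizon (default 500 time units).
#' @param tol steady-state residual tolerance (default 1e-6).
#' @param method `"rk45"` (compiled) or `"lsoda"` (deSolve).
#' @return list with `x` (named state), `t`, `converged`, `resid`.
#' @export
steady_state <- function(circ, x0 = NULL, t_max = 500, tol = 1e-6,
                         method = c("rk45", "lsoda")) {
  method <- match.arg(method)
  if (t_max <= 0) stop("t_max must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  n <- nrow(circ$nodes)
  if (is.null(x0)) x0 <- numeric(n)
  if (length(x0) != n) stop("x0 must have one entry per node")
  if (any(x0 < 0) || any(x0 > circ$nodes$total + 1e-12))
    stop("x0 must lie inside the box [0, total]")
  if (method == "rk45") {
    res <- cpp_steady_state(encode_circuit(circ), as.numeric(x0), t_max, tol)
  } else {
    f <- assemble_rhs(circ)
    derivs <- function(t, y, p) list(as.numeric(f(y)))
    chunk <- min(50, t_max)
    t <- 0; y <- as.numeric(x0); conv <- FALSE
    while (t < t_max) {
      tt <- seq(0, min(chunk, t_max - t), length.out = 11)
      sol <- deSolve::lsoda(y, tt, derivs, parms = NULL,
                            rtol = 1e-6, atol = 1e-9)
      y <- as.numeric(sol[nrow(sol), -1])
      t <- t + tt[length(tt)]
      if (max(abs(f(y))) < tol) { conv <- TRUE; break }
    }
    res <- list(x = y, t = t, converged = conv, resid = max(abs(f(y))))
  }
  res$x <- setNames(as.numeric(res$x), circ$nodes$name)
  res
}

#' Steady-state dose response under expression scaling
#'
#' Scans the dose node's expression total over `dose_grid` (fractions of wild
#' type); at each dose the steady state is computed and the readout node's
#' activity recorded. The default `init = "fresh"` starts every dose from the
#' all-inactive state, so the curve is single-valued even inside bistable
#' regions; `init = "continuation"` carries the previous steady state forward.
#' Nonconverged points are flagged in the output, never dropped.
#'
#' @param circ a `circuit`.
#' @param dose_node node whose total is scanned.
#' @param dose_grid increasing vector of expression fractions in `[0, 1]`.
#' @param readout_node node whose steady-state activity is recorded
#'   (default: the circuit output).
#' @param init `"fresh"` or `"continuation"`.
#' @param t_max,tol as in [steady_state()].
#' @return a `dose_response` data frame with columns `dose_fraction`,
#'   `readout`, `converged`; attributes `readout_total` (the readout node's
#'   base expression total, used to normalize emergence slopes) and `states`
#'   (full steady-state matrix).
#' @export
dose_response <- function(circ, dose_node, dose_grid,
                          readout_node = circ$output,
                          init = c("fresh", "continuation"),
                          t_max = 500, tol = 1e-6) {
  init <- match.arg(init)
  if (any(dose_grid < 0) || any(dose_grid > 1) || is.unsorted(dose_grid))
    stop("dose_grid must be increasing within [0, 1]")
  di <- node_index(circ, dose_node)
  ri <- node_index(circ, readout_node)
  res <- cpp_dose_response(encode_circuit(circ), di, as.numeric(dose_grid), ri,
                           t_max, tol, init == "continuation")
  out <- data.frame(dose_fraction = dose_grid,
                    readout = as.numeric(res$readout),
                    converged = as.logical(res$converged))
  class(out) <- c("dose_response", "data.frame")
  attr(out, "readout_total") <- circ$nodes$total[ri]
  attr(out, "dose_node") <- dose_node
  attr(out, "readout_node") <- readout_node
  states <- res$states
  colnames(states) <- circ$nodes$name
  attr(out, "states") <- states
  out
}

#' Locate the stable steady states of a circuit
#'
#' Integrates to steady state from `n_starts` uniform random initial
#' conditions inside the state box and clusters the converged endpoints in
#' max-norm with radius `cluster_tol`; each cluster mean is re-polished by a
#' final [steady_state()] run. Deterministic for a fixed `seed`.
#'
#' @param circ a `circuit`.
#' @param n_starts number of random starts (`>= 2`).
#' @param seed optional integer seed (the caller's RNG stream is preserved).
#' @param cluster_tol clustering radius in max-norm.
#' @param t_max,tol as in [steady_state()].
#' @return matrix of distinct attractors (one row each, named columns), with
#'   attribute `counts` (basin draw counts among the random starts).
#' @export
find_attractors <- function(circ, n_starts = 50, seed = NULL,
                            cluster_tol = 1e-3, t_max = 500, tol = 1e-6) {
  if (n_starts < 2) stop("n_starts must be >= 2")
  n <- nrow(circ$nodes)
  enc <- encode_circuit(circ)
  starts <- with_seed(seed,
    matrix(runif(n_starts * n), n_starts, n) *
      rep(circ$nodes$total, each = n_starts))
  ends <- matrix(NA_real_, 0, n)
  for (i in seq_len(n_starts)) {
    r <- cpp_steady_state(enc, starts[i, ], t_max, tol)
    if (r$converged) ends <- rbind(ends, as.numeric(r$x))
  }
  if (!nrow(ends)) stop("no start converged to a steady state")
  # greedy max-norm clustering
  reps <- list(); counts <- integer()
  for (i in seq_len(nrow(ends))) {
    hit <- FALSE
    for (ci in seq_along(reps)) {
      if (max(abs(ends[i, ] - reps[[ci]]$center)) < cluster_tol) {
        reps[[ci]]$members <- rbind(reps[[ci]]$members, ends[i, ])
        reps[[ci]]$center <- colMeans(reps[[ci]]$members)
        counts[ci] <- counts[ci] + 1L
        hit <- TRUE; break
      }
    }
    if (!hit) {
      reps[[length(reps) + 1]] <- list(center = ends[i, ],
                                       members = matrix(ends[i, ], 1))
      counts <- c(counts, 1L)
    }
  }
  out <- t(vapply(reps, function(r) {
    p <- cpp_steady_state(enc, pmin(pmax(r$center, 0), circ$nodes$total),
                          t_max, tol)
    as.numeric(p$x)
  }, numeric(n)))
  colnames(out) <- circ$nodes$name
  # polishing may fuse near-duplicate clusters
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) for (ji in seq_len(i - 1)) {
    if (keep[i] && keep[ji] && max(abs(out[i, ] - out[ji, ])) < cluster_tol) {
      keep[i] <- FALSE
      counts[ji] <- counts[ji] + counts[i]
    }
  }
  res <- out[keep, , drop = FALSE]
  attr(res, "counts") <- counts[keep]
  res
}
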