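#' Label death-mode states along a stochastic trajectory
#'
#' Thresholds the pRIP3 (readout) coordinate with hysteresis: values above
#' `high` are necroptosis, below `low` apoptosis, and in-band samples retain
#' the previous label so threshold chatter does not inflate dwell counts.
#' Leading in-band time (before the first committed label) is `"transient"`
#' and excluded from the occupancy probabilities.
#'
#' @param x readout values at equally spaced sample times.
#' @param low,high hysteresis thresholds, `low < high`.
#' @param dt sampling interval (default 1; only scales durations).
#' @return a `dwell_record`: list with `labels`, `segments` (data frame of
#'   `state`, `duration`), and occupancy probabilities `p` over labeled
#'   states.
#' @export
label_states <- function(x, low, high, dt = 1) {
  if (low >= high) stop("hysteresis thresholds must satisfy low < high")
  lab <- ifelse(x > high, "necroptosis", ifelse(x < low, "apoptosis", NA))
  for (i in seq_along(lab)[-1]) if (is.na(lab[i])) lab[i] <- lab[i - 1]
  lab[is.na(lab)] <- "transient"
  keep <- lab != "transient"
  segments <- if (any(keep)) {
    r <- rle(lab[keep])
    data.frame(state = r$values, duration = r$lengths * dt,
               stringsAsFactors = FALSE)
  } else data.frame(state = character(), duration = numeric())
  p <- if (any(keep)) {
    tab <- tapply(rep(dt, sum(keep)), lab[keep], sum)
    as.numeric(tab) / sum(tab)
  } else numeric(0)
  if (any(keep)) names(p) <- names(tapply(rep(dt, sum(keep)), lab[keep], sum))
  structure(list(labels = lab, segments = segments, p = p),
            class = "dwell_record")
}

#' Shannon entropy of death-mode occupancy
#'
#' `S = -sum p_i log2(p_i)` in bits, with `0 log 0 = 0`. For two death modes
#' S ranges from 0 (fully ordered fate) to 1 bit (maximal uncertainty between
#' apoptosis and necroptosis); it is invariant under permutation of the state
#' labels.
#'
#' @param p occupancy probabilities (nonnegative, summing to 1), e.g. the `p`
#'   component of a [label_states()] record.
#' @return S in bits.
#' @export
shannon_entropy <- function(p) {
  if (inherits(p, "dwell_record")) p <- p$p
  if (!length(p)) stop("no labeled states: occupancy is empty")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("p must be a probability vector summing to 1")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Hysteresis thresholds from the deterministic attractors
#'
#' Places the hysteresis band at 40% and 60% of the distance between the low
#' and high deterministic attractor readout values at the current parameter
#' point.
#'
#' @param circ a `circuit`.
#' @param readout_node node defining the labeling axis.
#' @param n_starts,seed,... passed to [find_attractors()].
#' @return c(low, high), or `NULL` when the system is monostable.
#' @export
attractor_thresholds <- function(circ, readout_node, n_starts = 20,
                                 seed = NULL, ...) {
  att <- find_attractors(circ, n_starts = n_starts, seed = seed, ...)
  v <- sort(att[, readout_node])
  if (length(v) < 2) return(NULL)
  lo <- v[1]; hi <- v[length(v)]
  c(lo + 0.4 * (hi - lo), lo + 0.6 * (hi - lo))
}

#' Shannon-entropy phase map over dose and one interaction strength
#'
#' For every cell of the (dose level, term strength) grid, the coexistence
#' region is determined from the deterministic attractors; inside it a long
#' Langevin trajectory is labeled by [label_states()] and the dwell-time
#' Shannon entropy is computed, while monostable cells report S = 0 (ordered
#' fate). In the reference model the high-entropy band sits where RIP1 is
#' near the necroptosis emergence level, and larger `k5` shifts that band to
#' larger RIP1.
#'
#' @param model a `death_circuit`.
#' @param rip1_grid RIP1 expression levels (columns of the map).
#' @param term term label varied (`"k3"`, `"k5"`, `"k7"`, or `"k9"`).
#' @param term_grid strengths for that term (rows of the map).
#' @param sigma,dt,mode Langevin noise settings.
#' @param horizon labeled simulation length after burn-in (time units).
#' @param burn_in discarded initial time.
#' @param n_starts multistart count for the coexistence mask.
#' @param seed integer seed (substreams per cell).
#' @return list with `S` (matrix term x dose), `coexistent` (logical mask),
#'   `rip1` and `term_values`.
#' @export
entropy_phase_map <- function(model, rip1_grid, term = "k5", term_grid,
                              sigma = 0.005, dt = 0.01,
                              mode = "additive", horizon = 5000,
                              burn_in = 0.1 * horizon,
                              n_starts = 20, seed = 1) {
  if (!length(rip1_grid) || !length(term_grid)) stop("grids must be nonempty")
  S <- matrix(0, length(term_grid), length(rip1_grid))
  mask <- matrix(FALSE, length(term_grid), length(rip1_grid))
  cell <- 0
  for (i in seq_along(term_grid)) {
    mi <- set_term_k(model, term, term_grid[i])
    for (jj in seq_along(rip1_grid)) {
      cell <- cell + 1
      circ <- set_total(mi$circuit, "RIP1", rip1_grid[jj])
      thr <- tryCatch(
        attractor_thresholds(circ, "RIP3", n_starts = n_starts,
                             seed = seed + cell),
        error = function(e) NULL)
      if (is.null(thr)) next
      mask[i, jj] <- TRUE
      att <- find_attractors(circ, n_starts = n_starts, seed = seed + cell)
      x0 <- att[which.min(att[, "RIP3"]), ]
      traj <- simulate_langevin(circ, x0 = x0, t_max = burn_in + horizon,
                                dt = dt, sigma = sigma, mode = mode,
                                stride = max(1L, round(0.1 / dt)),
                                seed = seed + 7919L * cell)
      keep <- traj[, "time"] >= burn_in
      rec <- label_states(traj[keep, "RIP3"], thr[1], thr[2])
      S[i, jj] <- if (length(rec$p) >= 1) shannon_entropy(rec$p) else 0
    }
  }
  list(S = S, coexistent = mask, rip1 = rip1_grid, term_values = term_grid)
}
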