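#' Simulate a Langevin trajectory of a circuit
#'
#' Euler--Maruyama integration of `dx = F(x) dt + noise`, where the white
#' Gaussian noise has autocovariance `<xi_i(t) xi_i(t')> = 2 sigma
#' delta(t - t')`, i.e. each step adds `sqrt(2 sigma dt) N(0,1)` per
#' component (scaled by the current level in `"multiplicative"` mode).
#' Boundaries at 0 and the expression totals are reflecting, preserving box
#' invariance under noise. Reproducible given `seed`.
#'
#' @param circ a `circuit`.
#' @param x0 initial state (default all-inactive).
#' @param t_max horizon; `dt` Euler step (default 0.01).
#' @param sigma noise intensity (default 0.005).
#' @param mode `"additive"` or `"multiplicative"`.
#' @param stride record every `stride` steps.
#' @param seed optional integer seed.
#' @return matrix with a `time` column and one column per node.
#' @export
simulate_langevin <- function(circ, x0 = NULL, t_max, dt = 0.01,
                              sigma = 0.005, mode = c("additive", "multiplicative"),
                              stride = 1L, seed = NULL) {
  mode <- match.arg(mode)
  if (dt <= 0) stop("dt must be > 0")
  if (t_max < dt) stop("t_max must be >= dt")
  n <- nrow(circ$nodes)
  if (is.null(x0)) x0 <- numeric(n)
  nsteps <- ceiling(t_max / dt)
  path <- with_seed(seed,
    cpp_simulate_langevin(encode_circuit(circ), as.numeric(x0), dt,
                          as.integer(nsteps), sigma,
                          mode == "multiplicative", as.integer(stride)))
  colnames(path) <- circ$nodes$name
  cbind(time = seq(0, by = dt * stride, length.out = nrow(path)), path)
}

#' Trajectory-density potential landscape on a 2-D projection
#'
#' Runs `n_init` Langevin trajectories from uniform random initial states,
#' accumulates their post-burn-in occupancy on an `bins x bins` lattice over
#' two chosen projections (each axis is a node or a sum of nodes, e.g. total
#' active caspase-8 `C8a + C8b`), normalizes to a density `rho`, and derives
#' the quasi-potential `U = -ln(rho + eps)` with `eps = 1/(total points)` so
#' U is finite everywhere and its minima coincide with density maxima. This
#' trajectory-density estimator stands in for the stationary distribution of
#' the associated Fokker--Planck equation.
#'
#' @param circ a `circuit`.
#' @param axes list of two character vectors naming the node(s) summed on
#'   each axis.
#' @param n_init number of random initial conditions (default 10000).
#' @param t_max horizon per trajectory; `burn_in` discarded initial time
#'   (default 20% of `t_max`).
#' @param dt,sigma,mode as in [simulate_langevin()].
#' @param stride accumulate every `stride` steps (bounds memory and sample
#'   autocorrelation).
#' @param bins lattice size per axis (default 200).
#' @param seed optional integer seed.
#' @return object of class `landscape`: list with `density`, `U`, axis break
#'   midpoints `x`, `y`, axis labels, and `total_points`.
#' @export
estimate_landscape <- function(circ, axes, n_init = 10000, t_max = 50,
                               burn_in = 0.2 * t_max, dt = 0.01,
                               sigma = 0.005,
                               mode = c("additive", "multiplicative"),
                               stride = 10L, bins = 200L, seed = NULL) {
  mode <- match.arg(mode)
  if (n_init < 1) stop("n_init must be >= 1")
  if (burn_in >= t_max) stop("burn_in must be smaller than t_max")
  ax1 <- vapply(axes[[1]], function(nm) node_index(circ, nm), integer(1))
  ax2 <- vapply(axes[[2]], function(nm) node_index(circ, nm), integer(1))
  ax1max <- max(sum(circ$nodes$total[ax1]), 1e-12)
  ax2max <- max(sum(circ$nodes$total[ax2]), 1e-12)
  res <- with_seed(seed,
    cpp_accumulate_landscape(encode_circuit(circ), as.integer(n_init), dt,
                             t_max, burn_in, as.integer(stride), sigma,
                             mode == "multiplicative",
                             as.integer(ax1), as.integer(ax2),
                             as.integer(bins), as.integer(bins),
                             ax1max, ax2max))
  if (res$total <= 0) stop("no post-burn-in samples accumulated")
  rho <- res$counts / res$total
  eps <- 1 / res$total
  structure(list(density = rho, U = -log(rho + eps),
                 x = (seq_len(bins) - 0.5) / bins * ax1max,
                 y = (seq_len(bins) - 0.5) / bins * ax2max,
                 axes = c(paste(axes[[1]], collapse = "+"),
                          paste(axes[[2]], collapse = "+")),
                 total_points = res$total),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("<landscape> ", nrow(x$U), "x", ncol(x$U), " lattice over (",
      x$axes[1], ", ", x$axes[2], "); ", format(x$total_points),
      " points\n", sep = "")
  invisible(x)
}

#' Count potential basins by persistence
#'
#' Identifies local minima of the potential `U` and merges pairs whose
#' separating barrier is shallower than `depth_threshold` (watershed by
#' immersion with persistence merging). Returns the surviving basin count,
#' basin membership masks, minima locations, and the occupancy mass of each
#' basin; masses sum to 1.
#'
#' @param land a [estimate_landscape()] object (or a list with `U` and
#'   `density` matrices).
#' @param depth_threshold minimal barrier depth (in U units) separating two
#'   basins.
#' @return list with `n_basins`, `assignment` (integer matrix), `minima`
#'   (data frame row/col/U), and `mass` (occupancy per basin).
#' @export
count_basins <- function(land, depth_threshold = 1) {
  U <- land$U
  rho <- land$density
  nr <- nrow(U); nc <- ncol(U)
  ord <- order(U)
  lab <- integer(nr * nc)            # 0 = unlabeled
  parent <- integer(0)               # union-find
  minU <- numeric(0)
  minpos <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (cell in ord) {
    r <- ((cell - 1) %% nr) + 1
    cc <- ((cell - 1) %/% nr) + 1
    nb <- c(if (r > 1) cell - 1, if (r < nr) cell + 1,
            if (cc > 1) cell - nr, if (cc < nc) cell + nr)
    roots <- unique(vapply(lab[nb][lab[nb] > 0], find, integer(1)))
    if (!length(roots)) {
      parent <- c(parent, length(parent) + 1L)
      minU <- c(minU, U[cell]); minpos <- c(minpos, cell)
      lab[cell] <- length(parent)
    } else if (length(roots) == 1) {
      lab[cell] <- roots
    } else {
      # this cell is a saddle between >= 2 basins: merge shallow ones
      deepest <- roots[which.min(minU[roots])]
      for (rt in setdiff(roots, deepest)) {
        if (U[cell] - minU[rt] < depth_threshold) parent[rt] <- deepest
      }
      lab[cell] <- find(deepest)
    }
  }
  root_of <- vapply(lab, find, integer(1))
  keep <- sort(unique(root_of))
  assignment <- matrix(match(root_of, keep), nr, nc)
  mass <- vapply(seq_along(keep), function(i)
    sum(rho[assignment == i]), numeric(1))
  minima <- data.frame(
    row = ((minpos[keep] - 1) %% nr) + 1,
    col = ((minpos[keep] - 1) %/% nr) + 1,
    U = minU[keep])
  list(n_basins = length(keep), assignment = assignment,
       minima = minima, mass = mass)
}
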