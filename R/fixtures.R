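#' Synthetic fixtures with planted ground truth
#'
#' Generates the self-contained test objects the analysis pipeline is
#' validated against; every fixture stores its planted ground truth and is
#' bit-identical when regenerated from the same `(kind, seed)`.
#'
#' Kinds:
#' * `planted_IFFL`: a three-node incoherent-feedforward circuit (direct
#'   activation A -> C against the indirect A -> B -| C arm) with a parameter
#'   set verified at generation time (by direct simulation) to pass the
#'   biphasic and emergence thresholds; failed draws advance to the next
#'   substream and are logged in `attempts`.
#' * `toy_bistable`: a two-node mutual-activation switch with two verified
#'   attractors (both satisfy `max|F| < tol`).
#' * `monotone_doseresponse` / `biphasic_doseresponse`: pseudo densitometry
#'   curves (normalized dose response with multiplicative log-normal noise,
#'   coefficient of variation `cv`, default 0.2) with planted peak/end/H.
#' * `two_gaussian_density`: an analytic two-well mixture density on a
#'   lattice, for basin-counting checks (planted weights are the basin
#'   masses).
#' * `ou_node`: a single self-decaying node whose Langevin stationary
#'   variance has the closed form `sigma / d`.
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed.
#' @param options named list of kind-specific overrides (`cv`, `weights`,
#'   `d`, `sigma`, `grid_n`, ...).
#' @return a `fixture`: list with `kind`, `seed`, kind-specific data, and
#'   `ground_truth`.
#' @export
make_fixture <- function(kind = c("planted_IFFL", "toy_bistable",
                                  "monotone_doseresponse",
                                  "biphasic_doseresponse",
                                  "two_gaussian_density", "ou_node"),
                         seed = 1, options = list()) {
  kind <- match.arg(kind)
  opt <- function(name, default)
    if (!is.null(options[[name]])) options[[name]] else default
  fx <- switch(kind,
    planted_IFFL = {
      code <- encode_topology(c(1L, 1L, 0L, -1L, 0L, 0L, 0L, 0L))
      # A->B +, A->C +, B->C - : direct + against indirect - (IFFL)
      circ0 <- topology_circuit(code, 3)
      grid <- seq(0, 1, length.out = 21)
      attempts <- 0
      repeat {
        attempts <- attempts + 1
        rg <- sampling_ranges(n_samples = 1, seed = seed + attempts - 1)
        smp <- lhs_sample(circ0, rg)
        circ <- circuit_with_params(circ0, as.numeric(smp[1, ]))
        cur <- dose_response(circ, "A", grid, "C")
        bd <- classify_biphasic(cur)
        ed <- classify_emergent(cur)
        if (all(cur$converged) && bd$flag && ed$flag) {
          break
        }
        if (attempts > 5000) stop("no passing planted-IFFL parameters found")
      }
      list(circuit = circ, code = code, dose_grid = grid,
           attempts = attempts,
           ground_truth = list(BD = TRUE, ED = TRUE,
                               bd_value = bd$value, ed_slope = ed$max_slope))
    },
    toy_bistable = {
      nodes <- data.frame(name = c("X", "Y"), total = 1, d = 1, basal = 0.02)
      edges <- data.frame(source = c("X", "Y"), target = c("Y", "X"),
                          sign = 1, k = 5, j = 0.6, n = 4)
      circ <- circuit(nodes, edges, input = "X", output = "Y")
      lo <- steady_state(circ, c(0, 0))
      hi <- steady_state(circ, c(1, 1))
      if (!lo$converged || !hi$converged ||
          max(abs(lo$x - hi$x)) < 1e-2)
        stop("toy bistable fixture failed verification")
      list(circuit = circ,
           ground_truth = list(attractors = rbind(low = lo$x, high = hi$x)))
    },
    monotone_doseresponse = ,
    biphasic_doseresponse = {
      grid <- seq(0, 1, length.out = opt("grid_n", 51))
      cv <- opt("cv", 0.2)
      total <- opt("total", 1)
      clean <- if (kind == "monotone_doseresponse") {
        total * grid^2 / (grid^2 + 0.2^2)
      } else {
        total * (grid^4 / (grid^4 + 0.08^4)) * (0.45^2 / (grid^2 + 0.45^2)) /
          max((grid^4 / (grid^4 + 0.08^4)) * (0.45^2 / (grid^2 + 0.45^2)))
      }
      sdlog <- sqrt(log(1 + cv^2))
      noisy <- with_seed(seed,
        clean * exp(rnorm(length(grid), -sdlog^2 / 2, sdlog)))
      if (cv == 0) noisy <- clean
      cur <- data.frame(dose_fraction = grid, readout = noisy,
                        converged = TRUE)
      class(cur) <- c("dose_response", "data.frame")
      attr(cur, "readout_total") <- total
      list(curve = cur, clean = clean,
           ground_truth = list(peak = max(clean), end = clean[length(clean)],
                               total = total,
                               H = (max(clean) - clean[length(clean)]) / total))
    },
    two_gaussian_density = {
      nb <- opt("grid_n", 80)
      wts <- opt("weights", c(0.3, 0.7))
      centers <- opt("centers", list(c(0.25, 0.7), c(0.75, 0.3)))
      sdv <- opt("sd", 0.07)
      xs <- (seq_len(nb) - 0.5) / nb
      g2 <- function(cen) outer(xs, xs, function(a, b)
        exp(-((a - cen[1])^2 + (b - cen[2])^2) / (2 * sdv^2)))
      dens <- wts[1] * g2(centers[[1]]) + wts[2] * g2(centers[[2]])
      dens <- dens / sum(dens)
      land <- structure(list(density = dens,
                             U = -log(dens + 1 / sum(dens > 0)),
                             x = xs, y = xs, axes = c("x", "y"),
                             total_points = Inf),
                        class = "landscape")
      list(landscape = land,
           ground_truth = list(weights = wts / sum(wts),
                               centers = centers, n_basins = length(wts)))
    },
    ou_node = {
      # basal production keeps the mean mid-box so the reflecting boundaries
      # are many standard deviations away and the free Ornstein-Uhlenbeck
      # closed form applies: relaxation rate r = basal + d, stationary
      # variance sigma / r around mean basal * T / r.
      d <- opt("d", 0.25)
      basal <- opt("basal", 0.25)
      sigma <- opt("sigma", 0.002)
      nodes <- data.frame(name = "X", total = 1, d = d, basal = basal)
      edges <- data.frame(source = character(), target = character(),
                          sign = numeric(), k = numeric(), j = numeric(),
                          n = numeric())
      circ <- circuit(nodes, edges, input = "X", output = "X", s = 0)
      r <- basal + d
      list(circuit = circ, sigma = sigma,
           ground_truth = list(stationary_var = sigma / r,
                               mean = basal / r, rate = r))
    })
  structure(c(list(kind = kind, seed = seed), fx), class = "fixture")
}
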