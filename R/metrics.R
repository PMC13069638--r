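#' Biphasic scale coefficient H
#'
#' `H = (peak - end) / total`, where `peak` is the maximum readout over the
#' dose grid, `end` the readout at the last (100%) dose, and `total` the
#' readout node's expression total. H lies in `[-1, 1]` and is nonnegative
#' whenever the grid maximum is global.
#'
#' @param curve a [dose_response()] object (or data frame with a `readout`
#'   column).
#' @param total readout expression total; defaults to the curve's
#'   `readout_total` attribute.
#' @return H (dimensionless).
#' @export
compute_H <- function(curve, total = attr(curve, "readout_total")) {
  if (!length(curve$readout)) stop("empty dose-response curve")
  if (is.null(total) || total <= 0) stop("readout total must be > 0")
  (max(curve$readout) - curve$readout[length(curve$readout)]) / total
}

#' Classify biphasic dynamics (BD)
#'
#' The biphasic value is `(peak - end) / peak`; the flag is set when the value
#' is at least `threshold` (default 1%, inclusive). A curve with zero peak has
#' no response and is not biphasic by definition (value 0, flag `FALSE`).
#'
#' @param curve a [dose_response()] object.
#' @param threshold flag threshold on the relative peak-to-end drop.
#' @return list with `flag` and `value`.
#' @export
classify_biphasic <- function(curve, threshold = 0.01) {
  if (!length(curve$readout)) stop("empty dose-response curve")
  peak <- max(curve$readout)
  if (peak <= 0) return(list(flag = FALSE, value = 0))
  value <- (peak - curve$readout[length(curve$readout)]) / peak
  list(flag = value >= threshold, value = value)
}

#' Classify emergent dynamics (ED)
#'
#' The emergence score is the maximum sliding-window slope
#' `max (delta readout / total) / (delta dose)` over all windows spanning
#' `window` of the dose axis; readout is normalized by the readout node's
#' expression total so the score is dimensionless (a score of 5 means the
#' output rises by 50% of its total over a 10% dose increment). The flag is
#' set at `threshold` (default 5).
#'
#' @param curve a [dose_response()] object on an equally spaced grid.
#' @param window width of the sliding window as a fraction of the dose axis
#'   (default 0.1); must be an integer multiple of the grid spacing.
#' @param threshold flag threshold on the window slope.
#' @param readout_total normalization; defaults to the curve attribute.
#' @return list with `flag` and `max_slope`.
#' @export
classify_emergent <- function(curve, window = 0.1, threshold = 5,
                              readout_total = attr(curve, "readout_total")) {
  g <- curve$dose_fraction
  if (length(g) < 2) stop("dose grid too short")
  h <- g[2] - g[1]
  if (window < h - 1e-9) stop("window smaller than the grid spacing")
  wsteps <- window / h
  if (abs(wsteps - round(wsteps)) > 1e-6)
    stop("grid spacing must divide the window")
  wsteps <- round(wsteps)
  if (is.null(readout_total) || readout_total <= 0)
    stop("readout total must be > 0")
  y <- curve$readout / readout_total
  i <- seq_len(length(g) - wsteps)
  slopes <- (y[i + wsteps] - y[i]) / (g[i + wsteps] - g[i])
  ms <- max(slopes)
  list(flag = ms >= threshold, max_slope = ms)
}

#' Classify coexistent dynamics (CD)
#'
#' Probes multistability along the dose axis: at each dose the dose node's
#' total is fixed and [find_attractors()] is run; the flag is set when at
#' least one dose supports two or more distinct stable states (e.g. an
#' apoptotic low-pRIP3/high-C8 state coexisting with a necroptotic
#' high-pRIP3 state).
#'
#' @param circ a `circuit`.
#' @param dose_node node whose total is scanned.
#' @param dose_grid doses to probe.
#' @param n_starts random starts per dose (`>= 10`).
#' @param seed integer seed (per-dose substreams are derived from it).
#' @param cluster_tol clustering radius in max-norm.
#' @param t_max,tol integration settings as in [steady_state()].
#' @param early_stop stop scanning doses once coexistence is found (the
#'   reported interval is then truncated at that dose); used by the
#'   screening module where only the flag matters.
#' @return list with `flag`, `interval` (doses with >= 2 attractors), and
#'   `n_attractors` per dose (`NA` where no start converged or, with
#'   `early_stop`, where scanning ended).
#' @export
classify_coexistent <- function(circ, dose_node, dose_grid, n_starts = 20,
                                seed = NULL, cluster_tol = 1e-3,
                                t_max = 500, tol = 1e-6,
                                early_stop = FALSE) {
  if (n_starts < 10) stop("n_starts must be >= 10")
  di <- node_index(circ, dose_node)
  counts <- with_seed(seed,
    cpp_attractor_counts(encode_circuit(circ), di, as.numeric(dose_grid),
                         as.integer(n_starts), t_max, tol, cluster_tol,
                         early_stop))
  multi <- !is.na(counts) & counts >= 2
  list(flag = any(multi), interval = dose_grid[multi],
       n_attractors = as.integer(counts))
}

#' Classify the regulation type of an H curve
#'
#' Over an expression scan, H may fall monotonically (negative regulation),
#' rise monotonically (positive regulation), or change nonlinearly
#' (bell-shaped regulation). Steps with `|delta H| <= tol` count as flat so
#' numerical jitter at screening tolerances does not flip the class.
#'
#' @param H_values H along increasing expression levels (`>= 4` points).
#' @param tol flatness tolerance (default 0.005).
#' @return one of `"negative"`, `"positive"`, `"bell"`.
#' @export
classify_regulation <- function(H_values, tol = 0.005) {
  if (length(H_values) < 4) stop("need at least 4 scan points")
  dh <- diff(H_values)
  up <- dh > tol
  down <- dh < -tol
  if (!any(up)) return("negative")  # includes the all-flat case
  if (!any(down)) return("positive")
  "bell"
}

fpl_fun <- function(x, A, B, xmid, scal) A + (B - A) / (1 + exp((xmid - x) / scal))

fit_fpl_one <- function(x, y) {
  if (length(x) < 4 || sd(y) < 1e-10) {
    return(list(A = mean(y), B = mean(y), xmid = mean(x), scal = 1,
                degenerate = TRUE, residuals = y - mean(y)))
  }
  incr <- unname(coef(stats::lm(y ~ x))[2]) >= 0
  A0 <- if (incr) min(y) else max(y)
  B0 <- if (incr) max(y) else min(y)
  start <- list(A = A0, B = B0, xmid = mean(range(x)),
                scal = diff(range(x)) / 4 * if (incr) 1 else -1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fpl_fun(x, A, B, xmid, scal), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(A = A0, B = B0, xmid = mean(range(x)), scal = start$scal,
                degenerate = TRUE, residuals = rep(NA_real_, length(y))))
  cf <- as.list(coef(fit))
  c(cf, list(degenerate = FALSE, residuals = as.numeric(residuals(fit))))
}

#' Piecewise four-parameter-logistic fit of H versus expression level
#'
#' Fits a four-parameter logistic (4PL)
#' `H(x) = A + (B - A) / (1 + exp((xmid - x)/scal))` separately below and
#' above `breakpoint` (default 10% expression, where the reference model's H
#' attains its minimum). For the increasing upper branch the fitted `B` is
#' the upper asymptote -- the ceiling H cannot exceed -- and `xmid` is the
#' location of the maximal increase rate.
#'
#' @param levels expression levels (fractions of wild type).
#' @param H_values H at each level.
#' @param breakpoint split point inside the level range.
#' @return list with `lower`, `upper` (4PL parameter lists, `degenerate` flag
#'   and residuals), `upper_asymptote`, `max_slope_location` (both from the
#'   upper branch), and `lower_max_decline_location`.
#' @export
fit_fpl_piecewise <- function(levels, H_values, breakpoint = 0.1) {
  if (breakpoint <= min(levels) || breakpoint >= max(levels))
    stop("breakpoint must lie inside the level range")
  lo <- levels <= breakpoint
  lower <- fit_fpl_one(levels[lo], H_values[lo])
  upper <- fit_fpl_one(levels[!lo], H_values[!lo])
  up_asym <- max(upper$A, upper$B)
  list(lower = lower, upper = upper,
       upper_asymptote = up_asym,
       max_slope_location = upper$xmid,
       lower_max_decline_location = lower$xmid)
}
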