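#' Latin hypercube sampling ranges for circuit parameters
#'
#' Default ranges follow common practice for coarse-grained circuit
#' screening: maximal rates `k` in 0.1--10 and half-saturations `j` in
#' 0.001--100 (both log-uniform), deactivation rates `d` in 0.01--1
#' (log-uniform), integer Hill coefficients `n` in 1--4, and stimulation `s`
#' uniform in 0--1.
#'
#' @param k,j,d two-element ranges (log-uniform strata).
#' @param n two-element integer range (uniform strata).
#' @param s two-element range (uniform strata).
#' @param n_samples number of parameter sets.
#' @param seed optional integer seed.
#' @return a `sampling_ranges` list.
#' @export
sampling_ranges <- function(k = c(0.1, 10), j = c(0.001, 100),
                            d = c(0.01, 1), n = c(1L, 4L), s = c(0, 1),
                            n_samples = 50000, seed = NULL) {
  stopifnot(k[1] > 0, j[1] > 0, d[1] > 0, n[1] >= 1, n_samples >= 1)
  structure(list(k = k, j = j, d = d, n = as.integer(n), s = s,
                 n_samples = as.integer(n_samples), seed = seed),
            class = "sampling_ranges")
}

#' Latin hypercube sample of a circuit's parameter space
#'
#' Draws one stratified sample per equal-probability stratum and dimension:
#' per edge a `(k, j, n)` triple, per node a deactivation rate `d`, and one
#' stimulation level `s`. Log-scaled dimensions are stratified in log space;
#' the integer Hill dimension maps strata to `{1, ..., 4}` with equal
#' frequency. Reproducible given `ranges$seed`.
#'
#' @param circ a `circuit` (provides edge and node counts and names).
#' @param ranges a [sampling_ranges()] object.
#' @return data frame with `3E + N + 1` columns named `k.<i>`, `j.<i>`,
#'   `n.<i>` per edge index, `d.<node>`, and `s`.
#' @export
lhs_sample <- function(circ, ranges) {
  E <- nrow(circ$edges); N <- nrow(circ$nodes)
  ns <- ranges$n_samples
  dims <- 3 * E + N + 1
  u <- with_seed(ranges$seed, lhs::randomLHS(ns, dims))
  logmap <- function(uu, rg) exp(log(rg[1]) + uu * (log(rg[2]) - log(rg[1])))
  out <- matrix(NA_real_, ns, dims)
  for (e in seq_len(E)) {
    out[, e] <- logmap(u[, e], ranges$k)
    out[, E + e] <- logmap(u[, E + e], ranges$j)
    nlev <- ranges$n[1]:ranges$n[2]
    out[, 2 * E + e] <- nlev[pmin(length(nlev),
                                  floor(u[, 2 * E + e] * length(nlev)) + 1)]
  }
  for (i in seq_len(N))
    out[, 3 * E + i] <- logmap(u[, 3 * E + i], ranges$d)
  out[, dims] <- ranges$s[1] + u[, dims] * (ranges$s[2] - ranges$s[1])
  out <- as.data.frame(out)
  names(out) <- c(paste0("k.", seq_len(E)), paste0("j.", seq_len(E)),
                  paste0("n.", seq_len(E)), paste0("d.", circ$nodes$name), "s")
  out
}

# Run the compiled BD/ED batch screen for a sample table on a fixed topology.
screen_be_batch <- function(circ, samples, dose_node, readout_node,
                            dose_grid, window = 0.1, t_max = 500,
                            tol = 1e-6) {
  di <- node_index(circ, dose_node)
  ri <- node_index(circ, readout_node)
  h <- dose_grid[2] - dose_grid[1]
  wsteps <- round(window / h)
  if (abs(window / h - wsteps) > 1e-6)
    stop("dose grid spacing must divide the emergence window")
  e <- circ$edges
  res <- cpp_screen_be(nrow(circ$nodes),
                       as.integer(ifelse(e$source == ".stim", 0L,
                                         match(e$source, circ$nodes$name))),
                       as.integer(match(e$target, circ$nodes$name)),
                       as.integer(e$sign),
                       as.numeric(circ$nodes$total),
                       as.numeric(circ$nodes$basal),
                       as.matrix(samples), di, ri,
                       as.numeric(dose_grid),
                       circ$nodes$total[ri], as.integer(wsteps),
                       t_max, tol,
                       identical(circ$denominator, "jn"))
  as.data.frame(res)
}

circuit_with_params <- function(circ, row) {
  E <- nrow(circ$edges)
  circ$edges$k <- as.numeric(row[seq_len(E)])
  circ$edges$j <- as.numeric(row[E + seq_len(E)])
  circ$edges$n <- as.integer(round(as.numeric(row[2 * E + seq_len(E)])))
  circ$nodes$d <- as.numeric(row[3 * E + seq_len(nrow(circ$nodes))])
  circ$s <- as.numeric(row[3 * E + nrow(circ$nodes) + 1])
  circ
}

#' Random-parameter screen of a fixed circuit topology
#'
#' Draws a Latin hypercube sample, evaluates each parameter set's
#' steady-state dose response, and classifies biphasic (BD, relative
#' peak-to-end drop >= 1%), emergent (ED, window slope >= 5), and -- for
#' parameter sets passing both ("BE") -- coexistent (CD, multistability at
#' some dose) dynamics. CD is evaluated only where BE holds since the
#' composite "BEC" class is the conjunction BD & ED & CD; this makes
#' `P(BEC) <= P(BE)` exact by construction.
#'
#' @param circ a `circuit` (topology and base totals; sampled parameters
#'   overwrite edge and node rates).
#' @param ranges a [sampling_ranges()] object.
#' @param dose_node,readout_node dose and readout nodes (default: circuit
#'   input/output).
#' @param dose_grid equally spaced dose grid (default 21 points).
#' @param criteria subset of `c("BD", "ED", "CD")` to evaluate.
#' @param bd_threshold,ed_threshold,ed_window classifier settings.
#' @param cd_n_starts multistart count per dose for the CD probe.
#' @param cd_seed seed for the CD probes.
#' @param t_max,tol integration settings.
#' @return a `screen_result`: list with `samples` (per-set flags/values),
#'   `summary` (probabilities with binomial standard errors), and the
#'   configuration.
#' @export
screen_topology <- function(circ, ranges, dose_node = circ$input,
                            readout_node = circ$output,
                            dose_grid = seq(0, 1, length.out = 21),
                            criteria = c("BD", "ED", "CD"),
                            bd_threshold = 0.01, ed_threshold = 5,
                            ed_window = 0.1, cd_n_starts = 20,
                            cd_seed = 1, t_max = 500, tol = 1e-6) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  samples <- lhs_sample(circ, ranges)
  res <- screen_be_batch(circ, samples, dose_node, readout_node, dose_grid,
                         window = ed_window, t_max = t_max, tol = tol)
  res$BD <- res$bd >= bd_threshold & res$peak > 0
  res$ED <- res$ed >= ed_threshold
  res$BE <- res$BD & res$ED
  res$CD <- NA
  if ("CD" %in% criteria && any(res$BE)) {
    idx <- which(res$BE)
    for (ii in seq_along(idx)) {
      ci <- circuit_with_params(circ, as.numeric(samples[idx[ii], ]))
      cd <- classify_coexistent(ci, dose_node, dose_grid,
                                n_starts = cd_n_starts,
                                seed = cd_seed + idx[ii], t_max = t_max,
                                tol = tol, early_stop = TRUE)
      res$CD[idx[ii]] <- cd$flag
    }
  }
  res$BEC <- res$BE & !is.na(res$CD) & res$CD
  ok <- res$nonconv == 0
  p <- function(flag) mean(flag[ok])
  se <- function(flag) sqrt(p(flag) * (1 - p(flag)) / sum(ok))
  summary <- data.frame(
    quantity = c("P_BD", "P_ED", "P_BE", "P_BEC", "P_CD_given_BE"),
    value = c(p(res$BD), p(res$ED), p(res$BE), p(res$BEC),
              if (any(res$BE[ok])) mean(res$CD[res$BE & ok], na.rm = TRUE)
              else NA_real_),
    se = c(se(res$BD), se(res$ED), se(res$BE), se(res$BEC),
           if (any(res$BE[ok]))
             sqrt(mean(res$CD[res$BE & ok], na.rm = TRUE) *
                  (1 - mean(res$CD[res$BE & ok], na.rm = TRUE)) /
                  sum(res$BE & ok))
           else NA_real_))
  structure(list(samples = cbind(samples, res), summary = summary,
                 n_evaluated = sum(ok), n_nonconverged = sum(!ok),
                 dose_grid = dose_grid, criteria = criteria,
                 dose_node = dose_node, readout_node = readout_node,
                 ranges = ranges),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> ", nrow(x$samples), " parameter sets (",
      x$n_nonconverged, " with nonconverged doses)\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Term-removal probabilities under random parameters
#'
#' Re-screens the same Latin hypercube sample with one labeled term's maximal
#' rate forced to zero, one term at a time, reporting the probability of
#' biphasic-emergent (BE) dynamics per removal. In the death circuit only
#' removal of an incoherent-feedforward term (`k5`, `k7`, `k9`) drives the
#' probability to zero.
#'
#' @param model a `death_circuit`.
#' @param ranges a [sampling_ranges()] object.
#' @param terms term labels to remove (default all nine).
#' @param dose_grid dose grid for the RIP1 scan.
#' @param bd_threshold,ed_threshold,ed_window,t_max,tol classifier and
#'   integration settings as in [screen_topology()].
#' @return data frame with `term`, `P_BE`, `se`, plus the intact-circuit row
#'   (`term = "none"`).
#' @export
term_removal_probabilities <- function(model, ranges,
                                       terms = names(model$label_map),
                                       dose_grid = seq(0, 1, length.out = 21),
                                       bd_threshold = 0.01, ed_threshold = 5,
                                       ed_window = 0.1, t_max = 500,
                                       tol = 1e-6) {
  circ <- model$circuit
  samples <- lhs_sample(circ, ranges)
  eval_one <- function(label, smp) {
    res <- screen_be_batch(circ, smp, "RIP1", "RIP3", dose_grid,
                           window = ed_window, t_max = t_max, tol = tol)
    ok <- res$nonconv == 0
    be <- res$bd >= bd_threshold & res$peak > 0 & res$ed >= ed_threshold
    pb <- mean(be[ok])
    data.frame(term = label, P_BE = pb,
               se = sqrt(pb * (1 - pb) / sum(ok)))
  }
  out <- eval_one("none", samples)
  edge_key <- paste(circ$edges$source, circ$edges$target)
  for (tm in terms) {
    e <- model$label_map[[tm]]
    ei <- match(paste(e[1], e[2]), edge_key)
    smp <- samples
    smp[[paste0("k.", ei)]] <- 0
    out <- rbind(out, eval_one(tm, smp))
  }
  out
}

#' Regulation-type census over BEC-passing parameter sets
#'
#' For every parameter set that achieved BEC dynamics in `screen`, recomputes
#' H at a series of readout-protein expression levels and classifies the
#' regulation of H as negative, positive, or bell-shaped via
#' [classify_regulation()].
#'
#' @param screen a [screen_topology()] result with CD evaluated.
#' @param circ the screened `circuit`.
#' @param scan_node node whose expression is scanned (e.g. `"RIP3"`).
#' @param levels expression levels (>= 4).
#' @param dose_node,readout_node,dose_grid,t_max,tol as in the screen.
#' @param tol_flat flatness tolerance for [classify_regulation()].
#' @return list with `proportions` (named, summing to 1 over
#'   negative/positive/bell), `classes` per sample, and `H` (matrix sample x
#'   level).
#' @export
regulation_type_census <- function(screen, circ, scan_node = "RIP3",
                                   levels = c(0.2, 0.4, 0.6, 0.8, 1),
                                   dose_node = screen$dose_node,
                                   readout_node = screen$readout_node,
                                   dose_grid = screen$dose_grid,
                                   t_max = 500, tol = 1e-6,
                                   tol_flat = 0.005) {
  idx <- which(screen$samples$BEC %in% TRUE)
  if (!length(idx)) stop("no BEC-passing samples in the screen")
  E <- nrow(circ$edges); N <- nrow(circ$nodes)
  cols <- seq_len(3 * E + N + 1)
  smp <- as.matrix(screen$samples[idx, cols])
  ri <- node_index(circ, readout_node)
  H <- matrix(NA_real_, length(idx), length(levels))
  for (li in seq_along(levels)) {
    ci <- set_total(circ, scan_node, levels[li])
    res <- screen_be_batch(ci, smp, dose_node, readout_node, dose_grid,
                           t_max = t_max, tol = tol)
    H[, li] <- (res$peak - res$end) / ci$nodes$total[ri]
  }
  classes <- apply(H, 1, classify_regulation, tol = tol_flat)
  prop <- prop.table(table(factor(classes,
                                  levels = c("negative", "positive", "bell"))))
  list(proportions = c(prop), classes = classes, H = H, levels = levels)
}
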